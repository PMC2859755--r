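#' Define a finite sequence alphabet
#'
#' An alphabet is an ordered set of `S >= 2` distinct single characters mapped
#' bijectively to the integer codes `1..S`.  Models and datasets store
#' sequences as integer codes; the alphabet is kept alongside for decoding.
#'
#' @param symbols Character vector of distinct single characters.
#' @return An object of class `seq_alphabet` with elements `symbols` and `S`.
#' @examples
#' dna_alphabet()
#' make_alphabet(c("0", "1"))
#' @export
make_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) stop("an alphabet needs at least 2 symbols")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  structure(list(symbols = symbols, S = length(symbols)), class = "seq_alphabet")
}

#' @describeIn make_alphabet The DNA alphabet A, C, G, T (codes 1..4).
#' @export
dna_alphabet <- function() make_alphabet(c("A", "C", "G", "T"))

#' @export
print.seq_alphabet <- function(x, ...) {
  cat("<seq_alphabet> S =", x$S, ":", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

#' Encode character sequences as integer codes
#'
#' @param strings Character vector of sequences (case-insensitive for DNA-style
#'   upper-case alphabets).
#' @param alphabet A [make_alphabet()] object.
#' @return List of integer vectors, one per input string.
#' @export
encode_sequences <- function(strings, alphabet) {
  lookup <- seq_len(alphabet$S)
  names(lookup) <- alphabet$symbols
  lapply(seq_along(strings), function(j) {
    chars <- strsplit(toupper(strings[[j]]), "", fixed = TRUE)[[1]]
    codes <- unname(lookup[chars])
    if (anyNA(codes)) {
      off <- which(is.na(codes))[1]
      stop(sprintf("record %d contains non-alphabet character '%s' at offset %d",
                   j, chars[off], off))
    }
    as.integer(codes)
  })
}

#' Decode integer-coded sequences back to strings
#'
#' @param x Integer matrix (one row per sequence) or list of integer vectors.
#' @param alphabet A [make_alphabet()] object.
#' @return Character vector.
#' @export
decode_sequences <- function(x, alphabet) {
  if (is.matrix(x)) x <- asplit(x, 1)
  vapply(x, function(s) paste(alphabet$symbols[s], collapse = ""), character(1))
}
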