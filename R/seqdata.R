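#' Labeled fixed-length sequence dataset
#'
#' Sequences are stored integer-encoded in an `N x L` matrix together with a
#' class label in `1..C` per sequence.  All sequences share the same length
#' `L`; this is the unit of data consumed by every model in the package.
#'
#' @param x Integer matrix (`N x L`), list of equal-length integer vectors, or
#'   character vector of equal-length strings.
#' @param labels Integer class labels, length `N` (recycled if length 1).
#' @param alphabet A [make_alphabet()] object.
#' @param C Number of classes; defaults to `max(labels)`.
#' @return Object of class `labeled_dataset` with elements `x`, `labels`,
#'   `alphabet`, `L`, `C`.
#' @export
labeled_dataset <- function(x, labels, alphabet = dna_alphabet(), C = NULL) {
  if (is.character(x)) x <- encode_sequences(x, alphabet)
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(x) && length(unique(lens)) != 1L)
      stop("sequences have differing lengths: ", paste(sort(unique(lens)), collapse = ", "))
    x <- if (length(x)) do.call(rbind, x) else matrix(integer(), 0L, 0L)
  }
  storage.mode(x) <- "integer"
  n <- nrow(x)
  labels <- as.integer(rep_len(labels, n))
  if (n > 0L) {
    if (any(x < 1L | x > alphabet$S)) stop("symbol codes outside [1, S]")
    if (any(labels < 1L)) stop("labels must be positive integers")
  }
  C <- as.integer(C %||% max(labels, 1L))
  if (n > 0L && any(labels > C)) stop("labels exceed C")
  structure(list(x = x, labels = labels, alphabet = alphabet,
                 L = ncol(x), C = C),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> N = %d, L = %d, C = %d; class sizes: %s\n",
              nrow(x$x), x$L, x$C,
              paste(tabulate(x$labels, x$C), collapse = ", ")))
  invisible(x)
}

#' Number of sequences in a dataset
#' @param dataset A [labeled_dataset()].
#' @export
n_sequences <- function(dataset) nrow(dataset$x)

#' Concatenate labeled datasets
#'
#' @param ... [labeled_dataset()] objects over the same alphabet and length.
#' @param C Class count of the result (default: max over inputs).
#' @export
combine_datasets <- function(..., C = NULL) {
  ds <- list(...)
  L <- unique(vapply(ds, function(d) d$L, integer(1)))
  if (length(L) != 1L) stop("datasets have differing sequence lengths")
  labeled_dataset(do.call(rbind, lapply(ds, function(d) d$x)),
                  unlist(lapply(ds, function(d) d$labels)),
                  ds[[1]]$alphabet,
                  C = C %||% max(vapply(ds, function(d) d$C, integer(1))))
}

#' Read one class of sequences from a FASTA file
#'
#' All records receive the same class label.  Lower-case characters are
#' upper-cased; any character outside the alphabet (e.g. IUPAC ambiguity
#' codes) is rejected with the record and offset named.  By default all
#' records must share one length; set `fixed_length = FALSE` to obtain a
#' variable-length sequence list (e.g. as input to [chunk_sequences()]).
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param alphabet A [make_alphabet()] object.
#' @param label Class index assigned to every record.
#' @param fixed_length Enforce equal record lengths and return a
#'   [labeled_dataset()]; otherwise return a list of integer vectors with
#'   attributes `label` and `alphabet`.
#' @return A [labeled_dataset()], or a list when `fixed_length = FALSE`.
#' @export
read_fasta <- function(path, alphabet = dna_alphabet(), label = 1L,
                       fixed_length = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  strings <- as.character(recs)
  if (length(strings) == 0L) warning("empty FASTA file: ", path)
  seqs <- tryCatch(encode_sequences(strings, alphabet), error = function(e) {
    stop(sprintf("%s (file %s, record name '%s')", conditionMessage(e), path,
                 names(strings)[as.integer(sub("^record (\\d+).*", "\\1",
                                               conditionMessage(e)))] %||% "?"),
         call. = FALSE)
  })
  if (!fixed_length) {
    attr(seqs, "label") <- as.integer(label)
    attr(seqs, "alphabet") <- alphabet
    return(seqs)
  }
  lens <- lengths(seqs)
  if (length(seqs) && length(unique(lens)) != 1L)
    stop("records have differing lengths (", paste(sort(unique(lens)), collapse = ", "),
         "); use fixed_length = FALSE for variable-length input")
  labeled_dataset(seqs, rep(as.integer(label), length(seqs)), alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param dataset A [labeled_dataset()] or list of integer vectors.
#' @param path Output file.
#' @param alphabet Alphabet for decoding (taken from the dataset if present).
#' @export
write_fasta <- function(dataset, path, alphabet = NULL) {
  if (inherits(dataset, "labeled_dataset")) {
    alphabet <- dataset$alphabet
    strings <- decode_sequences(dataset$x, alphabet)
  } else {
    alphabet <- alphabet %||% attr(dataset, "alphabet") %||% dna_alphabet()
    strings <- decode_sequences(dataset, alphabet)
  }
  names(strings) <- sprintf("seq_%d", seq_along(strings))
  Biostrings::writeXStringSet(Biostrings::BStringSet(strings), path)
  invisible(path)
}

#' Cut variable-length sequences into fixed-length windows
#'
#' Each input sequence is split into consecutive non-overlapping windows of
#' length `k`; a trailing remainder shorter than `k` is discarded.  This
#' mirrors the usual preprocessing of long background sequences (e.g. exons
#' cut into 100-mers) into units comparable with fixed-length signal sites.
#'
#' @param sequences List of integer vectors (e.g. from
#'   `read_fasta(fixed_length = FALSE)`) or a [labeled_dataset()].
#' @param k Window length (`k >= 1`).
#' @param label Class label for the output; defaults to the input's label.
#' @param alphabet Alphabet (taken from the input if available).
#' @return A [labeled_dataset()] with `L = k`.
#' @export
chunk_sequences <- function(sequences, k, label = NULL, alphabet = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (inherits(sequences, "labeled_dataset")) {
    label <- label %||% sequences$labels[1] %||% 1L
    alphabet <- sequences$alphabet
    sequences <- asplit(sequences$x, 1)
  } else {
    label <- label %||% attr(sequences, "label") %||% 1L
    alphabet <- alphabet %||% attr(sequences, "alphabet") %||% dna_alphabet()
  }
  windows <- list()
  for (s in sequences) {
    nw <- length(s) %/% k
    if (nw >= 1L)
      windows <- c(windows, lapply(seq_len(nw), function(j) s[((j - 1L) * k + 1L):(j * k)]))
  }
  if (length(windows) == 0L) warning("all input sequences shorter than k; empty dataset")
  labeled_dataset(windows, rep(as.integer(label), length(windows)), alphabet)
}

#' Stratified holdout split with training-set subsampling
#'
#' Per class independently, a fraction `holdout_fraction` of the sequences
#' (rounded half-up) is held out as the test set; the remainder forms a
#' preliminary training pool from which a uniformly random subset of size
#' `max(1, round(train_fraction * pool))` is drawn as the final training set.
#' The subsampling step is what lets an experiment vary the effective training
#' set size while scoring the same held-out test sequences.
#'
#' @param fg,bg [labeled_dataset()]s for the foreground (label 1) and
#'   background (label 2) class.
#' @param holdout_fraction Fraction held out for testing, in (0, 1).
#' @param train_fraction Fraction of the preliminary pool used for training,
#'   in (0, 1].
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with [labeled_dataset()]s `train` and `test` (labels 1 = fg,
#'   2 = bg), plus `train_idx`/`test_idx` bookkeeping.
#' @export
stratified_holdout_split <- function(fg, bg, holdout_fraction = 0.1,
                                     train_fraction = 1.0, seed = 1L) {
  if (!(holdout_fraction > 0 && holdout_fraction < 1))
    stop("holdout_fraction must be in (0, 1)")
  if (!(train_fraction > 0 && train_fraction <= 1))
    stop("train_fraction must be in (0, 1]")
  if (fg$L != bg$L) stop("fg and bg must share sequence length")
  classes <- list(fg = fg, bg = bg)
  withr::with_seed(seed, {
    parts <- lapply(seq_along(classes), function(ci) {
      d <- classes[[ci]]
      n <- n_sequences(d)
      if (n < 2L) stop("class ", ci, " has fewer than 2 sequences; cannot stratify")
      n_test <- min(max(round_half_up(holdout_fraction * n), 1L), n - 1L)
      test_idx <- sort(sample.int(n, n_test))
      pool <- setdiff(seq_len(n), test_idx)
      n_train <- max(1L, round_half_up(train_fraction * length(pool)))
      train_idx <- if (n_train == length(pool)) pool else sort(sample(pool, n_train))
      list(train = train_idx, test = test_idx)
    })
  })
  take <- function(which) {
    labeled_dataset(
      rbind(classes$fg$x[parts[[1]][[which]], , drop = FALSE],
            classes$bg$x[parts[[2]][[which]], , drop = FALSE]),
      c(rep(1L, length(parts[[1]][[which]])), rep(2L, length(parts[[2]][[which]]))),
      fg$alphabet, C = 2L)
  }
  list(train = take("train"), test = take("test"),
       train_idx = list(fg = parts[[1]]$train, bg = parts[[2]]$train),
       test_idx = list(fg = parts[[1]]$test, bg = parts[[2]]$test))
}

#' Serialize a dataset to a two-column text table
#'
#' Plain-text fixture format: one row per sequence, columns `sequence` and
#' `class`, tab-separated.
#' @param dataset A [labeled_dataset()].
#' @param path Output file; `read_dataset_table()` reads it back.
#' @export
write_dataset_table <- function(dataset, path) {
  utils::write.table(
    data.frame(sequence = decode_sequences(dataset$x, dataset$alphabet),
               class = dataset$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_table
#' @param alphabet Alphabet used for decoding.
#' @export
read_dataset_table <- function(path, alphabet = dna_alphabet()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  labeled_dataset(tab$sequence, tab$class, alphabet)
}

#' Sufficient statistics of a dataset under a classifier structure
#'
#' Tallies the class counts `N_c` and, for every log-linear feature, the
#' number of training sequences of that class activating it:
#' `n_{c,i} = sum_n I(c_n = c) f_{c,i}(x_n)`.  For moral-BN structures this is
#' the familiar table of symbol counts per position and parent realization;
#' generative training reduces to smoothing these relative frequencies.
#'
#' @param dataset A [labeled_dataset()].
#' @param structures A [model_structure] or list of per-class structures.
#' @param C Number of classes (defaults to the dataset's).
#' @return Object of class `count_table`: `N_c` (per-class counts), `n` (flat
#'   count vector aligned with the model's parameter layout, class entries
#'   first), and `N`.
#' @export
count_statistics <- function(dataset, structures, C = dataset$C) {
  index <- build_feature_index(structures, C)
  if (n_sequences(dataset) > 0L && dataset$L != index$structures[[1]]$L)
    stop("dataset length L does not match structure")
  n <- numeric(index$Q)
  Nc <- tabulate(dataset$labels, C)
  n[seq_len(C)] <- Nc
  for (c in seq_len(C)) {
    rows <- dataset$labels == c
    if (!any(rows)) next
    rel <- activated_features(index$structures[[c]],
                              dataset$x[rows, , drop = FALSE])
    n[index$offset[c] + seq_len(index$P[c])] <-
      accumulate_weights(rel, rep(1, sum(rows)), index$P[c])
  }
  structure(list(N_c = Nc, n = n, N = sum(Nc), index = index),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> N = %d (%s)\n", x$N, paste(x$N_c, collapse = ", ")))
  invisible(x)
}
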