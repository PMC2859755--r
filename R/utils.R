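# Internal numerical helpers.  All probability arithmetic in the package is
# done in the log domain; these are the only places where exp() of potentially
# large magnitudes appears, always shifted by the maximum.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

# round-half-up; R's round() uses banker's rounding which would make holdout
# sizes depend on parity
round_half_up <- function(x) floor(x + 0.5)

# sum weights w into P bins addressed by the integer matrix idx (one column
# per feature group, entries in 1..P)
accumulate_weights <- function(idx, w, P) {
  v <- rowsum(rep(w, ncol(idx)), as.vector(idx))
  out <- numeric(P)
  out[as.integer(rownames(v))] <- v[, 1L]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
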