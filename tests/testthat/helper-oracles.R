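# Independent brute-force oracles used across the suite.  They deliberately
# avoid the package's feature-index machinery: likelihoods are evaluated by
# explicit loops over positions and parents, normalization constants by
# explicit enumeration of all S^L sequences.

oracle_all_sequences <- function(L, S) {
  if (L == 0) return(matrix(integer(), 1, 0))
  rec <- oracle_all_sequences(L - 1, S)
  do.call(rbind, lapply(seq_len(S), function(b) cbind(rec, b)))
}

# unnormalized log score of one sequence under one class, by explicit loops
oracle_log_score <- function(model, x, cl) {
  st <- model$index$structures[[cl]]
  off <- model$index$offset[cl]
  S <- st$S
  val <- model$lambda[cl]
  if (st$kind == "moral_bn") {
    pos_off <- st$layout$pos_offset
    for (l in seq_len(st$L)) {
      pa <- st$parents[[l]]
      a <- 1
      if (length(pa) > 0)
        for (j in seq_along(pa)) a <- a + (x[pa[j]] - 1) * S^(j - 1)
      val <- val + model$lambda[off + pos_off[l] + (a - 1) * S + x[l]]
    }
  } else {
    for (p in seq_len(nrow(st$pairs))) {
      b1 <- x[st$pairs[p, 1]]; b2 <- x[st$pairs[p, 2]]
      val <- val + model$lambda[off + (p - 1) * S^2 + (b2 - 1) * S + b1]
    }
  }
  val
}

oracle_log_partition <- function(model) {
  st <- model$index$structures[[1]]
  X <- oracle_all_sequences(st$L, st$S)
  vals <- unlist(lapply(seq_len(model$C), function(cl)
    apply(X, 1, function(x) oracle_log_score(model, x, cl))))
  m <- max(vals)
  m + log(sum(exp(vals - m)))
}

# direct evaluation of the moral-BN likelihood in the probability
# parameterization (class probability times the chain of CPDs)
oracle_theta_log_joint <- function(theta, x, cl) {
  st <- theta$index$structures[[cl]]
  p <- log(theta$class_probs[cl])
  for (l in seq_len(st$L)) {
    pa <- st$parents[[l]]
    a <- 1
    if (length(pa) > 0)
      for (j in seq_along(pa)) a <- a + (x[pa[j]] - 1) * st$S^(j - 1)
    p <- p + log(theta$cpds[[cl]][[l]][x[l], a])
  }
  p
}

# random anchored model on given structures
random_model <- function(structures, C, sd = 0.7, seed = NULL) {
  idx <- seqmrf:::build_feature_index(structures, C)
  draw <- function() {
    lam <- numeric(idx$Q)
    lam[idx$free] <- stats::rnorm(length(idx$free), 0, sd)
    mrf_model(structures, C, lam)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# O(n^2) Mann-Whitney statistic with ties counted one half
oracle_auc_roc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 2]
  mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
}

# dense achievable-point interpolation of the PR curve (step in TP units)
oracle_auc_pr <- function(scores, labels, step = 1e-4) {
  pos <- labels == 1
  ord <- order(scores, decreasing = TRUE)
  p <- pos[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  last <- which(diff(c(grp, Inf)) != 0)
  TP <- c(0, cumsum(p)[last]); FP <- c(0, cumsum(!p)[last]); P <- sum(pos)
  area <- 0
  for (j in seq_len(length(TP) - 1)) {
    ta <- TP[j]; tb <- TP[j + 1]
    if (tb == ta) next
    ts <- seq(ta, tb, by = step)
    fp <- FP[j] + (FP[j + 1] - FP[j]) * (ts - ta) / (tb - ta)
    pr <- ts / (ts + fp)
    if (ta == 0) pr[1] <- if (FP[j] > 0) 0 else tb / (tb + FP[j + 1] - FP[j])
    r <- ts / P
    area <- area + sum(diff(r) * (pr[-1] + pr[-length(pr)]) / 2)
  }
  area
}

# exhaustive threshold scan for the fixed-sensitivity operating point
oracle_threshold_scan <- function(scores, labels, sn_target) {
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    if (sum(pred & labels == 1) / sum(labels == 1) >= sn_target)
      return(c(fpr = sum(pred & labels == 2) / sum(labels == 2),
               ppv = sum(pred & labels == 1) / sum(pred)))
  }
  c(fpr = NA_real_, ppv = NA_real_)
}

write_temp_fasta <- function(records, width = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (i in seq_along(records)) {
    lines <- c(lines, paste0(">rec", i))
    s <- records[i]
    if (is.null(width)) lines <- c(lines, s)
    else lines <- c(lines, substring(s, seq(1, nchar(s), width),
                                     pmin(seq(1, nchar(s), width) + width - 1,
                                          nchar(s))))
  }
  writeLines(lines, path)
  path
}
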