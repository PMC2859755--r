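# Classification performance measures.  Scores are log posterior odds of the
# foreground class (class 1 = positive); any strictly monotone transform
# leaves every measure unchanged.

# achievable (TP, FP) points at decreasing score thresholds, ties grouped
confusion_path <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == 1L
  if (!any(pos) || all(pos))
    stop("curve metrics need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # indices of the last element of each tie group, in descending-score order
  grp <- cumsum(!duplicated(s))
  last <- which(diff(c(grp, Inf)) != 0)
  TP <- cumsum(p)[last]
  FP <- cumsum(!p)[last]
  list(TP = TP, FP = FP, P = sum(pos), N = sum(!pos),
       thresholds = s[!duplicated(s)])
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over all score thresholds, with tied scores
#' grouped into single threshold steps; equal to the Mann-Whitney pairwise
#' statistic with ties counted one half.
#'
#' @param scores Real discrimination score per sequence (higher = more
#'   foreground-like).
#' @param labels True classes (1 = positive/foreground, 2 = negative).
#' @export
auc_roc <- function(scores, labels) {
  cp <- confusion_path(scores, labels)
  tpr <- c(0, cp$TP / cp$P)
  fpr <- c(0, cp$FP / cp$N)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Area under the precision-recall curve
#'
#' Uses the achievable-point interpolation of Davis & Goadrich: between
#' consecutive achievable confusion points, true positives are stepped one at
#' a time with false positives interpolated linearly, which makes precision a
#' smooth hyperbolic function of the true-positive count; each segment is
#' integrated in closed form.  `interpolation = "trapezoid"` instead applies
#' the (optimistic) linear trapezoid directly to the achievable points, for
#' sensitivity analysis.
#'
#' @inheritParams auc_roc
#' @param interpolation `"davis_goadrich"` (default) or `"trapezoid"`.
#' @export
auc_pr <- function(scores, labels, interpolation = c("davis_goadrich", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  cp <- confusion_path(scores, labels)
  TP <- c(0, cp$TP); FP <- c(0, cp$FP); P <- cp$P
  if (interpolation == "trapezoid") {
    keep <- TP > 0
    r <- TP[keep] / P
    p <- TP[keep] / (TP[keep] + FP[keep])
    r <- c(0, r); p <- c(p[1], p)
    return(sum(diff(r) * (p[-1] + p[-length(p)]) / 2))
  }
  area <- 0
  for (j in seq_len(length(TP) - 1L)) {
    ta <- TP[j]; tb <- TP[j + 1L]
    if (tb == ta) next
    s <- (FP[j + 1L] - FP[j]) / (tb - ta)     # FP per TP along the segment
    u <- 1 + s
    v <- FP[j] - s * ta
    # integral of t / (u t + v) dt from ta to tb, divided by P (recall scale)
    seg <- if (abs(v) < 1e-12) (tb - ta) / u
           else (tb - ta) / u - (v / u^2) * log((u * tb + v) / (u * ta + v))
    area <- area + seg / P
  }
  area
}

#' Threshold-fixed performance measures
#'
#' Computes the false positive rate and positive predictive value at the
#' largest threshold attaining sensitivity `>= sn_target` (the most
#' conservative threshold reaching the target), and the sensitivity at the
#' smallest threshold keeping specificity `>= sp_target`.
#'
#' @inheritParams auc_roc
#' @param sn_target Sensitivity target (default 0.95).
#' @param sp_target Specificity target (default 0.999).
#' @return List with `fpr_at_sn`, `ppv_at_sn`, `sn_at_sp` and the two
#'   thresholds used.
#' @export
thresholded_metrics <- function(scores, labels, sn_target = 0.95,
                                sp_target = 0.999) {
  if (sn_target > 1 || sn_target <= 0 || sp_target > 1 || sp_target <= 0)
    stop("targets must lie in (0, 1]")
  cp <- confusion_path(scores, labels)
  sn <- cp$TP / cp$P
  sp <- 1 - cp$FP / cp$N
  i <- which(sn >= sn_target)[1]              # largest threshold reaching Sn
  fpr <- cp$FP[i] / cp$N
  ppv <- cp$TP[i] / (cp$TP[i] + cp$FP[i])
  ok <- sp >= sp_target
  sn_at_sp <- if (any(ok)) max(sn[ok]) else 0
  thr_sp <- if (any(ok)) cp$thresholds[max(which(ok))] else Inf
  list(fpr_at_sn = fpr, ppv_at_sn = ppv, sn_at_sp = sn_at_sp,
       threshold_sn = cp$thresholds[i], threshold_sp = thr_sp)
}

#' Full performance report of a scored test set
#'
#' The measure suite used throughout the case-study protocols: FPR at
#' sensitivity 0.95, sensitivity at specificity 0.999, PPV at sensitivity
#' 0.95, AUC-ROC and AUC-PR.
#'
#' @inheritParams thresholded_metrics
#' @return One-row `data.frame` with columns `fpr_at_sn`, `sn_at_sp`,
#'   `ppv_at_sn`, `auc_roc`, `auc_pr`, `n_pos`, `n_neg`.
#' @export
performance_report <- function(scores, labels, sn_target = 0.95,
                               sp_target = 0.999) {
  tm <- thresholded_metrics(scores, labels, sn_target, sp_target)
  data.frame(fpr_at_sn = tm$fpr_at_sn, sn_at_sp = tm$sn_at_sp,
             ppv_at_sn = tm$ppv_at_sn,
             auc_roc = auc_roc(scores, labels),
             auc_pr = auc_pr(scores, labels),
             n_pos = sum(labels == 1L), n_neg = sum(labels != 1L))
}

#' Classifier specification for comparison experiments
#'
#' @param structures Per-class structures (see [train_classifier()]).
#' @param principle `"MAP"` or `"MSP"`.
#' @param ess Equivalent sample size per class.
#' @param M Mixture components per class.
#' @param tolerance,max_iterations,restarts Optimizer settings forwarded to
#'   [training_config()].
#' @export
classifier_spec <- function(structures, principle = "MAP", ess = 4, M = 1L,
                            tolerance = 1e-4, max_iterations = 500L,
                            restarts = NULL) {
  structure(list(structures = structures, principle = principle, ess = ess,
                 M = M, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 restarts = restarts),
            class = "classifier_spec")
}

#' Repeated stratified-holdout comparison experiment
#'
#' In each repeat, both classes are split into a preliminary training pool
#' and a test set; for each training fraction a random subset of the pool is
#' drawn once and used by all classifiers, which are then scored on the same
#' test set.  Means and standard errors of each performance measure are
#' reported per classifier and fraction.
#'
#' @param fg,bg [labeled_dataset()]s (labels 1 and 2).
#' @param specs Named list of [classifier_spec()]s.
#' @param fractions Training fractions swept (subset of (0, 1]).
#' @param repeats Number of holdout repeats.
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @param holdout_fraction Test fraction per repeat.
#' @return List with `raw` (one row per repeat x fraction x classifier) and
#'   `summary` (long table: classifier, fraction, metric, mean, se).
#' @export
run_holdout_experiment <- function(fg, bg, specs, fractions = 1.0,
                                   repeats = 10L, seed = 1L,
                                   holdout_fraction = 0.1) {
  stopifnot(length(specs) >= 1, !is.null(names(specs)))
  raw <- list()
  for (r in seq_len(repeats)) {
    split <- stratified_holdout_split(fg, bg, holdout_fraction, 1.0,
                                      seed = seed + 7919L * r)
    pool <- split$train
    test <- split$test
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      sub <- subsample_per_class(pool, f, seed = seed + 7919L * r + 31L * fi)
      for (nm in names(specs)) {
        sp <- specs[[nm]]
        cfg <- training_config(sp$principle, ess = sp$ess,
                               tolerance = sp$tolerance,
                               max_iterations = sp$max_iterations,
                               restarts = sp$restarts,
                               seed = seed + 7919L * r + 31L * fi)
        cl <- withCallingHandlers(
          train_classifier(sp$structures, sub, cfg, M = sp$M, C = 2L),
          warning = function(w) {
            if (grepl("convergence tolerance", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
        rep_row <- performance_report(score_sequences(cl, test), test$labels)
        rep_row$classifier <- nm
        rep_row$fraction <- f
        rep_row$repeat_id <- r
        rep_row$converged <- cl$log$converged
        raw[[length(raw) + 1L]] <- rep_row
      }
    }
  }
  raw <- do.call(rbind, raw)
  metrics <- c("fpr_at_sn", "sn_at_sp", "ppv_at_sn", "auc_roc", "auc_pr")
  summ <- do.call(rbind, lapply(split(raw, list(raw$classifier, raw$fraction), drop = TRUE),
    function(g) do.call(rbind, lapply(metrics, function(m)
      data.frame(classifier = g$classifier[1], fraction = g$fraction[1],
                 metric = m, mean = mean(g[[m]]),
                 se = stats::sd(g[[m]]) / sqrt(nrow(g)))))))
  rownames(summ) <- NULL
  list(raw = raw, summary = summ)
}

# draw a per-class uniform subsample of a two-class dataset
subsample_per_class <- function(dataset, fraction, seed) {
  if (fraction >= 1) return(dataset)
  withr::with_seed(seed, {
    keep <- unlist(lapply(seq_len(dataset$C), function(c) {
      idx <- which(dataset$labels == c)
      n <- max(1L, round_half_up(fraction * length(idx)))
      sort(sample(idx, n))
    }))
  })
  labeled_dataset(dataset$x[keep, , drop = FALSE], dataset$labels[keep],
                  dataset$alphabet, C = dataset$C)
}
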