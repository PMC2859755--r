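#' Sequence classifier in natural (log-linear) parameterization
#'
#' An `mrf_model` holds one structure per class and a flat natural-parameter
#' vector `lambda` of length `C + sum_c P_c`: entries `1..C` are the class
#' parameters `lambda_c` (last class anchored to 0), followed by each class's
#' within-class feature block (one entry per feature, the last entry of every
#' simplex-equivalent group anchored to 0).  The joint likelihood is
#' `p(x, c) = exp(lambda_c + sum_i lambda_{c,i} f_{c,i}(x)) / Z(lambda)` with
#' a single normalization constant over all classes and sequences.
#'
#' @param structures A [model_structure] shared by all classes, or a list of
#'   per-class structures (e.g. a PWM foreground and an order-3 Markov
#'   background).
#' @param C Number of classes (default 2: foreground, background).
#' @param lambda Optional parameter vector; anchored entries must be 0
#'   (defaults to the all-zero, i.e. uniform, model).
#' @return Object of class `mrf_model`.
#' @export
mrf_model <- function(structures, C = 2L, lambda = NULL) {
  index <- build_feature_index(structures, C)
  if (is.null(lambda)) lambda <- numeric(index$Q)
  if (length(lambda) != index$Q)
    stop("lambda has length ", length(lambda), ", expected ", index$Q)
  if (any(abs(lambda[index$anchors]) > 1e-12))
    stop("anchored entries of lambda must be exactly 0")
  if (any(!is.finite(lambda))) stop("lambda must be finite")
  lambda[index$anchors] <- 0
  structure(list(index = index, lambda = lambda, C = index$C),
            class = "mrf_model")
}

#' @export
print.mrf_model <- function(x, ...) {
  cat(sprintf("<mrf_model> C = %d, %d parameters (%d free)\n",
              x$C, x$index$Q, length(x$index$free)))
  for (c in seq_len(x$C)) print(x$index$structures[[c]])
  invisible(x)
}

# within-class lambda block of class c
class_block <- function(model, c) {
  idx <- model$index
  model$lambda[idx$offset[c] + seq_len(idx$P[c])]
}

# ---- exact inference per class -----------------------------------------
#
# For a chain (order-k Markov) structure, the per-class normalization constant
# and feature expectations are computed by a forward-backward sum-product
# recursion over the S^min(l,k) histories; for any other structure (trees,
# pairwise MRFs) by exhaustive enumeration guarded at S^L <= 2^20 states.

chain_inference <- function(structure, lam, want_marginals = TRUE) {
  L <- structure$L; S <- structure$S; k <- structure$order
  lay <- structure$layout
  tab <- lapply(seq_len(L), function(l)
    matrix(lam[lay$pos_offset[l] + seq_len(S * lay$n_real[l])], nrow = S))
  if (k == 0L) {
    lse <- vapply(tab, function(m) logsumexp(m[, 1]), numeric(1))
    logZ <- sum(lse)
    if (!want_marginals) return(list(logZ = logZ))
    E <- unlist(lapply(seq_len(L), function(l) exp(tab[[l]][, 1] - lse[l])))
    return(list(logZ = logZ, E = E))
  }
  n_state <- function(l) if (l == 0L) 1L else S^min(l, k)
  # per position: flattened transition index over (hprev fastest, then b)
  hidx <- lapply(seq_len(L), function(l) {
    m_prev <- min(l - 1L, k)
    hprev <- rep(seq_len(n_state(l - 1L)), times = S)
    b <- rep(seq_len(S), each = n_state(l - 1L))
    if (m_prev < k) hprev + (b - 1L) * S^m_prev
    else (hprev - 1L) %/% S + (b - 1L) * S^(k - 1L) + 1L
  })
  Fwd <- vector("list", L + 1L); Fwd[[1]] <- 0
  for (l in seq_len(L)) {
    V <- rep(Fwd[[l]], times = S) + as.vector(t(tab[[l]]))
    m <- max(V)
    Fwd[[l + 1L]] <- m + log(as.vector(rowsum(exp(V - m), hidx[[l]])))
  }
  logZ <- logsumexp(Fwd[[L + 1L]])
  if (!want_marginals) return(list(logZ = logZ))
  Bwd <- vector("list", L + 1L); Bwd[[L + 1L]] <- rep(0, n_state(L))
  for (l in seq.int(L, 1L)) {
    np <- n_state(l - 1L)
    V <- as.vector(t(tab[[l]])) + Bwd[[l + 1L]][hidx[[l]]]
    m <- max(V)
    Bwd[[l]] <- m + log(as.vector(rowsum(exp(V - m), rep(seq_len(np), times = S))))
  }
  E <- numeric(lay$P)
  for (l in seq_len(L)) {
    np <- n_state(l - 1L)
    flat <- exp(rep(Fwd[[l]], times = S) + as.vector(t(tab[[l]])) +
                  Bwd[[l + 1L]][hidx[[l]]] - logZ)
    # reorder from (hprev fastest) to the layout's (symbol fastest)
    E[lay$pos_offset[l] + seq_len(S * np)] <-
      as.vector(t(matrix(flat, nrow = np)))
  }
  list(logZ = logZ, E = E)
}

enumeration_inference <- function(structure, lam, want_marginals = TRUE,
                                  guard = 2^20) {
  X <- all_sequences(structure$L, structure$S, guard)
  idx <- activated_features(structure, X)
  sc <- rowSums(matrix(lam[idx], nrow = nrow(idx)))
  logZ <- logsumexp(sc)
  if (!want_marginals) return(list(logZ = logZ))
  w <- exp(sc - logZ)
  list(logZ = logZ, E = accumulate_weights(idx, w, structure$layout$P),
       states = X, weights = w)
}

class_inference <- function(structure, lam, want_marginals = TRUE,
                            guard = 2^20) {
  if (structure$kind == "moral_bn" && !is.na(structure$order))
    chain_inference(structure, lam, want_marginals)
  else enumeration_inference(structure, lam, want_marginals, guard)
}

# ---- scores and likelihoods --------------------------------------------

#' Unnormalized log score of sequences under each class
#'
#' Returns the matrix `lambda_c + sum_i lambda_{c,i} f_{c,i}(x)` (the log of
#' the joint-likelihood numerator) for every sequence and class.
#'
#' @param model An [mrf_model()].
#' @param X Integer sequence matrix (`N x L`), a single integer vector, or a
#'   [labeled_dataset()].
#' @return Numeric `N x C` matrix.
#' @export
score_matrix <- function(model, X) {
  if (inherits(X, "labeled_dataset")) X <- X$x
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  idx <- model$index
  out <- matrix(0, nrow(X), model$C)
  for (c in seq_len(model$C)) {
    rel <- activated_features(idx$structures[[c]], X)
    out[, c] <- model$lambda[c] +
      rowSums(matrix(model$lambda[idx$offset[c] + rel], nrow = nrow(X)))
  }
  out
}

#' @rdname score_matrix
#' @param x A single sequence (integer vector).
#' @param c Class index.
#' @export
log_score <- function(model, x, c) {
  score_matrix(model, matrix(as.integer(x), nrow = 1L))[1L, c]
}

#' Log normalization constant of the joint model
#'
#' `log Z(lambda) = log sum_{c,x} exp(log_score(x, c))`, computed in the log
#' domain by the per-class chain recursion or guarded enumeration.
#'
#' @param model An [mrf_model()].
#' @param guard Maximum number of enumerated states for non-chain structures.
#' @export
log_partition <- function(model, guard = 2^20) {
  logZc <- vapply(seq_len(model$C), function(c)
    class_inference(model$index$structures[[c]], class_block(model, c),
                    want_marginals = FALSE, guard = guard)$logZ, numeric(1))
  logsumexp(model$lambda[seq_len(model$C)] + logZc)
}

#' Joint log likelihood log p(x, c | lambda)
#'
#' @inheritParams score_matrix
#' @param cl Class index per sequence (recycled).
#' @export
log_joint <- function(model, X, cl) {
  if (inherits(X, "labeled_dataset")) { cl <- X$labels; X <- X$x }
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  sc <- score_matrix(model, X)
  sc[cbind(seq_len(nrow(X)), rep_len(as.integer(cl), nrow(X)))] -
    log_partition(model)
}

#' Class log posteriors log p(c | x, lambda)
#'
#' The normalization constant cancels between classes, so this is computed
#' purely from the per-class scores (no partition constant involved).
#'
#' @inheritParams score_matrix
#' @return `N x C` matrix of log posterior probabilities.
#' @export
class_log_posterior <- function(model, X) {
  sc <- score_matrix(model, X)
  sc - row_logsumexp(sc)
}

#' Expected feature activations under the model
#'
#' Returns `E_p[f_i]` for every entry of the flat parameter vector: the class
#' marginals `p(c)` for the class block and `p(c) * E[f_i | c]` for
#' within-class features.  This is the partition-gradient of the log-linear
#' model and the workhorse of all gradient-based training.
#'
#' @param model An [mrf_model()].
#' @inheritParams log_partition
#' @export
feature_expectations <- function(model, guard = 2^20) {
  idx <- model$index
  inf <- lapply(seq_len(model$C), function(c)
    class_inference(idx$structures[[c]], class_block(model, c), guard = guard))
  logZc <- vapply(inf, `[[`, numeric(1), "logZ")
  lp <- model$lambda[seq_len(model$C)] + logZc
  pc <- exp(lp - logsumexp(lp))
  E <- numeric(idx$Q)
  E[seq_len(model$C)] <- pc
  for (c in seq_len(model$C))
    E[idx$offset[c] + seq_len(idx$P[c])] <- pc[c] * inf[[c]]$E
  E
}

# ---- theta parameterization --------------------------------------------

#' Conditional-probability (theta) parameters of a moral-BN classifier
#'
#' @param structures Per-class structures as in [mrf_model()] (must all be of
#'   kind `moral_bn`).
#' @param C Number of classes.
#' @param class_probs Probability vector over classes.
#' @param cpds Per class, a list over positions `l` of `S x S^|Pa(l)|`
#'   matrices whose columns are the conditional distributions of the symbol at
#'   `l` given each parent realization.
#' @return Object of class `theta_params`.
#' @export
theta_params <- function(structures, C, class_probs, cpds) {
  index <- build_feature_index(structures, C)
  if (any(vapply(index$structures, function(s) s$kind, character(1)) != "moral_bn"))
    stop("theta parameters are defined for moral-BN structures only")
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (any(class_probs < 0)) stop("class_probs must be non-negative")
  for (c in seq_len(C)) for (l in seq_along(cpds[[c]])) {
    cs <- colSums(cpds[[c]][[l]])
    if (any(abs(cs - 1) > 1e-9)) stop("CPD columns must sum to 1 (class ", c,
                                      ", position ", l, ")")
    if (any(cpds[[c]][[l]] < 0)) stop("CPD entries must be non-negative")
  }
  structure(list(index = index, C = as.integer(C),
                 class_probs = as.numeric(class_probs), cpds = cpds),
            class = "theta_params")
}

#' @export
print.theta_params <- function(x, ...) {
  cat(sprintf("<theta_params> C = %d, class_probs = %s\n", x$C,
              paste(signif(x$class_probs, 4), collapse = ", ")))
  invisible(x)
}

#' Map natural parameters to conditional probabilities
#'
#' Computes `theta_c` as the class marginal of `p_lambda` and
#' `theta_{c,l,b,a}` as the conditional probability of symbol `b` at position
#' `l` given parent realization `a` under `p_lambda(. | c)`, via the chain
#' sum-product recursion or guarded enumeration.
#'
#' @param model An [mrf_model()] whose structures are all moral BNs.
#' @inheritParams log_partition
#' @return A [theta_params()] object.
#' @export
lambda_to_theta <- function(model, guard = 2^20) {
  idx <- model$index
  if (any(vapply(idx$structures, function(s) s$kind, character(1)) != "moral_bn"))
    stop("lambda_to_theta requires moral-BN structures")
  inf <- lapply(seq_len(model$C), function(c)
    class_inference(idx$structures[[c]], class_block(model, c), guard = guard))
  logZc <- vapply(inf, `[[`, numeric(1), "logZ")
  lp <- model$lambda[seq_len(model$C)] + logZc
  pc <- exp(lp - logsumexp(lp))
  cpds <- lapply(seq_len(model$C), function(c) {
    st <- idx$structures[[c]]; lay <- st$layout; S <- st$S
    lapply(seq_len(st$L), function(l) {
      m <- matrix(inf[[c]]$E[lay$pos_offset[l] + seq_len(S * lay$n_real[l])],
                  nrow = S)
      cs <- colSums(m)
      if (any(cs <= 0))
        stop("parent realization with zero marginal mass at position ", l,
             "; cannot condition")
      sweep(m, 2, cs, "/")
    })
  })
  theta_params(idx$structures, model$C, pc, cpds)
}

# decode realization code a (over parents p_1 < ... < p_m) into the symbol at
# the j-th parent
decode_symbol <- function(a, j, S) ((a - 1L) %/% S^(j - 1L)) %% S + 1L

#' Map conditional probabilities to anchored natural parameters
#'
#' Constructs the unique anchored `lambda` with `p_lambda = p_theta`
#' pointwise.  Blocks are processed in reverse topological order: each block
#' is anchored by subtracting its own log-probability at the anchor symbol,
#' and the subtracted term - a function of the block's parent realization -
#' is absorbed into the conditional table of the topologically last parent
#' (whose parent set contains the remaining parents because the network is
#' moral), or into the class parameter for parentless positions.  Requires
#' strictly positive `theta` (boundary values have no finite natural
#' parameters).
#'
#' @param theta A [theta_params()] object.
#' @return An [mrf_model()] with the same structures.
#' @export
theta_to_lambda <- function(theta) {
  idx <- theta$index
  C <- theta$C
  if (any(theta$class_probs <= 0))
    stop("theta contains zero entries; use a positive prior (no finite lambda image)")
  lambda <- numeric(idx$Q)
  class_raw <- numeric(C)
  for (c in seq_len(C)) {
    st <- idx$structures[[c]]; S <- st$S; lay <- st$layout
    if (any(vapply(theta$cpds[[c]], function(m) any(m <= 0), logical(1))))
      stop("theta contains zero entries; use a positive prior (no finite lambda image)")
    phi <- lapply(theta$cpds[[c]], log)
    acc <- 0
    for (l in seq.int(st$L, 1L)) {
      anchor_log <- phi[[l]][S, ]                    # over realizations a
      block <- sweep(phi[[l]], 2, anchor_log, "-")   # anchored: row S == 0
      lambda[idx$offset[c] + lay$pos_offset[l] + seq_len(S * lay$n_real[l])] <-
        as.vector(block)
      pa <- st$parents[[l]]
      if (length(pa) == 0L) {
        acc <- acc + anchor_log[1]
      } else {
        pk <- pa[length(pa)]
        rest <- pa[-length(pa)]
        papk <- st$parents[[pk]]
        pos_in_papk <- match(rest, papk)
        if (anyNA(pos_in_papk))
          stop("structure is not moral: parents of node ", l,
               " are not contained in the parent closure of node ", pk)
        Rk <- lay$n_real[pk]
        for (ap in seq_len(Rk)) for (b in seq_len(S)) {
          vals <- integer(length(pa))
          if (length(rest))
            vals[seq_along(rest)] <- decode_symbol(ap, pos_in_papk, S)
          vals[length(pa)] <- b
          a_code <- 1L + sum((vals - 1L) * S^(seq_along(pa) - 1L))
          phi[[pk]][b, ap] <- phi[[pk]][b, ap] + anchor_log[a_code]
        }
      }
    }
    class_raw[c] <- log(theta$class_probs[c]) + acc
  }
  lambda[seq_len(C)] <- class_raw - class_raw[C]
  mrf_model(idx$structures, C, lambda)
}

# ---- mixtures ----------------------------------------------------------

#' Mixture of MRF models per class
#'
#' Each class `c` carries `M_c` component models over the class's structure;
#' the joint likelihood is
#' `p(x, c) = softmax(gamma)_c * sum_m softmax(u_c)_m p_{c,m}(x)`, with
#' `p_{c,m}(x) = exp(sum_i lambda_{c,m,i} f_i(x)) / Z_{c,m}` a normalized
#' within-class model.  Class logits `gamma` and per-class weight logits `u_c`
#' are anchored (last entry 0) so the whole mixture lives in one unconstrained
#' real vector.  `M = 1` reduces exactly to an [mrf_model()] (see
#' [as_mixture()]).
#'
#' @param structures Per-class structures (a single structure is shared).
#' @param C Number of classes.
#' @param M Components per class (scalar or length-`C` vector).
#' @param class_logits Length-`C` vector, last entry 0.
#' @param weight_logits List per class of length-`M_c` vectors, last entry 0.
#' @param comps List per class of lists of within-class parameter blocks
#'   (anchored; length `P_c` each).
#' @return Object of class `mixture_model`.
#' @export
mixture_model <- function(structures, C = 2L, M = 2L, class_logits = NULL,
                          weight_logits = NULL, comps = NULL) {
  index <- build_feature_index(structures, C)
  M <- rep_len(as.integer(M), C)
  if (any(M < 1L)) stop("M must be >= 1")
  class_logits <- class_logits %||% numeric(C)
  if (abs(class_logits[C]) > 1e-12) stop("last class logit must be 0")
  weight_logits <- weight_logits %||% lapply(M, numeric)
  comps <- comps %||% lapply(seq_len(C), function(c)
    replicate(M[c], numeric(index$P[c]), simplify = FALSE))
  for (c in seq_len(C)) {
    if (length(weight_logits[[c]]) != M[c] || abs(weight_logits[[c]][M[c]]) > 1e-12)
      stop("weight logits of class ", c, " must have length M with last entry 0")
    g <- index$structures[[c]]$layout$groups
    for (m in seq_len(M[c])) {
      if (length(comps[[c]][[m]]) != index$P[c])
        stop("component block size mismatch")
      if (any(abs(comps[[c]][[m]][g$start + g$size - 1L]) > 1e-12))
        stop("anchored entries of component blocks must be 0")
    }
  }
  structure(list(index = index, C = as.integer(C), M = M,
                 class_logits = as.numeric(class_logits),
                 weight_logits = lapply(weight_logits, as.numeric),
                 comps = comps),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> C = %d, components per class: %s\n",
              x$C, paste(x$M, collapse = ", ")))
  invisible(x)
}

#' Embed a single MRF model as a one-component mixture
#'
#' The embedding is exact: `mixture_log_joint()` of the result equals
#' [log_joint()] of the input for every sequence and class.
#'
#' @param model An [mrf_model()].
#' @export
as_mixture <- function(model) {
  idx <- model$index
  logZc <- vapply(seq_len(model$C), function(c)
    class_inference(idx$structures[[c]], class_block(model, c),
                    want_marginals = FALSE)$logZ, numeric(1))
  gam <- model$lambda[seq_len(model$C)] + logZc
  gam <- gam - gam[model$C]
  mixture_model(idx$structures, model$C, M = 1L, class_logits = gam,
                weight_logits = lapply(seq_len(model$C), function(c) 0),
                comps = lapply(seq_len(model$C), function(c)
                  list(class_block(model, c))))
}

log_softmax <- function(x) x - logsumexp(x)

# per-class, per-component log density terms for a sequence matrix:
# list over classes of N x M_c matrices log w_{c,m} + s_{c,m}(x) - log Z_{c,m}
mixture_component_terms <- function(mix, X, guard = 2^20) {
  idx <- mix$index
  lapply(seq_len(mix$C), function(c) {
    st <- idx$structures[[c]]
    rel <- activated_features(st, X)
    lw <- log_softmax(mix$weight_logits[[c]])
    terms <- matrix(0, nrow(X), mix$M[c])
    for (m in seq_len(mix$M[c])) {
      lam <- mix$comps[[c]][[m]]
      logZ <- class_inference(st, lam, want_marginals = FALSE, guard = guard)$logZ
      terms[, m] <- lw[m] + rowSums(matrix(lam[rel], nrow = nrow(X))) - logZ
    }
    terms
  })
}

#' Joint log likelihood of a mixture model
#'
#' @param mix A [mixture_model()].
#' @inheritParams score_matrix
#' @param cl Class index per sequence (recycled); omit (NULL) to obtain the
#'   full `N x C` matrix of `log p(x, c)`.
#' @export
mixture_log_joint <- function(mix, X, cl = NULL) {
  if (inherits(X, "labeled_dataset")) { if (is.null(cl)) cl <- X$labels; X <- X$x }
  if (!is.matrix(X)) X <- matrix(as.integer(X), nrow = 1L)
  lg <- log_softmax(mix$class_logits)
  terms <- mixture_component_terms(mix, X)
  out <- vapply(seq_len(mix$C), function(c) lg[c] + row_logsumexp(terms[[c]]),
                numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X))
  if (is.null(cl)) return(out)
  out[cbind(seq_len(nrow(X)), rep_len(as.integer(cl), nrow(X)))]
}

#' Class log posteriors of a mixture model
#' @inheritParams mixture_log_joint
#' @export
mixture_class_log_posterior <- function(mix, X) {
  lj <- mixture_log_joint(mix, X)
  lj - row_logsumexp(lj)
}

# ---- sampling ----------------------------------------------------------

default_alphabet_for <- function(S) {
  if (S <= 4L) make_alphabet(c("A", "C", "G", "T")[seq_len(S)])
  else make_alphabet(c(LETTERS, letters)[seq_len(S)])
}

# ancestral sampling of n sequences from one class's CPDs (moral BN,
# positions in topological = index order)
sample_moral_bn <- function(st, cpds, n) {
  S <- st$S
  X <- matrix(0L, n, st$L)
  for (l in seq_len(st$L)) {
    pa <- st$parents[[l]]
    a <- rep(1L, n)
    if (length(pa))
      for (j in seq_along(pa)) a <- a + (X[, pa[j]] - 1L) * S^(j - 1L)
    cdf <- apply(cpds[[l]], 2, cumsum)          # S x R
    u <- stats::runif(n)
    X[, l] <- rowSums(u > t(cdf)[a, , drop = FALSE]) + 1L
  }
  X
}

# exact categorical sampling from an enumerated within-class distribution
sample_enumerated <- function(st, lam, n, guard = 2^20) {
  inf <- enumeration_inference(st, lam, want_marginals = TRUE, guard = guard)
  rows <- sample.int(nrow(inf$states), n, replace = TRUE, prob = inf$weights)
  inf$states[rows, , drop = FALSE]
}

# CPDs of a within-class chain model given its lambda block
chain_cpds <- function(st, lam) {
  inf <- chain_inference(st, lam, want_marginals = TRUE)
  lay <- st$layout; S <- st$S
  lapply(seq_len(st$L), function(l) {
    m <- matrix(inf$E[lay$pos_offset[l] + seq_len(S * lay$n_real[l])], nrow = S)
    cs <- colSums(m)
    cs[cs <= 0] <- 1        # unreachable realizations: uniform placeholder
    m[, colSums(m) <= 0] <- 1 / S
    sweep(m, 2, pmax(colSums(m), .Machine$double.xmin), "/")
  })
}

sample_class_component <- function(st, lam, n, guard = 2^20) {
  if (st$kind == "moral_bn" && !is.na(st$order))
    sample_moral_bn(st, chain_cpds(st, lam), n)
  else sample_enumerated(st, lam, n, guard)
}

#' Draw labeled sequences from a model
#'
#' I.i.d. draws from `p(x, c)`: ancestral sampling for moral-BN structures,
#' exact categorical sampling over the enumerated joint for (small) pairwise
#' MRFs.  Deterministic given `seed`.
#'
#' @param params A [theta_params()], [mrf_model()] or [mixture_model()].
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param alphabet Alphabet attached to the returned dataset.
#' @return A [labeled_dataset()].
#' @export
sample_sequences <- function(params, n, seed, alphabet = NULL) {
  UseMethod("sample_sequences")
}

#' @export
sample_sequences.theta_params <- function(params, n, seed, alphabet = NULL) {
  idx <- params$index
  alphabet <- alphabet %||% default_alphabet_for(idx$structures[[1]]$S)
  withr::with_seed(seed, {
    cl <- sample.int(params$C, n, replace = TRUE, prob = params$class_probs)
    Xs <- vector("list", params$C)
    for (c in seq_len(params$C)) {
      nc <- sum(cl == c)
      if (nc) Xs[[c]] <- sample_moral_bn(idx$structures[[c]], params$cpds[[c]], nc)
    }
  })
  assemble_samples(Xs, cl, idx$structures[[1]]$L, alphabet, params$C)
}

#' @export
sample_sequences.mrf_model <- function(params, n, seed, alphabet = NULL) {
  idx <- params$index
  alphabet <- alphabet %||% default_alphabet_for(idx$structures[[1]]$S)
  logZc <- vapply(seq_len(params$C), function(c)
    class_inference(idx$structures[[c]], class_block(params, c),
                    want_marginals = FALSE)$logZ, numeric(1))
  lp <- params$lambda[seq_len(params$C)] + logZc
  pc <- exp(lp - logsumexp(lp))
  withr::with_seed(seed, {
    cl <- sample.int(params$C, n, replace = TRUE, prob = pc)
    Xs <- vector("list", params$C)
    for (c in seq_len(params$C)) {
      nc <- sum(cl == c)
      if (nc) Xs[[c]] <- sample_class_component(idx$structures[[c]],
                                                class_block(params, c), nc)
    }
  })
  assemble_samples(Xs, cl, idx$structures[[1]]$L, alphabet, params$C)
}

#' @export
sample_sequences.mixture_model <- function(params, n, seed, alphabet = NULL) {
  idx <- params$index
  alphabet <- alphabet %||% default_alphabet_for(idx$structures[[1]]$S)
  pc <- exp(log_softmax(params$class_logits))
  withr::with_seed(seed, {
    cl <- sample.int(params$C, n, replace = TRUE, prob = pc)
    Xs <- vector("list", params$C)
    for (c in seq_len(params$C)) {
      nc <- sum(cl == c)
      if (!nc) next
      w <- exp(log_softmax(params$weight_logits[[c]]))
      comp <- sample.int(params$M[c], nc, replace = TRUE, prob = w)
      Xc <- matrix(0L, nc, idx$structures[[c]]$L)
      for (m in seq_len(params$M[c])) {
        nm <- sum(comp == m)
        if (nm) Xc[comp == m, ] <- sample_class_component(
          idx$structures[[c]], params$comps[[c]][[m]], nm)
      }
      Xs[[c]] <- Xc
    }
  })
  assemble_samples(Xs, cl, idx$structures[[1]]$L, alphabet, params$C)
}

assemble_samples <- function(Xs, cl, L, alphabet, C) {
  X <- matrix(0L, length(cl), L)
  for (c in seq_len(C)) if (sum(cl == c)) X[cl == c, ] <- Xs[[c]]
  labeled_dataset(X, cl, alphabet, C = C)
}

# ---- serialization -----------------------------------------------------

structure_descriptor <- function(st) {
  list(kind = st$kind, L = st$L, S = st$S,
       parents = if (st$kind == "moral_bn") lapply(st$parents, as.integer),
       pairs = if (st$kind == "pairwise_mrf") unclass(st$pairs))
}

structure_from_descriptor <- function(d) {
  if (d$kind == "moral_bn")
    make_structure(lapply(d$parents, as.integer), S = d$S, check = FALSE)
  else
    make_pairwise_mrf_structure(d$L, d$S, matrix(unlist(d$pairs), ncol = 2L))
}

#' Serialize a model to a versioned JSON text file
#'
#' Parameters round-trip exactly (full double precision).
#'
#' @param model An [mrf_model()] or [mixture_model()].
#' @param path Output file.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "mrf_model")) {
    list(format = "seqmrf-model", version = 1L, type = "mrf_model",
         C = model$C,
         structures = lapply(model$index$structures, structure_descriptor),
         lambda = model$lambda, anchors = model$index$anchors)
  } else if (inherits(model, "mixture_model")) {
    list(format = "seqmrf-model", version = 1L, type = "mixture_model",
         C = model$C, M = model$M,
         structures = lapply(model$index$structures, structure_descriptor),
         class_logits = model$class_logits,
         weight_logits = model$weight_logits,
         comps = model$comps)
  } else stop("unsupported model type")
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$format, "seqmrf-model"))
    stop("not a seqmrf model archive (or truncated file): ", path)
  sts <- lapply(obj$structures, structure_from_descriptor)
  if (obj$type == "mrf_model") {
    mrf_model(sts, obj$C, as.numeric(unlist(obj$lambda)))
  } else {
    mixture_model(sts, obj$C, M = as.integer(unlist(obj$M)),
                  class_logits = as.numeric(unlist(obj$class_logits)),
                  weight_logits = lapply(obj$weight_logits, function(v) as.numeric(unlist(v))),
                  comps = lapply(obj$comps, function(cc) lapply(cc, function(v) as.numeric(unlist(v)))))
  }
}
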