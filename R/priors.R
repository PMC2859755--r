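#' Dirichlet log density
#'
#' Log density of a Dirichlet distribution with normalization
#' `Gamma(sum alpha) / prod Gamma(alpha_i)`.  Boundary simplex points get
#' `+Inf` when some `alpha_i < 1` (density pole) and `-Inf` when
#' `alpha_i > 1`.
#'
#' @param phi Probability vector (must sum to 1 within 1e-9).
#' @param alpha Positive hyper-parameter vector of the same length.
#' @export
dirichlet_log_pdf <- function(phi, alpha) {
  if (length(phi) != length(alpha)) stop("phi and alpha length mismatch")
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (abs(sum(phi) - 1) > 1e-9) stop("phi is not on the simplex (sums to ",
                                     format(sum(phi)), ")")
  if (any(phi < 0)) stop("phi must be non-negative")
  norm <- lgamma(sum(alpha)) - sum(lgamma(alpha))
  terms <- (alpha - 1) * log(phi)
  terms[alpha == 1] <- 0                       # 0 * log(0) := 0 at exponent 0
  if (any(phi == 0 & alpha < 1)) {
    warning("phi on the simplex boundary with alpha < 1: density is infinite")
    return(Inf)
  }
  norm + sum(terms)
}

#' Hyper-parameters of the product-Dirichlet / transformed-Dirichlet prior
#'
#' Holds per-class equivalent sample sizes `alpha_c` and a flat vector of
#' per-feature pseudo-counts aligned with the model's parameter layout (class
#' entries first, then each class's feature block).
#'
#' @param structures Per-class structures as in [mrf_model()].
#' @param C Number of classes.
#' @param class_alpha Equivalent sample size per class (`alpha_c > 0`).
#' @param alpha Optional within-class pseudo-count vector (flat, length
#'   `C + sum_c P_c`); defaults to the BDeu construction (see
#'   [bdeu_hyperparameters()]).
#' @return Object of class `hyper_params` with `class_alpha`, `alpha`
#'   (flat vector), `total` (`sum alpha_c`) and the feature index.
#' @export
make_hyperparameters <- function(structures, C, class_alpha, alpha = NULL) {
  index <- build_feature_index(structures, C)
  class_alpha <- rep_len(as.numeric(class_alpha), C)
  if (any(class_alpha <= 0)) stop("equivalent sample sizes must be positive")
  if (is.null(alpha)) {
    alpha <- numeric(index$Q)
    alpha[seq_len(C)] <- class_alpha
    for (c in seq_len(C)) {
      st <- index$structures[[c]]
      alpha[index$offset[c] + seq_len(index$P[c])] <- bdeu_block_alpha(st, class_alpha[c])
    }
  }
  if (length(alpha) != index$Q) stop("alpha has wrong length")
  if (any(alpha <= 0)) stop("all alpha entries must be positive")
  structure(list(index = index, C = as.integer(C), class_alpha = class_alpha,
                 alpha = alpha, total = sum(class_alpha)),
            class = "hyper_params")
}

# BDeu pseudo-counts for one class's feature block: uniform pseudo-data over
# Sigma^L gives alpha_c / (S * S^|Pa(l)|) per moral-BN entry and
# alpha_c / S^2 per pairwise-MRF entry.
bdeu_block_alpha <- function(st, ess) {
  S <- st$S
  if (st$kind == "moral_bn") {
    lay <- st$layout
    unlist(lapply(seq_len(st$L), function(l)
      rep(ess / (S * lay$n_real[l]), S * lay$n_real[l])))
  } else {
    rep(ess / S^2, st$layout$P)
  }
}

#' BDeu hyper-parameters from equivalent sample sizes
#'
#' The BDeu rule places a uniform pseudo-data mass of `alpha_c` sequences over
#' all `S^L` sequences of class `c`, giving joint pseudo-counts
#' `alpha_{c,x} = alpha_c / S^L` and marginal pseudo-counts
#' `alpha_{c,l,b,a} = alpha_c / (S * S^|Pa(l)|)` for every moral-BN feature.
#' With the DNA alphabet and `alpha_c = 32` this yields pseudo-counts of 8 for
#' every PWM entry and 8 (first position) / 2 (conditional entries) for a WAM.
#' For pairwise-MRF feature groups the uniform pseudo-data restricted to one
#' position pair gives `alpha_c / S^2` per entry.
#'
#' @param structures Per-class structures as in [mrf_model()].
#' @param ess Equivalent sample size per class (scalar or length-`C`).
#' @param C Number of classes.
#' @return A [make_hyperparameters()] object.
#' @export
bdeu_hyperparameters <- function(structures, ess, C = 2L) {
  make_hyperparameters(structures, C, ess)
}

#' @export
print.hyper_params <- function(x, ...) {
  cat(sprintf("<hyper_params> C = %d, ess = %s, total = %g\n", x$C,
              paste(x$class_alpha, collapse = ", "), x$total))
  invisible(x)
}

#' Product-Dirichlet log prior density on theta parameters
#'
#' Sum of independent Dirichlet log densities: one over the class
#' probabilities and one per conditional-distribution block `(c, l, a)`.
#'
#' @param theta A [theta_params()] object.
#' @param hyper A matching [make_hyperparameters()] object.
#' @export
product_dirichlet_log_pdf <- function(theta, hyper) {
  idx <- theta$index
  if (idx$Q != hyper$index$Q) stop("theta and hyper shapes do not match")
  out <- dirichlet_log_pdf(theta$class_probs, hyper$class_alpha)
  for (c in seq_len(theta$C)) {
    st <- idx$structures[[c]]; lay <- st$layout; S <- st$S
    ablock <- hyper$alpha[idx$offset[c] + seq_len(idx$P[c])]
    for (l in seq_len(st$L)) {
      am <- matrix(ablock[lay$pos_offset[l] + seq_len(S * lay$n_real[l])], nrow = S)
      for (a in seq_len(lay$n_real[l]))
        out <- out + dirichlet_log_pdf(theta$cpds[[c]][[l]][, a], am[, a])
    }
  }
  out
}

#' Transformed-Dirichlet log prior on natural parameters (unnormalized)
#'
#' The product-Dirichlet prior pushed forward through the theta-to-lambda
#' change of variables, up to an additive constant:
#' `sum_c alpha_c lambda_c + sum_{c,i} alpha_{c,i} lambda_{c,i}
#'  - alpha * log Z(lambda)` with `alpha = sum_c alpha_c`.  The same
#' expression defines the prior for general (non-moral) MRF structures, where
#' it is the conjugate prior of the exponential family.  It is log-concave,
#' quadratic near its maximum and asymptotically linear in the tails.
#'
#' @param model An [mrf_model()].
#' @param hyper A matching [make_hyperparameters()] object.
#' @inheritParams log_partition
#' @export
mrf_log_prior <- function(model, hyper, guard = 2^20) {
  if (length(hyper$alpha) != model$index$Q)
    stop("hyper-parameters do not match the model layout")
  sum(hyper$alpha * model$lambda) - hyper$total * log_partition(model, guard)
}

#' Log prior of a mixture model
#'
#' Product over components of the transformed-Dirichlet prior, each component
#' carrying the full per-class equivalent sample size, times symmetric
#' Dirichlet(`alpha_c / M_c`) weights and a Dirichlet(`alpha_c`) class prior
#' (all expressed on logits, unnormalized).
#'
#' @param mix A [mixture_model()].
#' @param hyper A [make_hyperparameters()] object on the shared structures.
#' @export
mixture_log_prior <- function(mix, hyper) {
  idx <- mix$index
  lg <- log_softmax(mix$class_logits)
  out <- sum(hyper$class_alpha * lg)
  for (c in seq_len(mix$C)) {
    lw <- log_softmax(mix$weight_logits[[c]])
    out <- out + sum(hyper$class_alpha[c] / mix$M[c] * lw)
    awithin <- hyper$alpha[idx$offset[c] + seq_len(idx$P[c])]
    for (m in seq_len(mix$M[c])) {
      lam <- mix$comps[[c]][[m]]
      logZ <- class_inference(idx$structures[[c]], lam,
                              want_marginals = FALSE)$logZ
      out <- out + sum(awithin * lam) - hyper$class_alpha[c] * logZ
    }
  }
  out
}

# ---- numerical validators ----------------------------------------------

# free theta coordinates (drop the last entry of each simplex block), in the
# same order as the free lambda coordinates of the layout
theta_free_coords <- function(theta) {
  idx <- theta$index
  out <- theta$class_probs[-theta$C]
  for (c in seq_len(theta$C)) {
    st <- idx$structures[[c]]
    for (l in seq_len(st$L))
      out <- c(out, as.vector(theta$cpds[[c]][[l]][-st$S, , drop = FALSE]))
  }
  out
}

model_with_free <- function(index, free_values) {
  lambda <- numeric(index$Q)
  lambda[index$free] <- free_values
  mrf_model(index$structures, index$C, lambda)
}

#' Numerical pushforward check of the transformed Dirichlet prior
#'
#' Validates, at random parameter points, that the analytic transformed prior
#' equals the product-Dirichlet density pushed through the lambda-to-theta map
#' with a finite-difference Jacobian, up to one additive constant (the dropped
#' normalizer).  With hyper-parameters violating the consistency condition the
#' difference is not constant, which the report flags.
#'
#' @param structures Per-class moral-BN structures (small: the map is
#'   evaluated exactly).
#' @param C Number of classes.
#' @param hyper A [make_hyperparameters()] object.
#' @param n_points Number of random lambda points.
#' @param seed Integer seed.
#' @param sd Spread of the random points.
#' @param tol Spread below which the difference counts as constant.
#' @return List with `diffs` (per-point difference), `spread`
#'   (`max - min`), and `constant` (logical).
#' @export
pushforward_check <- function(structures, C, hyper, n_points = 20, seed = 1,
                              sd = 0.5, tol = 1e-4) {
  index <- build_feature_index(structures, C)
  d <- length(index$free)
  tmap <- function(free) theta_free_coords(lambda_to_theta(model_with_free(index, free)))
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(n_points), function(i) {
      free <- stats::rnorm(d, 0, sd)
      J <- matrix(0, d, d)
      for (j in seq_len(d)) {
        h <- 1e-5 * (1 + abs(free[j]))
        ep <- free; ep[j] <- ep[j] + h
        em <- free; em[j] <- em[j] - h
        J[, j] <- (tmap(ep) - tmap(em)) / (2 * h)
      }
      ldet <- determinant(J, logarithm = TRUE)
      if (!is.finite(ldet$modulus))
        stop("singular finite-difference Jacobian")
      model <- model_with_free(index, free)
      push <- product_dirichlet_log_pdf(lambda_to_theta(model), hyper) +
        as.numeric(ldet$modulus)
      push - mrf_log_prior(model, hyper)
    }, numeric(1))
  })
  spread <- diff(range(diffs))
  list(diffs = diffs, spread = spread, constant = spread < tol)
}

#' Likelihood equivalence of reversed order-1 parameterizations
#'
#' A left-to-right and a right-to-left order-1 Markov model on `L = 2`
#' positions represent the same joint distributions.  Under BDeu priors with a
#' common equivalent sample size, the product-Dirichlet prior of either
#' factorization pushes forward to the same density on the joint distribution
#' (the BDe consistency condition is exactly what makes this hold).  The check
#' transforms both priors to the joint-table parameterization with
#' finite-difference Jacobians and reports the maximum relative mismatch over
#' random joint tables.
#'
#' @param S Alphabet size.
#' @param ess Equivalent sample size.
#' @param n_points Number of random joint distributions tested.
#' @param seed Integer seed.
#' @return List with `max_rel_diff` and the per-point log densities.
#' @export
prior_equivalence_check <- function(S = 4L, ess = 32, n_points = 5, seed = 1) {
  qfree_to_q <- function(f) {
    q <- matrix(0, S, S)
    q[seq_len(S^2 - 1L)] <- f
    q[S, S] <- 1 - sum(f)
    q
  }
  theta_lr <- function(q) {                 # p(x1) and p(x2 | x1)
    m1 <- rowSums(q)
    cpd <- t(sweep(q, 1, m1, "/"))          # S x S, column = given x1
    c(m1[-S], as.vector(cpd[-S, , drop = FALSE]))
  }
  theta_rl <- function(q) {
    m2 <- colSums(q)
    cpd <- sweep(q, 2, m2, "/")             # column = given x2
    c(m2[-S], as.vector(cpd[-S, , drop = FALSE]))
  }
  dens_lr <- function(q) {
    m1 <- rowSums(q); cpd <- t(sweep(q, 1, m1, "/"))
    dirichlet_log_pdf(m1, rep(ess / S, S)) +
      sum(vapply(seq_len(S), function(a)
        dirichlet_log_pdf(cpd[, a], rep(ess / S^2, S)), numeric(1)))
  }
  dens_rl <- function(q) {
    m2 <- colSums(q); cpd <- sweep(q, 2, m2, "/")
    dirichlet_log_pdf(m2, rep(ess / S, S)) +
      sum(vapply(seq_len(S), function(a)
        dirichlet_log_pdf(cpd[, a], rep(ess / S^2, S)), numeric(1)))
  }
  fd_jacobian <- function(fun, f) {
    d <- length(f)
    y0 <- fun(qfree_to_q(f))
    J <- matrix(0, length(y0), d)
    for (j in seq_len(d)) {
      h <- 1e-6
      ep <- f; ep[j] <- ep[j] + h
      em <- f; em[j] <- em[j] - h
      J[, j] <- (fun(qfree_to_q(ep)) - fun(qfree_to_q(em))) / (2 * h)
    }
    J
  }
  res <- withr::with_seed(seed, {
    t(vapply(seq_len(n_points), function(i) {
      q <- matrix(stats::rgamma(S^2, 3, 1), S, S)
      q <- q / sum(q)
      f <- q[seq_len(S^2 - 1L)]
      llr <- dens_lr(q) +
        as.numeric(determinant(fd_jacobian(theta_lr, f), TRUE)$modulus)
      lrl <- dens_rl(q) +
        as.numeric(determinant(fd_jacobian(theta_rl, f), TRUE)$modulus)
      c(lr = llr, rl = lrl)
    }, numeric(2)))
  })
  max_rel <- max(abs(res[, 1] - res[, 2]) / pmax(abs(res[, 1]), 1))
  list(max_rel_diff = max_rel, densities = res)
}

#' Curvature profile of the log prior along one free coordinate
#'
#' Numerically estimates the second derivative of [mrf_log_prior()] along one
#' free coordinate over a grid, holding all other parameters at zero.  The
#' transformed Dirichlet prior is strictly log-concave with near-constant
#' curvature around its maximum (Gaussian-like) and curvature decaying to
#' zero in the far tails (Laplace-like).
#'
#' @param structures,C,hyper As in [pushforward_check()].
#' @param coord Free-coordinate index profiled (default 1 within the first
#'   within-class block).
#' @param grid Lambda values at which to evaluate.
#' @param h Finite-difference step.
#' @return Data frame with `lambda`, `log_prior`, `curvature`.
#' @export
prior_curvature_profile <- function(structures, C, hyper,
                                    coord = NULL,
                                    grid = seq(-20, 20, by = 0.5), h = 1e-3) {
  index <- build_feature_index(structures, C)
  coord <- coord %||% which(index$free > C)[1]
  at <- function(v) {
    free <- numeric(length(index$free))
    free[coord] <- v
    mrf_log_prior(model_with_free(index, free), hyper)
  }
  vals <- vapply(grid, at, numeric(1))
  curv <- vapply(grid, function(v) (at(v + h) - 2 * at(v) + at(v - h)) / h^2,
                 numeric(1))
  data.frame(lambda = grid, log_prior = vals, curvature = curv)
}
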