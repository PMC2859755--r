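#' Training configuration
#'
#' @param principle `"MAP"` (generative: prior times joint likelihood) or
#'   `"MSP"` (discriminative: prior times conditional likelihood of the
#'   labels).
#' @param ess Equivalent sample size per class.
#' @param tolerance Convergence threshold on the projected gradient
#'   (max-abs).
#' @param max_iterations Iteration cap of the quasi-Newton optimizer.
#' @param restarts Number of random restarts (relevant for mixtures, whose
#'   posterior surface is multimodal; single models start at lambda = 0).
#' @param seed Integer seed for restart jitter.
#' @param guard Enumeration guard forwarded to inference.
#' @export
training_config <- function(principle = c("MAP", "MSP"), ess = 4,
                            tolerance = 1e-6, max_iterations = 5000L,
                            restarts = NULL, seed = 1L, guard = 2^20) {
  principle <- match.arg(principle)
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(principle = principle, ess = ess, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 restarts = restarts, seed = as.integer(seed), guard = guard),
            class = "training_config")
}

# sparse indicator design of a dataset under one class structure (N x P);
# per-sequence scores and weighted feature accumulations become one sparse
# product each
dataset_design <- function(st, xmat) {
  idx <- activated_features(st, xmat)
  Matrix::sparseMatrix(i = rep(seq_len(nrow(idx)), ncol(idx)),
                       j = as.vector(idx), x = 1,
                       dims = c(nrow(idx), st$layout$P))
}

# cached exact-inference engine for one class structure: avoids re-enumerating
# states on every optimizer iteration
make_engine <- function(st, guard = 2^20) {
  if (st$kind == "moral_bn" && !is.na(st$order)) {
    function(lam, want_marginals = TRUE) chain_inference(st, lam, want_marginals)
  } else {
    X <- all_sequences(st$L, st$S, guard)
    idx <- activated_features(st, X)
    # sparse indicator matrix: states x features; scores and expectations
    # become one sparse product each
    M <- Matrix::sparseMatrix(i = rep(seq_len(nrow(idx)), ncol(idx)),
                              j = as.vector(idx), x = 1,
                              dims = c(nrow(idx), st$layout$P))
    function(lam, want_marginals = TRUE) {
      sc <- as.vector(M %*% lam)
      logZ <- logsumexp(sc)
      if (!want_marginals) return(list(logZ = logZ))
      w <- exp(sc - logZ)
      list(logZ = logZ, E = as.vector(Matrix::crossprod(M, w)))
    }
  }
}

# full-length expectation vector and log partition from per-class engines
model_expectations <- function(lambda, index, engines) {
  C <- index$C
  inf <- lapply(seq_len(C), function(c)
    engines[[c]](lambda[index$offset[c] + seq_len(index$P[c])]))
  logZc <- vapply(inf, `[[`, numeric(1), "logZ")
  lp <- lambda[seq_len(C)] + logZc
  logZ <- logsumexp(lp)
  pc <- exp(lp - logZ)
  E <- numeric(index$Q)
  E[seq_len(C)] <- pc
  for (c in seq_len(C))
    E[index$offset[c] + seq_len(index$P[c])] <- pc[c] * inf[[c]]$E
  list(logZ = logZ, E = E)
}

#' MAP objective (log posterior) and its gradient
#'
#' `value = sum_i (n_i + alpha_i) lambda_i - (N + alpha) log Z(lambda)`, the
#' log of prior times joint likelihood up to an additive constant;
#' `gradient_i = (n_i + alpha_i) - (N + alpha) E_p[f_i]` with model
#' expectations from the exact sum-product/enumeration inference.  Anchored
#' coordinates carry gradient 0.
#'
#' @param model An [mrf_model()].
#' @param counts A [count_statistics()] table.
#' @param hyper A [make_hyperparameters()] object.
#' @return List with `value` and full-length `gradient`.
#' @export
map_objective <- function(model, counts, hyper) {
  index <- model$index
  engines <- lapply(index$structures, make_engine)
  me <- model_expectations(model$lambda, index, engines)
  a <- counts$n + hyper$alpha
  tot <- counts$N + hyper$total
  g <- a - tot * me$E
  g[index$anchors] <- 0
  list(value = sum(a * model$lambda) - tot * me$logZ, gradient = g)
}

#' Closed-form MAP estimate for moral-BN classifiers
#'
#' The stationary point of the MAP objective in the probability
#' parameterization: smoothed relative frequencies
#' `theta_c = (N_c + alpha_c) / (N + alpha)` and
#' `theta_{c,l,b,a} = (n_{c,l,b,a} + alpha_{c,l,b,a}) /
#'  sum_b' (n_{c,l,b',a} + alpha_{c,l,b',a})`.
#'
#' @param counts A [count_statistics()] table over moral-BN structures.
#' @param hyper A matching [make_hyperparameters()] object.
#' @return A [theta_params()] object.
#' @export
map_closed_form <- function(counts, hyper) {
  index <- counts$index
  C <- index$C
  if (any(vapply(index$structures, function(s) s$kind, character(1)) != "moral_bn"))
    stop("closed-form MAP requires moral-BN structures; use numerical training")
  class_probs <- (counts$N_c + hyper$class_alpha) / (counts$N + hyper$total)
  cpds <- lapply(seq_len(C), function(c) {
    st <- index$structures[[c]]; lay <- st$layout; S <- st$S
    sm <- counts$n[index$offset[c] + seq_len(index$P[c])] +
      hyper$alpha[index$offset[c] + seq_len(index$P[c])]
    lapply(seq_len(st$L), function(l) {
      m <- matrix(sm[lay$pos_offset[l] + seq_len(S * lay$n_real[l])], nrow = S)
      sweep(m, 2, colSums(m), "/")
    })
  })
  theta_params(index$structures, C, class_probs, cpds)
}

#' MSP objective (log supervised posterior) and its gradient
#'
#' `value = sum_n log p(c_n | x_n, lambda) + log prior(lambda)`.  The data
#' term is partition-free (softmax residuals over per-class scores); the
#' prior term contributes `alpha_i - alpha E_p[f_i]`, which requires the
#' model expectations.
#'
#' @inheritParams map_objective
#' @param dataset A [labeled_dataset()].
#' @export
msp_objective <- function(model, dataset, hyper) {
  index <- model$index
  engines <- lapply(index$structures, make_engine)
  designs <- lapply(index$structures, dataset_design, xmat = dataset$x)
  msp_value_grad(model$lambda, index, engines, designs, dataset$labels, hyper)
}

msp_value_grad <- function(lambda, index, engines, designs, labels, hyper) {
  C <- index$C
  N <- length(labels)
  sc <- matrix(0, N, C)
  for (c in seq_len(C))
    sc[, c] <- lambda[c] +
      as.vector(designs[[c]] %*% lambda[index$offset[c] + seq_len(index$P[c])])
  clp <- sc - row_logsumexp(sc)
  me <- model_expectations(lambda, index, engines)
  value <- sum(clp[cbind(seq_len(N), labels)]) +
    sum(hyper$alpha * lambda) - hyper$total * me$logZ
  resid <- -exp(clp)
  resid[cbind(seq_len(N), labels)] <- resid[cbind(seq_len(N), labels)] + 1
  g <- hyper$alpha - hyper$total * me$E
  g[seq_len(C)] <- g[seq_len(C)] + colSums(resid)
  for (c in seq_len(C))
    g[index$offset[c] + seq_len(index$P[c])] <-
      g[index$offset[c] + seq_len(index$P[c])] +
      as.vector(Matrix::crossprod(designs[[c]], resid[, c]))
  g[index$anchors] <- 0
  list(value = value, gradient = g)
}

# quasi-Newton maximization with value/gradient computed jointly; returns the
# optim result plus an objective trace.  The relative-improvement stop is
# tied to the gradient tolerance so loose experiment-scale settings do not
# burn iterations on sub-resolution refinements.
maximize <- function(par, fn_both, tolerance, max_iterations) {
  factr <- max(10, min(1e7, tolerance * 1e10))
  cache <- new.env()
  trace <- numeric(0)
  eval_both <- function(p) {
    if (is.null(cache$p) || !identical(p, cache$p)) {
      cache$p <- p
      cache$res <- fn_both(p)
      trace[length(trace) + 1L] <<- cache$res$value
    }
    cache$res
  }
  res <- stats::optim(par,
                      fn = function(p) eval_both(p)$value,
                      gr = function(p) eval_both(p)$gradient,
                      method = "L-BFGS-B",
                      control = list(fnscale = -1,
                                     maxit = max_iterations,
                                     pgtol = tolerance,
                                     factr = factr))
  list(par = res$par, value = res$value, converged = res$convergence == 0L,
       message = res$message, trace = trace)
}

#' Train a classifier by MAP or MSP under the transformed Dirichlet prior
#'
#' For `M = 1` MAP on moral-BN structures the estimate is the closed-form
#' smoothed-frequency solution mapped through [theta_to_lambda()]; every
#' other case (MSP, pairwise MRFs, mixtures) runs the best of `restarts`
#' quasi-Newton ascents from (jittered) zero initializations.  MAP and MSP
#' use the same hyper-parameters, so differences between the two trained
#' classifiers are attributable to the learning principle alone.
#'
#' @param structures A [model_structure] or list of per-class structures.
#' @param train_data A [labeled_dataset()].
#' @param config A [training_config()].
#' @param M Mixture components per class (scalar or per-class vector);
#'   `M = 1` trains a single model.
#' @param C Number of classes.
#' @return Object of class `seqmrf_classifier` with elements `model` (an
#'   [mrf_model()] or [mixture_model()]), `hyper`, `config`, `principle` and
#'   `log` (objective trace of the best restart, `converged` flag).
#' @export
train_classifier <- function(structures, train_data, config = training_config(),
                             M = 1L, C = train_data$C) {
  index <- build_feature_index(structures, C)
  hyper <- make_hyperparameters(index$structures, C, config$ess)
  M <- rep_len(as.integer(M), C)
  single <- all(M == 1L)
  restarts <- config$restarts %||% (if (single) 1L else 4L)
  fit <- if (single) {
    train_single(index, train_data, hyper, config, restarts)
  } else {
    train_mixture(index, train_data, hyper, config, M, restarts)
  }
  structure(c(fit, list(hyper = hyper, config = config,
                        principle = config$principle)),
            class = "seqmrf_classifier")
}

train_single <- function(index, train_data, hyper, config, restarts) {
  counts <- count_statistics(train_data, index$structures, index$C)
  all_moral <- all(vapply(index$structures,
                          function(s) s$kind == "moral_bn", logical(1)))
  if (config$principle == "MAP" && all_moral) {
    model <- theta_to_lambda(map_closed_form(counts, hyper))
    obj <- map_objective(model, counts, hyper)
    return(list(model = model,
                log = list(objective = obj$value, trace = obj$value,
                           converged = TRUE, method = "closed_form")))
  }
  engines <- lapply(index$structures, function(s) make_engine(s, config$guard))
  fn_both <- if (config$principle == "MAP") {
    a <- counts$n + hyper$alpha
    tot <- counts$N + hyper$total
    function(free) {
      lambda <- numeric(index$Q); lambda[index$free] <- free
      me <- model_expectations(lambda, index, engines)
      list(value = sum(a * lambda) - tot * me$logZ,
           gradient = (a - tot * me$E)[index$free])
    }
  } else {
    designs <- lapply(index$structures, dataset_design, xmat = train_data$x)
    labels <- train_data$labels
    function(free) {
      lambda <- numeric(index$Q); lambda[index$free] <- free
      r <- msp_value_grad(lambda, index, engines, designs, labels, hyper)
      list(value = r$value, gradient = r$gradient[index$free])
    }
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) numeric(length(index$free)) else
      withr::with_seed(config$seed + r, stats::rnorm(length(index$free), 0, 0.05))
    run <- maximize(init, fn_both, config$tolerance, config$max_iterations)
    if (is.null(best) || run$value > best$value) best <- run
  }
  if (!best$converged)
    warning("optimizer did not meet the convergence tolerance; returning best iterate")
  lambda <- numeric(index$Q); lambda[index$free] <- best$par
  list(model = mrf_model(index$structures, index$C, lambda),
       log = list(objective = best$value, trace = best$trace,
                  converged = best$converged, method = "quasi_newton",
                  restarts = restarts))
}

# ---- mixtures ----------------------------------------------------------

# free-vector packing for the mixture parameterization:
# [gamma_{1..C-1}, per class u_{c,1..M-1}, per class/component free block]
mixture_packing <- function(index, M) {
  C <- index$C
  blocks <- lapply(seq_len(C), function(c) {
    g <- index$structures[[c]]$layout$groups
    setdiff(seq_len(index$P[c]), g$start + g$size - 1L)
  })
  sizes <- c(C - 1L, M - 1L,
             unlist(lapply(seq_len(C), function(c) rep(length(blocks[[c]]), M[c]))))
  list(blocks = blocks, total = sum(sizes))
}

mixture_unpack <- function(free, index, M, packing) {
  C <- index$C
  pos <- 0L
  take <- function(k) {
    v <- free[pos + seq_len(k)]; pos <<- pos + k; v
  }
  gamma <- c(take(C - 1L), 0)
  u <- lapply(seq_len(C), function(c) c(take(M[c] - 1L), 0))
  comps <- lapply(seq_len(C), function(c) lapply(seq_len(M[c]), function(m) {
    lam <- numeric(index$P[c])
    lam[packing$blocks[[c]]] <- take(length(packing$blocks[[c]]))
    lam
  }))
  list(gamma = gamma, u = u, comps = comps)
}

mixture_pack <- function(mix, packing) {
  C <- mix$C
  c(mix$class_logits[-C],
    unlist(lapply(seq_len(C), function(c) mix$weight_logits[[c]][-mix$M[c]])),
    unlist(lapply(seq_len(C), function(c) lapply(seq_len(mix$M[c]), function(m)
      mix$comps[[c]][[m]][packing$blocks[[c]]]))))
}

# joint value+gradient of the mixture MAP / MSP objective in the packed
# parameterization.  Gradients follow the standard responsibility algebra of
# mixture models; the prior contributes per-component pseudo-counts minus
# component expectations.
mixture_value_grad <- function(free, index, M, packing, engines, designs,
                               labels, hyper, principle) {
  C <- index$C
  N <- length(labels)
  p <- mixture_unpack(free, index, M, packing)
  lg <- log_softmax(p$gamma)
  pg <- exp(lg)
  inf <- lapply(seq_len(C), function(c)
    lapply(seq_len(M[c]), function(m) engines[[c]](p$comps[[c]][[m]])))
  lw <- lapply(seq_len(C), function(c) log_softmax(p$u[[c]]))
  # per class: N x M matrix of log w_m + s_m(x) - log Z_m over all sequences
  terms <- lapply(seq_len(C), function(c) {
    t_ <- matrix(0, N, M[c])
    for (m in seq_len(M[c]))
      t_[, m] <- lw[[c]][m] +
        as.vector(designs[[c]] %*% p$comps[[c]][[m]]) -
        inf[[c]][[m]]$logZ
    t_
  })
  cond <- vapply(seq_len(C), function(c) row_logsumexp(terms[[c]]), numeric(N))
  cond <- matrix(cond, nrow = N)              # log p(x | c)
  lj <- sweep(cond, 2, lg, "+")               # log p(x, c)
  resp <- lapply(seq_len(C), function(c) exp(terms[[c]] - cond[, c]))

  # prior value
  awithin <- lapply(seq_len(C), function(c)
    hyper$alpha[index$offset[c] + seq_len(index$P[c])])
  prior <- sum(hyper$class_alpha * lg) +
    sum(vapply(seq_len(C), function(c)
      sum(hyper$class_alpha[c] / M[c] * lw[[c]]), numeric(1))) +
    sum(vapply(seq_len(C), function(c)
      sum(vapply(seq_len(M[c]), function(m)
        sum(awithin[[c]] * p$comps[[c]][[m]]) -
          hyper$class_alpha[c] * inf[[c]][[m]]$logZ, numeric(1))), numeric(1)))

  ii <- cbind(seq_len(N), labels)
  if (principle == "MAP") {
    value <- sum(lj[ii]) + prior
    wclass <- matrix(0, N, C)                 # weight of each (n, c) in grads
    wclass[ii] <- 1
  } else {
    clp <- lj - row_logsumexp(lj)
    value <- sum(clp[ii]) + prior
    wclass <- -exp(clp)
    wclass[ii] <- wclass[ii] + 1
  }
  Nc_eff <- colSums(wclass)
  # data part sum_n w_nc plus prior alpha_c, minus the softmax pullback; for
  # MSP the class-posterior residuals already sum to the data part
  g_gamma <- Nc_eff + hyper$class_alpha -
    (if (principle == "MAP") N + hyper$total else hyper$total) * pg
  g_u <- vector("list", C)
  g_comp <- vector("list", C)
  for (c in seq_len(C)) {
    wm <- resp[[c]] * wclass[, c]             # N x M weights
    col <- colSums(wm)
    g_u[[c]] <- col + hyper$class_alpha[c] / M[c] -
      (sum(wclass[, c]) + hyper$class_alpha[c]) * exp(lw[[c]])
    g_comp[[c]] <- lapply(seq_len(M[c]), function(m) {
      acc <- as.vector(Matrix::crossprod(designs[[c]], wm[, m]))
      (acc + awithin[[c]]) - (col[m] + hyper$class_alpha[c]) * inf[[c]][[m]]$E
    })
  }
  gradient <- c(g_gamma[-C],
                unlist(lapply(seq_len(C), function(c) g_u[[c]][-M[c]])),
                unlist(lapply(seq_len(C), function(c) lapply(seq_len(M[c]), function(m)
                  g_comp[[c]][[m]][packing$blocks[[c]]]))))
  list(value = value, gradient = gradient)
}

train_mixture <- function(index, train_data, hyper, config, M, restarts) {
  packing <- mixture_packing(index, M)
  engines <- lapply(index$structures, function(s) make_engine(s, config$guard))
  designs <- lapply(index$structures, dataset_design, xmat = train_data$x)
  labels <- train_data$labels
  fn_both <- function(free)
    mixture_value_grad(free, index, M, packing, engines, designs, labels,
                       hyper, config$principle)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- withr::with_seed(config$seed + r,
                             stats::rnorm(packing$total, 0, 0.05))
    run <- maximize(init, fn_both, config$tolerance, config$max_iterations)
    if (is.null(best) || run$value > best$value) best <- run
  }
  if (!best$converged)
    warning("optimizer did not meet the convergence tolerance; returning best iterate")
  p <- mixture_unpack(best$par, index, M, packing)
  model <- mixture_model(index$structures, index$C, M,
                         class_logits = p$gamma, weight_logits = p$u,
                         comps = p$comps)
  list(model = model,
       log = list(objective = best$value, trace = best$trace,
                  converged = best$converged, method = "quasi_newton",
                  restarts = restarts))
}

#' @export
print.seqmrf_classifier <- function(x, ...) {
  cat(sprintf("<seqmrf_classifier> principle = %s, ess = %s, objective = %.4f, converged = %s\n",
              x$principle, paste(x$hyper$class_alpha, collapse = "/"),
              x$log$objective, x$log$converged))
  invisible(x)
}

#' Log posterior odds scores of test sequences
#'
#' For a two-class classifier, the discrimination score of each sequence is
#' `log p(c = 1 | x) - log p(c = 2 | x)`; the partition constant cancels.
#'
#' @param classifier A `seqmrf_classifier`, [mrf_model()] or
#'   [mixture_model()].
#' @param dataset A [labeled_dataset()] (or sequence matrix).
#' @return Numeric score vector.
#' @export
score_sequences <- function(classifier, dataset) {
  model <- if (inherits(classifier, "seqmrf_classifier")) classifier$model
           else classifier
  clp <- if (inherits(model, "mixture_model"))
    mixture_class_log_posterior(model, if (inherits(dataset, "labeled_dataset")) dataset$x else dataset)
  else class_log_posterior(model, dataset)
  if (ncol(clp) != 2L) stop("scores are defined for two-class models")
  clp[, 1] - clp[, 2]
}

#' Save / load a trained classifier archive
#'
#' The archive is a JSON text file bundling the model, the hyper-parameter
#' audit table and the training log.
#'
#' @param classifier A `seqmrf_classifier`.
#' @param path Output file.
#' @export
write_classifier <- function(classifier, path) {
  tmp_model <- tempfile(fileext = ".json")
  on.exit(unlink(tmp_model))
  write_model(classifier$model, tmp_model)
  obj <- list(format = "seqmrf-classifier", version = 1L,
              principle = classifier$principle,
              ess = classifier$hyper$class_alpha,
              model = jsonlite::fromJSON(readLines(tmp_model),
                                         simplifyVector = FALSE),
              log = classifier$log[c("objective", "converged", "method")])
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  if (!identical(obj$format, "seqmrf-classifier"))
    stop("not a seqmrf classifier archive (or truncated file): ", path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj$model, digits = I(17), auto_unbox = TRUE,
                              null = "null"), tmp)
  model <- read_model(tmp)
  hyper <- make_hyperparameters(model$index$structures, model$C,
                                as.numeric(unlist(obj$ess)))
  structure(list(model = model, hyper = hyper,
                 config = training_config(obj$principle,
                                          ess = as.numeric(unlist(obj$ess))),
                 principle = obj$principle,
                 log = lapply(obj$log, unlist)),
            class = "seqmrf_classifier")
}
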