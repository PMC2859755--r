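# central finite-difference gradient oracle on free coordinates
fd_gradient <- function(fn, x0, h = 1e-6) {
  vapply(seq_along(x0), function(j) {
    e <- numeric(length(x0)); e[j] <- h
    (fn(x0 + e) - fn(x0 - e)) / (2 * h)
  }, numeric(1))
}

test_that("MAP and MSP analytic gradients match finite differences", {
  st <- list(make_markov_structure(3, 1, 3), make_markov_structure(3, 0, 3))
  idx <- seqmrf:::build_feature_index(st, 2)
  d <- sample_sequences(mrf_model(st, 2), 40, seed = 60)
  cnt <- count_statistics(d, st, 2)
  hy <- bdeu_hyperparameters(st, c(3, 7), 2)
  embed <- function(free) {
    lam <- numeric(idx$Q); lam[idx$free] <- free
    mrf_model(st, 2, lam)
  }
  withr::with_seed(61, {
    x0 <- rnorm(length(idx$free), 0, 0.4)
    r_map <- map_objective(embed(x0), cnt, hy)
    expect_lt(max(abs(fd_gradient(function(v) map_objective(embed(v), cnt, hy)$value, x0) -
                        r_map$gradient[idx$free])), 1e-6)
    r_msp <- msp_objective(embed(x0), d, hy)
    expect_lt(max(abs(fd_gradient(function(v) msp_objective(embed(v), d, hy)$value, x0) -
                        r_msp$gradient[idx$free])), 1e-6)
    # ascent property: small steps along the gradient increase the value
    for (r in list(r_map, r_msp)) {
      g <- r$gradient[idx$free]
      fn <- if (identical(r, r_map)) function(v) map_objective(embed(v), cnt, hy)$value
            else function(v) msp_objective(embed(v), d, hy)$value
      expect_gt(fn(x0 + 1e-4 * g / sqrt(sum(g^2))), r$value)
    }
  })

  # pairwise MRF gradients too
  stp <- make_pairwise_mrf_structure(3, 3)
  idxp <- seqmrf:::build_feature_index(stp, 2)
  dp <- sample_sequences(mrf_model(stp, 2), 30, seed = 62)
  cntp <- count_statistics(dp, stp, 2)
  hyp <- bdeu_hyperparameters(stp, c(4, 4), 2)
  embedp <- function(free) {
    lam <- numeric(idxp$Q); lam[idxp$free] <- free
    mrf_model(stp, 2, lam)
  }
  withr::with_seed(63, {
    x0 <- rnorm(length(idxp$free), 0, 0.3)
    rp <- map_objective(embedp(x0), cntp, hyp)
    expect_lt(max(abs(fd_gradient(function(v) map_objective(embedp(v), cntp, hyp)$value, x0) -
                        rp$gradient[idxp$free])), 1e-6)
  })
})

test_that("with equal class ESS and no data, the uniform model is the MAP fixed point", {
  st <- list(make_markov_structure(3, 1, 3), make_markov_structure(3, 0, 3))
  empty <- labeled_dataset(matrix(integer(), 0, 3),
                           integer(), make_alphabet(c("A", "C", "G")), C = 2)
  cnt0 <- count_statistics(empty, st, 2)
  hy <- bdeu_hyperparameters(st, 5, 2)
  r0 <- map_objective(mrf_model(st, 2), cnt0, hy)
  expect_lt(max(abs(r0$gradient)), 1e-12)
  # and the closed form returns the BDeu-uniform theta
  th <- map_closed_form(cnt0, hy)
  expect_equal(th$class_probs, c(0.5, 0.5))
  expect_true(all(abs(unlist(th$cpds) - 1 / 3) < 1e-12))
})

test_that("closed-form MAP is the smoothed-frequency estimate", {
  alph <- dna_alphabet()
  st <- make_markov_structure(1, 0, 4)
  d <- labeled_dataset(matrix(1L, 10, 1), 1L, alph, C = 1)
  cnt <- count_statistics(d, st, 1)
  hy <- bdeu_hyperparameters(st, 4, 1)   # alpha = 1 per symbol
  th <- map_closed_form(cnt, hy)
  expect_equal(th$cpds[[1]][[1]][, 1], c(11, 1, 1, 1) / 14)
})

test_that("closed-form MAP equals numerical MAP through theta for chain orders", {
  withr::with_seed(64, {
    for (k in 0:2) {
      st <- make_markov_structure(4, k, 4)
      gen <- random_model(st, 2, sd = 0.4)
      d <- sample_sequences(gen, 150, seed = 70 + k)
      cnt <- count_statistics(d, st, 2)
      hy <- bdeu_hyperparameters(st, c(4, 16), 2)
      idx <- seqmrf:::build_feature_index(st, 2)
      closed <- map_closed_form(cnt, hy)
      engines <- lapply(idx$structures, seqmrf:::make_engine)
      a <- cnt$n + hy$alpha; tot <- cnt$N + hy$total
      fb <- function(free) {
        lam <- numeric(idx$Q); lam[idx$free] <- free
        me <- seqmrf:::model_expectations(lam, idx, engines)
        list(value = sum(a * lam) - tot * me$logZ,
             gradient = (a - tot * me$E)[idx$free])
      }
      run <- seqmrf:::maximize(numeric(length(idx$free)), fb, 1e-10, 8000)
      lam <- numeric(idx$Q); lam[idx$free] <- run$par
      num <- lambda_to_theta(mrf_model(st, 2, lam))
      expect_lt(max(abs(num$class_probs - closed$class_probs)), 1e-4)
      expect_lt(max(abs(unlist(num$cpds) - unlist(closed$cpds))), 1e-4)
    }
  })
})

test_that("training is deterministic given config, seed and data", {
  st <- make_markov_structure(4, 0, 4)
  d <- sample_sequences(mrf_model(st, 2), 80, seed = 65)
  cfg <- training_config("MSP", ess = c(2, 4), tolerance = 1e-5, seed = 9)
  c1 <- train_classifier(st, d, cfg)
  c2 <- train_classifier(st, d, cfg)
  expect_identical(c1$model$lambda, c2$model$lambda)

  cfgm <- training_config("MAP", ess = c(2, 4), tolerance = 1e-4,
                          max_iterations = 400, seed = 9)
  m1 <- suppressWarnings(train_classifier(st, d, cfgm, M = 2))
  m2 <- suppressWarnings(train_classifier(st, d, cfgm, M = 2))
  expect_identical(m1$model$comps, m2$model$comps)
})

test_that("MAP parameter recovery improves with sample size", {
  st <- make_markov_structure(5, 0, 4)
  gen <- random_model(st, 2, sd = 0.8, seed = 66)
  th_true <- lambda_to_theta(gen)
  errs <- vapply(c(100, 1000, 10000), function(n) {
    d <- sample_sequences(gen, n, seed = n)
    cl <- train_classifier(st, d, training_config("MAP", ess = c(1, 1)))
    th <- lambda_to_theta(cl$model)
    max(abs(unlist(th$cpds) - unlist(th_true$cpds)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("MSP attains at least the MAP training conditional likelihood", {
  st <- list(make_markov_structure(4, 0, 4), make_markov_structure(4, 1, 4))
  gen <- random_model(st, 2, sd = 0.5, seed = 67)
  d <- sample_sequences(gen, 200, seed = 68)
  cll <- function(cl) sum(class_log_posterior(cl$model, d$x)[
    cbind(seq_len(n_sequences(d)), d$labels)])
  cmap <- train_classifier(st, d, training_config("MAP", ess = c(2, 2)))
  cmsp <- train_classifier(st, d, training_config("MSP", ess = c(2, 2),
                                                  tolerance = 1e-5))
  expect_gte(cll(cmsp), cll(cmap) - 1e-6)
})

test_that("with a dominant prior the MSP optimum approaches the MAP optimum", {
  st <- make_markov_structure(3, 0, 4)
  d <- sample_sequences(random_model(st, 2, sd = 1, seed = 69), 40, seed = 70)
  big <- 1e6
  cmap <- train_classifier(st, d, training_config("MAP", ess = c(big, big)))
  cmsp <- train_classifier(st, d, training_config("MSP", ess = c(big, big),
                                                  tolerance = 1e-4))
  expect_lt(max(abs(cmap$model$lambda - cmsp$model$lambda)), 1e-2)
})

test_that("vanishing ESS recovers relative frequencies, including zeros", {
  alph <- dna_alphabet()
  st <- make_markov_structure(2, 0, 4)
  d <- labeled_dataset(c("AA", "AC", "AC"), 1L, alph, C = 1)
  cnt <- count_statistics(d, st, 1)
  th <- map_closed_form(cnt, bdeu_hyperparameters(st, 1e-8, 1))
  expect_equal(th$cpds[[1]][[1]][, 1], c(1, 0, 0, 0), tolerance = 1e-8)
  expect_equal(th$cpds[[1]][[2]][, 1], c(1, 2, 0, 0) / 3, tolerance = 1e-8)
})

test_that("a two-component mixture dominates the single model on bimodal data", {
  stm <- make_markov_structure(4, 0, 4)
  mkcomp <- function(cons) {
    lam <- numeric(n_structure_features(stm))
    for (l in 1:4) {
      v <- rep(-1.5, 4); v[cons[l]] <- 1.5; v <- v - v[4]
      lam[(l - 1) * 4 + 1:4] <- v
    }
    lam
  }
  mix_true <- mixture_model(stm, C = 2, M = c(2L, 1L),
                            class_logits = c(0, 0),
                            weight_logits = list(c(0, 0), 0),
                            comps = list(list(mkcomp(c(1, 1, 2, 2)),
                                              mkcomp(c(4, 3, 4, 3))),
                                         list(numeric(16))))
  d <- sample_sequences(mix_true, 300, seed = 71)
  cfg <- training_config("MAP", ess = c(4, 4), tolerance = 1e-5,
                         max_iterations = 2000, seed = 5)
  c1 <- train_classifier(stm, d, cfg)
  c2 <- suppressWarnings(train_classifier(stm, d, cfg, M = c(2L, 1L)))
  # same objective family: the single model is an M = 1 mixture
  v1 <- sum(mixture_log_joint(as_mixture(c1$model), d)) +
    mixture_log_prior(as_mixture(c1$model), c1$hyper)
  expect_equal(v1, c1$log$objective, tolerance = 1e-6)
  expect_gte(c2$log$objective, c1$log$objective)
})
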