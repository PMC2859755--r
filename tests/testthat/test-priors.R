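test_that("Dirichlet log density: uniform value, normalization, boundary", {
  expect_equal(dirichlet_log_pdf(rep(0.25, 4), rep(1, 4)), log(6))
  expect_error(dirichlet_log_pdf(c(0.5, 0.4), c(1, 1)), "simplex")
  expect_error(dirichlet_log_pdf(c(0.5, 0.5), c(1, -1)), "positive")
  expect_warning(v <- dirichlet_log_pdf(c(0, 1), c(0.5, 1)), "boundary")
  expect_identical(v, Inf)

  # density integrates to 1 over the simplex (midpoint rule, S = 2)
  for (a in list(c(1, 1), c(2, 1), c(3.5, 0.8))) {
    h <- 1e-4
    grid <- seq(h / 2, 1 - h / 2, by = h)
    total <- sum(exp(vapply(grid, function(p)
      dirichlet_log_pdf(c(p, 1 - p), a), numeric(1)))) * h
    expect_equal(total, 1, tolerance = 1e-3)
  }
})

test_that("product-Dirichlet prior sums the per-block densities", {
  st <- make_markov_structure(2, 1, 3)
  hy <- bdeu_hyperparameters(st, c(3, 5), 2)
  m <- random_model(st, 2, seed = 50)
  th <- lambda_to_theta(m)
  val <- product_dirichlet_log_pdf(th, hy)
  ref <- dirichlet_log_pdf(th$class_probs, hy$class_alpha)
  for (cl in 1:2) {
    aw <- hy$alpha[hy$index$offset[cl] + seq_len(hy$index$P[cl])]
    lay <- st$layout
    for (l in 1:2) {
      am <- matrix(aw[lay$pos_offset[l] + seq_len(3 * lay$n_real[l])], nrow = 3)
      for (a in seq_len(lay$n_real[l]))
        ref <- ref + dirichlet_log_pdf(th$cpds[[cl]][[l]][, a], am[, a])
    }
  }
  expect_equal(val, ref, tolerance = 1e-12)

  # single-class single-position model collapses to one Dirichlet density
  st1 <- make_markov_structure(1, 0, 4)
  hy1 <- bdeu_hyperparameters(st1, 4, 1)
  th1 <- lambda_to_theta(random_model(st1, 1, seed = 51))
  expect_equal(product_dirichlet_log_pdf(th1, hy1),
               dirichlet_log_pdf(1, 4) + dirichlet_log_pdf(th1$cpds[[1]][[1]][, 1],
                                                           rep(1, 4)),
               tolerance = 1e-12)
})

test_that("BDeu construction reproduces the worked pseudo-count values", {
  pwm <- make_markov_structure(16, 0, 4)
  h <- bdeu_hyperparameters(pwm, 32, C = 2)
  expect_true(all(h$alpha[h$index$offset[1] + seq_len(h$index$P[1])] == 8))

  wam <- make_markov_structure(7, 1, 4)
  h2 <- bdeu_hyperparameters(wam, 32, C = 2)
  first <- h2$alpha[h2$index$offset[1] + 1:4]
  cond <- h2$alpha[h2$index$offset[1] + 4 + seq_len(h2$index$P[1] - 4)]
  expect_true(all(first == 8))
  expect_true(all(cond == 2))

  h3 <- bdeu_hyperparameters(make_markov_structure(5, 0, 4), 4, C = 1)
  expect_true(all(h3$alpha[-1] == 1))

  # consistency: per-group sums reproduce the parent-realization pseudo-mass
  for (k in 0:2) {
    st <- make_markov_structure(4, k, 3)
    hk <- bdeu_hyperparameters(st, 9, C = 1)
    g <- st$layout$groups
    aw <- hk$alpha[1 + seq_len(st$layout$P)]
    for (j in seq_len(nrow(g))) {
      blk <- aw[g$start[j] + seq_len(g$size[j]) - 1]
      expect_equal(sum(blk), 9 / st$layout$n_real[g$position[j]])
    }
  }

  # pairwise groups get the uniform per-pair mass alpha_c / S^2
  hp <- bdeu_hyperparameters(make_pairwise_mrf_structure(7, 4), 32, C = 2)
  expect_true(all(hp$alpha[-(1:2)] == 2))
})

test_that("the transformed prior is conjugate: posterior = prior at alpha + counts", {
  st <- list(make_markov_structure(3, 1, 4), make_markov_structure(3, 0, 4))
  hy <- bdeu_hyperparameters(st, c(4, 8), 2)
  gen <- mrf_model(st, 2)
  d <- sample_sequences(gen, 50, seed = 52)
  cnt <- count_statistics(d, st, 2)
  hpost <- make_hyperparameters(st, 2, hy$class_alpha + cnt$N_c,
                                alpha = hy$alpha + cnt$n)
  withr::with_seed(53, {
    errs <- replicate(100, {
      m <- random_model(st, 2)
      abs(mrf_log_prior(m, hpost) -
            (mrf_log_prior(m, hy) + sum(log_joint(m, d$x, d$labels))))
    })
  })
  expect_lt(max(errs), 1e-10)

  # all-zero lambda plug-in value
  m0 <- mrf_model(st, 2)
  expect_equal(mrf_log_prior(m0, hy), -hy$total * log(2 * 4^3),
               tolerance = 1e-12)
})

test_that("pushforward of the product-Dirichlet equals the analytic prior", {
  st <- make_markov_structure(1, 0, 2)
  hy <- bdeu_hyperparameters(st, 3, C = 1)
  pf <- pushforward_check(st, 1, hy, n_points = 20, seed = 54)
  expect_lt(pf$spread, 1e-5)
  expect_true(pf$constant)

  st2 <- make_markov_structure(2, 1, 2)
  hy2 <- bdeu_hyperparameters(st2, c(2, 3), C = 2)
  pf2 <- pushforward_check(st2, 2, hy2, n_points = 20, seed = 55)
  expect_lt(pf2$spread, 1e-4)

  # consistency-violating hyper-parameters are flagged as non-constant
  bad <- hy2
  bad$alpha[bad$index$offset[1] + 1] <- bad$alpha[bad$index$offset[1] + 1] + 3
  pf3 <- pushforward_check(st2, 2, bad, n_points = 20, seed = 55)
  expect_false(pf3$constant)
})

test_that("reversed order-1 factorizations carry the same BDeu prior density", {
  eq <- prior_equivalence_check(S = 4, ess = 32, n_points = 5, seed = 56)
  expect_lt(eq$max_rel_diff, 1e-6)
  eq2 <- prior_equivalence_check(S = 2, ess = 5, n_points = 5, seed = 57)
  expect_lt(eq2$max_rel_diff, 1e-6)
})

test_that("log prior is Gaussian-like near its maximum, Laplace-like in the tails", {
  st <- make_markov_structure(1, 0, 2)
  hy <- bdeu_hyperparameters(st, 2, C = 1)
  prof <- prior_curvature_profile(st, 1, hy)
  expect_true(all(prof$curvature < 0))
  near <- prof$curvature[abs(prof$lambda) <= 0.1]
  far <- prof$curvature[abs(prof$lambda) >= 19]
  expect_lt(diff(range(near)), 0.01 * abs(mean(near)))
  expect_true(all(abs(far) < 1e-3 * abs(mean(near))))
  # asymptotic slopes: alpha_i on the left, alpha_i - alpha/2 on the right
  lp <- prof$log_prior
  n <- nrow(prof)
  slope_left <- (lp[2] - lp[1]) / 0.5
  slope_right <- (lp[n] - lp[n - 1]) / 0.5
  expect_equal(slope_left, 1, tolerance = 1e-3)    # alpha_i = 2/2 = 1
  expect_equal(slope_right, 1 - 2, tolerance = 1e-3)
})

test_that("mixture prior reduces to the single-model prior at M = 1", {
  st <- make_markov_structure(3, 1, 3)
  hy <- bdeu_hyperparameters(st, c(3, 6), 2)
  m <- random_model(st, 2, seed = 58)
  expect_equal(mixture_log_prior(as_mixture(m), hy), mrf_log_prior(m, hy),
               tolerance = 1e-9)
})
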