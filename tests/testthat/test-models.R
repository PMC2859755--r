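test_that("log scores are the additive log-linear form", {
  st <- make_markov_structure(4, 1, 4)
  m0 <- mrf_model(st, C = 2)
  expect_equal(log_score(m0, c(1, 2, 3, 4), 1), 0)

  withr::with_seed(31, {
    for (i in 1:5) {
      m <- random_model(list(make_markov_structure(3, 1, 3),
                             make_markov_structure(3, 2, 3)), 2)
      X <- oracle_all_sequences(3, 3)
      for (r in sample(nrow(X), 6)) for (cl in 1:2)
        expect_equal(log_score(m, X[r, ], cl),
                     oracle_log_score(m, X[r, ], cl), tolerance = 1e-12)
    }
  })
})

test_that("log partition matches uniform closed form and brute force", {
  expect_equal(log_partition(mrf_model(make_markov_structure(3, 1, 4), C = 2)),
               log(2 * 4^3))
  # single class, L = 1, anchored lambda (1,0,0,0)
  st1 <- make_markov_structure(1, 0, 4)
  m1 <- mrf_model(st1, C = 1, lambda = c(0, 1, 0, 0, 0))
  expect_equal(log_partition(m1), log(exp(1) + 3))

  withr::with_seed(32, {
    # chain recursion vs enumeration for orders 0..3 at L = 6
    for (k in 0:3) {
      m <- random_model(make_markov_structure(6, k, 2), 2)
      expect_equal(log_partition(m), oracle_log_partition(m), tolerance = 1e-10)
    }
    # pairwise MRF via guarded enumeration
    mp <- random_model(make_pairwise_mrf_structure(4, 3), 2, sd = 0.5)
    expect_equal(log_partition(mp), oracle_log_partition(mp), tolerance = 1e-10)
  })
})

test_that("enumeration guard fails loudly on intractable state spaces", {
  st <- make_pairwise_mrf_structure(8, 4)
  m <- mrf_model(st, C = 2)
  expect_error(log_partition(m, guard = 2^10), "guard")
})

test_that("exp(log_joint) is a probability distribution over (x, c)", {
  withr::with_seed(33, {
    structures <- list(
      make_markov_structure(4, 0, 3),
      make_markov_structure(4, 2, 3),
      make_structure(list(integer(), 1L, 2L, 2L), S = 3),   # tree
      make_pairwise_mrf_structure(4, 3))
    for (st in structures) {
      m <- random_model(st, 2)
      X <- oracle_all_sequences(4, 3)
      total <- sum(exp(c(log_joint(m, X, 1), log_joint(m, X, 2))))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  })
  # all-zero lambda: every outcome has probability 1 / (C S^L)
  m0 <- mrf_model(make_markov_structure(3, 0, 4), C = 2)
  expect_equal(log_joint(m0, c(1, 1, 1), 2), -log(2 * 4^3))
})

test_that("class posteriors are partition-free and joint-consistent", {
  m0 <- mrf_model(make_markov_structure(3, 0, 4), C = 2)
  expect_equal(class_log_posterior(m0, c(2, 3, 4))[1, ], rep(log(0.5), 2))

  withr::with_seed(34, {
    m <- random_model(make_markov_structure(4, 1, 3), 2)
    X <- oracle_all_sequences(4, 3)[sample(81, 10), ]
    lj <- cbind(log_joint(m, X, 1), log_joint(m, X, 2))
    clp <- class_log_posterior(m, X)
    expect_equal(clp, lj - seqmrf:::row_logsumexp(lj), tolerance = 1e-12)
    # two classes with score difference d: posterior = logistic(d)
    sc <- score_matrix(m, X)
    d <- sc[, 1] - sc[, 2]
    expect_equal(exp(clp[, 1]), stats::plogis(d), tolerance = 1e-12)
  })
})

test_that("theta and lambda parameterizations are a bijection", {
  withr::with_seed(35, {
    for (spec in list(list(make_markov_structure(3, 0, 4), 2),
                      list(make_markov_structure(3, 1, 3), 2),
                      list(make_markov_structure(2, 1, 4), 1),
                      list(make_structure(list(integer(), 1L, 1L), S = 3), 2))) {
      m <- random_model(spec[[1]], spec[[2]])
      th <- lambda_to_theta(m)
      # simplex invariants
      expect_equal(sum(th$class_probs), 1, tolerance = 1e-12)
      for (cl in seq_len(th$C)) for (l in seq_along(th$cpds[[cl]]))
        expect_equal(colSums(th$cpds[[cl]][[l]]), rep(1, ncol(th$cpds[[cl]][[l]])),
                     tolerance = 1e-12)
      # theta likelihood (explicit CPD chain) equals the MRF likelihood
      X <- oracle_all_sequences(spec[[1]]$L, spec[[1]]$S)
      for (r in sample(nrow(X), 5)) for (cl in seq_len(th$C))
        expect_equal(oracle_theta_log_joint(th, X[r, ], cl),
                     log_joint(m, X[r, ], cl), tolerance = 1e-10)
      # round trip lambda -> theta -> lambda
      m2 <- theta_to_lambda(th)
      expect_equal(m2$lambda, m$lambda, tolerance = 1e-8)
    }
  })
})

test_that("PWM maps have the softmax / log-ratio closed forms", {
  withr::with_seed(36, {
    m <- random_model(make_markov_structure(4, 0, 4), 1)
    th <- lambda_to_theta(m)
    for (l in 1:4) {
      block <- m$lambda[1 + (l - 1) * 4 + 1:4]
      expect_equal(th$cpds[[1]][[l]][, 1], exp(block) / sum(exp(block)),
                   tolerance = 1e-12)
    }
    m2 <- theta_to_lambda(th)
    for (l in 1:4)
      expect_equal(m2$lambda[1 + (l - 1) * 4 + 1:4],
                   log(th$cpds[[1]][[l]][, 1]) - log(th$cpds[[1]][[l]][4, 1]),
                   tolerance = 1e-12)
  })
})

test_that("boundary theta has no finite natural parameters", {
  st <- make_markov_structure(2, 0, 2)
  th <- theta_params(st, 1, 1, list(list(matrix(c(1, 0), 2), matrix(c(0.5, 0.5), 2))))
  expect_error(theta_to_lambda(th), "zero")
  expect_error(lambda_to_theta(mrf_model(make_pairwise_mrf_structure(3, 2), 1)),
               "moral")
})

test_that("a PWM expressed with pairwise Kronecker indicators is the same model", {
  withr::with_seed(37, {
    L <- 4; S <- 3
    pwm <- random_model(make_markov_structure(L, 0, S), 2, sd = 0.8)
    stp <- make_pairwise_mrf_structure(L, S)
    idxp <- seqmrf:::build_feature_index(stp, 2)
    lam <- numeric(idxp$Q)
    # spread each single-position field over the pairs containing it; the
    # constants removed when re-anchoring each pair group are absorbed into
    # the class parameters
    shift <- numeric(2)
    for (cl in 1:2) {
      h <- matrix(pwm$lambda[2 + (cl - 1) * (L * S) + seq_len(L * S)], nrow = S)
      for (p in seq_len(nrow(stp$pairs))) {
        l1 <- stp$pairs[p, 1]; l2 <- stp$pairs[p, 2]
        block <- outer(h[, l1] / (L - 1), h[, l2] / (L - 1), "+")
        shift[cl] <- shift[cl] + block[S, S]
        block <- block - block[S, S]          # re-anchor the pair group
        rng <- idxp$offset[cl] + (p - 1) * S^2 + seq_len(S^2)
        lam[rng] <- as.vector(block)
      }
    }
    lam[1:2] <- pwm$lambda[1:2] + shift
    lam[1:2] <- lam[1:2] - lam[2]
    mp <- mrf_model(stp, 2, lam)
    X <- oracle_all_sequences(L, S)
    for (cl in 1:2)
      expect_equal(log_joint(mp, X, cl), log_joint(pwm, X, cl),
                   tolerance = 1e-10)
  })
})

test_that("mixtures collapse, normalize and match the probability-domain oracle", {
  withr::with_seed(38, {
    st <- make_markov_structure(3, 1, 3)
    m <- random_model(st, 2)
    X <- oracle_all_sequences(3, 3)
    mx1 <- as_mixture(m)
    expect_equal(mixture_log_joint(mx1, X, 1), log_joint(m, X, 1),
                 tolerance = 1e-10)

    # two identical components with equal weights = the single component
    idx <- seqmrf:::build_feature_index(st, 2)
    blocks <- lapply(1:2, function(cl) seqmrf:::class_block(m, cl))
    mx2 <- mixture_model(st, 2, M = 2,
                         class_logits = mx1$class_logits,
                         weight_logits = list(c(0, 0), c(0, 0)),
                         comps = lapply(blocks, function(b) list(b, b)))
    expect_equal(mixture_log_joint(mx2, X, 2), log_joint(m, X, 2),
                 tolerance = 1e-10)

    # random mixture: normalization and exhaustive probability-domain oracle
    mkblock <- function() {
      g <- st$layout$groups
      b <- rnorm(st$layout$P, 0, 0.6)
      b[g$start + g$size - 1] <- 0
      b
    }
    mx <- mixture_model(st, 2, M = 2, class_logits = c(0.4, 0),
                        weight_logits = list(c(0.3, 0), c(-0.2, 0)),
                        comps = list(list(mkblock(), mkblock()),
                                     list(mkblock(), mkblock())))
    lj <- mixture_log_joint(mx, X)
    expect_equal(sum(exp(lj)), 1, tolerance = 1e-10)
    # oracle: mix in probability domain with enumerated component joints
    pg <- exp(mx$class_logits - max(mx$class_logits))
    pg <- pg / sum(pg)
    for (cl in 1:2) {
      w <- exp(mx$weight_logits[[cl]]); w <- w / sum(w)
      pcomp <- sapply(1:2, function(mm) {
        sc <- apply(X, 1, function(x) {
          idxf <- seqmrf:::activated_features(st, matrix(x, 1))
          sum(mx$comps[[cl]][[mm]][idxf])
        })
        exp(sc) / sum(exp(sc))
      })
      expect_equal(exp(lj[, cl]), pg[cl] * as.vector(pcomp %*% w),
                   tolerance = 1e-10)
    }
  })
})

test_that("sampling is seed-deterministic and recovers planted distributions", {
  st <- make_markov_structure(4, 1, 4)
  m <- random_model(st, 2, seed = 40)
  d1 <- sample_sequences(m, 300, seed = 17)
  d2 <- sample_sequences(m, 300, seed = 17)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$labels, d2$labels)

  # deterministic CPDs produce a single repeated sequence
  stp <- make_markov_structure(3, 0, 2)
  thd <- theta_params(stp, 1, 1, list(lapply(1:3, function(l)
    matrix(c(1 - 1e-12, 1e-12), 2))))
  dd <- sample_sequences(thd, 50, seed = 2)
  expect_true(all(dd$x == 1L))

  # uniform model: per-position symbol frequencies within 4 SE of 1/S
  mu <- mrf_model(make_markov_structure(5, 0, 4), C = 1)
  du <- sample_sequences(mu, 10000, seed = 3)
  freqs <- apply(du$x, 2, tabulate, nbins = 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freqs - 0.25) < 4 * se))

  # planted order-1 chain: empirical transitions recover theta within 4 SE
  m1 <- random_model(make_markov_structure(2, 1, 3), 1, sd = 0.5, seed = 41)
  th <- lambda_to_theta(m1)
  d <- sample_sequences(m1, 10000, seed = 4)
  for (a in 1:3) {
    rows <- d$x[, 1] == a
    if (sum(rows) < 100) next
    phat <- tabulate(d$x[rows, 2], 3) / sum(rows)
    p <- th$cpds[[1]][[2]][, a]
    expect_true(all(abs(phat - p) < 4 * sqrt(p * (1 - p) / sum(rows))))
  }
})

test_that("model serialization round-trips exactly", {
  m <- random_model(list(make_markov_structure(3, 1, 4),
                         make_markov_structure(3, 0, 4)), 2, seed = 42)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$lambda, m$lambda)
  expect_equal(m2$index$structures[[2]]$parents, m$index$structures[[2]]$parents)

  mx <- as_mixture(m)
  write_model(mx, path)
  mx2 <- read_model(path)
  expect_identical(mx2$class_logits, mx$class_logits)
  expect_identical(mx2$comps, mx$comps)

  writeLines('{"broken": true}', path)
  expect_error(read_model(path), "archive|truncated|model")
})
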