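#' Synthetic benchmark scenario specification
#'
#' Two scenario families emulate the shapes of typical binding-site
#' case-study data without any external downloads:
#'
#' * `tfbs_like`: a set of aligned fixed-length motif occurrences (default
#'   257 sites of 16 bp, the scale of a typical transcription-factor data
#'   set) against background windows cut from longer sequences generated by a
#'   homogeneous higher-order Markov chain (default 267 source sequences of
#'   255 bp, cut into 100-mers and then into motif-length windows, about
#'   68 kb in total).
#' * `splice_like`: short donor-site-like motifs (default 7 bp) with a
#'   near-obligate central dinucleotide, two latent subclasses, and planted
#'   *non-adjacent* pairwise dependencies that differ between subclasses -
#'   the data shape that favors pairwise MRFs and mixtures over inhomogeneous
#'   Markov models.
#'
#' The `divergence` knob scales how far all planted distributions sit from
#' uniform; at `divergence = 0` foreground and background are exactly uniform
#' and no classifier can beat chance.
#'
#' @param scenario `"tfbs_like"` or `"splice_like"`.
#' @param L_fg Motif length (default 16 / 7).
#' @param n_fg Number of foreground sites (default 257 / 800).
#' @param n_bg Number of background windows (default: derived from 267
#'   chunked source sequences for `tfbs_like`; 2400 for `splice_like`).
#' @param bg_order Markov order of the background chain (default 3 / 1).
#' @param divergence Effect-size knob (>= 0, default 1).
#' @param subclasses Number of planted foreground subclasses (default 1 / 2).
#' @param dep_pairs For `splice_like`, list of position pairs carrying the
#'   planted couplings, one entry per subclass (recycled).
#' @param seed Integer seed.
#' @export
scenario_spec <- function(scenario = c("tfbs_like", "splice_like"),
                          L_fg = NULL, n_fg = NULL, n_bg = NULL,
                          bg_order = NULL, divergence = 1,
                          subclasses = NULL, dep_pairs = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  tf <- scenario == "tfbs_like"
  spec <- list(scenario = scenario,
               L_fg = as.integer(L_fg %||% if (tf) 16L else 7L),
               n_fg = as.integer(n_fg %||% if (tf) 257L else 800L),
               n_bg = if (is.null(n_bg)) NULL else as.integer(n_bg),
               bg_order = as.integer(bg_order %||% if (tf) 3L else 1L),
               divergence = divergence,
               subclasses = as.integer(subclasses %||% if (tf) 1L else 2L),
               dep_pairs = dep_pairs %||%
                 if (!tf) list(c(1L, 6L), c(2L, 7L)) else list(),
               seed = as.integer(seed))
  if (spec$n_fg <= 0 || spec$divergence < 0 || spec$subclasses < 1)
    stop("invalid scenario specification")
  structure(spec, class = "scenario_spec")
}

#' Draw the planted generating models of a scenario
#'
#' Foreground conditional distributions are drawn from Dirichlet
#' distributions tilted towards a random consensus symbol per position
#' (`Dirichlet(kappa e_cons + 1)` with `kappa = 10 * divergence`, giving
#' information contents typical of real binding sites at `divergence = 1`).
#' For `splice_like`, each subclass is a pairwise MRF over all position pairs
#' whose natural parameters carry the per-position consensus fields, a strong
#' fixed central `G-T` dinucleotide, and a subclass-specific coupling on one
#' non-adjacent position pair.  The background is a homogeneous order-`k`
#' Markov chain with a mild composition bias (scaled by `divergence`).
#'
#' @param spec A [scenario_spec()].
#' @return List of class `planted_model` with `fg` (per-subclass parameters),
#'   `bg` (Markov chain), and `spec`.
#' @export
make_planted_model <- function(spec) {
  S <- 4L
  L <- spec$L_fg
  dv <- spec$divergence
  withr::with_seed(spec$seed, {
    fg <- lapply(seq_len(spec$subclasses), function(m) {
      cons <- sample.int(S, L, replace = TRUE)
      if (dv == 0) {
        probs <- matrix(1 / S, S, L)
      } else {
        # per-position tilt kappa_l = 4 * divergence, scaled by a random
        # informativeness factor: at divergence 1 this gives total
        # information contents around 8-10 bits per 16 bp motif, the range
        # typical of real transcription-factor binding sites
        kap <- 4 * dv * stats::runif(L, 0.3, 1.7)
        probs <- vapply(seq_len(L), function(l) {
          a <- rep(1, S); a[cons[l]] <- a[cons[l]] + kap[l]
          g <- stats::rgamma(S, a, 1); g / sum(g)
        }, numeric(S))
      }
      if (spec$scenario == "tfbs_like")
        return(list(type = "pwm", probs = probs, consensus = cons))
      # splice-like: pairwise MRF with fields + planted coupling
      st <- make_pairwise_mrf_structure(L, S)
      lam <- numeric(n_structure_features(st))
      h <- log(probs)                       # per-position field from tilt
      h <- sweep(h, 2, h[S, ], "-")
      h[, c(3L, 4L)] <- 0
      h[1:4, 3L] <- c(-6, -6, 0, -6) * (dv > 0)   # near-obligate G
      h[1:4, 4L] <- c(-6, -6, -6, 0) * (dv > 0)   # near-obligate T
      deg <- L - 1L
      pairs <- st$pairs
      for (p in seq_len(nrow(pairs))) {
        l1 <- pairs[p, 1]; l2 <- pairs[p, 2]
        block <- outer(h[, l1] / deg, h[, l2] / deg, "+")
        lam[(p - 1L) * S^2 + seq_len(S^2)] <- as.vector(block)
      }
      dep <- spec$dep_pairs[[(m - 1L) %% length(spec$dep_pairs) + 1L]]
      pidx <- which(pairs[, 1] == dep[1] & pairs[, 2] == dep[2])
      if (length(pidx) != 1L) stop("dep_pair not in structure: ",
                                   paste(dep, collapse = ","))
      J <- matrix(0, S, S)
      combos <- if (m %% 2L == 1L) cbind(c(1L, 2L), c(1L, 2L))
                else cbind(c(3L, 4L), c(4L, 3L))
      J[combos] <- 2 * dv
      lam[(pidx - 1L) * S^2 + seq_len(S^2)] <-
        lam[(pidx - 1L) * S^2 + seq_len(S^2)] + as.vector(J)
      # re-anchor every pair group (last entry 0)
      for (p in seq_len(nrow(pairs))) {
        rng <- (p - 1L) * S^2 + seq_len(S^2)
        lam[rng] <- lam[rng] - lam[rng[S^2]]
      }
      list(type = "pairwise", structure = st, lambda = lam,
           consensus = cons, dep_pair = dep)
    })
    base <- if (dv == 0) rep(1 / S, S) else {
      b <- c(0.3, 0.2, 0.2, 0.3)            # mild AT-rich composition bias
      (1 - min(dv, 1)) * rep(1 / S, S) + min(dv, 1) * b
    }
    k <- spec$bg_order
    trans <- matrix(rep(base, each = S^k), nrow = S^k)  # rows: k-mer context
    if (dv > 0) {
      jitter <- matrix(stats::rgamma(S^k * S, 40, 1), nrow = S^k)
      jitter <- jitter / rowSums(jitter)
      trans <- 0.5 * trans + 0.5 * ((1 - min(dv, 1)) / S +
                                      min(dv, 1) * jitter)
      trans <- trans / rowSums(trans)
    }
    bg <- list(order = k, base = base, trans = trans)
  })
  structure(list(fg = fg, bg = bg, spec = spec), class = "planted_model")
}

# simulate one homogeneous Markov chain sequence of length len
sample_markov_chain <- function(bg, len, S = 4L) {
  x <- integer(len)
  for (i in seq_len(len)) {
    p <- if (i <= bg$order) bg$base else {
      ctx <- 1L + sum((x[(i - bg$order):(i - 1L)] - 1L) * S^(seq_len(bg$order) - 1L))
      bg$trans[ctx, ]
    }
    x[i] <- sample.int(S, 1L, prob = p)
  }
  x
}

#' Generate a labeled synthetic benchmark
#'
#' Samples the foreground sites and background windows of a scenario from its
#' planted models and returns them together with the ground truth (for
#' parameter-recovery tests).  Background sequences are generated as long
#' Markov-chain sequences, cut into 100-mers and then into motif-length
#' windows, mirroring the usual preprocessing of real background sets.
#'
#' @param spec A [scenario_spec()].
#' @param model Optional pre-drawn [make_planted_model()] (drawn from `spec`
#'   otherwise).
#' @return List with `fg` and `bg` ([labeled_dataset()]s, labels 1 and 2) and
#'   `truth` (the planted model).
#' @export
generate_benchmark <- function(spec, model = NULL) {
  model <- model %||% make_planted_model(spec)
  S <- 4L
  L <- spec$L_fg
  alph <- dna_alphabet()
  withr::with_seed(spec$seed + 1L, {
    # foreground
    sub <- sample.int(spec$subclasses, spec$n_fg, replace = TRUE)
    fg_rows <- matrix(0L, spec$n_fg, L)
    for (m in seq_len(spec$subclasses)) {
      nm <- sum(sub == m)
      if (!nm) next
      comp <- model$fg[[m]]
      fg_rows[sub == m, ] <- if (comp$type == "pwm") {
        vapply(seq_len(L), function(l)
          sample.int(S, nm, replace = TRUE, prob = comp$probs[, l]),
          integer(nm))
      } else {
        inf <- enumeration_inference(comp$structure, comp$lambda)
        inf$states[sample.int(nrow(inf$states), nm, replace = TRUE,
                              prob = inf$weights), , drop = FALSE]
      }
    }
    # background: long chains -> 100-mers -> L-windows
    if (spec$scenario == "tfbs_like") {
      n_src <- 267L
      src_len <- 255L
      src <- lapply(seq_len(n_src), function(i)
        sample_markov_chain(model$bg, src_len, S))
      hundred <- chunk_sequences(src, 100L, label = 2L, alphabet = alph)
      bg <- chunk_sequences(hundred, L, label = 2L)
      if (!is.null(spec$n_bg) && n_sequences(bg) > spec$n_bg) {
        keep <- sort(sample.int(n_sequences(bg), spec$n_bg))
        bg <- labeled_dataset(bg$x[keep, , drop = FALSE], 2L, alph, C = 2L)
      }
    } else {
      n_bg <- spec$n_bg %||% 2400L
      win_per_src <- 100L %/% L
      n_src <- ceiling(n_bg / win_per_src)
      src <- lapply(seq_len(n_src), function(i)
        sample_markov_chain(model$bg, 100L, S))
      bg <- chunk_sequences(src, L, label = 2L, alphabet = alph)
      bgx <- bg$x[seq_len(n_bg), , drop = FALSE]
      if (spec$divergence > 0) {
        # decoy windows: non-sites sharing the obligatory G-T dinucleotide,
        # as in real donor / non-donor benchmark sets
        bgx[, 3L] <- 3L
        bgx[, 4L] <- 4L
      }
      bg <- labeled_dataset(bgx, 2L, alph, C = 2L)
    }
  })
  fg <- labeled_dataset(fg_rows, 1L, alph, C = 2L)
  bg <- labeled_dataset(bg$x, 2L, alph, C = 2L)
  list(fg = fg, bg = bg, truth = model, subclass = sub)
}
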