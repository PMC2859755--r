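#' Model structures for sequence MRFs
#'
#' A model structure declares, for one class, which log-linear features a
#' sequence model has.  Two kinds are supported:
#'
#' * `moral_bn`: a moral Bayesian network given by per-position parent sets
#'   `Pa(l)`.  Features are indexed by (position `l`, symbol `b`, parent
#'   realization `a`); special cases are the PWM (all parent sets empty), the
#'   WAM (order-1 chain), higher-order inhomogeneous Markov chains, and
#'   Bayesian trees.
#' * `pairwise_mrf`: an undirected model with one binary indicator per
#'   position pair `(l1 < l2)` and symbol pair `(b1, b2)`.
#'
#' Within each simplex-equivalent feature group (one `(l, a)` block of `S`
#' entries, or one `(l1, l2)` block of `S^2` entries) the last natural
#' parameter is anchored to zero, so the number of free parameters matches the
#' probability parameterization.
#'
#' @name model_structure
NULL

new_structure <- function(kind, L, S, parents = NULL, pairs = NULL, order = NA) {
  L <- as.integer(L); S <- as.integer(S)
  st <- structure(list(kind = kind, L = L, S = S, parents = parents,
                       pairs = pairs, order = order),
                  class = "model_structure")
  st$layout <- structure_layout(st)
  st
}

# Per-class feature layout: relative indices 1..P, group table, per-position
# (or per-pair) offsets.  Relative index of a moral-BN feature (l, b, a) is
# pos_offset[l] + (a - 1) * S + b; of a pairwise feature (p, b1, b2) it is
# (p - 1) * S^2 + (b2 - 1) * S + b1.
structure_layout <- function(st) {
  S <- st$S
  if (st$kind == "moral_bn") {
    R <- vapply(st$parents, function(p) S^length(p), numeric(1))
    block <- S * R
    pos_offset <- c(0, cumsum(block))[seq_len(st$L)]
    g_pos <- rep(seq_len(st$L), R)
    g_start <- pos_offset[g_pos] + (unlist(lapply(R, seq_len)) - 1L) * S + 1L
    groups <- data.frame(start = as.integer(g_start), size = S,
                         position = g_pos,
                         realization = as.integer(unlist(lapply(R, seq_len))))
    list(P = as.integer(sum(block)), pos_offset = as.integer(pos_offset),
         n_real = as.integer(R), groups = groups)
  } else {
    np <- nrow(st$pairs)
    groups <- data.frame(start = as.integer((seq_len(np) - 1L) * S^2 + 1L),
                         size = as.integer(S^2), position = seq_len(np),
                         realization = 1L)
    list(P = as.integer(np * S^2), groups = groups)
  }
}

#' Inhomogeneous Markov model structure of a given order
#'
#' Order 0 is the PWM model, order 1 the WAM model.  `Pa(l)` consists of the
#' `min(order, l - 1)` immediately preceding positions, so the parent DAG is a
#' chain whose parent sets are cliques (hence moral).
#'
#' @param L Sequence length.
#' @param order Markov order `k`, `0 <= k < L`.
#' @param S Alphabet size (4 for DNA).
#' @return A `model_structure` of kind `moral_bn`.
#' @examples
#' make_markov_structure(16, 0)  # PWM over a 16 bp site
#' make_markov_structure(7, 1)   # WAM
#' @export
make_markov_structure <- function(L, order, S = 4L) {
  L <- as.integer(L); order <- as.integer(order)
  if (order < 0L || order >= L) stop("order must satisfy 0 <= order < L")
  parents <- lapply(seq_len(L), function(l)
    if (l == 1L || order == 0L) integer()
    else seq.int(max(1L, l - order), l - 1L))
  new_structure("moral_bn", L, S, parents = parents, order = order)
}

#' Moral Bayesian network structure from explicit parent sets
#'
#' @param parents List of integer vectors, `parents[[l]]` giving `Pa(l)`.
#'   Parents must precede their child (the position order is taken as the
#'   topological order).
#' @param S Alphabet size.
#' @param check Verify morality (see [check_morality()]) and fail if violated.
#' @export
make_structure <- function(parents, S = 4L, check = TRUE) {
  L <- length(parents)
  parents <- lapply(parents, function(p) as.integer(sort(p)))
  for (l in seq_len(L))
    if (length(parents[[l]]) && max(parents[[l]]) >= l)
      stop("parents must precede their child (node ", l, ")")
  ord <- if (L > 1L) {
    spans <- vapply(seq_len(L), function(l)
      if (length(parents[[l]])) l - min(parents[[l]]) else 0L, integer(1))
    k <- max(spans)
    chain <- all(vapply(seq_len(L), function(l)
      identical(parents[[l]],
                if (l == 1L) integer() else seq.int(max(1L, l - k), l - 1L)),
      logical(1)))
    if (chain) k else NA_integer_
  } else 0L
  st <- new_structure("moral_bn", L, S, parents = parents, order = ord)
  if (check) {
    m <- check_morality(st)
    if (!m$moral)
      stop("parent graph is not moral; first violation: parents ",
           paste(m$violations[[1]][1:2], collapse = ","), " of node ",
           m$violations[[1]][3], " are not connected")
  }
  st
}

#' All-pairs Markov random field structure
#'
#' One indicator feature per unordered position pair and symbol pair:
#' `choose(L, 2) * S^2` features of the form
#' `I(x_l1 = b1) * I(x_l2 = b2)`.  For DNA donor sites with `L = 7` variable
#' positions this gives 336 indicator functions.
#'
#' @param L Sequence length (`L >= 2`).
#' @param S Alphabet size.
#' @param pairs Optional 2-column matrix restricting the model to specific
#'   position pairs (rows `(l1, l2)`, `l1 < l2`); default all pairs.
#' @export
make_pairwise_mrf_structure <- function(L, S = 4L, pairs = NULL) {
  L <- as.integer(L)
  if (L < 2L) stop("a pairwise MRF needs L >= 2")
  if (is.null(pairs)) pairs <- t(utils::combn(L, 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy l1 < l2")
  if (any(pairs < 1L | pairs > L)) stop("pair positions outside [1, L]")
  key <- paste(pairs[, 1], pairs[, 2])
  if (anyDuplicated(key)) stop("duplicate position pairs")
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  new_structure("pairwise_mrf", L, S, pairs = pairs)
}

#' @export
print.model_structure <- function(x, ...) {
  if (x$kind == "moral_bn") {
    lab <- if (!is.na(x$order)) sprintf(" (Markov order %d)", x$order) else ""
    cat(sprintf("<model_structure> moral_bn%s, L = %d, S = %d, %d features\n",
                lab, x$L, x$S, x$layout$P))
  } else {
    cat(sprintf("<model_structure> pairwise_mrf, L = %d, S = %d, %d pairs, %d features\n",
                x$L, x$S, nrow(x$pairs), x$layout$P))
  }
  invisible(x)
}

#' Check that a directed structure is moral
#'
#' A DAG is moral iff for each node every pair of its parents is itself
#' connected by a parent relation.  Markov-chain structures and trees (at most
#' one parent per node) are always moral.
#'
#' @param structure A `moral_bn` [model_structure].
#' @return List with `moral` (logical) and `violations` (list of triples
#'   `c(p1, p2, child)`).
#' @export
check_morality <- function(structure) {
  stopifnot(structure$kind == "moral_bn")
  parents <- structure$parents
  violations <- list()
  for (l in seq_along(parents)) {
    pa <- parents[[l]]
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in seq.int(i + 1L, length(pa))) {
      p1 <- pa[i]; p2 <- pa[j]
      linked <- p1 %in% parents[[p2]] || p2 %in% parents[[p1]]
      if (!linked) violations[[length(violations) + 1L]] <- c(p1, p2, l)
    }
  }
  list(moral = length(violations) == 0L, violations = violations)
}

#' Number of within-class features of a structure
#' @param structure A [model_structure].
#' @export
n_structure_features <- function(structure) structure$layout$P

#' Number of free parameters of a classifier
#'
#' One parameter per feature group is anchored to zero, so the count is
#' `(C - 1)` class parameters plus, per class, the within-class features minus
#' one anchor per group.  For a moral BN this equals
#' `sum_l (S - 1) * S^|Pa(l)|` per class.
#'
#' @param structure A [model_structure] (shared by all classes) or a list of
#'   per-class structures.
#' @param C Number of classes.
#' @export
count_free_parameters <- function(structure, C = 2L) {
  idx <- build_feature_index(structure, C)
  length(idx$free)
}

# ---- classifier-level feature index ------------------------------------

# Flat parameter layout for a C-class model: entries 1..C are the class
# parameters (lambda_C anchored to 0), followed by each class's within-class
# block.  Absolute index of within-class feature i of class c is
# offset[c] + i.
build_feature_index <- function(structures, C) {
  C <- as.integer(C)
  if (inherits(structures, "model_structure"))
    structures <- rep(list(structures), C)
  if (length(structures) != C) stop("need one structure per class")
  P <- vapply(structures, function(s) s$layout$P, integer(1))
  offset <- C + c(0L, cumsum(P))[seq_len(C)]
  anchors <- C
  for (c in seq_len(C)) {
    g <- structures[[c]]$layout$groups
    anchors <- c(anchors, offset[c] + g$start + g$size - 1L)
  }
  Q <- C + sum(P)
  structure(list(C = C, structures = structures, P = P, offset = offset,
                 Q = Q, anchors = sort(unique(anchors)),
                 free = setdiff(seq_len(Q), anchors)),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("<feature_index> C = %d, %d parameters (%d free, %d anchored)\n",
              x$C, x$Q, length(x$free), length(x$anchors)))
  invisible(x)
}

# Relative (within-class) indices of the features activated by each sequence:
# an N x G integer matrix, one column per moral-BN position or MRF pair.
# Evaluating all indicators on a sequence activates exactly one feature per
# group column.
activated_features <- function(structure, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != structure$L) stop("sequence length does not match structure L")
  S <- structure$S
  if (structure$kind == "moral_bn") {
    lay <- structure$layout
    idx <- matrix(0L, nrow(X), structure$L)
    for (l in seq_len(structure$L)) {
      pa <- structure$parents[[l]]
      a <- rep(1L, nrow(X))
      if (length(pa))
        for (j in seq_along(pa)) a <- a + (X[, pa[j]] - 1L) * S^(j - 1L)
      idx[, l] <- lay$pos_offset[l] + (a - 1L) * S + X[, l]
    }
  } else {
    np <- nrow(structure$pairs)
    idx <- matrix(0L, nrow(X), np)
    for (p in seq_len(np)) {
      idx[, p] <- (p - 1L) * S^2 + (X[, structure$pairs[p, 2]] - 1L) * S +
        X[, structure$pairs[p, 1]]
    }
  }
  idx
}

# Enumerate all S^L sequences as an (S^L x L) matrix, position 1 varying
# fastest (consistent with the parent-realization encoding).
all_sequences <- function(L, S, guard = 2^20) {
  if (S^L > guard)
    stop(sprintf("state space S^L = %.3g exceeds the enumeration guard %.3g; exact inference for this structure is intractable",
                 S^L, guard))
  m <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), L)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
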