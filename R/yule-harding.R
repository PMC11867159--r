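# The Yule-Harding (YH) distribution on tree shapes and labelled trees, the
# uniform (PDA) model, discrete samplers for both, and the exact depth laws
# of a random leaf driven by Stirling numbers of the first kind.

#' Yule-Harding probability of a tree shape
#'
#' The probability that the shape of a tree grown under any neutral
#' speciation/extinction model (equivalently, the discrete YH leaf-attachment
#' process) equals `shape`:
#' \deqn{p(\tau) = 2^{n-1-s(\tau)} / \prod_{v \in IV_\tau} n_\tau(v),}
#' where \eqn{s(\tau)} counts symmetry vertices and \eqn{n_\tau(v)} is the
#' number of leaves below interior vertex \eqn{v} minus one.
#'
#' @param shape a `tree_shape`, or a binary `phylo` tree (its shape is taken).
#' @return An exact `rational` when representable below 2^53 (always for
#'   small n), otherwise a numeric probability computed in log space.
#' @examples
#' p <- yh_shape_probability(shape_of(harding_tree()))
#' format(p) # "1/6"
#' @export
yh_shape_probability <- function(shape) {
  if (inherits(shape, "phylo")) shape <- shape_of(shape)
  stopifnot(inherits(shape, "tree_shape"))
  if (shape$n < 2) stop("shape probabilities require n >= 2 leaves")
  e <- shape$n - 1 - shape$s
  tryCatch({
    den <- prod(as.numeric(shape$ntau))
    .rat_check(den); .rat_check(2^e)
    rational(2^e, den)
  }, error = function(err)
    exp(e * log(2) - sum(log(shape$ntau))))
}

#' Yule-Harding probability of a labelled tree
#'
#' Each of the n!/2^s(tau) labelled trees with shape tau is equally likely
#' under the YH model, so a labelled binary tree has probability
#' p(tau) 2^{s(tau)} / n! = 2^{n-1} / (n! \prod n_tau(v)).
#'
#' @param tree a binary labelled `phylo` tree (n >= 2).
#' @return An exact `rational` when representable, else numeric.
#' @examples
#' format(yh_tree_probability(harding_tree())) # "1/90"
#' @export
yh_tree_probability <- function(tree) {
  shape <- shape_of(tree)
  if (shape$n < 2) stop("tree probabilities require n >= 2 leaves")
  n <- shape$n
  tryCatch({
    num <- 2^(n - 1)
    den <- prod(as.numeric(shape$ntau))
    .rat_check(num); .rat_check(den); .rat_check(factorial(n))
    rational_div(rational(num, den), rational(factorial(n)))
  }, error = function(err)
    exp((n - 1) * log(2) - lfactorial(n) - sum(log(shape$ntau))))
}

# ---- growth structures shared by the discrete samplers --------------------

# a "grown_tree" is a parent-array representation: parent[v] = 0 for the
# root; is_leaf flags; optional per-leaf evolutionary depth (number of
# designated new-species edges on the root path)
.grown <- function(parent, is_leaf, evo_depth = NULL) {
  structure(list(parent = parent, is_leaf = is_leaf, evo_depth = evo_depth,
                 n = sum(is_leaf)),
            class = "grown_tree")
}

# convert to phylo (no edge lengths); tips labelled t1..tn in creation order
.grown_to_phylo <- function(g) {
  n <- g$n
  tips <- which(g$is_leaf)
  internals <- which(!g$is_leaf)
  root <- which(g$parent == 0L)
  # topological order of internal nodes: parent before child
  depth <- integer(length(g$parent))
  # parents may be created after children (root insertion), so compute depth
  # by repeated relaxation over the parent array
  repeat {
    nd <- ifelse(g$parent == 0L, 0L, depth[pmax(g$parent, 1L)] + 1L)
    if (all(nd == depth)) break
    depth <- nd
  }
  internals <- internals[order(depth[internals])]
  newid <- integer(length(g$parent))
  newid[tips] <- seq_len(n)
  newid[internals] <- n + seq_along(internals)
  nonroot <- which(g$parent != 0L)
  edge <- cbind(newid[g$parent[nonroot]], newid[nonroot])
  phy <- structure(list(edge = edge, Nnode = length(internals),
                        tip.label = paste0("t", seq_len(n))),
                   class = "phylo", order = NULL)
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (!is.null(g$evo_depth)) {
    ed <- g$evo_depth[tips]
    names(ed) <- phy$tip.label
    attr(phy, "evo_depth") <- ed
  }
  phy
}

#' Sample a Yule-Harding tree shape
#'
#' Discrete YH leaf-attachment process: start from the two-leaf tree and
#' repeatedly pick an existing leaf uniformly at random, attaching the new
#' leaf to the midpoint of its pendant edge. The attached leaf is recorded as
#' the designated new species ("offspring") at that split, and the offspring
#' designation of the initial two-leaf split is drawn uniformly, so the
#' returned evolutionary depths (attribute `"evo_depth"`) follow the
#' evolutionary-tree depth law.
#'
#' @param n number of leaves (>= 2).
#' @param seed optional integer seed (`set.seed`).
#' @param as_phylo return a `phylo` (default); if `FALSE`, return the raw
#'   parent-array `grown_tree` (faster for large ensembles).
#' @return A `phylo` with no edge lengths and attribute `evo_depth`, or a
#'   `grown_tree`.
#' @export
yh_sample <- function(n, seed = NULL, as_phylo = TRUE) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  is_leaf <- logical(nn)
  evo <- integer(nn)
  # node 1 = root; nodes 2, 3 = initial leaves
  parent[2:3] <- 1L
  is_leaf[2:3] <- TRUE
  off <- sample.int(2L, 1L) + 1L # which initial leaf is the offspring
  evo[off] <- 1L
  leaves <- c(2L, 3L)
  nxt <- 4L
  while (length(leaves) < n) {
    x <- leaves[sample.int(length(leaves), 1L)]
    v <- nxt; y <- nxt + 1L; nxt <- nxt + 2L
    parent[v] <- parent[x]
    parent[x] <- v
    parent[y] <- v
    is_leaf[y] <- TRUE
    evo[y] <- evo[x] + 1L # the attached leaf is the designated offspring
    leaves <- c(leaves, y)
  }
  g <- .grown(parent, is_leaf, evo)
  if (as_phylo) .grown_to_phylo(g) else g
}

#' Sample a uniform (PDA) labelled tree
#'
#' Uniform over all (2n-3)!! rooted binary labelled trees, by sequential
#' insertion: leaf k+1 is attached above a node chosen uniformly among the
#' 2k-1 nodes of the current tree (attachment above the root creates a new
#' root).
#'
#' @inheritParams yh_sample
#' @return A `phylo` with no edge lengths, or a `grown_tree`.
#' @export
pda_sample <- function(n, seed = NULL, as_phylo = TRUE) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  is_leaf <- logical(nn)
  parent[2:3] <- 1L
  is_leaf[2:3] <- TRUE
  nodes <- c(1L, 2L, 3L)
  nxt <- 4L
  for (k in seq_len(n - 2L) + 2L) {
    v <- nodes[sample.int(length(nodes), 1L)]
    w <- nxt; y <- nxt + 1L; nxt <- nxt + 2L
    parent[w] <- parent[v] # 0 when v is the root: w becomes the new root
    parent[v] <- w
    parent[y] <- w
    is_leaf[y] <- TRUE
    nodes <- c(nodes, w, y)
  }
  g <- .grown(parent, is_leaf)
  if (as_phylo) .grown_to_phylo(g) else g
}

#' Leaf counts of the two root subtrees
#'
#' Under the YH model the size of a uniformly chosen root subtree is uniform
#' on 1..n-1; under the PDA model one of the two is a single leaf with
#' probability n/(2n-3).
#'
#' @param tree a binary `phylo` or `grown_tree`.
#' @return Integer vector of length 2 (unordered).
#' @export
root_subtree_sizes <- function(tree) {
  if (inherits(tree, "grown_tree")) {
    cnt <- integer(length(tree$parent))
    cnt[tree$is_leaf] <- 1L
    ord <- .grown_postorder(tree)
    for (v in ord) if (tree$parent[v] != 0L)
      cnt[tree$parent[v]] <- cnt[tree$parent[v]] + cnt[v]
    root <- which(tree$parent == 0L)
    return(cnt[setdiff(which(tree$parent == root), root)])
  }
  n <- length(tree$tip.label)
  cnt <- .clade_sizes(tree)
  cnt[tree$edge[tree$edge[, 1] == n + 1L, 2]]
}

# children-before-parents ordering for a grown_tree
.grown_postorder <- function(g) {
  depth <- integer(length(g$parent))
  repeat {
    nd <- ifelse(g$parent == 0L, 0L, depth[pmax(g$parent, 1L)] + 1L)
    if (all(nd == depth)) break
    depth <- nd
  }
  order(depth, decreasing = TRUE)
}

#' PDA probability that a root subtree is a single leaf
#'
#' Exact probability n/(2n-3) that one of the two subtrees incident with the
#' root of a uniform (PDA) tree consists of a single leaf; converges to 1/2.
#'
#' @param n leaf count (>= 2).
#' @return Numeric probability.
#' @export
pda_single_leaf_root_prob <- function(n) {
  stopifnot(all(n >= 2))
  n / (2 * n - 3)
}

# ---- depth distributions --------------------------------------------------

#' Depth distribution of a random leaf under neutral models
#'
#' Exact law of the depth of a uniformly chosen extant leaf in an n-leaf
#' tree grown under any neutral model. For the reduced tree (depth = number
#' of edges from the root),
#' \deqn{P(D_n = k) = 2^k c(n-1, k) / n!, \quad k = 1, \dots, n-1,}
#' and for the reduced evolutionary tree (depth = number of designated
#' new-species edges on the root path),
#' \deqn{P(D_n' = k) = c(n, k+1) / n!, \quad k = 0, \dots, n-1,}
#' with c(.,.) the unsigned Stirling numbers of the first kind. The means
#' satisfy E[D_n'] = E[D_n]/2 = sum_{i=2}^n 1/i.
#'
#' @param n leaf count (>= 2).
#' @param variant `"reduced"` or `"evolutionary"`.
#' @return A data frame with columns `depth` and `prob`, of class
#'   `"depth_distribution"`, with attributes `n`, `variant`, `mean`, and --
#'   when exactly representable -- `prob_num`/`prob_den` (exact rationals)
#'   and `mean_rational`.
#' @examples
#' depth_distribution(3, "reduced")$prob # 1/3, 2/3
#' @export
depth_distribution <- function(n, variant = c("reduced", "evolutionary")) {
  variant <- match.arg(variant)
  if (length(n) != 1 || n < 2) stop("n must be a single integer >= 2")
  n <- as.integer(n)
  if (variant == "reduced") {
    k <- seq_len(n - 1L)
    exact <- tryCatch({
      row <- stirling_row(n - 1L)[k + 1L]
      pr <- rational(1, 1)
      probs <- vector("list", length(k))
      for (i in seq_along(k))
        probs[[i]] <- rational_mul(rational_div(rational(2^k[i]),
                                                rational(factorial(n))),
                                   rational(row[i]))
      probs
    }, error = function(e) NULL)
    if (is.null(exact)) {
      lp <- k * log(2) + log_stirling_row(n - 1L)[k + 1L] - lfactorial(n)
      prob <- exp(lp)
    }
  } else {
    k <- 0:(n - 1L)
    exact <- tryCatch({
      row <- stirling_row(n)[k + 2L]
      probs <- vector("list", length(k))
      for (i in seq_along(k))
        probs[[i]] <- rational_mul(rational_div(rational(1),
                                                rational(factorial(n))),
                                   rational(row[i]))
      probs
    }, error = function(e) NULL)
    if (is.null(exact)) {
      lp <- log_stirling_row(n)[k + 2L] - lfactorial(n)
      prob <- exp(lp)
    }
  }
  if (!is.null(exact)) {
    num <- vapply(exact, function(r) r$num, 0)
    den <- vapply(exact, function(r) r$den, 0)
    prob <- num / den
  }
  out <- data.frame(depth = k, prob = prob)
  class(out) <- c("depth_distribution", "data.frame")
  attr(out, "n") <- n
  attr(out, "variant") <- variant
  attr(out, "mean") <- sum(k * prob)
  if (!is.null(exact)) {
    attr(out, "prob_num") <- num
    attr(out, "prob_den") <- den
    m <- rational(0)
    for (i in seq_along(k))
      m <- rational_add(m, rational_mul(rational(k[i]), exact[[i]]))
    attr(out, "mean_rational") <- m
  }
  out
}

#' Harmonic-sum mean depth
#'
#' The exact mean sum_{i=2}^n 1/i shared (up to the factor 2) by the two
#' depth laws: E[D_n'] = E[D_n]/2 = sum_{i=2}^n 1/i.
#'
#' @param n leaf count (>= 2).
#' @param exact return an exact `rational` (n small enough) instead of a
#'   numeric.
#' @return Numeric or `rational`.
#' @export
harmonic_mean_depth <- function(n, exact = FALSE) {
  if (!exact) return(sum(1 / (2:n)))
  out <- rational(0)
  for (i in 2:n) out <- rational_add(out, rational(1, i))
  out
}

#' Total variation distance to the limiting Poisson depth law
#'
#' Distance between the evolutionary-tree depth law D_n' and the Poisson
#' distribution with mean log(n) + gamma - 1 (gamma the Euler-Mascheroni
#' constant), which it approaches as n grows.
#'
#' @param n leaf count (>= 2).
#' @return Numeric total variation distance in `[0, 1]`.
#' @export
poisson_depth_tv <- function(n) {
  dd <- depth_distribution(n, "evolutionary")
  m <- log(n) - digamma(1) - 1 # gamma = -digamma(1)
  q <- stats::dpois(dd$depth, m)
  0.5 * (sum(abs(dd$prob - q)) + stats::ppois(n - 1, m, lower.tail = FALSE))
}

# ---- MRCA of a random pair ------------------------------------------------

#' Limiting law of the MRCA-to-root distance
#'
#' For a uniformly chosen pair of leaves of a large YH tree, the number of
#' edges between their most recent common ancestor and the root converges to
#' a geometric law P(G = g) = (1/3)(2/3)^g.
#'
#' @param g non-negative integer (vectorized).
#' @return Numeric probabilities.
#' @export
mrca_root_geometric <- function(g) {
  stopifnot(all(g >= 0))
  (1 / 3) * (2 / 3)^g
}

#' Empirical MRCA-to-root distances on YH trees
#'
#' Samples YH trees and, for each, a uniform pair of distinct leaves,
#' returning the number of edges between their MRCA and the root.
#'
#' @param n leaf count per tree.
#' @param reps number of sampled trees (one pair each).
#' @param seed optional integer seed.
#' @return Integer vector of length `reps`.
#' @export
mrca_root_distances <- function(n, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- integer(reps)
  for (r in seq_len(reps)) {
    g <- yh_sample(n, as_phylo = FALSE)
    leaves <- which(g$is_leaf)
    pair <- leaves[sample.int(length(leaves), 2L)]
    anc1 <- .ancestor_path(g$parent, pair[1])
    anc2 <- .ancestor_path(g$parent, pair[2])
    common <- intersect(anc1, anc2)
    # distance from root to MRCA = edges above MRCA
    out[r] <- length(anc1) - match(common[1], anc1)
  }
  out
}

# ancestors of v from v's parent up to the root (root last)
.ancestor_path <- function(parent, v) {
  path <- integer(0)
  while (parent[v] != 0L) {
    v <- parent[v]
    path <- c(path, v)
  }
  path
}

#' Is the top of the tree the complete shape of depth k?
#'
#' `TRUE` iff the truncation of the tree to vertices at depth at most k is
#' the complete binary shape with all 2^k leaves at depth k -- equivalently,
#' iff no leaf of the tree has depth below k. For YH trees this probability
#' tends to 1 for fixed k as n grows (and does not for the PDA model).
#'
#' @param tree a binary `phylo` or `grown_tree`.
#' @param k depth (>= 1).
#' @return Logical.
#' @export
top_shape_is_complete <- function(tree, k) {
  stopifnot(k >= 1)
  if (inherits(tree, "grown_tree")) {
    parent <- tree$parent
    depth <- integer(length(parent))
    repeat {
      nd <- ifelse(parent == 0L, 0L, depth[pmax(parent, 1L)] + 1L)
      if (all(nd == depth)) break
      depth <- nd
    }
    return(min(depth[tree$is_leaf]) >= k)
  }
  d <- .node_depths(tree)
  min(d[seq_along(tree$tip.label)]) >= k
}
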