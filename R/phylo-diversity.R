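# Phylogenetic diversity (PD), PD maximization, PD indices, and the
# field-of-bullets extinction machinery on fixed trees, plus the limiting
# PD-loss curve phi_PD for birth-death trees.

#' Phylogenetic diversity of a leaf subset
#'
#' Rooted PD: the sum of the lengths of all edges whose clade intersects
#' `leaves` -- the length of the minimal subtree connecting `leaves` to the
#' root. The stem edge is excluded unless requested.
#'
#' @param tree a `phylo` with edge lengths.
#' @param leaves character vector of leaf labels (may be empty: PD 0).
#' @param include_stem add the `root.edge` length when `leaves` is non-empty.
#' @return Numeric PD value.
#' @examples
#' tr <- read_newick("((a:1,b:1):1,c:2);")
#' pd(tr, c("a", "c")) # 4
#' @export
pd <- function(tree, leaves, include_stem = FALSE) {
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  if (length(leaves) == 0) return(0)
  idx <- .tip_index(tree, leaves)
  ind <- numeric(length(tree$tip.label))
  ind[idx] <- 1
  cnt <- .clade_tip_sums(tree, ind)
  val <- sum(tree$edge.length[cnt[tree$edge[, 2]] > 0])
  if (include_stem && !is.null(tree$root.edge)) val <- val + tree$root.edge
  val
}

#' Maximum-PD subset of given size
#'
#' PD satisfies a strong exchange property, so the greedy algorithm --
#' repeatedly add the leaf with the largest PD gain -- returns a subset of
#' size `k` with maximal PD. Ties are broken towards the lexicographically
#' smallest leaf label, making the output deterministic.
#'
#' @param tree a `phylo` with edge lengths.
#' @param k subset size, 1..n.
#' @return List with `leaves` (in selection order) and `value`.
#' @export
max_pd_subset <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  paths <- lapply(tree$tip.label, function(l) path_to_leaf(tree, l))
  names(paths) <- tree$tip.label
  covered <- logical(nrow(tree$edge))
  chosen <- character(0)
  remaining <- sort(tree$tip.label)
  for (step in seq_len(k)) {
    gains <- vapply(remaining, function(l)
      sum(tree$edge.length[paths[[l]][!covered[paths[[l]]]]]), 0)
    best <- remaining[which.max(gains)] # which.max takes the first = smallest
    covered[paths[[best]]] <- TRUE
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  list(leaves = chosen, value = sum(tree$edge.length[covered]))
}

#' PD indices: fair proportion and equal splits
#'
#' Per-leaf apportionments of total PD of the form
#' \eqn{I(x) = \sum_{e \in P(x)} c_e(x) \ell_e} that sum to PD(X) over all
#' leaves. Fair proportion (FP, "evolutionary distinctiveness") uses
#' \eqn{c_e(x) = 1/n_e} (each edge shared equally among its descendant
#' leaves); equal splits (ES) uses \eqn{c_e(x) = 1/N_e(x)} with
#' \eqn{N_e(x)} the product of the out-degrees of the interior vertices
#' between e and x (the edge is halved at each junction on the way down, for
#' binary trees). `rule = "mix"` returns the convex combination
#' `alpha * FP + (1 - alpha) * ES`, also a PD index.
#'
#' @param tree a `phylo` with edge lengths.
#' @param rule `"fp"`, `"es"` or `"mix"`.
#' @param alpha weight of FP in the mix (0..1).
#' @return Named numeric vector over leaves, summing to `pd(tree, all)`.
#' @examples
#' tr <- read_newick("((a:1,b:1):1,c:2);")
#' pd_index(tr, "fp") # a and b: 1.5, c: 2
#' @export
pd_index <- function(tree, rule = c("fp", "es", "mix"), alpha = 0.5) {
  rule <- match.arg(rule)
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  if (rule == "mix") {
    stopifnot(alpha >= 0, alpha <= 1)
    return(alpha * pd_index(tree, "fp") + (1 - alpha) * pd_index(tree, "es"))
  }
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  cnt <- .clade_sizes(tree)
  outdeg <- tabulate(tree$edge[, 1], nbins = nn)
  # top-down pass, parents before children; the running value at node v is
  # the index contribution of all edges above v.  FP adds len/n_e per edge;
  # ES halves (divides by out-degree) the running sum at every junction it
  # passes, so the product of out-degrees between each edge and the leaf
  # builds up along the way down.
  acc <- numeric(nn)
  eo_idx <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  for (i in eo_idx) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]; len <- tree$edge.length[i]
    acc[ch] <- if (rule == "fp") acc[p] + len / cnt[ch]
               else acc[p] / outdeg[p] + len
  }
  vals <- acc[seq_len(n)]
  names(vals) <- tree$tip.label
  vals
}

#' Shapley value of leaves in the PD cooperative game
#'
#' Exhaustive Shapley computation for the game whose value on a coalition Y
#' is PD(Y). The fair-proportion index equals this Shapley value exactly;
#' this routine enumerates all coalitions and is the package's independent
#' route to that identity (n <= 8).
#'
#' @param tree a `phylo` with edge lengths, at most 8 leaves.
#' @param leaf optional single leaf label; default all leaves.
#' @return Named numeric vector of Shapley values.
#' @export
shapley_value <- function(tree, leaf = NULL) {
  n <- length(tree$tip.label)
  if (n > 8) stop("coalition enumeration refused for n > 8")
  labs <- tree$tip.label
  vals <- numeric(2^n) # PD of every coalition, indexed by bitmask + 1
  for (m in seq_len(2^n - 1))
    vals[m + 1] <- pd(tree, labs[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  wt <- factorial(0:(n - 1)) * factorial(n - 1 - 0:(n - 1)) / factorial(n)
  targets <- if (is.null(leaf)) labs else leaf
  out <- vapply(targets, function(l) {
    x <- match(l, labs)
    if (is.na(x)) stop("unknown leaf: ", l)
    bit <- 2^(x - 1)
    others <- (0:(2^n - 1))[bitwAnd(0:(2^n - 1), bit) == 0]
    sizes <- vapply(others, function(m) sum(bitwAnd(m, 2^(seq_len(n) - 1)) > 0), 0)
    sum(wt[sizes + 1] * (vals[others + bit + 1] - vals[others + 1]))
  }, 0)
  names(out) <- targets
  out
}

#' Index-vs-PD subset inequality
#'
#' For any PD index I and any subset Y, sum_{x in Y} I(x) <= PD(Y); the gap
#' is zero when Y = X or on star trees.
#'
#' @param tree a `phylo` with edge lengths.
#' @param Y character vector of leaf labels.
#' @inheritParams pd_index
#' @return List with `index_sum`, `pd`, `gap` (>= 0).
#' @export
index_subset_gap <- function(tree, Y, rule = c("fp", "es", "mix"),
                             alpha = 0.5) {
  idx <- pd_index(tree, rule, alpha)
  s <- sum(idx[.tip_index(tree, Y)])
  p <- pd(tree, Y)
  list(index_sum = s, pd = p, gap = p - s)
}

# ---- field-of-bullets extinction on fixed trees ---------------------------

# normalize an extinction-probability specification to a per-leaf vector
.eps_vector <- function(tree, eps) {
  n <- length(tree$tip.label)
  if (length(eps) == 1 && is.null(names(eps))) eps <- rep(eps, n)
  if (!is.null(names(eps))) {
    full <- rep(NA_real_, n)
    full[.tip_index(tree, names(eps))] <- eps
    if (anyNA(full)) stop("extinction probability missing for some leaves")
    eps <- full
  }
  if (length(eps) != n) stop("eps must be a scalar or one value per leaf")
  if (any(eps < 0 | eps > 1)) stop("extinction probabilities must be in [0,1]")
  eps
}

#' Expected proportion of PD lost under (generalized) field of bullets
#'
#' Species x survives independently with probability 1 - eps_x; an edge's
#' length is lost precisely when all its descendant leaves die, so the
#' expected proportion of PD lost is
#' \deqn{\sum_e \ell_e \prod_{x \in C(e)} \epsilon_x \Big/ \sum_e \ell_e.}
#'
#' @param tree a `phylo` with edge lengths.
#' @param eps single extinction probability (FOB), or a vector/named vector
#'   per leaf (gFOB).
#' @return Expected lost proportion in `[0, 1]`.
#' @examples
#' expected_pd_loss(read_newick("((a:1,b:1):1,c:2);"), 0.5) # 0.45
#' @export
expected_pd_loss <- function(tree, eps) {
  eps <- .eps_vector(tree, eps)
  prods <- .clade_tip_products(tree, eps)
  sum(tree$edge.length * prods[tree$edge[, 2]]) / sum(tree$edge.length)
}

#' Simulate field-of-bullets extinctions and the surviving PD fraction
#'
#' @param tree a `phylo` with edge lengths.
#' @param eps as in [expected_pd_loss()].
#' @param reps number of simulated extinction events.
#' @param seed optional integer seed.
#' @return Numeric vector: surviving PD proportion per replicate.
#' @export
simulate_pd_loss <- function(tree, eps, reps, seed = NULL) {
  eps <- .eps_vector(tree, eps)
  if (!is.null(seed)) set.seed(seed)
  tot <- sum(tree$edge.length)
  n <- length(tree$tip.label)
  out <- numeric(reps)
  for (i in seq_len(reps)) {
    alive <- stats::runif(n) >= eps
    cnt <- .clade_tip_sums(tree, as.numeric(alive))
    out[i] <- sum(tree$edge.length[cnt[tree$edge[, 2]] > 0]) / tot
  }
  out
}

#' Expected extra PD contributed by a species (psi and psi')
#'
#' Under the gFOB model, `psi` is the expected additional PD if species x is
#' present rather than absent at the future time,
#' \deqn{\psi_x = \sum_{e \in P(x)} \ell_e \prod_{s \in C(e) \setminus x} \epsilon_s,}
#' and `psi_prime = psi * eps_x` is the expected additional PD of x being
#' present rather than of uncertain state (the quantity used by the EDGE2
#' protocol). These are not PD indices: they do not sum to PD(X) except on
#' star trees.
#'
#' @inheritParams expected_pd_loss
#' @param leaf optional single leaf; default all leaves.
#' @return Named numeric vector.
#' @export
psi <- function(tree, eps, leaf = NULL) {
  eps <- .eps_vector(tree, eps)
  labs <- if (is.null(leaf)) tree$tip.label else leaf
  eidx <- .edge_of_child(tree)
  out <- vapply(labs, function(l) {
    x <- .tip_index(tree, l)
    e1 <- eps; e1[x] <- 1
    prods <- .clade_tip_products(tree, e1)
    path <- path_to_leaf(tree, l)
    sum(tree$edge.length[path] * prods[tree$edge[path, 2]])
  }, 0)
  names(out) <- labs
  out
}

#' @rdname psi
#' @export
psi_prime <- function(tree, eps, leaf = NULL) {
  eps <- .eps_vector(tree, eps)
  p <- psi(tree, eps, leaf)
  x <- .tip_index(tree, names(p))
  p * eps[x]
}

#' Fair proportion as the expected psi under a uniform extinction prior
#'
#' Under the FOB model with a single extinction probability eps, psi_x(eps)
#' is the polynomial sum_e l_e eps^(n_e - 1) over the root path of x.
#' Averaging over eps ~ Uniform(0, 1) integrates each term to l_e / n_e,
#' which is exactly the fair-proportion index. This routine builds the
#' polynomial and integrates it term by term (exactly), returning both
#' sides.
#'
#' @param tree a `phylo` with edge lengths.
#' @param leaf a single leaf label.
#' @return List with `fp`, `expected_psi` (equal up to rounding) and the
#'   polynomial as a data frame (`power`, `coef`).
#' @export
fp_as_expected_psi <- function(tree, leaf) {
  x <- .tip_index(tree, leaf)
  path <- path_to_leaf(tree, leaf)
  cnt <- .clade_sizes(tree)
  ne <- cnt[tree$edge[path, 2]]
  poly <- data.frame(power = ne - 1, coef = tree$edge.length[path])
  expected <- sum(poly$coef / (poly$power + 1)) # term-wise integral on [0,1]
  list(fp = unname(pd_index(tree, "fp")[leaf]), expected_psi = expected,
       polynomial = poly)
}

#' Evaluate psi_x as a function of a common extinction probability
#'
#' @param tree a `phylo` with edge lengths.
#' @param leaf a single leaf label.
#' @param eps_values numeric vector of FOB extinction probabilities.
#' @return Numeric vector `psi_x(eps)` of the same length.
#' @export
psi_curve <- function(tree, leaf, eps_values) {
  path <- path_to_leaf(tree, leaf)
  cnt <- .clade_sizes(tree)
  ne <- cnt[tree$edge[path, 2]]
  vapply(eps_values, function(e) sum(tree$edge.length[path] * e^(ne - 1)), 0)
}

# ---- phi_PD: limiting PD loss on birth-death trees ------------------------

#' Limiting proportion of PD surviving a field-of-bullets event
#'
#' For a birth-death tree (lambda > mu) grown long, the proportion of PD
#' surviving a FOB event with per-species survival probability s converges
#' to phi_PD(s). For Yule trees (mu = 0),
#' \deqn{\varphi_{PD}(s) = s \log(1/s) / (1 - s),}
#' and for mu > 0 with rho = mu/lambda,
#' \deqn{\varphi_{PD}(s) = \frac{\rho s}{\rho + s - 1}
#'   \cdot \frac{\log(s/(1-\rho))}{\log(1/(1-\rho))},}
#' with the removable singularity at rho = 1 - s filled by
#' `(1 - s)/log(1/s)`. The function is increasing, concave, at least s, and
#' approaches the unit step function as mu/lambda approaches 1.
#'
#' @param s survival probability in `[0, 1]` (vectorized).
#' @param lambda,mu birth and death rates with `lambda > mu >= 0`.
#' @return Numeric values in `[s, 1]`.
#' @examples
#' phi_pd(0.5) # log(2)
#' @export
phi_pd <- function(s, lambda = 1, mu = 0) {
  if (lambda <= mu || mu < 0) stop("requires lambda > mu >= 0")
  if (any(s < 0 | s > 1)) stop("s must be in [0, 1]")
  rho <- mu / lambda
  vapply(s, function(si) {
    if (si == 0) return(0)
    if (si == 1) return(1)
    if (rho == 0) return(si * log(1 / si) / (1 - si))
    if (abs(rho - (1 - si)) < 1e-12) return((1 - si) / log(1 / si))
    rho * si / (rho + si - 1) * log(si / (1 - rho)) / log(1 / (1 - rho))
  }, 0)
}

#' Empirical PD-surviving ratios on simulated birth-death trees
#'
#' Simulates birth-death trees conditioned on survival to age `t`, applies
#' one FOB draw to the extant leaves of each, and returns the realized
#' ratios PD(Y)/PD(X) on the reduced tree (stem excluded). The ensemble mean
#' approaches [phi_pd()] as lambda t grows.
#'
#' @param lambda,mu rates with lambda > mu.
#' @param s FOB survival probability.
#' @param t tree age.
#' @param reps ensemble size.
#' @param seed optional integer seed.
#' @return Numeric vector of ratios in `[0, 1]`. Replicates whose tree has a
#'   single surviving lineage (no non-stem edges, so the ratio is 0/0) are
#'   dropped; their frequency is reported in the attribute
#'   `"single_leaf_frac"`.
#' @export
phi_pd_empirical <- function(lambda, mu = 0, s, t, reps, seed = NULL) {
  if (lambda <= mu) stop("requires lambda > mu")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(reps)
  for (i in seq_len(reps)) {
    real <- simulate_bd(lambda, mu, duration = t, condition = "survival")
    if (real$n_extant == 1L) {
      # a single surviving lineage has no non-stem edges: PD(X) = 0 and the
      # ratio is undefined; such replicates are dropped (frequency reported)
      out[i] <- NA_real_
      next
    }
    if (mu == 0) {
      # no pruning: every segment except the origin (stem) is an edge
      cnt <- integer(real$n_seg)
      tips <- real$status == 0L
      cnt[tips] <- as.integer(stats::runif(sum(tips)) < s)
      for (v in order(real$birth, decreasing = TRUE)) {
        p <- real$parent[v]
        if (p != 0L) cnt[p] <- cnt[p] + cnt[v]
      }
      len <- real$end - real$birth
      keep <- real$parent != 0L
      out[i] <- sum(len[keep & cnt > 0L]) / sum(len[keep])
      next
    }
    et <- .reduced_edge_table(real)
    # FOB draw on the extant tips, then propagate any-survivor up the
    # reduced edges (rows are child edges keyed by bottom segment)
    rowof <- integer(max(et$bottom))
    rowof[et$bottom] <- seq_len(nrow(et))
    cnt <- integer(nrow(et))
    cnt[et$tip] <- as.integer(stats::runif(sum(et$tip)) < s)
    ord <- order(real$birth[et$bottom], decreasing = TRUE)
    for (j in ord) {
      if (et$top[j] != 0L)
        cnt[rowof[et$top[j]]] <- cnt[rowof[et$top[j]]] + cnt[j]
    }
    keep <- et$top != 0L # stem excluded
    out[i] <- sum(et$length[keep & cnt > 0]) / sum(et$length[keep])
  }
  structure(out[!is.na(out)],
            single_leaf_frac = mean(is.na(out)))
}

#' Expected edge count by clade size on Yule-Harding trees
#'
#' The expected number of edges of an n-leaf YH tree with exactly k
#' descendant leaves is 2n/(k(k+1)) for k <= n - 1; at k = 1 this is n, the
#' pendant-edge count. Summing the per-edge survival probability
#' 1 - (1-s)^k against these counts is the heuristic route to phi_PD.
#'
#' @param n leaf count.
#' @param k clade size (vectorized), 1..n-1.
#' @return Expected edge counts.
#' @export
yh_expected_edges_by_clade_size <- function(n, k) {
  stopifnot(all(k >= 1), all(k <= n - 1))
  2 * n / (k * (k + 1))
}

#' Mean fair proportion of a random leaf on a Yule tree
#'
#' Closed form (1/lambda)(1 + exp(-lambda t)) for the expected
#' fair-proportion index of a uniformly chosen leaf of a Yule tree grown
#' for time t; converges to 1/lambda as t grows.
#'
#' @param lambda birth rate.
#' @param t tree age (vectorized).
#' @return Numeric expected FP values.
#' @export
mean_fp_yule <- function(lambda, t) {
  stopifnot(lambda > 0, all(t >= 0))
  (1 + exp(-lambda * t)) / lambda
}
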