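# Feature diversity (FD) on fixed trees: combinatorial FD from feature
# assignments, the PD <-> FD representability results (nested supports), the
# stochastic gain/loss model of feature evolution along branches, the exact
# expected-FD recursion, and the expected-feature edge lengths used to
# compare expected FD loss with its PD proxy.

#' Feature assignments
#'
#' A feature assignment maps each species to the set of (discrete) features
#' it carries; each feature has a strictly positive weight. FD of a subset Y
#' is the total weight of features present in at least one member of Y.
#'
#' @param features named list: leaf label -> character vector of feature ids
#'   (possibly empty).
#' @param weights named numeric vector of positive weights per feature id;
#'   defaults to weight 1 for every feature appearing in `features`.
#' @return An object of class `"feature_assignment"`.
#' @examples
#' fa <- feature_assignment(list(x = c("f1", "f2"), y = c("f1", "f3"),
#'                               z = c("f2", "f3")))
#' fd(fa, c("x", "y")) # 3
#' @export
feature_assignment <- function(features, weights = NULL) {
  stopifnot(is.list(features), !is.null(names(features)),
            all(nzchar(names(features))))
  features <- lapply(features, as.character)
  all_feats <- unique(unlist(features, use.names = FALSE))
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(all_feats)), all_feats)
  missing <- setdiff(all_feats, names(weights))
  if (length(missing))
    stop("features without weights: ", paste(missing, collapse = ", "))
  if (any(weights <= 0)) stop("feature weights must be strictly positive")
  structure(list(features = features, weights = weights),
            class = "feature_assignment")
}

#' @export
print.feature_assignment <- function(x, ...) {
  cat(sprintf("feature assignment: %d species, %d features\n",
              length(x$features), length(x$weights)))
  invisible(x)
}

#' Feature diversity of a subset of species
#'
#' @param assignment a [feature_assignment()].
#' @param leaves character vector of species labels (may be empty: FD 0).
#' @return Total weight of features present in at least one member.
#' @export
fd <- function(assignment, leaves) {
  stopifnot(inherits(assignment, "feature_assignment"))
  if (length(leaves) == 0) return(0)
  unknown <- setdiff(leaves, names(assignment$features))
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  present <- unique(unlist(assignment$features[leaves], use.names = FALSE))
  sum(assignment$weights[present])
}

#' Represent PD as FD
#'
#' Assigns one feature per edge, carried by exactly the leaves below that
#' edge, with weight equal to the edge length; FD of the result equals
#' PD(T, l)(Y) for every subset Y. (The converse fails: FD with non-nested
#' supports cannot be represented as PD on any tree.)
#'
#' @param tree a `phylo` with edge lengths.
#' @param include_stem also create a feature for the stem edge (carried by
#'   all leaves); match the `include_stem` choice made for PD comparisons.
#' @return A [feature_assignment()].
#' @export
pd_as_fd <- function(tree, include_stem = FALSE) {
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  labs <- tree$tip.label
  feats <- stats::setNames(vector("list", length(labs)), labs)
  for (l in labs)
    feats[[l]] <- paste0("edge", path_to_leaf(tree, l))
  w <- stats::setNames(tree$edge.length, paste0("edge", seq_len(nrow(tree$edge))))
  if (include_stem && !is.null(tree$root.edge)) {
    feats <- lapply(feats, function(f) c(f, "stem"))
    w <- c(w, stem = tree$root.edge)
  }
  feature_assignment(feats, w)
}

# supports X_f = set of species carrying feature f
.feature_supports <- function(assignment) {
  pairs <- data.frame(
    leaf = rep(names(assignment$features),
               lengths(assignment$features)),
    feat = unlist(assignment$features, use.names = FALSE))
  split(pairs$leaf, pairs$feat)
}

#' Is a feature assignment nested (laminar)?
#'
#' The supports X_f form a nested family when any two are disjoint or one
#' contains the other -- exactly the condition under which FD can be
#' realized as PD on some tree (single gains, no losses).
#'
#' @param assignment a [feature_assignment()].
#' @return Logical; when `FALSE`, attribute `"violating_pair"` names two
#'   features whose supports properly overlap.
#' @export
is_nested <- function(assignment) {
  sup <- lapply(.feature_supports(assignment), unique)
  ids <- names(sup)
  if (length(sup) > 1) {
    for (i in seq_len(length(sup) - 1)) {
      for (j in (i + 1):length(sup)) {
        a <- sup[[i]]; b <- sup[[j]]
        int <- length(intersect(a, b))
        if (int > 0 && int < length(a) && int < length(b))
          return(structure(FALSE, violating_pair = c(ids[i], ids[j])))
      }
    }
  }
  TRUE
}

#' Build a tree realizing a nested feature assignment as PD
#'
#' For a nested assignment, constructs a rooted tree with non-negative edge
#' lengths whose PD function (stem included) equals FD: every support
#' becomes a cluster, features sharing a support stack their weights on one
#' edge, features carried by all species go on the stem, and species carried
#' by no feature attach with zero-length pendant edges (zero lengths are
#' permitted only in this construction).
#'
#' @param assignment a [feature_assignment()].
#' @return A list: `success` (logical); on success `tree` (a `phylo`, PD to
#'   be evaluated with `include_stem = TRUE`); on failure `violating_pair`.
#' @export
fd_to_pd_tree <- function(assignment) {
  nested <- is_nested(assignment)
  if (!isTRUE(nested))
    return(list(success = FALSE,
                violating_pair = attr(nested, "violating_pair")))
  leaves <- names(assignment$features)
  n <- length(leaves)
  sup <- .feature_supports(assignment)
  key <- vapply(sup, function(s) paste(sort(unique(s)), collapse = "\r"), "")
  wsum <- tapply(assignment$weights[names(sup)], key, sum)
  clus <- strsplit(names(wsum), "\r", fixed = TRUE)
  w <- as.numeric(wsum)
  rootkey <- paste(sort(leaves), collapse = "\r")
  stem <- 0
  full <- which(names(wsum) == rootkey)
  if (length(full)) {
    stem <- w[full]
    clus <- clus[-full]; w <- w[-full]
  }
  sizes <- lengths(clus)
  ord <- order(sizes, decreasing = TRUE)
  clus <- clus[ord]; w <- w[ord]; sizes <- sizes[ord]
  # vertex ids: tips 1..n, root n+1, one interior vertex per non-singleton
  # cluster; singleton clusters put their weight on the pendant edge
  singleton <- sizes == 1L
  nonsing <- which(!singleton)
  node_id <- integer(length(clus))
  node_id[nonsing] <- n + 1L + seq_along(nonsing)
  # parent of a cluster: smallest strictly containing non-singleton cluster
  parent_of <- function(members, upto) {
    best <- 0L # root
    for (j in rev(seq_len(upto))) { # scan larger clusters, smallest first
      if (singleton[j]) next
      if (sizes[j] > length(members) && all(members %in% clus[[j]]))
        return(node_id[j])
    }
    n + 1L
  }
  edges <- matrix(integer(0), 0, 2)
  elen <- numeric(0)
  for (i in seq_along(clus)) {
    if (singleton[i]) next
    p <- parent_of(clus[[i]], i - 1L)
    edges <- rbind(edges, c(p, node_id[i]))
    elen <- c(elen, w[i])
  }
  pw <- stats::setNames(rep(0, n), leaves)
  for (i in which(singleton)) pw[clus[[i]][1]] <- w[i]
  for (x in seq_len(n)) {
    members <- leaves[x]
    # smallest non-singleton cluster containing the leaf
    p <- n + 1L
    for (j in rev(seq_along(clus))) {
      if (!singleton[j] && members %in% clus[[j]]) { p <- node_id[j]; break }
    }
    edges <- rbind(edges, c(p, x))
    elen <- c(elen, pw[x])
  }
  tree <- structure(list(edge = edges, Nnode = 1L + length(nonsing),
                         tip.label = leaves, edge.length = elen,
                         root.edge = stem),
                    class = "phylo", order = NULL)
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(success = TRUE, tree = tree)
}

# ---- stochastic gain/loss model ------------------------------------------

#' Simulate feature gain and loss along a tree
#'
#' New features arise along every edge as a Poisson process with rate `r`
#' per unit time (each feature arises exactly once in the tree); every
#' feature copy is lost independently at rate `nu` on each branch, and a
#' loss removes the feature from that branch's entire descendant subtree
#' while copies on sibling branches persist. The stem edge (`root.edge`,
#' length 0 when absent) is included, with `F0` features present at its top.
#'
#' @param tree a `phylo` with edge lengths.
#' @param r gain rate (> 0) per unit time per lineage.
#' @param nu loss rate (>= 0) per feature per lineage.
#' @param F0 number of features present at the start of the stem.
#' @param seed optional integer seed.
#' @return A [feature_assignment()] of the features present at the leaves
#'   (unit weights), with attributes `gains` (data frame: feature, edge --
#'   0 for the stem --, position from the top of the edge) and `losses`
#'   (data frame: feature, edge on which that copy was lost).
#' @export
simulate_gain_loss <- function(tree, r, nu, F0 = 0, seed = NULL) {
  stopifnot(r > 0, nu >= 0, F0 >= 0)
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  gains <- list(); losses <- list()
  next_id <- 0L
  new_ids <- function(k) if (k > 0) next_id + seq_len(k) else integer(0)
  # stem edge first
  stem_len <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  at_node <- vector("list", nn)
  res <- .gl_edge(seq_len(F0), stem_len, r, nu, next_id)
  next_id <- res$next_id
  if (nrow(res$gains)) gains[[length(gains) + 1L]] <-
    cbind(edge = 0L, res$gains)
  if (length(res$lost)) losses[[length(losses) + 1L]] <-
    data.frame(feature = res$lost, edge = 0L)
  at_node[[n + 1L]] <- res$bottom
  eo_idx <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  for (i in eo_idx) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    res <- .gl_edge(at_node[[p]], tree$edge.length[i], r, nu, next_id)
    next_id <- res$next_id
    if (nrow(res$gains)) gains[[length(gains) + 1L]] <-
      cbind(edge = i, res$gains)
    if (length(res$lost)) losses[[length(losses) + 1L]] <-
      data.frame(feature = res$lost, edge = i)
    at_node[[ch]] <- res$bottom
  }
  feats <- stats::setNames(lapply(seq_len(n), function(x)
    as.character(at_node[[x]])), tree$tip.label)
  all_ids <- as.character(seq_len(next_id))
  fa <- feature_assignment(feats,
                           stats::setNames(rep(1, next_id), all_ids))
  attr(fa, "gains") <- if (length(gains)) do.call(rbind, gains)[
    , c("feature", "edge", "position")] else
      data.frame(feature = integer(0), edge = integer(0),
                 position = numeric(0))
  attr(fa, "losses") <- if (length(losses)) do.call(rbind, losses) else
    data.frame(feature = integer(0), edge = integer(0))
  fa
}

# one edge of the gain/loss process: thin incoming features, add newborns
.gl_edge <- function(incoming, len, r, nu, next_id) {
  lost <- integer(0)
  if (len > 0 && nu > 0 && length(incoming)) {
    gone <- stats::runif(length(incoming)) >= exp(-nu * len)
    lost <- incoming[gone]
    incoming <- incoming[!gone]
  }
  k <- if (len > 0) stats::rpois(1L, r * len) else 0L
  if (k > 0) {
    ids <- next_id + seq_len(k)
    next_id <- next_id + k
    pos <- stats::runif(k) * len
    kept <- if (nu > 0) stats::runif(k) < exp(-nu * (len - pos))
            else rep(TRUE, k)
    lost <- c(lost, ids[!kept])
    bottom <- c(incoming, ids[kept])
    gains <- data.frame(feature = ids, position = pos)
  } else {
    bottom <- incoming
    gains <- data.frame(feature = integer(0), position = numeric(0))
  }
  list(bottom = bottom, lost = lost, gains = gains, next_id = next_id)
}

# ---- expected FD ----------------------------------------------------------

# absence probabilities: q[v] = P(no leaf of Y below v retains a feature
# known to be present at v); under FOB marginalization with survival s the
# leaf base case is 1 - s instead of the Y indicator
.fd_absence <- function(tree, nu, Y = NULL, s = NULL) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  q <- numeric(nn)
  if (!is.null(s)) {
    q[seq_len(n)] <- 1 - s
  } else {
    q[seq_len(n)] <- 1
    q[.tip_index(tree, Y)] <- 0
  }
  if (tree$Nnode > 0) q[(n + 1):nn] <- 1
  eo_idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (i in eo_idx) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    surv <- exp(-nu * tree$edge.length[i])
    q[p] <- q[p] * (surv * q[ch] + 1 - surv)
  }
  q
}

# expected number of features arising on an edge of length len that are
# still present at its bottom
.gain_surviving <- function(r, nu, len) {
  # series branch keeps the nu -> 0 limit r*len numerically continuous
  small <- nu == 0 | nu * len < 1e-8
  ifelse(small, r * len * (1 - nu * len / 2),
         r * (1 - exp(-nu * pmax(len, 0))) / max(nu, .Machine$double.xmin))
}

#' Expected feature diversity under the gain/loss model
#'
#' Exact expectation of FD(Y) (unit feature weights) under the stochastic
#' gain/loss model: for every edge, the expected number of features that
#' arise on it and are still present at its bottom is r(1 - e^(-nu l))/nu,
#' and each such feature reaches at least one leaf of Y with probability
#' 1 - q(bottom), where the absence probabilities q satisfy the recursion
#' q(leaf) = 0 or 1 (membership of Y), and
#' q(v) = prod over child edges of `e^(-nu l) q(child) + 1 - e^(-nu l)`.
#' Setting `s` marginalizes over a field-of-bullets draw instead of a fixed
#' subset (leaf base case 1 - s). The stem edge and the `F0` features at its
#' top are included.
#'
#' @param tree a `phylo` with edge lengths.
#' @param r,nu gain and loss rates (`r > 0`, `nu >= 0`).
#' @param Y subset of leaf labels (default all leaves).
#' @param s optional FOB survival probability replacing `Y`.
#' @param F0 features present at the top of the stem.
#' @return Expected FD (a number).
#' @export
expected_fd <- function(tree, r, nu, Y = NULL, s = NULL, F0 = 0) {
  stopifnot(r > 0, nu >= 0, F0 >= 0)
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  if (is.null(Y) && is.null(s)) Y <- tree$tip.label
  q <- .fd_absence(tree, nu, Y, s)
  n <- length(tree$tip.label)
  tot <- sum(.gain_surviving(r, nu, tree$edge.length) *
               (1 - q[tree$edge[, 2]]))
  stem_len <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  root_q <- q[n + 1L]
  if (stem_len > 0)
    tot <- tot + .gain_surviving(r, nu, stem_len) * (1 - root_q)
  if (F0 > 0)
    tot <- tot + F0 * exp(-nu * stem_len) * (1 - root_q)
  tot
}

#' Expected-feature edge lengths
#'
#' For each edge e, the expected number of features that arise on e and are
#' present in at least one leaf of the tree:
#' l'(e) = r (1 - e^(-nu l_e))/nu (1 - q(bottom(e))) with q computed for
#' Y = X. These lengths sum to the expected FD of the whole leaf set and
#' turn the tree into the PD proxy used to bound expected FD loss.
#'
#' @inheritParams expected_fd
#' @return List with `edge_lengths` (per edge of `tree`), `stem` (the stem
#'   edge value) and `total`.
#' @export
edge_feature_lengths <- function(tree, r, nu) {
  stopifnot(r > 0, nu >= 0)
  q <- .fd_absence(tree, nu, Y = tree$tip.label)
  lens <- .gain_surviving(r, nu, tree$edge.length) * (1 - q[tree$edge[, 2]])
  stem_len <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  n <- length(tree$tip.label)
  stem <- if (stem_len > 0)
    .gain_surviving(r, nu, stem_len) * (1 - q[n + 1L]) else 0
  list(edge_lengths = lens, stem = stem, total = sum(lens) + stem)
}

#' Expected FD loss versus its PD proxy
#'
#' Compares the expected proportion of feature diversity surviving a
#' field-of-bullets event (per-species survival s) with the corresponding
#' PD proportion computed on the same tree re-weighted by the
#' expected-feature lengths l'. The FD proportion never exceeds the PD
#' proportion; equality holds at s in {0, 1} and on star trees.
#'
#' @inheritParams expected_fd
#' @param s FOB survival probability in `[0, 1]`.
#' @return List with `fd_ratio`, `pd_ratio`, `gap` (`pd_ratio - fd_ratio`,
#'   >= 0).
#' @export
fd_pd_proxy_gap <- function(tree, r, nu, s) {
  stopifnot(s >= 0, s <= 1)
  efd_x <- expected_fd(tree, r, nu, Y = tree$tip.label)
  efd_s <- expected_fd(tree, r, nu, s = s)
  lhs <- if (efd_x > 0) efd_s / efd_x else 1
  ef <- edge_feature_lengths(tree, r, nu)
  cnt <- .clade_sizes(tree)
  ne <- cnt[tree$edge[, 2]]
  n <- length(tree$tip.label)
  num <- sum(ef$edge_lengths * (1 - (1 - s)^ne)) +
    ef$stem * (1 - (1 - s)^n)
  rhs <- if (ef$total > 0) num / ef$total else 1
  list(fd_ratio = lhs, pd_ratio = rhs, gap = rhs - lhs)
}
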