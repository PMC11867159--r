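# Clade / path / depth queries on rooted `phylo` trees, plus internal
# traversal helpers shared by the model code.  Node numbering follows ape:
# tips 1..n, root n+1, interior nodes n+1..n+Nnode.

#' Parent vector of a rooted tree
#'
#' @param tree a `phylo` object.
#' @return Integer vector `p` with `p[v]` the parent node of `v` (0 for the
#'   root).
#' @export
tree_parents <- function(tree) {
  p <- integer(length(tree$tip.label) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# children list indexed by node
.tree_children <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nn)))
}

# edge row index keyed by child node (0 when the node is the root)
.edge_of_child <- function(tree) {
  idx <- integer(length(tree$tip.label) + tree$Nnode)
  idx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  idx
}

# per-node count of descendant tips (tips count themselves), via one
# postorder pass
.clade_sizes <- function(tree) {
  n <- length(tree$tip.label)
  cnt <- c(rep(1L, n), rep(0L, tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge)))
    cnt[eo$edge[i, 1]] <- cnt[eo$edge[i, 1]] + cnt[eo$edge[i, 2]]
  cnt
}

# per-node accumulation of arbitrary tip values (sum over descendant tips)
.clade_tip_sums <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  acc <- c(tip_values, rep(0, tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge)))
    acc[eo$edge[i, 1]] <- acc[eo$edge[i, 1]] + acc[eo$edge[i, 2]]
  acc
}

# per-node product of tip values over descendant tips
.clade_tip_products <- function(tree, tip_values) {
  n <- length(tree$tip.label)
  acc <- c(tip_values, rep(1, tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge)))
    acc[eo$edge[i, 1]] <- acc[eo$edge[i, 1]] * acc[eo$edge[i, 2]]
  acc
}

.tip_index <- function(tree, labels) {
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx))
    stop("unknown leaf label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Leaves descended from an edge
#'
#' Returns the clade `C(e)`: the set of leaf labels below edge `e`.
#'
#' @param tree a `phylo` object.
#' @param edge edge index (row number of `tree$edge`).
#' @return Character vector of leaf labels.
#' @examples
#' tr <- read_newick("((a,b),c);")
#' # the edge whose child subtree holds a and b:
#' e <- which(tr$edge[, 2] > ape::Ntip(tr))
#' clade(tr, e)
#' @export
clade <- function(tree, edge) {
  if (length(edge) != 1 || edge < 1 || edge > nrow(tree$edge))
    stop("unknown edge index: ", edge)
  n <- length(tree$tip.label)
  node <- tree$edge[edge, 2]
  if (node <= n) return(tree$tip.label[node])
  kids <- .tree_children(tree)
  tips <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- kids[[v]]
    tips <- c(tips, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  tree$tip.label[sort(tips)]
}

#' Root-to-leaf path
#'
#' Edges on the path from the root down to a leaf (`P(x)`), the sets over
#' which PD indices and the extinction-risk index psi are summed.
#'
#' @param tree a `phylo` object.
#' @param leaf a leaf label.
#' @return Integer vector of edge indices, ordered root to leaf. The stem
#'   edge, when present, is not part of the path.
#' @export
path_to_leaf <- function(tree, leaf) {
  x <- .tip_index(tree, leaf[1])
  parent <- tree_parents(tree)
  eidx <- .edge_of_child(tree)
  path <- integer(0)
  v <- x
  while (parent[v] != 0L) {
    path <- c(eidx[v], path)
    v <- parent[v]
  }
  path
}

#' Depth of a leaf
#'
#' Number of edges between the root and the leaf (stem edge excluded).
#'
#' @inheritParams path_to_leaf
#' @return Integer depth.
#' @export
leaf_depth <- function(tree, leaf) {
  length(path_to_leaf(tree, leaf))
}

# depths of all nodes (root = 0), one preorder pass
.node_depths <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  d <- integer(nn)
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(eo$edge))))
    d[eo$edge[i, 2]] <- d[eo$edge[i, 1]] + 1L
  d
}

#' Total edge length of a tree
#'
#' @param tree a `phylo` with edge lengths.
#' @param include_stem include the stem (`root.edge`) length.
#' @return Sum of edge lengths.
#' @export
total_length <- function(tree, include_stem = FALSE) {
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  s <- sum(tree$edge.length)
  if (include_stem && !is.null(tree$root.edge)) s <- s + tree$root.edge
  s
}

#' Classify edges of a rooted tree
#'
#' @param tree a `phylo` object.
#' @return Data frame with one row per edge: `edge` (index), `pendant`
#'   (ends at a leaf), `root_child` (starts at the root), and `length`
#'   (`NA` if absent).
#' @export
edge_classes <- function(tree) {
  n <- length(tree$tip.label)
  data.frame(
    edge = seq_len(nrow(tree$edge)),
    pendant = tree$edge[, 2] <= n,
    root_child = tree$edge[, 1] == n + 1L,
    length = if (is.null(tree$edge.length)) NA_real_ else tree$edge.length
  )
}
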