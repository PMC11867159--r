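# Unlabeled rooted binary tree shapes in canonical form.
#
# The canonical encoding is built bottom-up: a leaf encodes as "*", an
# interior vertex as "(A,B)" with the two child encodings in lexicographic
# order.  Two shapes are isomorphic iff their encodings are equal.  A vertex
# whose two child encodings are equal is a symmetry vertex; s(tau) counts
# them (the root included).  n_tau(v) is the number of leaves below interior
# vertex v minus one; together s(tau) and the n_tau(v) values determine the
# Yule-Harding probability of the shape.

.new_shape <- function(encoding, n, s, ntau) {
  structure(list(encoding = encoding, n = n, s = s, ntau = sort(ntau)),
            class = "tree_shape")
}

.shape_leaf <- .new_shape("*", 1L, 0L, integer(0))

.shape_join <- function(a, b) {
  enc <- if (a$encoding <= b$encoding)
    paste0("(", a$encoding, ",", b$encoding, ")")
  else
    paste0("(", b$encoding, ",", a$encoding, ")")
  .new_shape(enc, a$n + b$n,
             a$s + b$s + (a$encoding == b$encoding),
             c(a$ntau, b$ntau, a$n + b$n - 1L))
}

#' Canonical shape of a binary tree
#'
#' Drops leaf labels and edge lengths and returns the canonical form of the
#' resulting rooted binary tree shape. The encoding is invariant under leaf
#' relabeling and child reordering, and two trees have the same shape iff
#' their encodings are equal.
#'
#' @param tree a binary `phylo` object (or a single leaf).
#' @return An object of class `"tree_shape"`: list with `encoding`
#'   (canonical string), `n` (leaf count), `s` (number of symmetry vertices,
#'   root included when its two child subtrees are isomorphic) and `ntau`
#'   (sorted vector of descendant-leaf counts minus 1, one per interior
#'   vertex).
#' @examples
#' sh <- shape_of(read_newick("((a,b),c);"))
#' sh$s    # 1: the cherry is a symmetry vertex
#' sh$ntau # 1 2
#' @export
shape_of <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n == 1L) return(.shape_leaf)
  outdeg <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  if (any(outdeg[(n + 1):(n + tree$Nnode)] != 2L))
    stop("shape_of() supports binary trees only")
  nn <- n + tree$Nnode
  shp <- vector("list", nn)
  for (v in seq_len(n)) shp[[v]] <- .shape_leaf
  eo <- ape::reorder.phylo(tree, "postorder")
  # children appear before parents in postorder edge order
  kids <- vector("list", nn)
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    kids[[p]] <- c(kids[[p]], ch)
    if (length(kids[[p]]) == 2L)
      shp[[p]] <- .shape_join(shp[[kids[[p]][1]]], shp[[kids[[p]][2]]])
  }
  shp[[n + 1L]]
}

#' @export
format.tree_shape <- function(x, ...) {
  sprintf("tree shape: n = %d, s = %d, encoding %s", x$n, x$s, x$encoding)
}

#' @export
print.tree_shape <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`==.tree_shape` <- function(e1, e2) e1$encoding == e2$encoding

#' Newick form of a shape
#'
#' Serializes a shape as Newick with empty leaf labels, readable back by any
#' Newick parser.
#'
#' @param shape a `tree_shape`.
#' @return A Newick string such as `"((,),);"`.
#' @export
shape_as_newick <- function(shape) {
  s <- gsub("*", "", shape$encoding, fixed = TRUE)
  paste0(s, ";")
}

#' Shape statistics
#'
#' @param shape a `tree_shape`.
#' @param json if `TRUE`, return a JSON string (requires jsonlite).
#' @return List (or JSON) with `n`, `s` and the `ntau` multiset.
#' @export
shape_stats <- function(shape, json = FALSE) {
  out <- list(n = shape$n, s = shape$s, ntau = shape$ntau)
  if (json) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite needed for JSON output")
    return(jsonlite::toJSON(out, auto_unbox = TRUE))
  }
  out
}

#' Enumerate all binary tree shapes on n leaves
#'
#' All distinct rooted binary shapes, generated by the classical
#' pair-combination recursion; the counts are the Wedderburn-Etherington
#' numbers (1, 1, 1, 2, 3, 6, 11, ... for n = 1, 2, 3, ...).
#'
#' @param n leaf count, 1 to 20.
#' @return List of `tree_shape` objects, no duplicates.
#' @examples
#' length(enumerate_shapes(5)) # 3
#' @export
enumerate_shapes <- function(n) {
  if (length(n) != 1 || n < 1 || n > 20)
    stop("n must be a single integer in 1..20")
  n <- as.integer(n)
  memo <- vector("list", n)
  memo[[1]] <- list(.shape_leaf)
  for (m in seq_len(n)[-1]) {
    out <- list()
    for (a in seq_len(m %/% 2)) {
      b <- m - a
      A <- memo[[a]]; B <- memo[[b]]
      if (a < b) {
        for (x in A) for (y in B) out[[length(out) + 1L]] <- .shape_join(x, y)
      } else { # a == b: unordered pairs including equal pair
        for (i in seq_along(A)) for (j in i:length(A))
          out[[length(out) + 1L]] <- .shape_join(A[[i]], A[[j]])
      }
    }
    memo[[m]] <- out
  }
  memo[[n]]
}

#' Enumerate all rooted binary phylogenetic trees on a label set
#'
#' Generates every rooted binary tree with the given leaf labels by
#' sequential insertion (each new leaf attached above every subtree of every
#' smaller tree). The total count is the double factorial (2n-3)!!, and the
#' number of trees with a given shape tau is n!/2^s(tau).
#'
#' @param labels character vector of 2 to 8 distinct leaf labels.
#' @return A `multiPhylo` list of trees (no edge lengths).
#' @examples
#' length(enumerate_labeled_trees(c("a", "b", "c"))) # 3
#' @export
enumerate_labeled_trees <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2 || n > 8)
    stop("supported for 2 <= n <= 8 labels (combinatorial explosion beyond)")
  if (anyDuplicated(labels)) stop("labels must be distinct")
  trees <- list(list(labels[1], labels[2]))
  for (k in seq_len(n)[-(1:2)]) {
    nxt <- list()
    for (tr in trees)
      nxt <- c(nxt, .insert_everywhere(tr, labels[k]))
    trees <- nxt
  }
  txt <- paste(vapply(trees, .nested_newick, ""), collapse = "")
  out <- ape::read.tree(text = txt)
  if (inherits(out, "phylo")) out <- structure(list(out), class = "multiPhylo")
  out
}

# attach `lab` above every subtree of nested tree `tr` (a leaf label or a
# two-element list); attaching above the whole tree creates a new root
.insert_everywhere <- function(tr, lab) {
  res <- list(list(tr, lab))
  if (is.list(tr)) {
    for (x in .insert_everywhere(tr[[1]], lab))
      res[[length(res) + 1L]] <- list(x, tr[[2]])
    for (y in .insert_everywhere(tr[[2]], lab))
      res[[length(res) + 1L]] <- list(tr[[1]], y)
  }
  res
}

.nested_newick <- function(tr) {
  rec <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", rec(x[[1]]), ",", rec(x[[2]]), ")")
  }
  paste0(rec(tr), ";")
}

#' Wedderburn-Etherington counts
#'
#' Number of rooted binary tree shapes on n leaves, by the recursion implied
#' by the generating-function identity f(x) = x + (f(x)^2 + f(x^2))/2.
#'
#' @param n maximal leaf count.
#' @return Vector `w` with `w[m]` the number of shapes on `m` leaves.
#' @export
wedderburn_etherington <- function(n) {
  w <- numeric(n)
  w[1] <- 1
  for (m in seq_len(n)[-1]) {
    tot <- 0
    for (a in seq_len(m %/% 2)) {
      b <- m - a
      tot <- tot + if (a < b) w[a] * w[b] else w[a] * (w[a] + 1) / 2
    }
    w[m] <- tot
  }
  w
}
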