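#' Read a rooted phylogenetic tree from Newick text
#'
#' Thin wrapper around [ape::read.tree()] that adds the validation this
#' package's model code relies on: unique non-empty leaf labels, strictly
#' positive stored edge lengths, and (optionally) a fully binary topology.
#' A branch length attached to the outermost group is kept as the stem edge
#' (`root.edge` in the `phylo` object); the stem is excluded from diversity
#' computations by default throughout the package.
#'
#' @param text a Newick string (exactly one tree), or `NULL` if `file` given.
#' @param file path to a Newick file, read if `text` is `NULL`.
#' @param binary if `TRUE`, require every interior vertex to have out-degree
#'   exactly 2; otherwise out-degrees >= 2 are accepted (multifurcating input
#'   parses, but shape/probability operations will refuse it).
#' @return A validated `phylo` object (rooted; edges directed away from the
#'   root).
#' @examples
#' tr <- read_newick("((a:1,b:1):1,c:2);")
#' pd(tr, c("a", "b", "c")) # 5
#' @seealso [write_newick()], [validate_tree()]
#' @export
read_newick <- function(text = NULL, file = NULL, binary = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply Newick `text` or a `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  .check_parens(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  if (inherits(tree, "multiPhylo"))
    stop("expected a single Newick tree, found ", length(tree))
  validate_tree(tree, binary = binary)
}

.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  invisible(TRUE)
}

#' Validate the package's rooted-tree invariants
#'
#' Checks that leaf labels are unique and non-empty, that all stored edge
#' lengths are strictly positive, that parent/child pointers are consistent
#' (every node reachable from the root exactly once) and, if `binary = TRUE`,
#' that all interior vertices have out-degree 2.
#'
#' @param tree a `phylo` object.
#' @param binary require a binary tree.
#' @return `tree`, invisibly unchanged, or an error.
#' @export
validate_tree <- function(tree, binary = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  if (anyDuplicated(lab))
    stop("duplicate leaf label(s): ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  if (any(!nzchar(lab))) stop("empty leaf label")
  if (!is.null(tree$edge.length)) {
    bad <- which(!(tree$edge.length > 0))
    if (length(bad))
      stop("non-positive length on edge(s) ending at node(s) ",
           paste(tree$edge[bad, 2], collapse = ", "))
    if (!is.null(tree$root.edge) && !(tree$root.edge > 0))
      stop("non-positive stem (root) edge length")
  }
  n <- length(lab)
  parent <- tree_parents(tree)
  root <- n + 1L
  if (sum(parent == 0L) != 1L || parent[root] != 0L)
    stop("tree must have a unique root at node n+1")
  # each non-root node must appear exactly once as a child
  if (nrow(tree$edge) != n + tree$Nnode - 1L ||
      anyDuplicated(tree$edge[, 2]))
    stop("inconsistent parent/child structure")
  outdeg <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  if (any(outdeg[(n + 1):(n + tree$Nnode)] < 2L))
    stop("interior vertex with out-degree < 2 (unresolved unary node)")
  if (binary && any(outdeg > 2L))
    stop("tree is not binary (out-degree > 2 found)")
  invisible(tree)
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object; a stem edge (`root.edge`) is written as a
#'   branch length on the outermost group.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}
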