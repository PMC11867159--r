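# Worked-example fixtures and seeded random-tree generators used by the
# examples, the command-line interface and the test suite.

#' Harding's five-leaf example tree
#'
#' The classic rooted binary tree on five leaves from Harding's 1971 study
#' of tree-shape probabilities: the root splits 4 + 1 and the four-leaf
#' subtree is two cherries. Its shape has three symmetry vertices, shape
#' probability 1/6 under the Yule-Harding distribution, and the labelled
#' tree has probability 1/90.
#'
#' @return A `phylo` with leaves a..e (no edge lengths).
#' @examples
#' format(yh_shape_probability(harding_tree())) # "1/6"
#' @export
harding_tree <- function() {
  read_newick("(((a,b),(c,d)),e);", binary = TRUE)
}

#' A worked feature gain/loss extinction scenario
#'
#' A small synthetic arrangement of five features on six species, three of
#' which die in a rapid extinction event, chosen so that exactly three of
#' the five features survive: the surviving-feature ratio is 3/5 = 0.6.
#' (The arrangement reproduces the published counts of the classic
#' illustration of feature loss under a field-of-bullets event; the exact
#' branch placement of gains and losses is not part of the fixture.)
#'
#' @return A list: `tree` (six-leaf ultrametric `phylo`), `assignment`
#'   (a [feature_assignment()] of features alpha..epsilon), `extinct`
#'   (labels of the three leaves that die), `survivors` (the rest).
#' @examples
#' ex <- feature_loss_example()
#' fd(ex$assignment, ex$survivors) / fd(ex$assignment, names(ex$assignment$features))
#' @export
feature_loss_example <- function() {
  tree <- read_newick(
    "(((L1:1,L2:1):2,(L3:2,L4:2):1):1,(L5:3,L6:3):1);", binary = TRUE)
  assignment <- feature_assignment(list(
    L1 = c("alpha"),
    L2 = c("delta"),
    L3 = c("beta", "gamma"),
    L4 = c("epsilon"),
    L5 = c("gamma"),
    L6 = c("epsilon")))
  extinct <- c("L2", "L4", "L6")
  list(tree = tree, assignment = assignment, extinct = extinct,
       survivors = setdiff(tree$tip.label, extinct))
}

#' Seeded random trees
#'
#' Convenience generator for the three families of random trees used
#' throughout: discrete Yule-Harding shapes, uniform (PDA) trees, and
#' birth-death trees with edge lengths.
#'
#' @param kind `"yh"`, `"pda"`, or `"bd"`.
#' @param n leaf count (`"yh"`/`"pda"`), or target leaf count for `"bd"`
#'   (simulated with `condition = "fixed_n"`).
#' @param seed integer seed (required: fixtures are reproducible).
#' @param lambda,mu birth-death rates for `kind = "bd"`.
#' @return A `phylo`; birth-death trees carry edge lengths and a stem.
#' @export
random_tree <- function(kind = c("yh", "pda", "bd"), n, seed,
                        lambda = 1, mu = 0) {
  kind <- match.arg(kind)
  switch(kind,
         yh = yh_sample(n, seed = seed),
         pda = pda_sample(n, seed = seed),
         bd = reduce_tree(simulate_bd(lambda, mu, n_leaves = n,
                                      condition = "fixed_n", seed = seed)))
}

#' Random edge lengths for discrete trees
#'
#' Attaches independent uniform edge lengths to a discrete tree, for tests
#' and examples that need arbitrary positive lengths rather than
#' birth-death times.
#'
#' @param tree a `phylo` without (or with) edge lengths.
#' @param seed optional integer seed.
#' @param min,max range of the uniform lengths.
#' @return The tree with `edge.length` set.
#' @export
with_random_lengths <- function(tree, seed = NULL, min = 0.1, max = 1) {
  if (!is.null(seed)) set.seed(seed)
  tree$edge.length <- stats::runif(nrow(tree$edge), min, max)
  tree
}
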