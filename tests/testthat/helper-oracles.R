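# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's analytic code paths: they enumerate histories, subsets
# or extinction outcomes directly.

# --- exhaustive enumeration of the discrete YH attachment process ---------
# Returns the exact joint distribution of (plain depth, evolutionary depth)
# of a uniformly chosen leaf after growing to n leaves: every history is a
# sequence of leaf choices (and one initial offspring designation), all
# equally likely.  Attaching to leaf x pushes x one level down and adds the
# new leaf beside it; the attached leaf is the designated offspring.
yh_history_depth_oracle <- function(n) {
  acc <- new.env(parent = emptyenv())
  acc$tab <- list()
  add <- function(key, w) {
    acc$tab[[key]] <- (if (is.null(acc$tab[[key]])) 0 else acc$tab[[key]]) + w
  }
  recurse <- function(depth, evo, w) {
    k <- length(depth)
    if (k == n) {
      for (i in seq_len(k)) add(paste(depth[i], evo[i]), w / k)
      return(invisible())
    }
    for (x in seq_len(k)) {
      d2 <- depth; e2 <- evo
      d2[x] <- d2[x] + 1L
      d2 <- c(d2, d2[x])
      e2 <- c(e2, e2[x] + 1L)
      recurse(d2, e2, w / k)
    }
  }
  # two equally likely initial offspring designations at the root
  recurse(c(1L, 1L), c(0L, 1L), 0.5)
  recurse(c(1L, 1L), c(1L, 0L), 0.5)
  keys <- names(acc$tab)
  parts <- do.call(rbind, strsplit(keys, " "))
  data.frame(depth = as.integer(parts[, 1]), evo = as.integer(parts[, 2]),
             prob = unlist(acc$tab, use.names = FALSE))
}

# marginal law of one of the two columns of the oracle
oracle_marginal <- function(orc, what = c("depth", "evo")) {
  what <- match.arg(what)
  tapply(orc$prob, orc[[what]], sum)
}

# --- subsets of a label vector as a list ----------------------------------
all_subsets <- function(labs, include_empty = FALSE) {
  n <- length(labs)
  out <- lapply(seq_len(2^n - 1), function(m)
    labs[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  if (include_empty) out <- c(list(character(0)), out)
  out
}

# --- exhaustive field-of-bullets expectation oracles ----------------------
# expectation of f(survivor set) over all 2^n extinction outcomes with
# per-leaf extinction probabilities eps (named)
fob_expectation_oracle <- function(labs, eps, f) {
  n <- length(labs)
  tot <- 0
  for (m in 0:(2^n - 1)) {
    alive <- bitwAnd(m, 2^(seq_len(n) - 1)) > 0
    p <- prod(ifelse(alive, 1 - eps, eps))
    tot <- tot + p * f(labs[alive])
  }
  tot
}

# --- independent recursive isomorphism check for binary rooted trees ------
# works on nested list structures extracted from a phylo, with no reference
# to the canonical-encoding code
phylo_to_nested <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(v) {
    if (v <= n) return("leaf")
    lapply(kids[[as.character(v)]], rec)
  }
  rec(n + 1L)
}

nested_isomorphic <- function(a, b) {
  if (is.character(a) || is.character(b))
    return(is.character(a) && is.character(b))
  if (length(a) != length(b)) return(FALSE)
  # try matching children of a to children of b (binary: two orders)
  used <- logical(length(b))
  for (x in a) {
    hit <- FALSE
    for (j in seq_along(b)) {
      if (!used[j] && nested_isomorphic(x, b[[j]])) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# double factorial (2n-3)!!
double_factorial_odd <- function(n) prod(seq(1, 2 * n - 3, by = 2))

# number of cycles of a permutation (for the Stirling enumeration oracle)
perm_cycles <- function(p) {
  seen <- logical(length(p))
  cyc <- 0L
  for (i in seq_along(p)) {
    if (!seen[i]) {
      cyc <- cyc + 1L
      j <- i
      while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
    }
  }
  cyc
}
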