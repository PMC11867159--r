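# Constant-rate (and hook-extensible neutral) birth-death simulation.
#
# A realization keeps the full history as "segments": a segment is a maximal
# lineage interval between its birth (at a split, or time 0 for the origin)
# and its end (split, death, or the sampling time).  The complete, reduced
# and evolutionary views are all derived from the same segment arrays.  At
# each split exactly one of the two daughter segments carries the designated
# new-species ("offspring") flag, drawn uniformly, which is what the
# evolutionary views read.

#' Simulate a birth-death tree realization
#'
#' Exact stochastic simulation of a linear birth-death process starting from
#' a single lineage at time 0: each extant lineage independently splits at
#' rate `lambda` and dies at rate `mu`; when an event occurs the lineage
#' involved is chosen uniformly (the neutrality contract). Optional rate
#' hooks make the rates depend on time and the current lineage count while
#' preserving that per-lineage uniformity.
#'
#' Conditioning: `"none"` runs to `duration` (possibly extinct);
#' `"survival"` rejects realizations extinct at `duration`; `"fixed_n"`
#' (requires `n_leaves`) runs until the moment the leaf count would first
#' change from `n_leaves` to `n_leaves + 1` and samples just before that
#' split, rejecting realizations that die out first.
#'
#' @param lambda birth rate per lineage per unit time (> 0), or the cap used
#'   for thinning when `birth_rate_fn` is given.
#' @param mu death rate per lineage (>= 0), or the cap when `death_rate_fn`
#'   is given.
#' @param duration total time `t` (required unless `condition = "fixed_n"`).
#' @param n_leaves target leaf count for `condition = "fixed_n"`.
#' @param condition one of `"none"`, `"survival"`, `"fixed_n"`.
#' @param seed optional integer seed.
#' @param birth_rate_fn,death_rate_fn optional hooks `f(time, k)` giving the
#'   per-lineage rate at `time` with `k` extant lineages; must be bounded by
#'   `lambda` (resp. `mu`), which are then used as thinning caps.
#' @param max_tries rejection-sampling cap before giving up with an error.
#' @return An object of class `"bd_realization"`: segment arrays `parent`,
#'   `birth`, `end`, `status` (0 extant, 1 extinct, 2 split), `offspring`
#'   (designated new-species flag), plus `age` (sampling time), `n_extant`,
#'   and the parameters.
#' @examples
#' r <- simulate_bd(lambda = 1, duration = 2, condition = "survival", seed = 1)
#' r$n_extant
#' @export
simulate_bd <- function(lambda, mu = 0, duration = NULL, n_leaves = NULL,
                        condition = c("none", "survival", "fixed_n"),
                        seed = NULL, birth_rate_fn = NULL,
                        death_rate_fn = NULL, max_tries = 10000L) {
  condition <- match.arg(condition)
  stopifnot(lambda > 0, mu >= 0)
  if (condition == "fixed_n") {
    if (is.null(n_leaves) || n_leaves < 1) stop("fixed_n needs n_leaves >= 1")
  } else if (is.null(duration) || duration <= 0) {
    stop("duration > 0 required unless condition = 'fixed_n'")
  }
  if (!is.null(seed)) set.seed(seed)
  pure_yule <- mu == 0 && is.null(birth_rate_fn) && is.null(death_rate_fn)
  for (try in seq_len(max_tries)) {
    out <- if (pure_yule)
      .yule_once(lambda, duration, n_leaves, condition)
    else
      .bd_once(lambda, mu, duration, n_leaves, condition,
               birth_rate_fn, death_rate_fn)
    if (!is.null(out)) {
      out$params <- list(lambda = lambda, mu = mu, duration = duration,
                         n_leaves = n_leaves, condition = condition)
      return(out)
    }
  }
  stop("conditioning failed after ", max_tries, " attempts; ",
       "the requested condition is too unlikely under these rates")
}

# fast path for the pure Yule process (mu = 0, constant rate): event times
# and lineage choices are pre-generated in vectors, and only the segment
# bookkeeping runs in a loop
.yule_once <- function(lambda, duration, n_leaves, condition) {
  if (condition == "fixed_n") {
    nev <- n_leaves # events 1..n-1 are splits; event n sets the sample time
    times <- cumsum(stats::rexp(nev, lambda * seq_len(nev)))
    age <- times[nev]
    nsplit <- nev - 1L
  } else {
    # number of splits before `duration` is not known in advance: draw
    # waiting times in blocks until the cumulative time exceeds duration
    times <- numeric(0)
    total <- 0
    k0 <- 1L
    repeat {
      block <- stats::rexp(256L, lambda * (k0 + 0:255))
      cs <- total + cumsum(block)
      over <- which(cs > duration)
      if (length(over)) {
        times <- c(times, cs[seq_len(over[1] - 1L)])
        break
      }
      times <- c(times, cs)
      total <- cs[256L]
      k0 <- k0 + 256L
    }
    age <- duration
    nsplit <- length(times)
  }
  nseg <- 2L * nsplit + 1L
  parent <- integer(nseg); birth <- numeric(nseg); end <- numeric(nseg)
  status <- integer(nseg); offspring <- logical(nseg)
  cur <- integer(nsplit + 1L) # current segment of lineage j
  cur[1] <- 1L
  if (nsplit > 0L) {
    picks <- 1L + floor(stats::runif(nsplit) * seq_len(nsplit))
    offfirst <- stats::runif(nsplit) < 0.5
    nxt <- 2L
    for (ev in seq_len(nsplit)) {
      j <- picks[ev]
      v <- cur[j]
      end[v] <- times[ev]; status[v] <- 2L
      c1 <- nxt; c2 <- nxt + 1L; nxt <- nxt + 2L
      parent[c1] <- v; parent[c2] <- v
      birth[c1] <- times[ev]; birth[c2] <- times[ev]
      offspring[if (offfirst[ev]) c1 else c2] <- TRUE
      cur[j] <- c1
      cur[ev + 1L] <- c2
    }
  }
  leaves <- cur[seq_len(nsplit + 1L)]
  end[leaves] <- age
  status[leaves] <- 0L
  .bd_pack(parent, birth, end, status, offspring, nseg, age = age,
           n_extant = nsplit + 1L)
}

.bd_once <- function(lambda, mu, duration, n_leaves, condition,
                     birth_rate_fn, death_rate_fn) {
  cap <- 1024L
  parent <- integer(cap); birth <- numeric(cap); end <- numeric(cap)
  status <- integer(cap); offspring <- logical(cap)
  active <- integer(cap)
  nseg <- 1L
  birth[1] <- 0
  active[1] <- 1L; k <- 1L
  time <- 0
  thinning <- !is.null(birth_rate_fn) || !is.null(death_rate_fn)
  repeat {
    if (k == 0L) {
      if (condition == "none") {
        return(.bd_pack(parent, birth, end, status, offspring, nseg,
                        age = duration, n_extant = 0L))
      }
      return(NULL) # rejected
    }
    total <- k * (lambda + mu)
    dt <- stats::rexp(1L, total)
    tnew <- time + dt
    if (condition != "fixed_n" && tnew > duration) {
      idx <- active[seq_len(k)]
      end[idx] <- duration
      status[idx] <- 0L
      return(.bd_pack(parent, birth, end, status, offspring, nseg,
                      age = duration, n_extant = k))
    }
    is_birth <- stats::runif(1L) < lambda / (lambda + mu)
    if (thinning) {
      # accept the proposed event with probability rate(t)/cap
      rate <- if (is_birth) {
        if (is.null(birth_rate_fn)) lambda else birth_rate_fn(tnew, k)
      } else {
        if (is.null(death_rate_fn)) mu else death_rate_fn(tnew, k)
      }
      capr <- if (is_birth) lambda else mu
      if (rate > capr + 1e-12)
        stop("rate hook exceeds its cap (lambda/mu must bound the hook)")
      if (stats::runif(1L) >= rate / capr) {
        time <- tnew
        next
      }
    }
    if (condition == "fixed_n" && is_birth && k == n_leaves) {
      idx <- active[seq_len(k)]
      end[idx] <- tnew
      status[idx] <- 0L
      return(.bd_pack(parent, birth, end, status, offspring, nseg,
                      age = tnew, n_extant = k))
    }
    time <- tnew
    j <- sample.int(k, 1L)
    v <- active[j]
    if (is_birth) {
      if (nseg + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(birth) <- cap; length(end) <- cap
        length(status) <- cap; length(offspring) <- cap
        length(active) <- cap
        parent[is.na(parent)] <- 0L; status[is.na(status)] <- 0L
      }
      end[v] <- time; status[v] <- 2L
      c1 <- nseg + 1L; c2 <- nseg + 2L; nseg <- nseg + 2L
      parent[c1] <- v; parent[c2] <- v
      birth[c1] <- time; birth[c2] <- time
      off <- if (stats::runif(1L) < 0.5) c1 else c2
      offspring[off] <- TRUE
      active[j] <- c1
      k <- k + 1L
      active[k] <- c2
    } else {
      end[v] <- time; status[v] <- 1L
      active[j] <- active[k]
      k <- k - 1L
    }
  }
}

.bd_pack <- function(parent, birth, end, status, offspring, nseg, age,
                     n_extant) {
  idx <- seq_len(nseg)
  structure(list(parent = parent[idx], birth = birth[idx], end = end[idx],
                 status = status[idx], offspring = offspring[idx],
                 n_seg = nseg, age = age, n_extant = n_extant),
            class = "bd_realization")
}

#' @export
print.bd_realization <- function(x, ...) {
  cat(sprintf(
    "birth-death realization: %d segments, %d extant leaves, age %.4g\n",
    x$n_seg, x$n_extant, x$age))
  invisible(x)
}

# ---- derived views --------------------------------------------------------

# does each segment have at least one extant descendant?
.bd_survives <- function(real) {
  surv <- real$status == 0L
  ord <- order(real$birth, decreasing = TRUE)
  for (v in ord) {
    p <- real$parent[v]
    if (p != 0L && surv[v]) surv[p] <- TRUE
  }
  surv
}

# Edge table of the reduced tree: one row per edge, identified by the segment
# at its bottom; `top` is the segment whose split starts the edge (0 for the
# stem chain above the reduced root).  `first_seg` is the first segment of
# the chain below `top` (carrying the offspring designation the evolutionary
# view reads).  Lengths sum the time spans of the pruned chain exactly.
.reduced_edge_table <- function(real) {
  if (real$n_extant == 0L) stop("realization is extinct: no reduced tree")
  surv <- .bd_survives(real)
  is_tip <- real$status == 0L
  kids_surv <- integer(real$n_seg) # surviving-children count per segment
  for (v in which(surv)) {
    p <- real$parent[v]
    if (p != 0L) kids_surv[p] <- kids_surv[p] + 1L
  }
  retained <- surv & (is_tip | kids_surv == 2L)
  ord <- order(real$birth) # parents before children
  ranc <- integer(real$n_seg)   # nearest retained ancestor (0 above root)
  first <- integer(real$n_seg)  # first chain segment below that ancestor
  for (v in ord) {
    p <- real$parent[v]
    if (p == 0L) {
      ranc[v] <- 0L; first[v] <- v
    } else if (retained[p]) {
      ranc[v] <- p; first[v] <- v
    } else {
      ranc[v] <- ranc[p]; first[v] <- first[p]
    }
  }
  bot <- which(retained)
  tops <- ranc[bot]
  start <- numeric(length(bot)) # time at which each reduced edge begins
  start[tops == 0L] <- real$birth[first[bot][tops == 0L]]
  start[tops > 0L] <- real$end[tops[tops > 0L]]
  data.frame(bottom = bot, top = tops, first_seg = first[bot],
             length = real$end[bot] - start,
             tip = is_tip[bot],
             new_species = real$offspring[first[bot]])
}

# build a phylo from an edge table (rows with top == 0 describe the root and
# its stem)
.edge_table_to_phylo <- function(et, tip_labels = NULL) {
  tips <- et$bottom[et$tip]
  n <- length(tips)
  rootrow <- which(et$top == 0L)
  if (n == 1L) {
    # degenerate single-leaf tree: represent leaf with its stem as root.edge
    phy <- structure(list(edge = matrix(integer(0), 0, 2), Nnode = 0L,
                          tip.label = if (is.null(tip_labels)) "t1"
                                      else tip_labels,
                          edge.length = numeric(0),
                          root.edge = et$length[rootrow]),
                     class = "phylo")
    return(phy)
  }
  internals <- et$bottom[!et$tip]
  root_seg <- et$bottom[rootrow]
  newid <- integer(max(et$bottom))
  newid[tips] <- seq_len(n)
  internals <- c(root_seg, setdiff(internals, root_seg))
  newid[internals] <- n + seq_along(internals)
  keep <- et$top != 0L
  edge <- cbind(newid[et$top[keep]], newid[et$bottom[keep]])
  phy <- structure(list(edge = edge, Nnode = length(internals),
                        tip.label = if (is.null(tip_labels))
                          paste0("t", seq_len(n)) else tip_labels,
                        edge.length = et$length[keep],
                        root.edge = et$length[rootrow]),
                   class = "phylo", order = NULL)
  # permute per-edge annotations together with the edges
  idx <- ape::reorder.phylo(phy, "cladewise", index.only = TRUE)
  phy$edge <- phy$edge[idx, , drop = FALSE]
  phy$edge.length <- phy$edge.length[idx]
  attr(phy, "order") <- "cladewise"
  attr(phy, "bottom_seg") <- et$bottom[keep][idx]
  attr(phy, "new_species") <- et$new_species[keep][idx]
  phy
}

#' Reduced (reconstructed) tree of a realization
#'
#' Drops all lineages extinct before the sampling time, suppresses the
#' resulting out-degree-1 vertices (concatenating the time spans exactly) and
#' stores the stem -- the time from the origin to the first split with two
#' surviving sides -- as the `root.edge`, excluded from tree statistics by
#' default.
#'
#' @param real a `bd_realization` with at least one extant leaf.
#' @return An ultrametric `phylo`; tips are labelled `t1, t2, ...` in segment
#'   order.
#' @export
reduce_tree <- function(real) {
  stopifnot(inherits(real, "bd_realization"))
  .edge_table_to_phylo(.reduced_edge_table(real))
}

#' Reduced evolutionary tree of a realization
#'
#' The reduced tree together with the new-species annotation: an edge of the
#' reduced tree is a new-species ("horizontal") edge when the first segment
#' of the lineage chain it represents was the designated offspring at the
#' (visible) split above it; splits whose other side left no survivors do
#' not create new species. A leaf's evolutionary depth is the number of
#' new-species edges on its root path.
#'
#' @param real a `bd_realization` with at least one extant leaf.
#' @return A list: `tree` (the reduced `phylo`), `new_species` (logical per
#'   edge of `tree`), `evo_depth` (named integer vector per leaf).
#' @export
reduced_evolutionary <- function(real) {
  tree <- reduce_tree(real)
  if (length(tree$tip.label) == 1L)
    return(list(tree = tree,
                new_species = logical(0),
                evo_depth = stats::setNames(0L, tree$tip.label)))
  flags <- attr(tree, "new_species")
  # accumulate flagged-edge counts from the root down
  nn <- length(tree$tip.label) + tree$Nnode
  d <- integer(nn)
  eo_idx <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  for (i in eo_idx)
    d[tree$edge[i, 2]] <- d[tree$edge[i, 1]] + as.integer(flags[i])
  evo <- d[seq_along(tree$tip.label)]
  names(evo) <- tree$tip.label
  list(tree = tree, new_species = flags, evo_depth = evo)
}

#' Complete tree of a realization
#'
#' The full birth-death tree including lineages extinct before the sampling
#' time. Extinct tips end at their death times (the tree is not ultrametric)
#' and carry a label suffix.
#'
#' @param real a `bd_realization` with at least two segments.
#' @param extinct_suffix suffix appended to extinct tip labels.
#' @return A `phylo` with `root.edge` the stem (origin to first split).
#' @export
complete_tree <- function(real, extinct_suffix = "_x") {
  stopifnot(inherits(real, "bd_realization"))
  is_tip <- real$status != 2L
  if (sum(is_tip) < 2L) stop("complete tree needs at least one split")
  bot <- seq_len(real$n_seg)
  et <- data.frame(bottom = bot, top = real$parent[bot],
                   first_seg = bot,
                   length = real$end[bot] - real$birth[bot],
                   tip = is_tip[bot],
                   new_species = real$offspring[bot])
  # drop the origin segment as an edge: it is the stem; its children hang
  # from the root
  origin <- which(et$top == 0L & !et$tip)
  stopifnot(length(origin) == 1L)
  et$top[et$top == origin] <- 0L
  stem_len <- et$length[origin]
  et <- et[-origin, , drop = FALSE]
  # the root is the first split: mark exactly one row as the carrier of the
  # stem by convention of .edge_table_to_phylo (rows with top == 0)
  labs <- ifelse(real$status[et$bottom[et$tip]] == 1L,
                 paste0("t", et$bottom[et$tip], extinct_suffix),
                 paste0("t", et$bottom[et$tip]))
  # rebuild with a pseudo root row
  rootkids <- which(et$top == 0L)
  phy <- .edge_table_to_phylo(
    rbind(data.frame(bottom = max(et$bottom) + 1L, top = 0L,
                     first_seg = max(et$bottom) + 1L, length = stem_len,
                     tip = FALSE, new_species = FALSE),
          transform(et, top = ifelse(top == 0L, max(et$bottom) + 1L, top))),
    tip_labels = labs)
  phy
}

# pruning conservation helper: total pruned length
#' Length bookkeeping of a realization
#'
#' Total lineage-time of the complete tree, of the reduced tree (stem
#' included) and of the pruned extinct subtrees; pruning loses no length, so
#' complete = reduced + pruned exactly.
#'
#' @param real a `bd_realization` with extant leaves.
#' @return Named numeric vector `complete`, `reduced`, `pruned`.
#' @export
length_conservation <- function(real) {
  total <- sum(real$end - real$birth)
  et <- .reduced_edge_table(real)
  red <- sum(et$length)
  c(complete = total, reduced = red, pruned = total - red)
}

#' Event log of a realization
#'
#' One row per lineage segment: its parent segment, birth and end times,
#' fate (`extant`, `extinct` or `split`) and whether it was the designated
#' offspring at the split that created it.
#'
#' @param real a `bd_realization`.
#' @param file optional path; when given, the table is written as TSV.
#' @return A data frame (invisibly when written to a file).
#' @export
bd_event_log <- function(real, file = NULL) {
  stopifnot(inherits(real, "bd_realization"))
  out <- data.frame(lineage = seq_len(real$n_seg),
                    parent = real$parent,
                    birth = real$birth,
                    end = real$end,
                    fate = c("extant", "extinct", "split")[real$status + 1L],
                    offspring = real$offspring)
  if (is.null(file)) return(out)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

# ---- edge-length statistics ----------------------------------------------

#' Edge-length statistics of a (reduced) tree
#'
#' Per-tree summaries of the quantities whose laws are known for Yule trees
#' sampled just before the n-th split: a uniformly sampled pendant edge and
#' a uniformly sampled interior edge are Exponential(2 lambda); a root-child
#' edge has mean (1/lambda)(1 - 1/n); the total length S_n is
#' Gamma(n - 1, lambda). The stem edge is excluded throughout.
#'
#' @param tree an ultrametric `phylo` (typically from [reduce_tree()]).
#' @param sample_edges also draw one uniform pendant and (when present) one
#'   uniform interior edge and one root-child edge.
#' @return A list with `total`, `pendant_lengths`, `interior_lengths`,
#'   `rootchild_lengths`, `longest_pendant`, `shortest_interior`, and (if
#'   requested) `sampled_pendant`, `sampled_interior`, `sampled_rootchild`.
#' @export
edge_length_stats <- function(tree, sample_edges = TRUE) {
  ec <- edge_classes(tree)
  pend <- ec$length[ec$pendant]
  inter <- ec$length[!ec$pendant]
  rootc <- ec$length[ec$root_child]
  out <- list(total = sum(ec$length),
              pendant_lengths = pend,
              interior_lengths = inter,
              rootchild_lengths = rootc,
              longest_pendant = max(pend),
              shortest_interior = if (length(inter)) min(inter) else NA_real_)
  if (sample_edges) {
    out$sampled_pendant <- pend[sample.int(length(pend), 1L)]
    out$sampled_interior <- if (length(inter))
      inter[sample.int(length(inter), 1L)] else NA_real_
    out$sampled_rootchild <- rootc[sample.int(length(rootc), 1L)]
  }
  out
}

#' Longest-pendant-edge ratio ensemble
#'
#' Simulates birth-death trees conditioned on survival to time `t` and
#' returns the ratio L_t / t of the longest pendant edge to the tree age,
#' for the reduced view (limit 1/2 as lambda t grows) or the complete view
#' (limit (1 - mu/lambda)/2).
#'
#' @param lambda,mu birth and death rates, `lambda > mu`.
#' @param t tree age.
#' @param reps ensemble size.
#' @param seed optional integer seed.
#' @param view `"reduced"` or `"complete"`.
#' @return Numeric vector of length `reps` with values in `[0, 1]`.
#' @export
longest_pendant_ratio <- function(lambda, mu = 0, t, reps, seed = NULL,
                                  view = c("reduced", "complete")) {
  view <- match.arg(view)
  if (lambda <= mu) stop("requires lambda > mu")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(reps)
  for (i in seq_len(reps)) {
    real <- simulate_bd(lambda, mu, duration = t, condition = "survival")
    if (view == "reduced") {
      if (mu == 0) { # no pruning: pendant edges are the extant segments
        pend <- real$status == 0L & real$parent != 0L
        out[i] <- if (any(pend))
          max(real$end[pend] - real$birth[pend]) / t
        else real$age / t # single-leaf tree: the whole lineage is pendant
      } else {
        et <- .reduced_edge_table(real)
        pend <- et$tip
        out[i] <- max(et$length[pend]) / t
      }
    } else {
      tips <- real$status != 2L & real$parent != 0L
      out[i] <- if (any(tips))
        max(real$end[tips] - real$birth[tips]) / t
      else real$age / t
    }
  }
  out
}

#' Limiting law of the rescaled shortest interior edge of a Yule tree
#'
#' As lambda t grows, the shortest interior edge S_t of a Yule tree
#' satisfies P(S_t >= x e^(-lambda t) / lambda) -> 1/(1 + 2x). At x = 1/2
#' this gives probability 1/2: the shortest interior edge has about a 50%
#' chance of being smaller than the average interior edge length divided by
#' the expected number of leaves.
#'
#' @param x non-negative rescaled threshold (vectorized).
#' @return Numeric probabilities 1/(1 + 2x).
#' @export
shortest_interior_survival <- function(x) {
  if (any(x < 0)) stop("x must be non-negative")
  1 / (1 + 2 * x)
}

#' Empirical version of the shortest-interior-edge law
#'
#' Simulates Yule trees of age `t` (conditioned on at least one interior
#' edge) and estimates P(S_t >= x e^(-lambda t) / lambda).
#'
#' @param lambda birth rate.
#' @param t tree age.
#' @param x rescaled threshold (scalar).
#' @param reps ensemble size.
#' @param seed optional integer seed.
#' @return Estimated probability.
#' @export
shortest_interior_empirical <- function(lambda, t, x, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  thr <- x * exp(-lambda * t) / lambda
  hits <- 0L; got <- 0L
  while (got < reps) {
    real <- simulate_bd(lambda, 0, duration = t, condition = "survival")
    # Yule: every split segment except the origin is an interior edge
    inter <- real$status == 2L & real$parent != 0L
    if (!any(inter)) next
    got <- got + 1L
    if (min(real$end[inter] - real$birth[inter]) >= thr) hits <- hits + 1L
  }
  hits / reps
}
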