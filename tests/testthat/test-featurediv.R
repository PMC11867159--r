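test_that("FD counts feature weights over unions of species sets", {
  fa <- feature_assignment(list(x = c("f1", "f2"), y = c("f1", "f3"),
                                z = c("f2", "f3")))
  expect_equal(fd(fa, c("x", "y")), 3)
  expect_equal(fd(fa, "x"), 2)
  expect_equal(fd(fa, character(0)), 0)
  expect_error(fd(fa, "nope"), "unknown leaf")
  # weighted features
  fw <- feature_assignment(list(a = "f", b = c("f", "g")),
                           c(f = 2.5, g = 1.5))
  expect_equal(fd(fw, c("a", "b")), 4)
  expect_error(feature_assignment(list(a = "f"), c(f = -1)), "positive")

  # the worked five-feature extinction scenario: ratio 3/5
  ex <- feature_loss_example()
  all_leaves <- names(ex$assignment$features)
  expect_equal(fd(ex$assignment, all_leaves), 5)
  expect_equal(fd(ex$assignment, ex$survivors), 3)
  expect_equal(fd(ex$assignment, ex$survivors) /
                 fd(ex$assignment, all_leaves), 0.6)
  expect_length(ex$extinct, 3)
})

test_that("FD is submodular for arbitrary assignments", {
  set.seed(422)
  for (rep in 1:4) {
    labs <- paste0("s", 1:5)
    nf <- 6
    feats <- lapply(labs, function(l)
      paste0("f", which(runif(nf) < 0.5)))
    names(feats) <- labs
    w <- setNames(runif(nf, 0.5, 2), paste0("f", 1:nf))
    fa <- feature_assignment(feats, w)
    subs <- all_subsets(labs, include_empty = TRUE)
    for (i in seq(1, length(subs), by = 3)) {
      for (j in seq(2, length(subs), by = 5)) {
        A <- subs[[i]]; B <- subs[[j]]
        expect_lte(fd(fa, union(A, B)) + fd(fa, intersect(A, B)),
                   fd(fa, A) + fd(fa, B) + 1e-12)
      }
    }
  }
})

test_that("PD can be written as FD exactly, for every subset", {
  tr <- read_newick("((a:1,b:1):1,c:2);")
  fa <- pd_as_fd(tr)
  expect_length(fa$weights, 4)
  expect_equal(fd(fa, c("a", "c")), pd(tr, c("a", "c")))
  set.seed(423)
  for (n in c(4, 7)) {
    t2 <- with_random_lengths(yh_sample(n))
    fa2 <- pd_as_fd(t2)
    expect_true(isTRUE(is_nested(fa2)))
    for (Y in all_subsets(t2$tip.label))
      expect_equal(fd(fa2, Y), pd(t2, Y), tolerance = 1e-12)
  }
  # star tree: features are exactly the pendant edges
  star <- read_newick("(a:1,b:2,c:3);")
  fs <- pd_as_fd(star)
  expect_equal(lengths(fs$features), c(a = 1L, b = 1L, c = 1L))
  expect_equal(fd(fs, star$tip.label), total_length(star))
})

test_that("nestedness decides PD-representability, with reconstruction on
           success and a violating pair on failure", {
  bad <- feature_assignment(list(x = c("f1", "f2"), y = c("f1", "f3"),
                                 z = c("f2", "f3")))
  nb <- is_nested(bad)
  expect_false(isTRUE(nb))
  expect_length(attr(nb, "violating_pair"), 2)
  res <- fd_to_pd_tree(bad)
  expect_false(res$success)
  expect_length(res$violating_pair, 2)

  # round trip: pd_as_fd output reconstructs a tree with identical PD
  set.seed(424)
  for (n in c(5, 7)) {
    tr <- with_random_lengths(yh_sample(n))
    fa <- pd_as_fd(tr)
    res <- fd_to_pd_tree(fa)
    expect_true(res$success)
    for (Y in all_subsets(tr$tip.label))
      expect_equal(pd(res$tree, Y, include_stem = TRUE), fd(fa, Y),
                   tolerance = 1e-12)
  }

  # a feature shared by all species lands on the stem
  fa3 <- feature_assignment(list(a = "f", b = "f", c = "f"), c(f = 2))
  r3 <- fd_to_pd_tree(fa3)
  expect_true(r3$success)
  expect_equal(r3$tree$root.edge, 2)
  for (Y in all_subsets(c("a", "b", "c")))
    expect_equal(pd(r3$tree, Y, include_stem = TRUE), fd(fa3, Y))

  # species carrying no feature attach with zero-length edges
  fa4 <- feature_assignment(list(a = c("u", "v"), b = "u", c = character(0)),
                            c(u = 1, v = 2))
  r4 <- fd_to_pd_tree(fa4)
  expect_true(r4$success)
  for (Y in all_subsets(c("a", "b", "c")))
    expect_equal(pd(r4$tree, Y, include_stem = TRUE), fd(fa4, Y))
})

test_that("the gain/loss simulator reproduces the Poisson path laws", {
  set.seed(425)
  # a directed path of total length 3 reaching leaf a (stem 1 + pendant 2):
  # feature count at a is Poisson with mean (r/nu)(1 - exp(-nu L))
  tr <- read_newick("(a:2,b:0.5):1;")
  r <- 2; nu <- 1; L <- 3
  reps <- 12000
  cnt <- vapply(seq_len(reps), function(i)
    length(simulate_gain_loss(tr, r, nu)$features[["a"]]), 0L)
  m <- (r / nu) * (1 - exp(-nu * L))
  expect_lt(abs(mean(cnt) - m), 3 * sqrt(m / reps))
  obs <- table(factor(pmin(cnt, 8), levels = 0:8))
  expect_gt(chisq.test(obs, p = c(dpois(0:7, m),
                                  ppois(7, m, lower.tail = FALSE)))$p.value,
            0.001)

  # k initial features, long path: count converges to Poisson(r/nu),
  # forgetting the initial condition
  trL <- read_newick("(a:9,b:0.5):1;")
  cnt2 <- vapply(seq_len(6000), function(i)
    length(simulate_gain_loss(trL, r, nu, F0 = 5)$features[["a"]]), 0L)
  expect_lt(abs(mean(cnt2) - r / nu), 3 * sqrt((r / nu) / 6000) + 3e-4)

  # nu = 0: every feature that arises reaches all descendant leaves
  t4 <- with_random_lengths(yh_sample(4, seed = 8)); t4$root.edge <- 1
  fa0 <- simulate_gain_loss(t4, 1, 0, seed = 9)
  expect_equal(nrow(attr(fa0, "losses")), 0)
  gains <- attr(fa0, "gains")
  for (i in seq_len(nrow(gains))) {
    e <- gains$edge[i]
    carriers <- names(Filter(function(v) gains$feature[i] %in% v,
                             fa0$features))
    expected_carriers <- if (e == 0) t4$tip.label else clade(t4, e)
    expect_setequal(carriers, expected_carriers)
  }
})

test_that("the expected-FD recursion agrees with closed forms and Monte
           Carlo", {
  # single path: the Poisson mean
  tr <- read_newick("(a:2,b:0.5):1;")
  expect_equal(expected_fd(tr, 2, 1, Y = "a"), 2 * (1 - exp(-3)))
  # nu = 0, Y = X: every gain counts, including the stem
  t5 <- with_random_lengths(yh_sample(5, seed = 10)); t5$root.edge <- 0.7
  expect_equal(expected_fd(t5, 1.5, 0),
               1.5 * total_length(t5, include_stem = TRUE),
               tolerance = 1e-9)
  # F0 features only: F0 times the reach probability
  expect_equal(expected_fd(tr, r = 1e-12, nu = 1, Y = "a", F0 = 3),
               3 * exp(-3), tolerance = 1e-6)
  expect_error(expected_fd(tr, 1, -0.5), "nu")

  set.seed(426)
  t6 <- with_random_lengths(yh_sample(6)); t6$root.edge <- 0.5
  Y <- sort(t6$tip.label)[1:3]
  ef <- expected_fd(t6, 1, 0.7, Y = Y)
  sims <- vapply(seq_len(20000), function(i)
    length(unique(unlist(simulate_gain_loss(t6, 1, 0.7)$features[Y]))), 0L)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - ef), 3 * se)

  # FOB marginalization: s = 1 is Y = X; s = 0 gives 0
  expect_equal(expected_fd(t6, 1, 0.7, s = 1), expected_fd(t6, 1, 0.7))
  expect_equal(expected_fd(t6, 1, 0.7, s = 0), 0)
})

test_that("expected-feature edge lengths sum to expected FD and recover the
           path formula", {
  t6 <- with_random_lengths(yh_sample(6, seed = 11)); t6$root.edge <- 0.4
  ef <- edge_feature_lengths(t6, 1.2, 0.7)
  expect_equal(ef$total, expected_fd(t6, 1.2, 0.7), tolerance = 1e-12)
  # pendant edges: q(bottom) = 0, so l' = (r/nu)(1 - e^(-nu l))
  pend <- edge_classes(t6)$pendant
  expect_equal(ef$edge_lengths[pend],
               (1.2 / 0.7) * (1 - exp(-0.7 * t6$edge.length[pend])),
               tolerance = 1e-12)
  # nu = 0: l' = r l on every edge
  ef0 <- edge_feature_lengths(t6, 1.2, 0)
  expect_equal(ef0$edge_lengths, 1.2 * t6$edge.length, tolerance = 1e-12)
  expect_equal(ef0$stem, 1.2 * t6$root.edge, tolerance = 1e-12)
})

test_that("expected FD loss never beats its PD proxy, with equality at the
           boundaries and on star trees", {
  set.seed(427)
  for (rep in 1:50) {
    tr <- with_random_lengths(yh_sample(5)); tr$root.edge <- runif(1, 0.1, 1)
    g <- fd_pd_proxy_gap(tr, r = 1, nu = 1, s = 0.5)
    expect_gte(g$gap, 0)
    expect_gt(g$gap, 1e-12) # strict on binary non-star trees
    expect_equal(fd_pd_proxy_gap(tr, 1, 1, 1)$gap, 0, tolerance = 1e-12)
    expect_equal(fd_pd_proxy_gap(tr, 1, 1, 0)$gap, 0, tolerance = 1e-12)
  }
  # equality on star trees (no stem: with a positive stem the stem term
  # makes the bound strict as well)
  star <- read_newick("(a:1,b:2,c:3,d:1.5);")
  for (s in c(0.2, 0.5, 0.8))
    expect_equal(fd_pd_proxy_gap(star, 1, 0.8, s)$gap, 0, tolerance = 1e-12)
  star$root.edge <- 0.5
  expect_gt(fd_pd_proxy_gap(star, 1, 0.8, 0.5)$gap, 0)
  # a Monte Carlo cross-check of the FD ratio itself
  set.seed(428)
  tr <- with_random_lengths(yh_sample(5, seed = 12)); tr$root.edge <- 0.5
  g <- fd_pd_proxy_gap(tr, 1, 1, 0.5)
  reps <- 15000
  num <- den <- numeric(reps)
  for (i in seq_len(reps)) {
    fa <- simulate_gain_loss(tr, 1, 1)
    alive <- names(fa$features)[runif(5) < 0.5]
    num[i] <- fd(fa, alive)
    den[i] <- fd(fa, names(fa$features))
  }
  mc <- mean(num) / mean(den) # ratio of expectations, as in the bound
  se <- 3 * (sd(num) + sd(den)) / sqrt(reps) / mean(den)
  expect_lt(abs(mc - g$fd_ratio), se)
})
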