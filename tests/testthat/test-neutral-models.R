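test_that("Yule-Harding shape and tree probabilities reproduce the exact
           worked values and normalize", {
  ht <- harding_tree()
  expect_true(yh_shape_probability(ht) == rational(1, 6))
  expect_true(yh_tree_probability(ht) == rational(1, 90))
  expect_true(yh_shape_probability(read_newick("(a,b);")) == rational(1))
  expect_true(yh_tree_probability(read_newick("(a,b);")) == rational(1))
  # balanced fork on 4 leaves: 1/3 shape probability, 1/9 per labelled tree
  fork <- read_newick("((a,b),(c,d));")
  expect_true(yh_shape_probability(fork) == rational(1, 3))
  expect_true(yh_tree_probability(fork) == rational(1, 9))
  expect_error(yh_shape_probability(enumerate_shapes(1)[[1]]), "n >= 2")

  # exact normalization over shapes (n <= 10) and labelled trees (n <= 6)
  for (n in c(4, 7, 10)) {
    tot <- rational(0)
    for (sh in enumerate_shapes(n))
      tot <- rational_add(tot, yh_shape_probability(sh))
    expect_true(tot == rational(1))
  }
  for (n in c(4, 6)) {
    tot <- rational(0)
    for (tr in enumerate_labeled_trees(letters[1:n]))
      tot <- rational_add(tot, yh_tree_probability(tr))
    expect_true(tot == rational(1))
  }
})

test_that("YH sampler reproduces the shape law and the attachment process
           brute force", {
  set.seed(403)
  # n = 5 shape frequencies, chi-square at alpha = 0.001
  N <- 20000
  enc <- character(N)
  for (i in 1:N) enc[i] <- shape_of(yh_sample(5))$encoding
  shapes <- enumerate_shapes(5)
  pr <- vapply(shapes, function(s) as.numeric(yh_shape_probability(s)), 0)
  names(pr) <- vapply(shapes, function(s) s$encoding, "")
  counts <- table(factor(enc, levels = names(pr)))
  expect_gt(chisq.test(counts, p = pr)$p.value, 0.001)
  # Harding-tree shape frequency near 1/6 within 3 sigma
  f <- mean(enc == shape_of(harding_tree())$encoding)
  expect_lt(abs(f - 1/6), 3 * sqrt((1/6) * (5/6) / N))
  # n = 2: always the cherry
  expect_equal(shape_of(yh_sample(2))$encoding, "(*,*)")
  # n = 4 fork frequency ~ 1/3
  enc4 <- vapply(1:8000, function(i) shape_of(yh_sample(4))$encoding, "")
  expect_lt(abs(mean(enc4 == "((*,*),(*,*))") - 1/3),
            3 * sqrt((1/3) * (2/3) / 8000))
  # determinism under a seed
  expect_identical(write_newick(yh_sample(10, seed = 42)),
                   write_newick(yh_sample(10, seed = 42)))
})

test_that("PDA sampler is uniform and has the n/(2n-3) single-leaf root
           probability, exactly by enumeration and empirically", {
  # exact: fraction of labelled trees with a single-leaf root subtree
  for (n in c(4, 5, 6, 7)) {
    trees <- enumerate_labeled_trees(letters[1:n])
    single <- vapply(trees, function(t) min(root_subtree_sizes(t)) == 1, NA)
    expect_equal(mean(single), pda_single_leaf_root_prob(n))
  }
  # limit is 1/2
  expect_equal(pda_single_leaf_root_prob(1e9), 0.5, tolerance = 1e-8)

  set.seed(404)
  # uniformity over the 3 trees at n = 3
  N <- 9000
  nwk <- vapply(1:N, function(i) write_newick(pda_sample(3)), "")
  counts <- table(nwk)
  expect_length(counts, 3)
  expect_gt(chisq.test(counts)$p.value, 0.001)
  # n = 500: single-leaf root frequency within 3 sigma of 500/997
  M <- 1200
  f <- mean(vapply(1:M, function(i)
    min(root_subtree_sizes(pda_sample(500, as_phylo = FALSE))) == 1, NA))
  p0 <- pda_single_leaf_root_prob(500)
  expect_lt(abs(f - p0), 3 * sqrt(p0 * (1 - p0) / M))
})

test_that("depth distributions follow the Stirling-number laws and the
           exhaustive history oracle", {
  # printed three-leaf cases
  d3 <- depth_distribution(3, "reduced")
  expect_equal(attr(d3, "prob_num"), c(1, 2))
  expect_equal(attr(d3, "prob_den"), c(3, 3))
  e3 <- depth_distribution(3, "evolutionary")
  expect_equal(attr(e3, "prob_num"), c(1, 1, 1))
  expect_equal(attr(e3, "prob_den"), c(3, 2, 6))

  # n = 6: both variants against the exhaustive YH-history enumeration
  orc <- yh_history_depth_oracle(6)
  d6 <- depth_distribution(6, "reduced")
  expect_equal(as.numeric(oracle_marginal(orc, "depth")[as.character(d6$depth)]),
               d6$prob, tolerance = 1e-12)
  e6 <- depth_distribution(6, "evolutionary")
  expect_equal(as.numeric(oracle_marginal(orc, "evo")[as.character(e6$depth)]),
               e6$prob, tolerance = 1e-12)

  # support bounds: no mass at 0 (reduced) or >= n
  expect_equal(d6$depth, 1:5)
  expect_equal(e6$depth, 0:5)
  expect_error(depth_distribution(6, "nope"))
  expect_error(depth_distribution(1, "reduced"), "n must be")

  # mean identity E[D_n'] = E[D_n]/2 = sum_{i=2}^n 1/i, exact up to n = 12
  for (n in c(2, 5, 8, 12)) {
    h <- harmonic_mean_depth(n, exact = TRUE)
    mr <- attr(depth_distribution(n, "reduced"), "mean_rational")
    me <- attr(depth_distribution(n, "evolutionary"), "mean_rational")
    expect_true(me == h)
    expect_true(mr == rational_mul(h, rational(2)))
  }
})

test_that("evolutionary depth law is approached by the Poisson limit", {
  tvs <- vapply(c(5, 10, 100, 1000), poisson_depth_tv, 0)
  expect_true(all(tvs >= 0))
  expect_true(all(diff(tvs) < 0)) # decreasing along the sequence
  expect_lt(tvs[4], tvs[1])
  # independent recomputation at n = 5 from the exact row + dpois
  m <- log(5) - digamma(1) - 1
  p <- stirling_row(5)[2:6] / factorial(5)
  direct <- 0.5 * (sum(abs(p - dpois(0:4, m))) +
                     ppois(4, m, lower.tail = FALSE))
  expect_equal(poisson_depth_tv(5), direct, tolerance = 1e-12)
})

test_that("MRCA of a random pair sits near the root with the geometric
           limit law", {
  expect_equal(mrca_root_geometric(0), 1/3)
  expect_equal(sum(mrca_root_geometric(0:500)), 1, tolerance = 1e-12)
  set.seed(405)
  d <- mrca_root_distances(200, 4000)
  p0 <- mean(d == 0)
  expect_lt(abs(p0 - 1/3), 3 * sqrt((1/3) * (2/3) / 4000))
  # YH root split: size of a uniformly chosen root subtree is uniform on
  # 1..n-1 (chi-square, alpha = 0.001)
  M <- 20000
  sz <- integer(M)
  for (i in 1:M) {
    ss <- root_subtree_sizes(yh_sample(20, as_phylo = FALSE))
    sz[i] <- ss[sample.int(2, 1)]
  }
  expect_gt(chisq.test(table(factor(sz, levels = 1:19)))$p.value, 0.001)
})

test_that("the depth-k top of a YH tree becomes the complete shape as n
           grows", {
  # the complete shape itself and a small counterexample
  tau2 <- read_newick("(((a,b),(c,d)),((e,f),(g,h)));")
  expect_true(top_shape_is_complete(tau2, 2))
  expect_true(top_shape_is_complete(tau2, 3))
  expect_false(top_shape_is_complete(read_newick("((a,b),c);"), 2))
  set.seed(406)
  frac <- function(n, reps) mean(vapply(seq_len(reps), function(i)
    top_shape_is_complete(yh_sample(n, as_phylo = FALSE), 2), NA))
  f_small <- frac(50, 300)
  f_big <- frac(2000, 300)
  expect_gt(f_big, f_small)
})
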