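test_that("PD follows the rooted edge-union definition", {
  tr <- read_newick("((a:1,b:1):1,c:2);")
  expect_equal(pd(tr, c("a", "b", "c")), 5)
  expect_equal(pd(tr, c("a", "c")), 4)
  expect_equal(pd(tr, "a"), 2) # rooted: interior edge counts
  expect_equal(pd(tr, character(0)), 0)
  expect_error(pd(tr, c("a", "zz")), "zz")
  # monotone and submodular on exhaustive subsets of random 6-leaf trees
  set.seed(413)
  for (rep in 1:5) {
    t6 <- with_random_lengths(yh_sample(6))
    subs <- all_subsets(t6$tip.label)
    vals <- vapply(subs, function(Y) pd(t6, Y), 0)
    keys <- vapply(subs, function(Y) paste(sort(Y), collapse = ","), "")
    names(vals) <- keys
    vof <- function(Y) if (length(Y) == 0) 0 else
      vals[[paste(sort(Y), collapse = ",")]]
    for (i in seq(1, length(subs), by = 7)) {
      for (j in seq(2, length(subs), by = 11)) {
        A <- subs[[i]]; B <- subs[[j]]
        expect_lte(vof(union(A, B)) + vof(intersect(A, B)),
                   vof(A) + vof(B) + 1e-12)
        if (all(A %in% B)) expect_lte(vof(A), vof(B) + 1e-12)
      }
    }
  }
})

test_that("greedy PD maximization attains the exhaustive optimum", {
  star <- read_newick("(a:1,b:5,c:3,d:2);")
  expect_equal(max_pd_subset(star, 2)$leaves, c("b", "c"))
  set.seed(414)
  for (rep in 1:40) {
    tr <- with_random_lengths(if (rep %% 2) yh_sample(8) else pda_sample(8))
    expect_equal(max_pd_subset(tr, 8)$value, pd(tr, tr$tip.label))
    for (k in c(1, 3, 5)) {
      g <- max_pd_subset(tr, k)
      expect_length(g$leaves, k)
      expect_equal(g$value, pd(tr, g$leaves), tolerance = 1e-12)
      best <- max(combn(tr$tip.label, k, function(Y) pd(tr, Y)))
      expect_equal(g$value, best, tolerance = 1e-12)
    }
  }
  expect_error(max_pd_subset(star, 0), "k must be")
})

test_that("PD indices apportion total PD and fair proportion is the
           Shapley value", {
  # two-leaf tree: FP of a leaf is its pendant length
  t2 <- read_newick("(a:3,b:7);")
  expect_equal(unname(pd_index(t2, "fp")), c(3, 7))
  # three-leaf caterpillar with interior edge shared by the cherry
  t3 <- read_newick("((a:2,b:4):6,c:5);")
  fp <- pd_index(t3, "fp")
  es <- pd_index(t3, "es")
  expect_equal(unname(fp["a"]), 2 + 6 / 2)
  expect_equal(unname(es["a"]), 2 + 6 / 2) # binary: identical here
  expect_equal(sum(fp), pd(t3, t3$tip.label))

  set.seed(415)
  for (rep in 1:10) {
    tr <- with_random_lengths(yh_sample(sample(4:7, 1)))
    tot <- pd(tr, tr$tip.label)
    for (rule in c("fp", "es")) {
      v <- pd_index(tr, rule)
      expect_true(all(v > 0))
      expect_equal(sum(v), tot, tolerance = 1e-12)
    }
    mx <- pd_index(tr, "mix", alpha = 0.3)
    expect_equal(sum(mx), tot, tolerance = 1e-12)
    expect_equal(mx, 0.3 * pd_index(tr, "fp") + 0.7 * pd_index(tr, "es"))
    # FP = Shapley by coalition enumeration
    expect_equal(shapley_value(tr), pd_index(tr, "fp"), tolerance = 1e-12)
  }
  # star tree: Shapley is the pendant length
  star <- read_newick("(a:1,b:5,c:3);")
  expect_equal(unname(shapley_value(star)), c(1, 5, 3))
  expect_error(shapley_value(yh_sample(9, seed = 1)), "n > 8")
})

test_that("summed index values never exceed the PD of a subset", {
  star <- with_random_lengths(read_newick("(a,b,c,d);"), seed = 2)
  set.seed(416)
  for (Y in all_subsets(star$tip.label))
    expect_equal(index_subset_gap(star, Y)$gap, 0, tolerance = 1e-12)
  for (rep in 1:6) {
    tr <- with_random_lengths(yh_sample(7))
    for (rule in c("fp", "es")) {
      gaps <- vapply(all_subsets(tr$tip.label), function(Y)
        index_subset_gap(tr, Y, rule)$gap, 0)
      expect_true(all(gaps >= -1e-12))
    }
    expect_equal(index_subset_gap(tr, tr$tip.label)$gap, 0,
                 tolerance = 1e-12)
  }
})

test_that("expected PD loss matches outcome enumeration and simulation", {
  tr <- read_newick("((a:1,b:1):1,c:2);")
  expect_equal(expected_pd_loss(tr, 0.5), 0.45)
  expect_equal(expected_pd_loss(tr, 1), 1)
  expect_equal(expected_pd_loss(tr, 0), 0)
  expect_error(expected_pd_loss(tr, 1.2), "\\[0,1\\]")

  set.seed(417)
  tot <- pd(tr, tr$tip.label)
  # exhaustive oracle over the 8 extinction outcomes
  eps <- c(a = 0.3, b = 0.6, c = 0.2)
  lost_oracle <- 1 - fob_expectation_oracle(names(eps), eps,
                                            function(Y) pd(tr, Y)) / tot
  expect_equal(expected_pd_loss(tr, eps), lost_oracle, tolerance = 1e-12)

  # a larger random gFOB instance against the oracle
  t7 <- with_random_lengths(yh_sample(7))
  eps7 <- setNames(runif(7), t7$tip.label)
  oracle <- 1 - fob_expectation_oracle(t7$tip.label, eps7,
                                       function(Y) pd(t7, Y)) /
    pd(t7, t7$tip.label)
  expect_equal(expected_pd_loss(t7, eps7), oracle, tolerance = 1e-12)
  # monotone in each extinction probability
  eps_up <- eps7; eps_up[3] <- min(1, eps_up[3] + 0.2)
  expect_gte(expected_pd_loss(t7, eps_up), expected_pd_loss(t7, eps7))

  # Monte Carlo agreement
  sims <- simulate_pd_loss(tr, 0.5, reps = 20000)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(1 - sims) - 0.45), 3 * se)
})

test_that("psi and psi' equal their outcome-enumeration definitions", {
  t3 <- read_newick("((a:2,b:4):6,c:5);")
  expect_equal(unname(psi(t3, 0.5, "a")), 2 + 6 * 0.5)
  # eps = 0 for everyone: psi reduces to the pendant length
  expect_equal(unname(psi(t3, 0, "a")), 2)
  # star tree: psi is the pendant length whatever eps is
  star <- read_newick("(a:1,b:5,c:3);")
  expect_equal(unname(psi(star, 0.7, "a")), 1)

  set.seed(418)
  for (rep in 1:5) {
    tr <- with_random_lengths(yh_sample(sample(5:8, 1)))
    labs <- tr$tip.label
    eps <- setNames(runif(length(labs)), labs)
    for (x in labs[1:3]) {
      # oracle: E[PD(S_x + x) - PD(S_x)] over extinction outcomes of the
      # *other* species
      others <- setdiff(labs, x)
      orc <- fob_expectation_oracle(others, eps[others], function(Sx)
        pd(tr, c(Sx, x)) - pd(tr, Sx))
      expect_equal(unname(psi(tr, eps, x)), orc, tolerance = 1e-12)
      expect_equal(unname(psi_prime(tr, eps, x)),
                   unname(psi(tr, eps, x)) * eps[[x]], tolerance = 1e-14)
    }
    # psi is not a PD index: it does not sum to PD(X) on generic trees
    expect_false(abs(sum(psi(tr, eps)) - pd(tr, labs)) < 1e-9)
  }
})

test_that("fair proportion equals the expected psi under a uniform
           extinction prior", {
  t3 <- read_newick("((a:2,b:4):6,c:5);")
  r3 <- fp_as_expected_psi(t3, "a")
  expect_equal(r3$fp, 2 + 6 / 2)
  expect_equal(r3$expected_psi, r3$fp, tolerance = 1e-14)
  # the pendant edge contributes its full length on both sides
  expect_true(any(r3$polynomial$power == 0 & r3$polynomial$coef == 2))

  set.seed(419)
  for (rep in 1:5) {
    tr <- with_random_lengths(yh_sample(6))
    for (x in tr$tip.label[1:2]) {
      r <- fp_as_expected_psi(tr, x)
      expect_equal(r$expected_psi, r$fp, tolerance = 1e-10)
      # numeric quadrature of psi_x(eps) as an independent route
      quad <- integrate(function(e) psi_curve(tr, x, e), 0, 1,
                        rel.tol = 1e-10)$value
      expect_equal(quad, r$fp, tolerance = 1e-8)
    }
  }
})

test_that("phi_PD has the closed form, branch continuity and shape
           properties", {
  expect_equal(phi_pd(0.5), log(2), tolerance = 1e-12)
  expect_equal(phi_pd(1), 1)
  expect_equal(phi_pd(0), 0)
  expect_equal(phi_pd(1e-12), 0, tolerance = 1e-9)
  expect_error(phi_pd(0.5, 1, 1.2), "lambda > mu")
  expect_error(phi_pd(1.5), "\\[0, 1\\]")

  s <- seq(0.01, 0.99, by = 0.01)
  for (mu in c(0, 0.3, 0.8)) {
    v <- phi_pd(s, 1, mu)
    expect_true(all(diff(v) > 0))           # increasing
    expect_true(all(diff(diff(v)) < 1e-9))  # concave
    expect_true(all(v >= s))                # dominates species fraction
  }
  # continuity across the removable rho = 1 - s singularity
  for (mu in c(0.25, 0.6)) {
    sstar <- 1 - mu
    left <- phi_pd(sstar - 1e-7, 1, mu)
    mid <- phi_pd(sstar, 1, mu)
    right <- phi_pd(sstar + 1e-7, 1, mu)
    expect_lt(abs(left - mid), 1e-6)
    expect_lt(abs(right - mid), 1e-6)
  }
  # approach to the unit step as mu -> lambda (logarithmically slow)
  expect_gt(phi_pd(0.2, 1, 0.9), phi_pd(0.2, 1, 0))
  expect_gt(phi_pd(0.2, 1, 0.999), phi_pd(0.2, 1, 0.9))
  expect_gt(phi_pd(0.2, 1, 1 - 1e-9), 0.9)
  # Yule slope at s = 1 is 1/2 (pendant-edge share of PD)
  slope <- (phi_pd(1) - phi_pd(1 - 1e-6)) / 1e-6
  expect_equal(slope, 0.5, tolerance = 1e-4)
  # heuristic YH sum: ~ sum_k (1/(k(k+1)))(1 - (1-s)^k) -> phi_PD
  k <- 1:1e6
  approx <- sum((1 - (1 - 0.5)^k) / (k * (k + 1)))
  expect_equal(approx, phi_pd(0.5), tolerance = 1e-5) # series tail ~ 1/k_max
  # expected pendant count at k = 1 equals n
  expect_equal(yh_expected_edges_by_clade_size(10, 1), 10)
})

test_that("empirical PD ratios converge to phi_PD", {
  set.seed(420)
  r <- phi_pd_empirical(1, 0, s = 0.5, t = 10, reps = 120)
  expect_true(all(r >= 0 & r <= 1))
  expect_lt(abs(mean(r) - log(2)), 0.02)
  # s = 1 keeps everything
  r1 <- phi_pd_empirical(1, 0, s = 1, t = 2, reps = 5)
  expect_true(all(r1 == 1))
  # a mu > 0 case exercises the reduced-tree path
  r2 <- phi_pd_empirical(1, 0.4, s = 0.5, t = 7, reps = 60)
  expect_lt(abs(mean(r2) - phi_pd(0.5, 1, 0.4)), 0.05)
})

test_that("mean fair proportion of a random Yule leaf matches its closed
           form", {
  expect_equal(mean_fp_yule(2, 1e9), 0.5, tolerance = 1e-9)
  expect_equal(mean_fp_yule(1, 0), 2)
  set.seed(421)
  lam <- 1; t <- 3; reps <- 3000
  vals <- numeric(reps)
  for (i in seq_len(reps)) {
    real <- simulate_bd(lam, 0, duration = t, condition = "survival")
    vals[i] <- if (real$n_extant == 1) t else {
      tr <- reduce_tree(real)
      mean(pd_index(tr, "fp")) # FP of a uniform leaf, averaged exactly
    }
  }
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - mean_fp_yule(lam, t)), 3 * se)
})
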