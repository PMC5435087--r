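test_that("welch_t handles degenerate cases and is antisymmetric", {
  a <- c(1.1, 0.9, 1.0, 1.05)
  expect_equal(welch_t(a, a)$p, 1)
  sep <- welch_t(c(0, 0, 0, 0, 0), c(10, 10, 10, 10, 10.0001))
  expect_lt(sep$p, 1e-10)
  b <- c(2.2, 1.8, 2.1)
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  expect_equal(welch_t(a, b)$p, welch_t(b, a)$p)
  expect_error(welch_t(1, a), "at least 2")
  # both variances zero, equal means -> p = 1 by convention
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t(c(2, 2), c(3, 3))$p, 0)
})

test_that("welch_t p matches a permutation oracle within Monte Carlo error", {
  set.seed(5)
  a <- stats::rnorm(6, 0.0, 1)
  b <- stats::rnorm(7, 0.8, 1.4)
  p <- welch_t(a, b)$p
  nperm <- 1e5
  pp <- oracle_perm_p(a, b, nperm = nperm, seed = 2)
  mcse <- sqrt(pp * (1 - pp) / nperm)
  # permutation and Welch p agree for moderately separated normal samples
  expect_lt(abs(p - pp), max(2 * mcse, 0.02))
})

test_that("bh_fdr reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(0.037), 0.037)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order restored to input order
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- bh_fdr(p)
  expect_equal(q[order(p)], sort(q))
  expect_true(all(q >= 0 & q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("branch_scan flags planted shifts and respects sign bookkeeping", {
  # two-branch cherry with opposite-direction shifts on both branches
  tr <- read_tree(text = "(a:1,b:1);")
  set.seed(8)
  profiles <- list(
    "1" = affinity_profile(1, 5.3 + rnorm(5, 0, 0.05)),   # tip a: up
    "2" = affinity_profile(2, 3.7 + rnorm(5, 0, 0.05)),   # tip b: down
    "3" = affinity_profile(3, 4.5 + rnorm(5, 0, 0.05)))   # root
  scan <- branch_scan(tr, profiles)
  expect_s3_class(scan, "shift_scan")
  expect_equal(nrow(scan), 2L)
  expect_true(all(scan$significant))
  expect_equal(sign(scan$delta[scan$child == 1]), 1)
  expect_equal(sign(scan$delta[scan$child == 2]), -1)

  # all profiles identical constants -> no significance anywhere
  const <- lapply(1:3, function(nd) affinity_profile(nd, rep(4.5, 5)))
  names(const) <- as.character(1:3)
  null_scan <- branch_scan(tr, const)
  expect_false(any(null_scan$significant))
  expect_true(all(null_scan$p == 1))

  expect_error(branch_scan(tr, profiles[1:2]), "missing affinity")
})

test_that("branch_scan output is invariant to profile enumeration order", {
  tr <- sim_tree(10, seed = 14)
  sim <- simulate_bm_trait(tr, 0.2, seed = 15)
  set.seed(16)
  profiles <- lapply(seq_along(sim$values), function(nd) {
    affinity_profile(nd, sim$values[nd] + rnorm(5, 0, 0.1))
  })
  names(profiles) <- as.character(seq_along(sim$values))
  s1 <- branch_scan(tr, profiles)
  s2 <- branch_scan(tr, rev(profiles))
  expect_equal(s1, s2)
})

test_that("scan controls the FDR under a global null", {
  # no true shifts anywhere: the expected fraction of q < 0.05 branches
  # stays at or below 0.05 (BH validity under independence)
  tr <- sim_tree(16, seed = 1)
  n <- 16 + tr$Nnode
  set.seed(99)
  fp <- vapply(seq_len(1000), function(i) {
    profiles <- lapply(seq_len(n), function(nd) affinity_profile(nd, rnorm(5, 4.5, 0.1)))
    names(profiles) <- as.character(seq_len(n))
    mean(branch_scan(tr, profiles)$significant)
  }, 0)
  expect_lte(mean(fp), 0.05 + 2 * stats::sd(fp) / sqrt(length(fp)))
})

test_that("robustness_test separates shifted from matched distributions", {
  set.seed(21)
  sampled <- rnorm(100, 5, 0.1)
  shifted <- rnorm(5, 5 + 10 * 0.1, 0.1)
  expect_false(robustness_test(shifted, sampled)$robust)
  matched <- rnorm(5, 5, 0.1)
  rt <- robustness_test(matched, sampled)
  expect_true(rt$p > 0 && rt$p <= 1)
})

test_that("ambiguity_correlation recovers exact monotone relations", {
  x <- seq(0.5, 1, length.out = 10)
  names(x) <- paste0("n", 1:10)
  lin <- 2 * x + 1
  ac <- ambiguity_correlation(x, lin)
  expect_equal(ac$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ac$spearman_rho, 1, tolerance = 1e-12)

  nonlin <- -exp(5 * x)          # anti-monotone but curved
  ac2 <- ambiguity_correlation(x, nonlin)
  expect_equal(ac2$spearman_rho, -1, tolerance = 1e-12)
  expect_gt(ac2$pearson_r, -1)
  expect_lt(ac2$pearson_r, 0)

  expect_error(ambiguity_correlation(x, stats::setNames(rep(1, 10), names(x))),
               "constant")
  expect_error(ambiguity_correlation(x[1:2], lin[1:2]), ">= 3")
})

test_that("ambiguity correlation is centered on zero under independence", {
  # independent posteriors and affinities: the correlation averages to ~0
  # (note the expected magnitude E|r| at n = 100 is ~0.08, so the mean of
  # the signed coefficient is the quantity that vanishes)
  set.seed(42)
  rs <- vapply(seq_len(1000), function(i) {
    x <- stats::setNames(runif(100, 0.5, 1), paste0("n", 1:100))
    y <- stats::setNames(rnorm(100, 4.8, 0.4), paste0("n", 1:100))
    ambiguity_correlation(x, y)$pearson_r
  }, 0)
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("kde_mode finds the density peak with documented tie handling", {
  set.seed(31)
  x <- rnorm(1e4, 4.65, 0.1)
  expect_lt(abs(kde_mode(x) - 4.65), 0.02)

  # exactly symmetric bimodal sample: tie goes to the lower peak
  y <- c(rnorm(500, -2, 0.1), rnorm(500, 2, 0.1))
  y <- c(y, -y)                   # force exact symmetry
  expect_lt(kde_mode(y, bandwidth = 0.2), 0)

  z <- 3 + rnorm(100, 0, 1e-4)
  expect_lt(abs(kde_mode(z) - 3), 1e-3)
  expect_error(kde_mode(1), "n >= 2")
})

test_that("scan report writes the documented TSV columns", {
  tr <- read_tree(text = "(a:1,b:1);")
  profiles <- lapply(1:3, function(nd) affinity_profile(nd, c(4.4, 4.5, 4.6)))
  names(profiles) <- as.character(1:3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(branch_scan(tr, profiles), path)
  tab <- read_tsv(path)
  expect_setequal(names(tab), c("parent", "child", "child_label", "delta",
                                "t", "p", "q", "significant", "robust"))
})
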