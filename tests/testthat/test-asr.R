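# Likelihood and marginal reconstruction against enumeration oracles.

test_that("substitution model satisfies rate-matrix invariants", {
  for (gap in c(TRUE, FALSE)) {
    m <- aa_model("LG", alpha = 0.6, k = 4, gap_state = gap)
    expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji
    DB <- m$pi * m$Q
    expect_equal(max(abs(DB - t(DB))), 0, tolerance = 1e-12)
    # mean rate 1
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
    # gamma category rates average to 1
    expect_equal(mean(m$rates), 1, tolerance = 1e-12)
    # P(t) rows are probabilities and P(0) = I
    P <- transition_matrix(m, 0.7)
    expect_equal(rowSums(P), rep(1, length(m$pi)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(transition_matrix(m, 0), diag(length(m$pi)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(aa_model(alpha = -1), "positive")
})

test_that("two-leaf and zero-length likelihoods match closed forms", {
  m <- aa_model("LG", alpha = 1, k = 1, gap_state = TRUE, gap_freq = 0.1)
  # two leaves, one site: direct summation over the ancestral state
  tr <- read_tree(text = "(a:0.3,b:0.5);")
  msa <- as_msa(c(a = "H", b = "-"))
  P1 <- transition_matrix(m, 0.3); P2 <- transition_matrix(m, 0.5)
  i <- match("H", m$states); j <- match("-", m$states)
  expect_equal(tree_log_likelihood(msa, tr, m),
               log(sum(m$pi * P1[, i] * P2[, j])), tolerance = 1e-12)
  # zero-length limit with identical leaf states -> log pi_state
  tr0 <- read_tree(text = "(a:0,b:0);")
  msa0 <- as_msa(c(a = "W", b = "W"))
  expect_equal(tree_log_likelihood(msa0, tr0, m),
               log(m$pi[["W"]]), tolerance = 1e-9)
  # pairing error
  expect_error(tree_log_likelihood(as_msa(c(x = "A")), tr, m), "missing")
})

test_that("likelihood matches enumeration oracle with gamma and gaps", {
  fx <- fixture_small()
  m <- aa_model("LG", alpha = 0.8, k = 3, gap_state = TRUE, gap_freq = 0.08)
  orc <- oracle_asr(fx$msa, fx$tree, m)
  expect_equal(tree_log_likelihood(fx$msa, fx$tree, m), orc$loglik,
               tolerance = 1e-9)
})

test_that("marginal posteriors equal enumeration marginals (<=5 leaves, <=3 sites)", {
  skip_if_not_installed("Matrix")
  cases <- list(
    list(tree = "((a:0.2,b:0.4):0.3,(c:0.1,d:0.6):0.2);",
         msa = c(a = "HKA", b = "H-A", c = "QKV", d = "XRV"),
         alpha = 0.8, k = 3),
    list(tree = "(((a:0.15,b:0.25):0.1,c:0.5):0.2,(d:0.3,e:0.45):0.35);",
         msa = c(a = "MR", b = "MK", c = "-K", d = "LX", e = "LR"),
         alpha = 1.2, k = 2),
    list(tree = "((a:0.05,b:2.5):0.4,c:0.9);",
         msa = c(a = "C", b = "G", c = "C"),
         alpha = 1, k = 1)
  )
  for (cs in cases) {
    tr <- read_tree(text = cs$tree)
    msa <- as_msa(cs$msa)
    m <- aa_model("LG", alpha = cs$alpha, k = cs$k, gap_state = TRUE,
                  gap_freq = 0.08)
    orc <- oracle_asr(msa, tr, m)
    rec <- marginal_asr(msa, tr, m)
    expect_equal(rec$log_likelihood, orc$loglik, tolerance = 1e-9)
    for (key in names(orc$posterior)) {
      expect_lt(max(abs(rec$posterior[[key]] - orc$posterior[[key]])), 1e-9)
      expect_equal(rowSums(rec$posterior[[key]]),
                   rep(1, nrow(rec$posterior[[key]])), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("likelihood is invariant under re-rooting (time-reversible model)", {
  set.seed(11)
  tr <- sim_tree(8, seed = 21)
  m <- aa_model("LG", alpha = 0.9, k = 2, gap_state = TRUE, gap_freq = 0.05)
  sim <- simulate_alignment(tr, m, n_sites = 15, seed = 22)
  ll <- tree_log_likelihood(sim$msa, tr, m)
  utr <- ape::unroot(tr)
  for (nd in c(10L, 12L, 14L)) {
    rtr <- ape::root(utr, node = nd, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(sim$msa, rtr, m), ll, tolerance = 1e-8)
  }
})

test_that("identical leaves give that residue as ML state everywhere", {
  tr <- read_tree(text = "((a:1.5,b:2.0):1.0,(c:0.8,d:2.5):1.2);")
  msa <- as_msa(c(a = "HHH", b = "HHH", c = "HHH", d = "HHH"))
  m <- aa_model("LG", k = 1)
  rec <- marginal_asr(msa, tr, m)
  expect_true(all(unlist(rec$ml_sequence) == "HHH"))
})

test_that("long terminal branches pull the parent posterior toward the prior", {
  # as the leaf's branch grows, its influence vanishes: the parent posterior
  # converges monotonically to what the remaining data imply
  m <- aa_model("LG", k = 1, gap_state = FALSE)
  devs <- vapply(c(1, 10, 100), function(t) {
    tr <- read_tree(text = sprintf("(a:0.1,(b:0.1,c:%f):0.1);", t))
    msa <- as_msa(c(a = "A", b = "A", c = "W"))
    rec <- marginal_asr(msa, tr, m)
    # reference: c fully uninformative
    msa_ref <- as_msa(c(a = "A", b = "A", c = "X"))
    ref <- marginal_asr(msa_ref, tr, m)
    max(abs(rec$posterior[["5"]] - ref$posterior[["5"]]))
  }, 0)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-10)
})

test_that("sample_ancestral is seeded, honors n, and matches posteriors", {
  fx <- fixture_small()
  m <- aa_model("LG", alpha = 1, k = 2, gap_state = TRUE, gap_freq = 0.08)
  rec <- marginal_asr(fx$msa, fx$tree, m)
  draws <- sample_ancestral(rec, 5L, n = 20L, seed = 9)
  expect_length(draws, 20L)
  expect_identical(draws, sample_ancestral(rec, 5L, n = 20L, seed = 9))
  expect_error(sample_ancestral(rec, 1L), "internal")

  # degenerate posterior: all draws identical
  rec2 <- rec
  pm <- rec2$posterior[["5"]] * 0; pm[, 1] <- 1
  rec2$posterior[["5"]] <- pm
  expect_length(unique(sample_ancestral(rec2, 5L, n = 50L, seed = 1)), 1L)

  # law of large numbers: per-site draw frequencies within 3 binomial SEs
  big <- sample_ancestral(rec, 5L, n = 10000L, seed = 4)
  chars <- do.call(rbind, strsplit(big, "", fixed = TRUE))
  pm <- rec$posterior[["5"]]
  for (site in seq_len(ncol(chars))) {
    for (s in which(pm[site, ] > 0.01)) {
      p <- pm[site, s]
      fhat <- mean(chars[, site] == rec$states[s])
      expect_lt(abs(fhat - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-9)
    }
  }
})

test_that("node_mean_posterior averages the ML-state posterior", {
  rec <- structure(list(
    posterior = list("3" = rbind(c(0.8, 0.2, 0), c(0.6, 0.4, 0))),
    ml_sequence = c("3" = "AA"),
    states = c("A", "R", "N")), class = "asr_recon")
  expect_equal(node_mean_posterior(rec, 3), 0.7)
  # uniform posterior over k states -> 1/k
  k <- 3
  rec$posterior[["3"]] <- matrix(1 / k, 2, k)
  expect_equal(node_mean_posterior(rec, 3), 1 / k)
  expect_error(node_mean_posterior(rec, 1), "internal")
})

test_that("gamma shape estimation recovers a reasonable optimum", {
  tr <- sim_tree(8, seed = 31)
  m_true <- aa_model("LG", alpha = 0.5, k = 4, gap_state = FALSE)
  sim <- simulate_alignment(tr, m_true, n_sites = 120, seed = 32)
  m0 <- aa_model("LG", alpha = 2, k = 4, gap_state = FALSE)
  mfit <- fit_gamma_shape(sim$msa, tr, m0)
  # fitted alpha must beat the starting value in likelihood
  expect_gt(tree_log_likelihood(sim$msa, tr, mfit),
            tree_log_likelihood(sim$msa, tr, m0))
  expect_true(mfit$alpha > 0.2 && mfit$alpha < 1.5)
})

test_that("posterior table and ancestral FASTA exports are well-formed", {
  fx <- fixture_small()
  m <- aa_model("LG", k = 1, gap_state = TRUE, gap_freq = 0.08)
  rec <- marginal_asr(fx$msa, fx$tree, m)
  tab <- asr_posterior_table(rec)
  expect_equal(nrow(tab), 3L * 3L)   # 3 internal nodes x 3 sites
  expect_equal(rowSums(tab[, -(1:2)]), rep(1, nrow(tab)), tolerance = 1e-9,
               ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_ancestral_fasta(rec, path, n_sampled = 2L, seed = 1)
  out <- read_alignment(path)
  expect_equal(nrow(out), 3L + 3L * 2L)
})
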