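# Seed-exact generators for every input the pipeline consumes, each paired
# with machine-readable ground truth so downstream inference can be scored
# against what was actually simulated.

#' Simulate a pure-birth tree with uniform branch lengths
#'
#' Default synthetic phylogeny: 32 leaves, pure-birth (Yule) topology,
#' branch lengths drawn Uniform(0.05, 0.5) substitutions/site — the scale of
#' a deep protein-domain phylogeny while staying small enough for fast
#' tests.
#'
#' @param n_leaves Number of leaves (default 32).
#' @param seed Integer seed.
#' @param blen_range Branch-length range (substitutions/site).
#' @return A rooted `phylo` tree with tip labels `t1..tn`.
#' @export
sim_tree <- function(n_leaves = 32L, seed = 1L, blen_range = c(0.05, 0.5)) {
  local_seed(seed, {
    tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
    tr$edge.length <- stats::runif(nrow(tr$edge), blen_range[1L], blen_range[2L])
    tr$tip.label <- paste0("t", seq_len(n_leaves))
    tr$node.label <- NULL
    tr
  })
}

#' Simulate an alignment down a tree under a substitution model
#'
#' The root sequence is drawn from the model's equilibrium frequencies and
#' evolved along each branch with the model's transition probabilities
#' (including discrete-gamma site rates, assigned per site); the states at
#' every node are recorded as ground truth.
#'
#' @param tree A rooted `phylo` tree.
#' @param model A [aa_model()] object.
#' @param n_sites Number of alignment columns (>= 1).
#' @param seed Integer seed.
#' @return List with `msa` (leaf alignment, an [as_msa()] object) and
#'   `truth`: list with `sequences` (named character vector over all node
#'   numbers), `site_rates`, `seed`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L) {
  if (n_sites < 1L) stop("'n_sites' must be >= 1", call. = FALSE)
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  ns <- length(model$states)
  plen <- parent_edge_length(tree)
  local_seed(seed, {
    rate_idx <- sample.int(model$k, n_sites, replace = TRUE)
    site_rates <- model$rates[rate_idx]
    states <- matrix(NA_integer_, n, n_sites)
    states[root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = model$pi)
    tr <- ape::reorder.phylo(tree, "postorder")
    Pcache <- vector("list", model$k)
    for (i in rev(seq_len(nrow(tr$edge)))) {   # preorder
      p <- tr$edge[i, 1L]; chd <- tr$edge[i, 2L]
      for (s in seq_len(n_sites)) {
        ci <- rate_idx[s]
        key <- as.character(chd)
        if (is.null(Pcache[[ci]])) Pcache[[ci]] <- list()
        P <- Pcache[[ci]][[key]]
        if (is.null(P)) {
          P <- transition_matrix(model, plen[chd], model$rates[ci])
          Pcache[[ci]][[key]] <- P
        }
        states[chd, s] <- sample.int(ns, 1L, prob = P[states[p, s], ])
      }
    }
    seqs <- apply(states, 1L, function(r) paste(model$states[r], collapse = ""))
    names(seqs) <- as.character(seq_len(n))
    leaf <- seqs[seq_len(ntip)]
    names(leaf) <- tree$tip.label
    list(msa = as_msa(leaf),
         truth = list(sequences = seqs, site_rates = site_rates, seed = seed))
  })
}

#' Default two-site affinity motif
#'
#' A contact-histidine analog worth +0.7 pKd and a basic-patch analog worth
#' +0.3 pKd, giving the scan multi-site shift structure to find.
#'
#' @param his_site,basic_site Alignment columns carrying the two motifs.
#' @return A weights list for [synthetic_predictor()].
#' @export
default_affinity_weights <- function(his_site = 5L, basic_site = 12L) {
  stats::setNames(list(c(H = 0.7), c(K = 0.3, R = 0.3)),
                  c(his_site, basic_site))
}

#' Simulate replicate affinity profiles for every node
#'
#' Each node's replicates are the deterministic motif score of the node's
#' TRUE simulated sequence plus iid Gaussian noise — the generative twin of
#' [synthetic_predictor()]. Ground truth records each branch on which the
#' noiseless score changes.
#'
#' @param tree The tree the sequences were simulated on.
#' @param truth The `truth` element of [simulate_alignment()].
#' @param weights Site/residue weights (default [default_affinity_weights()]).
#' @param baseline Baseline pKd.
#' @param noise_sd Replicate noise standard deviation.
#' @param n_reps Replicates per node (default 5).
#' @param seed Integer seed.
#' @return List with `profiles` (named list of [affinity_profile()] keyed by
#'   node number) and `truth`: data frame of true shift branches (`parent`,
#'   `child`, `delta`) plus `score` (named noiseless pKd per node).
#' @export
simulate_affinity_profiles <- function(tree, truth, weights = default_affinity_weights(),
                                       baseline = 4.3, noise_sd = 0.1,
                                       n_reps = 5L, seed = 1L) {
  predict0 <- synthetic_predictor(weights, baseline, noise_sd = 0)
  score <- vapply(truth$sequences, function(s) predict0(s, 1L, 1L), 0)
  n <- length(score)
  local_seed(seed, {
    profiles <- lapply(seq_len(n), function(nd) {
      reps <- score[nd] + stats::rnorm(n_reps, 0, noise_sd)
      affinity_profile(nd, reps, "ml")
    })
    names(profiles) <- as.character(seq_len(n))
    edge <- tree$edge
    delta <- score[edge[, 2L]] - score[edge[, 1L]]
    shifts <- data.frame(parent = edge[, 1L], child = edge[, 2L],
                         delta = unname(delta))[delta != 0, , drop = FALSE]
    rownames(shifts) <- NULL
    list(profiles = profiles,
         truth = list(shift_branches = shifts, score = score, seed = seed))
  })
}

#' Simulate a Brownian-motion trait with branch rate multipliers
#'
#' Root value 0; each child value is its parent's plus Gaussian noise with
#' variance `sigma2 * multiplier * branch length`; optional observation
#' noise is added on top.
#'
#' @param tree A rooted `phylo` tree.
#' @param sigma2 Base rate (>= 0).
#' @param shifts Named multiplier vector keyed by node number (as in
#'   [rate_state()]).
#' @param ses Observation noise: single value or named vector keyed by node
#'   number (default 0).
#' @param seed Integer seed.
#' @return List with `values` (observed, named by node number over all
#'   nodes), `true_values` (noiseless node states) and `truth` metadata.
#' @export
simulate_bm_trait <- function(tree, sigma2, shifts = numeric(0), ses = 0,
                              seed = 1L) {
  if (length(shifts) > 0L && any(shifts <= 0)) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  n <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  eff <- effective_multipliers(tree, shifts)
  plen <- parent_edge_length(tree)
  sev <- if (length(ses) == 1L) rep(ses, n) else {
    v <- rep(0, n); v[as.integer(names(ses))] <- ses; v
  }
  local_seed(seed, {
    x <- rep(NA_real_, n)
    x[root] <- 0
    tr <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[i, 1L]; chd <- tr$edge[i, 2L]
      x[chd] <- x[p] + stats::rnorm(1, 0, sqrt(sigma2 * eff[chd] * plen[chd]))
    }
    obs <- x + stats::rnorm(n, 0, sev)
    names(obs) <- names(x) <- as.character(seq_len(n))
    list(values = obs, true_values = x,
         truth = list(sigma2 = sigma2, shifts = shifts, ses = sev, seed = seed))
  })
}

#' Simulate a 1:1 Langmuir binding sensorgram
#'
#' Association `R(t) = Rmax * C/(C + Kd) * (1 - exp(-(kon*C + koff) t))`,
#' dissociation from the association endpoint with rate `koff = kon * Kd`;
#' Gaussian noise is added and `n_controls` noise-only control probes are
#' emitted on the same time grid.
#'
#' @param kd Dissociation constant (molar, > 0).
#' @param kon Association rate constant (1/(M s), > 0).
#' @param concs Concentration series (molar); defaults to a 2-fold dilution
#'   series spanning Kd.
#' @param rmax Maximal response (default 1).
#' @param t_assoc,t_dissoc Phase durations in seconds (defaults 360 and 240,
#'   i.e. 6 and 4 minutes).
#' @param dt Sampling interval in seconds. The measurement default of 3 ms
#'   gives very large series; 0.5 s is the desk-scale default here.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param n_controls Number of control probes.
#' @param seed Integer seed.
#' @return List with `sensorgram` (a [sensorgram()]) and `truth`
#'   (`kd`, `kon`, `koff`, `rmax`, `seed`).
#' @export
simulate_sensorgram <- function(kd, kon, concs = kd * 2^seq(-3, 4),
                                rmax = 1, t_assoc = 360, t_dissoc = 240,
                                dt = 0.5, noise_sd = 0, n_controls = 2L,
                                seed = 1L) {
  if (kd <= 0 || kon <= 0) stop("'kd' and 'kon' must be > 0", call. = FALSE)
  koff <- kon * kd
  ta <- seq(dt, t_assoc, by = dt)
  td <- seq(dt, t_dissoc, by = dt)
  local_seed(seed, {
    rows <- lapply(seq_along(concs), function(i) {
      C <- concs[i]
      req <- rmax * C / (C + kd)
      kobs <- kon * C + koff
      ra <- req * (1 - exp(-kobs * ta))
      rd <- ra[length(ra)] * exp(-koff * td)
      data.frame(time_s = c(ta, t_assoc + td), conc_M = C,
                 response = c(ra, rd) + stats::rnorm(length(ta) + length(td), 0, noise_sd),
                 probe_id = paste0("probe", i),
                 phase = rep(c("association", "dissociation"),
                             c(length(ta), length(td))))
    })
    ctls <- lapply(seq_len(n_controls), function(j) {
      data.frame(time_s = c(ta, t_assoc + td), conc_M = 0,
                 response = stats::rnorm(length(ta) + length(td), 0, noise_sd),
                 probe_id = paste0("control", j),
                 phase = rep(c("association", "dissociation"),
                             c(length(ta), length(td))))
    })
    sg <- sensorgram(do.call(rbind, c(rows, ctls)),
                     controls = paste0("control", seq_len(n_controls)))
    list(sensorgram = sg,
         truth = list(kd = kd, kon = kon, koff = koff, rmax = rmax, seed = seed))
  })
}
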