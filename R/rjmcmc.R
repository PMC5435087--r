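# Reversible-jump MCMC over branch rate-shift configurations of the
# Brownian-motion model. The shift count has a Poisson prior, shift
# locations are uniform over non-root nodes without replacement, and log
# multipliers are Gaussian. Birth proposals draw the multiplier from its
# prior, which cancels the multiplier prior in the acceptance ratio and
# needs no further Jacobian term; all continuous parameters are proposed by
# symmetric random walks on log (sigma2, multipliers) or natural (root
# value) scale.

#' Configuration for [rjmcmc_run()]
#'
#' @param generations Chain length (default 100000).
#' @param thin Sampling interval in generations (default 100).
#' @param burnin Fraction of samples discarded from the start (default
#'   0.25).
#' @param chains Number of independent runs (default 4).
#' @param seed Base seed; chain `i` uses `seed + i - 1`.
#' @param lambda Poisson prior mean on the number of shifts (default 1).
#' @param tau Prior standard deviation of log rate multipliers (default 1).
#' @param use_ancestral_values Use trait values observed at internal nodes
#'   (if present) in the likelihood? Default `TRUE`; with `FALSE` internal
#'   observations are dropped and only leaves inform the model.
#' @param prior_only Disable the likelihood (sample the prior); used for
#'   MCMC correctness checks.
#' @return A `bm_config` list.
#' @export
bm_config <- function(generations = 100000L, thin = 100L, burnin = 0.25,
                      chains = 4L, seed = 1L, lambda = 1, tau = 1,
                      use_ancestral_values = TRUE, prior_only = FALSE) {
  generations <- as.integer(generations); thin <- as.integer(thin)
  if (generations < thin) stop("'generations' must be >= 'thin'", call. = FALSE)
  if (generations < 10L * thin) {
    stop("chain too short: 'generations' must be >= 10 * 'thin'", call. = FALSE)
  }
  if (burnin < 0 || burnin >= 1) stop("'burnin' must be in [0, 1)", call. = FALSE)
  if (chains < 1L) stop("'chains' must be >= 1", call. = FALSE)
  if (lambda <= 0 || tau <= 0) stop("'lambda' and 'tau' must be > 0", call. = FALSE)
  structure(list(generations = generations, thin = thin, burnin = burnin,
                 chains = as.integer(chains), seed = as.integer(seed),
                 lambda = lambda, tau = tau,
                 use_ancestral_values = isTRUE(use_ancestral_values),
                 prior_only = isTRUE(prior_only)),
            class = "bm_config")
}

# single chain; returns a shift_posterior
rjmcmc_chain <- function(tree, values, ses, config, seed) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  eligible <- setdiff(seq_len(n), root)
  N <- length(eligible)
  par <- parent_vec(tree)
  tr_post <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- tr_post$edge[rev(seq_len(nrow(tr_post$edge))), , drop = FALSE]
  eff_of <- function(snode, smult) {
    eff <- rep(1, n)
    if (length(snode) > 0L) {
      shift_at <- rep(NA_real_, n)
      shift_at[snode] <- smult
      for (i in seq_len(nrow(pre_edges))) {
        p <- pre_edges[i, 1L]; chd <- pre_edges[i, 2L]
        eff[chd] <- if (is.na(shift_at[chd])) eff[p] else shift_at[chd]
      }
    }
    eff
  }
  lik <- if (config$prior_only) function(s2, mu0, eff) 0 else
    bm_lik_builder(tree, values, ses)

  obs <- as.numeric(values)
  mu_prior_mean <- mean(obs)
  mu_prior_sd <- 10 * max(stats::sd(obs), 1e-3)
  lambda <- config$lambda; tau <- config$tau

  log_prior <- function(lsig, mu0, logm) {
    k <- length(logm)
    stats::dpois(k, lambda, log = TRUE) - lchoose(N, k) +
      sum(stats::dnorm(logm, 0, tau, log = TRUE)) +
      stats::dunif(lsig, -20, 20, log = TRUE) +
      stats::dnorm(mu0, mu_prior_mean, mu_prior_sd, log = TRUE)
  }

  local_seed(seed, {
    lsig <- log(max(stats::var(obs), 1e-4))
    mu0 <- mu_prior_mean
    snode <- integer(0)        # shift node numbers
    slogm <- numeric(0)        # shift log multipliers
    eff <- rep(1, n)
    cur_ll <- lik(exp(lsig), mu0, eff)
    cur_lp <- log_prior(lsig, mu0, slogm)

    nsamp <- config$generations %/% config$thin
    trace <- data.frame(gen = integer(nsamp), sigma2 = numeric(nsamp),
                        mu0 = numeric(nsamp), n_shifts = integer(nsamp),
                        loglik = numeric(nsamp))
    samp_shifts <- vector("list", nsamp)
    si <- 0L
    accepted <- 0L

    shifts_vec <- function(nodes, logm) {
      stats::setNames(exp(logm), as.character(nodes))
    }

    for (gen in seq_len(config$generations)) {
      u <- stats::runif(1)
      prop <- NULL
      if (u < 0.25) {                    # birth
        if (length(snode) < N) {
          free <- setdiff(eligible, snode)
          nd <- free[sample.int(length(free), 1L)]
          lm <- stats::rnorm(1, 0, tau)
          prop <- list(snode = c(snode, nd), slogm = c(slogm, lm),
                       lsig = lsig, mu0 = mu0,
                       lqf = -log(length(free)) + stats::dnorm(lm, 0, tau, log = TRUE),
                       lqr = -log(length(snode) + 1L))
        }
      } else if (u < 0.5) {              # death
        if (length(snode) > 0L) {
          j <- sample.int(length(snode), 1L)
          prop <- list(snode = snode[-j], slogm = slogm[-j],
                       lsig = lsig, mu0 = mu0,
                       lqf = -log(length(snode)),
                       lqr = -log(N - length(snode) + 1L) +
                         stats::dnorm(slogm[j], 0, tau, log = TRUE))
        }
      } else if (u < 0.75) {             # move: reassign one shift node
        if (length(snode) > 0L && length(snode) < N) {
          j <- sample.int(length(snode), 1L)
          free <- setdiff(eligible, snode)
          nd <- free[sample.int(length(free), 1L)]
          ns <- snode; ns[j] <- nd
          prop <- list(snode = ns, slogm = slogm, lsig = lsig, mu0 = mu0,
                       lqf = 0, lqr = 0)
        }
      } else {                           # scale sigma2 / root value / multiplier
        what <- sample.int(if (length(snode) > 0L) 3L else 2L, 1L)
        if (what == 1L) {
          prop <- list(snode = snode, slogm = slogm,
                       lsig = lsig + stats::rnorm(1, 0, 0.4), mu0 = mu0,
                       lqf = 0, lqr = 0)
        } else if (what == 2L) {
          prop <- list(snode = snode, slogm = slogm, lsig = lsig,
                       mu0 = mu0 + stats::rnorm(1, 0, 0.4 * max(stats::sd(obs), 1e-3)),
                       lqf = 0, lqr = 0)
        } else {
          j <- sample.int(length(slogm), 1L)
          sm <- slogm; sm[j] <- sm[j] + stats::rnorm(1, 0, 0.4)
          prop <- list(snode = snode, slogm = sm, lsig = lsig, mu0 = mu0,
                       lqf = 0, lqr = 0)
        }
      }
      if (!is.null(prop)) {
        new_eff <- eff_of(prop$snode, exp(prop$slogm))
        new_ll <- lik(exp(prop$lsig), prop$mu0, new_eff)
        new_lp <- log_prior(prop$lsig, prop$mu0, prop$slogm)
        la <- (new_ll + new_lp) - (cur_ll + cur_lp) + prop$lqr - prop$lqf
        if (is.finite(la) && log(stats::runif(1)) < la) {
          snode <- prop$snode; slogm <- prop$slogm
          lsig <- prop$lsig; mu0 <- prop$mu0
          eff <- new_eff; cur_ll <- new_ll; cur_lp <- new_lp
          accepted <- accepted + 1L
        }
      }
      if (gen %% config$thin == 0L) {
        si <- si + 1L
        trace$gen[si] <- gen
        trace$sigma2[si] <- exp(lsig)
        trace$mu0[si] <- mu0
        trace$n_shifts[si] <- length(snode)
        trace$loglik[si] <- cur_ll
        samp_shifts[[si]] <- list(nodes = snode, mult = exp(slogm), eff = eff)
      }
    }

    keep <- seq_len(nsamp) > floor(config$burnin * nsamp)
    summarize_chain(tree, trace, samp_shifts, keep, par,
                    acceptance = accepted / config$generations)
  })
}

summarize_chain <- function(tree, trace, samp_shifts, keep, par, acceptance) {
  n <- ape::Ntip(tree) + tree$Nnode
  kept <- samp_shifts[keep]
  m <- length(kept)
  up <- dn <- numeric(n)
  effsum <- numeric(n)
  for (s in kept) {
    effsum <- effsum + s$eff
    if (length(s$nodes) > 0L) {
      parent_eff <- ifelse(par[s$nodes] == 0L, 1, s$eff[pmax(par[s$nodes], 1L)])
      inc <- s$mult > parent_eff
      up[s$nodes[inc]] <- up[s$nodes[inc]] + 1
      dn[s$nodes[!inc]] <- dn[s$nodes[!inc]] + 1
    }
  }
  nm <- as.character(seq_len(n))
  structure(list(tree = tree,
                 p_shift = stats::setNames((up + dn) / m, nm),
                 p_shift_up = stats::setNames(up / m, nm),
                 p_shift_down = stats::setNames(dn / m, nm),
                 mean_multiplier = stats::setNames(effsum / m, nm),
                 trace = trace[keep, , drop = FALSE],
                 full_trace = trace,
                 n_samples = m, acceptance = acceptance),
            class = "shift_posterior")
}

#' Reversible-jump MCMC over Brownian-motion rate shifts
#'
#' Runs `config$chains` independent Metropolis-Hastings chains with
#' birth/death/move/scale proposals (25% each) over rate-shift
#' configurations, thins each chain, discards burn-in, and pools post
#' burn-in samples across chains. Reproducible for a given `config$seed`.
#'
#' @param tree A rooted `phylo` tree.
#' @param values Named numeric vector of trait observations keyed by node
#'   number (leaves, optionally internal nodes).
#' @param ses Optional named numeric vector of standard errors.
#' @param config A [bm_config()] object.
#' @return A `shift_posterior` object with pooled per-node shift
#'   probabilities (`p_shift`, split into `p_shift_up` / `p_shift_down` by
#'   whether the sampled multiplier exceeds the parent's effective rate),
#'   per-branch `mean_multiplier`, pooled `trace`, per-chain results in
#'   `$runs` and, for >= 2 chains, `$asdsf`.
#' @export
rjmcmc_run <- function(tree, values, ses = NULL, config = bm_config()) {
  if (!inherits(config, "bm_config")) stop("'config' must be a bm_config")
  ntip <- ape::Ntip(tree)
  if (!config$use_ancestral_values) {
    keep <- as.integer(names(values)) <= ntip
    values <- values[keep]
    if (!is.null(ses)) ses <- ses[as.integer(names(ses)) <= ntip]
  }
  if (length(values) < 3L) stop("need >= 3 observed values", call. = FALSE)
  runs <- lapply(seq_len(config$chains), function(i) {
    rjmcmc_chain(tree, values, ses, config, seed = config$seed + i - 1L)
  })
  if (config$chains == 1L) {
    out <- runs[[1L]]
    out$runs <- runs
    out$config <- config
    return(out)
  }
  n <- ape::Ntip(tree) + tree$Nnode
  msum <- function(f) Reduce(`+`, lapply(runs, `[[`, f)) / length(runs)
  wsum <- function(f) {
    tot <- vapply(runs, `[[`, 0, "n_samples")
    Reduce(`+`, Map(function(r, w) r[[f]] * w, runs, tot)) / sum(tot)
  }
  out <- structure(list(tree = tree,
                        p_shift = wsum("p_shift"),
                        p_shift_up = wsum("p_shift_up"),
                        p_shift_down = wsum("p_shift_down"),
                        mean_multiplier = wsum("mean_multiplier"),
                        trace = do.call(rbind, lapply(seq_along(runs), function(i) {
                          tr <- runs[[i]]$trace; tr$chain <- i; tr
                        })),
                        n_samples = sum(vapply(runs, `[[`, 0, "n_samples")),
                        runs = runs, config = config),
                   class = "shift_posterior")
  out$asdsf <- asdsf(runs)
  out
}

#' @export
print.shift_posterior <- function(x, ...) {
  top <- sort(x$p_shift, decreasing = TRUE)
  top <- top[top > 0]
  cat(sprintf("BM rate-shift posterior: %d pooled samples\n", x$n_samples))
  if (!is.null(x$asdsf)) {
    cat(sprintf("  ASDSF = %.4g (%s)\n", x$asdsf$asdsf,
                if (x$asdsf$converged) "converged, < 0.01" else ">= 0.01"))
  }
  if (length(top) > 0L) {
    show <- utils::head(top, 5L)
    cat("  top shift nodes:",
        paste(sprintf("%s (%.2f)", names(show), show), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a shift posterior as a per-node table
#'
#' @param posterior A [rjmcmc_run()] result.
#' @param path Optional TSV output path.
#' @return Data frame with `node`, `p_shift_up`, `p_shift_down`,
#'   `mean_multiplier`.
#' @export
shift_posterior_table <- function(posterior, path = NULL) {
  out <- data.frame(node = as.integer(names(posterior$p_shift)),
                    p_shift_up = unname(posterior$p_shift_up),
                    p_shift_down = unname(posterior$p_shift_down),
                    mean_multiplier = unname(posterior$mean_multiplier))
  if (!is.null(path)) write_tsv(out, path)
  out
}
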