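# Brownian-motion model of trait evolution on a phylogeny with
# branch-specific rate multipliers. The trait variance accumulated along a
# branch is sigma2 * multiplier * branch length (branch lengths in
# substitutions/site, so sigma2 is the coefficient of proportionality
# between trait change and sequence change). Observation noise enters as
# per-observation squared standard errors.

#' Rate-shift state for the Brownian-motion model
#'
#' A shift placed at node `n` applies its multiplier to the branch above `n`
#' and to every descendant branch, until overridden by a nested shift deeper
#' in the subtree.
#'
#' @param sigma2 Base trait variance per substitution/site (> 0).
#' @param root_value Trait value at the root.
#' @param shifts Named numeric vector of rate multipliers (> 0) keyed by
#'   node number; the root cannot carry a shift.
#' @return A `rate_state` list.
#' @export
rate_state <- function(sigma2, root_value = 0, shifts = numeric(0)) {
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be > 0", call. = FALSE)
  }
  if (length(shifts) > 0L && any(shifts <= 0)) {
    stop("rate multipliers must be > 0", call. = FALSE)
  }
  structure(list(sigma2 = sigma2, root_value = root_value, shifts = shifts),
            class = "rate_state")
}

#' Effective per-branch rate multipliers implied by a set of shifts
#'
#' @param tree A rooted `phylo` tree.
#' @param shifts Named numeric vector of multipliers keyed by node number.
#' @return Numeric vector over all nodes: the multiplier applying to the
#'   branch above each node (1 at the root and wherever no shift is
#'   inherited).
#' @export
effective_multipliers <- function(tree, shifts) {
  n <- ape::Ntip(tree) + tree$Nnode
  eff <- rep(1, n)
  if (length(shifts) == 0L) return(eff)
  shift_at <- rep(NA_real_, n)
  shift_at[as.integer(names(shifts))] <- shifts
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(tr$edge)))) {   # preorder: parents first
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    eff[ch] <- if (!is.na(shift_at[ch])) shift_at[ch] else eff[p]
  }
  eff
}

# Precompute tree bookkeeping for repeated BM likelihood evaluation.
# Returns a closure f(sigma2, root_value, eff) -> log-likelihood, where eff
# is the per-node effective-multiplier vector.
bm_lik_builder <- function(tree, values, ses = NULL) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  obs <- rep(NA_real_, n); sev <- rep(0, n)
  idx <- as.integer(names(values))
  if (length(idx) == 0L || anyNA(idx) || any(idx < 1L | idx > n)) {
    stop("'values' names must be node numbers of the tree", call. = FALSE)
  }
  obs[idx] <- values
  if (!is.null(ses)) sev[as.integer(names(ses))] <- ses
  plen <- parent_edge_length(tree)
  ch <- children_list(tree)
  post <- postorder_nodes(tree)
  root <- ntip + 1L
  tipV0 <- ifelse(is.na(obs[seq_len(ntip)]), Inf, sev[seq_len(ntip)]^2)

  function(sigma2, root_value, eff) {
    mu <- c(obs[seq_len(ntip)], rep(NA_real_, n - ntip))
    V <- c(tipV0, rep(Inf, n - ntip))
    ll <- 0
    for (nd in post) {
      kids <- ch[[nd]]
      ms <- mu[kids]
      vs <- V[kids] + sigma2 * eff[kids] * plen[kids]
      if (!is.na(obs[nd])) { ms <- c(ms, obs[nd]); vs <- c(vs, sev[nd]^2) }
      keep <- is.finite(vs) & !is.na(ms)
      ms <- ms[keep]; vs <- vs[keep]
      if (length(ms) == 0L) { mu[nd] <- NA_real_; V[nd] <- Inf; next }
      m <- ms[1L]; v <- vs[1L]
      for (i in seq_along(ms)[-1L]) {
        tot <- v + vs[i]
        ll <- ll + stats::dnorm(ms[i] - m, 0, sqrt(tot), log = TRUE)
        m <- (vs[i] * m + v * ms[i]) / tot
        v <- v * vs[i] / tot
      }
      mu[nd] <- m; V[nd] <- v
    }
    if (is.finite(V[root])) {
      ll <- ll + stats::dnorm(mu[root], root_value, sqrt(V[root]), log = TRUE)
    }
    ll
  }
}

#' Brownian-motion log-likelihood with rate shifts and measurement error
#'
#' Gaussian log-density of the observed trait values under the shifted BM
#' model, computed by pruning (no dense covariance inversion). Values may be
#' supplied at leaves only or at leaves and internal nodes; internal
#' observations enter as observations with their own standard errors.
#' Observations with infinite standard error are ignored.
#'
#' @param tree A rooted `phylo` tree.
#' @param values Named numeric vector of observed trait values keyed by node
#'   number.
#' @param ses Named numeric vector of standard errors (>= 0) over the same
#'   nodes; missing entries default to 0.
#' @param state A [rate_state()] object.
#' @return Log-likelihood.
#' @export
bm_log_likelihood <- function(tree, values, ses = NULL, state) {
  if (!inherits(state, "rate_state")) {
    stop("'state' must be a rate_state", call. = FALSE)
  }
  lik <- bm_lik_builder(tree, values, ses)
  lik(state$sigma2, state$root_value, effective_multipliers(tree, state$shifts))
}

#' Average standard deviation of shift posterior probabilities across runs
#'
#' Convergence diagnostic for independent MCMC runs on the same tree: the
#' mean over nodes of the across-run sample standard deviation (n-1
#' denominator) of the per-node posterior shift probability. Chains are
#' conventionally called converged when this falls below 0.01.
#'
#' @param runs List of >= 2 `shift_posterior` objects from [rjmcmc_run()]
#'   (for a multi-chain result, its `$runs` element).
#' @return List with `asdsf` and logical `converged` (asdsf < 0.01).
#' @export
asdsf <- function(runs) {
  if (length(runs) < 2L) stop("need >= 2 runs", call. = FALSE)
  if (!all(vapply(runs, function(r)
    identical(names(r$p_shift), names(runs[[1L]]$p_shift)), TRUE))) {
    stop("runs were computed on different trees", call. = FALSE)
  }
  pmat <- vapply(runs, function(r) r$p_shift, numeric(length(runs[[1L]]$p_shift)))
  pmat <- matrix(pmat, ncol = length(runs))
  val <- mean(apply(pmat, 1L, stats::sd))
  list(asdsf = val, converged = val < 0.01)
}
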