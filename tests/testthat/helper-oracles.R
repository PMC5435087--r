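# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the code paths they check: transition probabilities
# come from Matrix::expm rather than the package's eigendecomposition,
# likelihoods and marginals from exhaustive enumeration rather than
# pruning, BM densities from a dense multivariate normal, and clade
# frequencies from ape::prop.part.

# brute-force tree log-likelihood and marginal posteriors by enumerating
# all joint internal-node state assignments (feasible for <= 5 leaves and a
# handful of sites)
oracle_asr <- function(msa, tree, model) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  ns <- length(model$states)
  internal <- (ntip + 1L):n
  plen <- affshift:::parent_edge_length(tree)
  par <- affshift:::parent_vec(tree)
  nsite <- ncol(msa)
  tipvec <- function(chr) affshift:::tip_state_vec(chr, model)

  post <- lapply(internal, function(nd) matrix(0, nsite, ns))
  names(post) <- as.character(internal)
  site_ll <- numeric(nsite)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(internal))))
  colnames(grid) <- as.character(internal)

  for (site in seq_len(nsite)) {
    wtot <- matrix(0, nrow(grid), model$k)
    for (ci in seq_len(model$k)) {
      P <- lapply(seq_len(n), function(nd) {
        if (is.na(plen[nd])) return(NULL)
        as.matrix(Matrix::expm(model$Q * plen[nd] * model$rates[ci]))
      })
      w <- model$pi[grid[, as.character(root)]]
      for (nd in setdiff(internal, root)) {
        w <- w * P[[nd]][cbind(grid[, as.character(par[nd])],
                               grid[, as.character(nd)])]
      }
      for (tp in seq_len(ntip)) {
        tv <- tipvec(unclass(msa)[tree$tip.label[tp], site])
        w <- w * as.numeric(P[[tp]] %*% tv)[grid[, as.character(par[tp])]]
      }
      wtot[, ci] <- w
    }
    w <- rowSums(wtot) / model$k
    site_ll[site] <- log(sum(w))
    for (nd in internal) {
      key <- as.character(nd)
      for (s in seq_len(ns)) {
        post[[key]][site, s] <- sum(w[grid[, key] == s]) / sum(w)
      }
    }
  }
  list(loglik = sum(site_ll), posterior = post)
}

# dense multivariate-normal BM log-likelihood (shared-path covariance plus
# diagonal measurement error), observations at any subset of nodes
oracle_bm_loglik <- function(tree, values, ses, state) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  par <- affshift:::parent_vec(tree)
  plen <- affshift:::parent_edge_length(tree)
  eff <- effective_multipliers(tree, state$shifts)
  path <- function(i) { p <- integer(0); while (i != root) { p <- c(p, i); i <- par[i] }; p }
  obs_nodes <- as.integer(names(values))
  sev <- rep(0, length(obs_nodes))
  if (!is.null(ses)) {
    m <- match(obs_nodes, as.integer(names(ses)))
    sev[!is.na(m)] <- ses[m[!is.na(m)]]
  }
  keep <- is.finite(sev)
  obs_nodes <- obs_nodes[keep]; x <- as.numeric(values)[keep]; sev <- sev[keep]
  m <- length(obs_nodes)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    sh <- intersect(path(obs_nodes[i]), path(obs_nodes[j]))
    S[i, j] <- sum(state$sigma2 * eff[sh] * plen[sh])
  }
  S <- S + diag(sev^2, m)
  d <- x - state$root_value
  as.numeric(-0.5 * (m * log(2 * pi) + determinant(S)$modulus +
                       t(d) %*% solve(S) %*% d))
}

# permutation-test two-tailed p for a difference in means
oracle_perm_p <- function(a, b, nperm = 1e5, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  z <- c(a, b); na <- length(a)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nperm)) {
    idx <- sample.int(length(z), na)
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / nperm
}

# clade frequencies across rooted trees on a common taxon set, via
# ape::prop.part (independent of the package's own clade coding)
oracle_clade_freqs <- function(trees) {
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")
  data.frame(clade = out, count = attr(pp, "number"),
             size = lengths(pp), stringsAsFactors = FALSE)
}

# complete-graph edge list among ids at a common E-value
clique_edges <- function(ids, e) {
  g <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  g <- g[g$a < g$b, ]
  data.frame(g, e = e)
}

# non-trivial clades of a single tree as sorted "a|b|c" keys (via prop.part)
tree_clades_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")
  sizes <- lengths(pp)
  keys[sizes >= 2 & sizes < ape::Ntip(tree)]
}

# small fixed 4-taxon alignment/tree pair used across tests
fixture_small <- function() {
  tree <- read_tree(text = "((a:0.2,b:0.4)0.9:0.3,(c:0.1,d:0.6)0.7:0.2);")
  msa <- as_msa(c(a = "HKA", b = "H-A", c = "QKV", d = "XRV"))
  list(tree = tree, msa = msa)
}
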