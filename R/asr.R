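# Tree likelihood by pruning and marginal ancestral sequence reconstruction
# with per-site posteriors, plus posterior sampling of ancestral sequences.

# indicator partial-likelihood vector for one observed character
tip_state_vec <- function(ch, model) {
  ns <- length(model$states)
  v <- numeric(ns)
  if (ch == AMBIG) {
    v[seq_len(20L)] <- 1        # unknown residue: any amino acid, not a gap
  } else if (ch == GAP && !model$gap_state) {
    v[] <- 1                    # gap as missing data in the 20-state model
  } else {
    i <- match(ch, model$states)
    if (is.na(i)) stop("character not in model alphabet: ", ch, call. = FALSE)
    v[i] <- 1
  }
  v
}

check_pairing <- function(msa, tree) {
  miss <- setdiff(tree$tip.label, rownames(msa))
  if (length(miss) > 0L) {
    stop("tree leaves missing from alignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

# One full pruning pass. Returns, per gamma category: scaled downward
# partials per node (states x sites), per-site log scaling totals, and the
# per-site log-likelihood; plus the transition matrices used.
pruning_pass <- function(msa, tree, model, keep_partials = FALSE) {
  check_pairing(msa, tree)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nsite <- ncol(msa)
  ns <- length(model$states)
  ch <- children_list(tree)
  plen <- parent_edge_length(tree)
  post <- postorder_nodes(tree)
  root <- ntip + 1L

  tipmat <- lapply(seq_len(ntip), function(i) {
    s <- unclass(msa)[tree$tip.label[i], ]
    vapply(s, tip_state_vec, numeric(ns), model = model)
  })

  cats <- vector("list", model$k)
  for (ci in seq_len(model$k)) {
    r <- model$rates[ci]
    Pmats <- vector("list", ntip + nnode)
    for (nd in seq_len(ntip + nnode)) {
      if (!is.na(plen[nd])) Pmats[[nd]] <- transition_matrix(model, plen[nd], r)
    }
    D <- vector("list", ntip + nnode)
    logscale <- matrix(0, nrow = ntip + nnode, ncol = nsite)
    for (i in seq_len(ntip)) D[[i]] <- tipmat[[i]]
    for (nd in post) {
      part <- matrix(1, ns, nsite)
      sc <- numeric(nsite)
      for (cc in ch[[nd]]) {
        part <- part * (Pmats[[cc]] %*% D[[cc]])
        sc <- sc + logscale[cc, ]
      }
      mx <- apply(part, 2L, max)
      mx[mx == 0] <- 1          # impossible site; keep zeros, loglik -> -Inf
      part <- sweep(part, 2L, mx, "/")
      D[[nd]] <- part
      logscale[nd, ] <- sc + log(mx)
    }
    sitelik <- colSums(D[[root]] * model$pi)
    cats[[ci]] <- list(D = if (keep_partials) D else NULL,
                       Pmats = if (keep_partials) Pmats else NULL,
                       logscale = logscale[root, ],
                       site_loglik = log(sitelik) + logscale[root, ])
  }
  list(cats = cats, root = root, ntip = ntip, nnode = nnode,
       nsite = nsite, ns = ns, children = ch)
}

#' Phylogenetic log-likelihood of an alignment
#'
#' Felsenstein pruning over all ancestral states, mixed over discrete-gamma
#' rate categories with equal weights.
#'
#' @param msa An [as_msa()] object containing every tree leaf.
#' @param tree A rooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @param model A [aa_model()] object.
#' @return The log-likelihood (a single number).
#' @export
tree_log_likelihood <- function(msa, tree, model) {
  pp <- pruning_pass(msa, tree, model)
  sl <- vapply(pp$cats, `[[`, numeric(pp$nsite), "site_loglik")
  sl <- matrix(sl, nrow = pp$nsite)
  sum(apply(sl, 1L, logsumexp) - log(model$k))
}

#' Marginal ancestral sequence reconstruction
#'
#' For every internal node and alignment column, computes the posterior
#' probability of each character state by combining the partial likelihoods
#' below and above the node, re-weighted by the root prior; with several
#' gamma categories the posterior is the mixture across categories weighted
#' by per-site category likelihoods. The maximum-likelihood sequence takes
#' the per-site argmax (ties broken alphabetically by state symbol).
#'
#' @inheritParams tree_log_likelihood
#' @return An object of class `asr_recon` with elements `posterior` (list
#'   keyed by internal node number: sites x states probability matrix),
#'   `ml_sequence` (named character vector), `mean_posterior` (named numeric,
#'   mean over sites of the ML state's posterior), `log_likelihood`, `tree`,
#'   `states`.
#' @export
marginal_asr <- function(msa, tree, model) {
  if (!ape::is.rooted(tree)) {
    stop("marginal reconstruction requires a rooted tree", call. = FALSE)
  }
  pp <- pruning_pass(msa, tree, model, keep_partials = TRUE)
  ntip <- pp$ntip; nsite <- pp$nsite; ns <- pp$ns
  root <- pp$root
  ch <- pp$children
  internal <- ntip + seq_len(pp$nnode)

  # per-site category weights from per-category site log-likelihoods
  sl <- vapply(pp$cats, `[[`, numeric(nsite), "site_loglik")
  sl <- matrix(sl, nrow = nsite)
  totll <- apply(sl, 1L, logsumexp)
  w <- exp(sl - totll)                      # nsite x k

  postr <- vector("list", length(internal))
  names(postr) <- as.character(internal)
  for (ii in seq_along(postr)) postr[[ii]] <- matrix(0, nsite, ns)

  pre <- rev(postorder_nodes(tree))         # parents before children
  for (ci in seq_len(model$k)) {
    D <- pp$cats[[ci]]$D
    P <- pp$cats[[ci]]$Pmats
    U <- vector("list", ntip + pp$nnode)
    U[[root]] <- matrix(model$pi, ns, nsite)
    for (nd in pre) {
      kids <- ch[[nd]]
      M <- lapply(kids, function(cc) P[[cc]] %*% D[[cc]])
      for (j in seq_along(kids)) {
        cc <- kids[[j]]
        if (cc <= ntip) next
        up <- U[[nd]]
        for (s in seq_along(kids)) if (s != j) up <- up * M[[s]]
        up <- crossprod(P[[cc]], up)        # t(P) %*% up
        mx <- apply(up, 2L, max)
        mx[mx == 0] <- 1
        U[[cc]] <- sweep(up, 2L, mx, "/")
      }
    }
    for (nd in internal) {
      J <- U[[nd]] * D[[nd]]                # ns x nsite, unnormalized joint
      cs <- colSums(J)
      cs[cs == 0] <- 1
      pc <- t(J) / cs                       # nsite x ns
      key <- as.character(nd)
      postr[[key]] <- postr[[key]] + pc * w[, ci]
    }
  }

  # ML sequence with alphabetical tie-break on the state symbol
  ord <- order(model$states)
  mlseq <- character(length(internal))
  meanp <- numeric(length(internal))
  for (ii in seq_along(internal)) {
    pm <- postr[[ii]]
    colnames(pm) <- model$states
    pick <- apply(pm[, ord, drop = FALSE], 1L, which.max)
    mlseq[ii] <- paste(model$states[ord][pick], collapse = "")
    meanp[ii] <- mean(pm[cbind(seq_len(nsite), ord[pick])])
    postr[[ii]] <- pm
  }
  names(mlseq) <- names(postr)
  names(meanp) <- names(postr)
  structure(list(posterior = postr, ml_sequence = mlseq,
                 mean_posterior = meanp,
                 log_likelihood = sum(totll) - nsite * log(model$k),
                 tree = tree, states = model$states),
            class = "asr_recon")
}

#' @export
print.asr_recon <- function(x, ...) {
  cat(sprintf(
    "Marginal ancestral reconstruction: %d internal nodes, %d sites, logL = %.4f\n",
    length(x$posterior), nrow(x$posterior[[1L]]), x$log_likelihood))
  invisible(x)
}

#' Sample ancestral sequences from per-site posteriors
#'
#' Each sequence is drawn independently, site `i` from the node's site-`i`
#' posterior state distribution.
#'
#' @param recon An [marginal_asr()] result.
#' @param node Internal node number.
#' @param n Number of sequences to draw (default 20).
#' @param seed Integer seed; draws are reproducible.
#' @return Character vector of `n` sequences.
#' @export
sample_ancestral <- function(recon, node, n = 20L, seed = 1L) {
  key <- as.character(node)
  if (!key %in% names(recon$posterior)) {
    stop("not an internal node of the reconstruction: ", node, call. = FALSE)
  }
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  pm <- recon$posterior[[key]]
  states <- recon$states
  local_seed(seed, {
    vapply(seq_len(n), function(dummy) {
      idx <- apply(pm, 1L, function(p) sample.int(length(states), 1L, prob = p))
      paste(states[idx], collapse = "")
    }, "")
  })
}

#' Mean posterior probability of the ML state at a node
#'
#' @inheritParams sample_ancestral
#' @return Mean over alignment columns of the posterior probability of the
#'   maximum-likelihood state; a reconstruction-ambiguity summary in (0, 1].
#' @export
node_mean_posterior <- function(recon, node) {
  key <- as.character(node)
  if (!key %in% names(recon$posterior)) {
    stop("not an internal node of the reconstruction: ", node, call. = FALSE)
  }
  pm <- recon$posterior[[key]]
  ml <- strsplit(recon$ml_sequence[[key]], "", fixed = TRUE)[[1L]]
  mean(pm[cbind(seq_len(nrow(pm)), match(ml, recon$states))])
}

#' Estimate the gamma shape parameter by likelihood maximization
#'
#' One-dimensional golden-section/parabolic search (`stats::optimize`) over
#' log-alpha, tolerance 1e-4.
#'
#' @inheritParams tree_log_likelihood
#' @param interval Search range for alpha.
#' @return The input model with `alpha` (and category rates) replaced by the
#'   maximum-likelihood estimate.
#' @export
fit_gamma_shape <- function(msa, tree, model, interval = c(0.05, 50)) {
  f <- function(la) {
    m <- model
    m$alpha <- exp(la)
    m$rates <- discrete_gamma_rates(m$alpha, m$k)
    -tree_log_likelihood(msa, tree, m)
  }
  opt <- stats::optimize(f, interval = log(interval), tol = 1e-4)
  model$alpha <- exp(opt$minimum)
  model$rates <- discrete_gamma_rates(model$alpha, model$k)
  model
}

#' Export per-node posteriors as a tidy table
#'
#' @param recon An [marginal_asr()] result.
#' @param path Optional TSV output path.
#' @return Data frame with columns `node`, `site` and one probability column
#'   per state.
#' @export
asr_posterior_table <- function(recon, path = NULL) {
  rows <- lapply(names(recon$posterior), function(key) {
    pm <- recon$posterior[[key]]
    data.frame(node = as.integer(key), site = seq_len(nrow(pm)), pm,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("node", "site", recon$states)
  if (!is.null(path)) write_tsv(out, path)
  out
}

#' Export ML (and optionally sampled) ancestral sequences as FASTA
#'
#' @param recon An [marginal_asr()] result.
#' @param path Output FASTA path.
#' @param n_sampled If > 0, additionally write `n_sampled` posterior draws
#'   per node (headers `node<id>_sample<j>`).
#' @param seed Seed for the sampled sequences.
#' @return `path`, invisibly.
#' @export
write_ancestral_fasta <- function(recon, path, n_sampled = 0L, seed = 1L) {
  seqs <- recon$ml_sequence
  names(seqs) <- paste0("node", names(seqs), "_ml")
  if (n_sampled > 0L) {
    for (key in names(recon$posterior)) {
      draws <- sample_ancestral(recon, as.integer(key), n_sampled, seed)
      names(draws) <- paste0("node", key, "_sample", seq_along(draws))
      seqs <- c(seqs, draws)
    }
  }
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
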