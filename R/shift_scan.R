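# Branch-wise scan for affinity shifts: Welch tests on parent-vs-child
# replicate pKd vectors, Benjamini-Hochberg FDR across all branches, and the
# robustness / ambiguity diagnostics that accompany the scan.

#' Welch's unequal-variance t test
#'
#' Two-tailed unpaired t statistic with Satterthwaite degrees of freedom.
#' When both samples have zero variance: p = 1 if the means are equal
#' (t = 0), otherwise p = 0 (infinite t).
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_t requires at least 2 observations per sample", call. = FALSE)
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order (monotone after cumulative-minimum
#'   enforcement).
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Scan every branch of a phylogeny for affinity shifts
#'
#' For each non-root branch, compares the parent's and child's replicate pKd
#' vectors with [welch_t()]; p-values are corrected jointly across all
#' branches with [bh_fdr()] and branches are flagged significant at
#' `q < alpha`.
#'
#' @param tree A rooted `phylo` tree.
#' @param profiles Named list of [affinity_profile()] objects keyed by node
#'   number; every node in the tree needs a profile with >= 2 replicates.
#' @param alpha FDR significance level (default 0.05).
#' @return A `shift_scan` data frame with one row per branch: `parent`,
#'   `child`, `child_label` (tip label or empty), `delta` (child mean minus
#'   parent mean pKd), `t`, `p`, `q`, `significant`, `robust` (NA until
#'   filled by [robustness_test()]).
#' @export
branch_scan <- function(tree, profiles, alpha = 0.05) {
  stopif_not_scalar_prob(alpha, "alpha")
  need <- as.character(sort(unique(as.vector(tree$edge))))
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0L) {
    stop("missing affinity profiles for node(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  res <- lapply(seq_len(nrow(tree$edge)), function(i) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    pp <- profiles[[as.character(p)]]
    cp <- profiles[[as.character(c)]]
    wt <- welch_t(cp$replicates, pp$replicates)
    data.frame(parent = p, child = c,
               child_label = if (c <= ntip) tree$tip.label[c] else "",
               delta = cp$mean - pp$mean, t = wt$t, p = wt$p)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$parent, out$child), , drop = FALSE]
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out$robust <- NA
  class(out) <- c("shift_scan", "data.frame")
  out
}

#' Robustness of a node's affinity to reconstruction ambiguity
#'
#' Compares the replicate affinities of the maximum-likelihood ancestral
#' sequence against the pooled affinities of sequences sampled from the
#' ancestral posterior. The node is robust when the two are not
#' significantly different (`p > alpha`).
#'
#' @param ml_reps Replicate pKd values of the ML ancestral sequence.
#' @param sampled_reps Pooled replicate pKd values over all posterior-draw
#'   sequences (default 20 draws per node).
#' @param alpha Significance level (default 0.05).
#' @return List with `p` and logical `robust`.
#' @export
robustness_test <- function(ml_reps, sampled_reps, alpha = 0.05) {
  wt <- welch_t(ml_reps, sampled_reps)
  list(p = wt$p, robust = wt$p > alpha)
}

#' Correlation between reconstruction ambiguity and predicted affinity
#'
#' Pearson and Spearman correlations between per-node mean posterior
#' probabilities and pKd estimates, with t-distributed significance.
#'
#' @param mean_posteriors Named numeric vector (per node).
#' @param pkds Named numeric vector over the same nodes.
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`.
#' @export
ambiguity_correlation <- function(mean_posteriors, pkds) {
  common <- intersect(names(mean_posteriors), names(pkds))
  if (length(common) >= 3L) {
    x <- mean_posteriors[common]; y <- pkds[common]
  } else {
    x <- mean_posteriors; y <- pkds
  }
  if (length(x) < 3L || length(x) != length(y)) {
    stop("need >= 3 paired nodes", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Mode of a Gaussian kernel density estimate
#'
#' Density evaluated on a 512-point grid spanning the data range plus three
#' bandwidths on each side; Silverman's rule of thumb by default. Ties go to
#' the lower value (first grid argmax).
#'
#' @param values Numeric vector (n >= 2).
#' @param bandwidth Either `"silverman"` or a positive number.
#' @return The grid point of maximal estimated density.
#' @export
kde_mode <- function(values, bandwidth = "silverman") {
  if (length(values) < 2L) stop("kde_mode requires n >= 2", call. = FALSE)
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values) else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  d <- stats::density(values, bw = bw, n = 512L, cut = 3)
  d$x[which.max(d$y)]
}

#' Write a shift-scan report to TSV
#'
#' @param scan A [branch_scan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  write_tsv(as.data.frame(scan), path)
}
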