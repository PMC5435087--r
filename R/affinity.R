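# pKd algebra, replicate aggregation, and the pluggable affinity-predictor
# contract. Kd is stored in molar internally; convert at I/O only.

#' Convert a dissociation constant to pKd
#'
#' `pKd = -log10(Kd)` with Kd in molar; higher pKd means higher affinity.
#'
#' @param kd Dissociation constant in molar (> 0).
#' @return pKd (dimensionless).
#' @export
pkd_from_kd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("'kd' must be a positive finite concentration in molar", call. = FALSE)
  }
  -log10(kd)
}

#' Convert pKd back to a dissociation constant (molar)
#'
#' Exact inverse of [pkd_from_kd()].
#'
#' @param pkd pKd value(s).
#' @return Kd in molar.
#' @export
kd_from_pkd <- function(pkd) {
  if (any(!is.finite(pkd))) stop("'pkd' must be finite", call. = FALSE)
  10^(-pkd)
}

#' Fold change between two dissociation constants
#'
#' Ratio of the larger to the smaller Kd, so the result is always >= 1 and
#' symmetric in argument order.
#'
#' @param kd_a,kd_b Dissociation constants (same units, > 0).
#' @return Fold change (>= 1).
#' @export
fold_change <- function(kd_a, kd_b) {
  if (any(c(kd_a, kd_b) <= 0)) stop("Kd values must be > 0", call. = FALSE)
  max(kd_a, kd_b) / min(kd_a, kd_b)
}

#' Mean and standard error of replicate measurements
#'
#' @param values Numeric vector of replicate values (n >= 1).
#' @return List with `mean`, `se` (sd/sqrt(n), sample sd with n-1 degrees of
#'   freedom) and `n`. A single replicate yields `se = 0` with a warning.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(values)
  if (n == 1L) {
    warning("single replicate: standard error reported as 0")
    return(list(mean = values, se = 0, n = 1L))
  }
  list(mean = mean(values), se = stats::sd(values) / sqrt(n), n = n)
}

#' Construct a per-node affinity profile
#'
#' @param node Node number the replicates belong to.
#' @param replicates Numeric vector of replicate pKd values.
#' @param source One of `"ml"`, `"sampled"`, `"experimental"`.
#' @return An `affinity_profile` list with `node`, `replicates`, `mean`,
#'   `se`, `n`, `source`.
#' @export
affinity_profile <- function(node, replicates, source = c("ml", "sampled", "experimental")) {
  source <- match.arg(source)
  agg <- suppressWarnings(aggregate_replicates(replicates))
  structure(list(node = node, replicates = replicates, mean = agg$mean,
                 se = agg$se, n = agg$n, source = source),
            class = "affinity_profile")
}

#' Synthetic additive affinity predictor
#'
#' Stand-in for a structure-based affinity predictor, used to exercise the
#' pipeline with known ground truth. The noiseless prediction for a sequence
#' is `baseline` plus the sum of per-site, per-residue weights; each
#' replicate adds independent Gaussian noise.
#'
#' @param weights Named list mapping alignment column (as integer-valued
#'   name) to a named numeric vector of per-residue pKd contributions.
#' @param baseline Baseline pKd for a sequence carrying no weighted residue.
#' @param noise_sd Replicate noise standard deviation (pKd units).
#' @return A predictor closure `f(sequence, n_replicates, seed)` returning a
#'   numeric vector of replicate pKd values; identical `(sequence, seed)`
#'   give identical output.
#' @export
synthetic_predictor <- function(weights, baseline = 4.3, noise_sd = 0.1) {
  sites <- as.integer(names(weights))
  if (anyNA(sites)) stop("weight names must be alignment column indices", call. = FALSE)
  score <- function(sequence) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    if (any(sites > length(chars) | sites < 1L)) {
      stop("weight site index out of sequence range", call. = FALSE)
    }
    s <- baseline
    for (i in seq_along(sites)) {
      w <- weights[[i]][chars[sites[i]]]
      if (!is.na(w)) s <- s + unname(w)
    }
    s
  }
  function(sequence, n_replicates = 5L, seed = 1L) {
    mu <- score(sequence)
    local_seed(seed, mu + stats::rnorm(n_replicates, 0, noise_sd))
  }
}

#' Write affinity profiles to a TSV table
#'
#' Columns: `node`, `source`, `rep_1..rep_n`, `mean`, `se`.
#'
#' @param profiles List of [affinity_profile()] objects.
#' @param path Optional output path.
#' @return The data frame, invisibly written to `path` when given.
#' @export
write_affinity_tsv <- function(profiles, path = NULL) {
  nrep <- max(vapply(profiles, function(p) length(p$replicates), 1L))
  rows <- lapply(profiles, function(p) {
    reps <- c(p$replicates, rep(NA_real_, nrep - length(p$replicates)))
    c(list(node = p$node, source = p$source),
      stats::setNames(as.list(reps), paste0("rep_", seq_len(nrep))),
      list(mean = p$mean, se = p$se))
  })
  out <- do.call(rbind.data.frame, rows)
  if (!is.null(path)) write_tsv(out, path)
  out
}

#' Read affinity profiles from a TSV table written by [write_affinity_tsv()]
#'
#' @param path Input path.
#' @return Named list of [affinity_profile()] objects keyed by node number.
#' @export
read_affinity_tsv <- function(path) {
  tab <- read_tsv(path)
  repcols <- grep("^rep_", names(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    reps <- as.numeric(tab[i, repcols])
    affinity_profile(tab$node[i], reps[!is.na(reps)], tab$source[i])
  })
  names(out) <- as.character(tab$node)
  out
}
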