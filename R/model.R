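# Empirical amino-acid substitution models, optionally extended with a gap
# state, plus discrete-gamma rate heterogeneity and transition probabilities
# computed through a symmetric eigendecomposition (stable for branch lengths
# up to tens of substitutions/site).

# amino-acid order used by the empirical matrices (PAML convention),
# matching AA_LETTERS in io.R

empirical_rates <- function(name = c("LG", "WAG", "JTT")) {
  name <- match.arg(name)
  dat <- get(paste0(".", name), envir = asNamespace("phangorn"))
  S <- matrix(0, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  S[lower.tri(S)] <- dat$Q
  S <- S + t(S)
  bf <- as.numeric(dat$bf)
  names(bf) <- AA_LETTERS
  list(S = S, freqs = bf / sum(bf))
}

#' Build an amino-acid substitution model
#'
#' Constructs a time-reversible rate matrix from empirical exchangeabilities
#' and equilibrium frequencies, normalized to one expected substitution per
#' site per unit branch length, with discrete-gamma rate variation across
#' sites (equal category weights).
#'
#' When `gap_state = TRUE` the alignment gap `-` is modelled as a 21st
#' character state with uniform exchangeability (`gap_exchange`) to every
#' amino acid, so insertions and deletions are reconstructed like ordinary
#' states. With `gap_state = FALSE` the model has 20 states and gaps are
#' treated as missing data.
#'
#' @param exchange Empirical exchangeability set: `"LG"` (default), `"WAG"`
#'   or `"JTT"`.
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param k Number of discrete gamma categories (>= 1); `k = 1` disables
#'   rate variation.
#' @param gap_state Model the gap as a 21st state?
#' @param gap_freq Equilibrium frequency of the gap state; typically
#'   estimated from the alignment via [estimate_gap_freq()]. Amino-acid
#'   frequencies are rescaled to sum to `1 - gap_freq`.
#' @param gap_exchange Exchangeability between the gap state and every amino
#'   acid (uniform by construction).
#' @param freqs Optional length-20 replacement for the empirical amino-acid
#'   frequencies (normalized internally).
#' @return An object of class `subst_model` with elements `states`, `pi`,
#'   `Q`, `alpha`, `k`, `rates` (category rates) and the eigendecomposition
#'   used by [transition_matrix()].
#' @export
aa_model <- function(exchange = "LG", alpha = 1, k = 4L,
                     gap_state = TRUE, gap_freq = 0.05, gap_exchange = 1,
                     freqs = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("'alpha' must be a positive number", call. = FALSE)
  }
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  emp <- empirical_rates(exchange)
  f20 <- if (is.null(freqs)) emp$freqs else {
    stopifnot(length(freqs) == 20L, all(freqs > 0))
    freqs / sum(freqs)
  }
  if (gap_state) {
    stopif_not_scalar_prob(gap_freq, "gap_freq")
    if (gap_freq <= 0 || gap_freq >= 1) {
      stop("'gap_freq' must be in (0, 1) when gap_state = TRUE", call. = FALSE)
    }
    states <- c(AA_LETTERS, GAP)
    S <- matrix(gap_exchange, 21, 21, dimnames = list(states, states))
    S[1:20, 1:20] <- emp$S
    diag(S) <- 0
    pi <- c(f20 * (1 - gap_freq), gap_freq)
    names(pi) <- states
  } else {
    states <- AA_LETTERS
    S <- emp$S
    pi <- f20
  }
  Q <- S * rep(pi, each = length(pi))   # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))              # mean rate
  Q <- Q / mu
  # symmetric eigendecomposition of diag(sqrt(pi)) Q diag(1/sqrt(pi))
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = exchange, states = states, pi = pi, Q = Q,
                 alpha = alpha, k = as.integer(k),
                 rates = discrete_gamma_rates(alpha, k),
                 gap_state = gap_state,
                 eigval = eig$values,
                 left = eig$vectors / sp,           # diag(1/sqrt(pi)) V
                 right = t(eig$vectors * sp)),      # V' diag(sqrt(pi))
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model: %d states, gamma(alpha = %.4g, k = %d)%s\n",
              x$name, length(x$states), x$alpha, x$k,
              if (x$gap_state) ", gap as 21st state" else ""))
  invisible(x)
}

# mean-one discrete gamma category rates (equal-probability bins,
# category rate = conditional mean within the bin)
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  r <- k * diff(c(0, p))
  r / (sum(r) / k) * 1  # already mean 1 up to rounding; renormalize exactly
}

#' Transition probability matrix P(t)
#'
#' @param model A [aa_model()] object.
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param rate Rate multiplier (e.g. a gamma category rate).
#' @return Row-stochastic matrix of state transition probabilities.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  P <- model$left %*% (exp(model$eigval * t * rate) * model$right)
  P[P < 0] <- 0
  P / rowSums(P)
  }

#' Estimate the gap-state equilibrium frequency from an alignment
#'
#' @param msa An [as_msa()] object.
#' @param floor Lower bound, so alignments without gaps still yield a proper
#'   21-state model.
#' @return Proportion of gap characters, bounded below by `floor`.
#' @export
estimate_gap_freq <- function(msa, floor = 1e-3) {
  max(mean(unclass(msa) == GAP), floor)
}
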