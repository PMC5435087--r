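# Fitting binding constants from label-free sensorgram data: steady-state
# Kd from plateau responses, Km from initial association rates, and Welch
# comparison of replicate constants on the pKd scale.

#' Construct a sensorgram object
#'
#' Long-format container for a label-free binding time course: one response
#' value per probe, concentration and time point, with association and
#' dissociation phases labelled and zero-concentration control probes kept
#' alongside analysis probes.
#'
#' @param data Data frame with columns `time_s`, `conc_M`, `response`,
#'   `probe_id`, `phase` (`"association"` or `"dissociation"`).
#' @param controls Character vector of `probe_id`s that are controls.
#' @return A `sensorgram` object (the data frame plus a `controls`
#'   attribute).
#' @export
sensorgram <- function(data, controls = character(0)) {
  need <- c("time_s", "conc_M", "response", "probe_id", "phase")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("sensorgram data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (p in unique(data$probe_id)) {
    tt <- data$time_s[data$probe_id == p]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("times must be strictly increasing within probe ", p, call. = FALSE)
    }
  }
  structure(data, controls = controls, class = c("sensorgram", "data.frame"))
}

#' Subtract averaged control probes from analysis probes
#'
#' Control probe responses are averaged pointwise on the shared time grid
#' and subtracted from every analysis probe, removing instrument drift.
#'
#' @param data A [sensorgram()] with at least one control probe.
#' @return A `sensorgram` containing only the corrected analysis probes.
#' @export
subtract_reference <- function(data) {
  ctl <- attr(data, "controls")
  if (length(ctl) == 0L) stop("no control probes present", call. = FALSE)
  ctl_rows <- data$probe_id %in% ctl
  grid <- sort(unique(data$time_s[!ctl_rows]))
  cmat <- vapply(ctl, function(p) {
    d <- data[data$probe_id == p, ]
    if (!identical(sort(unique(d$time_s)), grid)) {
      stop("control probe time grid is not aligned with analysis probes",
           call. = FALSE)
    }
    d$response[order(d$time_s)]
  }, numeric(length(grid)))
  ctl_mean <- rowMeans(cmat)
  out <- data[!ctl_rows, , drop = FALSE]
  for (p in unique(out$probe_id)) {
    rows <- which(out$probe_id == p)
    rows <- rows[order(out$time_s[rows])]
    if (length(rows) != length(grid)) {
      stop("analysis probe ", p, " is not on the shared time grid", call. = FALSE)
    }
    out$response[rows] <- out$response[rows] - ctl_mean
  }
  sensorgram(as.data.frame(out), controls = character(0))
}

# hyperbolic least squares y = ymax * x / (K + x), multi-start
fit_hyperbola <- function(x, y, label = "K") {
  if (length(x) < 4L) stop("need >= 4 points for a hyperbolic fit", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop(label, " fit unidentifiable: responses do not vary (saturation only?)",
         call. = FALSE)
  }
  ymax0 <- max(y) * 1.05
  half <- x[which.min(abs(y - ymax0 / 2))]
  starts <- unique(c(exp(mean(log(x[x > 0]))), half))
  best <- NULL
  for (k0 in starts) {
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ ymax * x / (K + x),
                   start = list(ymax = ymax0, K = k0),
                   lower = c(ymax = 1e-12, K = 1e-15),
                   algorithm = "port",
                   control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop(label, " fit failed to converge from all starting values", call. = FALSE)
  }
  co <- stats::coef(best$fit)
  list(K = unname(co["K"]), ymax = unname(co["ymax"]), rss = best$rss,
       residuals = stats::resid(best$fit))
}

#' Steady-state one-site binding fit
#'
#' Least-squares fit of `R = Rmax * C / (Kd + C)` to plateau responses
#' across a concentration series (nonlinear regression, Levenberg-style
#' `nls` with multi-start: Kd initialized at the geometric mean of the
#' concentrations and at the concentration nearest half-maximal response).
#'
#' @param concs Concentrations in molar (>= 4 values).
#' @param plateaus Steady-state responses at those concentrations.
#' @return List with `kd` (molar), `rmax`, `rss`, `residuals`.
#' @export
steady_state_fit <- function(concs, plateaus) {
  f <- fit_hyperbola(concs, plateaus, label = "Kd")
  list(kd = f$K, rmax = f$ymax, rss = f$rss, residuals = f$residuals)
}

#' Association-phase binding rates from full time courses
#'
#' Per concentration, fits the one-site association curve
#' `R(t) = Req * (1 - exp(-k_obs * t))` to the association phase. With
#' `rate_type = "initial"` (default) the reported rate is the analytic
#' initial slope `Req * k_obs` of the fitted curve at t = 0, which is more
#' noise-robust than a finite-difference slope. With `rate_type =
#' "windowed"` the rate is the mean binding rate over the observation window
#' `R(T)/T = Req * (1 - exp(-k_obs * T)) / T`: this is what a fixed-length
#' readout actually measures, and because it saturates with Req it is the
#' quantity whose half-maximal concentration (Km) is comparable to the
#' steady-state Kd under ideal 1:1 kinetics (the true instantaneous initial
#' rate, `Rmax * kon * C`, is linear in concentration and has no finite
#' half-max). Concentrations whose early phase decreases beyond noise
#' tolerance are excluded with a warning; zero-concentration series get
#' rate 0.
#'
#' @param data A [sensorgram()] (already reference-subtracted).
#' @param rate_type `"initial"` or `"windowed"` (see above).
#' @param window Window length in seconds for `"windowed"`; defaults to the
#'   full association phase.
#' @return Data frame with `conc_M`, `rate`, `k_obs`, `req`.
#' @export
association_rates <- function(data, rate_type = c("initial", "windowed"),
                              window = NULL) {
  rate_type <- match.arg(rate_type)
  assoc <- data[data$phase == "association" & !(data$probe_id %in% attr(data, "controls")), ]
  out <- lapply(split(assoc, assoc$conc_M), function(d) {
    cc <- d$conc_M[1L]
    if (cc == 0) {
      return(data.frame(conc_M = cc, rate = 0, k_obs = NA_real_, req = 0))
    }
    d <- d[order(d$time_s), ]
    tt <- d$time_s      # association-phase time since phase start (R(0) = 0)
    rr <- d$response
    early <- rr[tt <= max(tt) / 5]
    if (length(early) > 3L) {
      sl <- stats::coef(stats::lm(early ~ seq_along(early)))[2L]
      if (sl < -3 * stats::sd(early - stats::fitted(stats::lm(early ~ seq_along(early))))) {
        warning("non-monotone early association at conc ", cc, "; excluded")
        return(NULL)
      }
    }
    req0 <- max(rr)
    # log-linear start for k_obs, then multi-start exponential fit
    frac <- pmin(rr / (req0 * 1.001), 1 - 1e-12)
    yln <- -log(1 - frac)
    k0 <- max(sum(tt * yln) / sum(tt^2), 1e-9)
    best <- NULL
    for (ks in k0 * c(0.1, 1, 10)) {
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(rr ~ req * (1 - exp(-k * tt)),
                     start = list(req = req0, k = ks),
                     lower = c(req = 1e-12, k = 1e-9), algorithm = "port",
                     control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
    if (is.null(best)) {
      warning("association fit failed at conc ", cc, "; excluded")
      return(NULL)
    }
    co <- stats::coef(best$fit)
    req <- unname(co["req"]); kobs <- unname(co["k"])
    rate <- if (rate_type == "initial") req * kobs else {
      Tw <- if (is.null(window)) max(tt) else window
      req * (1 - exp(-kobs * Tw)) / Tw
    }
    data.frame(conc_M = cc, rate = rate, k_obs = kobs, req = req)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Km from initial binding rates
#'
#' Hyperbolic fit `rate = Vmax * C / (Km + C)`; Km is the concentration at
#' half-maximal initial binding rate. Set `interpolate = TRUE` to instead
#' linearly interpolate the concentration at half the maximal observed rate.
#'
#' @param rates Data frame with columns `conc_M` and `rate` (>= 4 rows),
#'   e.g. from [association_rates()].
#' @param interpolate Use interpolation instead of the fit.
#' @return List with `km` (molar), `vmax`, `rss` (fit route only).
#' @export
km_fit <- function(rates, interpolate = FALSE) {
  if (interpolate) {
    half <- max(rates$rate) / 2
    km <- stats::approx(rates$rate, rates$conc_M, xout = half, ties = "ordered")$y
    return(list(km = km, vmax = max(rates$rate), rss = NA_real_))
  }
  f <- fit_hyperbola(rates$conc_M, rates$rate, label = "Km")
  list(km = f$K, vmax = f$ymax, rss = f$rss)
}

#' Compare replicate binding constants
#'
#' Welch's two-tailed unequal-variance t test on -log10-transformed
#' constants (the pKd scale, on which replicate errors are closer to
#' Gaussian).
#'
#' @param reps_a,reps_b Replicate Kd (or Km) values in molar, >= 2 each.
#' @return List with `t`, `df`, `p`.
#' @export
compare_affinities <- function(reps_a, reps_b) {
  welch_t(pkd_from_kd(reps_a), pkd_from_kd(reps_b))
}

#' Aggregate replicate fits into a binding-constant summary
#'
#' Means and standard errors are computed on the pKd scale and reported on
#' both scales.
#'
#' @param kds Replicate Kd values (molar).
#' @param kms Optional replicate Km values (molar).
#' @return A `binding_fit` list with `kd`, `kd_se_pkd`, `pkd`, and when
#'   given, `km`, `km_se_pkd`, `pkm` (geometric-mean constants back on the
#'   molar scale).
#' @export
binding_fit <- function(kds, kms = NULL) {
  pk <- suppressWarnings(aggregate_replicates(pkd_from_kd(kds)))
  out <- list(kd = kd_from_pkd(pk$mean), pkd = pk$mean, kd_se_pkd = pk$se,
              n = pk$n)
  if (!is.null(kms)) {
    pm <- suppressWarnings(aggregate_replicates(pkd_from_kd(kms)))
    out$km <- kd_from_pkd(pm$mean); out$pkm <- pm$mean; out$km_se_pkd <- pm$se
  }
  structure(out, class = "binding_fit")
}
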