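# Enzyme kinetics from plate-reader time courses: NADH oxidation, citrate
# synthase, Amplex Red ROS, GSH alkylation kinetics.

#' NADH concentration from dual-wavelength absorbance
#'
#' `c(t) = (A340 - A380) / (eps * path)` with
#' `eps(340-380) = 4.81 mM^-1 cm^-1`.
#'
#' @param a340,a380 absorbance vectors (same length).
#' @param constants an [assay_constants()] list.
#' @return NADH concentration series (mM).
#' @export
nadh_concentration <- function(a340, a380, constants = assay_constants()) {
  if (missing(a380) || is.null(a380)) stop("reference signal A380 is required")
  stopifnot(length(a340) == length(a380), constants$path_cm > 0)
  (a340 - a380) / (constants$eps_nadh_340_380 * constants$path_cm)
}

#' Maximal linear rate by sliding-window regression
#'
#' Slides a fixed-width ordinary-least-squares window along the trace and
#' returns the window with the steepest slope in the assay direction
#' (`decrease` for consumption, `increase` for production); ties are broken
#' by the earliest window. The returned rate is positive in the assay
#' direction.
#'
#' @param time time points (strictly increasing, same unit as the rate).
#' @param signal concentration (or signal) series.
#' @param window_samples window width in samples (default 10, >= 5).
#' @param direction `"decrease"` (default; consumption assays) or
#'   `"increase"`.
#' @return List of class `RateEstimate`: `rate` (positive), `slope` (signed),
#'   `window` (start/end times), `r_squared`, `window_idx`.
#' @export
max_linear_rate <- function(time, signal, window_samples = 10,
                            direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(length(time) == length(signal), window_samples >= 5)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  n <- length(time)
  if (n < window_samples) stop("fewer samples than window width")
  w <- as.integer(window_samples)
  starts <- seq_len(n - w + 1L)
  slopes <- numeric(length(starts))
  r2 <- numeric(length(starts))
  for (s in starts) {
    idx <- s:(s + w - 1L)
    x <- time[idx]; y <- signal[idx]
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc^2); sxy <- sum(xc * yc); syy <- sum(yc^2)
    slopes[s] <- sxy / sxx
    r2[s] <- if (syy > 0) (sxy^2) / (sxx * syy) else 1
  }
  score <- if (direction == "decrease") -slopes else slopes
  best <- which.max(score)  # which.max returns the earliest tie
  idx <- best:(best + w - 1L)
  structure(list(rate = max(score[best], 0) * sign(1),
                 slope = slopes[best],
                 window = c(start = time[idx[1]], end = time[idx[w]]),
                 r_squared = r2[best], window_idx = idx),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate: rate %.6g over [%g, %g] (R^2 = %.4f)\n",
              x$rate, x$window["start"], x$window["end"], x$r_squared))
  invisible(x)
}

#' Rotenone-sensitive rate and fraction
#'
#' `sensitive = total - background`; `fraction = sensitive / total`.
#'
#' @param rate_total maximal rate without inhibitor (>= 0).
#' @param rate_rotenone background rate with rotenone (>= 0).
#' @return List with `sensitive_rate` and `sensitive_fraction` (`NA` when the
#'   total rate is 0).
#' @examples
#' rotenone_sensitive_rate(100, 18) # 82, 0.82
#' @export
rotenone_sensitive_rate <- function(rate_total, rate_rotenone) {
  stopifnot(rate_total >= 0, rate_rotenone >= 0)
  sens <- rate_total - rate_rotenone
  frac <- if (rate_total == 0) NA_real_ else sens / rate_total
  list(sensitive_rate = sens, sensitive_fraction = frac)
}

#' Reactivation lag of a consumption trace
#'
#' Estimates the instantaneous consumption rate by centered sliding-window
#' regression, then reports the lag as the first time the smoothed rate
#' reaches 50% of its maximum (linearly interpolated between window
#' centers); a trace already at half-maximal rate in its first window has
#' lag 0.
#'
#' @param time time points (min).
#' @param conc concentration series (consumed species, e.g. NADH in mM).
#' @param window_samples smoothing window (default 5 samples).
#' @return List of class `ReactivationProfile`: `lag_time`, `t_max_rate`,
#'   `max_rate`, `initial_rate` (all rates positive for consumption), or an
#'   error when the maximal rate is 0.
#' @export
reactivation_lag <- function(time, conc, window_samples = 5) {
  stopifnot(length(time) == length(conc), window_samples >= 3)
  n <- length(time)
  w <- as.integer(window_samples)
  if (n < w + 2) stop("trace too short for lag estimation")
  starts <- seq_len(n - w + 1L)
  centers <- numeric(length(starts))
  rates <- numeric(length(starts))
  for (s in starts) {
    idx <- s:(s + w - 1L)
    x <- time[idx]; y <- conc[idx]
    xc <- x - mean(x)
    rates[s] <- -sum(xc * (y - mean(y))) / sum(xc^2)  # consumption positive
    centers[s] <- mean(x)
  }
  max_rate <- max(rates)
  if (max_rate <= 0) stop("maximal rate is 0: lag undefined")
  half <- max_rate / 2
  i_max <- which.max(rates)
  lag <- if (rates[1] >= half) {
    0
  } else {
    k <- which(rates >= half)[1]
    # linear interpolation between window centers k-1 and k
    centers[k - 1] + (half - rates[k - 1]) /
      (rates[k] - rates[k - 1]) * (centers[k] - centers[k - 1])
  }
  structure(list(lag_time = lag, t_max_rate = centers[i_max],
                 max_rate = max_rate, initial_rate = rates[1]),
            class = "ReactivationProfile")
}

#' Citrate synthase rate from an A412 trace
#'
#' Converts the DTNB/TNB2- absorbance trace to concentration with
#' `eps(412) = 13600 M^-1 cm^-1` and extracts the maximal linear production
#' rate.
#'
#' @param time_min time (min).
#' @param a412 absorbance at 412 nm.
#' @param constants an [assay_constants()] list.
#' @param window_samples sliding-window width.
#' @return `RateEstimate` with `rate` in uM TNB2- per minute.
#' @export
citrate_synthase_rate <- function(time_min, a412,
                                  constants = assay_constants(),
                                  window_samples = 10) {
  conc_uM <- a412 / (constants$eps_tnb_412 * constants$path_cm) * 1e6
  max_linear_rate(time_min, conc_uM, window_samples, direction = "increase")
}

#' H2O2 production rates from Amplex Red fluorescence
#'
#' Fits a linear standard curve (fluorescence vs known H2O2 concentration,
#' at least 3 points) and converts the maximal linear fluorescence slope of
#' each
#' sample trace into an H2O2 production rate. Rates are flagged as
#' extrapolated when the trace's fluorescence leaves the standard range.
#'
#' @param traces `data.frame` with columns `well`, `time_min`,
#'   `fluorescence`.
#' @param standards `data.frame` with columns `conc_uM`, `fluorescence`.
#' @param window_samples sliding-window width (default 10).
#' @param protein_mg optional named vector (by well) of protein mass; when
#'   given, rates are also returned as nmol/min/mg assuming a 0.2 mL well.
#' @return `data.frame`: `well`, `rate_uM_per_min`, `r_squared`,
#'   `extrapolated`, and `rate_nmol_min_mg` when protein is supplied.
#' @export
amplex_quantify <- function(traces, standards, window_samples = 10,
                            protein_mg = NULL) {
  stopifnot(all(c("well", "time_min", "fluorescence") %in% names(traces)),
            all(c("conc_uM", "fluorescence") %in% names(standards)))
  if (nrow(standards) < 3) stop("need >= 3 standard points")
  if (length(unique(standards$conc_uM)) < 2) stop("degenerate standards")
  fit <- stats::lm(fluorescence ~ conc_uM, data = standards)
  gain <- unname(stats::coef(fit)[2])
  rng <- range(standards$fluorescence)
  out <- lapply(split(traces, traces$well), function(tr) {
    est <- max_linear_rate(tr$time_min, tr$fluorescence, window_samples,
                           direction = "increase")
    data.frame(well = tr$well[1],
               rate_uM_per_min = est$rate / gain,
               r_squared = est$r_squared,
               extrapolated = any(tr$fluorescence < rng[1] |
                                  tr$fluorescence > rng[2]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(protein_mg)) {
    # uM/min in 0.2 mL -> nmol/min, per mg protein
    res$rate_nmol_min_mg <- res$rate_uM_per_min * 0.2 /
      unname(protein_mg[res$well])
  }
  res
}

#' Hydrogen peroxide stock concentration from A240
#'
#' `c = A240 / (43.5 * path) * dilution`, in molar. The default 1 cm path
#' reflects cuvette-based quantification of the stock.
#'
#' @param a240 absorbance at 240 nm (>= 0).
#' @param dilution dilution factor applied before measurement.
#' @param path_cm cuvette path length (cm).
#' @return Concentration (M).
#' @examples
#' h2o2_stock_concentration(0.435) # 0.01 M = 10 mM
#' @export
h2o2_stock_concentration <- function(a240, dilution = 1, path_cm = 1) {
  stopifnot(a240 >= 0, dilution > 0, path_cm > 0)
  a240 / (assay_constants()$eps_h2o2_240 * path_cm) * dilution
}

#' Fit pseudo-first-order GSH alkylation kinetics
#'
#' Fits `f(t) = 1 - exp(-k * [IAM] * t)` to labeled-fraction time points by
#' nonlinear least squares (excess alkylator, pseudo-first-order regime) and
#' returns the second-order rate constant and the half-time.
#'
#' @param time_s time points (s).
#' @param fraction labeled fractions in `[0, 1]`.
#' @param iam_conc alkylator concentration (M).
#' @return List with `k` (M^-1 s^-1), `k_obs` (s^-1), `half_time_s`, and a
#'   `warning` field for grossly non-monotone data.
#' @export
fit_gsh_labeling <- function(time_s, fraction, iam_conc) {
  stopifnot(length(time_s) == length(fraction), iam_conc > 0,
            all(fraction >= -1e-9), all(fraction <= 1 + 1e-9))
  warn <- NULL
  if (length(fraction) > 2) {
    drops <- diff(fraction)
    if (any(drops < -0.2)) {
      warn <- "labeled fraction decreases grossly over time; fit suspect"
      warning(warn)
    }
  }
  if (all(fraction <= 1e-12)) {
    return(list(k = 0, k_obs = 0, half_time_s = Inf, warning = warn))
  }
  # start from the linearized slope, refined by nls
  ok <- fraction < 1 & time_s > 0
  k0 <- if (any(ok)) {
    stats::median(-log(1 - fraction[ok]) / time_s[ok])
  } else 1 / max(time_s)
  # scaleOffset makes the convergence test valid on zero-residual data
  fit <- try(stats::nls(fraction ~ 1 - exp(-kobs * time_s),
                        start = list(kobs = k0),
                        control = stats::nls.control(warnOnly = TRUE,
                                                     scaleOffset = 1)),
             silent = TRUE)
  k_obs <- if (inherits(fit, "try-error")) k0 else
    unname(stats::coef(fit)["kobs"])
  list(k = k_obs / iam_conc, k_obs = k_obs,
       half_time_s = log(2) / k_obs, warning = warn)
}
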