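# Exposure quantification: XIC integration, channel proportions, labeling
# scheme resolution, replicate aggregation, standard curves.

#' Integrate an extracted ion chromatogram
#'
#' Trapezoidal integral of centroided intensities whose m/z lies within
#' `mz_tol_ppm` of `target_mz`, over a retention-time window. Points of
#' several co-eluting species inside the tolerance are kept (nearest-m/z wins
#' when two targets would claim the same point is the caller's concern; a
#' single-target call keeps all in-tolerance points). Returns 0 when no
#' points match.
#'
#' @param chromatogram `data.frame` with columns `rt_min`, `mz`, `intensity`.
#' @param target_mz target m/z.
#' @param mz_tol_ppm tolerance in ppm (default 10).
#' @param rt_window length-2 numeric window in minutes; default full trace.
#' @return Peak area (intensity x minutes).
#' @export
integrate_xic <- function(chromatogram, target_mz, mz_tol_ppm = 10,
                          rt_window = NULL) {
  stopifnot(is.data.frame(chromatogram),
            all(c("rt_min", "mz", "intensity") %in% names(chromatogram)))
  if (nrow(chromatogram) == 0) stop("empty chromatogram")
  stopifnot(mz_tol_ppm > 0)
  if (is.null(rt_window)) {
    rt_window <- range(chromatogram$rt_min)
  }
  tol <- target_mz * mz_tol_ppm * 1e-6
  keep <- abs(chromatogram$mz - target_mz) <= tol &
    chromatogram$rt_min >= rt_window[1] & chromatogram$rt_min <= rt_window[2]
  pts <- chromatogram[keep, , drop = FALSE]
  if (nrow(pts) < 2) return(0)
  pts <- pts[order(pts$rt_min), , drop = FALSE]
  sum(diff(pts$rt_min) * (utils::head(pts$intensity, -1) +
                          utils::tail(pts$intensity, -1)) / 2)
}

#' Exposed fraction from a two-channel measurement
#'
#' `area_first / (area_first + area_second)`, where the first label marks
#' thiols exposed in the native state and the second label marks thiols
#' revealed only after denaturation and reduction. Which isotopologue plays
#' the "first" role is immaterial (the labeling order is interchangeable).
#'
#' @param area_first_label area of the native-step channel.
#' @param area_second_label area of the post-reduction channel.
#' @return Fraction in `[0, 1]`, or `NA` when both areas are 0.
#' @examples
#' exposure_fraction(930, 70) # 0.93
#' @export
exposure_fraction <- function(area_first_label, area_second_label) {
  stopifnot(area_first_label >= 0, area_second_label >= 0)
  total <- area_first_label + area_second_label
  if (total == 0) return(NA_real_)
  area_first_label / total
}

#' Per-channel proportions of summed peak area
#'
#' @param areas named numeric vector of channel areas (>= 2 channels).
#' @return Named proportions summing to 1, or all-`NA` when the total is 0.
#' @examples
#' channel_proportions(c(L = 50, H = 30, NEM = 20))
#' @export
channel_proportions <- function(areas) {
  stopifnot(is.numeric(areas), length(areas) >= 2, !is.null(names(areas)),
            all(areas >= 0))
  total <- sum(areas)
  if (total == 0) return(stats::setNames(rep(NA_real_, length(areas)),
                                         names(areas)))
  areas / total
}

#' Define a differential labeling scheme
#'
#' A `LabelScheme` is an ordered list of steps, each applying one label in a
#' context: `native-exposed` (the step that marks thiols accessible in the
#' native state), `denatured-reduced` (the final step after denaturation and
#' chemical reduction), or `post-electrophoresis` (the intermediate step of
#' the three-label gel workflow). A reversible first step (MMTS) must be
#' followed by a `displacement` step naming the label that replaces it.
#'
#' @param steps list of steps, each a list with `name`, `label`, `context`
#'   (`native-exposed`, `denatured-reduced`, `post-electrophoresis`,
#'   `displacement`), and optional `reversible` flag.
#' @return Object of class `LabelScheme`.
#' @seealso [two_label_scheme()], [mmts_scheme()], [three_label_scheme()]
#' @export
label_scheme <- function(steps) {
  ctx <- vapply(steps, `[[`, character(1), "context")
  if (sum(ctx == "native-exposed") != 1) {
    stop("exactly one step must target native-exposed thiols")
  }
  if (ctx[length(ctx)] != "denatured-reduced") {
    stop("the final step must follow denaturation and reduction")
  }
  rev1 <- isTRUE(steps[[1]]$reversible)
  if (rev1 && (length(steps) < 2 || ctx[2] != "displacement")) {
    stop("a reversible first step must be followed by a displacement step")
  }
  structure(list(steps = steps), class = "LabelScheme")
}

#' Two-label exposure scheme
#'
#' Native-exposed thiols receive the first label; denaturation and reduction
#' expose the remainder for the second label.
#'
#' @param first,second label names (default light then heavy IAM; the order
#'   may be swapped).
#' @return A `LabelScheme`.
#' @export
two_label_scheme <- function(first = "IAM-light", second = "IAM-heavy") {
  label_scheme(list(
    list(name = "native", label = first, context = "native-exposed"),
    list(name = "reduce", label = second, context = "denatured-reduced")))
}

#' MMTS block-and-replace scheme
#'
#' Native-exposed thiols are reversibly blocked with MMTS, which is displaced
#' under denaturing conditions by the displacement label; reduction then
#' frees occluded thiols for the final label. The displacement channel
#' therefore reports native exposure.
#'
#' @param displaced_by label replacing MMTS (default light IAM).
#' @param final post-reduction label (default heavy IAM).
#' @return A `LabelScheme`.
#' @export
mmts_scheme <- function(displaced_by = "IAM-light", final = "IAM-heavy") {
  label_scheme(list(
    list(name = "block", label = "MMTS", context = "native-exposed",
         reversible = TRUE),
    list(name = "displace", label = displaced_by, context = "displacement"),
    list(name = "reduce", label = final, context = "denatured-reduced")))
}

#' Three-label gel scheme
#'
#' Native-exposed thiols are labeled in the active state, a second label
#' marks thiols newly exposed upon deactivation, and after electrophoresis,
#' denaturation and reduction a third label captures thiols never exposed in
#' the native states.
#'
#' @param active,deactive,final the three label names.
#' @return A `LabelScheme`.
#' @export
three_label_scheme <- function(active = "NEM", deactive = "IAM-light",
                               final = "IAM-heavy") {
  label_scheme(list(
    list(name = "active", label = active, context = "native-exposed"),
    list(name = "deactive", label = deactive,
         context = "post-electrophoresis"),
    list(name = "reduce", label = final, context = "denatured-reduced")))
}

#' Map channel proportions to exposure classes
#'
#' Applies a [label_scheme()] to a set of channel proportions. The channel of
#' the native-exposed step (or, in MMTS schemes, the displacement channel)
#' counts as exposed during step 1; the post-reduction channel counts as
#' occluded; an intermediate channel counts as exposed only after
#' deactivation.
#'
#' @param scheme a `LabelScheme`.
#' @param proportions named numeric vector of channel proportions (names are
#'   label names); must sum to 1.
#' @param species_id identifier carried into the result.
#' @return Object of class `ExposureResult`: list with `species_id`,
#'   `proportions`, `classes` (named: exposed / newly_exposed / occluded) and
#'   `exposed_fraction`.
#' @examples
#' resolve_scheme(two_label_scheme(), c("IAM-light" = 0.65, "IAM-heavy" = 0.35))
#' @export
resolve_scheme <- function(scheme, proportions, species_id = NA_character_) {
  stopifnot(inherits(scheme, "LabelScheme"))
  ctx <- vapply(scheme$steps, `[[`, character(1), "context")
  labels <- vapply(scheme$steps, `[[`, character(1), "label")
  # channel that reports native exposure: displacement channel if present
  exposed_lab <- if ("displacement" %in% ctx) {
    labels[ctx == "displacement"]
  } else {
    labels[ctx == "native-exposed"]
  }
  occluded_lab <- labels[ctx == "denatured-reduced"]
  newly_lab <- labels[ctx == "post-electrophoresis"]
  known <- c(exposed_lab, occluded_lab, newly_lab)
  orphan <- setdiff(names(proportions), known)
  if (length(orphan) > 0) {
    stop("channel(s) with no generating scheme step: ",
         paste(orphan, collapse = ", "))
  }
  p <- function(lab) if (length(lab) && lab %in% names(proportions)) {
    unname(proportions[[lab]])
  } else 0
  classes <- c(exposed = p(exposed_lab), occluded = p(occluded_lab))
  if (length(newly_lab)) {
    classes <- c(classes[1], newly_exposed = p(newly_lab), classes[2])
  }
  structure(list(species_id = species_id, proportions = proportions,
                 classes = classes,
                 exposed_fraction = unname(classes["exposed"])),
            class = "ExposureResult")
}

#' @export
print.ExposureResult <- function(x, ...) {
  cat(sprintf("ExposureResult %s: exposed %.3f (%s)\n",
              x$species_id, x$exposed_fraction,
              paste(sprintf("%s=%.3f", names(x$classes), x$classes),
                    collapse = ", ")))
  invisible(x)
}

#' Estimate exposure from a replicate peak-area table
#'
#' Computes the exposed fraction per replicate from a long-format peak-area
#' table, then aggregates: mean across replicates with the standard error as
#' dispersion. Peptide species with more than one cysteine should be excluded
#' upstream (channel areas are not site-resolvable).
#'
#' @param peaks `data.frame` with columns `species_id`, `channel`,
#'   `replicate`, `area`.
#' @param scheme a [label_scheme()]; channel names in `peaks` must be label
#'   names of the scheme.
#' @return `data.frame` with one row per species: `species_id`,
#'   `exposed_fraction`, `se`, `n_replicates`, plus one `prop_<class>` column
#'   per exposure class (mean across replicates).
#' @export
estimate_exposure <- function(peaks, scheme = two_label_scheme()) {
  stopifnot(is.data.frame(peaks),
            all(c("species_id", "channel", "replicate", "area") %in%
                names(peaks)))
  out <- lapply(split(peaks, peaks$species_id), function(sp) {
    reps <- split(sp, sp$replicate)
    res <- lapply(reps, function(r) {
      areas <- stats::setNames(r$area, r$channel)
      pr <- channel_proportions(areas)
      if (all(is.na(pr))) return(NULL)
      resolve_scheme(scheme, pr, species_id = sp$species_id[1])
    })
    res <- Filter(Negate(is.null), res)
    if (length(res) == 0) {
      return(data.frame(species_id = sp$species_id[1],
                        exposed_fraction = NA_real_, se = NA_real_,
                        n_replicates = 0L))
    }
    fr <- vapply(res, `[[`, numeric(1), "exposed_fraction")
    cls <- do.call(rbind, lapply(res, `[[`, "classes"))
    d <- data.frame(species_id = sp$species_id[1],
                    exposed_fraction = mean(fr),
                    se = stats::sd(fr) / sqrt(length(fr)),
                    n_replicates = length(fr))
    cm <- colMeans(cls)
    for (nm in names(cm)) d[[paste0("prop_", nm)]] <- unname(cm[nm])
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit an internal-standard calibration curve
#'
#' Ordinary least squares of response ratio (analyte area / internal-standard
#' area) against known amount. Rows with a zero internal-standard area are
#' dropped before fitting.
#'
#' @param known_amounts numeric vector of spiked amounts (>= 3 points).
#' @param analyte_areas analyte peak areas.
#' @param is_areas matching internal-standard peak areas.
#' @return Object of class `StandardCurve`: list with `slope`, `intercept`,
#'   `r_squared`, `amounts`, `ratios`, `fit` (the `lm` object).
#' @export
fit_standard_curve <- function(known_amounts, analyte_areas, is_areas) {
  stopifnot(length(known_amounts) == length(analyte_areas),
            length(known_amounts) == length(is_areas))
  keep <- is_areas > 0
  amounts <- known_amounts[keep]
  ratios <- analyte_areas[keep] / is_areas[keep]
  if (length(amounts) < 3) stop("at least 3 usable calibration points needed")
  if (length(unique(amounts)) < 2) stop("degenerate design: amounts all equal")
  fit <- stats::lm(ratios ~ amounts)
  # R^2 computed directly: summary.lm warns on noiseless calibration data
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ratios - mean(ratios))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 amounts = amounts, ratios = ratios, fit = fit),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve: ratio = %.4g * amount + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify an unknown from a standard curve
#'
#' Inverts the fitted line: `amount = (ratio - intercept) / slope`, where
#' `ratio = area / is_area`.
#'
#' @param area analyte peak area.
#' @param is_area internal-standard area (> 0).
#' @param curve a [fit_standard_curve()] result.
#' @return Estimated amount.
#' @export
quantify_amount <- function(area, is_area, curve) {
  stopifnot(inherits(curve, "StandardCurve"))
  if (any(is_area <= 0)) stop("internal-standard area must be positive")
  (area / is_area - curve$intercept) / curve$slope
}

#' Read a peak-area table
#'
#' @param path CSV with header columns `species_id`, `channel`, `replicate`,
#'   `area`.
#' @return Validated `data.frame`.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "channel", "replicate", "area")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$area < 0)) stop("peak areas must be >= 0")
  df
}

#' Read a centroided chromatogram
#'
#' @param path CSV with header columns `rt_min`, `mz`, `intensity`.
#' @return Validated `data.frame` ordered by retention time.
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rt_min", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("chromatogram missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$intensity < 0)) stop("intensities must be >= 0")
  df[order(df$rt_min), , drop = FALSE]
}
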