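# Seeded synthetic-data generators producing every input the pipeline
# consumes, with ground-truth sidecars for automated scoring.
#
# Noise models: log-normal multiplicative for MS peak areas, Gaussian
# additive for absorbance/fluorescence. Every generator is a pure function
# of its arguments: a fixed seed gives identical output.

# log-normal factor with unit mean and the requested coefficient of variation
.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a differential-labeling peak-area table
#'
#' Emulates the measurement model behind XIC-based exposure quantification:
#' per replicate, a total species abundance is drawn (log-normal around
#' `mean_total`), split between the first-label and second-label channels by
#' the true exposed fraction, and each channel area receives independent
#' multiplicative log-normal noise with the stated CV.
#'
#' @param true_fractions named numeric vector: condition -> true exposed
#'   fraction in `[0, 1]`.
#' @param n_replicates replicates per condition (default 6).
#' @param cv channel-area coefficient of variation (default 0.05).
#' @param channels length-2 character vector naming the first (native-step)
#'   and second (post-reduction) label channels.
#' @param mean_total mean total peak area.
#' @param total_cv CV of the total-abundance draw (default 0.3).
#' @param seed RNG seed.
#' @return List with `peaks` (`data.frame`: `species_id`, `channel`,
#'   `replicate`, `area`) and `truth` (the input fractions and settings).
#' @export
gen_peak_table <- function(true_fractions, n_replicates = 6, cv = 0.05,
                           channels = c("IAM-light", "IAM-heavy"),
                           mean_total = 1e6, total_cv = 0.3, seed = 1) {
  stopifnot(!is.null(names(true_fractions)),
            all(true_fractions >= 0), all(true_fractions <= 1),
            cv >= 0, n_replicates >= 1, length(channels) == 2)
  set.seed(seed)
  rows <- list()
  for (cond in names(true_fractions)) {
    f <- true_fractions[[cond]]
    totals <- mean_total * .lognorm_noise(n_replicates, total_cv)
    a1 <- totals * f * .lognorm_noise(n_replicates, cv)
    a2 <- totals * (1 - f) * .lognorm_noise(n_replicates, cv)
    rows[[cond]] <- data.frame(
      species_id = cond,
      channel = rep(channels, each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      area = c(a1, a2), stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  list(peaks = peaks,
       truth = list(true_fractions = as.list(true_fractions),
                    n_replicates = n_replicates, cv = cv,
                    channels = channels, seed = seed))
}

#' Generate a centroided chromatogram with Gaussian peaks
#'
#' @param species `data.frame` with columns `mz`, `rt_min` (apex), `sd_min`
#'   (peak width) and `height`; zero-height species are omitted.
#' @param rt_range length-2 retention-time range (min).
#' @param dt_min sampling interval (min); default 1 s.
#' @param baseline_noise SD of additive Gaussian baseline noise.
#' @param seed RNG seed.
#' @return List with `chromatogram` (`rt_min`, `mz`, `intensity`) and
#'   `truth` (programmed areas `height * sd * sqrt(2*pi)` per species).
#' @export
gen_chromatograms <- function(species, rt_range = c(0, 10), dt_min = 1 / 60,
                              baseline_noise = 0, seed = 1) {
  stopifnot(all(c("mz", "rt_min", "sd_min", "height") %in% names(species)))
  set.seed(seed)
  species <- species[species$height > 0, , drop = FALSE]
  times <- seq(rt_range[1], rt_range[2], by = dt_min)
  rows <- lapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    intensity <- s$height * exp(-(times - s$rt_min)^2 / (2 * s$sd_min^2))
    if (baseline_noise > 0) {
      intensity <- pmax(0, intensity + stats::rnorm(length(times), 0,
                                                    baseline_noise))
    }
    data.frame(rt_min = times, mz = s$mz, intensity = intensity)
  })
  chrom <- do.call(rbind, rows)
  chrom <- chrom[order(chrom$rt_min, chrom$mz), , drop = FALSE]
  rownames(chrom) <- NULL
  list(chromatogram = chrom,
       truth = list(areas = stats::setNames(
         species$height * species$sd_min * sqrt(2 * pi),
         as.character(species$mz)), seed = seed))
}

#' Generate NADH-oxidation plate traces
#'
#' Integrates the A/D simulator to produce dual-wavelength absorbance traces
#' of NADH consumption: the instantaneous consumption rate is
#' `rate_active * activity(t)` until NADH is depleted; rotenone wells
#' contain only the background rate. Wells: `active` (all-A start),
#' `deactive` (all-D start, reactivating with substrate at the programmed
#' `k_a`, so the half-maximal-rate lag is `log(2)/k_a`), and their
#' `_rotenone` pairs.
#'
#' @param params an [ad_params()]; `k_a` sets the deactive-well lag.
#' @param rate_active maximal NADH consumption rate (mM/min at activity 1).
#' @param nadh0 initial NADH concentration (mM), default 0.2.
#' @param background_rate rotenone-insensitive rate (mM/min).
#' @param duration_min trace length (min).
#' @param dt_s sampling interval (s), default 12.
#' @param noise_sd SD of additive absorbance noise.
#' @param a380 constant reference absorbance.
#' @param constants an [assay_constants()] list (path length, extinction).
#' @return List with `traces` (`data.frame`: `well`, `condition`,
#'   `rotenone`, `time_s`, `a340`, `a380`) and `truth` (programmed rates and
#'   the deactive-well lag in min).
#' @export
gen_absorbance_traces <- function(params = ad_params(), rate_active = 0.05,
                                  nadh0 = 0.2, background_rate = 0.009,
                                  duration_min = 30, dt_s = 12,
                                  noise_sd = 0, a380 = 0.1,
                                  constants = assay_constants(), seed = 1) {
  set.seed(seed)
  times_min <- seq(0, duration_min, by = dt_s / 60)
  eps_path <- constants$eps_nadh_340_380 * constants$path_cm
  wells <- list(
    active = list(init = c(1, 0, 0, 0), rotenone = FALSE),
    deactive = list(init = c(0, 1, 0, 0), rotenone = FALSE),
    active_rotenone = list(init = c(1, 0, 0, 0), rotenone = TRUE),
    deactive_rotenone = list(init = c(0, 1, 0, 0), rotenone = TRUE))
  protocol <- data.frame(t_min = 0, event = "add_substrate")
  rows <- lapply(names(wells), function(w) {
    cfg <- wells[[w]]
    if (cfg$rotenone) {
      # complex I blocked: background consumption only
      rate <- rep(background_rate, length(times_min))
    } else {
      traj <- simulate_ad(params, protocol, dt = dt_s / 60,
                          horizon = duration_min, init = cfg$init)
      rate <- background_rate + rate_active * traj$activity
    }
    # integrate consumption (trapezoid), clip at depletion
    consumed <- c(0, cumsum(diff(times_min) *
                            (utils::head(rate, -1) + utils::tail(rate, -1)) / 2))
    nadh <- pmax(0, nadh0 - consumed)
    a340 <- a380 + nadh * eps_path
    if (noise_sd > 0) a340 <- a340 + stats::rnorm(length(a340), 0, noise_sd)
    data.frame(well = w, condition = sub("_rotenone$", "", w),
               rotenone = cfg$rotenone, time_s = times_min * 60,
               a340 = a340, a380 = a380, stringsAsFactors = FALSE)
  })
  traces <- do.call(rbind, rows)
  rownames(traces) <- NULL
  list(traces = traces,
       truth = list(rate_active = rate_active,
                    background_rate = background_rate,
                    lag_deactive_min = log(2) / params$k_a,
                    nadh0 = nadh0, noise_sd = noise_sd, seed = seed))
}

# icosahedron vertices (unit circumradius)
.icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, p), c(0, -1, p), c(0, 1, -p), c(0, -1, -p),
    c(1, p, 0), c(-1, p, 0), c(1, -p, 0), c(-1, -p, 0),
    c(p, 0, 1), c(-p, 0, 1), c(p, 0, -1), c(-p, 0, -1))
  v / sqrt(1 + p^2)
}

#' Generate a toy multi-subunit complex with engineered cysteines
#'
#' Builds a reference protein with cysteines at specified positions, a
#' gapless multi-species alignment in which selected cysteines are
#' substituted in one species (not conserved), a pair of toy structures in
#' which each cysteine's gamma-sulfur is either free (exposed) or enclosed
#' in an icosahedral carbon cage at 2.5 A (buried, SASA 0), and an
#' annotation table. Burial is set independently per structural state, so
#' candidate-pattern sites (buried in the active structure, exposed in the
#' deactive one) can be engineered with exact ground truth.
#'
#' @param n_species number of species in the alignment (>= 2).
#' @param length_aa reference protein length.
#' @param cys `data.frame` with columns `position`, `conserved` (logical),
#'   `buried_active`, `buried_deactive` (logical), and optional `annotation`.
#' @param seed RNG seed (controls the non-cysteine residues).
#' @return List with `sequences` (named character; first entry `species1` is
#'   the reference), `alignment` (identical here: the toy alignment is
#'   gapless), `atoms_active` / `atoms_deactive` (atom tables for
#'   [gamma_s_sasa()]), `annotations`, and `truth` (the `cys` table).
#' @export
gen_toy_complex <- function(n_species = 3, length_aa = 60,
                            cys = data.frame(
                              position = c(10, 25, 40),
                              conserved = c(TRUE, TRUE, FALSE),
                              buried_active = c(TRUE, FALSE, FALSE),
                              buried_deactive = c(FALSE, FALSE, FALSE)),
                            seed = 1) {
  stopifnot(n_species >= 2, all(cys$position >= 1),
            all(cys$position <= length_aa))
  set.seed(seed)
  # background residues: no C, K, R except engineered sites and spaced
  # tryptic anchors so every cysteine lands in a detectable peptide
  bg <- c("A", "G", "L", "S", "T", "V", "E", "D", "F", "P", "N", "Q", "Y")
  ref <- sample(bg, length_aa, replace = TRUE)
  ref[cys$position] <- "C"
  anchors <- setdiff(seq(12, length_aa - 1, by = 12),
                     c(cys$position, cys$position + 1L))
  ref[anchors] <- "K"
  ref[anchors + 1L][ref[anchors + 1L] == "P"] <- "A"
  seqs <- stats::setNames(vector("list", n_species),
                          paste0("species", seq_len(n_species)))
  seqs[[1]] <- ref
  for (s in 2:n_species) {
    v <- ref
    if (s == 2) {
      v[cys$position[!cys$conserved]] <- "S"  # break conservation
    }
    seqs[[s]] <- v
  }
  sequences <- vapply(seqs, paste, character(1), collapse = "")

  make_atoms <- function(buried) {
    rows <- list()
    serial <- 0L
    for (i in seq_len(nrow(cys))) {
      center <- c(20 * i, 0, 0)   # 20 A spacing: no cross-occlusion
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, atom_name = "SG", resname = "CYS", chain = "A",
        resid = cys$position[i], x = center[1], y = center[2], z = center[3],
        element = "S", stringsAsFactors = FALSE)
      if (buried[i]) {
        cage <- .icosahedron() * 2.5
        for (j in seq_len(nrow(cage))) {
          serial <- serial + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            serial = serial, atom_name = "C", resname = "DUM", chain = "B",
            resid = 900L + 12L * i + j, x = center[1] + cage[j, 1],
            y = center[2] + cage[j, 2], z = center[3] + cage[j, 3],
            element = "C", stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  ann <- if ("annotation" %in% names(cys)) {
    data.frame(position = cys$position, annotation = cys$annotation,
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = cys$position, annotation = "none",
               stringsAsFactors = FALSE)
  }
  list(sequences = sequences, alignment = sequences,
       atoms_active = make_atoms(cys$buried_active),
       atoms_deactive = make_atoms(cys$buried_deactive),
       annotations = ann, truth = cys)
}

#' Generate a GSH alkylation time course
#'
#' Noiseless fractions follow `1 - exp(-k * [IAM] * t)` exactly; Gaussian
#' noise (clipped to `[0, 1]`) is added on top.
#'
#' @param k second-order rate constant (M^-1 s^-1), default 0.25 (so
#'   `k_obs = 0.005 s^-1` at the standard 20 mM alkylator).
#' @param iam_conc alkylator concentration (M), default 0.02.
#' @param times_s sampling times (s).
#' @param noise_sd additive Gaussian noise SD on the fraction.
#' @param seed RNG seed.
#' @return List with `data` (`time_s`, `fraction`) and `truth`.
#' @export
gen_gsh_timecourse <- function(k = 0.25, iam_conc = 0.02,
                               times_s = seq(0, 600, by = 30),
                               noise_sd = 0, seed = 1) {
  set.seed(seed)
  f <- 1 - exp(-k * iam_conc * times_s)
  if (noise_sd > 0) {
    f <- pmin(1, pmax(0, f + stats::rnorm(length(f), 0, noise_sd)))
  }
  list(data = data.frame(time_s = times_s, fraction = f),
       truth = list(k = k, iam_conc = iam_conc, k_obs = k * iam_conc,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate Amplex Red standards and sample traces
#'
#' Standards follow `F = gain * conc + offset` over 0-2.5 uM hydrogen
#' peroxide; sample wells accumulate fluorescence linearly at the programmed
#' H2O2 production rates.
#'
#' @param rates_uM_per_min named vector of programmed production rates by
#'   well.
#' @param gain fluorescence units per uM.
#' @param offset baseline fluorescence.
#' @param duration_min,dt_s trace length and sampling.
#' @param noise_frac relative Gaussian noise on fluorescence (e.g. 0.01).
#' @param seed RNG seed.
#' @return List with `standards` (`conc_uM`, `fluorescence`), `traces`
#'   (`well`, `time_min`, `fluorescence`) and `truth`.
#' @export
gen_amplex <- function(rates_uM_per_min = c(active = 0.5, deactive = 0.05),
                       gain = 1000, offset = 50, duration_min = 5,
                       dt_s = 12, noise_frac = 0, seed = 1) {
  set.seed(seed)
  conc <- seq(0, 2.5, by = 0.25)
  f_std <- gain * conc + offset
  if (noise_frac > 0) {
    f_std <- f_std * (1 + stats::rnorm(length(f_std), 0, noise_frac))
  }
  times <- seq(0, duration_min, by = dt_s / 60)
  traces <- do.call(rbind, lapply(names(rates_uM_per_min), function(w) {
    f <- offset + gain * rates_uM_per_min[[w]] * times
    if (noise_frac > 0) f <- f * (1 + stats::rnorm(length(f), 0, noise_frac))
    data.frame(well = w, time_min = times, fluorescence = f,
               stringsAsFactors = FALSE)
  }))
  rownames(traces) <- NULL
  list(standards = data.frame(conc_uM = conc, fluorescence = f_std),
       traces = traces,
       truth = list(rates_uM_per_min = as.list(rates_uM_per_min),
                    gain = gain, offset = offset, noise_frac = noise_frac,
                    seed = seed))
}
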