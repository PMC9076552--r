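# Active/deactive state analysis: activity-exposure regression, the binary
# model reference line, and a first-order kinetic simulator of the
# A / D / alkylated state model.

#' Linear regression with a 95% confidence band
#'
#' Ordinary least squares of exposure (%) on activity (%) with the t-based
#' pointwise confidence band, as used to relate enzyme activity to cysteine
#' exposure across conditions.
#'
#' @param activity activity values (% of matched active control).
#' @param exposure exposed fractions (%).
#' @param level confidence level (default 0.95).
#' @param at activity values at which to evaluate the band (default: a grid
#'   over the observed range).
#' @return List with `slope`, `intercept`, `fit` (the `lm` object), and
#'   `band` (`data.frame`: `activity`, `fit`, `lwr`, `upr`).
#' @export
regression_with_ci <- function(activity, exposure, level = 0.95, at = NULL) {
  stopifnot(length(activity) == length(exposure))
  if (length(activity) < 3) stop("need >= 3 points for regression")
  d <- data.frame(activity = activity, exposure = exposure)
  fit <- stats::lm(exposure ~ activity, data = d)
  if (is.null(at)) at <- seq(min(activity), max(activity), length.out = 50)
  pred <- stats::predict(fit, newdata = data.frame(activity = at),
                         interval = "confidence", level = level)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit,
       band = data.frame(activity = at, fit = pred[, "fit"],
                         lwr = pred[, "lwr"], upr = pred[, "upr"]))
}

#' Deviation from the binary-model reference line
#'
#' The binary model (occluded when active, exposed when deactive) predicts
#' the optimal inverse correlation `exposure% = 100 - activity%`. The
#' deviation is reported as `line - observed`, so a point lying *below* the
#' line (less exposure than the binary model predicts) has a **positive**
#' deviation.
#'
#' @param activity activity (% of active control).
#' @param exposure observed exposure (%).
#' @return Signed vertical deviation (line minus observed), vectorized.
#' @examples
#' binary_model_deviation(100, 0)   # 0: on the line
#' binary_model_deviation(100, 65)  # -65: above the line at full activity
#' @export
binary_model_deviation <- function(activity, exposure) {
  (100 - activity) - exposure
}

#' Kinetic parameters of the A/D/alkylation model
#'
#' First-order rate constants for the four-pool model: active (A), deactive
#' (D), alkylated-active (A-alk) and alkylated-locked (D-locked).
#' Deactivation A->D proceeds at `k_d` when no substrate is present;
#' reactivation D->A at `k_a` when substrate is present; alkylation at
#' `k_x * c` sends D to the permanently inactive D-locked pool, and
#' `k_x * c * p_exposed` sends A to A-alk (the fraction of active enzyme
#' with a reactive, exposed cysteine). A-alk remains catalytically competent
#' and can never enter the locked pool.
#'
#' @param k_d deactivation rate (min^-1, 37 C, no substrate).
#' @param k_a reactivation rate (min^-1, substrate present).
#' @param k_x alkylation rate (min^-1 per unit alkylator concentration).
#' @param p_exposed fraction of A-state enzyme with reactive cysteine
#'   (free parameter; maximal observed active-state alkylation was ~80%).
#' @return List of class `ADKineticParams`.
#' @export
ad_params <- function(k_d = 0.15, k_a = 0.4, k_x = 0.05, p_exposed = 0.8) {
  stopifnot(k_d >= 0, k_a >= 0, k_x >= 0, p_exposed >= 0, p_exposed <= 1)
  structure(list(k_d = k_d, k_a = k_a, k_x = k_x, p_exposed = p_exposed),
            class = "ADKineticParams")
}

# Generator matrix for a constant-condition segment.
# State order: A, D, A_alk, D_locked. Columns are source pools.
.ad_generator <- function(params, substrate, alkylator) {
  kd <- if (substrate) 0 else params$k_d
  ka <- if (substrate) params$k_a else 0
  kxA <- params$k_x * alkylator * params$p_exposed
  kxD <- params$k_x * alkylator
  Q <- matrix(0, 4, 4)
  # A -> D, A -> A_alk
  Q[2, 1] <- kd; Q[3, 1] <- kxA; Q[1, 1] <- -(kd + kxA)
  # D -> A, D -> D_locked
  Q[1, 2] <- ka; Q[4, 2] <- kxD; Q[2, 2] <- -(ka + kxD)
  Q
}

#' Simulate the A/D/alkylation state model under a protocol
#'
#' Integrates the four-pool first-order model with exact matrix-exponential
#' updates within constant-condition segments (no step-size artifacts; pool
#' conservation is exact to numerical precision). The protocol is a list of
#' timed events: `add_substrate`, `remove_substrate`, `add_alkylator`
#' (with `value` = concentration, in the units of `1/k_x`), and
#' `quench_alkylator`.
#'
#' @param params an [ad_params()] object.
#' @param protocol_events `data.frame` (or list of lists) with columns
#'   `t_min`, `event`, and optional `value`; times must be >= 0.
#' @param dt output sampling interval (min).
#' @param horizon total simulated time (min).
#' @param init initial pool fractions `c(A, D, A_alk, D_locked)`, summing
#'   to 1 (default: all active).
#' @return `data.frame` of class `ADKineticState` rows: `time`, `A`, `D`,
#'   `A_alk`, `D_locked`, `substrate`, `alkylator`, `activity`.
#' @examples
#' tr <- simulate_ad(ad_params(k_d = 0.1),
#'                   data.frame(t_min = 0, event = "remove_substrate"),
#'                   dt = 0.5, horizon = 20)
#' @export
simulate_ad <- function(params, protocol_events = NULL, dt = 0.1,
                        horizon = 60, init = c(1, 0, 0, 0)) {
  stopifnot(inherits(params, "ADKineticParams"), dt > 0, horizon > 0,
            length(init) == 4, all(init >= 0),
            abs(sum(init) - 1) < 1e-9)
  ev <- if (is.null(protocol_events)) {
    data.frame(t_min = numeric(0), event = character(0), value = numeric(0))
  } else {
    as.data.frame(protocol_events)
  }
  if (!"value" %in% names(ev)) ev$value <- NA_real_
  if (nrow(ev) > 0 && any(ev$t_min < 0)) stop("event times must be >= 0")
  known <- c("add_substrate", "remove_substrate", "add_alkylator",
             "quench_alkylator")
  if (nrow(ev) > 0 && !all(ev$event %in% known)) {
    stop("unknown event(s): ",
         paste(setdiff(ev$event, known), collapse = ", "))
  }
  ev <- ev[order(ev$t_min), , drop = FALSE]

  times <- seq(0, horizon, by = dt)
  substrate <- FALSE
  alkylator <- 0
  # apply any t = 0 events before the first step
  apply_events <- function(rows) {
    for (i in rows) {
      switch(ev$event[i],
             add_substrate = substrate <<- TRUE,
             remove_substrate = substrate <<- FALSE,
             add_alkylator = {
               if (is.na(ev$value[i]) || ev$value[i] < 0) {
                 stop("add_alkylator requires a non-negative value")
               }
               alkylator <<- ev$value[i]
             },
             quench_alkylator = alkylator <<- 0)
    }
  }
  apply_events(which(ev$t_min == 0))
  state <- init
  out <- matrix(NA_real_, length(times), 4)
  cond <- matrix(NA_real_, length(times), 2)
  out[1, ] <- state
  cond[1, ] <- c(substrate, alkylator)
  done <- ev$t_min == 0
  for (k in 2:length(times)) {
    t0 <- times[k - 1]; t1 <- times[k]
    # event times partition [t0, t1) into constant-condition pieces
    pend <- which(!done & ev$t_min > t0 & ev$t_min <= t1)
    cur <- t0
    for (i in pend) {
      if (ev$t_min[i] > cur) {
        Q <- .ad_generator(params, substrate, alkylator)
        state <- as.numeric(Matrix::expm(Q * (ev$t_min[i] - cur)) %*% state)
        cur <- ev$t_min[i]
      }
      apply_events(i)
      done[i] <- TRUE
    }
    if (t1 > cur) {
      Q <- .ad_generator(params, substrate, alkylator)
      state <- as.numeric(Matrix::expm(Q * (t1 - cur)) %*% state)
    }
    out[k, ] <- state
    cond[k, ] <- c(substrate, alkylator)
  }
  res <- data.frame(time = times, A = out[, 1], D = out[, 2],
                    A_alk = out[, 3], D_locked = out[, 4],
                    substrate = as.logical(cond[, 1]),
                    alkylator = cond[, 2])
  res$activity <- activity_from_state(res)
  class(res) <- c("ADKineticState", class(res))
  res
}

#' Activity fraction from pool state
#'
#' Maps pool fractions to the measurable activity: the electron-transfer
#' competent pools are A and A-alk (alkylation during turnover leaves
#' activity intact); D contributes only after reactivation (i.e., after
#' moving into A); D-locked never contributes.
#'
#' @param state a row set of [simulate_ad()] output, or any list/data.frame
#'   with elements `A` and `A_alk`.
#' @return Activity fraction(s) in `[0, 1]`.
#' @export
activity_from_state <- function(state) {
  state$A + state$A_alk
}
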