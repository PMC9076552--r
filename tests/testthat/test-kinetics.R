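# Rate extraction from plate-reader traces.

test_that("nadh_concentration converts dual-wavelength absorbance", {
  k <- assay_constants(path_cm = 1)
  expect_equal(nadh_concentration(0.00481, 0, k), 0.001)  # 1 uM in mM
  expect_equal(nadh_concentration(0.5, 0.5, k), 0)
  # halving the path doubles the concentration
  expect_equal(nadh_concentration(0.1, 0, assay_constants(path_cm = 0.5)),
               2 * nadh_concentration(0.1, 0, k))
  expect_error(nadh_concentration(0.1, NULL), "A380")
  # linearity property over random inputs
  set.seed(1)
  dA <- runif(20); path <- runif(20, 0.2, 1)
  for (i in 1:20) {
    expect_equal(nadh_concentration(2 * dA[i], 0,
                                    assay_constants(path_cm = path[i])),
                 2 * nadh_concentration(dA[i], 0,
                                        assay_constants(path_cm = path[i])))
  }
})

test_that("max_linear_rate finds the steepest window", {
  t <- seq(0, 600, by = 10)
  expect_equal(max_linear_rate(t, 1 - 0.01 * t)$rate, 0.01,
               tolerance = 1e-12)
  # piecewise: slow then steep consumption
  y <- ifelse(t < 300, 1 - 0.002 * t, 1 - 0.002 * 300 - 0.01 * (t - 300))
  est <- max_linear_rate(t, y)
  expect_equal(est$rate, 0.01, tolerance = 1e-9)
  expect_gte(est$window["start"], 300)
  # constant trace -> 0
  expect_equal(max_linear_rate(t, rep(2, length(t)))$rate, 0)
  expect_error(max_linear_rate(t[1:5], (1:5) * 1.0, window_samples = 10),
               "fewer samples")
  expect_error(max_linear_rate(c(0, 0, 1, 2, 3), 1:5, window_samples = 5),
               "strictly increasing")
})

test_that("rate estimators are unbiased under absorbance noise", {
  # Max-of-noisy-window-slopes estimators carry an upward selection bias that
  # grows as windows shrink; the assay protocol averages technical replicate
  # wells and fits a wide window, which keeps |bias| < 2% at 1% noise
  # (see the methods vignette for the selection-bias analysis).
  set.seed(21)
  t_min <- seq(0, 30, by = 0.2)          # 12-s sampling
  eps_path <- 4.81 * 0.55
  rate <- 0.01                           # mM/min
  signal0 <- 0.2 * eps_path              # initial NADH absorbance, ~0.53
  est <- replicate(200, {
    a_mean <- rowMeans(replicate(3, {    # technical triplicate
      0.2 * eps_path - rate * eps_path * t_min +
        rnorm(length(t_min), 0, 0.01 * signal0)
    }))
    conc <- a_mean / eps_path
    max_linear_rate(t_min, conc, window_samples = 40)$rate
  })
  expect_lt(abs(mean(est) - rate), 0.02 * rate)
})

test_that("rotenone_sensitive_rate subtracts background", {
  r <- rotenone_sensitive_rate(100, 18)
  expect_equal(r$sensitive_rate, 82)
  expect_equal(r$sensitive_fraction, 0.82)
  expect_equal(rotenone_sensitive_rate(7, 0)$sensitive_fraction, 1)
  expect_equal(rotenone_sensitive_rate(7, 7)$sensitive_rate, 0)
  expect_true(is.na(rotenone_sensitive_rate(0, 0)$sensitive_fraction))
})

test_that("reactivation_lag recovers programmed lags", {
  t <- seq(0, 20, by = 0.2)  # min
  # immediately linear trace -> lag 0
  expect_equal(reactivation_lag(t, 1 - 0.02 * t)$lag_time, 0)
  # logistic instantaneous rate, midpoint at 8 min
  r <- function(tt) 0.02 / (1 + exp(-(tt - 8) / 1.5))
  conc <- 1 - cumsum(c(0, (r(t[-1]) + r(t[-length(t)])) / 2 * diff(t)))
  lag <- reactivation_lag(t, conc)$lag_time
  expect_equal(lag, 8, tolerance = 0.21)
  # zero-rate plateau of 5 min then full rate
  conc2 <- 1 - pmax(0, t - 5) * 0.02
  lag2 <- reactivation_lag(t, conc2)$lag_time
  expect_equal(lag2, 5, tolerance = 0.21)
  expect_error(reactivation_lag(t, rep(1, length(t))), "lag undefined")
})

test_that("citrate_synthase_rate converts and is shift invariant", {
  t <- seq(0, 10, by = 7 / 60)
  k <- assay_constants(path_cm = 1)
  # A412 rising 0.0136/min -> 1 uM/min
  est <- citrate_synthase_rate(t, 0.1 + 0.0136 * t, k)
  expect_equal(est$rate, 1, tolerance = 1e-9)
  expect_equal(citrate_synthase_rate(t, rep(0.3, length(t)), k)$rate, 0)
  expect_equal(citrate_synthase_rate(t, 0.5 + 0.0136 * t, k)$rate,
               est$rate, tolerance = 1e-9)
})

test_that("amplex_quantify inverts the standard curve", {
  std <- data.frame(conc_uM = seq(0, 2.5, 0.5),
                    fluorescence = 1000 * seq(0, 2.5, 0.5))
  t <- seq(0, 5, by = 0.2)
  tr <- rbind(data.frame(well = "a", time_min = t,
                         fluorescence = 500 * t),
              data.frame(well = "b", time_min = t,
                         fluorescence = rep(100, length(t))))
  res <- amplex_quantify(tr, std)
  expect_equal(res$rate_uM_per_min[res$well == "a"], 0.5, tolerance = 1e-9)
  expect_equal(res$rate_uM_per_min[res$well == "b"], 0)
  expect_error(amplex_quantify(tr, std[1:2, ]), "3")
  # noisy recovery within 3%
  g <- gen_amplex(c(w1 = 0.5), noise_frac = 0.01, seed = 4)
  r2 <- amplex_quantify(g$traces, g$standards, window_samples = 15)
  expect_equal(r2$rate_uM_per_min, 0.5, tolerance = 0.03)
})

test_that("h2o2_stock_concentration applies Beer-Lambert with dilution", {
  expect_equal(h2o2_stock_concentration(0.435), 0.01)  # 10 mM
  expect_equal(h2o2_stock_concentration(0), 0)
  expect_equal(h2o2_stock_concentration(0.435, dilution = 10), 0.1)
})

test_that("fit_gsh_labeling recovers the rate constant", {
  g <- gen_gsh_timecourse(k = 0.25, iam_conc = 0.02)  # k_obs = 0.005 /s
  fit <- fit_gsh_labeling(g$data$time_s, g$data$fraction, 0.02)
  expect_equal(fit$k, 0.25, tolerance = 0.01)
  expect_equal(fit$half_time_s, log(2) / 0.005, tolerance = 0.01)
  # all-zero fractions -> k = 0
  z <- fit_gsh_labeling(c(0, 60, 120), c(0, 0, 0), 0.02)
  expect_equal(z$k, 0)
  expect_equal(z$half_time_s, Inf)
  # model limit: f(Inf) = 1
  expect_equal(1 - exp(-fit$k_obs * 1e9), 1)
  expect_warning(fit_gsh_labeling(c(0, 60, 120, 180), c(0, 0.8, 0.2, 0.9),
                                  0.02), "decreases")
})
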