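test_that("exponential recoil fit recovers generating parameters on noiseless curves", {
  p <- control_kv_params()
  curve <- model_retraction_curve(p)  # released at 60 min >> tau
  fit <- fit_exponential_recoil(curve)
  expect_false(fit$no_recoil)
  expect_equal(fit$tau_fit, 5, tolerance = 1e-6)
  expect_equal(fit$stretch_length, 40, tolerance = 1e-4)
  expect_equal(fit$rest_length, 20, tolerance = 1e-4)
  expect_equal(fit$initial_recoil, fit$stretch_length / fit$tau_fit,
               tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("retraction curves given in seconds are converted at ingest", {
  p <- control_kv_params()
  curve <- model_retraction_curve(p)
  curve_s <- data.frame(t_s = curve$t_min * 60, length_um = curve$length_um)
  fit <- fit_exponential_recoil(curve_s)
  expect_equal(fit$tau_fit, 5, tolerance = 1e-6)
})

test_that("a flat curve is flagged no-recoil instead of fitted", {
  flat <- data.frame(t_min = seq(0, 10, 0.5), length_um = 20)
  fit <- fit_exponential_recoil(flat)
  expect_true(fit$no_recoil)
  expect_identical(fit$stretch_length, 0)
  expect_true(is.na(fit$tau_fit))
  expect_error(fit_exponential_recoil(flat[1:3, ]), "5 samples")
})

test_that("mean fitted tau is within 5% of truth over 20 noisy replicates", {
  p <- control_kv_params()
  curve <- model_retraction_curve(p)
  set.seed(42)
  taus <- replicate(20, {
    noisy <- curve
    noisy$length_um <- noisy$length_um + rnorm(nrow(noisy), 0, 0.5)
    fit_exponential_recoil(noisy)$tau_fit
  })
  expect_lt(abs(mean(taus) - 5) / 5, 0.05)
})

test_that("recoil-ratio regression classifies the three material classes", {
  spec <- function(seed) experiment_spec(n = 30, sampling_interval = 0.25,
                                         duration = 30, seed = seed)
  ctl <- simulate_ablation(spec(11), make_preset("control", "cell"),
                           curves = FALSE)
  res <- recoil_ratio_regression(ctl$records)
  expect_identical(res$classification, "plastic-constant")
  expect_equal(res$mean_ratio, 0.25, tolerance = 0.05)

  tkv <- simulate_ablation(spec(12), make_preset("tkv", "cell"),
                           curves = FALSE)
  res <- recoil_ratio_regression(tkv$records)
  expect_identical(res$classification, "elastic-increasing")
  expect_gte(max(tkv$records$ratio), 0.45)

  mx <- simulate_ablation(spec(13), make_preset("maxwell_demo", "cell"),
                          curves = FALSE)
  expect_identical(recoil_ratio_regression(mx$records)$classification,
                   "maxwell-decreasing")
})

test_that("wound-response records are excluded, degenerate ranges refused", {
  rec <- data.frame(length_before_um = seq(8, 16, length.out = 10),
                    ratio = 0.25 + rnorm(10, 0, 1e-3))
  rec$ratio[3] <- -0.1  # cell longer after 'relaxation': active constriction
  expect_message(res <- recoil_ratio_regression(rec), "excluded")
  expect_identical(res$n_excluded, 1L)
  expect_identical(res$n, 9L)
  narrow <- data.frame(length_before_um = seq(10, 11, length.out = 10),
                       ratio = 0.25)
  expect_error(recoil_ratio_regression(narrow), "degenerate")
  expect_error(recoil_ratio_regression(rec[1:5, ]), "6 usable")
})

test_that("elongation speed: exact zeros, offset invariance, unit equivariance", {
  flat <- data.frame(time_min = 0:10, length_um = 60)
  expect_equal(elongation_speed(flat)$speed_um_per_min, 0)
  tr <- model_trajectory("RATCHET", traction_schedule(Inf),
                         make_preset("control", "tissue")$params,
                         seq(0, 300, 0.5))
  sp <- elongation_speed(tr, window = c(100, 300))
  shifted <- tr
  shifted$length_um <- shifted$length_um + 123
  expect_equal(elongation_speed(shifted, c(100, 300))$speed_um_per_min,
               sp$speed_um_per_min, tolerance = 1e-12)
  rescaled <- tr
  rescaled$time_min <- rescaled$time_min * 60  # pretend seconds grid
  expect_equal(elongation_speed(rescaled,
                                c(6000, 18000))$speed_um_per_min,
               sp$speed_um_per_min / 60, tolerance = 1e-12)
  # a pure Kelvin-Voigt trajectory has negligible late slope
  kv <- model_trajectory("KELVIN_VOIGT", traction_schedule(Inf),
                         control_kv_params(), seq(0, 300, 0.5))
  expect_lt(abs(elongation_speed(kv, c(100, 300))$speed_um_per_min),
            0.01 * 40 / 5)
  expect_error(elongation_speed(kv, c(400, 500)), "no data")
})

test_that("5PL fit recovers known parameters and its analytic maximum slope", {
  x <- seq(0, 10, length.out = 50)
  truth <- list(lower = 2, upper = 10, xmid = 5, b = 0.3, s = 2)
  y <- do.call(epirheo:::logistic5, c(list(x = x), truth))
  fit <- fit_logistic5_max_speed(data.frame(x = x, y = y))
  for (nm in names(truth))
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-3)
  # independent oracle: numeric 1D maximization of the analytic derivative
  opt <- optimize(function(z) abs(do.call(epirheo:::logistic5_deriv,
                                          c(list(x = z), truth))),
                  range(x), maximum = TRUE)
  expect_equal(fit$max_speed, opt$objective, tolerance = 1e-6)
  expect_equal(fit$x_at_max, opt$maximum, tolerance = 1e-4)
})

test_that("5PL symmetric case has its inflection at xmid; degenerate input refused", {
  x <- seq(0, 10, length.out = 40)
  y <- epirheo:::logistic5(x, 0, 1, 4, 0.5, 1)
  fit <- fit_logistic5_max_speed(data.frame(x = x, y = y))
  expect_equal(fit$s, 1, tolerance = 1e-3)
  expect_equal(fit$x_at_max, 4, tolerance = 1e-3)  # log10(1)/b = 0
  expect_error(fit_logistic5_max_speed(data.frame(x = x, y = rep(1, 40))),
               "degenerate|constant")
  expect_error(fit_logistic5_max_speed(data.frame(x = x[1:5], y = y[1:5])),
               "8 points")
})
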