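test_that("presets carry the canonical constants and are deterministic", {
  ctl <- make_preset("control")
  expect_equal(ctl$params$tau, 5)
  expect_equal(rest_length_agg(ctl$params), 20)
  expect_equal(stretch_agg(ctl$params), 40)
  expect_equal((ctl$params$l0 + ctl$params$stretch) / ctl$params$period,
               0.2)  # asymptotic plastic elongation rate
  expect_identical(make_preset("tkv")$params$period, Inf)
  expect_equal(make_preset("tkv")$params$tau, ctl$params$tau)
  cell <- make_preset("control", "cell")
  expect_equal(cell$params$stretch, cell$params$l0 / 3)
  expect_identical(make_preset("control"), make_preset("control"))
  expect_error(make_preset("wild_type"), "available")
})

test_that("noiseless control trajectory runs 60 to 90 um over the 150-min closure", {
  ctl <- make_preset("control", noise_sd = 0, cv = 0)
  sp <- experiment_spec(n = 1, sampling_interval = 0.5, duration = 150,
                        seed = 1)
  tr <- simulate_trajectories(sp, ctl)
  expect_equal(tr$length_um[1], 60, tolerance = 0.5 / 60)
  expect_equal(tr$length_um[nrow(tr)], 90, tolerance = 0.5 / 90)
  # a tkv (pure Kelvin-Voigt) tissue stays flat once equilibrated
  tkv <- make_preset("tkv", noise_sd = 0, cv = 0)
  trk <- simulate_trajectories(sp, tkv)
  expect_lt(diff(range(trk$length_um)), 0.01)
})

test_that("generation is bit-reproducible under (preset, spec, seed)", {
  ctl <- make_preset("control")
  sp <- experiment_spec(n = 3, sampling_interval = 1, duration = 60,
                        seed = 7)
  expect_identical(simulate_trajectories(sp, ctl),
                   simulate_trajectories(sp, ctl))
  abl <- simulate_ablation(experiment_spec(n = 5, sampling_interval = 0.25,
                                           duration = 30, seed = 7),
                           make_preset("control", "cell"))
  abl2 <- simulate_ablation(experiment_spec(n = 5, sampling_interval = 0.25,
                                            duration = 30, seed = 7),
                            make_preset("control", "cell"))
  expect_identical(abl$records, abl2$records)
  expect_identical(abl$curves, abl2$curves)
  expect_error(experiment_spec(n = 3, sampling_interval = 1, duration = 60),
               "seed")
})

test_that("with zero noise the generator reproduces the closed forms exactly", {
  ctl <- make_preset("control", noise_sd = 0, cv = 0)
  sp <- experiment_spec(n = 1, sampling_interval = 0.5, duration = 100,
                        seed = 3)
  tr <- simulate_trajectories(sp, ctl, equilibrate = FALSE)
  cf <- model_trajectory("RATCHET", traction_schedule(Inf), ctl$params,
                         tr$time_min)
  expect_equal(tr$length_um, cf$length_um, tolerance = 1e-12)
  # changing only the seed changes only the noise, not the mean
  noisy1 <- simulate_trajectories(experiment_spec(n = 1, duration = 100,
                                                  seed = 4), ctl)
  noisy2 <- simulate_trajectories(experiment_spec(n = 1, duration = 100,
                                                  seed = 5), ctl)
  expect_identical(noisy1$length_um, noisy2$length_um)  # sd = 0 here
})

test_that("ablation simulation: constant 25% control ratios, rising tkv ratios", {
  sp <- experiment_spec(n = 15, sampling_interval = 0.25, duration = 30,
                        seed = 21)
  ctl <- simulate_ablation(sp, make_preset("control", "cell", noise_sd = 0,
                                           cv = 0, ratio_sd = 0),
                           curves = FALSE)
  # length-independent up to the 1/n unit discretization
  expect_true(all(abs(ctl$records$ratio - 0.25) < 0.01))
  expect_gt(max(ctl$records$length_before_um) /
              min(ctl$records$length_before_um), 1.4)

  tkv <- simulate_ablation(sp, make_preset("tkv", "cell", noise_sd = 0,
                                           cv = 0, ratio_sd = 0),
                           curves = FALSE)
  ord <- order(tkv$records$length_before_um)
  expect_true(all(diff(tkv$records$ratio[ord]) > 0))
  # a fully stretched cell sits at twice its rest length: ratio 1/2
  pk <- make_preset("tkv", "cell")$params
  expect_equal(recoil_ratio_theory("KELVIN_VOIGT", 2 * rest_length_agg(pk),
                                   pk), 0.5)
})

test_that("noisy seeded curves all converge through the recoil fitter", {
  sp <- experiment_spec(n = 10, sampling_interval = 0.25, duration = 30,
                        seed = 33)
  abl <- simulate_ablation(sp, make_preset("control", "cell"))
  fits <- lapply(split(abl$curves, abl$curves$cell_id),
                 fit_exponential_recoil)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  taus <- vapply(fits, `[[`, numeric(1), "tau_fit")
  expect_equal(mean(taus), 5, tolerance = 0.25)
})

test_that("releasing before tau warns about the partial-stretch regime", {
  sp <- experiment_spec(n = 2, sampling_interval = 0.25, duration = 10,
                        t_release = 2, seed = 8)
  expect_warning(simulate_ablation(sp, make_preset("tkv", "cell"),
                                   curves = FALSE), "partial-stretch")
})
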