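test_that("Kelvin-Voigt creep: rest at t = 0, saturates at the stretch amplitude, continuous at release", {
  p <- control_kv_params()
  never <- traction_schedule(Inf)
  expect_identical(kv_length(0, never, p), 20)
  # after 12 characteristic times the 40-um amplitude is developed up to
  # the exact exponential remainder 40*e^-12 ~ 2.5e-4 um
  expect_equal(kv_length(60, never, p), 60, tolerance = 1e-5)
  # one characteristic time: 63.2% of the amplitude (frozen from
  # 20 + 40*(1 - e^-1); numeric-integration agreement is checked separately)
  expect_equal(kv_length(5, never, p), 45.28482, tolerance = 1e-6)
  sched <- traction_schedule(12.5)
  eps <- 1e-9
  expect_equal(kv_length(12.5 - eps, sched, p),
               kv_length(12.5 + eps, sched, p), tolerance = 1e-6)
  # full relaxation returns to the pre-traction rest length (no memory)
  expect_equal(kv_length(1e4, sched, p), 20, tolerance = 1e-9)
})

test_that("Maxwell/KV creep: linear flow plus elastic transient; flow is permanent", {
  # sigma/eta_M = l0/period = 0.2 um/min
  p <- material_params(l0 = 20, stretch = 40, tau = 5, period = 100)
  expect_identical(maxwellkv_length(0, traction_schedule(Inf), p), 20)
  # late-time slope under traction is the flow rate
  slope <- (maxwellkv_length(200, traction_schedule(Inf), p) -
            maxwellkv_length(150, traction_schedule(Inf), p)) / 50
  expect_equal(slope, 0.2, tolerance = 1e-9)
  # released at 100 min: 0.2 * 100 = 20 um retained at t -> infinity
  sched <- traction_schedule(100)
  expect_equal(maxwellkv_length(1e5, sched, p), 20 + 20, tolerance = 1e-9)
  expect_error(maxwellkv_length(10, sched, control_kv_params()),
               "kv_length")
})

test_that("ratchet with infinite period reduces exactly to Kelvin-Voigt", {
  p <- material_params(l0 = 0.3, stretch = 0.1, tau = 5, period = Inf,
                       n0 = 20L)
  sched <- traction_schedule(40)
  times <- seq(0, 80, by = 0.5)
  r <- ratchet_length(times, sched, p)
  expect_identical(r$length_um, kv_length(times, sched, p))
  expect_true(all(r$n_units == 20L))
})

test_that("ratchet adds units with floor semantics and keeps them after release", {
  p <- cell_ratchet_params()  # p = 20 min
  never <- traction_schedule(Inf)
  r <- ratchet_length(c(19.99, 20, 39.99, 40), never, p)
  expect_identical(r$n_units, c(20L, 21L, 21L, 22L))
  # jump at the addition instant is exactly l0 (new unit starts unstretched)
  just_before <- ratchet_length(20 - 1e-6, never, p)$length_um
  at <- ratchet_length(20, never, p)$length_um
  expect_equal(at - just_before, p$l0, tolerance = 1e-6)
  # unit count frozen after release
  sched <- traction_schedule(50)
  r2 <- ratchet_length(c(50, 60, 200), sched, p)
  expect_true(all(r2$n_units == 22L))
  # full relaxation retains the grown rest length
  expect_equal(r2$length_um[3], 22 * p$l0, tolerance = 1e-8)
})

test_that("release decomposition: model-specific permanent deformation", {
  p <- control_kv_params()
  d <- release_decomposition("KELVIN_VOIGT", traction_schedule(60), p)
  expect_identical(d$l_deform, 0)
  expect_equal(d$l_stretch, 40, tolerance = 1e-5)  # t_release >> tau
  expect_equal(d$rest_length + d$l_stretch, d$length_at_release)

  pm <- material_params(l0 = 20, stretch = 40, tau = 5, period = 100)
  dm <- release_decomposition("MAXWELL_KV", traction_schedule(100), pm)
  expect_equal(dm$l_deform, 0.2 * 100, tolerance = 1e-12)

  pr <- cell_ratchet_params()
  dr <- release_decomposition("RATCHET", traction_schedule(10 * 20), pr)
  expect_equal(dr$l_deform, 10 * pr$l0, tolerance = 1e-12)
  expect_identical(dr$n_units, 30L)
  # the decomposition is consistent with the trajectory at release
  expect_equal(dr$length_at_release,
               ratchet_length(200, traction_schedule(200), pr)$length_um,
               tolerance = 1e-12)
  expect_error(release_decomposition("KELVIN_VOIGT", traction_schedule(Inf),
                                     p), "finite")
})

test_that("theoretical recoil ratios carry the three discrimination signatures", {
  pr <- cell_ratchet_params()  # stretch = l0/3
  lens <- seq(8, 16, by = 1)
  rr <- recoil_ratio_theory("RATCHET", lens, pr)
  expect_true(all(abs(rr - 0.25) < 1e-12))  # constant, exactly sigma/k over (l0 + sigma/k)

  pk <- material_params(l0 = 0.3, stretch = 0.3, tau = 5, n0 = 20L)
  rest <- rest_length_agg(pk)
  expect_equal(recoil_ratio_theory("KELVIN_VOIGT", 2 * rest, pk), 0.5)
  rk <- recoil_ratio_theory("KELVIN_VOIGT", lens, pk)
  expect_true(all(diff(rk) > 0))  # increasing with length
  expect_error(recoil_ratio_theory("KELVIN_VOIGT", rest / 2, pk), "rest")

  pm <- material_params(l0 = 0.3, stretch = 0.1, tau = 5, period = 5,
                        n0 = 20L)
  base <- rest_length_agg(pm) + stretch_agg(pm)
  rm <- recoil_ratio_theory("MAXWELL_KV", c(base, 2 * base), pm)
  expect_equal(rm[2], rm[1] / 2, tolerance = 1e-12)  # halves when length doubles
  expect_true(all(diff(recoil_ratio_theory("MAXWELL_KV",
                                           seq(base, 2 * base, length.out = 5),
                                           pm)) < 0))
})

test_that("ablation proxies: definitions, exact identity, and the numeric derivative", {
  p <- control_kv_params()
  pr <- ablation_proxies_theory(p)
  expect_equal(pr$initial_recoil, 8)   # 40 um / 5 min
  expect_equal(pr$char_time, 5)
  expect_equal(pr$total_recoil, 40)
  expect_equal(pr$initial_recoil * pr$char_time, pr$total_recoil,
               tolerance = 1e-12)
  # initial recoil equals the retraction speed just after release
  sched <- traction_schedule(60)
  h <- 1e-6
  v0 <- -(kv_length(60 + h, sched, p) - kv_length(60, sched, p)) / h
  expect_equal(v0, pr$initial_recoil, tolerance = 1e-4)
  # doubling tau at fixed stretch halves the initial recoil only
  p2 <- material_params(l0 = 20, stretch = 40, tau = 10)
  pr2 <- ablation_proxies_theory(p2)
  expect_equal(pr2$initial_recoil, pr$initial_recoil / 2)
  expect_equal(pr2$total_recoil, pr$total_recoil)
  # no stretch: nothing to recoil
  pz <- ablation_proxies_theory(material_params(l0 = 20, stretch = 0,
                                                tau = 5))
  expect_false(pz$defined)
  expect_identical(pz$total_recoil, 0)
})
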