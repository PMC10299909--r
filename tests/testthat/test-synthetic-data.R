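# Generators: closed-form agreement at zero noise, determinism, validation.

test_that("dose-response generator matches the operational model at zero noise", {
  spec <- op_spec(conc = c(-20, seq(-10, -4, length.out = 7), 3))
  dr <- generate_dose_response(spec)
  # zero-dose limit: response = basal at every replicate
  expect_equal(dr$response[dr$log_conc == -20], rep(2, 3), tolerance = 1e-10)
  # saturating limit: basal + (em - basal) tau / (1 + tau)
  tau <- 10^spec$log_tau
  plateau <- spec$basal + (spec$em - spec$basal) * tau / (1 + tau)
  expect_equal(dr$response[dr$log_conc == 3], rep(plateau, 3), tolerance = 1e-6)
  # whole grid equals the closed form to <= 1e-10 relative
  m <- operational_model(spec$basal, spec$em, spec$log_ka, spec$log_tau)
  expect_equal(dr$response, eval_operational(m, dr$log_conc), tolerance = 1e-10)
})

test_that("generators are bit-identical under a fixed seed", {
  spec <- op_spec(noise_sd = 5, seed = 42L)
  expect_identical(generate_dose_response(spec), generate_dose_response(spec))
  bspec <- binding_curve_spec("competition_two_site",
                              conc_grid = seq(-12, -4, length.out = 10),
                              top = 1, bottom = 0, p_ic50_high = 9,
                              p_ic50_low = 6.5, fraction_high = 0.6,
                              noise_sd = 0.05, seed = 11L)
  expect_identical(generate_binding_curve(bspec), generate_binding_curve(bspec))
  mspec <- markov_trace_spec(500, 0.2, 0.02, 0.01,
                             c(chi1_n652 = "dihedral"), 20, 25, 180, 25,
                             seed = 5L)
  expect_identical(generate_markov_trace(mspec), generate_markov_trace(mspec))
})

test_that("spec validation names the violated invariant", {
  expect_error(dose_response_spec(10, 5, -7, 0, c(-9, -8)), "em")
  expect_error(dose_response_spec(0, 100, -7, 0, c(-8, -9)), "conc_grid")
  expect_error(op_spec(noise_sd = -1), "noise_sd")
  expect_error(binding_curve_spec("competition_one_site",
                                  conc_grid = c(-9, -8), top = 1, bottom = 0,
                                  p_ic50_high = 8, p_ic50_low = 6,
                                  fraction_high = 0.5),
               "two-site parameters")
  expect_error(binding_curve_spec("competition_two_site",
                                  conc_grid = c(-9, -8), top = 1, bottom = 0,
                                  p_ic50_high = 6, p_ic50_low = 8,
                                  fraction_high = 0.5),
               "p_ic50_high")
  expect_error(markov_trace_spec(10, 1, 0.5, 0.5, c(x = "distance"),
                                 1, 0, 1, 1), "SDs")
  expect_error(markov_trace_spec(10, 1, 0.5, 0.5, c(x = "distance"),
                                 1, 1, 1, 1, burn_in_ns = 100), "burn_in_ns")
})

test_that("binding-curve generator reproduces its closed forms", {
  # saturation at [A] = Kd with NS = 0 gives Bmax / 2
  bs <- binding_curve_spec("saturation", conc_grid = c(-10, -9.5, -9, -8.5),
                           bmax = 800, p_kd_radioligand = 9, ns_slope = 0)
  cv <- generate_binding_curve(bs)
  expect_equal(cv$signal[cv$series == "total" & cv$log_conc == -9], 400,
               tolerance = 1e-10)
  expect_true(all(cv$signal[cv$series == "nonspecific"] == 0))
  # two-site with fraction_high = 1 collapses onto the one-site curve
  grid <- seq(-12, -4, length.out = 9)
  two <- generate_binding_curve(binding_curve_spec(
    "competition_two_site", conc_grid = grid, top = 1, bottom = 0,
    p_ic50_high = 8, p_ic50_low = 6, fraction_high = 1))
  one <- generate_binding_curve(binding_curve_spec(
    "competition_one_site", conc_grid = grid, top = 1, bottom = 0,
    p_ic50_high = 8))
  expect_equal(two$signal, one$signal, tolerance = 1e-12)
  # no-competitor limit approaches Top
  low <- generate_binding_curve(binding_curve_spec(
    "competition_one_site", conc_grid = c(-30, -8), top = 3, bottom = 1,
    p_ic50_high = 8))
  expect_equal(low$signal[low$log_conc == -30], 3, tolerance = 1e-10)
})

test_that("markov traces honor the chain and the wrapping convention", {
  # absorbing chain: all frames open
  sp <- markov_trace_spec(2000, 0.2, 0, 0.3, c(d = "distance"), 12, 0.5,
                          8, 0.5, initial_state = "open", seed = 2L)
  tr <- generate_markov_trace(sp)
  expect_true(all(attr(tr, "true_state")))
  # symmetric chain converges to occupancy 1/2 within 3 binomial SEs
  n <- 200000
  sp2 <- markov_trace_spec(n, 0.1, 0.01, 0.01, c(d = "distance"), 12, 0.5,
                           8, 0.5, seed = 3L)
  occ <- mean(attr(generate_markov_trace(sp2), "true_state"))
  # effective sample size for an autocorrelated 2-state chain:
  # n * (p_oc + p_co) / (2 - p_oc - p_co) independent switches
  se <- sqrt(0.25 / (n * 0.02 / 1.98))
  expect_lt(abs(occ - 0.5), 3 * se)
  # dihedral emissions near the seam wrap into (-180, 180]
  sp3 <- markov_trace_spec(5000, 0.1, 0, 1, c(chi = "dihedral"),
                           170, 20, 170, 20, initial_state = "open", seed = 4L)
  chi <- generate_markov_trace(sp3)$chi
  expect_true(all(chi > -180 & chi <= 180))
  expect_true(any(chi < -150))           # mass that crossed the seam
})
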