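# Binding equations, competition fits and the Cheng-Prusoff conversion.

test_that("eval_saturation reproduces hand-computed values", {
  m <- saturation_model(b_max = 1000, p_ka = 9, ns_slope = 0)
  expect_identical(eval_saturation(m, 0), 0)
  expect_equal(eval_saturation(m, 1e-9), 500)      # [A] = Kd, NS = 0
  # direct substitution with a nonspecific component
  m2 <- saturation_model(1000, 9, ns_slope = 1e6)
  expect_equal(eval_saturation(m2, 1e-9), 500 + 1e6 * 1e-9)
  expect_error(eval_saturation(m, -1e-9), "non-negative")
})

test_that("fit_saturation recovers parameters and fails loudly on flat data", {
  spec <- binding_curve_spec("saturation",
                             conc_grid = seq(-11, -8, length.out = 8),
                             bmax = 1000, p_kd_radioligand = 9.5,
                             ns_slope = 2e9, noise_sd = 0)
  fit <- fit_saturation(generate_binding_curve(spec))
  expect_false(is_fit_failure(fit))
  expect_equal(unname(fit$par), c(1000, 9.5, 2e9), tolerance = 1e-6)

  flat <- data.frame(series = rep(c("total", "nonspecific"), each = 5),
                     log_conc = rep(seq(-10, -8, length.out = 5), 2),
                     signal = 7)
  expect_true(is_fit_failure(fit_saturation(flat)))
})

test_that("fit_saturation recovers pKd from noisy replicated data", {
  # scaled-down recovery study: 40 seeds (8 concentrations, 3 replicates,
  # noise 2% of Bmax)
  errs <- vapply(1:40, function(s) {
    spec <- binding_curve_spec("saturation",
                               conc_grid = seq(-11, -8, length.out = 8),
                               bmax = 1000, p_kd_radioligand = 9.5,
                               ns_slope = 2e9, n_replicates = 3,
                               noise_sd = 20, seed = s)
    fit <- fit_saturation(generate_binding_curve(spec))
    fit$par[["p_ka"]] - 9.5
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 0.1)
  expect_lt(abs(stats::median(errs)), 0.05)
})

test_that("eval_two_site reproduces limits and hand-evaluated points", {
  m <- two_site_model(top = 1, bottom = 0, log_ic50_high = -10,
                      log_ic50_low = -7, fraction_high = 0.5)
  expect_equal(eval_two_site(m, -40), 1, tolerance = 1e-12)
  # log[B] at the midpoint of the two logIC50s: the two terms sum to 1/2
  expect_equal(eval_two_site(m, -8.5), 0.5, tolerance = 1e-12)
  m1 <- two_site_model(2, 1, -8, -8, 1)
  expect_equal(eval_two_site(m1, -8), 1.5)         # f1 = 1 at its logIC50
})

test_that("eval_two_site is monotone non-increasing in log[B]", {
  set.seed(101)
  grid <- seq(-13, -3, length.out = 60)
  for (i in 1:25) {
    l1 <- runif(1, -12, -6)
    m <- two_site_model(top = runif(1, 1, 10), bottom = runif(1, 0, 0.9),
                        log_ic50_high = l1,
                        log_ic50_low = l1 + runif(1, 0, 4),
                        fraction_high = runif(1))
    expect_true(all(diff(eval_two_site(m, grid)) <= 1e-12))
  }
})

test_that("fit_competition recovers noiseless one- and two-site parameters", {
  grid <- seq(-12, -4, length.out = 12)
  one <- generate_binding_curve(binding_curve_spec(
    "competition_one_site", conc_grid = grid, top = 1, bottom = 0,
    p_ic50_high = 8.3))
  f1 <- fit_competition(one, sites = "one")
  expect_equal(f1$par[["log_ic50"]], -8.3, tolerance = 1e-6)

  two <- generate_binding_curve(binding_curve_spec(
    "competition_two_site", conc_grid = grid, top = 1, bottom = 0,
    p_ic50_high = 9.6, p_ic50_low = 6.6, fraction_high = 0.6))
  f2 <- fit_competition(two, sites = "two")
  expect_equal(unname(f2$par),
               c(1, 0, -9.6, -6.6, 0.6), tolerance = 1e-4)
  expect_length(f2$warnings, 0)
})

test_that("auto mode selects one site when the sites are unresolvable", {
  grid <- seq(-12, -4, length.out = 12)
  close_sites <- generate_binding_curve(binding_curve_spec(
    "competition_two_site", conc_grid = grid, top = 1, bottom = 0,
    p_ic50_high = 7.8, p_ic50_low = 7.5, fraction_high = 0.5,
    n_replicates = 3, noise_sd = 0.02, seed = 8L))
  fit <- fit_competition(close_sites, sites = "auto")
  expect_identical(fit$model, "one_site")
  # and clearly separated noiseless sites stay two-site
  far <- generate_binding_curve(binding_curve_spec(
    "competition_two_site", conc_grid = grid, top = 1, bottom = 0,
    p_ic50_high = 9.6, p_ic50_low = 6.6, fraction_high = 0.6))
  expect_identical(fit_competition(far, sites = "auto")$model, "two_site")
})

test_that("fit_competition round-trips random identifiable two-site curves", {
  set.seed(77)
  grid <- seq(-13, -3, length.out = 14)
  for (i in 1:5) {
    theta <- c(top = runif(1, 0.8, 2), bottom = runif(1, 0, 0.3),
               log_ic50_high = runif(1, -11, -9),
               log_ic50_low = runif(1, -7.5, -5.5),
               fraction_high = runif(1, 0.3, 0.7))
    m <- do.call(two_site_model, as.list(theta))
    dat <- data.frame(log_conc = grid, signal = eval_two_site(m, grid))
    fit <- fit_competition(dat, sites = "two")
    expect_equal(unname(fit$par), unname(theta), tolerance = 1e-3)
  }
})

test_that("cheng_prusoff matches hand arithmetic and is unit-invariant", {
  expect_equal(cheng_prusoff(1e-8, 2e-10, 1e-10),
               -log10(1e-8 / 3), tolerance = 1e-12)   # pKi 8.477
  expect_equal(round(cheng_prusoff(1e-8, 2e-10, 1e-10), 3), 8.477)
  expect_equal(cheng_prusoff(1e-8, 1e-9, 1e-9), -log10(5e-9))  # [A*] = Kd
  expect_equal(cheng_prusoff(1e-8, 1e-15, 1e-9), 8, tolerance = 1e-6)
  # scaling all three molar inputs by the same unit factor changes nothing
  # in the implied Ki ratio: pKi shifts by exactly -log10(scale)
  s <- 1e9
  expect_equal(cheng_prusoff(1e-8 * s, 2e-10 * s, 1e-10 * s),
               cheng_prusoff(1e-8, 2e-10, 1e-10) - log10(s))
  expect_error(cheng_prusoff(-1, 1, 1), "ic50")
})
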