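# Ternary complex model: equilibrium solver, competition prediction,
# cooperativity fit, free energies.

test_that("g_tot = 0 reduces the ternary model to simple one-site binding", {
  tm <- ternary_model(6.9, 10^3.3, 8, r_tot = 1e-10, g_tot = 0)
  s <- solve_equilibrium(tm, c(1e-8, 1e-6))
  expect_true(all(s$RG == 0) && all(s$LRG == 0))
  # LR / R = [L]free / K_L
  expect_equal(s$LR / s$R, s$L / 10^-6.9, tolerance = 1e-9)
})

test_that("alpha = 1 decouples ligand binding from the G-protein level", {
  frac_bound <- function(g_tot) {
    tm <- ternary_model(7, 1, 8, r_tot = 5e-9, g_tot = g_tot)
    s <- solve_equilibrium(tm, 1e-7)
    (s$LR + s$LRG) / 1e-7
  }
  f <- vapply(c(0, 1e-9, 1e-7, 1e-5), frac_bound, numeric(1))
  expect_equal(max(f) - min(f), 0, tolerance = 1e-10)
})

test_that("the solver matches the brute-force bisection oracle and conserves mass", {
  set.seed(404)
  for (i in 1:200) {
    p_k_l <- runif(1, 5, 10); p_k_g <- runif(1, 6, 10)
    alpha <- 10^runif(1, 0, 4)
    r_tot <- 10^runif(1, -12, -8); g_tot <- 10^runif(1, -10, -6)
    l_tot <- 10^runif(1, -10, -5)
    tm <- ternary_model(p_k_l, alpha, p_k_g, r_tot, g_tot)
    s <- solve_equilibrium(tm, l_tot)
    o <- oracle_ternary_bisect(r_tot, g_tot, l_tot,
                               10^-p_k_l, alpha, 10^-p_k_g)
    for (sp in c("R", "G", "LR", "RG", "LRG")) {
      denom <- max(abs(o[[sp]]), r_tot * 1e-6)
      expect_lt(abs(s[[sp]] - o[[sp]]) / denom, 1e-8)
    }
    expect_lt(abs(s$R + s$LR + s$RG + s$LRG - r_tot) / r_tot, 1e-10)
    expect_lt(abs(s$G + s$RG + s$LRG - g_tot) / g_tot, 1e-10)
    expect_lt(abs(s$L + s$LR + s$LRG - l_tot) / l_tot, 1e-10)
  }
})

test_that("G saturation shifts the apparent affinity by log10(alpha)", {
  grid <- seq(-14, -3, length.out = 16)
  rl <- list(p_kd = 9.5, conc = 10^-9.5)
  fit_pki <- function(g_tot) {
    tm <- ternary_model(6.9, 10^3.5, 8, r_tot = 1e-13, g_tot = g_tot)
    cv <- predict_competition_curve(tm, rl$p_kd, rl$conc, grid)
    f <- fit_competition(cv, sites = "one", radioligand_conc = rl$conc,
                         radioligand_p_kd = rl$p_kd)
    f$p_ki_high
  }
  shift <- fit_pki(1e-5) - fit_pki(0)
  expect_lt(abs(shift - 3.5), 0.05)
})

test_that("fitted high-affinity fraction increases along a G-protein ladder", {
  # biphasic displacement needs limiting G (g_tot < r_tot, tight G binding):
  # the receptors holding a G protein make up the high-affinity fraction, so
  # fraction_high tracks the G:R ratio
  grid <- seq(-12, -3, length.out = 14)
  fracs <- vapply(c(2e-10, 4.5e-10, 7e-10), function(g_tot) {
    tm <- ternary_model(6.9, 10^3.3, 10, r_tot = 1e-9, g_tot = g_tot)
    cv <- predict_competition_curve(tm, 8, 1e-8, grid)
    fit_competition(cv, sites = "two")$par[["fraction_high"]]
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  expect_equal(fracs, c(2e-10, 4.5e-10, 7e-10) / 1e-9, tolerance = 0.15)
  # alpha = 1 gives a strictly one-site displacement curve (receptor kept
  # trace relative to the ligands so depletion does not bend the curve)
  tm1 <- ternary_model(6.9, 1, 8, r_tot = 1e-15, g_tot = 1e-8)
  cv1 <- predict_competition_curve(tm1, 9.5, 10^-9.5, grid)
  expect_identical(fit_competition(cv1, sites = "auto")$model, "one_site")
})

test_that("fit_ternary is the identity on noiseless curves", {
  g_ladder <- c(0, 1e-9, 1e-8, 1e-7)
  grid <- seq(-11, -3, length.out = 10)
  curves <- lapply(g_ladder, function(g) {
    predict_competition_curve(ternary_model(6.9, 10^3.3, 8, 1e-10, g),
                              9.5, 10^-9.5, grid)
  })
  fit <- fit_ternary(curves, g_ladder, 1e-10, 9.5, 10^-9.5)
  expect_false(is_fit_failure(fit))
  expect_equal(unname(fit$par), c(6.9, 3.3, 8), tolerance = 1e-3)
  expect_length(fit$warnings, 0)
})

test_that("alpha is flagged unidentifiable without a G titration", {
  grid <- seq(-10, -4, length.out = 10)
  cv <- predict_competition_curve(ternary_model(6.9, 10^3.3, 8, 1e-10, 0),
                                  9.5, 10^-9.5, grid)
  fit <- fit_ternary(list(cv), 0, 1e-10, 9.5, 10^-9.5)
  expect_false(is_fit_failure(fit))
  expect_true(any(grepl("not identifiable", fit$warnings)))
  expect_false(is.null(fit$profile_alpha))
})

test_that("free energies close the thermodynamic cycle and match pK identities", {
  expect_equal(free_energies(ternary_model(0, 1, 5, 0, 0))$dg_l_r, 0,
               tolerance = 1e-12)
  set.seed(17)
  for (i in 1:50) {
    tm <- ternary_model(runif(1, 3, 12), 10^runif(1, -2, 5),
                        runif(1, 3, 12), 1e-9, 1e-8,
                        temperature = sample(c(298.15, 310.15), 1))
    fe <- free_energies(tm)
    expect_lt(abs(fe$dg_l_r + fe$dg_g_lr - (fe$dg_g_r + fe$dg_l_rg)), 1e-9)
    expect_lt(abs((fe$dg_l_rg - fe$dg_l_r) - fe$ddg_coupling), 1e-9)
  }
})

test_that("the printed pKi pair implies a >1000-fold shift and ~5 kcal/mol", {
  # high-affinity (G-protein-bound) pKi: 7.10 at one subtype, 10.42 at the
  # other
  fold <- affinity_fold_shift(7.10, 10.42)
  expect_gt(fold, 1000)
  expect_equal(fold, 10^3.32, tolerance = 1e-12)
  for (temp in c(298.15, 310.15)) {
    ddg <- delta_delta_g(7.10, 10.42, temperature = temp)
    expect_equal(signif(abs(ddg), 1), 5)
  }
})
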