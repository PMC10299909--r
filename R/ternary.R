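# Ternary complex model: ligand (L), receptor (R) and G protein (G) in
# mass-action equilibrium forming LR, RG and LRG, with cooperativity alpha
# linking the two binding events. Includes an exact equilibrium solver,
# prediction of radioligand competition curves versus G-protein concentration,
# a global cooperativity fit, and conversion to state free energies.

#' Ternary complex model
#'
#' Equilibrium scheme `R + L <-> LR`, `R + G <-> RG`, `LR + G <-> LRG`,
#' `RG + L <-> LRG`. The agonist binds the free receptor with dissociation
#' constant `10^-p_k_l` and the G-protein-bound receptor `alpha`-fold tighter
#' (`pKi_high = p_k_l + log10(alpha)`); microscopic reversibility fixes the
#' fourth constant.
#'
#' @param p_k_l agonist affinity for the free receptor, -log10 molar
#'   (the low-affinity pKi).
#' @param alpha cooperativity: fold-increase of agonist affinity at the
#'   G-protein-bound receptor (> 0).
#' @param p_k_g G-protein affinity for the free receptor, -log10 molar.
#' @param r_tot,g_tot total receptor and G-protein concentrations, molar.
#' @param temperature kelvin (default 310.15; 298.15 selectable).
#' @return an object of class `ternary_model`.
#' @export
ternary_model <- function(p_k_l, alpha, p_k_g, r_tot, g_tot,
                          temperature = 310.15) {
  check_number(p_k_l, "p_k_l")
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(p_k_g, "p_k_g")
  check_number(r_tot, "r_tot", lower = 0)
  check_number(g_tot, "g_tot", lower = 0)
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  structure(list(p_k_l = p_k_l, alpha = alpha, p_k_g = p_k_g,
                 r_tot = r_tot, g_tot = g_tot, temperature = temperature),
            class = "ternary_model")
}

## --- core solver ----------------------------------------------------------

# Mass-action residuals for free receptor r and free G protein g (vectors over
# conditions). `ligands` is a list of lists with elements tot (vector or
# scalar), k (dissociation constant, molar) and alpha.
tc_parts <- function(r, g, g_tot, k_g, ligands) {
  sum_r <- 0; sum_g <- 0
  ls <- vector("list", length(ligands))
  for (i in seq_along(ligands)) {
    li <- ligands[[i]]
    denom <- 1 + r / li$k + li$alpha * r * g / (li$k * k_g)
    l_free <- li$tot / denom
    ls[[i]] <- l_free
    sum_r <- sum_r + (l_free / li$k) * (1 + li$alpha * g / k_g)
    sum_g <- sum_g + li$alpha * l_free / li$k
  }
  list(l_free = ls, sum_r = sum_r, sum_g = sum_g)
}

tc_residual <- function(r, g, r_tot, g_tot, k_g, ligands) {
  p <- tc_parts(r, g, g_tot, k_g, ligands)
  f1 <- r * (1 + g / k_g + p$sum_r) - r_tot
  f2 <- g * (1 + (r / k_g) * (1 + p$sum_g)) - g_tot
  cbind(f1, f2)
}

# Solve for free r and g; vectorized over conditions (length of tot vectors).
# Damped fixed point to get close, then log-space Newton with a numeric
# Jacobian, then per-element nested bisection for any stragglers.
solve_free_rg <- function(r_tot, g_tot, k_g, ligands, tol = 1e-12,
                          max_iter = 4000) {
  m <- max(vapply(ligands, function(l) length(l$tot), integer(1)), 1L)
  ligands <- lapply(ligands, function(l) { l$tot <- rep_len(l$tot, m); l })
  if (r_tot == 0) {
    return(list(r = rep(0, m), g = rep(g_tot, m), converged = TRUE))
  }
  scale_r <- r_tot
  scale_g <- max(g_tot, .Machine$double.xmin)
  rel_res <- function(r, g) {
    f <- tc_residual(r, g, r_tot, g_tot, k_g, ligands)
    pmax(abs(f[, 1]) / scale_r, abs(f[, 2]) / scale_g)
  }
  r <- rep(r_tot, m)
  g <- rep(g_tot, m)
  if (g_tot == 0) {
    # binary limit: only L/R binding remains
    for (it in seq_len(max_iter)) {
      p <- tc_parts(r, g, g_tot, k_g, ligands)
      r_new <- r_tot / (1 + p$sum_r)
      r <- sqrt(r * r_new)
      if (all(rel_res(r, g) <= tol)) break
    }
    return(list(r = r, g = g, converged = all(rel_res(r, g) <= tol)))
  }
  # damped fixed point
  for (it in seq_len(200)) {
    p <- tc_parts(r, g, g_tot, k_g, ligands)
    r_new <- r_tot / (1 + g / k_g + p$sum_r)
    g_new <- g_tot / (1 + (r / k_g) * (1 + p$sum_g))
    r <- sqrt(r * r_new)
    g <- sqrt(g * g_new)
    if (it %% 10 == 0 && all(rel_res(r, g) <= 1e-6)) break
  }
  # Newton in (log r, log g)
  res_vec <- function(u, v) tc_residual(exp(u), exp(v), r_tot, g_tot, k_g, ligands)
  u <- log(r); v <- log(g)
  for (it in seq_len(60)) {
    f <- res_vec(u, v)
    cur <- pmax(abs(f[, 1]) / scale_r, abs(f[, 2]) / scale_g)
    if (all(cur <= tol)) break
    h <- 1e-7
    fu <- (res_vec(u + h, v) - f) / h
    fv <- (res_vec(u, v + h) - f) / h
    det <- fu[, 1] * fv[, 2] - fv[, 1] * fu[, 2]
    det[det == 0] <- NA
    du <- -(f[, 1] * fv[, 2] - f[, 2] * fv[, 1]) / det
    dv <- -(fu[, 1] * f[, 2] - fu[, 2] * f[, 1]) / det
    du[!is.finite(du)] <- 0
    dv[!is.finite(dv)] <- 0
    du <- pmin(pmax(du, -4), 4)
    dv <- pmin(pmax(dv, -4), 4)
    # elementwise backtracking: halve steps that do not reduce the residual
    lam <- rep(1, m)
    for (bt in 1:30) {
      new_res <- {
        f2 <- res_vec(u + lam * du, v + lam * dv)
        pmax(abs(f2[, 1]) / scale_r, abs(f2[, 2]) / scale_g)
      }
      bad <- new_res > cur & lam > 1e-6
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    u <- u + lam * du
    v <- v + lam * dv
  }
  r <- exp(u); g <- exp(v)
  bad <- rel_res(r, g) > tol
  if (any(bad)) {
    for (i in which(bad)) {
      ligs_i <- lapply(ligands, function(l) list(tot = l$tot[i], k = l$k,
                                                 alpha = l$alpha))
      rg <- tc_bisect_one(r_tot, g_tot, k_g, ligs_i, tol)
      r[i] <- rg[1]; g[i] <- rg[2]
    }
  }
  list(r = r, g = g, converged = all(rel_res(r, g) <= tol * 100))
}

# Nested bisection for a single condition: for each trial free r, solve the
# G-conservation (monotone in g) by bisection, then bisect the R residual.
tc_bisect_one <- function(r_tot, g_tot, k_g, ligands, tol) {
  g_given_r <- function(r) {
    lo <- 0; hi <- g_tot
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      f2 <- tc_residual(r, mid, r_tot, g_tot, k_g, ligands)[, 2]
      if (f2 > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- 0; hi <- r_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    g <- g_given_r(mid)
    f1 <- tc_residual(mid, g, r_tot, g_tot, k_g, ligands)[, 1]
    if (f1 > 0) hi <- mid else lo <- mid
  }
  r <- (lo + hi) / 2
  c(r, g_given_r(r))
}

#' Solve the ternary-complex equilibrium
#'
#' Exact mass-action equilibrium of ligand, receptor and G protein. The four
#' equilibrium constants (with the alpha-linked high-affinity constants) and
#' the three conservation laws are satisfied to a relative residual of 1e-10
#' or better; the solver reduces the system to the free receptor and free
#' G-protein concentrations and refines a damped Newton iteration with a
#' bisection fallback, which brackets the unique physical root.
#'
#' @param model a [ternary_model()].
#' @param l_tot total ligand concentration(s), molar (vectorized).
#' @return a data frame with one row per `l_tot` and columns `L`, `R`, `G`,
#'   `LR`, `RG`, `LRG` (molar).
#' @export
solve_equilibrium <- function(model, l_tot) {
  check_that(inherits(model, "ternary_model"), "`model` must be a ternary_model")
  check_that(is.numeric(l_tot) && all(is.finite(l_tot)) && all(l_tot >= 0),
             "`l_tot` must be non-negative molar concentrations")
  k_l <- 10^(-model$p_k_l)
  k_g <- 10^(-model$p_k_g)
  ligs <- list(list(tot = l_tot, k = k_l, alpha = model$alpha))
  sol <- solve_free_rg(model$r_tot, model$g_tot, k_g, ligs)
  if (!sol$converged) {
    res <- tc_residual(sol$r, sol$g, model$r_tot, model$g_tot, k_g,
                       lapply(ligs, function(l) {
                         l$tot <- rep_len(l$tot, length(sol$r)); l
                       }))
    stop(sprintf("equilibrium solver did not converge (max residual %.3g)",
                 max(abs(res))))
  }
  r <- sol$r; g <- sol$g
  denom <- 1 + r / k_l + model$alpha * r * g / (k_l * k_g)
  l <- rep_len(l_tot, length(r)) / denom
  data.frame(L = l, R = r, G = g,
             LR = l * r / k_l,
             RG = r * g / k_g,
             LRG = model$alpha * l * r * g / (k_l * k_g))
}

#' Predict a radioligand competition curve from the ternary model
#'
#' Computes, at each competitor concentration, the equilibrium fraction of an
#' antagonist radioligand that remains receptor-bound when the competitor and
#' G protein are present. The radioligand is treated as G-insensitive by
#' default (`radioligand_alpha = 1`: equal affinity for R and RG), as for an
#' inverse/neutral antagonist. Output is compatible with [fit_competition()].
#'
#' @param model a [ternary_model()] describing the competitor and G protein.
#' @param radioligand_p_kd radioligand pKd, -log10 molar.
#' @param radioligand_conc radioligand concentration, molar.
#' @param competitor_grid competitor concentrations, log10 molar.
#' @param radioligand_alpha cooperativity of the radioligand (default 1).
#' @param normalize divide by the zero-competitor bound signal (default TRUE).
#' @return a `binding_curve_set` with columns `series`, `log_conc`, `signal`,
#'   `replicate`; `signal` is bound radioligand (fraction of the
#'   zero-competitor level if normalized, else molar).
#' @export
predict_competition_curve <- function(model, radioligand_p_kd,
                                      radioligand_conc, competitor_grid,
                                      radioligand_alpha = 1,
                                      normalize = TRUE) {
  check_that(inherits(model, "ternary_model"), "`model` must be a ternary_model")
  check_number(radioligand_p_kd, "radioligand_p_kd")
  check_number(radioligand_conc, "radioligand_conc", lower = 0, strict_lower = TRUE)
  check_that(is.numeric(competitor_grid) && all(is.finite(competitor_grid)),
             "`competitor_grid` must be finite log10 molar values")
  bound <- tc_bound_radioligand(model, radioligand_p_kd, radioligand_conc,
                                c(0, 10^competitor_grid), radioligand_alpha)
  signal <- bound[-1]
  if (normalize) signal <- signal / bound[1]
  structure(
    data.frame(series = "competition", log_conc = competitor_grid,
               signal = signal, replicate = 1L, stringsAsFactors = FALSE),
    ground_truth = model,
    class = c("binding_curve_set", "data.frame")
  )
}

# Bound radioligand (NR + NRG, molar) at each competitor total (molar vector).
tc_bound_radioligand <- function(model, radioligand_p_kd, radioligand_conc,
                                 competitor_tot, radioligand_alpha = 1) {
  k_l <- 10^(-model$p_k_l)
  k_g <- 10^(-model$p_k_g)
  k_n <- 10^(-radioligand_p_kd)
  m <- length(competitor_tot)
  ligs <- list(
    list(tot = competitor_tot, k = k_l, alpha = model$alpha),
    list(tot = rep(radioligand_conc, m), k = k_n, alpha = radioligand_alpha)
  )
  sol <- solve_free_rg(model$r_tot, model$g_tot, k_g, ligs)
  r <- sol$r; g <- sol$g
  n_free <- radioligand_conc /
    (1 + r / k_n + radioligand_alpha * r * g / (k_n * k_g))
  n_free * (r / k_n) * (1 + radioligand_alpha * g / k_g)
}

#' Globally fit the ternary complex model across a G-protein titration
#'
#' Fits the agonist's free-receptor affinity `p_k_l`, the cooperativity
#' `log10(alpha)` and the G-protein affinity `p_k_g` to a set of radioligand
#' competition curves collected at known total G-protein concentrations, by
#' least squares on predicted versus observed displacement. A global signal
#' scale (profiled analytically) maps the predicted bound fraction onto the
#' observed signal.
#'
#' @param curves list of data frames with columns `log_conc` (competitor,
#'   log10 molar) and `signal`.
#' @param g_tot numeric vector of total G-protein concentrations (molar), one
#'   per curve; at least two distinct values (one near zero) are needed to
#'   identify all parameters.
#' @param r_tot total receptor concentration, molar.
#' @param radioligand_p_kd,radioligand_conc radioligand pKd (-log10 molar)
#'   and concentration (molar).
#' @param temperature kelvin, stored in the returned model.
#' @return a `ternary_fit` with the fitted [ternary_model()] (at `g_tot` of
#'   the last curve), `par`/`se` on the log scale (`p_k_l`, `log_alpha`,
#'   `p_k_g`), the signal `scale`, `rss`, `aicc` and `warnings` (including an
#'   unidentifiability warning with profile-likelihood bounds on
#'   `log10(alpha)` when no curve approaches G saturation) — or a fit-failure
#'   object.
#' @export
fit_ternary <- function(curves, g_tot, r_tot, radioligand_p_kd,
                        radioligand_conc, temperature = 310.15) {
  check_that(is.list(curves) && length(curves) >= 1 &&
               all(vapply(curves, function(d) {
                 is.data.frame(d) && all(c("log_conc", "signal") %in% names(d))
               }, logical(1))),
             "`curves` must be a list of data frames with log_conc and signal")
  check_that(is.numeric(g_tot) && length(g_tot) == length(curves) &&
               all(is.finite(g_tot)) && all(g_tot >= 0),
             "`g_tot` must be one non-negative molar value per curve")
  check_number(r_tot, "r_tot", lower = 0, strict_lower = TRUE)
  check_number(radioligand_p_kd, "radioligand_p_kd")
  check_number(radioligand_conc, "radioligand_conc", lower = 0, strict_lower = TRUE)

  y <- unlist(lapply(curves, function(d) d$signal), use.names = FALSE)
  predict_all <- function(p_k_l, log_alpha, p_k_g) {
    unlist(lapply(seq_along(curves), function(i) {
      mod <- ternary_model(p_k_l, 10^log_alpha, p_k_g, r_tot, g_tot[i],
                           temperature)
      b <- tc_bound_radioligand(mod, radioligand_p_kd, radioligand_conc,
                                c(0, 10^curves[[i]]$log_conc))
      b[-1] / b[1]
    }), use.names = FALSE)
  }
  resid_fn <- function(par) {
    b <- predict_all(par[1], par[2], par[3])
    s <- sum(b * y) / sum(b * b)          # profiled global scale
    s * b - y
  }
  all_logc <- unlist(lapply(curves, function(d) d$log_conc))
  pkl0 <- -stats::median(all_logc)
  starts <- list()
  for (la0 in c(1, 3)) for (pkg0 in c(7, 9)) {
    starts[[length(starts) + 1]] <- c(pkl0, la0, pkg0)
  }
  fit <- least_squares(resid_fn, starts,
                       lower = c(2, -2, 2), upper = c(14, 8, 14),
                       par_names = c("p_k_l", "log_alpha", "p_k_g"),
                       factr = 1e7)
  if (is_fit_failure(fit)) return(fit)
  b <- predict_all(fit$par[1], fit$par[2], fit$par[3])
  scale <- sum(b * y) / sum(b * b)

  warnings <- character(0)
  profile <- NULL
  alpha_se <- fit$se[["log_alpha"]]
  no_titration <- length(unique(g_tot)) < 2 ||
    max(g_tot) < 0.1 * 10^(-fit$par[["p_k_g"]])
  if (no_titration || fit$singular ||
      (is.finite(alpha_se) && alpha_se > 1.5) || is.na(alpha_se)) {
    grid <- seq(-2, 8, by = 0.5)
    prss <- vapply(grid, function(la) {
      sub <- function(par) resid_fn(c(par[1], la, par[2]))
      f <- least_squares(sub, list(fit$par[c(1, 3)]),
                         lower = c(2, 2), upper = c(14, 14),
                         par_names = c("p_k_l", "p_k_g"))
      if (is_fit_failure(f)) Inf else f$rss
    }, numeric(1))
    # profile-likelihood band: RSS within a chi-square(1) increment
    n <- length(y)
    cutoff <- min(prss) * (1 + stats::qchisq(0.95, 1) / max(1, n - 3))
    inside <- grid[prss <= cutoff]
    profile <- list(grid = grid, rss = prss,
                    lower = min(inside), upper = max(inside))
    if (no_titration || diff(range(c(profile$lower, profile$upper))) >= 6) {
      warnings <- c(warnings, sprintf(
        "cooperativity alpha not identifiable from these curves; profile-likelihood bounds on log10(alpha): [%.1f, %.1f]",
        profile$lower, profile$upper))
    }
  }
  model <- ternary_model(fit$par[["p_k_l"]], 10^fit$par[["log_alpha"]],
                         fit$par[["p_k_g"]], r_tot, g_tot[length(g_tot)],
                         temperature)
  structure(c(fit, list(model = model, scale = scale, warnings = warnings,
                        profile_alpha = profile)),
            class = "ternary_fit")
}

#' @export
print.ternary_fit <- function(x, ...) {
  cat("Ternary complex model fit\n")
  cat(sprintf("  pK_L (low-affinity pKi)  = %s +/- %s\n",
              fmt_num(x$par[["p_k_l"]]), fmt_num(x$se[["p_k_l"]])))
  cat(sprintf("  log10 alpha              = %s +/- %s\n",
              fmt_num(x$par[["log_alpha"]]), fmt_num(x$se[["log_alpha"]])))
  cat(sprintf("  pK_G                     = %s +/- %s\n",
              fmt_num(x$par[["p_k_g"]]), fmt_num(x$se[["p_k_g"]])))
  cat(sprintf("  implied high-affinity pKi = %s\n",
              fmt_num(x$par[["p_k_l"]] + x$par[["log_alpha"]])))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Binding free energies of the ternary-complex states
#'
#' Converts the model's association constants (`10^pK` per molar, 1 M
#' standard state) to binding free energies `dG = -RT ln(10) pK` in kcal/mol
#' for the four edges of the thermodynamic cycle, plus the coupling energy
#' `ddG = -RT ln(alpha)` shared by both faces of the cycle. The cycle closes
#' by construction: `dG(L,R) + dG(G,LR) = dG(G,R) + dG(L,RG)`.
#'
#' @param model a [ternary_model()].
#' @param temperature kelvin; defaults to the model's temperature.
#' @return a `state_free_energies` list with `dg_l_r`, `dg_l_rg`, `dg_g_r`,
#'   `dg_g_lr`, `ddg_coupling` (kcal/mol) and `temperature`.
#' @export
free_energies <- function(model, temperature = model$temperature) {
  check_that(inherits(model, "ternary_model"), "`model` must be a ternary_model")
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  rt <- R_KCAL * temperature
  log_alpha <- log10(model$alpha)
  dg <- function(p_k) -rt * log(10) * p_k
  out <- list(
    dg_l_r = dg(model$p_k_l),
    dg_l_rg = dg(model$p_k_l + log_alpha),
    dg_g_r = dg(model$p_k_g),
    dg_g_lr = dg(model$p_k_g + log_alpha),
    ddg_coupling = -rt * log(model$alpha),
    temperature = temperature
  )
  structure(out, class = "state_free_energies")
}

#' @export
print.state_free_energies <- function(x, ...) {
  cat(sprintf("Binding free energies (kcal/mol, %g K, 1 M standard state)\n",
              x$temperature))
  cat(sprintf("  L + R   -> LR  : %8.3f\n", x$dg_l_r))
  cat(sprintf("  L + RG  -> LRG : %8.3f\n", x$dg_l_rg))
  cat(sprintf("  G + R   -> RG  : %8.3f\n", x$dg_g_r))
  cat(sprintf("  G + LR  -> LRG : %8.3f\n", x$dg_g_lr))
  cat(sprintf("  coupling ddG   : %8.3f\n", x$ddg_coupling))
  invisible(x)
}

#' Free-energy difference between two affinities
#'
#' `ddG = -RT ln(10) (p_k_b - p_k_a)` in kcal/mol: the difference in binding
#' free energy between two measured pK values (e.g. the same agonist at two
#' receptor-G-protein complexes).
#'
#' @param p_k_a,p_k_b the two affinities, -log10 molar.
#' @param temperature kelvin.
#' @return kcal/mol; negative when `p_k_b` binds tighter.
#' @export
delta_delta_g <- function(p_k_a, p_k_b, temperature = 310.15) {
  check_number(p_k_a, "p_k_a")
  check_number(p_k_b, "p_k_b")
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  -R_KCAL * temperature * log(10) * (p_k_b - p_k_a)
}
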