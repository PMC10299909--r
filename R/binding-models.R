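# Radioligand binding models: one-site saturation, one/two-site competition,
# and the Cheng-Prusoff IC50 -> Ki conversion.

#' One-site saturation binding model
#'
#' `Y = Bmax [A] / ([A] + K_A) + NS [A]`, where `[A]` is the free radioligand
#' concentration, `K_A = 10^-p_ka` its equilibrium dissociation constant and
#' `NS` a linear nonspecific component shared between total and nonspecific
#' series.
#'
#' @param b_max maximal specific binding (signal units, > 0).
#' @param p_ka radioligand pKd, -log10 molar.
#' @param ns_slope nonspecific slope, signal per molar (>= 0).
#' @return an object of class `saturation_model`.
#' @export
saturation_model <- function(b_max, p_ka, ns_slope = 0) {
  check_number(b_max, "b_max", lower = 0, strict_lower = TRUE)
  check_number(p_ka, "p_ka")
  check_number(ns_slope, "ns_slope", lower = 0)
  structure(list(b_max = b_max, p_ka = p_ka, ns_slope = ns_slope),
            class = "saturation_model")
}

#' Evaluate the one-site saturation model
#'
#' @param model a [saturation_model()].
#' @param conc radioligand concentration(s) in molar (>= 0).
#' @return predicted total binding signal.
#' @export
eval_saturation <- function(model, conc) {
  check_that(inherits(model, "saturation_model"), "`model` must be a saturation_model")
  check_that(is.numeric(conc) && all(is.finite(conc)) && all(conc >= 0),
             "`conc` must be non-negative molar concentrations")
  ka <- 10^(-model$p_ka)
  model$b_max * conc / (conc + ka) + model$ns_slope * conc
}

#' Globally fit the one-site saturation model to total and nonspecific binding
#'
#' Total and nonspecific series are fitted jointly by least squares with the
#' nonspecific slope `NS` shared, as is conventional for whole-cell or
#' nanodisc saturation assays.
#'
#' @param total a `binding_curve_set` (or data frame with `log_conc`, `signal`)
#'   of total binding; if it carries a `series` column with both series and
#'   `nonspecific` is `NULL`, the split is taken from that column.
#' @param nonspecific matching nonspecific-binding table, or `NULL`.
#' @return a `saturation_fit`: parameters (`b_max`, `p_ka`, `ns_slope`),
#'   standard errors, residual sum of squares and AICc — or a fit-failure
#'   object (see [is_fit_failure()]).
#' @export
fit_saturation <- function(total, nonspecific = NULL) {
  if (is.null(nonspecific) && !is.null(total$series)) {
    nonspecific <- total[total$series == "nonspecific", , drop = FALSE]
    total <- total[total$series == "total", , drop = FALSE]
  }
  check_that(is.data.frame(total) && nrow(total) > 0 &&
               all(c("log_conc", "signal") %in% names(total)),
             "`total` must have columns log_conc and signal")
  check_that(is.data.frame(nonspecific) && nrow(nonspecific) > 0 &&
               all(c("log_conc", "signal") %in% names(nonspecific)),
             "`nonspecific` must have columns log_conc and signal")
  check_that(length(unique(total$log_conc)) >= 4,
             "need >= 4 distinct radioligand concentrations")
  if (diff(range(c(total$signal, nonspecific$signal))) <= 0) {
    return(fit_failure("zero dynamic range: signals are constant"))
  }
  conc_t <- 10^total$log_conc
  conc_n <- 10^nonspecific$log_conc
  y_t <- total$signal
  y_n <- nonspecific$signal
  # par = (b_max, p_ka, ns_slope)
  resid_fn <- function(par) {
    ka <- 10^(-par[2])
    c(par[1] * conc_t / (conc_t + ka) + par[3] * conc_t - y_t,
      par[3] * conc_n - y_n)
  }
  ns0 <- max(0, stats::coef(stats::lm(y_n ~ 0 + conc_n))[[1]])
  bmax0 <- max(y_t) - ns0 * max(conc_t)
  if (!is.finite(bmax0) || bmax0 <= 0) bmax0 <- max(y_t)
  pka_starts <- logc_starts(range(-total$log_conc), 5)
  starts <- lapply(pka_starts, function(p) c(bmax0, p, ns0))
  fit <- least_squares(resid_fn, starts,
                       lower = c(1e-12, min(-total$log_conc) - 3, 0),
                       upper = c(Inf, max(-total$log_conc) + 3, Inf),
                       par_names = c("b_max", "p_ka", "ns_slope"))
  if (is_fit_failure(fit)) return(fit)
  if (fit$singular) {
    return(fit_failure("saturation parameters not identifiable",
                       diagnostics = fit))
  }
  structure(c(fit, list(model = saturation_model(fit$par[["b_max"]],
                                                 fit$par[["p_ka"]],
                                                 fit$par[["ns_slope"]]))),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("One-site saturation fit\n")
  cat(sprintf("  Bmax  = %s +/- %s\n", fmt_num(x$par[["b_max"]]), fmt_num(x$se[["b_max"]])))
  cat(sprintf("  pKd   = %s +/- %s\n", fmt_num(x$par[["p_ka"]]), fmt_num(x$se[["p_ka"]])))
  cat(sprintf("  NS    = %s +/- %s\n", fmt_num(x$par[["ns_slope"]]), fmt_num(x$se[["ns_slope"]])))
  cat(sprintf("  RSS %s, AICc %s\n", fmt_num(x$rss), fmt_num(x$aicc)))
  invisible(x)
}

#' Two-site competition binding model
#'
#' `Y = (Top - Bottom) (f1 / (1 + 10^(logB - logIC50_1)) +
#' (1 - f1) / (1 + 10^(logB - logIC50_2))) + Bottom`, with site 1 the
#' high-affinity site (`log_ic50_high <= log_ic50_low`). Setting
#' `fraction_high = 1` gives the one-site inhibition mass-action curve.
#'
#' @param top,bottom maximal and minimal asymptotes (signal units).
#' @param log_ic50_high,log_ic50_low log10 molar IC50s of the high- and
#'   low-affinity sites.
#' @param fraction_high proportion of high-affinity sites in `[0, 1]`.
#' @return an object of class `two_site_model`.
#' @export
two_site_model <- function(top, bottom, log_ic50_high, log_ic50_low,
                           fraction_high) {
  check_number(top, "top")
  check_number(bottom, "bottom")
  check_that(top >= bottom, "`top` must be >= `bottom`")
  check_number(log_ic50_high, "log_ic50_high")
  check_number(log_ic50_low, "log_ic50_low")
  check_that(log_ic50_high <= log_ic50_low,
             "`log_ic50_high` must be <= `log_ic50_low`")
  check_number(fraction_high, "fraction_high", lower = 0, upper = 1)
  structure(list(top = top, bottom = bottom, log_ic50_high = log_ic50_high,
                 log_ic50_low = log_ic50_low, fraction_high = fraction_high),
            class = "two_site_model")
}

#' Evaluate the two-site competition model
#'
#' @param model a [two_site_model()].
#' @param log_b competitor concentration(s), log10 molar.
#' @return predicted binding signal.
#' @export
eval_two_site <- function(model, log_b) {
  check_that(inherits(model, "two_site_model"), "`model` must be a two_site_model")
  check_that(is.numeric(log_b), "`log_b` must be numeric")
  f1 <- model$fraction_high
  span <- model$top - model$bottom
  span * (f1 / (1 + 10^(log_b - model$log_ic50_high)) +
            (1 - f1) / (1 + 10^(log_b - model$log_ic50_low))) + model$bottom
}

# Numerical-precision RSS floor for model selection between nested curve
# models fitted to the same data.
selection_floor <- function(y) length(y) * (1e-7 * diff(range(y)))^2

# Internal: fit the one-site inhibition curve (top, bottom, log_ic50).
fit_competition_one <- function(log_b, y) {
  resid_fn <- function(par) {
    (par[1] - par[2]) / (1 + 10^(log_b - par[3])) + par[2] - y
  }
  starts <- lapply(logc_starts(range(log_b), 5),
                   function(l) c(max(y), min(y), l))
  least_squares(resid_fn, starts,
                lower = c(-Inf, -Inf, min(log_b) - 4),
                upper = c(Inf, Inf, max(log_b) + 4),
                par_names = c("top", "bottom", "log_ic50"),
                rss_floor = selection_floor(y))
}

# Internal: fit the two-site curve with fraction_high in [0,1]; sites are
# relabeled after the fit so that site 1 is the high-affinity one.
fit_competition_two <- function(log_b, y) {
  resid_fn <- function(par) {
    (par[1] - par[2]) * (par[5] / (1 + 10^(log_b - par[3])) +
                           (1 - par[5]) / (1 + 10^(log_b - par[4]))) +
      par[2] - y
  }
  ls <- logc_starts(range(log_b), 5)
  starts <- list()
  for (i in seq_along(ls)) for (j in seq_along(ls)) {
    if (j > i) starts[[length(starts) + 1]] <- c(max(y), min(y), ls[i], ls[j], 0.5)
  }
  fit <- least_squares(resid_fn, starts,
                       lower = c(-Inf, -Inf, min(log_b) - 4, min(log_b) - 4, 0),
                       upper = c(Inf, Inf, max(log_b) + 4, max(log_b) + 4, 1),
                       par_names = c("top", "bottom", "log_ic50_high",
                                     "log_ic50_low", "fraction_high"),
                       rss_floor = selection_floor(y))
  if (is_fit_failure(fit)) return(fit)
  # relabel: Eq. is symmetric under (site1 <-> site2, f1 <-> 1-f1)
  if (fit$par[["log_ic50_high"]] > fit$par[["log_ic50_low"]]) {
    fit$par[c("log_ic50_high", "log_ic50_low")] <-
      fit$par[c("log_ic50_low", "log_ic50_high")]
    fit$se[c("log_ic50_high", "log_ic50_low")] <-
      fit$se[c("log_ic50_low", "log_ic50_high")]
    fit$par[["fraction_high"]] <- 1 - fit$par[["fraction_high"]]
  }
  fit
}

#' Fit one- and two-site competition binding curves
#'
#' Bounded multi-start least squares for the inhibition mass-action curve.
#' In `"auto"` mode both the one- and the two-site model are fitted and the
#' one with the lower AICc is selected (both fits are kept in the result).
#' IC50s are converted to pKi via [cheng_prusoff()] when the radioligand
#' concentration and pKd are supplied.
#'
#' @param data a `binding_curve_set` or data frame with columns `log_conc`
#'   (competitor, log10 molar) and `signal`.
#' @param sites `"auto"`, `"one"` or `"two"`.
#' @param radioligand_conc radioligand concentration in molar (optional).
#' @param radioligand_p_kd radioligand pKd, -log10 molar (optional).
#' @return a `competition_fit` with elements `model` (`"one_site"` or
#'   `"two_site"`), `par`, `se`, `rss`, `aicc`, `p_ki_high`/`p_ki_low` (when
#'   convertible), `warnings`, and `candidates` (both fits in auto mode) — or
#'   a fit-failure object.
#' @export
fit_competition <- function(data, sites = c("auto", "one", "two"),
                            radioligand_conc = NULL, radioligand_p_kd = NULL) {
  sites <- match.arg(sites)
  check_that(is.data.frame(data) && all(c("log_conc", "signal") %in% names(data)),
             "`data` must have columns log_conc and signal")
  check_that(length(unique(data$log_conc)) >= 6,
             "need >= 6 distinct competitor concentrations")
  log_b <- data$log_conc
  y <- data$signal
  if (diff(range(y)) <= 0) return(fit_failure("zero dynamic range"))

  fits <- list()
  if (sites %in% c("auto", "one")) fits$one_site <- fit_competition_one(log_b, y)
  if (sites %in% c("auto", "two")) fits$two_site <- fit_competition_two(log_b, y)
  ok <- !vapply(fits, is_fit_failure, logical(1))
  if (!any(ok)) return(fit_failure("no competition model converged"))
  fits <- fits[ok]
  pick <- names(fits)[which.min(vapply(fits, function(f) f$aicc, numeric(1)))]
  fit <- fits[[pick]]

  warnings <- character(0)
  if (pick == "two_site") {
    f1 <- fit$par[["fraction_high"]]
    if (f1 <= 1e-6 || f1 >= 1 - 1e-6) {
      warnings <- c(warnings,
                    "fraction_high pinned at a bound; two sites not resolved")
    }
  }
  out <- c(fit, list(model = pick, warnings = warnings, candidates = fits))
  if (!is.null(radioligand_conc) && !is.null(radioligand_p_kd)) {
    kd <- 10^(-radioligand_p_kd)
    if (pick == "two_site") {
      out$p_ki_high <- cheng_prusoff(10^fit$par[["log_ic50_high"]],
                                     radioligand_conc, kd)
      out$p_ki_low <- cheng_prusoff(10^fit$par[["log_ic50_low"]],
                                    radioligand_conc, kd)
    } else {
      out$p_ki_high <- cheng_prusoff(10^fit$par[["log_ic50"]],
                                     radioligand_conc, kd)
      out$p_ki_low <- out$p_ki_high
    }
  }
  structure(out, class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Competition binding fit (%s)\n", x$model))
  for (nm in names(x$par)) {
    cat(sprintf("  %-14s = %s +/- %s\n", nm, fmt_num(x$par[[nm]]), fmt_num(x$se[[nm]])))
  }
  if (!is.null(x$p_ki_high)) {
    cat(sprintf("  pKi high %s, pKi low %s\n", fmt_num(x$p_ki_high), fmt_num(x$p_ki_low)))
  }
  cat(sprintf("  RSS %s, AICc %s\n", fmt_num(x$rss), fmt_num(x$aicc)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to pKi
#'
#' `Ki = IC50 / (1 + [A*]/Kd)` for a competitor displacing a radioligand
#' present at concentration `[A*]` with dissociation constant `Kd`.
#'
#' @param ic50 half-maximal inhibitory concentration, molar (> 0).
#' @param radioligand_conc radioligand concentration, molar (> 0).
#' @param radioligand_kd radioligand dissociation constant, molar (> 0).
#' @return the competitor pKi (-log10 molar). The result is unit-invariant as
#'   long as the three molar inputs share a unit.
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_kd) {
  check_number(ic50, "ic50", lower = 0, strict_lower = TRUE)
  check_number(radioligand_conc, "radioligand_conc", lower = 0, strict_lower = TRUE)
  check_number(radioligand_kd, "radioligand_kd", lower = 0, strict_lower = TRUE)
  ki <- ic50 / (1 + radioligand_conc / radioligand_kd)
  -log10(ki)
}

#' Affinity fold-shift between two pK values
#'
#' Converts a pair of -log10 molar affinities into the fold-ratio of the
#' corresponding association constants; e.g. the fold-increase in agonist
#' affinity when the receptor is G-protein-bound, or the fold-difference of
#' one receptor subtype over another.
#'
#' @param p_k_ref,p_k_test reference and test affinities, -log10 molar.
#' @return `10^(p_k_test - p_k_ref)`, the fold-change in affinity.
#' @export
affinity_fold_shift <- function(p_k_ref, p_k_test) {
  check_number(p_k_ref, "p_k_ref")
  check_number(p_k_test, "p_k_test")
  10^(p_k_test - p_k_ref)
}
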