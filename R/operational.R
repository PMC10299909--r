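# Three-parameter logistic potency fits and the Black-Leff operational model
# of agonism, including expression-corrected efficacy (tau_C).

#' Operational model of agonism
#'
#' Response of a system with maximal capacity `Em` and basal output `Basal`
#' to an agonist with functional dissociation constant `K_A = 10^log_ka` and
#' efficacy index `tau = 10^log_tau` (tau = R_T / K_E: total receptor density
#' over the agonist-receptor complex concentration producing half of Em):
#'
#' `Y = Basal + (Em - Basal) / (1 + (10^logK_A + 10^logA) / (10^logtau 10^logA))`
#'
#' The transducer slope is fixed at 1.
#'
#' @param basal basal response (response units).
#' @param em maximal possible system response (must exceed `basal`).
#' @param log_ka log10 molar agonist functional dissociation constant.
#' @param log_tau log10 efficacy index.
#' @return an object of class `operational_model`.
#' @export
operational_model <- function(basal, em, log_ka, log_tau) {
  check_number(basal, "basal")
  check_number(em, "em")
  check_that(em > basal, "`em` must be greater than `basal`")
  check_number(log_ka, "log_ka")
  check_number(log_tau, "log_tau")
  structure(list(basal = basal, em = em, log_ka = log_ka, log_tau = log_tau),
            class = "operational_model")
}

#' Evaluate the operational model
#'
#' @param model an [operational_model()].
#' @param log_a agonist concentration(s), log10 molar.
#' @return predicted response. Monotone non-decreasing in both `log_a` and
#'   the model's `log_tau`; the high-concentration plateau is
#'   `Basal + (Em - Basal) tau / (1 + tau)`.
#' @export
eval_operational <- function(model, log_a) {
  check_that(inherits(model, "operational_model"),
             "`model` must be an operational_model")
  check_that(is.numeric(log_a), "`log_a` must be numeric")
  op_response(log_a, model$basal, model$em, model$log_ka, model$log_tau)
}

# vectorized core, used by the fitters
op_response <- function(log_a, basal, em, log_ka, log_tau) {
  basal + (em - basal) / (1 + (10^log_ka + 10^log_a) / (10^log_tau * 10^log_a))
}

#' Fit a three-parameter logistic concentration-response curve
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^(logEC50 - log[A]))` with Hill
#' slope fixed at 1; reports potency as pEC50 = -logEC50.
#'
#' @param data a `dose_response_set` or data frame with columns `log_conc`
#'   (log10 molar) and `response`.
#' @return a `logistic_fit` with `par` (`top`, `bottom`, `log_ec50`), `se`,
#'   `p_ec50`, `rss`, `aicc` — or a fit-failure object.
#' @export
fit_logistic <- function(data) {
  check_that(is.data.frame(data) && all(c("log_conc", "response") %in% names(data)),
             "`data` must have columns log_conc and response")
  check_that(length(unique(data$log_conc)) >= 5,
             "need >= 5 distinct concentrations")
  log_a <- data$log_conc
  y <- data$response
  if (diff(range(y)) <= 0) return(fit_failure("zero dynamic range: flat data"))
  resid_fn <- function(par) {
    par[2] + (par[1] - par[2]) / (1 + 10^(par[3] - log_a)) - y
  }
  starts <- lapply(logc_starts(range(log_a), 5),
                   function(l) c(max(y), min(y), l))
  fit <- least_squares(resid_fn, starts,
                       lower = c(-Inf, -Inf, min(log_a) - 4),
                       upper = c(Inf, Inf, max(log_a) + 4),
                       par_names = c("top", "bottom", "log_ec50"))
  if (is_fit_failure(fit)) return(fit)
  if (fit$singular) {
    return(fit_failure("logistic parameters not identifiable", diagnostics = fit))
  }
  fit$p_ec50 <- -fit$par[["log_ec50"]]
  structure(fit, class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Three-parameter logistic fit (Hill slope = 1)\n")
  cat(sprintf("  Top %s, Bottom %s, pEC50 %s +/- %s\n",
              fmt_num(x$par[["top"]]), fmt_num(x$par[["bottom"]]),
              fmt_num(x$p_ec50), fmt_num(x$se[["log_ec50"]])))
  invisible(x)
}

#' Fit the operational model of agonism
#'
#' Least-squares fit of the operational model to one curve or to a panel of
#' ligands measured in the same cells/assay. With a panel, `Em` and `Basal`
#' are global parameters shared across ligands while `logK_A` and `logtau`
#' are per-ligand, matching the convention of constraining the system
#' parameters per cell line. For high-efficacy agonists `logK_A` is poorly
#' identified from functional data alone and should be fixed to the
#' binding-derived pKi via `log_ka_fixed`.
#'
#' @param data a `dose_response_set` or data frame with columns `log_conc`,
#'   `response` and (for panels) `ligand`.
#' @param log_ka_fixed `NULL` (fit logK_A freely), a single value, or a named
#'   vector keyed by ligand. Values are log10 molar (i.e. `-pKi`).
#' @param shared_em_basal share `Em`/`Basal` across ligands (default `TRUE`
#'   when several ligands are present).
#' @return an `operational_fit` with global `basal`/`em` (+SE), a per-ligand
#'   table `ligands` (`log_ka`, `log_tau`, SEs, whether K_A was fixed),
#'   `warnings`, `rss`, `aicc` — or a fit-failure object. `Basal` is
#'   constrained non-negative.
#' @export
fit_operational <- function(data, log_ka_fixed = NULL, shared_em_basal = TRUE) {
  check_that(is.data.frame(data) && all(c("log_conc", "response") %in% names(data)),
             "`data` must have columns log_conc and response")
  if (is.null(data$ligand)) data$ligand <- "ligand"
  ligands <- unique(data$ligand)
  if (!shared_em_basal && length(ligands) > 1) {
    fits <- lapply(ligands, function(l) {
      fit_operational(data[data$ligand == l, , drop = FALSE],
                      log_ka_fixed = ka_for(log_ka_fixed, l))
    })
    names(fits) <- ligands
    return(structure(list(per_ligand = fits), class = "operational_fit_list"))
  }

  y <- data$response
  if (diff(range(y)) <= 0) return(fit_failure("zero dynamic range: flat data"))
  nl <- length(ligands)
  ka_fix <- vapply(ligands, function(l) {
    v <- ka_for(log_ka_fixed, l)
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  free_ka <- is.na(ka_fix)

  # parameter vector: basal, span (= em - basal), then per ligand
  # [log_ka (if free)], log_tau
  par_names <- c("basal", "span")
  for (i in seq_len(nl)) {
    if (free_ka[i]) par_names <- c(par_names, paste0("log_ka.", ligands[i]))
    par_names <- c(par_names, paste0("log_tau.", ligands[i]))
  }
  lig_index <- match(data$ligand, ligands)
  log_a <- data$log_conc

  unpack <- function(par) {
    basal <- par[1]; em <- par[1] + par[2]
    kas <- numeric(nl); taus <- numeric(nl)
    j <- 3
    for (i in seq_len(nl)) {
      if (free_ka[i]) { kas[i] <- par[j]; j <- j + 1 } else kas[i] <- ka_fix[i]
      taus[i] <- par[j]; j <- j + 1
    }
    list(basal = basal, em = em, log_ka = kas, log_tau = taus)
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    op_response(log_a, p$basal, p$em, p$log_ka[lig_index],
                p$log_tau[lig_index]) - y
  }

  rng <- range(log_a)
  mk_start <- function(ka0, tau0) {
    p <- c(max(0, min(y)), max(y) - max(0, min(y)))
    for (i in seq_len(nl)) {
      if (free_ka[i]) p <- c(p, ka0)
      p <- c(p, tau0)
    }
    p
  }
  starts <- list()
  for (ka0 in logc_starts(rng, 3)) for (tau0 in c(-0.5, 0, 1)) {
    starts[[length(starts) + 1]] <- mk_start(ka0, tau0)
  }
  lower <- c(0, 1e-9)
  upper <- c(Inf, Inf)
  for (i in seq_len(nl)) {
    if (free_ka[i]) { lower <- c(lower, rng[1] - 6); upper <- c(upper, rng[2] + 6) }
    lower <- c(lower, -6); upper <- c(upper, 6)
  }
  fit <- least_squares(resid_fn, starts, lower, upper, par_names, factr = 10)
  if (is_fit_failure(fit)) return(fit)

  warnings <- character(0)
  # unidentifiable joint K_A/tau fit: near-perfect parameter correlation
  if (!is.null(fit$cov) && !fit$singular) {
    cor_mat <- stats::cov2cor(fit$cov)
    rownames(cor_mat) <- colnames(cor_mat) <- par_names
    for (i in seq_len(nl)) {
      if (free_ka[i]) {
        r <- cor_mat[paste0("log_ka.", ligands[i]), paste0("log_tau.", ligands[i])]
        if (is.finite(r) && abs(r) > 0.999) {
          warnings <- c(warnings, sprintf(
            "logK_A and logtau nearly unidentifiable for '%s' (|cor| = %.4f); consider fixing K_A",
            ligands[i], abs(r)))
        }
      }
    }
  } else if (fit$singular) {
    warnings <- c(warnings, "singular information matrix; SEs unavailable")
  }

  p <- unpack(fit$par)
  se_em <- if (!is.null(fit$cov) && !fit$singular) {
    sqrt(fit$cov[1, 1] + fit$cov[2, 2] + 2 * fit$cov[1, 2])
  } else NA_real_
  lig_tab <- data.frame(
    ligand = ligands,
    log_ka = p$log_ka,
    log_ka_se = vapply(seq_len(nl), function(i) {
      if (free_ka[i]) fit$se[[paste0("log_ka.", ligands[i])]] else 0
    }, numeric(1)),
    log_ka_fixed = !free_ka,
    log_tau = p$log_tau,
    log_tau_se = vapply(seq_len(nl), function(i) {
      fit$se[[paste0("log_tau.", ligands[i])]]
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(basal = p$basal, basal_se = fit$se[["basal"]],
                 em = p$em, em_se = se_em,
                 ligands = lig_tab, warnings = warnings,
                 par = fit$par, se = fit$se, cov = fit$cov,
                 rss = fit$rss, n = fit$n, aicc = fit$aicc),
            class = "operational_fit")
}

ka_for <- function(log_ka_fixed, ligand) {
  if (is.null(log_ka_fixed)) return(NULL)
  if (length(log_ka_fixed) == 1 && is.null(names(log_ka_fixed))) {
    return(as.numeric(log_ka_fixed))
  }
  if (ligand %in% names(log_ka_fixed)) return(as.numeric(log_ka_fixed[[ligand]]))
  NULL
}

#' @export
print.operational_fit <- function(x, ...) {
  cat("Operational model fit\n")
  cat(sprintf("  Basal %s +/- %s, Em %s +/- %s\n",
              fmt_num(x$basal), fmt_num(x$basal_se),
              fmt_num(x$em), fmt_num(x$em_se)))
  print(x$ligands, row.names = FALSE)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Correct operational efficacy for receptor expression
#'
#' The efficacy index tau is proportional to total receptor density R_T, so
#' estimates from cell lines with different expression are not directly
#' comparable. The default convention rescales the target receptor's tau to
#' the reference receptor's expression level:
#' `tau_C = tau_target * expression_reference / expression_target`
#' (equivalently `log tau_C = log tau + log10(expr_ref / expr_target)`).
#' `convention = "literal"` applies the inverse ratio
#' (`tau * expression_target / expression_reference`) instead.
#'
#' @param log_tau log10 efficacy of the target receptor.
#' @param log_tau_se its standard error (default 0).
#' @param expression_target,expression_reference receptor expression (e.g.
#'   Bmax in fmol/mg), both > 0 and in the same units.
#' @param convention `"normalize"` (default; uses tau proportional to R_T) or
#'   `"literal"`.
#' @return a list with `log_tau_c` and `log_tau_c_se`. Swapping the two
#'   expression arguments exactly inverts the correction.
#' @export
correct_efficacy_for_expression <- function(log_tau, log_tau_se = 0,
                                            expression_target,
                                            expression_reference,
                                            convention = c("normalize", "literal")) {
  convention <- match.arg(convention)
  check_number(log_tau, "log_tau")
  check_number(log_tau_se, "log_tau_se", lower = 0)
  check_number(expression_target, "expression_target", lower = 0, strict_lower = TRUE)
  check_number(expression_reference, "expression_reference", lower = 0, strict_lower = TRUE)
  shift <- log10(expression_reference / expression_target)
  if (convention == "literal") shift <- -shift
  # a deterministic shift on the log scale leaves the SE unchanged
  list(log_tau_c = log_tau + shift, log_tau_c_se = log_tau_se)
}
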