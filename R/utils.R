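# Internal validation and fitting machinery shared across modules.

## --- validation -----------------------------------------------------------

abort_invalid <- function(msg, class = "gpcrsel_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort_invalid(msg)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  check_that(is_number(x), sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  check_that(lo_ok && hi_ok,
             sprintf("`%s` = %g violates the bound [%s%g, %g%s]", name, x,
                     if (strict_lower) "(" else "", lower,
                     upper, if (strict_upper) ")" else ""))
  invisible(x)
}

## --- least-squares engine -------------------------------------------------

# Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# Corrected Akaike information criterion for a Gaussian least-squares fit.
# k counts the mean parameters; the residual variance adds one. `rss_floor`
# guards model selection on (near-)noiseless data: below numeric precision a
# smaller RSS carries no evidence, so parsimony should win.
aicc_from_rss <- function(rss, n, k, rss_floor = 0) {
  kk <- k + 1
  aic <- n * log(max(rss, rss_floor) / n) + 2 * kk
  if (n - kk - 1 > 0) aic + 2 * kk * (kk + 1) / (n - kk - 1) else Inf
}

#' @keywords internal
fit_failure <- function(reason, diagnostics = list()) {
  structure(list(failed = TRUE, reason = reason, diagnostics = diagnostics),
            class = c("gpcrsel_fit_failure", "list"))
}

#' Test whether a fit result signals failure
#'
#' Fitting functions in this package return an explicit failure object (rather
#' than raising an error or returning silent defaults) when the optimizer does
#' not converge or the data cannot identify the model.
#'
#' @param x an object returned by one of the `fit_*` functions.
#' @return `TRUE` if `x` is a fit-failure marker.
#' @export
is_fit_failure <- function(x) inherits(x, "gpcrsel_fit_failure")

#' @export
print.gpcrsel_fit_failure <- function(x, ...) {
  cat("<fit failure>", x$reason, "\n")
  invisible(x)
}

# Bounded multi-start nonlinear least squares.
#
# residual_fn(par) must return the residual vector. Starts is a list of
# numeric start vectors; the best converged solution by RSS wins. Asymptotic
# standard errors come from sigma^2 (J'J)^-1 with a numeric Jacobian.
least_squares <- function(residual_fn, starts, lower, upper, par_names,
                          n_obs = NULL, factr = 1e4, rss_floor = 0) {
  best <- NULL
  ssr <- function(par) {
    r <- residual_fn(par)
    if (any(!is.finite(r))) return(1e300)
    sum(r * r)
  }
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    opt <- tryCatch(
      stats::optim(p0, ssr, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = factr,
                                  # relative finite-difference steps: the
                                  # parameters span many orders of magnitude
                                  parscale = pmax(abs(p0), 1),
                                  ndeps = rep(1e-6, length(p0)))),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(fit_failure("optimizer failed from every start"))
  }
  par <- best$par
  names(par) <- par_names
  r <- residual_fn(par)
  n <- if (is.null(n_obs)) length(r) else n_obs
  k <- length(par)
  rss <- sum(r * r)
  se <- rep(NA_real_, k)
  singular <- FALSE
  J <- num_jacobian(residual_fn, par)
  # column-normalize before inverting: parameters can differ by many orders
  # of magnitude (e.g. Bmax vs a nonspecific slope per molar)
  cn <- sqrt(colSums(J^2))
  sigma2 <- if (n > k) rss / (n - k) else NA_real_
  cov <- NULL
  if (all(cn > 0) && all(is.finite(cn))) {
    Jn <- sweep(J, 2, cn, "/")
    cov_n <- tryCatch(solve(crossprod(Jn)) * sigma2, error = function(e) NULL)
    if (!is.null(cov_n)) cov <- cov_n / outer(cn, cn)
  }
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    singular <- TRUE
  } else {
    se <- sqrt(diag(cov))
  }
  names(se) <- par_names
  list(par = par, se = se, rss = rss, n = n, k = k,
       aicc = aicc_from_rss(rss, n, k, rss_floor),
       cov = cov, singular = singular, convergence = best$convergence)
}

# Geometric spread of start values across a log-concentration range.
logc_starts <- function(log_range, n = 5) {
  seq(log_range[1], log_range[2], length.out = n)
}

## --- shared small helpers -------------------------------------------------

# Gas constant in kcal mol^-1 K^-1.
R_KCAL <- 1.987204259e-3

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
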