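# Seeded generators for every input the pipeline consumes, with ground-truth
# parameters attached so downstream fits can be verified exactly.

#' Specify a synthetic concentration-response experiment
#'
#' Describes an agonist concentration-response curve drawn from the
#' operational model of agonism (see [eval_operational()]) with additive
#' homoscedastic Gaussian noise on the response scale.
#'
#' @param basal response in the absence of agonist (response units).
#' @param em maximal possible response of the system (must exceed `basal`).
#' @param log_ka log10 molar functional equilibrium dissociation constant.
#' @param log_tau log10 of the operational efficacy index tau.
#' @param conc_grid strictly increasing vector of log10 molar concentrations.
#' @param n_replicates replicates per concentration (>= 1).
#' @param noise_sd Gaussian noise standard deviation, response units
#'   (default 5% of `em`; the assays give no stated replicate noise, so this
#'   is a fixture choice, not a claim).
#' @param seed integer seed; the same spec and seed reproduce the data
#'   bit-for-bit.
#' @param ligand,receptor labels carried through to the generated table.
#' @return an object of class `dose_response_spec`.
#' @export
dose_response_spec <- function(basal, em, log_ka, log_tau, conc_grid,
                               n_replicates = 3, noise_sd = 0.05 * em,
                               seed = 1L, ligand = "ligand",
                               receptor = "receptor") {
  check_number(basal, "basal")
  check_number(em, "em")
  check_that(em > basal, "`em` must be greater than `basal`")
  check_number(log_ka, "log_ka")
  check_number(log_tau, "log_tau")
  check_that(is.numeric(conc_grid) && length(conc_grid) >= 1 &&
               all(is.finite(conc_grid)) && !is.unsorted(conc_grid, strictly = TRUE),
             "`conc_grid` must be strictly increasing and finite")
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  structure(list(basal = basal, em = em, log_ka = log_ka, log_tau = log_tau,
                 conc_grid = as.numeric(conc_grid),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 ligand = ligand, receptor = receptor),
            class = "dose_response_spec")
}

#' Generate a synthetic concentration-response data set
#'
#' Evaluates the operational model at the spec's concentration grid and adds
#' i.i.d. Gaussian noise. The true generating parameters are attached as the
#' `ground_truth` attribute.
#'
#' @param spec a [dose_response_spec()].
#' @return a `dose_response_set`: a data frame with columns `ligand`,
#'   `receptor`, `log_conc` (log10 molar), `response`, `replicate`.
#' @export
generate_dose_response <- function(spec) {
  check_that(inherits(spec, "dose_response_spec"),
             "`spec` must be a dose_response_spec")
  model <- operational_model(spec$basal, spec$em, spec$log_ka, spec$log_tau)
  grid <- rep(spec$conc_grid, each = spec$n_replicates)
  mu <- eval_operational(model, grid)
  set.seed(spec$seed)
  y <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
  out <- data.frame(
    ligand = spec$ligand, receptor = spec$receptor,
    log_conc = grid, response = y,
    replicate = rep(seq_len(spec$n_replicates), times = length(spec$conc_grid)),
    stringsAsFactors = FALSE
  )
  structure(out, ground_truth = spec,
            class = c("dose_response_set", "data.frame"))
}

#' Specify a synthetic radioligand binding experiment
#'
#' Three modes: `"saturation"` draws total and nonspecific binding from the
#' one-site saturation model ([eval_saturation()]); `"competition_one_site"`
#' and `"competition_two_site"` draw displacement curves from the one- or
#' two-site competition equation ([eval_two_site()]).
#'
#' @param mode one of `"saturation"`, `"competition_one_site"`,
#'   `"competition_two_site"`.
#' @param conc_grid log10 molar concentrations (radioligand for saturation,
#'   competitor otherwise), strictly increasing.
#' @param bmax,p_kd_radioligand,ns_slope saturation parameters: maximal
#'   specific binding (signal units), radioligand pKd (-log10 M), nonspecific
#'   slope (signal per molar).
#' @param top,bottom competition asymptotes (signal units), `top > bottom`.
#' @param p_ic50_high,p_ic50_low -log10 molar IC50 of the high- and
#'   low-affinity sites (`p_ic50_high >= p_ic50_low` when two-site).
#' @param fraction_high proportion of high-affinity sites in `[0, 1]`.
#' @param n_replicates replicates per concentration.
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed integer seed.
#' @return an object of class `binding_curve_spec`.
#' @export
binding_curve_spec <- function(mode = c("saturation", "competition_one_site",
                                        "competition_two_site"),
                               conc_grid,
                               bmax = NULL, p_kd_radioligand = NULL,
                               ns_slope = 0,
                               top = NULL, bottom = NULL,
                               p_ic50_high = NULL, p_ic50_low = NULL,
                               fraction_high = NULL,
                               n_replicates = 1, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  check_that(is.numeric(conc_grid) && length(conc_grid) >= 1 &&
               all(is.finite(conc_grid)) && !is.unsorted(conc_grid, strictly = TRUE),
             "`conc_grid` must be strictly increasing and finite")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_replicates, "n_replicates", lower = 1)
  if (mode == "saturation") {
    check_number(bmax, "bmax", lower = 0, strict_lower = TRUE)
    check_number(p_kd_radioligand, "p_kd_radioligand")
    check_number(ns_slope, "ns_slope", lower = 0)
  } else {
    check_number(top, "top")
    check_number(bottom, "bottom")
    check_that(top > bottom, "`top` must be greater than `bottom`")
    check_number(p_ic50_high, "p_ic50_high")
    if (mode == "competition_two_site") {
      check_number(p_ic50_low, "p_ic50_low")
      check_number(fraction_high, "fraction_high", lower = 0, upper = 1)
      check_that(p_ic50_high >= p_ic50_low,
                 "`p_ic50_high` must be >= `p_ic50_low` (high-affinity site binds tighter)")
    } else {
      check_that(is.null(p_ic50_low) && is.null(fraction_high),
                 "two-site parameters supplied in one-site mode")
    }
  }
  structure(list(mode = mode, conc_grid = as.numeric(conc_grid), bmax = bmax,
                 p_kd_radioligand = p_kd_radioligand, ns_slope = ns_slope,
                 top = top, bottom = bottom, p_ic50_high = p_ic50_high,
                 p_ic50_low = p_ic50_low, fraction_high = fraction_high,
                 n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "binding_curve_spec")
}

#' Generate a synthetic binding curve
#'
#' @param spec a [binding_curve_spec()].
#' @return a `binding_curve_set`: data frame with columns `series`
#'   (`"total"`/`"nonspecific"` for saturation, `"competition"` otherwise),
#'   `log_conc` (log10 molar), `signal`, `replicate`; true parameters in the
#'   `ground_truth` attribute.
#' @export
generate_binding_curve <- function(spec) {
  check_that(inherits(spec, "binding_curve_spec"),
             "`spec` must be a binding_curve_spec")
  grid <- rep(spec$conc_grid, each = spec$n_replicates)
  rep_id <- rep(seq_len(spec$n_replicates), times = length(spec$conc_grid))
  if (spec$mode == "saturation") {
    model <- saturation_model(spec$bmax, spec$p_kd_radioligand, spec$ns_slope)
    conc <- 10^grid
    mu_tot <- eval_saturation(model, conc)
    mu_ns <- spec$ns_slope * conc
    out <- data.frame(
      series = rep(c("total", "nonspecific"), each = length(grid)),
      log_conc = c(grid, grid), signal = c(mu_tot, mu_ns),
      replicate = c(rep_id, rep_id), stringsAsFactors = FALSE
    )
  } else {
    model <- if (spec$mode == "competition_two_site") {
      two_site_model(spec$top, spec$bottom,
                     log_ic50_high = -spec$p_ic50_high,
                     log_ic50_low = -spec$p_ic50_low,
                     fraction_high = spec$fraction_high)
    } else {
      two_site_model(spec$top, spec$bottom,
                     log_ic50_high = -spec$p_ic50_high,
                     log_ic50_low = -spec$p_ic50_high, fraction_high = 1)
    }
    out <- data.frame(series = "competition", log_conc = grid,
                      signal = eval_two_site(model, grid),
                      replicate = rep_id, stringsAsFactors = FALSE)
  }
  set.seed(spec$seed)
  out$signal <- out$signal + stats::rnorm(nrow(out), 0, spec$noise_sd)
  structure(out, ground_truth = spec,
            class = c("binding_curve_set", "data.frame"))
}

## --- two-state Markov feature traces -------------------------------------

# Wrap angles in degrees onto (-180, 180].
wrap_degrees <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Specify a synthetic two-state trajectory feature trace
#'
#' A hidden two-state ("open"/"closed") Markov chain with per-frame transition
#' probabilities; each named feature is emitted from a Gaussian whose mean and
#' SD depend on the hidden state. Dihedral features are wrapped onto
#' `(-180, 180]` degrees. This stands in for geometric features computed from
#' molecular-dynamics trajectories.
#'
#' @param n_frames number of frames.
#' @param dt frame spacing in ns.
#' @param p_open_to_closed,p_closed_to_open per-frame transition
#'   probabilities in `[0, 1]`.
#' @param features named feature kinds: a character vector whose names are the
#'   feature names and whose values are `"dihedral"` (degrees) or
#'   `"distance"` (Angstrom), e.g. `c(chi1_n652 = "dihedral")`.
#' @param open_mean,open_sd,closed_mean,closed_sd numeric vectors (one entry
#'   per feature) of emission means and SDs in the open and closed states.
#' @param burn_in_ns equilibration span recorded in the spec (must not exceed
#'   the trace length); downstream classifiers use it as the exclusion window.
#' @param initial_state `"open"` or `"closed"`.
#' @param simulation_id identifier carried into the output.
#' @param seed integer seed.
#' @return an object of class `markov_trace_spec`.
#' @export
markov_trace_spec <- function(n_frames, dt,
                              p_open_to_closed, p_closed_to_open,
                              features, open_mean, open_sd,
                              closed_mean, closed_sd,
                              burn_in_ns = 0, initial_state = c("open", "closed"),
                              simulation_id = "sim1", seed = 1L) {
  initial_state <- match.arg(initial_state)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(p_open_to_closed, "p_open_to_closed", lower = 0, upper = 1)
  check_number(p_closed_to_open, "p_closed_to_open", lower = 0, upper = 1)
  check_that(is.character(features) && length(features) >= 1 &&
               !is.null(names(features)) && all(nzchar(names(features))) &&
               all(features %in% c("dihedral", "distance")),
             "`features` must be a named character vector of 'dihedral'/'distance'")
  nf <- length(features)
  for (v in c("open_mean", "open_sd", "closed_mean", "closed_sd")) {
    val <- get(v)
    check_that(is.numeric(val) && length(val) == nf && all(is.finite(val)),
               sprintf("`%s` must be numeric of length %d", v, nf))
  }
  check_that(all(open_sd > 0) && all(closed_sd > 0), "emission SDs must be > 0")
  check_number(burn_in_ns, "burn_in_ns", lower = 0)
  check_that(n_frames * dt >= burn_in_ns,
             "`burn_in_ns` must not exceed the trace length n_frames * dt")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 p_open_to_closed = p_open_to_closed,
                 p_closed_to_open = p_closed_to_open,
                 features = features, open_mean = open_mean, open_sd = open_sd,
                 closed_mean = closed_mean, closed_sd = closed_sd,
                 burn_in_ns = burn_in_ns, initial_state = initial_state,
                 simulation_id = simulation_id, seed = as.integer(seed)),
            class = "markov_trace_spec")
}

#' Generate a synthetic trajectory feature trace
#'
#' @param spec a [markov_trace_spec()].
#' @return a `feature_series` data frame with columns `simulation_id`,
#'   `time_ns` and one column per feature; the true hidden state labels
#'   (`TRUE` = open) are in the `true_state` attribute and the spec in
#'   `ground_truth`.
#' @export
generate_markov_trace <- function(spec) {
  check_that(inherits(spec, "markov_trace_spec"),
             "`spec` must be a markov_trace_spec")
  set.seed(spec$seed)
  n <- spec$n_frames
  state <- logical(n)                      # TRUE = open
  state[1] <- spec$initial_state == "open"
  u <- stats::runif(n)
  for (i in seq_len(n - 1L)) {
    state[i + 1L] <- if (state[i]) u[i] >= spec$p_open_to_closed
                     else          u[i] <  spec$p_closed_to_open
  }
  out <- data.frame(simulation_id = spec$simulation_id,
                    time_ns = seq_len(n) * spec$dt,
                    stringsAsFactors = FALSE)
  for (j in seq_along(spec$features)) {
    mu <- ifelse(state, spec$open_mean[j], spec$closed_mean[j])
    sd <- ifelse(state, spec$open_sd[j], spec$closed_sd[j])
    x <- stats::rnorm(n, mu, sd)
    if (spec$features[j] == "dihedral") x <- wrap_degrees(x)
    out[[names(spec$features)[j]]] <- x
  }
  structure(out, ground_truth = spec, true_state = state,
            class = c("feature_series", "data.frame"))
}
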