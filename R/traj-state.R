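# Geometric features from trajectory coordinates, threshold state
# classifiers, per-simulation state frequencies and smoothed traces.

#' Residue map for trajectory feature computation
#'
#' Maps generic Ballesteros-Weinstein helix positions to sequence residue
#' numbers for one receptor subtype, so the same feature definitions apply
#' across subtypes. Only the positions actually used by the classifiers are
#' needed: 5.43/6.56 (interhelical channel), 4.57/6.55 (TM6 outward),
#' 3.46/6.37 (intracellular TM3-TM6 activation distance), 6.52 (the
#' asparagine whose chi1 rotamer reports channel opening), the ECL2 anchor
#' residue, and the ligand mid-tail atom name.
#'
#' @param subtype receptor identifier (e.g. `"M2"`).
#' @param ca named integer vector: Ballesteros-Weinstein position ->
#'   sequence residue number (injective).
#' @param n652 sequence residue number of the 6.52 asparagine.
#' @param ecl2 sequence residue number of the ECL2 anchor.
#' @param tail_atom ligand atom label for the tail metric (default `"C17"`,
#'   the mid-tail carbon; analogs with other tail lengths override this).
#' @return an object of class `residue_map`.
#' @export
residue_map <- function(subtype, ca, n652 = NULL, ecl2 = NULL,
                        tail_atom = "C17") {
  check_that(is.character(subtype) && length(subtype) == 1,
             "`subtype` must be a single string")
  check_that(is.numeric(ca) && !is.null(names(ca)) && all(nzchar(names(ca))),
             "`ca` must be a named numeric vector (BW position -> residue)")
  check_that(!anyDuplicated(ca), "`ca` mapping must be injective")
  structure(list(subtype = subtype, ca = ca, n652 = n652, ecl2 = ecl2,
                 tail_atom = tail_atom),
            class = "residue_map")
}

#' Built-in residue maps
#'
#' Returns the shipped residue map for a muscarinic receptor subtype. Only
#' positions with published sequence numbers are filled in: for M2, residues
#' 191 (5.43), 408 (6.56), 155 (4.57), 407 (6.55) and the ECL2 anchor 181;
#' for M4 the ECL2 anchor 190. Other entries must be supplied by the user.
#'
#' @param subtype `"M2"` or `"M4"`.
#' @return a [residue_map()].
#' @export
builtin_residue_map <- function(subtype = c("M2", "M4")) {
  subtype <- match.arg(subtype)
  switch(subtype,
    M2 = residue_map("M2",
                     ca = c("5.43" = 191, "6.56" = 408,
                            "4.57" = 155, "6.55" = 407),
                     ecl2 = 181),
    M4 = residue_map("M4", ca = c("5.43" = NA_real_)[0], ecl2 = 190)
  )
}

## --- geometry -------------------------------------------------------------

# Signed dihedral angle (degrees) for rows of 3-column matrices p1..p4,
# positive by the right-hand rule looking down the p2->p3 bond.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2 * b2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  # IUPAC sign (matches MDAnalysis/mdtraj): positive = clockwise rotation of
  # the far bond viewed along the central bond
  wrap_degrees(-atan2(y, x) * 180 / pi)
}

#' Compute trajectory features from a multi-frame coordinate table
#'
#' The native coordinate format is a long table with columns `frame` (integer,
#' 1-based), `atom` (label), `x`, `y`, `z` (Angstrom). C-alpha atoms are
#' labelled `CA_<residue>`, chi1 backbone/side-chain atoms `N_<residue>`,
#' `CA_<residue>`, `CB_<residue>`, `CG_<residue>`, and ligand atoms by their
#' plain name (e.g. `C17`). Every feature whose atoms appear in the table is
#' computed:
#' * `chi1_n652` — signed N-CA-CB-CG dihedral of the 6.52 asparagine, degrees
#'   in `(-180, 180]`;
#' * `d_tm5_tm6` — Calpha 5.43 to 6.56 distance, Angstrom;
#' * `d_tm4_tm6` — Calpha 4.57 to 6.55;
#' * `d_tm3_tm6_ic` — Calpha 3.46 to 6.37;
#' * `d_tail_ecl2` — ligand tail atom to ECL2 Calpha.
#'
#' @param frames coordinate table (data frame as above).
#' @param map a [residue_map()].
#' @param dt frame spacing in ns (default 1).
#' @param simulation_id identifier for the output series.
#' @return a `feature_series` data frame (`simulation_id`, `time_ns`, one
#'   column per computable feature). A feature whose atoms are present in
#'   some frames but missing in others raises an error naming the atom and
#'   frame.
#' @export
compute_features <- function(frames, map, dt = 1, simulation_id = "sim1") {
  check_that(is.data.frame(frames) &&
               all(c("frame", "atom", "x", "y", "z") %in% names(frames)),
             "`frames` must have columns frame, atom, x, y, z")
  check_that(inherits(map, "residue_map"), "`map` must be a residue_map")
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  frame_ids <- sort(unique(frames$frame))
  n <- length(frame_ids)

  coords_of <- function(label) {
    sub <- frames[frames$atom == label, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    idx <- match(frame_ids, sub$frame)
    if (anyNA(idx)) {
      abort_invalid(sprintf("atom '%s' missing in frame %d", label,
                            frame_ids[which(is.na(idx))[1]]))
    }
    as.matrix(sub[idx, c("x", "y", "z")])
  }
  dist_feature <- function(lab_a, lab_b) {
    a <- coords_of(lab_a); b <- coords_of(lab_b)
    if (is.null(a) || is.null(b)) return(NULL)
    sqrt(rowSums((a - b)^2))
  }
  ca_label <- function(bw) {
    if (!bw %in% names(map$ca) || is.na(map$ca[[bw]])) return(NULL)
    paste0("CA_", map$ca[[bw]])
  }
  pair <- function(bw1, bw2) {
    l1 <- ca_label(bw1); l2 <- ca_label(bw2)
    if (is.null(l1) || is.null(l2)) NULL else dist_feature(l1, l2)
  }

  out <- data.frame(simulation_id = simulation_id, time_ns = frame_ids * dt,
                    stringsAsFactors = FALSE)
  if (!is.null(map$n652)) {
    labs <- paste0(c("N_", "CA_", "CB_", "CG_"), map$n652)
    pts <- lapply(labs, coords_of)
    if (!any(vapply(pts, is.null, logical(1)))) {
      out$chi1_n652 <- dihedral_deg(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
  }
  for (feat in list(c("d_tm5_tm6", "5.43", "6.56"),
                    c("d_tm4_tm6", "4.57", "6.55"),
                    c("d_tm3_tm6_ic", "3.46", "6.37"))) {
    v <- pair(feat[2], feat[3])
    if (!is.null(v)) out[[feat[1]]] <- v
  }
  if (!is.null(map$ecl2)) {
    v <- dist_feature(map$tail_atom, paste0("CA_", map$ecl2))
    if (!is.null(v)) out$d_tail_ecl2 <- v
  }
  structure(out, class = c("feature_series", "data.frame"))
}

## --- classifiers ----------------------------------------------------------

make_state_series <- function(fs, state, exclude_ns, state_name) {
  eligible <- logical(nrow(fs))
  for (sim in unique(fs$simulation_id)) {
    sel <- fs$simulation_id == sim
    eligible[sel] <- fs$time_ns[sel] > exclude_ns
  }
  structure(
    data.frame(simulation_id = fs$simulation_id, time_ns = fs$time_ns,
               state = state, eligible = eligible, stringsAsFactors = FALSE),
    state_name = state_name, exclude_ns = exclude_ns,
    class = c("state_series", "data.frame")
  )
}

check_feature <- function(fs, feature) {
  check_that(is.data.frame(fs) &&
               all(c("simulation_id", "time_ns") %in% names(fs)),
             "`fs` must be a feature_series")
  check_that(feature %in% names(fs),
             sprintf("feature '%s' not present in the series", feature))
  invisible(fs[[feature]])
}

#' Classify frames as channel-open from the 6.52 chi1 rotamer
#'
#' A frame is "open" when the 6.52 asparagine chi1 angle lies strictly inside
#' the open interval (-50, 100) degrees, the rotamer adopted when the
#' TM5/TM6 interhelical channel is formed. Boundary values are excluded
#' (measure-zero on continuous data; the convention is documented here
#' because the thresholds are quoted without one). The first `exclude_ns` of
#' each simulation (equilibration) are masked ineligible.
#'
#' @param fs a `feature_series` with a `chi1_n652` column (degrees).
#' @param lower,upper interval bounds in degrees (defaults -50 and 100).
#' @param exclude_ns equilibration window, ns (default 50).
#' @return a `state_series` with columns `simulation_id`, `time_ns`, `state`,
#'   `eligible`.
#' @export
classify_channel_open <- function(fs, lower = -50, upper = 100,
                                  exclude_ns = 50) {
  chi1 <- check_feature(fs, "chi1_n652")
  make_state_series(fs, chi1 > lower & chi1 < upper, exclude_ns, "channel_open")
}

#' Classify frames as receptor-active from the TM3-TM6 distance
#'
#' Active when the intracellular Calpha 3.46-6.37 distance strictly exceeds
#' 10 Angstrom (the distance is about 8 Angstrom in the inactive state).
#'
#' @param fs a `feature_series` with a `d_tm3_tm6_ic` column (Angstrom).
#' @param threshold Angstrom (default 10).
#' @param exclude_ns equilibration window, ns (default 0; the activation
#'   label is mostly used to condition other frequencies, which carry their
#'   own exclusion windows).
#' @return a `state_series`.
#' @export
classify_active <- function(fs, threshold = 10, exclude_ns = 0) {
  d <- check_feature(fs, "d_tm3_tm6_ic")
  make_state_series(fs, d > threshold, exclude_ns, "active")
}

#' Classify frames as TM6-outward
#'
#' Outward when the Calpha 4.57-6.55 distance strictly exceeds 20.7 Angstrom.
#'
#' @param fs a `feature_series` with a `d_tm4_tm6` column (Angstrom).
#' @param threshold Angstrom (default 20.7).
#' @param exclude_ns equilibration window, ns (default 0).
#' @return a `state_series`.
#' @export
classify_tm6_outward <- function(fs, threshold = 20.7, exclude_ns = 0) {
  d <- check_feature(fs, "d_tm4_tm6")
  make_state_series(fs, d > threshold, exclude_ns, "tm6_outward")
}

#' Classify frames by vertical ligand tail pose
#'
#' Vertical when the distance from the ligand mid-tail atom to the ECL2
#' anchor Calpha is strictly below 8.9 Angstrom. The first 100 ns of each
#' simulation are masked by default.
#'
#' @param fs a `feature_series` with a `d_tail_ecl2` column (Angstrom).
#' @param threshold Angstrom (default 8.9).
#' @param exclude_ns equilibration window, ns (default 100).
#' @return a `state_series`.
#' @export
classify_tail_vertical <- function(fs, threshold = 8.9, exclude_ns = 100) {
  d <- check_feature(fs, "d_tail_ecl2")
  make_state_series(fs, d < threshold, exclude_ns, "tail_vertical")
}

## --- aggregation ----------------------------------------------------------

#' Per-simulation state frequency
#'
#' Fraction of eligible frames in the target state, one value per simulation
#' (each simulation is an independent sample for group statistics).
#' Optionally conditions on a second state series (e.g. restrict to frames
#' where the receptor remained active). A simulation with no eligible frames
#' is reported as `NA`, not zero.
#'
#' @param states a `state_series` (may contain several `simulation_id`s).
#' @param condition optional aligned `state_series`; only frames where it is
#'   `TRUE` (and eligible) enter the denominator.
#' @return a `frequency_estimate` data frame with columns `simulation_id`,
#'   `n_frames` (eligible frame count) and `frequency` in `[0, 1]`.
#' @export
state_frequency <- function(states, condition = NULL) {
  check_that(inherits(states, "state_series"), "`states` must be a state_series")
  ok <- states$eligible
  if (!is.null(condition)) {
    check_that(inherits(condition, "state_series"),
               "`condition` must be a state_series")
    check_that(nrow(condition) == nrow(states) &&
                 all(condition$simulation_id == states$simulation_id) &&
                 all(condition$time_ns == states$time_ns),
               "`condition` must be frame-aligned with `states`")
    ok <- ok & condition$eligible & condition$state
  }
  sims <- unique(states$simulation_id)
  res <- lapply(sims, function(sim) {
    sel <- states$simulation_id == sim & ok
    n <- sum(sel)
    data.frame(simulation_id = sim, n_frames = n,
               frequency = if (n == 0) NA_real_ else mean(states$state[sel]),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res),
            state_name = attr(states, "state_name"),
            class = c("frequency_estimate", "data.frame"))
}

#' Centered moving average of trajectory features
#'
#' Smooths each feature column with a centered moving mean over a time window
#' (default 30 ns); windows shrink at the edges of each simulation. The raw
#' series is retained in the `raw` attribute.
#'
#' @param fs a `feature_series`.
#' @param window_ns window width in ns; must be at least the frame spacing.
#' @param features columns to smooth (default: all feature columns).
#' @return a `feature_series` with smoothed feature values.
#' @export
moving_average <- function(fs, window_ns = 30, features = NULL) {
  check_that(is.data.frame(fs) &&
               all(c("simulation_id", "time_ns") %in% names(fs)),
             "`fs` must be a feature_series")
  if (is.null(features)) {
    features <- setdiff(names(fs), c("simulation_id", "time_ns"))
  }
  out <- fs
  half <- window_ns / 2 + 1e-9
  for (sim in unique(fs$simulation_id)) {
    sel <- which(fs$simulation_id == sim)
    t <- fs$time_ns[sel]
    if (length(t) > 1) {
      spacing <- min(diff(t))
      check_that(window_ns >= spacing,
                 sprintf("window (%g ns) is below the frame spacing (%g ns)",
                         window_ns, spacing))
    }
    # uniform sampling: O(n) via cumulative sums over an index window
    for (f in features) {
      x <- fs[[f]][sel]
      n <- length(x)
      lo <- findInterval(t - half, t) + 1L
      hi <- findInterval(t + half, t)
      cs <- cumsum(x)
      out[[f]][sel] <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
    }
  }
  structure(out, raw = fs, class = c("feature_series", "data.frame"))
}

#' Conditional state fractions with bootstrap confidence intervals
#'
#' Splits frames into two groups by a conditioning state (e.g. channel open
#' versus closed), aggregates frames across simulations within each group,
#' and reports the fraction of frames in the target state per group with a
#' percentile-bootstrap confidence interval over frames (68% by default).
#'
#' @param states_target target `state_series`.
#' @param condition_on aligned conditioning `state_series`.
#' @param level CI level (default 0.68).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the resampling.
#' @return a data frame with one row per group (`condition` TRUE/FALSE) and
#'   columns `fraction`, `ci_low`, `ci_high`, `n_frames`; an empty group
#'   yields `NA`s.
#' @export
grouped_fraction <- function(states_target, condition_on, level = 0.68,
                             n_boot = 10000, seed = 1L) {
  check_that(inherits(states_target, "state_series"),
             "`states_target` must be a state_series")
  check_that(inherits(condition_on, "state_series"),
             "`condition_on` must be a state_series")
  check_that(nrow(states_target) == nrow(condition_on) &&
               all(states_target$simulation_id == condition_on$simulation_id) &&
               all(states_target$time_ns == condition_on$time_ns),
             "series must be frame-aligned")
  ok <- states_target$eligible & condition_on$eligible
  one_group <- function(cond_value) {
    x <- states_target$state[ok & condition_on$state == cond_value]
    if (length(x) == 0) {
      return(data.frame(condition = cond_value, fraction = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n_frames = 0L))
    }
    ci <- bootstrap_ci(as.numeric(x), level = level, n_boot = n_boot,
                       seed = seed)
    data.frame(condition = cond_value, fraction = ci$mean,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               n_frames = length(x))
  }
  rbind(one_group(TRUE), one_group(FALSE))
}
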