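# Trajectory geometry, threshold classifiers, frequencies and smoothing.

coord_row <- function(frame, atom, xyz) {
  data.frame(frame = frame, atom = atom, x = xyz[1], y = xyz[2], z = xyz[3])
}

test_that("compute_features reproduces textbook geometry", {
  map <- residue_map("M2", ca = c("5.43" = 191, "6.56" = 408), n652 = 404)
  frames <- rbind(
    coord_row(1, "CA_191", c(0, 0, 0)), coord_row(1, "CA_408", c(3, 4, 0)),
    coord_row(1, "N_404", c(-1, 1, 0)), coord_row(1, "CA_404", c(0, 0, 0)),
    coord_row(1, "CB_404", c(1, 0, 0)), coord_row(1, "CG_404", c(2, 1, 0)),
    coord_row(2, "CA_191", c(0, 0, 0)), coord_row(2, "CA_408", c(3, 4, 0)),
    coord_row(2, "N_404", c(-1, 1, 0)), coord_row(2, "CA_404", c(0, 0, 0)),
    coord_row(2, "CB_404", c(1, 0, 0)), coord_row(2, "CG_404", c(2, -1, 0))
  )
  fs <- compute_features(frames, map, dt = 0.5)
  expect_equal(fs$d_tm5_tm6, c(5, 5))
  expect_equal(fs$chi1_n652, c(0, 180))   # cis then trans
  expect_equal(fs$time_ns, c(0.5, 1))
})

test_that("dihedrals match an independent vector-algebra oracle", {
  map <- residue_map("X", ca = c("5.43" = 1)[0], n652 = 9)
  set.seed(303)
  for (i in 1:40) {
    pts <- matrix(rnorm(12), 4, 3)
    frames <- rbind(coord_row(1, "N_9", pts[1, ]), coord_row(1, "CA_9", pts[2, ]),
                    coord_row(1, "CB_9", pts[3, ]), coord_row(1, "CG_9", pts[4, ]))
    fs <- compute_features(frames, map)
    expect_equal(fs$chi1_n652,
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("a missing atom is reported with atom and frame", {
  map <- residue_map("M2", ca = c("5.43" = 191, "6.56" = 408))
  frames <- rbind(
    coord_row(1, "CA_191", c(0, 0, 0)), coord_row(1, "CA_408", c(1, 0, 0)),
    coord_row(2, "CA_191", c(0, 0, 0))
  )
  expect_error(compute_features(frames, map), "CA_408.*frame 2")
})

test_that("threshold classifiers use strict bounds and time-based masks", {
  fs <- make_feature_series(data.frame(
    simulation_id = "s1", time_ns = c(25, 75, 125, 175),
    chi1_n652 = c(0, -50, 180, 99.999),
    d_tm3_tm6_ic = c(11, 8, 10, 10.001),
    d_tm4_tm6 = c(21, 20, 20.7, 25),
    d_tail_ecl2 = c(8.0, 9.5, 8.9, 8.89)
  ))
  open <- classify_channel_open(fs)
  expect_equal(open$state, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(open$eligible, c(FALSE, TRUE, TRUE, TRUE))  # first 50 ns masked
  act <- classify_active(fs)
  expect_equal(act$state, c(TRUE, FALSE, FALSE, TRUE))
  out <- classify_tm6_outward(fs)
  expect_equal(out$state, c(TRUE, FALSE, FALSE, TRUE))     # 20.7 exactly: inward
  tail <- classify_tail_vertical(fs)
  expect_equal(tail$state, c(TRUE, FALSE, FALSE, TRUE))    # 8.9 exactly: not vertical
  expect_equal(tail$eligible, c(FALSE, FALSE, TRUE, TRUE)) # first 100 ns masked
  expect_error(classify_channel_open(fs[, c("simulation_id", "time_ns")]),
               "chi1_n652")
})

test_that("classifiers are pure: permuting frames permutes labels identically", {
  set.seed(12)
  fs <- make_feature_series(data.frame(
    simulation_id = "s1", time_ns = seq_len(50) * 2,
    d_tm3_tm6_ic = runif(50, 7, 13)
  ))
  perm <- sample(50)
  fs_perm <- make_feature_series(fs[perm, ])
  expect_equal(classify_active(fs_perm)$state, classify_active(fs)$state[perm])
})

test_that("state_frequency counts eligible frames per simulation", {
  fs <- make_feature_series(data.frame(
    simulation_id = rep(c("a", "b"), each = 100),
    time_ns = rep(seq_len(100), 2),
    chi1_n652 = c(rep(0, 100), rep(c(0, 180), 50)),
    d_tm3_tm6_ic = rep(c(11, 8), 100)
  ))
  open <- classify_channel_open(fs, exclude_ns = 0)
  fr <- state_frequency(open)
  expect_equal(fr$frequency, c(1, 0.5))
  # active-only conditioning halves the denominator
  act <- classify_active(fs)
  fr_act <- state_frequency(open, condition = act)
  expect_equal(fr_act$n_frames, c(50, 50))
  # a simulation with no eligible frames is missing, not zero
  open_masked <- classify_channel_open(fs, exclude_ns = 1000)
  expect_true(all(is.na(state_frequency(open_masked)$frequency)))
  # upsampling by label duplication leaves frequencies unchanged
  fs2 <- make_feature_series(data.frame(
    simulation_id = rep(fs$simulation_id, each = 2),
    time_ns = rep(seq_len(100), 2, each = 2) + c(0, 0.5),
    chi1_n652 = rep(fs$chi1_n652, each = 2),
    d_tm3_tm6_ic = rep(fs$d_tm3_tm6_ic, each = 2)
  ))
  fr2 <- state_frequency(classify_channel_open(fs2, exclude_ns = 0))
  expect_equal(fr2$frequency, fr$frequency)
})

test_that("classifier frequency matches generator ground truth when separable", {
  sp <- markov_trace_spec(20000, 0.2, 0.02, 0.01,
                          c(chi1_n652 = "dihedral"), open_mean = 20,
                          open_sd = 10, closed_mean = 180, closed_sd = 10,
                          burn_in_ns = 0, seed = 99L)
  tr <- generate_markov_trace(sp)
  truth <- attr(tr, "true_state")
  freq <- state_frequency(classify_channel_open(tr, exclude_ns = 0))$frequency
  # analytic misclassification bound from the Gaussian emission tails,
  # accounting for wrapping (one period each side)
  p_in <- function(mean, sd) {
    sum(stats::pnorm(100 + c(-360, 0, 360), mean, sd) -
          stats::pnorm(-50 + c(-360, 0, 360), mean, sd))
  }
  miss <- max(1 - p_in(20, 10), p_in(180, 10))
  expect_lt(abs(freq - mean(truth)), miss + 3 / sqrt(length(truth)))
})

test_that("moving_average matches the brute-force windowed mean", {
  t <- seq_len(200) * 0.5
  set.seed(7)
  x <- rnorm(200)
  fs <- make_feature_series(data.frame(simulation_id = "s", time_ns = t, f = x))
  sm <- moving_average(fs, window_ns = 10)
  expect_equal(sm$f, oracle_moving_average(t, x, 10), tolerance = 1e-12)
  expect_equal(attr(sm, "raw")$f, x)
  # constant series unchanged; impulse spreads to 1/k
  const <- make_feature_series(data.frame(simulation_id = "s", time_ns = t,
                                          f = 3))
  expect_equal(moving_average(const, 10)$f, rep(3, 200))
  imp <- make_feature_series(data.frame(
    simulation_id = "s", time_ns = seq_len(101),
    f = c(rep(0, 50), 1, rep(0, 50))))
  sm_imp <- moving_average(imp, window_ns = 10)
  expect_equal(max(sm_imp$f), 1 / 11)
  expect_error(moving_average(fs, window_ns = 0.1), "spacing")
})

test_that("grouped_fraction pools frames and bootstraps within groups", {
  n <- 400
  mk_state <- function(state, eligible = TRUE) {
    structure(data.frame(simulation_id = "s", time_ns = seq_len(n),
                         state = state, eligible = eligible),
              class = c("state_series", "data.frame"))
  }
  # perfectly coupled labels give conditional fractions 1 and 0
  cond <- mk_state(rep(c(TRUE, FALSE), n / 2))
  res <- grouped_fraction(cond, cond, n_boot = 500)
  expect_equal(res$fraction, c(1, 0))
  # condition always true: the FALSE group is missing
  res2 <- grouped_fraction(cond, mk_state(rep(TRUE, n)), n_boot = 500)
  expect_true(is.na(res2$fraction[res2$condition == FALSE]))
  expect_equal(res2$n_frames[res2$condition == FALSE], 0)
  # independent labels: group fractions agree within joined CIs
  set.seed(31)
  tgt <- mk_state(runif(n) < 0.4)
  ind <- mk_state(runif(n) < 0.5)
  res3 <- grouped_fraction(tgt, ind, n_boot = 2000, seed = 3L)
  expect_lt(abs(res3$fraction[1] - res3$fraction[2]),
            (res3$ci_high[1] - res3$ci_low[1]) +
              (res3$ci_high[2] - res3$ci_low[2]))
})
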