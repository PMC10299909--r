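# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# Brute-force 2D bisection for the single-ligand ternary equilibrium over
# (free R, free G). Species are written out directly from the mass-action
# relations; no package internals are reused. Bisection runs on the log
# scale (both excess functions are monotone and cross once), so roots many
# orders of magnitude below the totals are still resolved to full precision.
oracle_ternary_bisect <- function(r_tot, g_tot, l_tot, k_l, alpha, k_g,
                                  iters = 90) {
  species <- function(r, g) {
    l <- l_tot / (1 + r / k_l + alpha * r * g / (k_l * k_g))
    list(L = l, R = r, G = g,
         LR = l * r / k_l, RG = r * g / k_g,
         LRG = alpha * l * r * g / (k_l * k_g))
  }
  g_excess <- function(r, g) {
    s <- species(r, g)
    g + s$RG + s$LRG - g_tot
  }
  g_of_r <- function(r) {
    if (g_tot == 0) return(0)
    lo <- log(g_tot) - 90; hi <- log(g_tot)
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (g_excess(r, exp(mid)) > 0) hi <- mid else lo <- mid
    }
    exp((lo + hi) / 2)
  }
  r_excess <- function(r) {
    s <- species(r, g_of_r(r))
    r + s$LR + s$RG + s$LRG - r_tot
  }
  lo <- log(r_tot) - 90; hi <- log(r_tot)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (r_excess(exp(mid)) > 0) hi <- mid else lo <- mid
  }
  r <- exp((lo + hi) / 2)
  species(r, g_of_r(r))
}

# Dihedral via an independent construction: angle between the bond-plane
# normals from acos, signed by the triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# Brute-force centered moving mean over a time window.
oracle_moving_average <- function(t, x, window_ns) {
  vapply(seq_along(t), function(i) {
    mean(x[abs(t - t[i]) <= window_ns / 2 + 1e-9])
  }, numeric(1))
}

# Exhaustive Mann-Whitney enumeration over all C(n_a + n_b, n_a) rank
# assignments (no ties): two-sided p for the observed U.
oracle_mwu_exact <- function(a, b) {
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  us <- colSums(matrix(seq_len(n)[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small builders used across test files.
make_feature_series <- function(df) {
  structure(df, class = c("feature_series", "data.frame"))
}

op_spec <- function(..., conc = seq(-10, -4, length.out = 8)) {
  defaults <- list(basal = 2, em = 100, log_ka = -7, log_tau = 0.5,
                   conc_grid = conc, n_replicates = 3, noise_sd = 0, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(dose_response_spec, args)
}
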