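# Resampling and rank statistics for simulation comparisons: percentile
# bootstrap CIs of the mean and the two-sided Mann-Whitney U test.

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the values with replacement, takes the mean of each resample and
#' returns order-statistic (percentile) endpoints. 68% intervals are the
#' convention for non-parametric per-simulation summaries (roughly one
#' standard error).
#'
#' @param values numeric vector (>= 1 finite value).
#' @param level interval level in (0, 1), default 0.68.
#' @param n_boot number of resamples (default 10000).
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @return a list with `mean` (the sample mean), `ci_low`, `ci_high`,
#'   `level`, `n_boot`.
#' @export
bootstrap_ci <- function(values, level = 0.68, n_boot = 10000, seed = 1L) {
  check_that(is.numeric(values) && length(values) >= 1 && all(is.finite(values)),
             "`values` must be a non-empty finite numeric vector")
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(n_boot, "n_boot", lower = 1)
  n <- length(values)
  set.seed(seed)
  # chunked so that frame-level inputs (n large) stay within memory
  chunk <- max(1L, min(n_boot, ceiling(2e7 / n)))
  means <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    idx <- sample.int(n, n * k, replace = TRUE)
    means[done + seq_len(k)] <- colMeans(matrix(values[idx], nrow = n))
    done <- done + k
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- stats::quantile(means, probs, type = 1, names = FALSE)
  list(mean = mean(values), ci_low = ci[1], ci_high = ci[2],
       level = level, n_boot = as.integer(n_boot))
}

# Exact null distribution of the Mann-Whitney U statistic (no ties):
# counts[u + 1] = number of the C(n_a + n_b, n_a) orderings with U = u, via
# the recurrence c(i, j, u) = c(i-1, j, u-j) + c(i, j-1, u) (largest pooled
# value is an a beating all j b's, or a b contributing nothing).
mwu_exact_counts <- function(n_a, n_b) {
  max_u <- n_a * n_b
  delta0 <- c(1, rep(0, max_u))
  prev <- rep(list(delta0), n_b + 1)     # i = 0 row
  for (i in seq_len(n_a)) {
    cur <- vector("list", n_b + 1)
    cur[[1]] <- delta0                   # j = 0
    for (j in seq_len(n_b)) {
      shifted <- c(rep(0, j), prev[[j + 1]][seq_len(max_u + 1 - j)])
      cur[[j + 1]] <- shifted + cur[[j]]
    }
    prev <- cur
  }
  prev[[n_b + 1]]
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from midranks (so ties are handled). The p value is exact by
#' enumeration of the null distribution when `n_a * n_b <= 400` and there are
#' no ties; otherwise a normal approximation with continuity and tie
#' correction is used. The method actually applied is recorded in the result.
#'
#' @param a,b numeric vectors (>= 1 value each).
#' @param alternative only `"two.sided"` is implemented.
#' @return a list with `U` (for sample `a`), `p`, `method` (`"exact"` or
#'   `"normal"`), `n_a`, `n_b`. `U(a, b) + U(b, a) = n_a * n_b` always.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  check_that(identical(alternative, "two.sided"),
             "only the two-sided alternative is implemented")
  check_that(is.numeric(a) && length(a) >= 1 && all(is.finite(a)),
             "`a` must be a non-empty finite numeric vector")
  check_that(is.numeric(b) && length(b) >= 1 && all(is.finite(b)),
             "`b` must be a non-empty finite numeric vector")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (!has_ties && n_a * n_b <= 400) {
    counts <- mwu_exact_counts(n_a, n_b)
    total <- sum(counts)
    p_le <- sum(counts[seq_len(u + 1)]) / total
    p_ge <- sum(counts[(u + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n_a * n_b / 12 * ((n + 1) - tie_term))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sigma     # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal"
  }
  list(U = u, p = p, method = method, n_a = n_a, n_b = n_b)
}

#' Compare two groups of per-simulation frequencies
#'
#' Convenience wrapper combining [bootstrap_ci()] per group with the
#' two-sided [mann_whitney_u()] test between groups.
#'
#' @param a,b numeric vectors of per-simulation values.
#' @param labels character vector of two group labels.
#' @param level CI level (default 0.68).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return a list with `groups` (data frame: label, n, mean, ci_low,
#'   ci_high) and `test` (the Mann-Whitney result).
#' @export
compare_groups <- function(a, b, labels = c("a", "b"), level = 0.68,
                           n_boot = 10000, seed = 1L) {
  ci_a <- bootstrap_ci(a, level = level, n_boot = n_boot, seed = seed)
  ci_b <- bootstrap_ci(b, level = level, n_boot = n_boot, seed = seed + 1L)
  groups <- data.frame(
    label = labels, n = c(length(a), length(b)),
    mean = c(ci_a$mean, ci_b$mean),
    ci_low = c(ci_a$ci_low, ci_b$ci_low),
    ci_high = c(ci_a$ci_high, ci_b$ci_high),
    stringsAsFactors = FALSE
  )
  list(groups = groups, test = mann_whitney_u(a, b))
}
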