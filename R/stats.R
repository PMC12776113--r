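# Exact tests and transforms used throughout the pipeline. Both tests are
# implemented here directly (point-probability binomial; midrank U with an
# exact null distribution by dynamic programming) rather than delegated, so
# that their definitions are explicit and unit-testable against brute-force
# enumeration.

#' Exact two-sided binomial test (point-probability method)
#'
#' Computes the two-sided p-value for observing `x` successes in `n`
#' Bernoulli trials under a null success probability `p0`. The two-sided
#' p-value is defined by the point-probability rule: it sums \eqn{\Pr(X = k)}
#' over every outcome `k` whose point probability does not exceed
#' \eqn{\Pr(X = x) (1 + 10^{-7})}. The small relative tolerance guards
#' against ties in point probabilities being broken by floating-point noise;
#' it matters for asymmetric nulls such as `p0 = 53/55`. All point
#' probabilities are handled in log space.
#'
#' @param x Observed number of successes (integer, `0 <= x <= n`).
#' @param n Number of trials (positive integer).
#' @param p0 Null success probability in `[0, 1]`.
#'
#' @return A single p-value in `(0, 1]`.
#'
#' @examples
#' binom_test_exact(23, 37, 0.5)   # no parent-child bias detectable
#' binom_test_exact(44, 53, 0.5)   # strong bias toward child loss
#' @export
binom_test_exact <- function(x, n, p0) {
  if (length(x) != 1L || length(n) != 1L || length(p0) != 1L)
    stop("x, n and p0 must be scalars", call. = FALSE)
  if (!is.finite(x) || !is.finite(n) || x != round(x) || n != round(n))
    stop("x and n must be integers", call. = FALSE)
  if (n < 1 || x < 0 || x > n)
    stop("require 0 <= x <= n with n >= 1", call. = FALSE)
  if (!is.finite(p0) || p0 < 0 || p0 > 1)
    stop("p0 must lie in [0, 1]", call. = FALSE)

  ld <- stats::dbinom(0:n, n, p0, log = TRUE)
  lx <- ld[x + 1L]
  keep <- ld <= lx + log1p(1e-7)
  lk <- ld[keep]
  # log-sum-exp over the retained outcomes
  m <- max(lk)
  p <- if (is.finite(m)) exp(m + log(sum(exp(lk - m)))) else 0
  min(1, max(p, .Machine$double.xmin))
}

# Exact null distribution of the Mann-Whitney U statistic for tie-free
# samples of sizes m and n: counts[u + 1] = number of the choose(m + n, m)
# rank assignments with U_A = u. Recurrence on whether the largest remaining
# rank belongs to sample A (it then beats every B observation, contributing
# j wins) or to sample B:
#   c(u; k, j) = c(u - j; k - 1, j) + c(u; k, j - 1)
# with c(u; k, 0) = c(u; 0, j) = [u == 0].
mw_count_dist <- function(m, n) {
  len <- m * n + 1L
  cur <- lapply(0:m, function(k) { v <- numeric(len); v[1L] <- 1; v })
  for (j in seq_len(n)) {
    nxt <- vector("list", m + 1L)
    v0 <- numeric(len)
    v0[1L] <- 1
    nxt[[1L]] <- v0
    for (k in seq_len(m)) {
      shifted <- c(numeric(j), nxt[[k]][seq_len(len - j)])
      nxt[[k + 1L]] <- shifted + cur[[k + 1L]]
    }
    cur <- nxt
  }
  cur[[m + 1L]]
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-based comparison of two independent samples. The U statistic is
#' computed from midranks, so tied observations each contribute 1/2. The
#' reported statistic is U for `sample_a` (number of pairs `(a, b)` with
#' `a > b`, ties counting 1/2); `U_a + U_b = n_a * n_b` always holds.
#'
#' With `mode = "auto"` the exact null distribution is enumerated when both
#' samples have at most 10 observations and no value is tied (within or
#' across samples); otherwise the normal approximation with tie correction
#' and continuity correction is used. `mode = "exact"` forces enumeration for
#' any tie-free samples; `mode = "approx"` forces the approximation. Exact
#' mode with ties falls back to the approximation with a warning, since the
#' enumerated distribution assumes distinct values.
#'
#' @param sample_a,sample_b Numeric vectors; `NA` values are dropped.
#' @param mode One of `"auto"`, `"exact"`, `"approx"`.
#'
#' @return A list with elements `u_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#'
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # exact p = 0.1
#' @export
mann_whitney <- function(sample_a, sample_b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0L)
    stop("sample_a is empty after missing-value removal", call. = FALSE)
  if (length(b) == 0L)
    stop("sample_b is empty after missing-value removal", call. = FALSE)
  m <- length(a)
  n <- length(b)

  r <- rank(c(a, b))            # midranks
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)

  use_exact <- !has_ties && (mode == "exact" || (mode == "auto" && m <= 10L && n <= 10L))
  if (mode == "exact" && has_ties) {
    warning("ties present; falling back to normal approximation", call. = FALSE)
  }

  if (use_exact) {
    counts <- mw_count_dist(m, n)
    total <- sum(counts)
    lower <- sum(counts[seq_len(u + 1L)]) / total        # P(U <= u)
    upper <- sum(counts[(u + 1L):(m * n + 1L)]) / total  # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- m * n / 2
    nt <- as.numeric(ties)
    sigma2 <- (m * n / 12) * ((m + n + 1) - sum(nt^3 - nt) / ((m + n) * (m + n - 1)))
    if (sigma2 <= 0) {
      p <- 1   # all observations identical
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approx"
  }

  list(u_statistic = u, p_value = max(p, .Machine$double.xmin),
       method = method, n_a = m, n_b = n)
}

#' Log transforms for feature comparisons
#'
#' Applies one of the three log10 transforms used for feature distributions,
#' with per-feature (not per-gene) exclusion of unusable values:
#'
#' * `log10_plus1` - `log10(v + 1)`; only missing values are excluded.
#'   Used for expression (FPKM) and interaction counts, which may be zero.
#' * `log10_ratio` - `log10(v)`; missing and nonpositive values are excluded.
#'   Used for Ka/Ks ratios.
#' * `log10_raw` - `log10(v)`; missing and nonpositive values are excluded.
#'   Used for TM-scores and pLDDT, which are positive on their scales.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param transform Transform name (see above).
#'
#' @return List with `values` (transformed, exclusions dropped) and
#'   `n_excluded`.
#' @export
apply_transform <- function(values, transform = c("log10_plus1", "log10_ratio", "log10_raw")) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(values))
  if (transform == "log10_plus1") {
    keep <- !is.na(values)
    out <- log10(values[keep] + 1)
  } else {
    keep <- !is.na(values) & values > 0
    out <- log10(values[keep])
  }
  list(values = out, n_excluded = sum(!keep))
}

#' Significance star label for a p-value
#'
#' Maps a p-value to the conventional star annotation with strict
#' thresholds: `***` if p < 0.001, `**` if p < 0.01, `*` if p < 0.05,
#' otherwise `ns`.
#'
#' @param p_value p-value(s) in `(0, 1]`.
#' @return Character vector of labels.
#' @export
star_label <- function(p_value) {
  stopifnot(all(p_value > 0 & p_value <= 1))
  ifelse(p_value < 0.001, "***",
         ifelse(p_value < 0.01, "**",
                ifelse(p_value < 0.05, "*", "ns")))
}
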