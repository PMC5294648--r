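#' Maximum Betti-0 curve difference (diff_max)
#'
#' The barcode-contrast statistic: evaluate `beta0_A - beta0_B` at every
#' breakpoint of either curve (step functions only change at breakpoints, so
#' the union of breakpoints covers every value a dense grid would find) and
#' return the signed difference of maximal absolute value. Ties on the
#' absolute value are broken by the smallest epsilon, then by positive sign.
#'
#' @param curve_a,curve_b `betti_curve` objects over the same partition size.
#' @return A `diff_max` object: list with `value` (signed) and
#'   `epsilon_at_max`.
#' @export
diff_max <- function(curve_a, curve_b) {
  if (curve_a$n0 != curve_b$n0)
    .xfnet_error("curves must be over the same partition size",
                 "xfnet_error_partition")
  grid <- sort(unique(c(0, curve_a$breakpoints, curve_b$breakpoints)))
  d <- betti_at(curve_a, grid) - betti_at(curve_b, grid)
  m <- max(abs(d))
  idx <- which(abs(d) == m)
  # grid is sorted: the first index is the smallest epsilon; a +/- tie at one
  # epsilon is impossible, but prefer the positive sign among equal-eps picks
  pos <- idx[d[idx] > 0]
  pick <- if (length(pos) && min(pos) == min(idx)) min(pos) else min(idx)
  structure(list(value = d[pick], epsilon_at_max = grid[pick]),
            class = "diff_max")
}

# fast path used by permutation engines: diff_max value from death vectors
# (already sorted: the kernel emits merges in ascending epsilon order)
.diffmax_value <- function(deaths_a, deaths_b, n0) {
  grid <- sort.int(unique(c(0, deaths_a, deaths_b)), method = "quick")
  d <- findInterval(grid, deaths_b) - findInterval(grid, deaths_a)
  d[which.max(abs(d))]
}

#' Wilcoxon signed-rank contrast between network types
#'
#' Tests per-subject `diff_max` values (time-delayed cross-frequency versus
#' non-time-delayed within-frequency curves, one value per subject) against
#' zero with a two-sided Wilcoxon signed-rank test (exact when feasible,
#' normal approximation otherwise). Zeros are dropped before ranking, as in
#' the standard signed-rank procedure; an all-zero input returns p = 1 by
#' convention.
#'
#' @param per_subject_diffmax Numeric vector, one value per subject, n >= 5.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
network_type_contrast <- function(per_subject_diffmax) {
  v <- as.numeric(per_subject_diffmax)
  if (length(v) < 5)
    .xfnet_error("need at least 5 subjects", "xfnet_error_n")
  nz <- v[v != 0]
  if (length(nz) == 0)
    return(list(statistic = 0, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Signal-detection d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with `z` the standard-normal
#' quantile. Extreme rates of 0 or 1 are replaced by `1/(2N)` and
#' `1 - 1/(2N)` (log-linear guard), so the score is always finite.
#'
#' Used for both behavioral scores: instruction compliance (R-hits versus
#' NR-hits) and memory performance (R-hits versus false alarms).
#'
#' @param hit_count,hit_total Hits and their trial total (total >= 1).
#' @param fa_count,fa_total False alarms (or the comparison hit class) and
#'   their trial total.
#' @return d-prime, a real number.
#' @examples
#' dprime(57, 100, 24, 100)
#' @export
dprime <- function(hit_count, hit_total, fa_count, fa_total) {
  if (hit_total < 1 || fa_total < 1)
    .xfnet_error("trial totals must be >= 1", "xfnet_error_counts")
  if (hit_count < 0 || hit_count > hit_total || fa_count < 0 || fa_count > fa_total)
    .xfnet_error("counts must be non-negative and bounded by their totals",
                 "xfnet_error_counts")
  stats::qnorm(.guard_rate(hit_count, hit_total)) -
    stats::qnorm(.guard_rate(fa_count, fa_total))
}

.guard_rate <- function(k, n) {
  r <- k / n
  r[r == 0] <- 1 / (2 * n)
  r[r == 1] <- 1 - 1 / (2 * n)
  r
}

#' Behavior correlation with Bonferroni correction
#'
#' Pearson correlation between a per-subject network quantity (e.g. the
#' single-linkage condition difference at one regional pair, or per-subject
#' `diff_max`) and a behavioral score, with a two-sided t-based p-value
#' (n - 2 degrees of freedom) and `p_bonferroni = min(1, p * m_tests)`.
#'
#' @param values,behavior Numeric vectors of equal length, n >= 4.
#' @param m_tests Number of tests in the family (e.g. the number of flagged
#'   regional pairs).
#' @return A list with `r`, `p` and `p_bonferroni`.
#' @export
behavior_correlation <- function(values, behavior, m_tests = 1) {
  values <- as.numeric(values); behavior <- as.numeric(behavior)
  if (length(values) != length(behavior))
    .xfnet_error("values and behavior must have equal length", "xfnet_error_n")
  if (length(values) < 4)
    .xfnet_error("need at least 4 subjects", "xfnet_error_n")
  if (stats::sd(values) == 0 || stats::sd(behavior) == 0)
    .xfnet_error("zero variance in correlation input", "xfnet_error_variance")
  ct <- stats::cor.test(values, behavior, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       p_bonferroni = min(1, ct$p.value * m_tests))
}

# one-sample / paired t statistic with the degenerate-spread convention:
# sd 0 and mean 0 -> t = 0 (p will be 1); sd 0 and mean != 0 -> +/- Inf
.tstat <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / (s / sqrt(length(x)))
}

# columnwise version for n x k matrices of per-subject values
.tstat_cols <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(colSums((X - rep(m, each = n))^2) / (n - 1))
  t <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  t
}
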