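#' Exact small-sample nonparametric tests
#'
#' Exact (enumeration-based) Mann-Whitney U and Wilcoxon signed-rank tests,
#' rank-biserial effect sizes and Hodges-Lehmann shift estimates with exact
#' distribution-free confidence intervals. These are the statistics suited
#' to group sizes of around five animals per arm, where asymptotic
#' approximations are unreliable: all p-values and critical values come
#' from the exact null distributions, computed by convolution recursions
#' equivalent to full enumeration of group assignments (U) or sign vectors
#' (signed rank).
#'
#' @name exact_tests
NULL

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for each attainable value u = 0..n1*n2, the number of the
#' choose(n1+n2, n1) equally likely group assignments of untied ranks that
#' produce U = u.
#'
#' @param n1,n2 group sizes.
#' @return Numeric vector of counts, index i holding the count for
#'   U = i - 1. Sums to `choose(n1 + n2, n1)`.
#' @export
mwu_null_counts <- function(n1, n2) {
  n <- n1 + n2
  smax <- n1 * n2 + n1 * (n1 + 1) / 2  # max rank sum of group 1
  # w[j + 1, s + 1]: subsets of {1..r} of size j with rank sum s
  w <- matrix(0, n1 + 1, smax + 1)
  w[1, 1] <- 1
  for (r in seq_len(n)) {
    for (j in min(r, n1):1) {
      w[j + 1, (r + 1):(smax + 1)] <-
        w[j + 1, (r + 1):(smax + 1)] + w[j, 1:(smax + 1 - r)]
    }
  }
  # U = ranksum - n1 (n1 + 1) / 2
  counts <- w[n1 + 1, (n1 * (n1 + 1) / 2 + 1):(smax + 1)]
  names(counts) <- 0:(n1 * n2)
  counts
}

#' Exact Mann-Whitney U test
#'
#' Two-sided exact test for a location difference between two independent
#' samples. The statistic is U = number of pairs (a_i, b_j) with
#' `b_j > a_i`, counting ties as 1/2. The two-sided p-value is
#' `2 * min(P(U <= u), P(U >= u))` under the exact untied null, capped
#' at 1.
#'
#' @param a,b numeric samples.
#' @return List with `statistic` (U), `p_value`, `n1`, `n2`.
#' @examples
#' exact_mann_whitney(1:5, 6:10)$p_value  # 2/252, prints as 0.008
#' @export
exact_mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n1 <- length(a); n2 <- length(b)
  cmp <- outer(a, b, function(x, y) (y > x) + 0.5 * (y == x))
  u <- sum(cmp)
  pooled <- c(a, b)
  if (anyDuplicated(pooled)) {
    # ties: exact permutation null of U conditional on the observed values
    counts <- mwu_tied_null_counts(rank(pooled), n1)
  } else {
    counts <- mwu_null_counts(n1, n2)
  }
  total <- sum(counts)
  support <- as.numeric(names(counts))
  p_le <- sum(counts[support <= u + 1e-9]) / total
  p_ge <- sum(counts[support >= u - 1e-9]) / total
  list(statistic = u, p_value = min(1, 2 * min(p_le, p_ge)),
       n1 = n1, n2 = n2)
}

# Exact permutation null of U for tied data: counts of U over all
# C(n, n1) assignments of the observed midranks to group 1, computed by a
# subset-sum DP on doubled midranks (integers even with average ranks).
# U = n1*n2 - (ranksum(group 1) - n1(n1+1)/2) with half-counted ties.
mwu_tied_null_counts <- function(midranks, n1) {
  n <- length(midranks)
  n2 <- n - n1
  r2 <- round(midranks * 2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  w <- matrix(0, n1 + 1, smax + 1)
  w[1, 1] <- 1
  for (r in r2) {
    for (j in min(n1, n):1) {
      idx <- (r + 1):(smax + 1)
      w[j + 1, idx] <- w[j + 1, idx] + w[j, idx - r]
    }
  }
  counts <- w[n1 + 1, ]
  keep <- counts > 0
  ranksum <- (0:smax)[keep] / 2
  u <- n1 * n2 - (ranksum - n1 * (n1 + 1) / 2)
  out <- counts[keep][order(u)]
  names(out) <- sort(u)
  out
}

# Null counts of the positive-rank sum W+ over all 2^n sign vectors.
# ranks may contain average (half-integer) ranks; doubled internally.
signed_rank_null_counts <- function(ranks) {
  scale <- if (max(abs(ranks - round(ranks))) < 1e-9) 1 else 2
  rs <- round(ranks * scale)
  if (max(abs(ranks * scale - rs)) > 1e-9)
    stop("ranks must be integers or half-integers")
  smax <- sum(rs)
  g <- numeric(smax + 1)
  g[1] <- 1
  for (r in rs) {
    shifted <- c(numeric(r), g[seq_len(smax + 1 - r)])
    g <- g + shifted
  }
  names(g) <- (0:smax) / scale
  g
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test on paired differences. Zero differences are
#' dropped; tied absolute differences receive average ranks. The statistic
#' W is the smaller of the positive- and negative-rank sums; the two-sided
#' p-value is `2 * min(P(W+ <= w+), P(W+ >= w+))` over all 2^n equally
#' likely sign assignments, capped at 1.
#'
#' @param diffs paired differences.
#' @return List with `statistic` (W), `w_plus`, `w_minus`, `p_value`,
#'   `n` (nonzero differences used), `n_zero` (dropped).
#' @examples
#' exact_wilcoxon_signed_rank(c(1, 2, 3, 4))$p_value  # 2/16 = 0.125
#' @export
exact_wilcoxon_signed_rank <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (anyNA(diffs)) stop("differences must not contain NA")
  n_zero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  if (!length(d)) stop("all differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  counts <- signed_rank_null_counts(r)
  total <- sum(counts)
  support <- as.numeric(names(counts))  # 0..sum(r) in steps of 1/2
  p_le <- sum(counts[support <= w_plus + 1e-9]) / total
  p_ge <- sum(counts[support >= w_plus - 1e-9]) / total
  list(statistic = min(w_plus, w_minus), w_plus = w_plus,
       w_minus = w_minus, p_value = min(1, 2 * min(p_le, p_ge)),
       n = length(d), n_zero = n_zero)
}

#' Rank-biserial correlation for two independent samples
#'
#' `r = (favorable - unfavorable) / (n1 * n2)` where favorable counts
#' cross-group pairs in which the first sample's value is larger; tied
#' pairs contribute zero. The sign indicates direction: positive means the
#' first sample tends to be larger.
#'
#' @param a,b numeric samples; `a` is the reference (first) sample.
#' @return Effect size in `[-1, 1]`.
#' @export
rank_biserial_unpaired <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  fav <- sum(outer(a, b, ">"))
  unfav <- sum(outer(a, b, "<"))
  (fav - unfav) / (length(a) * length(b))
}

#' Matched-pairs rank-biserial correlation
#'
#' `r = (W+ - W-) / (n (n + 1) / 2)` on the nonzero paired differences,
#' with average ranks for ties.
#'
#' @param diffs paired differences.
#' @return Effect size in `[-1, 1]`.
#' @export
rank_biserial_paired <- function(diffs) {
  d <- diffs[diffs != 0]
  if (!length(d)) stop("all differences are zero")
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / (length(d) * (length(d) + 1) / 2)
}

#' Hodges-Lehmann shift estimate with exact confidence interval
#'
#' Point estimate: the median of all n1*n2 pairwise differences
#' `a_i - b_j`. The exact (1 - alpha) confidence interval is
#' `[d_(k), d_(N + 1 - k)]` among the N = n1*n2 sorted pairwise
#' differences, with `k = U_crit + 1` where U_crit is the largest u such
#' that `2 * P(U <= u) <= alpha` under the exact Mann-Whitney null. When
#' even u = 0 exceeds the requested coverage the widest attainable
#' interval (k = 1) is returned and flagged.
#'
#' @param a,b numeric samples (n1, n2 >= 2); the shift is in the direction
#'   `a - b`.
#' @param conf_level confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high`, `conf_level`,
#'   `k`, and `flag` (`""` or `"coverage_unattainable"`).
#' @export
hodges_lehmann <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2) stop("need n1, n2 >= 2")
  d <- sort(as.vector(outer(a, b, "-")))
  n1 <- length(a); n2 <- length(b)
  counts <- mwu_null_counts(n1, n2)
  cdf <- cumsum(counts) / sum(counts)
  alpha <- 1 - conf_level
  ok <- which(2 * cdf <= alpha)  # index i corresponds to u = i - 1
  flag <- ""
  if (!length(ok)) {
    k <- 1L
    flag <- "coverage_unattainable"
  } else {
    k <- max(ok)  # u_crit = max(ok) - 1, k = u_crit + 1
  }
  n <- length(d)
  list(estimate = stats::median(d), ci_low = d[k], ci_high = d[n + 1 - k],
       conf_level = conf_level, k = k, flag = flag)
}

#' Hodges-Lehmann estimate for paired differences
#'
#' One-sample analogue used for paired comparisons: the median of the
#' Walsh averages `(d_i + d_j)/2, i <= j`, with the exact signed-rank
#' confidence interval (`k = W_crit + 1` where W_crit is the largest w
#' with `2 * P(W+ <= w) <= alpha`).
#'
#' @param diffs paired differences (>= 2 nonzero).
#' @param conf_level confidence level.
#' @return As [hodges_lehmann()].
#' @export
hodges_lehmann_paired <- function(diffs, conf_level = 0.95) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n < 2) stop("need at least 2 nonzero differences")
  w <- outer(d, d, "+") / 2
  walsh <- sort(w[upper.tri(w, diag = TRUE)])
  counts <- signed_rank_null_counts(seq_len(n))
  cdf <- cumsum(counts) / sum(counts)
  alpha <- 1 - conf_level
  ok <- which(2 * cdf <= alpha)
  flag <- ""
  if (!length(ok)) {
    k <- 1L
    flag <- "coverage_unattainable"
  } else {
    k <- max(ok)
  }
  m <- length(walsh)
  list(estimate = stats::median(walsh), ci_low = walsh[k],
       ci_high = walsh[m + 1 - k], conf_level = conf_level, k = k,
       flag = flag)
}
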