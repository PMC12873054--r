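# Shared fixtures and independent brute-force oracles for the test suite.

study_grid <- function() time_grid(65, 6.6)
study_aif <- function() make_aif(study_grid(), arrival_frame = 5,
                                 amplitude = 50)

# --- exact-test oracles (full enumeration, independent of the package's
# convolution recursions) ---

# Two-sided exact Mann-Whitney p by enumerating all C(n1+n2, n1) group
# assignments of the pooled observed values.
enum_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, function(p, q) (q > p) +
                                       0.5 * (q == p)))
  u_obs <- u_stat(a, b)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Null PMF of U by enumeration of rank subsets.
enum_mwu_counts <- function(n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  tabulate(us + 1, nbins = n1 * n2 + 1)
}

# Two-sided exact signed-rank p by enumerating all 2^n sign vectors.
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

enum_signed_rank_counts <- function(n) {
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% seq_len(n)
  tabulate(ws + 1, nbins = n * (n + 1) / 2 + 1)
}

# Hodges-Lehmann by direct definition.
brute_hl_estimate <- function(a, b) median(as.vector(outer(a, b, "-")))

# Direct trapezoidal convolution by explicit summation (independent of the
# package's FFT-based path).
conv_oracle <- function(f, g, dt_min) {
  n <- length(f)
  out <- numeric(n)
  for (k in 2:n) {
    j <- 1:k
    prod <- f[j] * g[k - j + 1]
    out[k] <- dt_min * (sum(prod) - 0.5 * prod[1] - 0.5 * prod[k])
  }
  out
}

# Patlak OLS via the explicit normal equations.
normal_eq_patlak <- function(ct, input, idx) {
  x <- cbind(cumulative_integral(input), input$cp)[idx, ]
  y <- ct[idx]
  solve(t(x) %*% x, t(x) %*% y)
}
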