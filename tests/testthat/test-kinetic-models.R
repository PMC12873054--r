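test_that("cumulative integral is the trapezoidal rule in minutes", {
  g <- time_grid(3, dt = 30)
  expect_equal(cumulative_integral(aif(g, c(0, 2, 4))), c(0, 0.5, 2.0))
  expect_equal(cumulative_integral(aif(g, rep(0, 3))), rep(0, 3))
  g4 <- time_grid(4, dt = 60)
  expect_equal(cumulative_integral(aif(g4, rep(1, 4))), c(0, 1, 2, 3))
})

test_that("Patlak forward matches its closed form for a constant AIF", {
  g <- time_grid(10, dt = 60)
  a <- aif(g, rep(1, 10))
  expect_equal(patlak_forward(0, 0, a)$ct, rep(0, 10))
  expect_equal(patlak_forward(0, 0.3, a)$ct, rep(0.3, 10))
  expect_equal(patlak_forward(0.06, 0.1, a)$ct, 0.1 + 0.06 * (0:9))
})

test_that("extended Tofts nests Patlak at kep = 0 and matches its constant-AIF closed form", {
  a <- study_aif()
  et <- extended_tofts_forward(0.0287, 0, 0.219, a)$ct
  pk <- patlak_forward(0.0287, 0.219, a)$ct
  expect_equal(et, pk, tolerance = 1e-12)
  expect_equal(extended_tofts_forward(0, 0.3, 0.2, a)$ct, 0.2 * a$cp)
  # constant AIF: ct -> vp + (k/e)(1 - exp(-e t)) within 1% at dt = 6.6 s
  g <- study_grid()
  ac <- aif(g, rep(1, 65))
  k <- 0.1; e <- 0.5; vp <- 0.2
  ct <- extended_tofts_forward(k, e, vp, ac)$ct
  t_min <- frame_times(g, "min")
  closed <- vp + (k / e) * (1 - exp(-e * t_min))
  expect_lt(max(abs(ct[-1] - closed[-1]) / closed[-1]), 0.01)
})

test_that("uptake model: vascular limit, zero input, and asymptotic leakage slope", {
  a <- study_aif()
  g <- study_grid()
  # ps = 0 reduces to a pure vascular compartment fp * exp(-t fp / vp)
  t_min <- frame_times(g, "min")
  direct <- conv_oracle(a$cp, 0.4 * exp(-t_min * 0.4 / 0.2), g$dt / 60)
  expect_equal(uptake_forward(0.4, 0, 0.2, a)$ct, direct, tolerance = 1e-12)
  expect_equal(uptake_forward(0.4, 0.1, 0.2, aif(g, rep(0, 65)))$ct,
               rep(0, 65))
  # constant input: late slope of ct equals fp * E per minute
  ac <- aif(g, rep(1, 65))
  ct <- uptake_forward(0.4, 0.1, 0.2, ac)$ct
  slope <- (ct[65] - ct[60]) / (t_min[65] - t_min[60])
  expect_equal(slope, 0.4 * 0.1 / 0.5, tolerance = 0.01)
})

test_that("exchange model: shared limit with uptake, confluent form, mass conservation", {
  a <- study_aif()
  ex <- exchange_forward(0.5, 0, 0.2, 0.3, a)$ct
  up <- uptake_forward(0.5, 0, 0.2, a)$ct
  expect_lt(max(abs(ex - up)), 1e-9)
  expect_equal(exchange_forward(0.5, 0.1, 0.2, 0.3,
                                aif(study_grid(), rep(0, 65)))$ct,
               rep(0, 65))
  # residue area over [0, Inf) = total distribution volume vp + ve
  auc <- stats::integrate(function(t) exchange_residue(t, 0.5, 0.1, 0.2, 0.3),
                          0, 500, rel.tol = 1e-10)$value
  expect_equal(auc, 0.5, tolerance = 0.005)
  # R(0) = fp always
  expect_equal(exchange_residue(0, 0.7, 0.2, 0.15, 0.25), 0.7)
  # confluent parameters (equal rates) stay finite and continuous
  r <- exchange_residue(seq(0, 5, 0.1), 1, 1e-9, 0.5, 0.5)
  expect_true(all(is.finite(r)))
})

test_that("forward models are linear in the AIF and non-negative for physical inputs", {
  a <- study_aif()
  a2 <- aif(a$grid, 3.7 * a$cp)
  for (fwd in list(function(x) patlak_forward(0.03, 0.2, x)$ct,
                   function(x) extended_tofts_forward(0.03, 0.4, 0.2, x)$ct,
                   function(x) uptake_forward(0.4, 0.05, 0.2, x)$ct,
                   function(x) exchange_forward(0.4, 0.05, 0.2, 0.3, x)$ct)) {
    y1 <- fwd(a)
    expect_equal(fwd(a2), 3.7 * y1, tolerance = 1e-10)
    expect_true(all(y1 >= -1e-12))
  }
  # Patlak is linear in (ktrans, vp)
  expect_equal(patlak_forward(0.02, 0.1, a)$ct + patlak_forward(0.01, 0.15, a)$ct,
               patlak_forward(0.03, 0.25, a)$ct)
})

test_that("halving the frame spacing changes forward curves by under 1%", {
  g <- study_grid()
  a <- study_aif()
  g2 <- time_grid(2 * g$n_frames - 1, g$dt / 2)
  cp2 <- stats::approx(frame_times(g), a$cp, frame_times(g2))$y
  a2 <- aif(g2, cp2)
  coarse_idx <- seq(1, g2$n_frames, by = 2)
  for (pair in list(
    list(function(x) extended_tofts_forward(0.03, 0.4, 0.2, x)$ct),
    list(function(x) uptake_forward(0.4, 0.05, 0.2, x)$ct),
    list(function(x) exchange_forward(0.4, 0.05, 0.2, 0.3, x)$ct))) {
    fwd <- pair[[1]]
    y1 <- fwd(a)
    y2 <- fwd(a2)[coarse_idx]
    expect_lt(max(abs(y2 - y1)) / max(abs(y1)), 0.01)
  }
})

test_that("invalid grids and parameters are rejected", {
  expect_error(time_grid(1, 6.6), "n_frames")
  expect_error(time_grid(10, 0), "dt")
  g <- time_grid(5, 6.6)
  expect_error(aif(g, 1:4), "n_frames")
  a <- aif(g, c(0, 0, 1, 2, 1))
  expect_error(patlak_forward(-0.1, 0.2, a), "ktrans")
  expect_error(patlak_forward(0.1, 1.2, a), "vp")
  expect_error(exchange_forward(0.5, 0.1, 0.6, 0.6, a), "vp \\+ ve")
  expect_error(uptake_forward(0, 0.1, 0.2, a), "fp")
})
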