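test_that("noiseless Patlak curves are recovered to machine precision", {
  a <- study_aif()
  # internal forms of the 16-h group medians (2.87 mL/100 mL/min, 21.89 mL/100 mL)
  ct <- patlak_forward(0.0287, 0.219, a)
  fit <- fit_patlak(ct, a)
  expect_equal(fit$params$ktrans, 0.0287, tolerance = 1e-10)
  expect_equal(fit$params$vp, 0.219, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  # pure plasma curve
  fit2 <- fit_patlak(tissue_curve(a$grid, 0.3 * a$cp), a)
  expect_equal(fit2$params$ktrans, 0, tolerance = 1e-12)
  expect_equal(fit2$params$vp, 0.3, tolerance = 1e-12)
  # zero curve
  fit3 <- fit_patlak(tissue_curve(a$grid, rep(0, 65)), a)
  expect_equal(fit3$params$ktrans, 0)
  expect_equal(fit3$params$vp, 0)
  expect_equal(fit3$rss, 0)
})

test_that("Patlak OLS agrees with the normal-equations closed form on random designs", {
  set.seed(11)
  g <- time_grid(20, 6.6)
  for (i in 1:20) {
    cp <- c(0, 0, abs(rnorm(18, 5, 2)))
    a <- aif(g, cp, arrival_frame = 3)
    ct <- tissue_curve(g, rnorm(20))
    win <- fit_window(3, 20)
    fit <- fit_patlak(ct, a, win)
    ref <- normal_eq_patlak(ct$ct, a, 3:20)
    expect_equal(max(fit$params$ktrans, 0), max(ref[1], 0), tolerance = 1e-10)
    expect_equal(max(fit$params$vp, 0), max(ref[2], 0), tolerance = 1e-10)
  }
})

test_that("negative OLS estimates are clipped and flagged, rss kept unclipped", {
  a <- study_aif()
  # a decaying curve forces a negative ktrans slope
  ct <- tissue_curve(a$grid, 0.3 * a$cp - 0.02 * cumulative_integral(a))
  fit <- fit_patlak(ct, a)
  expect_equal(fit$params$ktrans, 0)
  expect_true("ktrans_clipped" %in% fit$flags)
  expect_lt(fit$rss, 1e-20)  # rss of the unclipped solution
})

test_that("singular or undersized Patlak designs error", {
  g <- time_grid(65, 6.6)
  zero <- aif(g, c(0, 0, 0, 0, 1e-9, rep(0, 60)))
  ct <- tissue_curve(g, rep(1, 65))
  expect_error(fit_patlak(ct, zero, fit_window(10, 65)), "singular")
  a <- study_aif()
  expect_error(fit_patlak(ct, a, fit_window(64, 65)), "at least 3 frames")
})

test_that("AIC penalizes parameters and tracks rss in closed form", {
  expect_equal(aic_score(10, 60, 3) - aic_score(10, 60, 2), 2)
  expect_equal(aic_score(5, 60, 2) - aic_score(10, 60, 2), -60 * log(2))
  expect_identical(aic_score(0, 60, 2), -Inf)
  expect_error(aic_score(1, 3, 2), "n_obs")
  # AICc adds the small-sample correction
  expect_equal(aic_score(10, 60, 2, corrected = TRUE) - aic_score(10, 60, 2),
               2 * 3 * 4 / (60 - 4))
})

test_that("nonlinear fits recover their own noiseless curves", {
  a <- study_aif()
  ct <- extended_tofts_forward(0.02, 0.2, 0.25, a)
  fit <- fit_nonlinear(ct, a, "extended_tofts", seed = 1)
  expect_equal(fit$params$ktrans, 0.02, tolerance = 1e-4)
  expect_equal(fit$params$kep, 0.2, tolerance = 1e-3)
  expect_equal(fit$params$vp, 0.25, tolerance = 1e-4)

  ct2 <- uptake_forward(0.4, 0.05, 0.2, a)
  fit2 <- fit_nonlinear(ct2, a, "uptake", seed = 1)
  expect_equal(fit2$params$fp, 0.4, tolerance = 1e-3)
  expect_equal(fit2$params$ps, 0.05, tolerance = 1e-3)
  expect_equal(fit2$params$vp, 0.2, tolerance = 1e-3)
})

test_that("richer nested models never fit worse than their restrictions", {
  a <- study_aif()
  set.seed(21)
  truth <- patlak_forward(0.0287, 0.219, a)$ct
  for (i in 1:5) {
    ct <- tissue_curve(a$grid, truth + rnorm(65, 0, 0.05 * max(a$cp)))
    pat <- fit_patlak(ct, a)
    et <- fit_nonlinear(ct, a, "extended_tofts", seed = i)
    expect_lte(et$rss, pat$rss + 1e-8)  # Patlak = extended Tofts, kep = 0
    up <- fit_nonlinear(ct, a, "uptake", seed = i)
    ex <- fit_nonlinear(ct, a, "exchange", seed = i)
    # the uptake model is the ve -> Inf limit of the exchange model, which
    # lies outside the physical bound ve <= 1, so the exchange fit can only
    # approach the uptake rss; 2% covers the residual backflux
    expect_lte(ex$rss, up$rss * 1.02 + 1e-8)
  }
})

test_that("fits are deterministic given the seed and zero curves hit the floor", {
  a <- study_aif()
  ct <- tissue_curve(a$grid,
                     patlak_forward(0.01, 0.2, a)$ct + sin(1:65))
  f1 <- fit_nonlinear(ct, a, "uptake", seed = 99)
  f2 <- fit_nonlinear(ct, a, "uptake", seed = 99)
  expect_identical(f1, f2)
  z <- fit_nonlinear(tissue_curve(a$grid, rep(0, 65)), a, "extended_tofts",
                     seed = 1)
  expect_lt(z$rss, 1e-10)
  expect_lt(z$params$ktrans * max(cumulative_integral(a)) +
              z$params$vp * max(a$cp), 1e-4)
})

test_that("model selection picks the generating model and breaks ties by parsimony", {
  a <- study_aif()
  # noiseless Patlak curve: all nested fits perfect, fewest parameters wins
  sel <- select_model(patlak_forward(0.0287, 0.219, a), a, seed = 1)
  expect_equal(sel$model, "patlak")
  # strongly biexponential exchange curve: exchange wins
  sel2 <- select_model(exchange_forward(0.5, 0.1, 0.2, 0.3, a), a, seed = 1)
  expect_equal(sel2$model, "exchange")
  tab <- attr(sel2, "selection")
  expect_setequal(tab$model, c("patlak", "extended_tofts", "uptake",
                               "exchange"))
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  # zero curve: parameter-count tie-break
  sel3 <- select_model(tissue_curve(a$grid, rep(0, 65)), a, seed = 1)
  expect_equal(sel3$model, "patlak")
})
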