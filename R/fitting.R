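#' Fit window
#'
#' Frame range (1-based, inclusive) used for kinetic fitting. The default
#' window in the fitting functions starts at the detected bolus-arrival
#' frame and ends at the last frame.
#'
#' @param start_frame first fitted frame.
#' @param end_frame last fitted frame.
#' @return An object of class `fit_window`.
#' @export
fit_window <- function(start_frame, end_frame) {
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (is.na(start_frame) || is.na(end_frame) ||
      start_frame < 1L || start_frame >= end_frame)
    stop("need 1 <= start_frame < end_frame")
  structure(list(start_frame = start_frame, end_frame = end_frame),
            class = "fit_window")
}

default_window <- function(input) {
  start <- input$arrival_frame
  if (is.null(start)) start <- detect_bolus_arrival(input$cp)
  fit_window(start, input$grid$n_frames)
}

window_idx <- function(window, n_frames) {
  if (window$end_frame > n_frames)
    stop("fit window extends past the last frame")
  seq(window$start_frame, window$end_frame)
}

#' Akaike information criterion for a least-squares fit
#'
#' `AIC = n * log(rss / n) + 2 * (k + 1)`, counting the residual variance
#' as an estimated parameter alongside the k kinetic parameters. The
#' small-sample corrected variant (AICc) adds
#' `2 (k+1) (k+2) / (n - k - 2)`.
#'
#' @param rss residual sum of squares (>= 0). `rss = 0` yields `-Inf`
#'   (a perfect fit dominates any finite score).
#' @param n_obs number of fitted observations.
#' @param n_params number of free kinetic parameters k.
#' @param corrected use AICc instead of AIC.
#' @return AIC score (possibly `-Inf`).
#' @export
aic_score <- function(rss, n_obs, n_params, corrected = FALSE) {
  if (n_obs <= n_params + 1) stop("n_obs must exceed n_params + 1")
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) return(-Inf)
  a <- n_obs * log(rss / n_obs) + 2 * (n_params + 1)
  if (corrected)
    a <- a + 2 * (n_params + 1) * (n_params + 2) / (n_obs - n_params - 2)
  a
}

new_kinetic_fit <- function(model, params, rss, n_obs, flags = character(),
                            corrected = FALSE, ss_total = NULL) {
  # residuals at the level of solver round-off are an exact fit: treat as
  # rss = 0 so model selection falls through to the parsimony tie-break
  if (!is.null(ss_total) && rss < 1e-12 * max(ss_total, 1)) rss <- 0
  n_params <- length(params)
  structure(list(model = model, params = params, rss = rss,
                 n_obs = n_obs, n_params = n_params,
                 aic = aic_score(rss, n_obs, n_params, corrected),
                 flags = flags),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit: %s> rss = %.4g, AIC = %.2f (n = %d)\n",
              x$model, x$rss, x$aic, x$n_obs))
  cat("  ", paste(sprintf("%s = %.5g", names(x$params), unlist(x$params)),
                  collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Shared OLS core for the Patlak design [cumulative integral, cp].
# y may be a matrix (frames x curves); returns coefficients, rss per curve.
patlak_ols <- function(x_design, y) {
  y <- as.matrix(y)
  xtx <- crossprod(x_design)
  if (!is.finite(rcond_2x2(xtx)) || rcond_2x2(xtx) < 1e-14)
    stop("singular Patlak design: AIF has no energy in the fit window")
  beta <- solve(xtx, crossprod(x_design, y))
  resid <- y - x_design %*% beta
  list(coef = beta, rss = colSums(resid^2))
}

rcond_2x2 <- function(m) {
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  s <- max(abs(m))
  if (s == 0) return(0)
  abs(d) / (s * s)
}

#' Fit the Patlak model to a tissue curve
#'
#' Ordinary least squares of the tissue enhancement on the two regressors
#' (running integral of the AIF, instantaneous AIF) over the fit window.
#' The slope on the integral term is `ktrans` (min^-1), the slope on the
#' plasma term is `vp`. Negative estimates are clipped to zero and flagged
#' (`"ktrans_clipped"` / `"vp_clipped"`); the reported residual sum of
#' squares is that of the unclipped least-squares solution.
#'
#' @param curve a [tissue_curve()].
#' @param input an [aif()] on the same grid.
#' @param window a [fit_window()]; default spans bolus arrival to the last
#'   frame.
#' @return A `kinetic_fit` with `params$ktrans` and `params$vp`.
#' @export
fit_patlak <- function(curve, input, window = NULL) {
  if (!same_grid(curve$grid, input$grid))
    stop("curve and AIF must share the same time grid")
  if (is.null(window)) window <- default_window(input)
  idx <- window_idx(window, input$grid$n_frames)
  if (length(idx) < 3L) stop("need at least 3 frames in the fit window")
  x <- cbind(cumulative_integral(input), input$cp)[idx, , drop = FALSE]
  fit <- patlak_ols(x, curve$ct[idx])
  ktrans <- fit$coef[1, 1]
  vp <- fit$coef[2, 1]
  flags <- character()
  if (ktrans < 0) { ktrans <- 0; flags <- c(flags, "ktrans_clipped") }
  if (vp < 0) { vp <- 0; flags <- c(flags, "vp_clipped") }
  new_kinetic_fit("patlak", list(ktrans = ktrans, vp = vp),
                  rss = unname(fit$rss), n_obs = length(idx), flags = flags,
                  ss_total = sum(curve$ct[idx]^2))
}

model_spec <- function(model) {
  switch(model,
    extended_tofts = list(
      par = c("ktrans", "kep", "vp"),
      lower = c(0, 0, 0), upper = c(10, 10, 1),
      fwd = function(p, input)
        extended_tofts_forward(p[1], p[2], p[3], input)$ct),
    uptake = list(
      par = c("fp", "ps", "vp"),
      lower = c(1e-6, 0, 1e-6), upper = c(10, 10, 1),
      fwd = function(p, input) uptake_forward(p[1], p[2], p[3], input)$ct),
    exchange = list(
      par = c("fp", "ps", "vp", "ve"),
      lower = c(1e-6, 0, 1e-6, 1e-6), upper = c(10, 10, 1, 1),
      fwd = function(p, input)
        exchange_forward(p[1], p[2], p[3], p[4], input)$ct),
    stop("unknown model: ", model)
  )
}

#' Fit a nonlinear compartment model by bounded multi-start least squares
#'
#' Minimizes the residual sum of squares of the named forward model
#' (`"extended_tofts"`, `"uptake"` or `"exchange"`) within physiological
#' bounds (rates in `[0, 10]` min^-1, volume fractions in `[0, 1]`, with
#' `vp + ve <= 1` enforced by penalty for the exchange model). Optimization
#' restarts from `n_starts` Latin-hypercube points; the result is
#' deterministic given the seed.
#'
#' In addition to the Latin-hypercube points, nested-model warm starts are
#' used so richer models never fit worse than their restrictions: the
#' extended Tofts fit starts once from the (closed-form) Patlak solution
#' with `kep = 0`, and the exchange fit starts once from the uptake
#' solution with `ve` at the volume bound.
#'
#' @inheritParams fit_patlak
#' @param model one of `"extended_tofts"`, `"uptake"`, `"exchange"`.
#' @param n_starts number of Latin-hypercube starting points.
#' @param seed RNG seed for the starting points.
#' @param warm_start optional numeric vector of model parameters used as
#'   an additional starting point (computed automatically when NULL).
#' @return A `kinetic_fit`.
#' @export
fit_nonlinear <- function(curve, input, model, window = NULL,
                          n_starts = 8L, seed = 1L, warm_start = NULL) {
  if (!same_grid(curve$grid, input$grid))
    stop("curve and AIF must share the same time grid")
  if (is.null(window)) window <- default_window(input)
  idx <- window_idx(window, input$grid$n_frames)
  spec <- model_spec(model)
  y <- curve$ct[idx]
  if (length(y) <= length(spec$par) + 1L)
    stop("too few frames in the fit window for ", model)

  obj <- function(p) {
    if (model == "exchange" && p[3] + p[4] > 1)
      return(1e12 * (p[3] + p[4]))
    sum((spec$fwd(p, input)[idx] - y)^2)
  }

  k <- length(spec$par)
  starts <- with_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(starts, 2, spec$upper - spec$lower, "*"),
                  2, spec$lower, "+")
  if (model == "exchange") {
    over <- starts[, 3] + starts[, 4] > 1
    starts[over, 3:4] <- starts[over, 3:4] * 0.99 /
      rowSums(starts[over, 3:4, drop = FALSE])
  }
  if (is.null(warm_start)) {
    warm_start <- tryCatch(switch(model,
      extended_tofts = {
        p <- fit_patlak(curve, input, window)$params
        c(p$ktrans, 0, min(p$vp, 1))
      },
      exchange = {
        p <- fit_nonlinear(curve, input, "uptake", window, n_starts,
                           seed)$params
        ve <- max(min(1 - p$vp - 1e-6, 1), 1e-6)
        c(p$fp, p$ps, p$vp, ve)
      },
      NULL), error = function(e) NULL)
  }
  if (!is.null(warm_start))
    starts <- rbind(pmin(pmax(warm_start, spec$lower), spec$upper), starts)

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], obj, lower = spec$lower, upper = spec$upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed for ", model)
  flags <- if (any_converged) character() else "not_converged"
  params <- as.list(best$par)
  names(params) <- spec$par
  new_kinetic_fit(model, params, rss = max(best$objective, 0),
                  n_obs = length(y), flags = flags, ss_total = sum(y^2))
}

# Evaluate expr with a private RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit all four models and select by AIC
#'
#' Fits the Patlak, extended Tofts, two-compartment uptake and
#' two-compartment exchange models to one curve and returns the fit with
#' the lowest AIC. Ties (including multiple perfect fits) are broken in
#' favor of the model with fewer parameters.
#'
#' @inheritParams fit_nonlinear
#' @return The winning `kinetic_fit`, with a `selection` attribute: a
#'   data.frame of model, n_params, rss, aic and delta_aic for all models
#'   that could be fitted.
#' @export
select_model <- function(curve, input, window = NULL, n_starts = 8L,
                         seed = 1L) {
  fits <- list(
    patlak = tryCatch(fit_patlak(curve, input, window),
                      error = function(e) e),
    extended_tofts = tryCatch(
      fit_nonlinear(curve, input, "extended_tofts", window, n_starts, seed),
      error = function(e) e),
    uptake = tryCatch(
      fit_nonlinear(curve, input, "uptake", window, n_starts, seed),
      error = function(e) e))
  exchange_warm <- if (!inherits(fits$uptake, "condition")) {
    p <- fits$uptake$params
    c(p$fp, p$ps, p$vp, max(min(1 - p$vp - 1e-6, 1), 1e-6))
  } else NULL
  fits$exchange <- tryCatch(
    fit_nonlinear(curve, input, "exchange", window, n_starts, seed,
                  warm_start = exchange_warm),
    error = function(e) e)
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok)) stop("no model could be fitted: ",
                     conditionMessage(fits[[1]]))
  fits <- fits[ok]
  tab <- data.frame(
    model = names(fits),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL)
  ord <- order(tab$aic, tab$n_params)
  tab$delta_aic <- tab$aic - tab$aic[ord[1]]
  tab$delta_aic[is.nan(tab$delta_aic)] <- 0  # several perfect fits
  winner <- fits[[tab$model[ord[1]]]]
  attr(winner, "selection") <- tab[ord, ]
  winner
}
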