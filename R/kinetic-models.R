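#' Forward tracer-kinetic models
#'
#' Forward (signal-generating) compartment models mapping an arterial input
#' function and kinetic parameters to a tissue enhancement curve. All models
#' operate directly on signal enhancement (S(t) - S0), assuming linearity
#' between enhancement and contrast concentration over the injected dose.
#' Rates (`ktrans`, `kep`, `fp`, `ps`) are in min^-1 and volume fractions
#' (`vp`, `ve`) are dimensionless; time is handled internally in minutes.
#' Quadrature is the trapezoidal rule on the uniform frame grid for both the
#' Patlak running integral and all residue-function convolutions, so nested
#' models agree exactly in their shared limits (e.g. extended Tofts with
#' `kep = 0` reproduces the Patlak forward curve to machine precision).
#'
#' @name kinetic_models
NULL

#' Running integral of the arterial input function
#'
#' Trapezoidal cumulative integral of the plasma curve with time in minutes,
#' the integral term of the Patlak model. The first element is 0.
#'
#' @param input an [aif()].
#' @return Numeric vector, unit of `cp` times minutes.
#' @examples
#' g <- time_grid(3, dt = 30)
#' cumulative_integral(aif(g, c(0, 2, 4)))  # 0.0 0.5 2.0
#' @export
cumulative_integral <- function(input) {
  if (!inherits(input, "aif")) stop("expected an 'aif' object")
  cp <- input$cp
  dt_min <- input$grid$dt / 60
  n <- length(cp)
  c(0, cumsum((cp[-1] + cp[-n]) / 2 * dt_min))
}

# Trapezoidal convolution of f with kernel g on a uniform grid (dt in min).
# Returns h with h[k] ~ integral_0^{t_k} f(tau) g(t_k - tau) dtau.
conv_trapz <- function(f, g, dt_min) {
  n <- length(f)
  s <- stats::convolve(f, rev(g), type = "open")[seq_len(n)]
  h <- dt_min * (s - 0.5 * (f[1] * g + f * g[1]))
  h[1] <- 0
  h
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a single value in [0, 1]", name))
}

check_rate <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || (positive && x <= 0))
    stop(sprintf("%s must be a single %s rate (min^-1)", name,
                 if (positive) "strictly positive" else "non-negative"))
}

#' Patlak forward model
#'
#' Linear graphical model for an intravascular-plus-leakage tissue, valid
#' when backflux is negligible over the imaging window:
#' `Ct(t) = ktrans * integral_0^t Cp + vp * Cp(t)`.
#'
#' @param ktrans volume transfer constant, min^-1 (reported as
#'   mL/100 mL/min after multiplying by 100).
#' @param vp fractional plasma volume in `[0, 1]` (reported as mL/100 mL
#'   after multiplying by 100).
#' @param input an [aif()].
#' @return A [tissue_curve()].
#' @examples
#' g <- time_grid(10, dt = 60)
#' a <- aif(g, rep(1, 10))
#' patlak_forward(0.06, 0.1, a)$ct  # 0.1 + 0.06 * t_min
#' @export
patlak_forward <- function(ktrans, vp, input) {
  check_rate(ktrans, "ktrans")
  check_fraction(vp, "vp")
  ct <- ktrans * cumulative_integral(input) + vp * input$cp
  tissue_curve(input$grid, ct)
}

#' Extended Tofts forward model
#'
#' Adds a first-order efflux rate `kep` to the plasma-plus-leakage picture:
#' `Ct = vp * Cp + ktrans * (Cp convolved with exp(-kep * t))`.
#' With `kep = 0` this reduces exactly to [patlak_forward()] because both
#' use the same trapezoidal quadrature.
#'
#' @param ktrans transfer constant, min^-1.
#' @param kep efflux rate, min^-1.
#' @param vp fractional plasma volume.
#' @param input an [aif()].
#' @return A [tissue_curve()].
#' @export
extended_tofts_forward <- function(ktrans, kep, vp, input) {
  check_rate(ktrans, "ktrans")
  check_rate(kep, "kep")
  check_fraction(vp, "vp")
  t_min <- frame_times(input$grid, "min") - input$grid$t0 / 60
  kern <- exp(-kep * t_min)
  ct <- vp * input$cp + ktrans * conv_trapz(input$cp, kern, input$grid$dt / 60)
  tissue_curve(input$grid, ct)
}

#' Residue function of the two-compartment uptake model
#'
#' `R(t) = fp * ((1 - E) * exp(-t / Tp) + E)` with extraction fraction
#' `E = ps / (ps + fp)` and plasma mean transit time `Tp = vp / (fp + ps)`.
#'
#' @param t time in minutes (vector).
#' @inheritParams uptake_forward
#' @return Numeric vector, R(t) in min^-1.
#' @export
uptake_residue <- function(t, fp, ps, vp) {
  e <- ps / (ps + fp)
  tp <- vp / (fp + ps)
  fp * ((1 - e) * exp(-t / tp) + e)
}

#' Two-compartment uptake forward model
#'
#' Convolution of the arterial input with the uptake residue function
#' ([uptake_residue()]); backflux from the extravascular compartment is
#' assumed negligible.
#'
#' @param fp plasma flow per unit tissue volume, min^-1 (> 0).
#' @param ps permeability-surface area product, min^-1.
#' @param vp fractional plasma volume in `(0, 1]`.
#' @param input an [aif()].
#' @return A [tissue_curve()].
#' @export
uptake_forward <- function(fp, ps, vp, input) {
  check_rate(fp, "fp", positive = TRUE)
  check_rate(ps, "ps")
  check_fraction(vp, "vp")
  if (vp <= 0) stop("vp must be > 0 for the uptake model")
  t_min <- frame_times(input$grid, "min") - input$grid$t0 / 60
  r <- uptake_residue(t_min, fp, ps, vp)
  tissue_curve(input$grid, conv_trapz(input$cp, r, input$grid$dt / 60))
}

#' Residue function of the two-compartment exchange model
#'
#' Biexponential impulse response of the plasma/interstitium mass balance:
#' `R(t) = fp * (A * exp(-alpha t) + (1 - A) * exp(-beta t))` where
#' `-alpha, -beta` are the eigenvalues of the two-compartment system matrix.
#' `R(0) = fp` and the area under R over `[0, Inf)` equals the total
#' distribution volume `vp + ve`. A confluent `t * exp` form is used when
#' the two rates coincide.
#'
#' @param t time in minutes (vector).
#' @inheritParams exchange_forward
#' @return Numeric vector, R(t) in min^-1.
#' @export
exchange_residue <- function(t, fp, ps, vp, ve) {
  # system matrix in amount coordinates:
  #   d/dt (vp*Cp', ve*Ce) = M (vp*Cp', ve*Ce) + (fp*Ca, 0)
  tr <- -((fp + ps) / vp + ps / ve)
  dt_ <- fp * ps / (vp * ve)
  disc <- tr * tr - 4 * dt_
  if (disc < 0) {
    if (disc > -1e-12 * tr * tr) disc <- 0
    else stop("negative discriminant: unphysical exchange parameters")
  }
  root <- sqrt(disc)
  alpha <- (-tr + root) / 2   # fast rate
  beta  <- (-tr - root) / 2   # slow rate
  c0 <- fp / vp
  if (root <= 1e-10 * abs(tr)) {
    # confluent limit alpha == beta
    fp * exp(-alpha * t) * (1 + (alpha - c0) * t)
  } else {
    fp * (exp(-alpha * t) * (beta - c0) + exp(-beta * t) * (c0 - alpha)) /
      (beta - alpha)
  }
}

#' Two-compartment exchange forward model
#'
#' Convolution of the arterial input with the biexponential residue function
#' ([exchange_residue()]). As `ps -> 0` the output converges to the
#' pure-vascular limit shared with [uptake_forward()].
#'
#' @param fp plasma flow, min^-1 (> 0).
#' @param ps permeability-surface area product, min^-1.
#' @param vp fractional plasma volume in `(0, 1]`.
#' @param ve extravascular-extracellular volume fraction in `(0, 1]`;
#'   `vp + ve` must not exceed 1.
#' @param input an [aif()].
#' @return A [tissue_curve()].
#' @export
exchange_forward <- function(fp, ps, vp, ve, input) {
  check_rate(fp, "fp", positive = TRUE)
  check_rate(ps, "ps")
  check_fraction(vp, "vp")
  check_fraction(ve, "ve")
  if (vp <= 0 || ve <= 0) stop("vp and ve must be > 0 for the exchange model")
  if (vp + ve > 1 + 1e-12) stop("vp + ve must not exceed 1")
  t_min <- frame_times(input$grid, "min") - input$grid$t0 / 60
  r <- exchange_residue(t_min, fp, ps, vp, ve)
  tissue_curve(input$grid, conv_trapz(input$cp, r, input$grid$dt / 60))
}
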