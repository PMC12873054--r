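#' Dynamic contrast-enhanced series
#'
#' A 4D signal array (x, y, z, frame) with its acquisition time grid.
#' Voxel and frame indices are 1-based (R convention); masks must share
#' the series' spatial grid voxel-for-voxel (no resampling).
#'
#' @param voxels 4D numeric array, dimensions (x, y, z, n_frames).
#' @param grid a [time_grid()] whose `n_frames` matches `dim(voxels)[4]`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return Object of class `dynamic_series`.
#' @export
dynamic_series <- function(voxels, grid, voxel_size = c(1, 1, 1)) {
  stopifnot_grid(grid)
  d <- dim(voxels)
  if (length(d) != 4L) stop("voxels must be a 4D array (x, y, z, frame)")
  if (d[4] != grid$n_frames)
    stop("4th array dimension must equal grid$n_frames")
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  structure(list(voxels = voxels, grid = grid,
                 voxel_size = as.numeric(voxel_size)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_series> %d x %d x %d voxels, %d frames (dt = %g s)\n",
              d[1], d[2], d[3], d[4], x$grid$dt))
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param label one of `"transplant"`, `"left_native"`, `"right_native"`,
#'   `"aorta"` (other labels are allowed but unused by the standard
#'   report).
#' @param mask 3D logical array aligned to the series' spatial grid.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(label, mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask '", label, "' is empty")
  structure(list(label = label, mask = mask), class = "roi_mask")
}

check_mask_fits <- function(series, roi) {
  if (!identical(dim(roi$mask), dim(series$voxels)[1:3]))
    stop("mask '", roi$label, "' does not match the series' spatial grid")
}

#' Voxel-wise signal enhancement
#'
#' Subtracts the per-voxel baseline signal S0, estimated as the mean of
#' the first `n_baseline_frames` frames (acquired before contrast
#' arrival), yielding absolute enhancement S(t) - S0.
#'
#' @param series a [dynamic_series()].
#' @param n_baseline_frames number of pre-contrast frames averaged into S0
#'   (default 3).
#' @return A `dynamic_series` of enhancement values.
#' @export
compute_enhancement <- function(series, n_baseline_frames = 3L) {
  nb <- as.integer(n_baseline_frames)
  nf <- series$grid$n_frames
  if (nb < 1L || nb >= nf)
    stop("n_baseline_frames must be in [1, n_frames - 1]")
  d <- dim(series$voxels)
  m <- matrix(series$voxels, prod(d[1:3]), d[4])
  s0 <- rowMeans(m[, seq_len(nb), drop = FALSE])
  enh <- array(m - s0, d)
  dynamic_series(enh, series$grid, series$voxel_size)
}

#' Detect the bolus-arrival frame
#'
#' First frame whose value exceeds the pre-contrast baseline mean by five
#' baseline standard deviations. For noiseless curves (zero baseline SD)
#' the threshold floor is 0.1% of the curve's peak.
#'
#' @param cp numeric enhancement curve (typically the aortic median).
#' @param n_baseline_frames frames treated as pre-contrast baseline.
#' @param k threshold in baseline standard deviations (default 5).
#' @return Frame index (1-based) of bolus arrival.
#' @export
detect_bolus_arrival <- function(cp, n_baseline_frames = 3L, k = 5) {
  nb <- as.integer(n_baseline_frames)
  if (nb < 1L || nb >= length(cp)) stop("invalid n_baseline_frames")
  mu <- mean(cp[seq_len(nb)])
  sd0 <- stats::sd(cp[seq_len(nb)])
  floor_ <- 1e-3 * max(abs(cp - mu))
  thr <- mu + k * max(sd0, floor_, .Machine$double.eps)
  idx <- which(cp > thr)
  idx <- idx[idx > nb]
  if (!length(idx)) stop("no bolus arrival detected")
  idx[1]
}

#' Extract the arterial input function from an aortic ROI
#'
#' Per-frame median (or mean) enhancement over the aorta voxels; frames
#' before the detected bolus arrival are set to zero.
#'
#' @param enhancement a [dynamic_series()] of enhancement values (see
#'   [compute_enhancement()]).
#' @param aorta a [roi_mask()].
#' @param n_baseline_frames baseline length used for arrival detection.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return An [aif()] with the arrival frame recorded.
#' @export
extract_aif <- function(enhancement, aorta, n_baseline_frames = 3L,
                        aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  check_mask_fits(enhancement, aorta)
  d <- dim(enhancement$voxels)
  m <- matrix(enhancement$voxels, prod(d[1:3]), d[4])[as.vector(aorta$mask), ,
                                                      drop = FALSE]
  cp <- if (aggregate == "median") apply(m, 2, stats::median)
        else colMeans(m)
  arrival <- detect_bolus_arrival(cp, n_baseline_frames)
  cp[seq_len(arrival - 1)] <- 0
  aif(enhancement$grid, cp, arrival_frame = arrival)
}

# Translate a 3D volume by an integer shift, zero-filling exposed edges.
translate3d <- function(vol, shift, fill = 0) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    s <- shift[i]
    if (abs(s) >= d[i]) return(out)
    if (s >= 0) { dst[[i]] <- (1 + s):d[i]; src[[i]] <- 1:(d[i] - s) }
    else { dst[[i]] <- 1:(d[i] + s); src[[i]] <- (1 - s):d[i] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

ncc_overlap <- function(a, b, shift) {
  # correlation of translate3d(a, shift) with b on the overlap region
  d <- dim(a)
  ia <- ib <- vector("list", 3)
  for (i in 1:3) {
    s <- shift[i]
    if (abs(s) >= d[i]) return(-Inf)
    if (s >= 0) { ib[[i]] <- (1 + s):d[i]; ia[[i]] <- 1:(d[i] - s) }
    else { ib[[i]] <- 1:(d[i] + s); ia[[i]] <- (1 - s):d[i] }
  }
  x <- as.vector(a[ia[[1]], ia[[2]], ia[[3]]])
  y <- as.vector(b[ib[[1]], ib[[2]], ib[[3]]])
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(-Inf)
  stats::cor(x, y)
}

#' Rigid (translation-only) motion correction
#'
#' Estimates a per-frame integer 3D translation by exhaustive search
#' within `max_shift` voxels, maximizing normalized cross-correlation
#' (NCC), and applies the best shift to each frame.
#'
#' The reference is built in two passes. The voxel-wise temporal median
#' volume of a moving series is itself motion-blurred, so the first pass
#' registers every frame to a sharp anchor: the single frame that best
#' matches the temporal median. The second pass re-registers every frame
#' against the temporal median of the corrected frames, which is sharp
#' once the frames are aligned. After each pass the shift set is
#' recentred to have zero median per axis — subject motion is excursions
#' about a central position, and recentring pins the corrected series to
#' that position rather than to the arbitrary anchor frame.
#'
#' Frames with no usable structure (flat, or best correlation below 0.1)
#' are left unshifted and flagged. Deterministic.
#'
#' @param series a [dynamic_series()].
#' @param max_shift search radius in voxels per axis (default 3).
#' @return The corrected `dynamic_series`, with attributes `shifts`
#'   (n_frames x 3 matrix of applied corrections) and `flagged_frames`.
#' @export
motion_correct <- function(series, max_shift = 3L) {
  d <- dim(series$voxels)
  if (d[4] < 2L) stop("need at least 2 frames")
  cand <- as.matrix(expand.grid(x = -max_shift:max_shift,
                                y = -max_shift:max_shift,
                                z = -max_shift:max_shift))
  # zero shift first so exact ties keep the identity
  cand <- cand[order(rowSums(abs(cand))), , drop = FALSE]

  register_all <- function(ref) {
    shifts <- matrix(0L, d[4], 3)
    flagged <- integer()
    for (f in seq_len(d[4])) {
      vol <- series$voxels[, , , f]
      if (stats::sd(vol) == 0) { flagged <- c(flagged, f); next }
      scores <- apply(cand, 1, function(s) ncc_overlap(vol, ref, s))
      if (!any(is.finite(scores)) || max(scores, na.rm = TRUE) < 0.1) {
        # uninformative frame (e.g. pure noise): leave in place
        flagged <- c(flagged, f)
        next
      }
      shifts[f, ] <- as.integer(cand[which.max(scores), ])
    }
    ok <- setdiff(seq_len(d[4]), flagged)
    center <- round(apply(shifts[ok, , drop = FALSE], 2, stats::median))
    shifts[ok, ] <- sweep(shifts[ok, , drop = FALSE], 2, as.integer(center))
    list(shifts = shifts, flagged = flagged)
  }

  apply_shifts <- function(shifts) {
    out <- series$voxels
    for (f in seq_len(d[4]))
      if (any(shifts[f, ] != 0L))
        out[, , , f] <- translate3d(series$voxels[, , , f], shifts[f, ])
    out
  }

  # pass 1: anchor = the frame that best matches the (blurred) temporal
  # median at zero displacement
  med0 <- array(apply(matrix(series$voxels, prod(d[1:3]), d[4]), 1,
                      stats::median), d[1:3])
  match0 <- vapply(seq_len(d[4]), function(f)
    ncc_overlap(series$voxels[, , , f], med0, c(0L, 0L, 0L)), numeric(1))
  anchor <- series$voxels[, , , which.max(match0)]
  p1 <- register_all(anchor)

  # pass 2: sharp reference = temporal median of the corrected frames
  corrected <- apply_shifts(p1$shifts)
  ref <- array(apply(matrix(corrected, prod(d[1:3]), d[4]), 1,
                     stats::median), d[1:3])
  p2 <- register_all(ref)

  res <- dynamic_series(apply_shifts(p2$shifts), series$grid,
                        series$voxel_size)
  attr(res, "shifts") <- p2$shifts
  attr(res, "flagged_frames") <- p2$flagged
  res
}

#' Voxel-wise Patlak parameter map over an ROI
#'
#' Fits the Patlak model independently to every voxel curve inside the
#' ROI (all voxels share the design matrix, so the whole map is one
#' batched least-squares solve, identical to [fit_patlak()] per voxel).
#' Outputs are converted to reported units: Ktrans in mL/100 mL/min and
#' vp in mL/100 mL (internal values times 100). Negative estimates are
#' clipped to zero and flagged per voxel; flags never abort the map.
#'
#' @param enhancement a [dynamic_series()] of enhancement values.
#' @param roi a [roi_mask()] (non-aortic kidney ROI).
#' @param input the [aif()] for this series.
#' @param window optional [fit_window()]; default bolus arrival to end.
#' @return Object of class `parameter_map`: 3D arrays `ktrans` and `vp`
#'   (NA outside the ROI, reported units), integer `flags` array (bit 1 =
#'   ktrans clipped, bit 2 = vp clipped), plus the roi and voxel count.
#' @export
map_roi <- function(enhancement, roi, input, window = NULL) {
  check_mask_fits(enhancement, roi)
  if (!same_grid(enhancement$grid, input$grid))
    stop("series and AIF must share the same time grid")
  if (is.null(window)) window <- default_window(input)
  idx <- window_idx(window, input$grid$n_frames)
  if (length(idx) < 3L) stop("need at least 3 frames in the fit window")
  d <- dim(enhancement$voxels)
  sel <- as.vector(roi$mask)
  y <- t(matrix(enhancement$voxels, prod(d[1:3]), d[4])[sel, idx,
                                                        drop = FALSE])
  x <- cbind(cumulative_integral(input), input$cp)[idx, , drop = FALSE]
  fit <- patlak_ols(x, y)
  kt <- fit$coef[1, ]
  vp <- fit$coef[2, ]
  flags <- as.integer(kt < 0) + 2L * as.integer(vp < 0)
  kt[kt < 0] <- 0
  vp[vp < 0] <- 0
  mk <- function(v) { a <- array(NA_real_, d[1:3]); a[sel] <- v; a }
  fl <- array(NA_integer_, d[1:3]); fl[sel] <- flags
  structure(list(roi = roi, ktrans = mk(kt * 100), vp = mk(vp * 100),
                 flags = fl, n_voxels = sum(sel),
                 rss = { a <- array(NA_real_, d[1:3]); a[sel] <- fit$rss; a }),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf(
    "<parameter_map> %s: %d voxels, median Ktrans %.2f, median vp %.2f\n",
    x$roi$label, x$n_voxels,
    stats::median(x$ktrans[x$roi$mask]), stats::median(x$vp[x$roi$mask])))
  invisible(x)
}

#' ROI summary of a parameter map
#'
#' Median Ktrans and vp over the successfully fitted voxels of the ROI,
#' in reported units (mL/100 mL/min, mL/100 mL). Voxels whose estimates
#' were clipped at zero participate in the median with their clipped
#' value — the median is unaffected by clipping as long as fewer than
#' half the voxels clip, whereas excluding them would truncate the lower
#' tail and bias the median upward at low SNR. The number of clipped
#' voxels is reported as `n_flagged`.
#'
#' @param pmap a `parameter_map` from [map_roi()].
#' @return List with `median_ktrans`, `median_vp`, `n_voxels`,
#'   `n_flagged`.
#' @export
summarize_roi <- function(pmap) {
  sel <- pmap$roi$mask & !is.na(pmap$flags)
  if (!any(sel)) stop("no successfully fitted voxels in ROI '",
                      pmap$roi$label, "'")
  list(median_ktrans = stats::median(pmap$ktrans[sel]),
       median_vp = stats::median(pmap$vp[sel]),
       n_voxels = pmap$n_voxels,
       n_flagged = sum(pmap$flags[sel] > 0L))
}

#' Run the full single-animal perfusion pipeline
#'
#' Enhancement computation, optional rigid motion correction, AIF
#' extraction from the aortic ROI, voxel-wise Patlak mapping of each
#' kidney ROI, and ROI median aggregation.
#'
#' @param series a [dynamic_series()] (raw signal).
#' @param masks named list of [roi_mask()]s; must contain `"aorta"`.
#' @param n_baseline_frames pre-contrast baseline length (default 3).
#' @param motion_correction apply [motion_correct()] first (default
#'   FALSE).
#' @param window optional [fit_window()] shared by all ROIs.
#' @param curve_first if TRUE, fit the ROI-median enhancement curve
#'   instead of computing per-voxel maps and taking the median of the
#'   parameters.
#' @return List with `aif`, `maps` (one `parameter_map` per kidney ROI;
#'   empty when `curve_first`), and `summary` (data.frame of roi_label,
#'   n_voxels, median_ktrans, median_vp, n_flagged).
#' @export
run_pipeline <- function(series, masks, n_baseline_frames = 3L,
                         motion_correction = FALSE, window = NULL,
                         curve_first = FALSE) {
  if (!"aorta" %in% names(masks)) stop("masks must include 'aorta'")
  if (motion_correction) series <- motion_correct(series)
  enh <- compute_enhancement(series, n_baseline_frames)
  input <- extract_aif(enh, masks$aorta, n_baseline_frames)
  kidney <- masks[setdiff(names(masks), "aorta")]
  maps <- list()
  rows <- list()
  for (lab in names(kidney)) {
    if (curve_first) {
      d <- dim(enh$voxels)
      m <- matrix(enh$voxels, prod(d[1:3]),
                  d[4])[as.vector(kidney[[lab]]$mask), , drop = FALSE]
      med_curve <- tissue_curve(enh$grid, apply(m, 2, stats::median))
      fit <- fit_patlak(med_curve, input, window)
      rows[[lab]] <- data.frame(
        roi_label = lab, n_voxels = nrow(m),
        median_ktrans = fit$params$ktrans * 100,
        median_vp = fit$params$vp * 100,
        n_flagged = length(fit$flags), stringsAsFactors = FALSE)
    } else {
      pm <- map_roi(enh, kidney[[lab]], input, window)
      maps[[lab]] <- pm
      s <- summarize_roi(pm)
      rows[[lab]] <- data.frame(
        roi_label = lab, n_voxels = s$n_voxels,
        median_ktrans = s$median_ktrans, median_vp = s$median_vp,
        n_flagged = s$n_flagged, stringsAsFactors = FALSE)
    }
  }
  list(aif = input, maps = maps,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
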