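#' Write a phantom study to disk
#'
#' Emits, per animal, the 4D series as NIfTI-1, a labeled integer mask
#' volume with a JSON label map, plus a study-level ground-truth TSV and
#' a JSON manifest pointing at every file. These are exactly the formats
#' [read_study_manifest()] and [cmd_fit()] consume.
#'
#' @param study a `phantom_study` from [render_study()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- list(aorta = 1L, transplant = 2L, left_native = 3L,
                 right_native = 4L)
  manifest <- list(dt = study$config$dt,
                   n_baseline_frames = 3L,
                   labels = labels, animals = list())
  for (an in study$animals) {
    series_file <- file.path(dir, paste0(an$id, "_series.nii.gz"))
    mask_file <- file.path(dir, paste0(an$id, "_masks.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(an$series$voxels), series_file)
    lab_vol <- array(0L, dim(an$masks[[1]]$mask))
    for (nm in names(labels)) lab_vol[an$masks[[nm]]$mask] <- labels[[nm]]
    RNifti::writeNifti(RNifti::asNifti(lab_vol), mask_file)
    manifest$animals[[an$id]] <- list(
      id = an$id, group = an$group,
      series = basename(series_file), masks = basename(mask_file))
  }
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a study manifest
#'
#' @param path path to a `manifest.json` written by [write_study()] (or
#'   hand-authored to the same schema).
#' @return List with `dt`, `labels`, and `animals` (each with resolved
#'   absolute `series`/`masks` paths and a `group` label).
#' @export
read_study_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  ids <- vapply(man$animals, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("animal ids in manifest must be unique")
  man$animals <- lapply(man$animals, function(a) {
    a$series <- file.path(base, a$series)
    a$masks <- file.path(base, a$masks)
    for (f in c("series", "masks"))
      if (!file.exists(a[[f]]))
        stop("file referenced by manifest does not exist: ", a[[f]])
    a
  })
  man
}

#' Read a 4D NIfTI dynamic series
#'
#' @param path NIfTI file with a 4D (x, y, z, t) volume.
#' @param dt frame spacing in seconds; overrides any TR stored in the
#'   NIfTI header (default 6.6).
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path, dt = 6.6) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img))
  if (length(dim(vox)) != 4L) stop("expected a 4D NIfTI volume: ", path)
  pix <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  dynamic_series(vox, time_grid(dim(vox)[4], dt), voxel_size = pix)
}

#' Read ROI masks from a labeled integer volume
#'
#' @param path NIfTI file with a 3D integer label volume.
#' @param labels named list mapping roi labels to integer codes.
#' @return Named list of [roi_mask()]s (labels absent from the volume are
#'   dropped with a warning).
#' @export
read_mask_volume <- function(path, labels) {
  img <- RNifti::readNifti(path)
  vol <- array(as.integer(round(as.numeric(img))), dim(img))
  if (length(dim(vol)) != 3L) stop("expected a 3D label volume: ", path)
  out <- list()
  for (nm in names(labels)) {
    m <- vol == labels[[nm]]
    if (!any(m)) {
      warning("label '", nm, "' not present in ", path)
      next
    }
    out[[nm]] <- roi_mask(nm, m)
  }
  out
}

#' Simulate a phantom study and write it to disk
#'
#' @param out_dir output directory.
#' @param config a [phantom_config()], or a path to a YAML file whose
#'   top-level keys are `phantom_config()` arguments, or NULL for
#'   defaults.
#' @param quiet suppress the truth-table summary printed on completion.
#' @return The study directory, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = NULL, quiet = FALSE) {
  if (is.null(config)) config <- phantom_config()
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(phantom_config, args)
  }
  study <- render_study(config)
  write_study(study, out_dir)
  if (!quiet) {
    cat("Simulated", length(study$animals), "animals into", out_dir, "\n")
    agg <- stats::aggregate(cbind(ktrans, vp) ~ group + roi_label,
                            study$truth, stats::median)
    print(agg, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Fit the perfusion pipeline for every animal in a manifest
#'
#' Runs enhancement, optional motion correction, AIF extraction,
#' voxel-wise Patlak mapping and ROI aggregation per animal, writing a
#' per-ROI summary TSV and per-animal parameter-map NIfTIs. A missing
#' kidney label skips that ROI with a warning; a missing aorta aborts
#' the animal (logged, not fatal to the run).
#'
#' @param manifest path to a study `manifest.json`.
#' @param out_dir output directory.
#' @param motion_correction,baseline_frames,curve_first pipeline options
#'   (see [run_pipeline()]).
#' @param model_selection additionally run [select_model()] on each ROI's
#'   median curve and write a delta-AIC table.
#' @param write_maps write Ktrans/vp maps as NIfTI (default TRUE).
#' @return The summary table, invisibly; written to
#'   `<out_dir>/roi_summary.tsv`.
#' @export
cmd_fit <- function(manifest, out_dir, motion_correction = FALSE,
                    baseline_frames = 3L, model_selection = FALSE,
                    curve_first = FALSE, write_maps = TRUE) {
  man <- read_study_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dt <- if (!is.null(man$dt)) man$dt else 6.6
  rows <- list()
  sel_rows <- list()
  for (a in man$animals) {
    series <- read_dynamic_series(a$series, dt)
    masks <- read_mask_volume(a$masks, man$labels)
    if (!"aorta" %in% names(masks)) {
      message("animal ", a$id, ": no aorta mask, skipped")
      next
    }
    res <- run_pipeline(series, masks,
                        n_baseline_frames = baseline_frames,
                        motion_correction = motion_correction,
                        curve_first = curve_first)
    message(sprintf("animal %s: AIF arrival frame %d, %d ROIs, %d flagged voxels",
                    a$id, res$aif$arrival_frame, nrow(res$summary),
                    sum(res$summary$n_flagged)))
    rows[[a$id]] <- cbind(animal_id = a$id, group = a$group, res$summary,
                          stringsAsFactors = FALSE)
    if (write_maps && length(res$maps)) {
      for (lab in names(res$maps)) {
        pm <- res$maps[[lab]]
        for (par in c("ktrans", "vp")) {
          vol <- pm[[par]]
          vol[is.na(vol)] <- 0
          RNifti::writeNifti(
            RNifti::asNifti(vol),
            file.path(out_dir, sprintf("%s_%s_%s.nii.gz", a$id, lab, par)))
        }
      }
    }
    if (model_selection) {
      enh <- compute_enhancement(series, baseline_frames)
      for (lab in setdiff(names(masks), "aorta")) {
        d <- dim(enh$voxels)
        m <- matrix(enh$voxels, prod(d[1:3]),
                    d[4])[as.vector(masks[[lab]]$mask), , drop = FALSE]
        med_curve <- tissue_curve(enh$grid, apply(m, 2, stats::median))
        win <- select_model(med_curve, res$aif)
        tab <- attr(win, "selection")
        sel_rows[[paste(a$id, lab)]] <-
          cbind(animal_id = a$id, roi_label = lab, tab,
                stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no animal could be analyzed")
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(summary, file.path(out_dir, "roi_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (model_selection) {
    sel <- do.call(rbind, c(sel_rows, list(make.row.names = FALSE)))
    utils::write.table(sel, file.path(out_dir, "model_selection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(summary)
}

#' Group-comparison report from a per-ROI summary TSV
#'
#' @param summary_tsv path to `roi_summary.tsv` (from [cmd_fit()]), with
#'   columns animal_id, group, roi_label, median_ktrans, median_vp.
#' @param out_dir output directory for `stats_report.tsv` and
#'   `stats_report.json`.
#' @param alpha significance level (default 0.05).
#' @param groups ordered group labels (first minus second).
#' @return The report data.frame, invisibly.
#' @export
cmd_stats <- function(summary_tsv, out_dir, alpha = 0.05,
                      groups = c("16h", "30min")) {
  tab <- utils::read.delim(summary_tsv, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "roi_label", "median_ktrans", "median_vp")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("summary TSV lacks columns: ", paste(missing_cols, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    if (!is.finite(tab$median_ktrans[i]) || !is.finite(tab$median_vp[i]))
      stop("non-numeric parameter value in summary TSV row ", i)
  }
  rep <- stats_report(tab, groups = groups, alpha = alpha)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rep, file.path(out_dir, "stats_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(rep, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rep)
}
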