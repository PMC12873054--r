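#' Compare a perfusion parameter between two arms
#'
#' Assembles the full exact-test report for one comparison: test statistic,
#' exact two-sided p-value, rank-biserial effect size, and Hodges-Lehmann
#' shift estimate with exact 95% confidence interval. Unpaired comparisons
#' (e.g. 16-h vs 30-min ischemia groups) use the exact Mann-Whitney U test;
#' paired comparisons (e.g. transplanted vs native kidney within animal)
#' use the exact Wilcoxon signed-rank test, dropping animals lacking either
#' member of the pair.
#'
#' Differences are oriented first-arm minus second-arm, so for the study
#' layout the conventions are (16h - 30min) and (transplant - native).
#' No multiplicity adjustment is applied.
#'
#' @param table data.frame of per-animal ROI summaries with columns
#'   `animal_id`, `group`, `roi_label`, `median_ktrans`, `median_vp`.
#' @param parameter `"ktrans"` or `"vp"`.
#' @param design `"unpaired"` or `"paired"`.
#' @param arm1,arm2 for `design = "unpaired"`: the two group labels
#'   compared on `roi` (arm1 minus arm2). For `design = "paired"`: the two
#'   ROI labels compared within `group` (arm1 minus arm2).
#' @param roi ROI label for unpaired comparisons (default `"transplant"`).
#' @param group group label for paired comparisons.
#' @param alpha significance level declared in the report (default 0.05).
#' @param conf_level confidence level of the Hodges-Lehmann interval.
#' @return An object of class `group_comparison`: a list with the design,
#'   sample sizes, statistic, `p_value`, `effect_size`, `hl_estimate`,
#'   `hl_ci_low`, `hl_ci_high`, `significant`, and the per-arm values.
#' @export
compare_groups <- function(table, parameter = c("ktrans", "vp"),
                           design = c("unpaired", "paired"),
                           arm1, arm2, roi = "transplant", group = NULL,
                           alpha = 0.05, conf_level = 0.95) {
  parameter <- match.arg(parameter)
  design <- match.arg(design)
  col <- paste0("median_", parameter)
  req <- c("animal_id", "group", "roi_label", col)
  if (!all(req %in% names(table)))
    stop("summary table must have columns: ", paste(req, collapse = ", "))

  if (design == "unpaired") {
    x1 <- table[table$group == arm1 & table$roi_label == roi, col]
    x2 <- table[table$group == arm2 & table$roi_label == roi, col]
    if (length(x1) < 2 || length(x2) < 2)
      stop("need at least 2 observations per arm")
    test <- exact_mann_whitney(x2, x1)  # U counts pairs with arm1 > arm2
    eff <- rank_biserial_unpaired(x1, x2)
    hl <- hodges_lehmann(x1, x2, conf_level)
    out <- list(design = "unpaired", parameter = parameter,
                arm1 = arm1, arm2 = arm2, roi = roi,
                n1 = length(x1), n2 = length(x2), n_dropped = 0L,
                statistic = test$statistic, statistic_name = "U",
                p_value = test$p_value, effect_size = eff,
                values1 = x1, values2 = x2)
  } else {
    if (is.null(group)) stop("paired design requires 'group'")
    sub <- table[table$group == group & table$roi_label %in% c(arm1, arm2), ]
    w <- stats::reshape(sub[, c("animal_id", "roi_label", col)],
                        idvar = "animal_id", timevar = "roi_label",
                        direction = "wide")
    c1 <- paste0(col, ".", arm1); c2 <- paste0(col, ".", arm2)
    if (!all(c(c1, c2) %in% names(w)))
      stop("no animals with both ROIs '", arm1, "' and '", arm2, "'")
    complete <- stats::complete.cases(w[, c(c1, c2)])
    n_dropped <- sum(!complete)
    w <- w[complete, ]
    if (nrow(w) < 2) stop("need at least 2 complete pairs")
    d <- w[[c1]] - w[[c2]]
    test <- exact_wilcoxon_signed_rank(d)
    eff <- rank_biserial_paired(d)
    hl <- hodges_lehmann_paired(d, conf_level)
    out <- list(design = "paired", parameter = parameter,
                arm1 = arm1, arm2 = arm2, group = group,
                n1 = test$n, n2 = test$n, n_dropped = n_dropped,
                statistic = test$statistic, statistic_name = "W",
                p_value = test$p_value, effect_size = eff,
                values1 = w[[c1]], values2 = w[[c2]])
  }
  out$hl_estimate <- hl$estimate
  out$hl_ci_low <- hl$ci_low
  out$hl_ci_high <- hl$ci_high
  out$conf_level <- conf_level
  out$alpha <- alpha
  out$significant <- out$p_value < alpha
  out$hl_flag <- hl$flag
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$design == "unpaired")
    sprintf("%s vs %s (%s)", x$arm1, x$arm2, x$roi)
  else sprintf("%s vs %s in %s", x$arm1, x$arm2, x$group)
  cat(sprintf("<group_comparison> %s, %s\n", x$parameter, lab))
  cat(sprintf("  %s = %g, p = %.3f%s, effect size = %.2f\n",
              x$statistic_name, x$statistic, x$p_value,
              if (x$significant) " *" else "", x$effect_size))
  cat(sprintf("  HL shift %.2f, %g%% CI [%.2f, %.2f]\n",
              x$hl_estimate, 100 * x$conf_level, x$hl_ci_low, x$hl_ci_high))
  invisible(x)
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.2f [%.2f-%.2f]", q[2], q[1], q[3])
}

comparison_row <- function(cmp) {
  data.frame(
    parameter = cmp$parameter, design = cmp$design,
    arm1 = cmp$arm1, arm2 = cmp$arm2,
    context = if (cmp$design == "unpaired") cmp$roi else cmp$group,
    n1 = cmp$n1, n2 = cmp$n2,
    arm1_median_iqr = med_iqr(cmp$values1),
    arm2_median_iqr = med_iqr(cmp$values2),
    statistic = cmp$statistic, p_value = cmp$p_value,
    effect_size = cmp$effect_size, hl_estimate = cmp$hl_estimate,
    hl_ci_low = cmp$hl_ci_low, hl_ci_high = cmp$hl_ci_high,
    significant = cmp$significant, stringsAsFactors = FALSE)
}

#' Full comparison report for a two-group transplant study
#'
#' Runs every comparison of the study layout on a per-animal summary
#' table: intergroup (group `arm1` vs `arm2` on the transplanted kidney,
#' unpaired, per parameter) and intragroup (transplant vs each native
#' kidney within each group, paired, per parameter).
#'
#' @param table per-animal summary table (see [compare_groups()]).
#' @param groups character vector of the two group labels, ordered so the
#'   first minus the second is the reported direction.
#' @param transplant_roi,native_rois ROI labels.
#' @param alpha significance level.
#' @return data.frame with one row per comparison; the list of
#'   `group_comparison` objects is attached as attribute `comparisons`.
#' @export
stats_report <- function(table, groups = c("16h", "30min"),
                         transplant_roi = "transplant",
                         native_rois = c("left_native", "right_native"),
                         alpha = 0.05) {
  cmps <- list()
  have_both <- all(groups %in% table$group)
  for (par in c("ktrans", "vp")) {
    if (have_both) {
      cmps[[length(cmps) + 1L]] <- compare_groups(
        table, par, "unpaired", arm1 = groups[1], arm2 = groups[2],
        roi = transplant_roi, alpha = alpha)
    }
    for (g in intersect(groups, unique(table$group))) {
      for (nat in native_rois) {
        cmp <- tryCatch(
          compare_groups(table, par, "paired", arm1 = transplant_roi,
                         arm2 = nat, group = g, alpha = alpha),
          error = function(e) NULL)
        if (!is.null(cmp)) cmps[[length(cmps) + 1L]] <- cmp
      }
    }
  }
  if (!length(cmps)) stop("no comparison could be computed")
  out <- do.call(rbind, lapply(cmps, comparison_row))
  attr(out, "comparisons") <- cmps
  out
}
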