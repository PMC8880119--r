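# Cohort-level slope statistics: participant-specific normalization of
# wave-speed gait-cycle curves, 2-degree bin averaging, zero-referencing of
# per-stride work to each participant's level condition, and separate
# incline/decline OLS fits of the change in net work against slope.

#' Normalize per-stride wave-speed curves to the level condition
#'
#' Divides every stride's wave-speed curve by that participant's mean of
#' per-stride peak wave speeds over level strides, making curves
#' dimensionless (level-condition peak = 1 on average) and comparable
#' across participants.
#'
#' @param curves list of per-stride wave-speed vectors (one per stride) or
#'   a strides-by-samples matrix.
#' @param slopes per-stride slope in degrees.
#' @param participants per-stride participant labels.
#' @param level_tol level-stride threshold in degrees.
#' @return curves in the input structure, normalized.
#' @export
normalize_wave_speed_curves <- function(curves, slopes, participants,
                                        level_tol = 1) {
  as_list <- !is.matrix(curves)
  if (!as_list) curves <- asplit(curves, 1)
  stopifnot(length(curves) == length(slopes),
            length(curves) == length(participants))
  peaks <- vapply(curves, max, numeric(1))
  norm <- numeric(length(curves))
  for (p in unique(participants)) {
    sel <- participants == p
    lev <- sel & abs(slopes) < level_tol
    if (!any(lev)) {
      stop("participant '", p, "' has no level strides to normalize against")
    }
    norm[sel] <- mean(peaks[lev])
  }
  out <- mapply(function(cv, nm) cv / nm, curves, norm, SIMPLIFY = FALSE)
  if (!as_list) out <- do.call(rbind, out)
  out
}

#' Bin-averaged gait-cycle curves
#'
#' Resamples each normalized stride curve onto a common percent-gait-cycle
#' grid and averages curves within each slope bin across all strides of all
#' participants.
#'
#' @param curves list of per-stride curves (or strides-by-samples matrix).
#' @param bins per-stride slope-bin centre in degrees.
#' @param bin_centers bins to report; default every populated bin. Empty
#'   requested bins are omitted with a warning.
#' @param n_points samples of the percent-gait-cycle grid (0-100%).
#' @return data.frame `pct_gait_cycle`, `bin_center_deg`,
#'   `mean_normalized_speed`, `n_strides`.
#' @export
bin_average_curves <- function(curves, bins, bin_centers = NULL,
                               n_points = 101) {
  if (is.matrix(curves)) curves <- asplit(curves, 1)
  stopifnot(length(curves) == length(bins))
  pct <- seq(0, 100, length.out = n_points)
  rs <- t(vapply(curves, function(cv) {
    resample_linear(seq(0, 100, length.out = length(cv)), cv, pct)
  }, numeric(n_points)))
  if (is.null(bin_centers)) bin_centers <- sort(unique(bins))
  out <- list()
  for (b in bin_centers) {
    sel <- bins == b
    if (!any(sel)) {
      warning("slope bin ", b, " deg is empty; omitted")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      pct_gait_cycle = pct, bin_center_deg = b,
      mean_normalized_speed = colMeans(rs[sel, , drop = FALSE]),
      n_strides = sum(sel))
  }
  do.call(rbind, out)
}

#' Zero-reference per-stride work to the level condition
#'
#' Subtracts each participant's mean work over level strides from all of
#' that participant's strides, removing inter-participant offsets before
#' pooled regression.
#'
#' @param work per-stride work values, J/kg.
#' @param participant per-stride participant labels.
#' @param level_mask logical, `TRUE` for level strides.
#' @return change in work from the level condition, J/kg.
#' @export
zero_reference_work <- function(work, participant, level_mask) {
  stopifnot(length(work) == length(participant),
            length(work) == length(level_mask))
  out <- numeric(length(work))
  for (p in unique(participant)) {
    sel <- participant == p
    lev <- sel & level_mask
    if (!any(lev)) {
      stop("participant '", p, "' has no level strides for zero-referencing")
    }
    out[sel] <- work[sel] - mean(work[lev])
  }
  out
}

seg_fit <- function(dwork, slopes, muscle, segment, alpha) {
  fit <- lm(dwork ~ slopes)
  sm <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(confint(fit, "slopes", level = 1 - alpha))
  structure(list(muscle = muscle, segment = segment,
                 coefficient = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se = unname(sm["slopes", "Std. Error"]),
                 p_value = unname(sm["slopes", "Pr(>|t|)"]),
                 ci_lower = ci[1], ci_upper = ci[2],
                 n_strides = length(dwork),
                 significant = unname(sm["slopes", "Pr(>|t|)"]) < alpha,
                 alpha = alpha),
            class = "slope_work_regression")
}

#' @export
print.slope_work_regression <- function(x, ...) {
  cat(sprintf("<%s %s: %+.4g J/kg/deg (95%% CI %+.4g..%+.4g), p = %.3g, n = %d>\n",
              x$muscle, x$segment, x$coefficient, x$ci_lower, x$ci_upper,
              x$p_value, x$n_strides))
  invisible(x)
}

#' Slope sensitivity of zero-referenced net work
#'
#' Fits separate ordinary least squares lines of the change in net work
#' against slope for declines and inclines, pooling strides across
#' participants. Boundary (0 degree) strides enter both segments by
#' default. Coefficients are tested at the `alpha` significance level.
#'
#' @param dwork zero-referenced per-stride net work, J/kg.
#' @param slopes per-stride slope in degrees.
#' @param muscle label stored in the results.
#' @param include_boundary include slope == 0 strides in both segments.
#' @param alpha significance level.
#' @param min_n minimum strides required per segment.
#' @return list with `decline` and `incline` `slope_work_regression`
#'   records (coefficient in J/kg per degree).
#' @export
fit_slope_sensitivity <- function(dwork, slopes, muscle = "muscle",
                                  include_boundary = TRUE, alpha = 0.05,
                                  min_n = 10) {
  stopifnot(length(dwork) == length(slopes))
  dec <- if (include_boundary) slopes <= 0 else slopes < 0
  inc <- if (include_boundary) slopes >= 0 else slopes > 0
  for (seg in list(c("decline", sum(dec)), c("incline", sum(inc)))) {
    if (as.integer(seg[2]) < min_n) {
      stop(seg[1], " segment has ", seg[2], " strides; need >= ", min_n)
    }
  }
  list(decline = seg_fit(dwork[dec], slopes[dec], muscle, "decline", alpha),
       incline = seg_fit(dwork[inc], slopes[inc], muscle, "incline", alpha))
}
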