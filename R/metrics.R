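#' Configuration for the instability metric chain
#'
#' @param window_repeats Half-width of the analysis window, in repeat
#'   units, around the modal repeat (default 40).
#' @param height_threshold_frac Minimum peak height as a fraction of the
#'   modal peak height (default 0.05, i.e. 5%); the comparison is
#'   inclusive.
#' @param week_days Days per week used to convert timepoints (default 7).
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(window_repeats = 40, height_threshold_frac = 0.05,
                           week_days = 7) {
  stopifnot(window_repeats > 0,
            height_threshold_frac >= 0, height_threshold_frac < 1,
            week_days > 0)
  structure(list(window_repeats = window_repeats,
                 height_threshold_frac = height_threshold_frac,
                 week_days = week_days),
            class = "metrics_config")
}

#' Call the modal peak of a calibrated trace
#'
#' The modal repeat is the repeat length of the highest peak. Ties are
#' broken toward the smaller repeat length.
#'
#' @param repeat_length,height Parallel vectors of peak repeat lengths and
#'   heights for one sample.
#' @return A list with `modal_repeat` and `modal_height`.
#' @export
call_modal_peak <- function(repeat_length, height) {
  keep <- !is.na(repeat_length) & !is.na(height) & height > 0
  if (!any(keep)) {
    stop("trace has no peak with positive height", call. = FALSE)
  }
  r <- repeat_length[keep]
  h <- height[keep]
  top <- which(h == max(h))
  i <- top[which.min(r[top])]
  list(modal_repeat = r[i], modal_height = h[i])
}

#' Restrict a trace to the analysis window and height threshold
#'
#' Retains peaks within `window_repeats` of the modal repeat whose height
#' is at least `height_threshold_frac` of the modal height (both
#' comparisons inclusive). The window is applied first, then the height
#' threshold; the modal peak itself always survives.
#'
#' @param trace Tibble with `repeat_length` and `height` columns for one
#'   sample.
#' @param modal Output of [call_modal_peak()] on the same trace.
#' @param cfg A [metrics_config()].
#' @return The filtered tibble (always at least one row).
#' @export
filter_window_threshold <- function(trace, modal, cfg = metrics_config()) {
  in_window <- abs(trace$repeat_length - modal$modal_repeat) <=
    cfg$window_repeats
  tall <- trace$height >= cfg$height_threshold_frac * modal$modal_height
  is_modal <- trace$repeat_length == modal$modal_repeat &
    trace$height == modal$modal_height
  trace[(in_window & tall) | is_modal, , drop = FALSE]
}

#' Height-weighted mean repeat length
#'
#' The central instability statistic: the arithmetic mean of repeat
#' lengths weighted by peak height, computed on the windowed, thresholded
#' trace.
#'
#' @param repeat_length,height Parallel vectors for one filtered trace.
#' @return The weighted mean, in repeat units.
#' @export
#' @examples
#' weighted_mean_repeat(c(113, 114, 115, 116, 117),
#'                      c(100, 300, 1000, 400, 200))  # 115.15
weighted_mean_repeat <- function(repeat_length, height) {
  total <- sum(height)
  if (!is.finite(total) || total <= 0) {
    stop("total peak height is not positive; cannot weight", call. = FALSE)
  }
  sum(repeat_length * height) / total
}

#' Average repeat gain versus baseline
#'
#' The difference between a sample's weighted mean repeat length and its
#' lineage's baseline (day-0) weighted mean. Baseline samples yield 0 by
#' construction.
#'
#' @param sample_mean Weighted mean repeat of the sample.
#' @param baseline_mean Weighted mean repeat of the lineage at day 0 (the
#'   arithmetic mean across day-0 replicates, if several).
#' @return Gain in repeat units.
#' @export
average_repeat_gain <- function(sample_mean, baseline_mean) {
  if (any(is.na(baseline_mean))) {
    stop("baseline mean is missing; lineage has no day-0 sample",
         call. = FALSE)
  }
  sample_mean - baseline_mean
}

#' Repeat gain per week from a through-origin fit
#'
#' Fits gain ~ weeks with the intercept fixed at zero, since the gain at
#' time 0 is 0 by definition. The slope has the closed form
#' sum(t * g) / sum(t^2) over the non-baseline points; with a single
#' timepoint it reduces to gain divided by weeks.
#'
#' @param weeks Elapsed weeks per point.
#' @param gain Average repeat gain per point.
#' @return Slope in repeat units per week.
#' @export
#' @examples
#' gain_per_week(c(0, 2, 4), c(0, 1.8, 4.2))  # 1.02
gain_per_week <- function(weeks, gain) {
  keep <- !is.na(weeks) & !is.na(gain)
  weeks <- weeks[keep]
  gain <- gain[keep]
  nonzero <- weeks > 0
  if (!any(nonzero)) {
    stop("all points are at week 0; slope is undefined", call. = FALSE)
  }
  sum(weeks * gain) / sum(weeks^2)
}

#' Optional linear detrending of raw trace heights
#'
#' Raw electropherogram signal loses amplitude with increasing fragment
#' size when no baseline correction has been applied upstream. This
#' utility divides each height by a linear trend fitted to the heights
#' over bp, re-levelling the trace. The metric chain assumes heights are
#' already bias-corrected (as instrument software does), so this is off
#' by default and provided as plumbing for raw exports.
#'
#' @param trace Peak tibble with `size_bp` and `height`.
#' @return The tibble with detrended `height`.
#' @export
detrend_heights <- function(trace) {
  if (nrow(trace) < 3L) return(trace)
  fit <- stats::lm(height ~ size_bp, data = trace)
  trend <- stats::fitted(fit)
  trend[trend <= 0] <- min(trace$height[trace$height > 0])
  trace$height <- trace$height * mean(trend) / trend
  trace
}

#' Run the full instability metric chain over a timecourse
#'
#' Per sample: modal peak, window/threshold filter, weighted mean repeat,
#' average repeat gain versus the lineage baseline. Per lineage (clone x
#' treatment x replicate by default): repeat gain per week from the
#' through-origin fit. Lineages with only day-0 samples get gain rows of 0
#' and a missing `gain_per_week` with a warning.
#'
#' @param traces Calibrated, annotated peak tibble (see
#'   [apply_calibration()] and [join_sample_sheet()]); standards are
#'   ignored.
#' @param cfg A [metrics_config()].
#' @param lineage_cols Metadata columns defining a lineage; defaults to
#'   `clone_id`, `treatment` and, when present, `replicate`.
#' @return A list with `samples` (one row per sample: `sample_id`, lineage
#'   columns, `timepoint_days`, `weeks`, `modal_repeat`, `modal_height`,
#'   `weighted_mean_repeat`, `n_peaks_used`, `average_repeat_gain`) and
#'   `lineages` (one row per lineage with `gain_per_week` and
#'   `n_timepoints`).
#' @export
analyze_timecourse <- function(traces, cfg = metrics_config(),
                               lineage_cols = NULL) {
  if (is.null(lineage_cols)) {
    lineage_cols <- intersect(c("clone_id", "treatment", "replicate"),
                              names(traces))
  }
  stopifnot(length(lineage_cols) > 0,
            all(c("sample_id", "timepoint_days", "repeat_length",
                  "height") %in% names(traces)))
  if ("known_repeat" %in% names(traces)) {
    traces <- traces[is.na(traces$known_repeat), , drop = FALSE]
  }

  per_sample <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sample_id", lineage_cols, "timepoint_days")))) |>
    dplyr::group_modify(function(df, key) {
      modal <- call_modal_peak(df$repeat_length, df$height)
      kept <- filter_window_threshold(df, modal, cfg)
      tibble::tibble(
        modal_repeat = modal$modal_repeat,
        modal_height = modal$modal_height,
        weighted_mean_repeat = weighted_mean_repeat(kept$repeat_length,
                                                    kept$height),
        n_peaks_used = nrow(kept)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(weeks = .data$timepoint_days / cfg$week_days)

  baselines <- per_sample |>
    dplyr::filter(.data$timepoint_days == 0) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(lineage_cols))) |>
    dplyr::summarise(baseline_mean = mean(.data$weighted_mean_repeat),
                     .groups = "drop")

  per_sample <- dplyr::left_join(per_sample, baselines, by = lineage_cols)
  if (any(is.na(per_sample$baseline_mean))) {
    missing <- per_sample |>
      dplyr::filter(is.na(.data$baseline_mean)) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(lineage_cols)))
    stop("lineage(s) without a day-0 baseline sample: ",
         paste(do.call(paste, c(missing, sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  per_sample$average_repeat_gain <-
    average_repeat_gain(per_sample$weighted_mean_repeat,
                        per_sample$baseline_mean)

  lineages <- per_sample |>
    dplyr::group_by(dplyr::across(dplyr::all_of(lineage_cols))) |>
    dplyr::summarise(
      gain_per_week = if (any(.data$weeks > 0)) {
        gain_per_week(.data$weeks, .data$average_repeat_gain)
      } else NA_real_,
      n_timepoints = dplyr::n_distinct(.data$timepoint_days),
      .groups = "drop"
    )
  if (any(is.na(lineages$gain_per_week))) {
    warning("lineage(s) with only day-0 samples: gain_per_week not ",
            "estimable", call. = FALSE)
  }
  per_sample <- dplyr::arrange(
    per_sample,
    dplyr::across(dplyr::all_of(c(lineage_cols, "timepoint_days",
                                  "sample_id"))))
  list(samples = per_sample, lineages = lineages)
}
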