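#' Fit a per-run bp-to-repeat calibration
#'
#' Capillary runs drift slightly in their size calibration, so repeat
#' lengths are mapped from fragment size separately for each run using
#' standards of known repeat length. Each standard is represented by its
#' modal (highest) peak's size in bp, and an ordinary least-squares line
#' `known_repeat ~ modal_bp` is fit, giving repeat(bp) = intercept +
#' slope * bp. For a pure CAG tract the slope should be close to 1/3
#' repeats per bp; a fit outside [0.25, 0.45] triggers a warning.
#'
#' @param standards Annotated peak tibble (see [join_sample_sheet()])
#'   containing the run's standard samples, i.e. rows with a non-missing
#'   `known_repeat`.
#' @param run_id Run to calibrate; standards are filtered to this run.
#' @return An object of class `calibration_model`: a list with `run_id`,
#'   `slope`, `intercept`, `n_standards`, `residuals` (repeat units, named
#'   by sample), and `bp_range` (bp span of the standards, used to flag
#'   extrapolation).
#' @export
#' @examples
#' peaks <- tibble::tibble(
#'   sample_id = c("std100", "std115"), run_id = "run1",
#'   size_bp = c(379, 424), height = c(1000, 1000),
#'   known_repeat = c(100, 115)
#' )
#' m <- fit_calibration(peaks, "run1")
#' m$slope      # 1/3
#' m$intercept  # -79/3
fit_calibration <- function(standards, run_id) {
  if ("run_id" %in% names(standards)) {
    standards <- standards[standards$run_id %in% run_id, , drop = FALSE]
  }
  standards <- standards[!is.na(standards$known_repeat), , drop = FALSE]
  if (nrow(standards) == 0L) {
    stop("no standards with known_repeat in run '", run_id, "'",
         call. = FALSE)
  }

  anchors <- standards |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      modal_bp = .data$size_bp[which.max(.data$height)],
      known_repeat = .data$known_repeat[1],
      .groups = "drop"
    )
  if (nrow(anchors) < 2L || length(unique(anchors$known_repeat)) < 2L) {
    stop("calibration for run '", run_id,
         "' needs >= 2 standards with distinct known repeat lengths",
         call. = FALSE)
  }
  if (length(unique(anchors$modal_bp)) < 2L) {
    stop("calibration standards for run '", run_id,
         "' have identical modal bp (collinear design)", call. = FALSE)
  }

  fit <- stats::lm(known_repeat ~ modal_bp, data = anchors)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    stop("calibration slope for run '", run_id,
         "' is not positive; check standards", call. = FALSE)
  }
  if (slope < 0.25 || slope > 0.45) {
    warning("calibration slope ", signif(slope, 4), " for run '", run_id,
            "' is outside [0.25, 0.45] repeats/bp, unusual for a CAG tract",
            call. = FALSE)
  }
  structure(
    list(
      run_id = run_id,
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      n_standards = nrow(anchors),
      residuals = stats::setNames(unname(stats::residuals(fit)),
                                  anchors$sample_id),
      bp_range = range(anchors$modal_bp)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> run %s: repeat = %.6g + %.6g * bp (%d standards, max |resid| %.3g)\n",
    x$run_id, x$intercept, x$slope, x$n_standards,
    if (length(x$residuals)) max(abs(x$residuals)) else NA_real_))
  invisible(x)
}

#' Fit calibrations for every run in an annotated peak table
#'
#' @param peaks Annotated peak tibble containing standards for each run.
#' @return A named list of [fit_calibration()] models, one per run.
#' @export
fit_calibrations <- function(peaks) {
  runs <- unique(peaks$run_id[!is.na(peaks$known_repeat)])
  if (!length(runs)) {
    stop("no runs with calibration standards found", call. = FALSE)
  }
  stats::setNames(lapply(runs, function(r) fit_calibration(peaks, r)), runs)
}

#' Convert fragment sizes to repeat units
#'
#' Applies a per-run affine calibration to a peak table, adding a
#' `repeat_length` column (fractional repeats are retained; no rounding).
#' Peaks sized beyond the bp span of the run's standards are converted but
#' flagged in the logical `extrapolated` column.
#'
#' @param model A `calibration_model`, or a named list of them (one per
#'   run) as returned by [fit_calibrations()].
#' @param trace Peak tibble; must carry `run_id` unless `force = TRUE`.
#' @param force Apply a single model across runs without matching
#'   `run_id` (cross-run application is otherwise an error).
#' @return The tibble with `repeat_length` and `extrapolated` columns,
#'   sorted so that repeat ordering mirrors bp ordering.
#' @export
apply_calibration <- function(model, trace, force = FALSE) {
  if (inherits(model, "calibration_model")) {
    if (!force) {
      runs <- unique(trace$run_id)
      if (!("run_id" %in% names(trace)) ||
          !all(runs %in% model$run_id)) {
        stop("trace run_id does not match calibration run '",
             model$run_id, "' (use force = TRUE to override)",
             call. = FALSE)
      }
    }
    trace$repeat_length <- model$intercept + model$slope * trace$size_bp
    trace$extrapolated <- trace$size_bp < model$bp_range[1] |
      trace$size_bp > model$bp_range[2]
    return(trace)
  }
  # named list of models: dispatch by run
  missing_runs <- setdiff(unique(trace$run_id), names(model))
  if (length(missing_runs)) {
    stop("no calibration model for run(s): ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  }
  parts <- lapply(split(trace, trace$run_id), function(chunk) {
    apply_calibration(model[[chunk$run_id[1]]], chunk)
  })
  dplyr::bind_rows(parts)
}

#' Invert a calibration (repeat units back to bp)
#'
#' @param model A `calibration_model`.
#' @param repeat_length Repeat lengths to convert.
#' @return Fragment sizes in bp.
#' @export
invert_calibration <- function(model, repeat_length) {
  (repeat_length - model$intercept) / model$slope
}

#' Write a calibration report
#'
#' One CSV row per run: `run_id`, `slope`, `intercept`, `n_standards`,
#' `max_abs_residual`.
#'
#' @param models Named list of `calibration_model` objects.
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
calibration_report <- function(models, path = NULL) {
  report <- dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(
      run_id = m$run_id, slope = m$slope, intercept = m$intercept,
      n_standards = m$n_standards,
      max_abs_residual = if (length(m$residuals)) max(abs(m$residuals))
                         else NA_real_
    )
  }))
  if (!is.null(path)) readr::write_csv(report, path)
  invisible(report)
}
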