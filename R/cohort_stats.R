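#' Normalize lineage rates to the vehicle group within each clone
#'
#' Clonal cell lines differ systematically in their expansion rate, so
#' treatment effects are expressed relative to each clone's vehicle
#' (e.g. DMSO) rate: every lineage's `gain_per_week` is divided by the
#' mean vehicle `gain_per_week` of the same clone. Vehicle rows then
#' average to 1 within each clone.
#'
#' @param results Lineage-level tibble (e.g. `analyze_timecourse()$lineages`)
#'   with a `treatment` column and the value column.
#' @param vehicle_label Treatment label of the vehicle group (default
#'   `"DMSO"`).
#' @param clone_col Column identifying the clone (default `"clone_id"`).
#' @param value_col Column to normalize (default `"gain_per_week"`).
#' @return The tibble with an added `relative_gain` column.
#' @export
normalize_to_vehicle <- function(results, vehicle_label = "DMSO",
                                 clone_col = "clone_id",
                                 value_col = "gain_per_week") {
  stopifnot(all(c("treatment", clone_col, value_col) %in% names(results)))
  vehicle <- results[results$treatment == vehicle_label, , drop = FALSE]
  means <- vehicle |>
    dplyr::group_by(dplyr::across(dplyr::all_of(clone_col))) |>
    dplyr::summarise(.vehicle_mean = mean(.data[[value_col]]),
                     .groups = "drop")
  missing <- setdiff(unique(results[[clone_col]]), means[[clone_col]])
  if (length(missing)) {
    stop("clone(s) without a '", vehicle_label, "' vehicle lineage: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(means$.vehicle_mean == 0)) {
    stop("vehicle mean gain_per_week is zero for clone(s): ",
         paste(means[[clone_col]][means$.vehicle_mean == 0],
               collapse = ", "), "; relative gain is undefined",
         call. = FALSE)
  }
  out <- dplyr::left_join(results, means, by = clone_col)
  out$relative_gain <- out[[value_col]] / out$.vehicle_mean
  out$.vehicle_mean <- NULL
  out
}

#' Welch two-sample contrast on the difference or ratio scale
#'
#' Two-tailed Welch (unequal-variance) t-test between two groups of
#' replicate values. On the `"difference"` scale the estimate is the mean
#' difference a - b with its 95% CI. On the `"ratio"` scale values must be
#' positive; the test is run on log-transformed values and the estimate
#' and CI are exponentiated, giving a fold change a/b.
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @param scale `"difference"` or `"ratio"`.
#' @param group_a,group_b Labels carried into the result.
#' @return A one-row tibble: `group_a`, `group_b`, `scale`, `estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, scale = c("difference", "ratio"),
                           group_a = "a", group_b = "b") {
  scale <- match.arg(scale)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (scale == "ratio") {
    if (any(a <= 0) || any(b <= 0)) {
      stop("ratio-scale contrast requires strictly positive values",
           call. = FALSE)
    }
    tt <- stats::t.test(log(a), log(b), var.equal = FALSE)
    est <- exp(unname(diff(rev(tt$estimate))))
    ci <- exp(tt$conf.int)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    est <- unname(diff(rev(tt$estimate)))
    ci <- tt$conf.int
  }
  tibble::tibble(
    group_a = group_a, group_b = group_b, scale = scale,
    estimate = est, ci_low = ci[1], ci_high = ci[2],
    p_value = if (is.nan(tt$p.value)) 1 else tt$p.value,
    n_a = length(a), n_b = length(b)
  )
}

#' Mean with a t-based 95% confidence interval
#'
#' @param values Numeric vector, length >= 2.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_group <- function(values, conf_level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to summarize", call. = FALSE)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tibble::tibble(mean = m, ci_low = m - tcrit * se, ci_high = m + tcrit * se,
                 n = n)
}
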