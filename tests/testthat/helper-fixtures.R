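# Shared fixture builders; everything is generated in code at test time.

make_trace <- function(repeat_length, height) {
  tibble::tibble(repeat_length = repeat_length, height = height)
}

# Minimal GeneMapper-style export written to a temp file.
write_gm_export <- function(rows, path = tempfile(fileext = ".txt")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

gm_rows <- function(sample, size, height, area = NA, dye = "B") {
  df <- data.frame(a = sample, b = dye, c = size, d = height, e = area,
                   check.names = FALSE)
  names(df) <- c("Sample File", "Dye", "Size", "Height", "Area")
  df
}

# Deterministic drifting populations: a fixed height shape translated by
# drift * weeks, so the weighted mean moves by exactly drift per week.
deterministic_populations <- function(days, drift_per_week,
                                      shape_repeats = 111:119,
                                      shape_counts = c(1, 3, 8, 15, 20,
                                                       15, 8, 3, 1) * 10) {
  dplyr::bind_rows(lapply(days, function(d) {
    tibble::tibble(timepoint_days = d,
                   repeat_length = shape_repeats + drift_per_week * d / 7,
                   count = shape_counts)
  }))
}

# Render a list of per-replicate populations into one annotated,
# calibrated table ready for analyze_timecourse().
render_and_calibrate <- function(pop_list, cfg) {
  pieces <- lapply(seq_along(pop_list), function(i) {
    out <- render_peak_table(pop_list[[i]], cfg,
                             standards = if (i == 1) c(95, 115, 135)
                                         else numeric(0),
                             sample_prefix = sprintf("rep%d", i),
                             seed = NULL)
    out$sheet$replicate <- i
    out
  })
  peaks <- dplyr::bind_rows(lapply(pieces, `[[`, "peaks"))
  sheet <- dplyr::bind_rows(lapply(pieces, `[[`, "sheet"))
  sheet$replicate[!is.na(sheet$known_repeat)] <- NA_integer_
  annotated <- suppressWarnings(join_sample_sheet(peaks, sheet))
  models <- fit_calibrations(annotated)
  apply_calibration(models, annotated)
}

# Independent Welch t-test oracle (textbook formulas).
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
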