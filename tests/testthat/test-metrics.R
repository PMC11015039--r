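test_that("modal peak is the highest, ties break to the smaller repeat", {
  expect_equal(call_modal_peak(c(113, 115, 117), c(100, 900, 300)),
               list(modal_repeat = 115, modal_height = 900))
  expect_equal(call_modal_peak(c(118, 110), c(500, 500)),
               list(modal_repeat = 110, modal_height = 500))
  expect_error(call_modal_peak(c(110, 111), c(0, 0)), "positive height")
})

test_that("window and height threshold apply the documented rule", {
  tr <- make_trace(c(74, 90, 90.5, 115, 155), c(600, 49, 50, 1000, 60))
  modal <- call_modal_peak(tr$repeat_length, tr$height)
  kept <- filter_window_threshold(tr, modal, metrics_config())
  # 74 outside [75,155]; 49 < 5% of 1000; boundary 50 kept (inclusive)
  expect_equal(kept$repeat_length, c(90.5, 115, 155))

  wide_open <- metrics_config(window_repeats = 1e9,
                              height_threshold_frac = 0)
  expect_equal(filter_window_threshold(tr, modal, wide_open), tr)
})

test_that("raising the threshold never retains more peaks", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    tr <- make_trace(sort(runif(n, 80, 150)), runif(n, 1, 1000))
    modal <- call_modal_peak(tr$repeat_length, tr$height)
    counts <- vapply(seq(0, 0.9, by = 0.1), function(f) {
      cfg <- metrics_config(height_threshold_frac = f)
      nrow(filter_window_threshold(tr, modal, cfg))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_true(all(counts >= 1))  # modal always survives
  }
})

test_that("weighted mean repeat matches the hand-summed example", {
  expect_equal(
    weighted_mean_repeat(c(113, 114, 115, 116, 117),
                         c(100, 300, 1000, 400, 200)),
    230300 / 2000)  # 115.15
  expect_equal(weighted_mean_repeat(c(100, 101, 102), c(1, 2, 1)), 101)
  expect_equal(weighted_mean_repeat(115, 7), 115)
  expect_error(weighted_mean_repeat(c(1, 2), c(0, 0)), "height")
})

test_that("weighted mean stays inside the analysis window", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    tr <- make_trace(sort(runif(n, 60, 180)), runif(n, 1, 1000))
    modal <- call_modal_peak(tr$repeat_length, tr$height)
    cfg <- metrics_config()
    kept <- filter_window_threshold(tr, modal, cfg)
    wm <- weighted_mean_repeat(kept$repeat_length, kept$height)
    expect_gte(wm, modal$modal_repeat - cfg$window_repeats)
    expect_lte(wm, modal$modal_repeat + cfg$window_repeats)
  }
})

test_that("average repeat gain is the difference from baseline", {
  expect_equal(average_repeat_gain(117.4, 115.15), 2.25)
  expect_equal(average_repeat_gain(115.15, 115.15), 0)
  expect_error(average_repeat_gain(117, NA_real_), "baseline")
})

test_that("gain per week is the through-origin slope", {
  expect_equal(gain_per_week(c(0, 2, 4), c(0, 1.8, 4.2)),
               (2 * 1.8 + 4 * 4.2) / (4 + 16))  # 1.02
  expect_equal(gain_per_week(2, 3.0), 1.5)  # single-timepoint rule
  t <- c(0, 1, 2, 3)
  expect_equal(gain_per_week(t, 1.34 * t), 1.34, tolerance = 1e-12)
  expect_error(gain_per_week(c(0, 0), c(0, 0)), "week 0")
})

test_that("full chain recovers a deterministic +1/week drift exactly", {
  cfg <- simulation_config(n_molecules = sum(c(1, 3, 8, 15, 20, 15, 8,
                                               3, 1) * 10),
                           stutter_ratio = 0, noise_sd = 0,
                           sizing_sd_bp = 0, seed = 11)
  pops <- deterministic_populations(c(0, 7, 14, 21, 28),
                                    drift_per_week = 1)
  calibrated <- render_and_calibrate(list(pops), cfg)
  res <- analyze_timecourse(calibrated)
  expect_equal(res$lineages$gain_per_week, 1.0, tolerance = 1e-9)
  base <- res$samples$average_repeat_gain[res$samples$timepoint_days == 0]
  expect_equal(base, 0)
})

test_that("row order and height scaling do not change the metrics", {
  cfg <- simulation_config(n_molecules = 740, stutter_ratio = 0.15,
                           noise_sd = 0, sizing_sd_bp = 0, seed = 3)
  pops <- deterministic_populations(c(0, 7, 14), drift_per_week = 1.5)
  calibrated <- render_and_calibrate(list(pops), cfg)
  res1 <- analyze_timecourse(calibrated)

  shuffled <- calibrated[sample(nrow(calibrated)), ]
  res2 <- analyze_timecourse(shuffled)
  expect_equal(res2$samples, res1$samples)
  expect_equal(res2$lineages, res1$lineages)

  scaled <- calibrated
  scaled$height <- scaled$height * 37.5
  res3 <- analyze_timecourse(scaled)
  expect_equal(res3$samples$weighted_mean_repeat,
               res1$samples$weighted_mean_repeat, tolerance = 1e-12)
  expect_equal(res3$lineages$gain_per_week, res1$lineages$gain_per_week,
               tolerance = 1e-12)
})

test_that("a common stutter kernel leaves the repeat gain unchanged", {
  # convolving every timepoint with the same kernel shifts all weighted
  # means equally, so gains are invariant while the window covers the
  # full support
  days <- c(0, 7, 14, 21)
  base_cfg <- simulation_config(n_molecules = 740, stutter_ratio = 0,
                                noise_sd = 0, sizing_sd_bp = 0, seed = 5)
  stut_cfg <- base_cfg
  stut_cfg$stutter_ratio <- 0.3
  pops <- deterministic_populations(days, drift_per_week = 2)
  res0 <- analyze_timecourse(render_and_calibrate(list(pops), base_cfg))
  res1 <- analyze_timecourse(render_and_calibrate(list(pops), stut_cfg))
  expect_equal(res1$samples$average_repeat_gain,
               res0$samples$average_repeat_gain, tolerance = 1e-6)
})

test_that("lineages without later timepoints warn and report NA slope", {
  cfg <- simulation_config(n_molecules = 740, stutter_ratio = 0,
                           noise_sd = 0, sizing_sd_bp = 0, seed = 2)
  pops <- deterministic_populations(0, drift_per_week = 1)
  calibrated <- render_and_calibrate(list(pops), cfg)
  expect_warning(res <- analyze_timecourse(calibrated), "day-0")
  expect_true(is.na(res$lineages$gain_per_week))
  expect_equal(res$samples$average_repeat_gain, 0)
})

test_that("missing baselines are an error naming the lineage", {
  cfg <- simulation_config(n_molecules = 740, stutter_ratio = 0,
                           noise_sd = 0, sizing_sd_bp = 0, seed = 2)
  pops <- deterministic_populations(c(7, 14), drift_per_week = 1)
  pops <- pops[pops$timepoint_days > 0, ]
  peaks <- render_peak_table(pops, cfg, sample_prefix = "x")
  annotated <- join_sample_sheet(peaks$peaks, peaks$sheet)
  models <- fit_calibrations(annotated)
  calibrated <- apply_calibration(models, annotated)
  expect_error(analyze_timecourse(calibrated), "baseline")
})

test_that("height detrending levels a linearly biased trace", {
  tr <- tibble::tibble(size_bp = seq(300, 500, by = 10))
  tr$height <- 1000 * (1 - 0.001 * tr$size_bp)
  flat <- detrend_heights(tr)
  expect_lt(stats::sd(flat$height) / mean(flat$height), 1e-6)
})
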