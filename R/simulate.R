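#' Configuration for the synthetic repeat-instability generator
#'
#' The generator emulates fragment-analysis data from a cell model
#' carrying an expanded CAG tract: a near-monomodal starting population
#' around 110-115 repeats, stochastic per-molecule drift of the order of
#' 1-2 repeats per week, optional mixture components producing bimodal
#' distributions (as seen when repair-pathway genes are knocked out in
#' pooled edits), PCR stutter ladders, and a size-dependent loss of
#' signal amplitude.
#'
#' Expansion kinetics use a per-molecule Poisson-difference step: over an
#' interval of `w` weeks a molecule gains `Pois(lambda_gain * w) -
#' Pois(lambda_loss * w)` repeats, with `lambda_gain - lambda_loss` equal
#' to the component drift and `lambda_gain + lambda_loss =
#' max(dispersion, |drift|)` so drift and spread are controlled
#' independently (at `dispersion <= |drift|` the step is a pure Poisson
#' in the drift direction).
#'
#' @param n_molecules Number of molecules (alleles) in the population.
#' @param initial_repeat Starting repeat length (default 115).
#' @param drift_per_week Expected repeat gain per molecule per week; may
#'   be negative (contraction).
#' @param dispersion Per-week variance of the step when it exceeds
#'   |drift| (see Details).
#' @param mixture Optional list of `(weight, drift)` pairs; weights must
#'   sum to 1. Overrides `drift_per_week`.
#' @param stutter_ratio Geometric per-step stutter fraction in [0, 1):
#'   the k-th minus-direction stutter peak has height `stutter_ratio^k`
#'   of its parent.
#' @param stutter_plus_ratio Optional plus-direction stutter fraction
#'   (default 0; slippage is predominantly minus-direction).
#' @param amplicon_offset_bp Amplicon size in bp at 0 repeats.
#' @param bp_per_repeat Base pairs per repeat unit (3 for CAG).
#' @param height_bias_slope Fractional signal loss per bp of fragment
#'   size (0 = bias-corrected signal).
#' @param noise_sd Multiplicative (log-normal) height noise SD.
#' @param sizing_sd_bp Capillary sizing jitter SD in bp.
#' @param seed Integer seed making the whole generator deterministic.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_molecules = 10000, initial_repeat = 115,
                              drift_per_week = 1.34, dispersion = 0.5,
                              mixture = NULL, stutter_ratio = 0.15,
                              stutter_plus_ratio = 0,
                              amplicon_offset_bp = 79, bp_per_repeat = 3,
                              height_bias_slope = 0, noise_sd = 0.05,
                              sizing_sd_bp = 0.15, seed = 1L) {
  if (n_molecules < 1) stop("n_molecules must be positive", call. = FALSE)
  stopifnot(bp_per_repeat > 0, stutter_ratio >= 0, stutter_ratio < 1,
            stutter_plus_ratio >= 0, stutter_plus_ratio < 1,
            dispersion >= 0, noise_sd >= 0, sizing_sd_bp >= 0)
  if (!is.null(mixture)) {
    w <- vapply(mixture, function(m) m$weight %||% m[[1]], numeric(1))
    if (abs(sum(w) - 1) > 1e-8) {
      stop("mixture weights must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(n_molecules = as.integer(n_molecules),
         initial_repeat = initial_repeat,
         drift_per_week = drift_per_week, dispersion = dispersion,
         mixture = mixture, stutter_ratio = stutter_ratio,
         stutter_plus_ratio = stutter_plus_ratio,
         amplicon_offset_bp = amplicon_offset_bp,
         bp_per_repeat = bp_per_repeat,
         height_bias_slope = height_bias_slope, noise_sd = noise_sd,
         sizing_sd_bp = sizing_sd_bp, seed = seed),
    class = "simulation_config"
  )
}

step_rates <- function(drift, dispersion) {
  v <- max(dispersion, abs(drift))
  c(gain = (v + drift) / 2, loss = (v - drift) / 2)
}

#' Simulate a repeat-population timecourse
#'
#' Evolves `n_molecules` repeat tracts over the requested timepoints.
#' Each molecule belongs to one mixture component (or the single default
#' component) and steps by a Poisson-difference draw per elapsed week;
#' trajectories are Markov in weeks and fully deterministic given the
#' seed.
#'
#' @param cfg A [simulation_config()].
#' @param timepoints_days Sampling days; must include 0.
#' @param seed Seed to apply (default `cfg$seed`; `NULL` uses the
#'   current RNG state).
#' @return A tibble with `timepoint_days`, `repeat_length`, `count`;
#'   counts at every timepoint sum to `n_molecules`.
#' @export
simulate_repeat_population <- function(cfg, timepoints_days,
                                       seed = cfg$seed) {
  if (!0 %in% timepoints_days) {
    stop("timepoints must include day 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  timepoints_days <- sort(unique(timepoints_days))

  comps <- cfg$mixture %||% list(list(weight = 1,
                                      drift = cfg$drift_per_week))
  w <- vapply(comps, function(m) m$weight %||% m[[1]], numeric(1))
  d <- vapply(comps, function(m) m$drift %||% m[[2]], numeric(1))
  n <- cfg$n_molecules
  # deterministic proportional split, remainder to the largest weights
  base <- floor(w * n)
  extra <- n - sum(base)
  if (extra > 0) {
    base[order(w * n - base, decreasing = TRUE)[seq_len(extra)]] <-
      base[order(w * n - base, decreasing = TRUE)[seq_len(extra)]] + 1L
  }
  comp_of <- rep(seq_along(comps), base)

  state <- rep(cfg$initial_repeat, n)
  out <- vector("list", length(timepoints_days))
  prev_day <- 0
  for (i in seq_along(timepoints_days)) {
    day <- timepoints_days[i]
    dw <- (day - prev_day) / 7
    if (dw > 0) {
      for (k in seq_along(comps)) {
        idx <- comp_of == k
        if (!any(idx)) next
        rates <- step_rates(d[k], cfg$dispersion)
        m <- sum(idx)
        state[idx] <- state[idx] +
          stats::rpois(m, rates["gain"] * dw) -
          stats::rpois(m, rates["loss"] * dw)
      }
    }
    tab <- table(state)
    out[[i]] <- tibble::tibble(
      timepoint_days = day,
      repeat_length = as.numeric(names(tab)),
      count = as.integer(tab)
    )
    prev_day <- day
  }
  dplyr::bind_rows(out)
}

#' Render repeat populations as a GeneMapper-style peak table
#'
#' Each allele of repeat length r becomes a peak at `amplicon_offset_bp +
#' bp_per_repeat * r` with height proportional to its molecule count.
#' PCR stutter adds minus-direction ladder peaks at geometric fractions
#' of the parent height; heights are then attenuated linearly with
#' fragment size (the negative signal bias of uncorrected traces),
#' jittered multiplicatively, and peak positions blurred by capillary
#' sizing noise. Standards are emitted as extra noiseless single-peak
#' traces with `known_repeat` set.
#'
#' @param populations Tibble from [simulate_repeat_population()].
#' @param cfg The [simulation_config()] used to generate them.
#' @param standards Numeric vector of known repeat lengths for the
#'   calibration standards (default `c(95, 115, 135)`).
#' @param run_id Run label for all emitted traces.
#' @param sample_prefix Prefix for generated sample ids.
#' @param seed Seed (default `cfg$seed + 1`; `NULL` uses current state).
#' @return A list with `peaks` (peak tibble: `sample_id`, `dye`,
#'   `size_bp`, `height`, `area`) and `sheet` (matching sample sheet
#'   rows).
#' @export
render_peak_table <- function(populations, cfg,
                              standards = c(95, 115, 135),
                              run_id = "run1", sample_prefix = "sim",
                              seed = if (is.null(cfg$seed)) NULL
                                     else cfg$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  height_scale <- 10000 / cfg$n_molecules

  render_one <- function(pop, sample_id) {
    h <- stats::setNames(pop$count * height_scale,
                         as.character(pop$repeat_length))
    # minus-direction geometric stutter ladder, floored at 1e-3 of parent
    ladder <- list(h)
    for (dir in c(-1, 1)) {
      ratio <- if (dir < 0) cfg$stutter_ratio else cfg$stutter_plus_ratio
      if (ratio <= 0) next
      k_max <- ceiling(log(1e-3) / log(ratio))
      for (k in seq_len(k_max)) {
        shifted <- stats::setNames(
          h * ratio^k, as.character(pop$repeat_length + dir * k))
        ladder[[length(ladder) + 1L]] <- shifted
      }
    }
    all_h <- unlist(ladder)
    agg <- tapply(all_h, names(all_h), sum)
    r <- as.numeric(names(agg))
    height <- as.numeric(agg)
    size <- cfg$amplicon_offset_bp + cfg$bp_per_repeat * r
    bias <- pmax(0, 1 - cfg$height_bias_slope * size)
    height <- height * bias
    if (all(height == 0)) {
      stop("height_bias_slope zeroes out every peak; lower it",
           call. = FALSE)
    }
    if (cfg$noise_sd > 0) {
      height <- height * exp(stats::rnorm(length(height), 0, cfg$noise_sd))
    }
    if (cfg$sizing_sd_bp > 0) {
      size <- size + stats::rnorm(length(size), 0, cfg$sizing_sd_bp)
    }
    ord <- order(size)
    tibble::tibble(sample_id = sample_id, dye = "B",
                   size_bp = size[ord], height = height[ord],
                   area = NA_real_)
  }

  days <- unique(populations$timepoint_days)
  peak_rows <- lapply(days, function(day) {
    pop <- populations[populations$timepoint_days == day, , drop = FALSE]
    render_one(pop, sprintf("%s_d%02d", sample_prefix, as.integer(day)))
  })
  sheet <- tibble::tibble(
    sample_id = sprintf("%s_d%02d", sample_prefix, as.integer(days)),
    run_id = run_id, clone_id = "clone1", treatment = "none",
    timepoint_days = days, is_baseline = days == 0,
    known_repeat = NA_real_
  )

  std_peaks <- lapply(seq_along(standards), function(i) {
    r <- standards[i]
    tibble::tibble(
      sample_id = sprintf("%s_std%d", sample_prefix, i), dye = "B",
      size_bp = cfg$amplicon_offset_bp + cfg$bp_per_repeat * r,
      height = 10000, area = NA_real_
    )
  })
  std_sheet <- tibble::tibble(
    sample_id = sprintf("%s_std%d", sample_prefix, seq_along(standards)),
    run_id = run_id, clone_id = NA_character_, treatment = NA_character_,
    timepoint_days = 0, is_baseline = FALSE, known_repeat = standards
  )

  list(peaks = dplyr::bind_rows(c(peak_rows, std_peaks)),
       sheet = dplyr::bind_rows(sheet, std_sheet))
}

#' Simulate a full multi-lineage timecourse experiment
#'
#' Generates one lineage per clone x treatment x replicate, each with a
#' baseline at day 0, renders all lineages plus one set of calibration
#' standards per run, and returns the joined, analysis-ready peak table
#' and sample sheet. Treatments scale the configured drift by their
#' multiplier, emulating instability-modifying drug or genetic
#' perturbations.
#'
#' @param cfg A [simulation_config()].
#' @param design List with `clones` (labels or count), `treatments`
#'   (named numeric drift multipliers, e.g. `c(DMSO = 1, drug = 0.5)`),
#'   `replicates` (count) and `timepoints_days` (must include 0).
#' @return A list with `peaks` and `sheet`, consumable by
#'   [join_sample_sheet()].
#' @export
simulate_timecourse <- function(cfg, design) {
  stopifnot(all(c("treatments", "replicates", "timepoints_days")
                %in% names(design)))
  if (!0 %in% design$timepoints_days) {
    stop("design must include day 0", call. = FALSE)
  }
  clones <- design$clones %||% "clone1"
  if (is.numeric(clones)) clones <- paste0("clone", seq_len(clones))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  grid <- expand.grid(clone_id = clones,
                      treatment = names(design$treatments),
                      replicate = seq_len(design$replicates),
                      stringsAsFactors = FALSE)
  pieces <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg_i <- cfg
    mult <- design$treatments[[g$treatment]]
    cfg_i$drift_per_week <- cfg$drift_per_week * mult
    if (!is.null(cfg_i$mixture)) {
      cfg_i$mixture <- lapply(cfg_i$mixture, function(m) {
        m$drift <- (m$drift %||% m[[2]]) * mult
        m
      })
    }
    pop <- simulate_repeat_population(cfg_i, design$timepoints_days,
                                      seed = NULL)
    prefix <- sprintf("%s_%s_r%d", g$clone_id, g$treatment, g$replicate)
    rendered <- render_peak_table(pop, cfg_i, standards = numeric(0),
                                  run_id = "run1", sample_prefix = prefix,
                                  seed = NULL)
    rendered$sheet$clone_id <- g$clone_id
    rendered$sheet$treatment <- g$treatment
    rendered$sheet$replicate <- g$replicate
    rendered
  })

  # shared per-run standards, noiseless
  std <- render_peak_table(
    tibble::tibble(timepoint_days = 0, repeat_length = cfg$initial_repeat,
                   count = cfg$n_molecules),
    cfg, standards = c(95, 115, 135), run_id = "run1",
    sample_prefix = "cal", seed = NULL)
  std$peaks <- std$peaks[grepl("_std", std$peaks$sample_id), , drop = FALSE]
  std$sheet <- std$sheet[grepl("_std", std$sheet$sample_id), , drop = FALSE]
  std$sheet$replicate <- NA_integer_

  peaks <- dplyr::bind_rows(c(lapply(pieces, `[[`, "peaks"),
                              list(std$peaks)))
  sheet <- dplyr::bind_rows(c(lapply(pieces, `[[`, "sheet"),
                              list(std$sheet)))
  list(peaks = peaks, sheet = sheet)
}

#' Simulate CRISPR amplicon editing-outcome tables
#'
#' For each clone in `truth`, emits an allele table with either one
#' dominant signature (homozygous) or two near-equal signatures
#' (heterozygous), plus an `error_rate` fraction of reads scattered over
#' spurious signatures, emulating sequencing and PCR noise.
#'
#' @param truth Tibble with `clone_id` and `zygosity`
#'   (`"homozygous"`/`"heterozygous"`).
#' @param error_rate Fraction of noise reads, in [0, 0.2].
#' @param n_reads Reads per clone (default 2000).
#' @param seed Optional seed.
#' @return Allele tibble with `clone_id`, `signature`, `reads`,
#'   `is_reference`.
#' @export
simulate_editing_outcomes <- function(truth, error_rate, n_reads = 2000,
                                      seed = NULL) {
  if (error_rate < 0 || error_rate > 0.2) {
    stop("error_rate must be in [0, 0.2]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  spurious <- paste0("noise_", 1:4)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    hom <- truth$zygosity[i] == "homozygous"
    alleles <- if (hom) "+1A_ins" else c("+1A_ins", "-2_del")
    p_true <- rep((1 - error_rate) / length(alleles), length(alleles))
    p <- c(p_true, rep(error_rate / length(spurious), length(spurious)))
    counts <- as.integer(stats::rmultinom(1, n_reads, p))
    tibble::tibble(
      clone_id = truth$clone_id[i],
      signature = c(alleles, spurious),
      reads = counts,
      is_reference = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  out[out$reads > 0, , drop = FALSE]
}
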