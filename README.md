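# repeatgain

Quantifies somatic CAG-repeat instability from capillary-electrophoresis
fragment analysis, for labs that track trinucleotide-repeat expansion in
cell models over weeks of culture (e.g. an expanded *HTT* exon 1 tract
knocked into an immortalized line) and need a reproducible route from
instrument peak tables to per-lineage expansion rates and treatment
contrasts. The package also ships two companion tools from the same kind
of study: an 85%-rule zygosity caller for CRISPR amplicon editing
outcomes, and a splice-junction saturation-mutagenesis screen with a
pluggable splice scorer.

## The metric chain

Fragment peaks (bp, height) are converted to repeat units with a per-run
affine calibration fit on standards of known repeat length:

    repeat(bp) = a + b * bp        (OLS of known repeat on modal-peak bp)

For each sample, the **modal repeat** m is the repeat length of the
highest peak. Peaks are restricted to a window of ±40 repeats around m
and to heights ≥ 5% of the modal height, then summarized by the
height-weighted mean repeat length:

    WMR = Σ r_i h_i / Σ h_i

The **average repeat gain** of a sample is its WMR minus its lineage's
day-0 WMR. The **gain per week** of a lineage is the slope of a linear
fit of gain on elapsed weeks with the intercept fixed at the origin,

    slope = Σ t_i g_i / Σ t_i²

which reduces to g/t when only one later timepoint exists. Treatment
effects are expressed per clone relative to the vehicle (DMSO) group and
compared with two-tailed Welch t-tests.

A synthetic-data generator (per-molecule Poisson-difference drift, PCR
stutter ladders, size-dependent signal bias, capillary sizing jitter)
provides the test bed; the whole pipeline is validated by recovering
known simulated drift rates.

## Worked example

```r
library(repeatgain)

cfg <- simulation_config(n_molecules = 5000, drift_per_week = 1.34, seed = 7)
sim <- simulate_timecourse(cfg, list(
  clones = 2, treatments = c(DMSO = 1, branaplam = 0.6), replicates = 3,
  timepoints_days = c(0, 7, 14, 21, 28)))

annotated  <- join_sample_sheet(sim$peaks, sim$sheet)
models     <- fit_calibrations(annotated)
calibrated <- apply_calibration(models, annotated)
res        <- analyze_timecourse(calibrated)
res$lineages
#>    clone_id treatment replicate gain_per_week n_timepoints
#>  1 clone1   DMSO              1         1.32             5
#>  2 clone1   DMSO              2         1.27             5
#>  3 clone1   DMSO              3         1.33             5
#>  4 clone1   branaplam         1         0.798            5
#>  ...
#> 12 clone2   branaplam         3         0.792            5

rel <- normalize_to_vehicle(res$lineages)
compare_groups(rel$relative_gain[rel$treatment == "branaplam"],
               rel$relative_gain[rel$treatment == "DMSO"],
               scale = "ratio", group_a = "branaplam", group_b = "DMSO")
#>   group_a   group_b scale estimate ci_low ci_high  p_value  n_a  n_b
#> 1 branaplam DMSO    ratio    0.603  0.592   0.614 6.86e-12    6    6
```

The simulated vehicle lineages expand at ~1.3 repeats/week, the treated
lineages at ~0.79; after clone-wise vehicle normalization the estimated
fold change is 0.60 (95% CI 0.59–0.61), recovering the configured 0.6×
drift multiplier.

The same stages are scriptable from a shell via the thin wrapper in
`inst/cli/repeatgain.R` (subcommands `simulate`, `calibrate`, `metrics`,
`stats`, `zygosity`, `screen`; defaults `--window 40`,
`--height-threshold 0.05`, `--flank 50`, `--delta-threshold 0.1`).

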