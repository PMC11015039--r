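---
title: "Measuring somatic repeat instability from fragment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring somatic repeat instability from fragment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatgain)
```

## The measurement problem

Somatic expansion of CAG repeats is a population phenomenon: within one
culture, individual DNA molecules carry slightly different repeat
lengths, and the whole distribution drifts longer over weeks. Capillary
electrophoresis of a repeat-spanning amplicon renders that distribution
as a ladder of peaks — one per repeat length, blurred by PCR stutter —
whose heights are proportional to molecule abundance. The quantity of
interest is not any single allele but how the *population mean* moves
with time, per lineage (one clone under one treatment in one well).

`repeatgain` implements the full chain from instrument peak tables to
per-lineage expansion rates, plus the treatment-contrast layer, a CRISPR
zygosity caller, a splice-junction saturation-mutagenesis screen, and
the synthetic-data generator used to validate everything.

## From base pairs to repeat units

Fragment sizes come out of the instrument in bp and must be converted to
repeat units. Because sizing drifts slightly between capillary runs, a
separate affine map is fit per run by ordinary least squares of known
repeat length on the modal-peak bp of each standard:

$$\text{repeat}(x) = a + b\,x$$

Design choices, where the procedure itself leaves them open:

* **Regression direction.** We fit repeat ~ bp rather than bp ~ repeat,
  so applying the calibration is a single affine evaluation. With two
  standards both directions give the same line; with more, the
  difference is negligible at the sub-repeat residuals typical of
  standards.
* **Anchor peak.** Each standard is represented by its modal (highest)
  peak, the standard's nominal allele.
* **No rounding.** Fractional repeat lengths are retained throughout;
  the weighted mean is a continuous statistic and integer binning would
  only add quantization error.
* For a pure CAG tract the slope should be ≈ 1/3 repeats/bp; fits
  outside [0.25, 0.45] warn. Peaks beyond the standards' bp span are
  converted but flagged as extrapolated. Runs without standards are
  refused rather than silently borrowing a pooled model.

## The instability metrics

Per sample: the **modal repeat** is the highest peak (ties break toward
the smaller repeat — a deterministic rule; ties are measure-zero on real
data). Analysis is restricted to a window of ±40 repeat units around the
modal repeat with a height threshold of 5% of the modal height, then the
**weighted mean repeat** $\sum r_i h_i / \sum h_i$ is computed.
**Average repeat gain** is the difference from the lineage's day-0
weighted mean (the arithmetic mean across day-0 replicates, if there are
several). **Gain per week** is the slope of gain on weeks with the
intercept pinned at the origin — the gain at time zero is zero by
construction — with closed form $\sum t_i g_i / \sum t_i^2$; a single
later timepoint reduces to $g/t$. Weeks are `timepoint_days / 7`
exactly.

Numerical conventions:

* The height threshold is **inclusive** (≥ 5% of modal height), and the
  window is applied before the threshold; for this modal-anchored rule
  the two orders retain the same peak set, only the per-step counts
  differ.
* Points at (0, 0) participate in the through-origin fit; they
  contribute nothing to either sum and are kept for transparency.
* All metrics are invariant to a positive rescaling of heights (the
  threshold is relative), and a stutter kernel applied identically at
  all timepoints cancels exactly in the gain, because convolution with a
  fixed kernel shifts every timepoint's weighted mean by the same
  constant while the window covers the full support.

Heights are assumed baseline-corrected upstream, as instrument software
does before exporting sized peaks; raw uncorrected traces lose amplitude
with fragment size, and `detrend_heights()` is provided (off by default)
to re-level such exports.

Two properties of the thresholded metric are worth knowing. First,
clipping at 5% of the modal height trims distribution tails; for the
right-skewed distributions that unidirectional expansion produces, this
gives a small proportional underestimate of the true population drift
(~2–3% in our validation runs) — a property of the metric itself, shared
by any thresholded estimator, not an implementation artifact. Second,
the ±40 window makes the metric robust to off-target amplification far
from the main population but means a lineage that drifts more than 40
repeats from baseline needs a wider window.

## Treatment contrasts

Clonal lines differ systematically in their baseline expansion rate, so
rates are first normalized per clone to the vehicle (DMSO) mean; vehicle
lineages then average to 1 within each clone and treated lineages read
as fold changes. Group contrasts are two-tailed Welch t-tests —
unequal-variance by default, since replicate variances differ across
treatments in practice. Ratio-scale estimates and CIs are computed on
log-transformed values and exponentiated. These are deliberately plain
t-based summaries, not model-based marginal effects; with few replicates
per group the two approaches differ little, and the t-based route keeps
the inferential machinery transparent.

## Zygosity calling

Amplicon-sequencing outcome tables are aggregated by indel signature
(position plus inserted/deleted sequence, not full read sequence, so
stray sequencing errors elsewhere in the read do not split an allele),
ranked by read fraction with a lexicographic tie-break, and a clone is
called homozygous when the top outcome exceeds — strictly — 85% of the
top-two mass. Reference alleles are eligible for either top-two slot, so
unedited clones call homozygous-reference. Single-outcome clones call
homozygous with a low-complexity warning. At 2% simulated sequencing
noise this rule is essentially error-free (200/200 correct calls in
validation); at 20% noise miscalls of heterozygotes appear, which is why
the simulator caps `error_rate` at 0.2.

## The pseudoexon saturation screen

Around each pseudoexon splice junction, the 50 nt on either side of the
exon–intron boundary are mutated to the three alternative nucleotides
(the boundary falls *between* positions, so 100 positions and 300 SNVs
per junction, truncated at sequence ends and de-duplicated across
overlapping windows). Each variant is scored by a pluggable backend —
any `function(sequence, junction)` returning a probability-like value in
[0, 1] — and classified by the signed delta against the reference
sequence: sensitizing at delta ≥ +0.1, interfering at ≤ −0.1. The 0.1
default is configurable; it sits well above the scorer's numerical noise
while keeping single-base consensus disruptions detectable. Variants
with a minor allele frequency above 1% are labelled common.

The shipped backend is a position-weight-matrix donor/acceptor scorer
built from consensus splice-site base frequencies, with summed
log-frequencies rescaled to [0, 1] between the worst and best possible
site. It is a real, if simple, splice-strength model: consensus sites
score exactly 1, disrupting the obligate GT/AG dinucleotides produces
large negative deltas, and — because deltas are score differences — the
reverse mutation exactly negates the forward one. It does not model
context beyond the site window, branch points, or exonic
splicing-regulatory elements, and its deltas are not calibrated against
any neural scorer's scale; conclusions about specific human variants
require plugging in such a scorer via the backend interface.

Minus-strand junctions are scored on the reverse-complemented window; an
exon is "annotated" when some annotation exon on the same sequence
matches both boundaries within 1 bp. Cross-dataset gene-set overlaps are
row-normalized (|row ∩ col| / |row|), hence asymmetric by design.

## The synthetic-data generator

The generator emulates the phenomenology of repeat-instability
experiments, not their biochemistry:

* **Drift.** Each molecule steps once per elapsed week by
  `Pois(λ_gain Δw) − Pois(λ_loss Δw)`, with `λ_gain − λ_loss` the
  component drift and `λ_gain + λ_loss = max(dispersion, |drift|)`.
  Drift and spread are thus controlled independently; at
  `dispersion ≤ |drift|` the step is a pure Poisson in the drift
  direction, and drift 0 with dispersion 0 is an exact fixed point.
  Defaults: 115 starting repeats (a typical juvenile-onset-range tract),
  drift 1.34 repeats/week (the magnitude seen in unperturbed engineered
  lines), dispersion 0.5/week.
* **Mixtures** of `(weight, drift)` components reproduce the bimodal
  distributions that arise when a repair-pathway gene is knocked out in
  a pooled population — one sub-population contracting or static, the
  other expanding.
* **Rendering.** An allele of r repeats sits at
  `amplicon_offset_bp + 3 r` bp (offset default 79). PCR stutter adds a
  minus-direction geometric ladder (`stutter_ratio^k`, default ratio
  0.15 — a placeholder, as stutter magnitude for 100+ CAG amplicons is
  not well characterized; it is exposed in the config). Heights decay
  linearly with fragment size when `height_bias_slope > 0` (default 0,
  i.e. bias-corrected signal), are jittered by multiplicative log-normal
  noise (default SD 0.05), and peak positions blur by Gaussian sizing
  error (default SD 0.15 bp). Standards render as noiseless single-peak
  traces.

What passing tests show — and what they do not. The generator produces
ideal single-locus traces: no off-scale peaks, no dye pull-up, no
ladder-misassignment, no secondary amplification products, and stutter
that is perfectly geometric and stationary. Pipeline validation on this
test bed demonstrates that the metric chain is internally correct
(exact on deterministic data, unbiased to within the stated tolerances
on stochastic data); it cannot certify performance on instrument
artifacts the generator does not emulate.

## Validation problem sizes

The validation suite runs the full pipeline at drifts {0, 0.5, 1, 2}
repeats/week with 10,000 molecules, 8 replicate lineages and weekly
timepoints over 4 weeks, recovering each drift within ±0.15; the 50/50
mixture of drifts 0 and 2 pools to 1.0 ± 0.15 with a strict interior
dip between modes at week 6; identical stutter at all timepoints moves
the estimated rate by < 0.05. Closed-form oracles (brute-force weighted
mean, through-origin slope vs. a pinned least-squares fit, exact affine
calibration recovery) run at 1000 random cases each, and Welch type-I
error and CI coverage are checked over 2000 null simulations. These
sizes give comfortable statistical resolution for the stated tolerances
while keeping the suite fast.

## Known limitations

* Per-run calibration assumes at least two standards per run; there is
  no local-regression (nonlinear) sizing correction.
* The expansion-rate estimator assumes gains accumulate linearly in
  time; saturating kinetics would need a different lineage-level model.
* The contrast layer offers plain t-based inference only — no
  mixed-effects modelling of clone as a random effect.
* The PWM splice scorer is a site-strength model, not a splicing code;
  see above.
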