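---
title: "Models and methods behind diaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind diaqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaqc)
```

# Scope

`diaqc` computes acquisition-level quality-control metrics for
data-independent acquisition (DIA) proteomics, with first-class support for
multiplexed plexDIA sets (non-isobaric mTRAQ labels, channels d0/d4/d8). It
covers four model areas: the Orbitrap duty-cycle timing model, the
elution-apex sampling model, data-driven MS2 isolation-window placement, and
the quality-control statistics computed from per-scan metadata and search
reports. A synthetic run generator ties them together so everything is
testable without instrument data. This vignette records the models, the
parameters that matter, and the design decisions that were genuinely open.

# Duty-cycle timing

A duty cycle is the repeating schedule of one or more MS1 survey scans and a
set of MS2 scans, one per isolation window. The per-scan time model is

```
scan_time = max(transient(resolving_power), max_injection_time) + overhead
```

because on an Orbitrap, ion accumulation for the next scan proceeds in
parallel with the running transient: a scan is limited by whichever is
longer. Transients follow the standard doubling law (64/128/256/512 ms at
17.5k/35k/70k/140k resolving power); the table is a configurable default
(`transient_ms()`), not a constant, because it differs across instrument
generations. `overhead_ms` defaults to 0; the parallel model with zero
overhead already reproduces the method timings we care about: a 1 MS1 + 2
MS2 method at 70k resolving power and 300 ms maximum injection gives a 0.9 s
cycle, and 1 MS1 + 16 MS2 gives a 5.1 s precursor sampling interval.

The MS1 sampling interval is defined as the **maximum** gap between
consecutive survey scans, computed across the cycle wrap-around
(`ms1_sampling_interval_s()`). With a single survey scan the gap equals the
cycle time; two evenly spaced survey scans in a 10-slot cycle shorten it to
5 scan times — almost, but not exactly, a halving, which is why adding a
survey scan is cheap relative to the sampling benefit.

# Apex sampling

Chromatographic peaks are modelled as Gaussians with SD `sigma_s` (seconds).
Sampling on a grid of spacing Δ with phase offset φ captures at most

```
exp(-d^2 / (2 sigma^2)),  d = distance from apex to the nearest sample
```

of the apex intensity. Under a uniform random phase, `d` is uniform on
[0, Δ/2], so the *median* captured fraction is `exp(-Δ^2 / (32 sigma^2))`
(`apex_sampling_ratio(..., phase = "median")`). This closed form is
cross-checked against Monte-Carlo phase sampling in the test suite (1e5
draws, 1% tolerance). `points_per_peak()` uses a base width of 4 sigma; that
constant is a convention (± 2 sigma covers ~95% of the peak area) and is
stated here rather than buried in code.

# Isolation-window placement

Three strategies produce a contiguous tiling of the precursor m/z range
(`validate_scheme()` enforces contiguity, positive widths, exact range
coverage to 1e-9 Th):

* `equal_mz_windows()` — n windows of equal width; the 380–1400 Th range at
  n = 8 gives 127.5 Th windows.
* `equal_tic_windows()` — boundaries at the k/n quantiles of the cumulative
  binned MS1 ion current, interpolated *linearly within bins* so that the
  result converges to the exact equal-current tiling as the histogram bin
  width shrinks (snap-to-edge would not). The m/z histogram default bin is
  2 Th.
* `equal_precursor_windows()` — boundaries at empirical k/n quantiles of
  identified precursor m/z, placed at the midpoint between adjacent order
  statistics. When duplicated m/z values straddle a cut, the cut shifts to
  the nearest position between distinct values; with heavy ties a ±1 count
  split can be infeasible, in which case the nearest feasible cut is used.

Windows are half-open `[lower, upper)`: a precursor exactly on a boundary
belongs to the upper window, which makes assignment deterministic. Boundary
rounding for instrument export (`round_scheme()`, 0.5 Th grid) is off by
default because it perturbs the equalization it follows.

# Quality-control metrics

* **Data completeness** is the Jaccard index |A∩B| / |A∪B| between
  identification sets, computed pairwise by channel or run. Two empty sets
  are defined complete (J = 1) with a warning. Across channels a precursor
  is keyed by its *stripped* sequence and charge, because the modified
  sequence embeds the channel's label tag.
* **Quantification variability** (single-proteome quality): per cell
  (run × channel), peptide intensities are collapsed over charge states
  (summed), the cell is normalized by its median peptide intensity, each
  peptide is divided by its mean across cells (removing ionization
  efficiency), and the CV (sample SD / mean) is computed per protein with at
  least `min_peptides` (default 3) peptides; the cell's score is the median
  CV over proteins. The per-cell median normalization step is what makes the
  metric exactly invariant to global per-cell scaling — without it the
  cross-cell peptide means couple the cells and the invariance fails; we
  consider this the intended definition since the metric is meant to compare
  cells of differing total signal.
* **Ratio distributions** use only precursors identified in *all* compared
  groups, and report per-group log2 ratios to a reference. Poor apex
  sampling depresses these medians, which is the quantitative signature of
  an over-long duty cycle.
* **FDR curves** (`ids_vs_fdr()`) must be fed an unfiltered report.
* **Binned metrics** default to 60 s retention-time bins and 10 Th m/z bins,
  all half-open; these are display resolutions, not model parameters.
* **S/N** matches each precursor to the nearest MS1 scan in retention time
  and the closest centroid within ±10 ppm. Per-peak noise values are a
  vendor extension that plain mzML files do not carry, so S/N is reported as
  missing for mzML input and is exercised on simulator output, which carries
  a configured noise floor.

# The feature finder

`detect_features()` is a deliberately minimal trace builder: centroids in
consecutive MS1 scans within 10 ppm of a trace's running median m/z are
chained greedily; a trace survives one missed scan (robustness to sampling
dropouts) and must span `min_scans = 3` scans. A coeluting partner trace at
+1.00335/z (z = 1..4) assigns charge. This is *not* a reimplementation of a
production feature finder: there is no isotope-pattern scoring, no hill
splitting, and no profile-mode support. It is sufficient for the QC
questions it serves — how many peptide-like features a schedule can see and
how long their elution is — and its elution length "at base" is defined as
the RT span of the trace.

# The synthetic run generator

`simulate_run()` draws a 3-plex experiment under an explicit generative
model chosen to emulate a ~100-cell-equivalent bulk plexDIA run on a 30 min
active gradient:

* **m/z**: a two-component log-normal mixture (modes near 560 and 1000 Th,
  weights 0.45/0.55, truncated to 380–1400 Th), calibrated so that roughly
  60% of precursors fall below the range midpoint — peptide digests are
  bottom-heavy in m/z, which is exactly what makes equal-width windows
  suboptimal.
* **Retention**: each precursor elutes when the gradient (piecewise-linear,
  default 8–32% B over minutes 3–33) crosses a per-precursor %B threshold
  drawn uniformly on 9–31%; elution profiles are Gaussian with log-normal
  widths (median 2.2 s, log-SD 0.6, so base widths of roughly 4–20 s).
* **Abundance**: log-normal apex ion flux (median 3e5 charges/ms, log-SD
  1.15, i.e. ~2 decades between the 5th and 95th percentile). The scale is
  set so that a handful of co-eluting precursors fill the 3e6-charge AGC
  target within a few ms, while empty windows sit at the maximum injection
  time — the regime real 100-cell runs show.
* **Channels**: mTRAQ mass offsets of +4.0071 Da per label over charge, one
  label site; per-channel relative abundance factors and presence
  probabilities.
* **Scans**: scheduled by the duty-cycle module; each scan's injection time
  follows the AGC law `min(max_IT, AGC_target / flux)` with flux summed over
  sampled isotope envelopes (3 isotopes, fractions 0.6/0.3/0.1) plus a
  baseline noise floor of 2000 charges/ms.
* **Identification** is phenomenological, not a search-engine model: a
  channel precursor is directly identified when its within-window flux share
  at apex exceeds a threshold *and* a Bernoulli draw with probability
  logistic in the log signal-to-interference ratio succeeds — so busier
  windows identify proportionally less. Missed channel copies of an
  identified precursor are recovered as "translated" identifications with
  probability 0.7. q-values are drawn from a two-component mixture (passing
  IDs below 0.009, marginal rows at 0.011–0.6) so FDR-threshold curves are
  informative.
* **MS1 quantification**: a precursor is MS1-quantified iff some survey scan
  samples it above the LOD (1e5 flux units, per-scan sampled intensity, not
  apex); its quantity is the sampled peak height, which is what couples the
  survey-scan schedule to MS1 coverage and ratio accuracy.

What the generator does **not** emulate: fragment spectra and chimeric
deconvolution, retention-time/sequence relationships, ion-mobility
dimensions, profile peaks, and search-engine scoring. Passing tests
therefore demonstrate that the *metrics and placement algorithms* behave
correctly under a controlled model of the acquisition physics — not that any
particular instrument will show effects of the simulated size.

# Problem sizes and numerical choices

The test suite simulates runs of 80–500 precursors over 5–34 min schedules,
which keeps the default suite within a few minutes on one CPU while leaving
every qualitative comparison (window fill patterns, equal-TIC variance
reduction, survey-scan gains, channel-ratio recovery at n = 500) with a
clear margin. All simulator randomness flows from a single mandatory seed;
reruns are bit-identical, and the end-to-end pipeline writes byte-identical
metric TSVs on repeated runs. Equality tolerances: tiling invariants at
1e-9 Th; TIC conservation at 1e-6 relative; Monte-Carlo cross-checks at 1%.

# Known limitations

* The identification model's absolute ID counts are not comparable to real
  search-engine output; only directions and relative comparisons are
  meaningful.
* `equal_tic_windows()` inherits the histogram's bin resolution; with the
  2 Th default the boundary error is below half a bin.
* The feature finder undercounts overlapping isobaric features by design
  (single-trace model).
* MaxQuant-style DDA evidence files are out of scope; the reader interface
  accepts only the DIA-NN report dialect (with a small column alias map).
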