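# diaqc

Acquisition quality control and method optimization for data-independent
acquisition (DIA) proteomics, including multiplexed plexDIA sets (mTRAQ
d0/d4/d8 channels).

DIA methods co-fragment everything inside wide precursor isolation windows
on a fixed duty cycle, so method quality is decided by acquisition-level
trade-offs that search-engine output alone does not expose: how many MS2
windows to use (spectral complexity vs. elution-peak sampling), where to
place their boundaries (ion current is far from uniform in m/z), how long
the LC gradient should be, and whether extra MS1 survey scans pay off.
`diaqc` is for mass-spectrometrists and computational proteomics people who
want those quantities computed from per-scan metadata (mzML) and
DIA-NN-style search reports, and who want window schemes derived from their
own data.

## The models at its core

* **Duty-cycle timing.** Per-scan time is `max(transient(R), IT_max) +
  overhead`, because accumulation parallelizes with the previous transient;
  transients follow the Orbitrap doubling law (256 ms at R = 70,000). A duty
  cycle of one survey scan and `n` MS2 scans therefore lasts
  `(n + 1) · scan_time`: 0.9 s for n = 2 and a 5.1 s MS1 sampling interval
  for n = 16 at 70k / 300 ms.
* **Apex sampling.** A Gaussian elution peak of SD σ sampled every Δ seconds
  is captured at `exp(−d²/2σ²)` of its apex, `d` the distance to the nearest
  sample; the median over a uniform phase is `exp(−Δ²/32σ²)`.
* **Window placement.** Contiguous tilings of the precursor range by equal
  m/z width, equal total ion current (cumulative-histogram quantiles,
  linearly interpolated within bins), or equal precursor count (order-
  statistic midpoints).
* **QC statistics.** Pairwise Jaccard data completeness, protein-level
  peptide CV (single-proteome quality), per-channel intensity and log2-ratio
  distributions, direct vs. translated identification counts, MS1-quantified
  fraction, IDs-vs-FDR curves, per-window accumulation times, TIC ion maps,
  a simple MS1 feature finder, and precursor signal-to-noise.
* **A synthetic 3-plex run simulator** with an explicit generative model
  (log-normal mixture m/z, gradient-mapped retention, Gaussian elution, AGC
  injection-time law, logistic interference-based identification), so every
  metric can be validated against ground truth without instrument files.

## Worked example

Simulate a 3-plex run acquired with 1 survey + 8 equal-width MS2 windows,
then compute channel-level QC and a data-driven window scheme:

```r
library(diaqc)

cyc <- duty_cycle(equal_mz_windows(c(380, 1400), 8), n_ms1 = 1L,
                  max_injection_ms = 251)
cyc
#> Duty cycle: 1 MS1 + 8 MS2 scans, RP 70000, max IT 251 ms
#>   scan time 256 ms, cycle 2.304 s, MS1 sampling interval 2.304 s

sim <- simulate_run(sim_config(n_precursors = 500, seed = 101), cyc)
sim$scans
#> ScanTable 'sim_seed101': 7965 scans (885 MS1, 7080 MS2), peaks loaded
#>   RT 0.0-2038.8 s, total TIC 5.15e+09

ms1_quant_fraction(sim$report)
#>         group n_records n_ms1 fraction
#> 1 sim_seed101      1342   901 0.671386

id_counts(sim$report, by = "channel", split_translated = TRUE)$counts
#>   group   n n_direct n_translated
#> 1    d0 443      352           91
#> 2    d4 453      359           94
#> 3    d8 446      338          108

round(completeness_matrix(sim$report, by = "channel"), 3)
#>       d0    d4    d8
#> d0 1.000 0.844 0.833
#> d4 0.844 1.000 0.850
#> d8 0.833 0.850 1.000

# place 8 windows carrying equal ion current, from this run's own MS1 data
scheme <- equal_tic_windows(mz_histogram(sim$scans), c(380, 1400), 8)
round(scheme$width, 1)
#> [1] 128.3  41.3  99.8 140.0  71.6 135.1 144.9 258.9
```

Reading: about 67% of identified precursors were also quantified at the MS1
level under this schedule; each channel gains ~90–110 identifications by
cross-channel translation; pairwise channel completeness sits near 0.85; and
equalizing ion current narrows the precursor-dense low-m/z windows (41 Th)
while widening the sparse high-m/z end (259 Th).

`qc_report(scans, table, out_dir)` writes every metric as a tidy TSV plus a
self-contained HTML report; `cmd_qc()`, `cmd_windows()` and
`cmd_simulate()` wrap the same functionality for file inputs, and
`inst/cli/diaqc.R` exposes them as a command line:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/diaqc.R", package = "diaqc"))') \
    simulate --seed 1 --out simdir
```

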