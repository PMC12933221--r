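# isqc — near real-time QC for internal-standardised LC-HRMS

`isqc` watches liquid-chromatography high-resolution mass-spectrometry
acquisitions as they land on disk and decides, injection by injection, whether
the instrument is still behaving. It is built for laboratories that co-inject
a fixed panel of isotopically labelled internal standards with every sample —
environmental surveillance, screening and similar long-running programmes —
where an undetected pump or detector fault can quietly ruin days of
irreplaceable samples before anyone reviews the batch.

## What it computes

For every internal standard in every run, `isqc` extracts an ion chromatogram
at exact mass ±20 ppm, smooths it twice with a quadratic five-point
Savitzky–Golay filter, finds the apex within a 27 s window around the
(drift-corrected) expected retention time, estimates baseline and noise from
two 15 s flanking windows, and accepts the peak when S/N > 5 with ≥ 5 points
above baseline + 2 × noise. Three metrics per standard feed two control
layers:

* **Univariate limits** against rolling 60-day medians: normalised intensity
  in 0.5–2.0, retention-time deviation within ±10 s, mass error within
  ±10 ppm. Stored expected retention times are corrected by the median
  internal-standard deviation in the most recent blank.
* **Multivariate control (MSPC)**: per parameter block (height ratios,
  retention-time ratios over all standard pairs, `R = v_i/(v_i+v_j)`, and raw
  per-standard mass errors), a PCA model of recent in-control runs is tested
  with Hotelling's *T²* (systematic shift inside the model subspace) and the
  squared prediction error SPE (deviation outside it), at a Bonferroni-corrected
  α = 0.05/6 ≈ 0.00833. A run is out of control when any block rejects both.
  This layer catches coordinated anomalies that breach no single limit — e.g.
  a ~1 ppm mass bias across all standards.

Results persist in a CSV-backed store; flagged runs produce plain-text alert
reports with the offending values and limits. DDA MS2 spectra of targets are
confirmed against a per-compound JSON library by binned (0.5 Da) cosine
similarity. A bundled simulator generates whole batches — nominal or with
injected faults (detector HV failure, pump-driven RT drift, mass-calibration
bias, post-maintenance gain) — so the entire pipeline is testable without
instrument data.

## Worked example

A 100-run in-control history, then three injections acquired during a
mass-calibration drift (every standard shifted by +0.3 to +1.3 ppm — far below
the ±10 ppm limit):

```r
library(isqc)

specs <- default_internal_standards()   # 8 deuterated ESI+ standards
cfg   <- qc_config()

hist  <- simulate_history(100, specs, cfg, seed = 1)
batch <- simulate_batch(scenario_config("ac_mass_bias", n_injections = 3,
                                        seed = 2), specs)
out   <- process_runs(batch$runs, pipeline_state(history = hist$history),
                      cfg, specs)
out$summary[, c("run_id", "pass", "category", "out_of_control", "flagged_blocks")]
#> # A tibble: 3 × 5
#>   run_id                     pass  category out_of_control flagged_blocks
#>   <chr>                      <lgl> <chr>    <lgl>          <chr>
#> 1 ac_mass_bias_s2_001_sample TRUE  pass     TRUE           mass_error
#> 2 ac_mass_bias_s2_002_sample TRUE  pass     TRUE           mass_error
#> 3 ac_mass_bias_s2_003_sample TRUE  pass     TRUE           mass_error

out$mspc[[1]]
#> <mspc_result> run ac_mass_bias_s2_001_sample: OUT OF CONTROL [mass_error]
#> # A tibble: 3 × 8
#>   block             t2 t2_limit t2_reject   spe spe_limit spe_reject flagged
#>   <chr>          <dbl>    <dbl> <lgl>     <dbl>     <dbl> <lgl>      <lgl>
#> 1 height          1.86     12.8 FALSE     35.9      45.4  FALSE      FALSE
#> 2 retention_time  3.77     12.8 FALSE      7.82     42.1  FALSE      FALSE
#> 3 mass_error     60.9      12.8 TRUE      20.8       6.58 TRUE       TRUE
```

Every injection passes univariate QC (`pass = TRUE`) — no mass error is
anywhere near 10 ppm — yet the mass-error block rejects both the D-statistic
(*T²* 60.9 against a limit of 12.8) and the Q-statistic (SPE 20.8 against
6.58), so each run is flagged out of control. `tidy()` on the result exposes
the per-block statistics, `autoplot()` draws the score × loading contribution
chart that names the standards driving the alarm, and `render_alert()` writes
the report file a shift operator would read.

Folder-based operation mirrors the same chain on mzML/mzXML files:
`process_folder()` handles one polling cycle (files untouched for ≥ 2 min, in
acquisition order, blanks refreshing the RT correction), `watch_folder()`
loops it, and `inst/cli/isqc.R` exposes `process`, `watch`, `simulate`,
`reanalyse`, `report` and `build-library` verbs for shell use.

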