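---
title: "Near real-time QC for internal-standardised LC-HRMS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Near real-time QC for internal-standardised LC-HRMS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isqc)
```

## The monitoring problem

Long-running LC-HRMS surveillance programmes co-inject a fixed panel of
isotopically labelled internal standards with every sample. Because those
standards are chemically identical to native analytes but cannot occur in the
matrix, their peak height, retention time and mass accuracy are a per-injection
readout of instrument health: detector gain, chromatographic delivery and mass
calibration. `isqc` evaluates every new acquisition against rolling,
method-specific expectations, in two complementary layers:

1. **Univariate control limits** per standard — normalised intensity,
   retention-time deviation and mass error against fixed thresholds — give
   predefined, directly interpretable quality criteria.
2. **Multivariate statistical process control (MSPC)** — PCA models of the
   correlation structure among standards, tested with Hotelling's $T^2$ and
   the squared prediction error (SPE) — detects coordinated anomalies that
   stay inside every univariate limit, such as a small but systematic mass
   bias across all standards.

Alerts are rendered as files, results land in a portable CSV-backed store, and
everything is testable end-to-end against a bundled batch simulator with
injectable instrument faults.

## Peak metrics

For each compound an extracted-ion chromatogram (EIC) is formed from the MS1
scans at exact mass ±20 ppm (`eic_ppm`). The window is twice the ±10 ppm mass
error limit on purpose: a peak whose mass drifts beyond the limit must still be
*measured*, otherwise the breach cannot be reported. The trace is smoothed
twice with a quadratic five-point Savitzky–Golay filter (interior weights
$(-3, 12, 17, 12, -3)/35$; the first and last two points use the asymmetric
quadratic fits over the nearest five points, so series length is preserved and
any polynomial of degree ≤ 2 passes through unchanged).

The apex is the maximum of the smoothed trace within ±13.5 s of the
(drift-corrected) expected retention time — the 27 s *extraction window*. Ties
resolve to the earlier retention time. Quantification then uses a ±9 s window
centred on the apex. Two 15 s noise windows flank the peak, one starting 30 s
before the apex, one 15 s after (half-open away from the peak). Noise is
max − min within each window and the smaller value is used, so an isobaric
co-eluting peak in one flank cannot masquerade as noise; the baseline is the
mean of the window that supplied the noise. A peak is accepted when S/N > 5
*and* at least 5 raw EIC points within the quantification window exceed
baseline + 2 × noise; with zero noise, S/N is treated as infinite so clean
synthetic peaks are not rejected by a division artefact. Height is the
smoothed apex minus the baseline. Mass error is the signed ppm deviation of
the mean m/z over the apex scan ± 2 neighbours, taking in each scan the most
intense centroid inside the EIC window (unweighted mean; the five most intense
spectra would weight the decision toward the apex and is not what "the five
spectra around the apex" suggests).

## Retention-time correction

Column ageing and replacement shift all retention times together. The stored
expected RTs are therefore corrected by a single additive shift: the median
deviation of all internal standards detected in the most recent blank, where
standards are searched with a tripled RT tolerance so that drift beyond the
sample-side window remains measurable. The shift is recomputed against the
*original* stored RTs at every blank — the newest blank wins and shifts never
compound, which prevents slow accumulation of estimation error. Targets are
corrected along with the standards: the drift is a property of the column, not
of the compound class.

## Univariate control

Expectations are rolling medians over the past 60 days, excluding the run
under evaluation and anything exactly 60 days old or older, and requiring at
least 5 prior detections before a median is trusted (below that the check is
skipped and logged, because a "median" of two runs would make normalised
intensity meaningless). Heights are pooled from sample runs only — blanks and
standards carry different effective levels — while RT medians use all run
types, since the standards elute identically in blanks. The limits (inclusive:
a value exactly at a limit passes):

| metric | limit | default |
|---|---|---|
| normalised intensity (height / 60-day median) | inside `intensity_limits` | 0.5–2.0 |
| retention-time deviation from the 60-day median | `rt_deviation_limit` | ±10 s |
| mass error | `mass_error_limit` | ±10 ppm |

An undetected standard is its own failure class (`missing_is`), which takes
precedence in the run category; otherwise runs breaching two different limit
types are `multiple`, matching the accounting convention used in long-term
reviews (flagged = missing + height + retention time + mass error + multiple).
Medians deliberately include failing runs — a robust statistic tolerates a
minority of faulty history — whereas the multivariate layer's training set
does not (below).

## Multivariate control

Height and retention time enter as ratios over all unique standard pairs,
$R = v_i / (v_i + v_j)$, 28 features for 8 standards. Ratios cancel shifts
common to all standards — detector-gain steps after maintenance move every
height by the same factor and leave every ratio untouched — so the
multivariate layer reacts to *pattern* changes, not level changes, which the
univariate layer already covers. Mass errors stay raw per-standard ppm values:
a common mass bias is precisely the signal of interest there. Missing
standards are zero-imputed *in the evaluated sample only*, making it maximally
anomalous; runs with missing standards never enter the training set, so the
imputation cannot contaminate the model.

The normal-operating-conditions (NOC) set contains sample runs from the past
60 days that passed univariate QC, have all `min_is_per_polarity` standards
detected, **and were not themselves declared out of control by the
multivariate tests**. The last condition is essential: a fault that breaches
no univariate limit (the motivating case being a small systematic mass bias)
would otherwise feed its own anomalous runs back into the rolling NOC and be
absorbed within a couple of injections — the model would learn the fault as
the new normal while it is still being alarmed on. Excluding alarmed runs is
standard SPC practice: "normal operating conditions" means in-control by every
deployed test.

Each block's NOC matrix is autoscaled (zero-variance features dropped and
recorded), decomposed by PCA, and the first `n_pcs = 3` components kept. For a
new run with scaled feature vector $x$, scores $t = P^\top x$:

$$T^2 = \sum_{i=1}^{k} \frac{t_i^2}{\lambda_i}, \qquad
  \mathrm{SPE} = \lVert x - P t \rVert^2,$$

with $\lambda_i$ the NOC score variances ($n-1$ denominator). Limits at the
Bonferroni-corrected level $\alpha = 0.05 / 6$ (six tests per run: $T^2$ and
SPE in each of three blocks; the divisor shrinks automatically when a block
lacks a model, and the correction can be disabled):

* $T^2$: the $F$-form for a new observation,
  $\frac{k(n-1)(n+1)}{n(n-k)} F_{1-\alpha}(k,\, n-k)$ — exact for Gaussian
  NOC, and converging to the $\chi^2_k$ quantile for large $n$.
* SPE: the moment-matched scaled chi-square $g\,\chi^2_{1-\alpha}(h)$ with
  $g = v/2m$, $h = 2m^2/v$ from the mean $m$ and variance $v$ of the NOC SPE
  values — simpler and more robust at small $n$ than the normal-quantile
  approximation.

A run is *out of control* when some block rejects **both** statistics (the
`"and"` rule; `"or"` is available because a residual-only rejection can be the
earliest symptom of a ratio-structure change, and operators differ on whether
that alone should alarm). Per-feature contributions are score × loading,
the standard fault-diagnosis readout; component signs are fixed by making each
component's largest-magnitude loading positive so contributions are
deterministic. PCA models are refitted from the rolling window at evaluation
time; with fewer than `min_noc = 20` eligible runs the multivariate layer
defers silently to the univariate checks.

### Calibration behaviour worth knowing

The $T^2$ limit is well calibrated at deployment-scale training sets (100
runs, 28 features): held-out false-rejection rates sit at or below the nominal
corrected $\alpha$, as does the combined and-rule rate. The SPE limit is
estimated from *in-sample* NOC residuals and is therefore optimistic at small
$n$ — with 100 training runs and 28 features the held-out SPE rate runs
several-fold above nominal (loading overfit of order $kp/n$), decaying to
nominal as the NOC grows. The and-rule absorbs this in the overall
out-of-control decision, whose false-alarm rate is bounded by the $T^2$ rate;
single SPE rejections should be read as advisory at small training sizes. The
test suite pins both behaviours: and-rule and $T^2$ rates within the
Monte-Carlo band at $n = 100$, SPE within the band in its exact regime (large
NOC, homogeneous residual spectrum).

## MS2 confirmation

Targets with a library entry are confirmed qualitatively: the DDA MS2 spectrum
whose precursor lies within the EIC window and whose retention time is nearest
the apex (within ±9 s) is binned at 0.5 Da (floor binning anchored at 0) and
compared with the library spectrum by plain cosine similarity on raw
intensities — no square-root weighting, keeping the score the plain dot
product of the two non-zero vectors. The matched-fragment count uses greedy
nearest one-to-one pairing within ±0.01 Da (the tolerance is configurable; no
canonical value exists). Libraries are one JSON document per compound whose
file stem must equal the compound identifier; mismatching files are rejected
with a warning so foreign libraries cannot silently mislabel. DIA spectra are
parsed but never matched.

## The batch simulator

The simulator generates full scan streams: MS1 scans every 0.5 s, one centroid
per compound channel, Gaussian peaks (sd 3 s) of base apex height 10^5 counts
over truncated white noise (sd 200 counts). Run-to-run variability is
lognormal with a component shared across standards (sdlog 0.08, detector gain)
and an independent per-standard component (sdlog 0.05); retention times jitter
by 1 s sd. Mass error follows QTOF behaviour — approximately constant across
the m/z range within a run — as a common per-run bias (sd 0.15 ppm) plus
per-scan centroid jitter (sd 0.3 ppm, i.e. ≈ 0.13 ppm on the five-scan mean).
These magnitudes describe a maintained QTOF behind a stable UHPLC method and
were fixed once; with them, a 100-run history passes univariate QC throughout,
which is what "in control" is supposed to mean.

Fault scenarios reproduce the failure modes the monitoring is meant to catch:

* `hv_failure` — degrading high-voltage supply: standards above m/z 236.15
  attenuated with larger losses at higher mass (log-m/z interpolation down to
  ×0.3 at the heaviest standard), lighter standards boosted ×1.5.
* `pump_drift` — failing organic-phase pump: retention times drift late,
  linearly across the batch up to 30 s for the earliest eluter, late eluters
  half as affected; drift beyond the 13.5 s search half-window makes standards
  vanish entirely.
* `ac_mass_bias` — mass-calibration drift after an air-conditioning outage:
  positive per-standard mass shifts alternating 0.3/1.3 ppm. The non-uniform
  profile matters: the uniform part of the shift moves the sample *inside* the
  model subspace ($T^2$), the standard-to-standard differences move it *out*
  (SPE), so both statistics reject while every |mass error| stays far below
  10 ppm — the canonical case of a fault only the multivariate layer sees.
* `post_maintenance_gain` — uniform ×2.5 intensity gain after detector
  maintenance: flagged by normalised intensity, invisible to height ratios by
  construction.

Random streams are seeded per `(seed, injection_index)`, so batches are
bitwise reproducible and order-independent. A measurement-level fast path
(`simulate_measurements()`, `simulate_history()`) draws from the same per-run
distributions without synthesising scans; the suite asserts its agreement with
the full-signal path.

What the simulator does **not** emulate: peak tailing and fronting, detector
saturation, matrix suppression, co-eluting interferences, DIA spectra, and
real blank contamination. Green tests on simulated batches therefore
demonstrate that the decision logic implements its definitions and detects the
modelled fault signatures — not that those thresholds are optimal for any
particular instrument. Limits are empirically method-specific and exposed in
[`qc_config()`].

## Numerical and design choices

* Per-scan EIC intensity is the *sum* of in-window centroids, robust to
  centroid splitting.
* Even-count medians are the mean of the two middle values.
* Rolling windows are open at both ends: a record exactly 60 days old is out,
  and a run is never its own history.
* Ratio of two zeros is 0 — a zero-imputed missing pair should look anomalous
  under reconstruction, not undefined.
* A new sample's deviation on a feature that was constant in the NOC enters
  the SPE as its squared deviation over a floor sd of 10⁻⁸: any movement on a
  frozen feature is treated as strong evidence.
* Quiet-period boundary for file readiness is inclusive (exactly 120 s of
  silence counts as ready).
* Problem sizes in the shipped tests and the acceptance script — 100-run
  histories, 25-injection batches, 2000-draw calibration — mirror a realistic
  60-day window and typical batch length while keeping a full run of the suite
  around a minute.

## Known limitations

* One additive RT shift per blank; no per-compound or nonlinear warping, so a
  selective chemistry change (one standard drifting alone) surfaces as a QC
  failure rather than being corrected away — intended, but worth knowing.
* $T^2$ limits blow up for very small NOC sizes; `min_noc` guards the floor,
  but limits from 20–30 runs are wide.
* Blank-contamination and TIC-level checks are out of scope.
* The store is desk-scale: atomic per-run replacement is implemented at the
  table level, not transactionally across concurrent writers.
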