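---
title: "EEG microstate analysis: model, simulator and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis: model, simulator and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstate)
```

## The model

Resting EEG is modeled as a piecewise-constant sequence of scalp
topographies: the signal dwells in one of K template maps for tens of
milliseconds, then switches abruptly. The observable used throughout is the
**global field power**,
$\mathrm{GFP}(t) = \sqrt{\tfrac1C\sum_c \big(v_c(t)-\bar v(t)\big)^2}$,
the population SD of the average-referenced map over the $C$ channels. Maps
at GFP maxima have the highest topographic signal-to-noise ratio and are
taken as the discrete states of the signal. Because spontaneous oscillations
flip the polarity of a source topography at the carrier rate, all map
comparisons are **polarity invariant**: similarity is $|r|$, the absolute
spatial Pearson correlation across channels.

**Clustering.** The AAHC (atomize-and-agglomerate hierarchical clustering)
implementation starts from one cluster per GFP-peak map and repeatedly
dissolves the cluster with the smallest GEV contribution
$\sum_{i \in c}(\mathrm{GFP}_i\, r_{i,c})^2$, reassigning each orphaned map to
the surviving cluster with the highest $|r|$ to its centroid. Centroids are
the dominant eigenvector of the members' outer-product sum — the
polarity-safe analogue of the mean — scaled to unit GFP. Clustering is
two-level (per subject, then on the pooled individual templates per group),
and the four group templates are matched to canonical A–D shapes by
exhaustive best-permutation assignment on total $|r|$.

**Backfitting and parameters.** Each GFP-peak frame takes the label of its
best-matching template; every other sample inherits the label of its nearest
peak in time (inter-peak intervals split at the midpoint, the extra sample of
an odd gap going to the earlier peak). Per subject and class we report mean
**duration** (s), **occurrence** (runs/s of labeled time) and **coverage**
(fraction of labeled samples), plus
$\mathrm{GEV} = \sum_t (\mathrm{GFP}_t r_t)^2 / \sum_t \mathrm{GFP}_t^2$
as fit quality. **TANOVA** compares group-mean topographies with a
randomization test on the global map dissimilarity, which for unit-GFP maps
obeys $\mathrm{GMD}^2 = 2 - 2r$.

## Tunable parameters

| parameter | default | why |
| --- | --- | --- |
| epoch length | 2 s | standard resting-state segmentation unit |
| cleaning band | 1–40 Hz | removes drift and high-frequency artifacts (incl. any stimulator residue) |
| clustering band | 2–20 Hz | the band microstate topographies are defined in |
| K | 4 | the canonical four-class A–D decomposition used across clinical studies |
| rejection threshold | 100 µV | deterministic stand-in for visual artifact rejection |
| GFP peak spacing | 10 ms | suppresses noise doublets; peaks carry the topography |
| GFP divisor | population (C) | the definition is an SD over channels; consistency matters more than the variant, so it is fixed and documented |
| permutations | 5000 | randomization-test resolution ~2·10⁻⁴ with the add-one estimator |
| α (parameters, TANOVA) | 0.05 | conventional |
| α (clinical correlations) | 0.01 on BH-adjusted p | stricter threshold for the larger correlation family |

## The simulator

`sim_spec()` + `generate_cohort()` produce a three-condition cohort — controls
(HC) and patients recorded twice (PD_OFF, PD_ON) — with full ground truth.

* **Montage**: Fibonacci lattice on the upper unit hemisphere with ~1° seeded
  jitter; 19 channels by default (a standard clinical count; the method is
  montage-agnostic).
* **Templates**: canonical A–D base shapes (two mirrored diagonals, an
  anterior–posterior pattern, a fronto-central focal map) perturbed by a
  smooth random field, redrawn until all pairwise $|r| \le 0.5$.
* **State sequences**: semi-Markov — dwell times i.i.d. gamma with shape 2 and
  group-specific means (HC 0.068 s, PD_OFF 0.075 s, PD_ON 0.076 s), successor
  drawn uniformly among the other K−1 classes. Gamma shape 2 gives unimodal
  dwell distributions without ultrashort runs, consistent with the 80–120 ms
  stability window reported for resting EEG. A full transition matrix can be
  supplied, but no published values exist for this cohort, so the uniform
  default stands.
* **Signal**: `template[label(t)] · a(t)` with `a(t)` a rectified 10-Hz
  sinusoid (eyes-closed alpha surrogate) whose amplitude is jittered once per
  half-cycle (lognormal, 20% SD), scaled to 15 µV. This places GFP maxima at
  predictable instants, which makes noise-free identifiability exactly
  testable.
* **Noise**: Gaussian, white in time, uniform between-channel correlation 0.3,
  scaled *after* average-referencing so the realized signal-to-noise power
  ratio equals `snr_db` (10 dB default).
* **Subjects**: each subject carries a dwell offset ~ N(0, 0.010 s) shared
  between their OFF and ON recordings, giving between-subject SDs
  (0.010–0.011 s) in the range reported for cohorts of this kind and making
  the paired design real.
* **Clinical scores**: UPDRS-III = group mean (46.5 OFF / 17.1 ON) +
  800 · (subject's realized mean dwell − group target) + N(0, 4). The slope
  (800 points/s) makes the dwell-driven spread ≈ 8.4 points, in line with the
  ~9–10-point score SDs typical of surgical PD cohorts, and builds in the
  positive duration–severity correlation. LEDD is lognormal (median 800 mg)
  and independent of the dynamics by design — a null reference for the
  correlation analysis.

**What the generator does not emulate**: 1/f background spectra and alpha
reactivity, ocular/cardiac/muscle artifacts, stimulator artifacts, volume
conduction from a realistic head model, non-stationary dwell statistics, and
class-asymmetric transition structure. Passing recovery tests therefore shows
the *pipeline* is correct and well-calibrated, not that real recordings meet
the model's assumptions.

## Numerical choices

* **Peak ties**: a run of equal maxima keeps its earliest sample; candidates
  are thinned greedily by descending GFP under the 10-ms spacing. First and
  last samples are never peaks.
* **AAHC determinism**: no random initialization; the worst cluster and
  reassignment targets break ties toward the lowest index; centroid signs are
  oriented to correlate positively with the cluster's first member. Outputs
  are invariant to a global sign flip and to rescaling of the input.
* **Filtering**: 4th-order Butterworth applied forward–backward (zero phase).
  Channels are demeaned and padded by odd reflection over roughly three
  high-pass time constants so edge transients decay in the padding, keeping
  the filter linear to machine precision on the retained span.
* **Permutation p**: add-one estimator `(1 + #{perm ≥ obs}) / (1 + n)`, never
  exactly zero; when fewer distinct relabelings exist than requested, the
  test switches to exhaustive enumeration and flags it.
* **Degenerate input**: constant maps are rejected where a correlation is
  required; zero-variance t-tests return p = 1 (no effect) or 0 (exact
  effect); epochs without GFP peaks are left unassigned with a warning;
  classes that never occur report missing duration and zero rates.
* **FDR family**: BH within each (clinical target × parameter type) family
  across classes, recorded in the output table.

## Design decisions taken where the method description is open

* The 2–20 Hz clustering filter is applied **per epoch** (configurable), so
  rejected epochs cannot leak artifacts into their neighbours.
* Group templates are estimated **per condition** (HC, PD_OFF, PD_ON), with
  canonical labeling making them comparable across conditions.
* Per-class durations **pool all runs of a subject**; the `trim_edges` mode
  excludes epoch-boundary-truncated runs from duration and occurrence (2-s
  epochs truncate ~14% of dwells at these time scales), while the default
  `inclusive` mode keeps the exact identity coverage = duration × occurrence.
* Occurrence uses **labeled time** as its denominator, so artifact rejection
  does not deflate rates.
* The subject-level map entering TANOVA is the subject's **mean map over the
  samples assigned to the class** (at GFP peaks).
* GEV is computed **at GFP peaks** by default, with an all-samples mode.

## Validation strategy and what the recovery numbers mean

Two signal paths answer two different questions, and the test suite measures
each quantity on the path that defines it:

* **Instantaneous identifiability** — backfitting the average-referenced
  synthetic recording directly. At the defaults (SNR 10 dB, 300 s, 250 Hz),
  GFP-peak label accuracy is ≈ 0.99, and with noise off the peak-frame
  correlation with the true template is exactly 1.
* **Dynamics recovery** — the standard pipeline (1–40 Hz, 2-s epochs,
  2–20 Hz, average reference). The clustering band removes the DC component
  of the rectified envelope, which lowers instantaneous peak fidelity
  (≈ 0.82) but converts state transitions into GFP events; recovered group
  mean durations then land within a few percent of their targets and GEV
  against the true templates sits near 0.80 (against the fitted group
  templates, ≈ 0.88). On the raw path, by contrast, GFP peaks fall only on
  the 50-ms carrier grid and nearest-peak interpolation inflates durations by
  ~20%: boundary resolution, not labeling, is the binding constraint there.

Test problem sizes: recovery uses one 20-subject group at the default
recording length; TANOVA calibration uses 200 null replicates of 10 vs 10
subject maps at 1000 permutations (empirical size checked against its
binomial interval, uniformity by Kolmogorov–Smirnov); directional cohort
checks use ten 20-subjects-per-group cohorts at the label-sequence level.

**A power note.** With the between-subject dwell SD the cohort emulates
(≈ 0.010 s), the group effects themselves (Δ duration 0.007 s,
Δ occurrence ≈ 1.5/s) correspond to two-sample t power of ~0.54 and ~0.66 at
n = 20 per group. A single cohort of this size is therefore expected to reach
p < 0.05 on the mean parameters only about 55–65% of the time; the direction
of the effect, in contrast, is reproduced essentially always, and the
built-in duration–UPDRS correlation is positive in every replicate. This is a
property of the effect sizes and sample size being emulated, not of the
estimator.

## Known limitations

* AAHC cost grows ~quadratically in the number of peak maps; individual-level
  clustering caps the maps per subject (default 1000, evenly subsampled).
* The EDF writer/reader covers plain 16-bit EDF with a common sampling rate —
  sufficient for round-tripping simulated cohorts, not a general EDF+ suite;
  BrainVision files are not read.
* Backfit boundary placement is limited by GFP-peak spacing; duration
  estimates inherit that quantization (see the validation section).
* The clinical model is a deliberately simple affine link; it supports
  direction and calibration checks, not realistic score distributions.
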