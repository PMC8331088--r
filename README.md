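# microstate

Resting-state EEG **microstate analysis** in R, with a ground-truth synthetic
cohort simulator for end-to-end validation.

Spontaneous EEG does not wander continuously between topographies: it remains
quasi-stable in one scalp map for ~80–120 ms, then switches abruptly to
another. These recurring maps — canonically four classes labeled **A–D** — are
the *microstates*, and the statistics of their switching (how long each state
lasts, how often it appears, what fraction of time it covers) are compact,
sub-second-resolution descriptors of whole-brain dynamics. Slowed microstate
dynamics (longer durations, fewer occurrences per second) have been reported
in Parkinson's disease and related disorders and track motor impairment, which
is the setting the package's simulator emulates: a healthy-control group plus
a patient group recorded with deep-brain stimulation OFF and ON.

The package is aimed at researchers who want a scriptable, fully testable
microstate pipeline: every stage is an ordinary R function operating on plain
matrices, and a generator with known ground truth makes recovery claims
checkable rather than anecdotal.

## The method

For an average-referenced map \(v(t)\) over \(C\) electrodes, the **global
field power** is the population SD across channels,

    GFP(t) = sqrt( (1/C) * sum_c ( v_c(t) - mean_c v(t) )^2 ),

and its local maxima are the moments of highest topographic signal-to-noise.
The analysis pipeline is:

1. **Preprocess** — band-pass 1–40 Hz, split into non-overlapping 2-s epochs,
   reject epochs exceeding ±100 µV, band-pass 2–20 Hz, re-reference to the
   common average.
2. **Cluster** — collect the maps at GFP peaks and run polarity-invariant
   **AAHC** (atomize-and-agglomerate hierarchical clustering): every map
   starts as its own cluster; the cluster contributing least **GEV** (global
   explained variance) is repeatedly dissolved and its members reassigned by
   highest absolute spatial correlation, until K = 4 clusters remain.
   Clustering is two-level: per subject first, then across the pooled
   individual templates of each group.
3. **Label** — match the four group templates to canonical A–D topographies by
   exhaustive best-permutation assignment.
4. **Backfit** — assign every GFP-peak frame to the template with the highest
   |spatial correlation|; samples between peaks inherit the nearest peak's
   label (midpoint split).
5. **Temporal parameters** — per subject and class: mean **duration** (s),
   **occurrence** (runs per second), **coverage** (fraction of labeled time),
   with `GEV = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2` as the fit quality.
6. **Statistics** — **TANOVA** (randomization test on the global map
   dissimilarity `GMD^2 = 2 - 2r` between group-mean maps), independent and
   paired t-tests on the temporal parameters, and Pearson correlations with
   clinical scores (UPDRS-III, LEDD) under Benjamini–Hochberg FDR control.

The simulator draws a quasi-uniform electrode montage, four separated
template maps, semi-Markov state sequences (gamma dwell times with
group-specific means: 0.068 s for controls, 0.075/0.076 s for patients
OFF/ON), multiplies templates by a rectified 10-Hz carrier, adds spatially
correlated Gaussian noise at a chosen SNR, and generates UPDRS-III scores as
an affine function of each subject's realized mean dwell (group means near
46.5 OFF / 17.1 ON).

## Worked example

```r
library(microstate)

cfg <- pipeline_config(
  sim = sim_spec(n_subjects_per_group = 5, n_channels = 19,
                 record_length = 60, seed = 1),
  n_permutations = 1000, seed = 1)

res <- run_pipeline(cfg, "demo_run")
report("demo_run")
```

```
Microstate pipeline report: demo_run

HC      mean duration 0.0719 s | total occurrence 13.91 /s | GEV 0.884 (SD 0.003)
PD_OFF  mean duration 0.0736 s | total occurrence 13.60 /s | GEV 0.883 (SD 0.007)
PD_ON   mean duration 0.0744 s | total occurrence 13.44 /s | GEV 0.886 (SD 0.007)

Significant parameter comparisons (alpha = 0.05): 3
  duration_s [mean]: p(HC|OFF)=0.182 p(HC|ON)=0.0291 p(OFF|ON)=0.541
  ...

TANOVA (topography, global map dissimilarity):
  class A HC_vs_PD_OFF: GMD=0.008 p=0.8492
  ...

Clinical correlations flagged (FDR-adjusted): 0
```

Reading it: the patient groups dwell longer in each microstate (0.0736/0.0744 s
vs 0.0719 s) and switch less often (13.6/13.4 vs 13.9 runs/s) — the built-in
group effect, already visible at n = 5 though mostly not yet significant. The
four templates explain ~88% of the GFP-weighted topographic variance. TANOVA
p-values are large because all groups share the same underlying template maps.
All tables (`params.csv`, `comparison.csv`, `tanova.csv`, `correlations.csv`,
`templates_<group>.csv`, `gev.csv`) plus a run-metadata JSON and a log are
written into the run directory, and a rerun with the same config and seed is
byte-identical.

A thin CLI does the same from a shell:

```sh
Rscript inst/cli/microstate-pipeline.R run-all --config cfg.yaml --out run_dir
Rscript inst/cli/microstate-pipeline.R report --run run_dir
```

## Package layout

| file | contents |
| --- | --- |
| `R/montage.R`, `R/templates.R`, `R/simulate.R` | montages, canonical/ground-truth templates, semi-Markov EEG simulator |
| `R/io.R`, `R/edf.R` | matrix+JSON-sidecar and 16-bit EDF readers/writers |
| `R/preprocess.R` | epoching, zero-phase Butterworth band-pass, average reference, artifact rejection, bad-channel interpolation |
| `R/gfp.R`, `R/cluster.R`, `R/backfit.R` | GFP, peak detection, AAHC, two-level clustering, canonical labeling, backfitting, GEV |
| `R/temporal.R` | run segmentation; duration / occurrence / coverage |
| `R/inference.R` | GMD, TANOVA, group t-tests, clinical correlations, FDR |
| `R/pipeline.R` | config (YAML round-trip), orchestration, reporting |

See `vignettes/microstate-analysis.Rmd` for the model, the simulator's design
choices and the package's validation strategy.
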