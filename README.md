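# replikinetics

Binding kinetics of DNA-replisome subunits from live-cell single-molecule
microscopy.

In *E. coli*, a pair of replisomes copies the 4.6 Mbp chromosome, and the
question of how stably each subunit — the Pol III polymerase and clamp
loader (together the Pol III\* subassembly), the β sliding clamp, the DnaB
helicase — stays bound to a working fork is answered in vivo by two
measurements: **sptPALM** (photoconvert ~one tagged molecule per cell and
time how long it persists as an immobile focus) and **FRAP** (bleach one
replisome focus and fit the fluorescence return). Neither observable is a
binding time by itself. Tracks end by photobleaching as well as unbinding;
FRAP traces are contaminated by acquisition bleaching and capped by the
bleached pool. This package implements the full inference chain for both,
plus the replication arithmetic derived from the resulting bound times,
and a synthetic-data generator with known ground truth that the test suite
uses to validate every stage.

## The models

Track durations end at the sum of the unbinding and bleaching rates
(competing risks):

    1/T_track = 1/T_bound + 1/T_bleach
    T_bound   = T_track * T_bleach / (T_bleach - T_track)

Bleaching accrues only during exposure, so stroboscopic protocols rescale
the bleach time by the duty cycle, `T_bleach = (t_interval/t_exp) *
T_constant`, with `T_constant` calibrated on a stable binder (LacI-like)
whose focus lifetime is pure bleaching. Accepted durations (short tracks
are discarded) follow a left-truncated exponential `f(x) = (1/τ)
exp(-(x-L)/τ)` with closed-form MLE `τ = mean - L`; the pipeline applies a
frame-grid correction on top (see the methods vignette). Errors come from
a 10,000-sample BCa bootstrap; near-bleach-limited binders get a joint
constrained fit, and a two-exponential mixture with a BIC + likelihood-ratio
criterion tests for a second binding regime. FRAP recovery is
reaction-limited, `y(t) = c - a exp(-b t)`, with bound time `1/b`.

## Worked example

Simulate a fast-exchanging (ε-like) subunit with a true bound time of
10 s, imaged with 0.5 s exposures at 1 s intervals, calibrate bleaching on
a stable binder, and recover the bound time:

```r
library(replikinetics)

st <- acquisition_settings(exposure_time = 0.5, interval_time = 1,
                           n_frames = 600)
sample <- gen_track_durations(
  track_sim_params(true_bound_time = 10, n_molecules = 300, seed = 7),
  st, label = "epsilon-like")
sample
#> Track-duration sample [epsilon-like]: n = 185, L = 4 s, mean = 10.9 s

control <- gen_bleach_control(
  track_sim_params(Inf, n_molecules = 300, seed = 8),
  acquisition_settings(0.5, 0.5, 2000), min_localizations = 4)
cal <- calibrate_bleach(control)
cal
#> Bleach calibration: T_constant = 14.9 s (from n = 251 control tracks)

bootstrap_estimate(sample, cal, n_boot = 10000, seed = 1)
#> Bound-time estimate [epsilon-like]: T_track = 7.38 s, T_bleach = 29.8 s -> T_bound = 9.8 s
#>   SE 1.1, 95% CI [7.95, 12.3] (bca, 10000 resamples), n = 185
```

The raw mean track duration (10.9 s, of which 4 s is the acceptance
threshold) says little by itself; after removing the truncation point and
the ~30 s effective bleach time, the 10 s ground truth is recovered inside
the bootstrap CI.

Derived replication metrics from the clamp kinetics (47 s clamp bound
time, 23 dimers per fork, 4.6 Mbp / 2 forks / 150 min):

```r
replication_report()
#> $loading_interval_s  2        (exact 2.043478)
#> $fork_rate_bp_s      260      (exact 255.5556)
#> $okazaki_length_bp   520      (exact chain 522.2222)
```

One new clamp is loaded per fork roughly every 2 s; at ~260 bp/s that is
an average Okazaki fragment of ~520 bp, while a polymerase bound for
4–12 s synthesizes ~1–3 kbp before being exchanged.

## The analysis workflow

`analysis/` holds numbered drivers that run the study end-to-end on
synthetic data, writing tables under `results/`:

1. `01_simulate.R` — generate the datasets (ε-like localization table,
   DnaB-like durations, bleach controls, FRAP ensembles) with a ground
   truth sidecar;
2. `02_track.R` — link, PSF-filter, threshold and GMM-select tracks;
3. `03_dwell.R` — bleach calibration, truncated MLE + BCa bootstrap,
   constrained DnaB fit, model selection, blinking analysis;
4. `04_frap.R` — FRAP filtering/normalization/correction and recovery
   fits (the DnaB-like ensemble is reported "bound-time not estimable");
5. `05_metrics.R` — the replication arithmetic above.

Run them in order from the repository root with `Rscript`.

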