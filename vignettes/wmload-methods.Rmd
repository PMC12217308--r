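---
title: "Decoding working-memory load from intracranial recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory load from intracranial recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmload)
```

`wmload` implements a complete analysis chain for asking how three medial and
lateral temporal regions — hippocampus (HIPP), entorhinal cortex (EC) and
lateral temporal cortex (LTC) — adapt to working-memory (WM) load in a
Sternberg letter task with set sizes 4, 6 and 8. The chain has four
scientific stages: spectral feature extraction, multivariate decoding of
load, inter-regional phase synchrony, and permutation-based statistics,
plus a synthetic-data generator that creates multi-subject studies with a
known ground-truth structure so every stage can be validated end to end
without patient data.

## Data model

A `recording_dataset` holds one subject's trial-epoched voltages
(`trials x channels x samples`, microvolts) with channel metadata (region,
hemisphere, optional seizure-onset-zone flag) and trial metadata (load,
correctness, probe/response for the behavioural stage). Epochs follow the
task layout on a half-open time axis relative to stimulus onset: 1 s
fixation baseline `[-1, 0)`, 2 s encoding `[0, 2)`, 3 s maintenance
`[2, 5)`, 2 s retrieval `[5, 7)`. Multi-subject studies are a `wm_study`, a
named list of per-subject datasets: because every subject has their own
electrode set, a single pooled tensor would have to pad channels that were
never recorded for a trial, so subjects stay separate and the pooling
happens at the feature level, where it is scientifically meant to happen
(trials are the samples, pooled across subjects).

On disk a dataset is a directory of one Arrow Feather table for the voltage
tensor, CSV tables for channels and trials, and a JSON sidecar for the
epoch layout — each piece readable from R, Python or the command line
without custom tooling. `common_average_reference()` is the one
preprocessing operation retained on this clean data: per sample, the mean
across contacts is subtracted; it is idempotent and undefined for a single
channel.

Analyses run on correct trials only by default (`correct_trials()`); this
is a flag, not a hard-wired rule.

## Time-frequency stage

Power and phase come from convolution with six-cycle complex Morlet
wavelets (`sigma_t = n_cycles / (2 pi f)`, truncated at three standard
deviations, FFT convolution with zero padding). Power uses a 1–100 Hz grid
in 1 Hz steps where the sampling rate allows, phase a 1–40 Hz grid; samples
closer than half a wavelet to the epoch edges are flagged in an
`edge_valid` mask, and the default epoch is long enough that maintenance-
window analyses never touch flagged samples. The wavelet gain is normalised
so a unit-amplitude sinusoid yields unit power at its carrier, which makes
the oracle tests readable; all downstream statistics are invariant to this
choice.

Task power is standardised per trial against the pre-stimulus baseline with
a bootstrap: for each (trial, channel, frequency) cell, the last 500 ms of
fixation provides `m` power samples; 1000 bootstrap draws of `m` samples
(with replacement) are averaged to form a null distribution of the baseline
mean, and every task sample is z-scored against that null's mean and SD.
Three reading decisions are built in:

* each bootstrap draw resamples as many points as the baseline holds — a
  bootstrap of the baseline mean, the variance-stable reading of an
  otherwise unstated draw size;
* the baseline is the *last* 500 ms of fixation, `[-0.5, 0)`, abutting
  stimulus onset;
* one null per (trial, channel, frequency), shared across that trial's
  task samples.

A consequence worth knowing before interpreting z maps: because the null is
a distribution of baseline *means*, its SD is roughly `sd(baseline)/sqrt(m)`,
so z values are scale-inflated by about `sqrt(m)` relative to an ordinary
z-score, and when the baseline holds only a few independent wavelet samples
(low frequencies: a 6-cycle wavelet at 5 Hz is 1.2 s long, against a 0.5 s
baseline) the per-trial null mean and SD are themselves noisy, which makes
the z distribution heavy-tailed and right-skewed even for a task period
statistically identical to baseline. The test suite asserts centring of the
null z distribution relative to its own spread rather than an absolute
band, and `sd_source = "raw"` offers the conventional raw-baseline-SD
variant, whose null z distribution is close to standard at moderate
frequencies. For the resampling itself, one weight matrix per call is drawn
(seeded) and applied to every cell's own baseline vector; each cell's null
is built from its own samples, and this implementation choice only makes
the computation a single matrix product per chunk.

## Decoding stage

Features are region-averaged: per trial, z-power is averaged over a
region's channels, restricted to 1–40 Hz and the maintenance window, and
flattened frequency-major. At the native 1 ms resolution that is
40 x 3000 = 120 000 features per trial; block-mean decimation along time
(default 15–30 in the packaged configurations) preserves band structure at
desk scale, and `decimation = 1` reproduces the full grid. The fixed
feature count regardless of electrode coverage is what forces channel
averaging — a region's trial is one observation, however many contacts
sampled it.

All decoders share one pipeline: stratified 70/30 split per class; PCA fit
on the training rows only, keeping the smallest number of components whose
cumulative explained variance reaches 99%; test rows projected through the
same centring and rotation; linear SVM with cost 1 (via `e1071`/libsvm);
accuracy is the plain proportion correct, repeated over (by default) 100
splits. One numerical choice matters here: PCA scores are divided by a
single scalar — the pooled RMS of the training scores — before the SVM,
with the same scalar applied to projected test data. Bootstrap-z features
live on an arbitrary and very large scale, and a fixed-cost margin is only
meaningful relative to the data scale; the one global factor changes
neither the PCA geometry, the component count, nor any of the pipeline's
comparisons, but it makes the cost-1 optimisation well-conditioned.

Significance uses a label-permutation null: labels are shuffled 100 times,
the complete split + PCA + SVM pipeline is rerun once per shuffle, and a
mean accuracy strictly above the null's 95th percentile (linear
interpolation; ties count as non-significant) is significant. The repeated
cross-validation accuracies are not independent (test sets overlap), so
permutation t tests comparing accuracy vectors between regions or groups
should be read descriptively, as in the literature this pipeline follows.

Cross-regional generalization trains on region A's training rows and tests
regions B and C on the *same held-out trials*, projected through A's fitted
PCA (centring included); any other choice of test trials would leak trial
identity between arms. A region's generalization is the mean of its two
transfer accuracies, and the diagonal of the train x test matrix equals the
single-region accuracies on the same seeds exactly — a property the tests
pin down.

Residual-based decoding asks how much of a region's load information is
shared with another region: per trial, the target's feature vector is
regressed on the regressor's feature vector (scalar intercept and slope
across the 120 000 feature positions — the only dimensionally possible
per-trial regression), and decoding is rerun on the residuals with the same
split seeds. The drop in accuracy measures shared information. Note what a
per-trial scalar regression can and cannot remove: it removes the part of
the target's *spectral pattern* that matches the regressor's pattern, so a
regressor whose spectrum is dominated by the shared component removes it
almost completely, while a regressor whose spectrum mixes the shared rows
with strong private structure removes it only partially.

Controls: `balanced_decode()` subsamples every class to the minimum class
count (10 resamples by default, per the trial-count control this pipeline
mirrors); `performance_group_decode()` splits subjects at the median load-8
accuracy (ties to the high group), pools trials within group, and compares
groups with permutation t tests.

## Connectivity stage

Phase-locking value between channels `a` and `b` at time `t` and frequency
`f` is the modulus of the trial-averaged unit phasor of the phase
difference:

$$\mathrm{PLV}_{a,b}(t,f) = \frac{1}{N}\left|\sum_{n=1}^{N}
\exp\!\big(i[\varphi_{n,a}(t,f)-\varphi_{n,b}(t,f)]\big)\right|$$

computed over each subject's correct trials of one load, for every
within-hemisphere cross-region channel pair (cross-hemisphere pairs are
excluded), on the 1–40 Hz maintenance grid. With a finite trial count PLV
has a positive floor (about `sqrt(pi)/(2 sqrt(N))` for independent phases —
0.063 at N = 200), which is load-independent and therefore harmless to the
load contrasts. Scalars are grand means over all channel pairs of a region
pair, frequencies in band and maintenance samples; for a full grid the
aggregation order is immaterial.

The scalar table (subject x region pair x load) feeds a one-way
repeated-measures ANOVA with load as the within-subject factor, reported
with the uncorrected F and p, the Greenhouse–Geisser epsilon and corrected
p (the sphericity treatment is otherwise unstated in this literature), and
Holm-corrected paired t tests as post hocs. The hub-specificity control
regresses, across the subject x load rows, the HIPP–LTC scalar PLV on the
two EC-involving scalar PLVs (OLS with intercept; a single-regressor
variant on the mean EC PLV is available via `regressors = "mean"`), then
reruns the ANOVA on the residuals. The exact regression design is an
implementation reading — it is stated prominently here because other
readings exist; with three loads and two regressors plus intercept the
design can absorb any load-mean pattern carried by the EC pairs, which is
precisely the point of the control.

## Behavioural stage

Capacity uses Pashler's estimator `K_P = (h - f) N / (1 - f)` per load from
hit rate `h` (responding "in" when the probe was in the set) and
false-alarm rate `f`; `K_max` is the maximum across loads.
`permutation_t_test()` is the shared machinery: Welch t by default (Student
behind a flag), null from group-preserving reassignments (unpaired) or sign
flips (paired), add-one-smoothed two-sided p, and exact enumeration for
small samples.

## The synthetic generator

`generate_dataset()` creates studies in which the ground truth mirrors the
phenomena the pipeline is meant to detect, so that parameter recovery — not
numeric reproduction of any published value — is the validation target.
Per subject and trial, each channel carries:

1. a *region oscillation* at a channel-specific carrier drawn from the
   region's band, with amplitude `power_by_load[load] x` a log-normal
   subject factor `x` a log-normal per-trial factor (`own_amp_sd`), plus a
   load-independent oscillation at the same carrier during the fixation
   baseline, so baseline z-scoring sees realistic statistics at the
   region's own frequency;
2. *hub-routed latent components*: each coupling between the hub (EC by
   default) and a target region is a pathway with its own latent frequency
   (24 Hz for EC-HIPP, 32 Hz for EC-LTC by default). Per trial and
   pathway, a shared log-normal amplitude fluctuation (`latent_amp_sd`)
   scales the broadcast itself; the hub and the pathway's target carry the
   component at the same `hub_weight`, the target with a von Mises phase
   offset of concentration `kappa_by_load[load]` (and optional extra relay
   gain noise, `relay_amp_sd`, off by default). The amplitude multiplier
   `latent_power_by_load` is the load signal the hub broadcasts; the
   concentrations are the load signal in connectivity, with closed-form
   expected narrow-band PLV `I1(kappa)/I0(kappa)`;
3. a *load-flat leak*: each non-hub region also receives the other
   pathway's component at a fixed amplitude (`cross_leak` times the
   across-load mean; `leak_load_mix` can re-introduce load scaling), with
   the region's own phase offset;
4. white noise (`noise_sd`).

Each contact flips the polarity of its latent copies at random (a dipole-
orientation stand-in). This keeps the shared component out of the common
average — with a handful of synthetic contacts, a polarity-aligned shared
oscillation would otherwise be largely removed by re-referencing — while
leaving power and pairwise phase locking untouched (a constant pi offset
does not change PLV).

Several of these choices are consequences of how the analyses themselves
behave, worked out during design and worth recording:

* *Two pathway frequencies, not one.* With a single shared carrier every
  region's load information lives in the same feature row, so any region
  regressed on any other removes it and no region can generalize better
  than another; the hub structure would be invisible to the residual and
  transfer analyses. With per-pathway frequencies the hub is the only
  region whose spectrum spans both load-carrying rows — which is what
  makes it decode best, transfer to both neighbours, and dominate residual
  removal.
* *Equal hub weight and mean-matched leaks.* Cross-regional testing
  projects the target's features through the training region's PCA
  centring, so a mean difference at any row the decoder weights becomes a
  constant decision offset that destroys transfer for reasons unrelated to
  information content. The hub therefore carries its copies at the same
  weight as the targets, and the leak amplitude is chosen so every
  region's mean spectrum is comparable at both pathway rows.
* *Load-flat leak amplitude.* If the leak carried the load multiplier, a
  target-trained decoder's weight on its (weak) leak row would be
  amplified on the other target's (strong) main row — a decoding bridge
  between the hub's targets that would let them generalize as well as the
  hub. A flat leak carries no decodable load power, yet its phase still
  holds the region's load-dependent von Mises offset, which is exactly
  what preserves the HIPP-LTC phase-locking load effect.
* *Shared per-pathway amplitude fluctuation.* Putting the trial-to-trial
  gain on the broadcast itself (rather than on the target's relay alone)
  means the hub's data are no noisier or cleaner than its targets' — so no
  region earns generalization merely by being an easy test set — and the
  hub's and target's realizations of the shared component match trial by
  trial, which is what per-trial residual regression removes.
* *Pathway frequencies in the upper decoding band.* The bootstrap z-score
  is stable only where the 500 ms baseline holds several independent
  wavelet samples; for six-cycle wavelets that favours frequencies well
  above ~15 Hz (see the time-frequency section). Discriminability per row
  is governed far more by this baseline stability than by oscillation
  amplitude — one of the clearest lessons of the calibration sweeps.

Default study conditions: 4 subjects, 60 trials per load, 4 channels per
region (two per hemisphere), 200 Hz sampling, 8 s epochs; bands HIPP
4-7 Hz, EC 10-13 Hz, LTC 36-39 Hz (all with per-trial log-normal
amplitude SD 0.3); pathway concentrations kappa 0.2/1.5/5 (EC-HIPP) and
0.15/1.2/4 (EC-LTC) for loads 4/6/8, each scaled per subject by a
log-normal factor (`subject_kappa_sd` 0.4) so the load ANOVAs face
realistic between-subject heterogeneity; latent amplitude multipliers
1/1.6/2.4 with shared per-pathway fluctuation `latent_amp_sd` 0.25;
`cross_leak` 0.9, load-flat. Effect sizes were fixed by a pre-validation
calibration sweep so that single-region accuracies land in the low-to-high
70s against permutation thresholds near 57% at the reference validation
size (6 subjects, 60 trials per load), and are not revisited.
`null_dataset()` flattens every load dependence (multipliers and kappas to
their load-4 value, behavioural accuracy to its mean) for type-I-error
calibration.

What the generator does *not* emulate: 1/f background spectra, epileptiform
artifacts, volume conduction beyond the common-average construction,
electrode drift, or any biophysical coupling mechanism. Passing the
recovery suite therefore shows the pipeline detects the modelled structure
at realistic sizes and rejects its absence — it does not certify
performance on clinical recordings.

## Statistical calibration choices

* Permutation null: one split per label shuffle, matching the "100
  shuffles" convention; repeats-per-shuffle is configurable.
* Thresholds: 95th percentile with linear interpolation; ties
  non-significant.
* Permutation p values: add-one smoothing, so p is never exactly zero.
* Median splits: ties to the high group, deterministically.
* Degenerate inputs error loudly: single-channel referencing, single-trial
  PLV, zero baseline variance (named cell), constant residual regressors,
  collinear PLV regressors, missing ANOVA cells.

## Reproducibility and problem sizes

Every random step — generation, bootstrap, splits, permutations,
subsampling — derives its stream from an explicit seed, and reruns are
bit-identical (the report writer's CSV output is byte-stable). The packaged
validation runs use reduced problem sizes chosen as the package's own
desk-scale defaults: 1–40 Hz in 1 Hz steps, 200–300 bootstrap draws,
decimation 15–30, 10–20 cross-validation repeats against 100-shuffle nulls,
4–6 subjects with 60 trials per load; the full-scale settings (1000 draws,
100 repeats, decimation 1) remain the function defaults.

## Known limitations

* The bootstrap-mean z convention is heavy-tailed at low frequencies for
  short baselines (see above); interpret low-frequency z maps with care or
  use the raw-SD variant.
* Pooled-trials decoding treats trials as exchangeable across subjects, as
  in the design this package follows; a grouped split is not the default
  and subject-level inference should use the per-subject PLV/behaviour
  tables.
* Cross-validation repeats share trials, so accuracy-vector t tests are
  descriptive, not exact.
* The EC-residualization regression design for PLV is one reading of an
  under-specified control; the flag documents the alternative.
* In the reference simulation, the margin by which hub-residualization
  out-removes cross-residualization on the hippocampus side is small: the
  per-trial scalar regression partially reflects removed signal into the
  (load-flat) leak row, an intrinsic property of a one-slope projection
  across feature positions.
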