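# wmload

Working-memory (WM) load analysis for trial-epoched intracranial EEG from
the hippocampus (HIPP), entorhinal cortex (EC), and lateral temporal cortex
(LTC): Morlet time-frequency power with bootstrap baseline z-scoring,
single-regional / cross-regional / residual-based linear-SVM decoding of WM
load with permutation statistics, phase-locking-value (PLV) connectivity
with repeated-measures load ANOVAs, behavioural capacity metrics, and a
synthetic multi-subject recording generator for end-to-end validation.

It is written for electrophysiologists and methods researchers who want a
tested, reproducible R implementation of this analysis family — and a
ground-truth simulator to probe when the analyses can and cannot recover
hub-like shared structure.

## The analyses

**Features.** Per trial and channel, power from six-cycle complex Morlet
wavelets (1–100 Hz) is z-scored against a bootstrap null of the 500 ms
pre-stimulus baseline mean (1000 draws). Decoding features are the region-
averaged z-power on the 1–40 Hz × 3 s maintenance grid, flattened
frequency-major — 40 × 3000 = 120 000 features per trial at 1 ms
resolution (block-mean time decimation available).

**Decoding.** Stratified 70/30 splits; PCA fit on training rows only,
keeping the fewest components reaching 99% cumulative variance; linear SVM
with cost 1; repeated cross-validation (default 100 repeats); significance
against a 100-shuffle label-permutation null at its 95th percentile.
Variants: cross-regional generalization (train on one region, test the
other two through the same PCA transform on the same held-out trials),
per-trial residual decoding (regress one region's 120 000-value feature
vector on another's, decode the residuals), balanced-trial-count controls,
and a median-split performance-group comparison.

**Connectivity.** For channels *a*, *b* and each time–frequency point,

    PLV_ab(t, f) = (1/N) | Σ_n exp(i [φ_na(t,f) − φ_nb(t,f)]) |

over a subject's correct trials of one load, for every within-hemisphere
cross-region channel pair (1–40 Hz, maintenance window), aggregated to one
scalar per subject × region pair × load, then a one-way repeated-measures
ANOVA with load as the within-subject factor (Greenhouse–Geisser reported,
Holm post hocs), plus an EC-residualized HIPP–LTC control.

**Behaviour.** Pashler's capacity `K_P = (hit − FA) · N / (1 − FA)` per
load, `K_max`, and permutation t tests (Welch default, exact enumeration
for small samples).

**Synthetic studies.** `generate_dataset()` builds multi-subject studies
with load-dependent band power, a hub region broadcasting load-modulated
latent oscillations over per-pathway frequencies, von Mises phase coupling
with load-dependent concentration (expected narrow-band PLV
`I1(κ)/I0(κ)`), log-normal subject and trial variability, and Bernoulli
behavioural responses — fully reproducible from one seed. `null_dataset()`
removes all load dependence for type-I-error calibration.

## A worked example

```r
library(wmload)

study <- generate_dataset(synthetic_config(seed = 1))   # 4 subjects, 60 trials/load, 4 ch/region
fms   <- extract_features(study, freqs = 1:40, n_boot = 300,
                          decimation = 30, seed = 2)
cfg   <- decoding_config(n_repeats = 20, n_perm = 100, seed = 3)

dec <- single_region_decode(filter_loads(fms$EC, c(6, 8)), cfg)
dec
#> <wm_decoding> EC load 6 vs 8: 76.5 +/- 3.3% (n=20 repeats)
#>   permutation 95% threshold 55.5% -> significant

xr <- cross_region_decode(lapply(fms, filter_loads, loads = c(6, 8)),
                          decoding_config(n_repeats = 20, n_perm = 0, seed = 3))
round(xr$generalization, 3)
#>  HIPP    EC   LTC
#> 0.581 0.646 0.523

plv <- plv_table(study)
plv_load_anova(plv, "EC-HIPP")[c("F", "df1", "df2", "p")]
#> $F
#> [1] 59.35282
#> $df1
#> [1] 2
#> $df2
#> [1] 6
#> $p
#> [1] 0.000111377
```

The decoder reads the entorhinal hub's load signal well above its
permutation threshold; the hub generalizes best to the other regions
because it shares its load signal with both; and EC–HIPP phase locking
increases with load. `run_experiment()` chains all stages (including
residual decoding, the EC-residualized PLV control, and the behavioural
summary) into a `wm_report`, and `write_report()` emits tidy CSVs and a
JSON summary that are byte-identical across reruns with the same seeds.

The exported functions and the methods vignette
(`vignettes/wmload-methods.Rmd`) are the package's interface; there is no
separate shell tool.

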