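# precisionMMN

Tools for studying how the *precision* (stability) of an auditory context
modulates deviance-detection brain potentials such as the mismatch
negativity (MMN).

In a precision-manipulated oddball paradigm, a Deviant tone (D) keeps a
fixed probability p(D) = 1/11 while the probability of the Standard tone
(S) is graded across four conditions — Oddball p(S) = 10/11, High
confidence 7/11, Low confidence 4/11, Random 1/11 — so that the stability
of the context varies while the surprisal of the deviant does not. If
event-related potentials carry precision-weighted prediction errors, the
deviant response should scale with p(S). `precisionMMN` provides everything
needed to build, simulate and analyze such a study:

* **Sequence generation** (`build_tone_set`, `generate_sequence`,
  `validate_sequence`) — 1650-tone condition blocks built from 150
  microsequences of 11 tones with exact role counts, boundary-repetition
  rules, 333 ms SOA, plus pure-tone audio synthesis.
* **Synthetic epoched EEG** (`simulate_dataset`) — 13-channel 10-20 data,
  500 Hz, epochs [-0.1, 0.3) s, with canonical P50/N1 components, a deviant
  modulation *linear in p(S)* in a 120-200 ms frontocentral window, subject
  random effects and AR(1) noise.
* **ERP pipeline** (`preprocess`) — baseline correction, joint-probability
  epoch rejection (3 SD), zero-phase forward-reverse 6th-order Butterworth
  low-pass at 25 Hz, per-cell averages and D-minus-S difference waves.
* **Cluster statistics** (`permutation_test`) — the mass-univariate
  correlation analysis described below.
* **Workbench** (`run_study`) — one call runs the whole study on synthetic
  data and writes tables, figures and a report.

## The statistic

At every time-electrode point, Pearson's *r* between p(S) and the ERP
amplitude is computed across all subject-by-condition observations and
transformed to *t* = *r* sqrt(*n* - 2) / sqrt(1 - *r*²). Points with |*t*|
above the two-tailed critical value at α = 0.05 are grouped into connected
clusters (adjacent time samples at one electrode; electrodes within a 2D
neighborhood radius at one sample; supra-threshold points additionally need
two supra-threshold neighboring electrodes). Each cluster is scored by its
**weighted cluster mass**

> wcm = sign × Σ (|t| − t_crit)^w,  w = 1 by default,

and referred to a Monte Carlo null distribution built from 20,000
permutations that shuffle each subject's four p(S) values within subject,
recording the maximum |wcm| per polarity. Cluster p-values use the add-one
estimator (1 + B)/(1 + N); each polarity family is tested at α/2.
Confirmatory window tests (Kruskal-Wallis with Tukey-Kramer post hocs on
ranks) back up the mass-univariate result at a chosen channel and window.

## Worked example

A reduced study (10 subjects, 40 epochs per cell, 500 permutations) on
synthetic data with the default planted slope of -4 uV per unit p(S):

```r
library(precisionMMN)
cfg <- study_config(
  simulation  = simulation_config(n_subjects = 10, n_epochs_per_type = 40),
  permutation = permutation_config(n_permutations = 500),
  targets     = "D",
  master_seed = 42
)
rep <- run_study(cfg, out_dir = NULL)
print(rep)
#> Study report: 1 analysis target(s): D
#>   D: 1 cluster(s), 1 significant; Kruskal-Wallis chi2 = 8.04 (df = 3, p = 0.0453)
rep$analyses$D$table[, 1:6]
#>   polarity       wcm     p_value significant t_start_ms t_end_ms
#> 1        - -36.63693 0.001996008        TRUE        136      178
round(colMeans(rep$analyses$D$window_means), 2)
#> oddball    high     low  random
#>   -2.97   -2.48   -1.64   -0.49
```

The analysis recovers the planted effect as a significant frontocentral
negative cluster (Fp2, Fz, F4, C4, Cz) spanning 136-178 ms — inside the
planted 120-200 ms modulation window — and the Fz window means (160-180 ms)
grade monotonically with p(S): the more stable the context, the more
negative the deviant response. At the full design (20 subjects, 135
epochs/cell, 20,000 permutations — the package defaults) the same call
reproduces the complete three-target analysis (D, S and difference waves).

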