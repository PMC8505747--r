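---
title: "Precision-graded oddball paradigms and cluster-based ERP correlation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-graded oddball paradigms and cluster-based ERP correlation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precisionMMN)
```

## The scientific problem

Predictive-coding accounts of auditory deviance detection hold that
event-related potentials (ERPs) such as the mismatch negativity (MMN) carry
precision-weighted prediction errors: the response to an unexpected sound
should scale not only with how unexpected it is, but with how *reliable*
(precise) the context that generated the expectation was. `precisionMMN`
implements the complete experimental and analytical machinery needed to test
this idea with a precision-manipulated oddball paradigm:

1. **Paradigm** — tone sequences in which a Deviant tone (D) keeps a fixed
   probability of 1/11 while the probability of the Standard tone (S) is
   graded across four conditions (10/11, 7/11, 4/11, 1/11), so that the
   stability — the precision — of the context varies while the surprisal of
   the deviant does not.
2. **Synthetic EEG** — an epoched-data generator that plants a deviant
   response whose amplitude is *linear in p(S)*, the effect the analysis is
   designed to detect.
3. **ERP pipeline** — baseline correction, joint-probability epoch
   rejection, averaging, zero-phase low-pass filtering, difference waves.
4. **Cluster statistics** — a mass-univariate correlation analysis over
   time x electrode with weighted-cluster-mass permutation correction, plus
   confirmatory Kruskal-Wallis / Tukey-Kramer window tests.

## Sequence generation

The tone alphabet is eleven pure tones, 3 equal-temperament semitone steps
apart from 440 Hz (A4) to 2489.02 Hz (Eb7); 880 Hz is the Standard and
1046.5 Hz the Deviant, the other nine tones are equiprobable fillers. A
condition block is 150 microsequences of 11 tones (1650 events at a 333 ms
onset asynchrony). Each microsequence contains exactly `p_s_numerator`
Standards, one Deviant, and fillers drawn uniformly *with replacement*; the
order is a uniform shuffle. This construction makes the marginal
probabilities exact by design — p(D) = 1/11 in every block, p(S) graded —
rather than approximate targets of an unconstrained sampler.

Two repetition rules are enforced by regenerating the offending
microsequence in full (with a retry budget of 1000, after which the
generator errors rather than silently relaxing a constraint):

* across a microsequence boundary no tone may repeat, except the Standard
  in the three oddball-like conditions (where S-S repetitions are the point
  of the design);
* in the random condition no two consecutive tones may share a frequency,
  within or across microsequences.

Within-microsequence order is otherwise an unconstrained uniform shuffle.
Whether the original design imposed further constraints (for example a ban
on deviants in the first position) is not recoverable; the uniform shuffle
is the minimal-assumption choice and is what `validate_sequence()` checks.

## The synthetic EEG generator

`simulate_dataset()` emulates the *statistical structure* the analysis
assumes, not the biophysics of EEG. Per epoch the signal is

```
x(c, t) = sum_k a_k(subject) * g(t; lat_k, width_k) * topo_k(c)
        + slope * p(S) * g(t; 160 ms, 20 ms) * topo_mod(c)   [D epochs only]
        + noise(c, t)
```

with Gaussian temporal kernels `g`. Defaults and why:

* **Components**: a positive P50 (peak 50 ms, width 15 ms, +2 uV) and a
  negative N1 (peak 100 ms, width 20 ms, -3 uV), both frontocentral. Only
  peak latencies are constrained by the canonical auditory ERP; Gaussian
  bumps are smooth, integrable in closed form, and make the planted-effect
  algebra exact (the window-mean slope is `slope * mean(kernel)` exactly,
  which the tests exploit).
* **Planted effect**: `precision_slope = -4` uV per unit p(S), confined to
  a 120-200 ms window with the frontocentral topography (Fz weight exactly
  1). The negative sign encodes the hypothesis under test: deviant
  responses grow more negative as the context stabilizes. Only D epochs are
  modulated by default; Standard epochs can be given their own slope
  (`s_slope`) for sensitivity studies, but the default of 0 mirrors a null
  Standard-tone result.
* **Subject random effect**: each component amplitude is perturbed per
  subject by N(0, 0.5 uV), giving realistic between-subject spread that is
  *constant across conditions* — exactly the nuisance a pooled correlation
  must survive.
* **Noise**: AR(1) in time with coefficient 0.95 and marginal sd 10 uV per
  channel, independent across channels and epochs. White noise would
  understate the temporal autocorrelation that cluster statistics must
  survive; 10 uV is a realistic single-trial amplitude for scalp EEG, and
  after averaging ~135 epochs leaves component-scale residual noise.
  `noise_model = "iid"` exists for closed-form oracle tests.
* **Geometry**: 13 channels (eleven 10-20 scalp sites plus both mastoids)
  in a 2D polar projection with the scalp rim normalized to radius 1;
  epochs span [-0.1, 0.3) s at 500 Hz — the half-open window makes the
  time axis exactly 200 samples.

What the generator does **not** emulate: volume-conducted channel
correlations, artifacts (blinks, muscle), drifts, latency jitter across
trials or subjects, and any nonlinearity of real evoked responses. Passing
tests therefore demonstrate that the *pipeline and statistics* behave as
specified on data with the designed covariance structure — they are not
evidence about real recordings.

## Preprocessing decisions

* **Joint-probability rejection**: the published procedure names only a
  3 SD limit on "improbable data". The implementation scores each epoch by
  its mean log-probability under a 50-bin empirical value distribution, per
  channel and globally; both statistics are z-scored across epochs and
  thresholded at the same z (default 3). Whether the original used the
  single-channel limit, the global limit, or both is unknowable; both-at-3
  is the default and both the bin count and threshold are exposed.
* **Filtering**: a forward-reverse 6th-order Butterworth low-pass at 25 Hz
  applied to the per-cell *averages*, not to single trials. A cited
  "(hamming window)" qualifier on an IIR filter is contradictory (windows
  parameterize FIR designs) and was not guessed at; the plain zero-phase
  Butterworth is implemented.
* **Trial selection**: every Deviant is paired with the closest strictly
  preceding Standard; a Deviant with no preceding Standard (only possible
  at a block start, at most one per sequence) is dropped, because the
  pairing rule is undefined there.
* **Missing cells** are flagged and propagated, never imputed.

## The cluster statistic

At each of the 200 x 13 time-electrode points, Pearson's r is computed
between p(S) and the ERP amplitude over all subject x condition
observations (pooled; a single r map is what the design implies, rather
than per-subject r maps aggregated afterwards), then transformed to
`t = r sqrt(n-2) / sqrt(1-r^2)`. Points with |t| above the two-tailed
critical value at `cluster_alpha = 0.05` are grouped into connected
components — same electrode at adjacent samples, or neighboring electrodes
(2D distance <= radius, default 0.55 layout units, which reproduces the
standard sparse-cap nearest-neighbor structure of 3-5 neighbors for
interior electrodes) at the same sample. The cluster-level statistic is the
weighted cluster mass

```
wcm = sign * sum((|t| - t_crit)^w),   w = 1 by default
```

with the exponent exposed as `wcm_weight` since the weighted-cluster-mass
family is tunable and the original choice is not recoverable.

The "minimum of two nearby electrodes" constraint is implemented per point:
a supra-threshold point survives only if at least `min_neighbor_channels`
(default 2) of its neighboring electrodes are supra-threshold with the same
sign at that sample — the convention of the standard cluster-permutation
framework. A whole-cluster reading (drop clusters spanning fewer than that
many electrodes) is available via `neighbor_rule = "cluster"`.

**Null distribution**: the repeated-measures design makes the four
predictor values exchangeable *within subject*; each permutation
independently shuffles each subject's four p(S) values, recomputes the map
and clusters, and records the maximum |wcm| per polarity. Cluster p-values
use the add-one estimator `(1 + B) / (1 + N)` — it cannot return 0 and
differs from the raw proportion by at most 1/(N+1). Significance is
declared at `final_alpha / 2` per polarity family (two-tailed correction).

Numerical edge cases: zero-variance points get r = 0 and a degenerate flag
(they can never enter a cluster); `1 - r^2` is floored at 1e-12 so |r| = 1
yields a large finite t; constant rejection scores yield z = 0 (nothing
rejected) rather than 0/0.

### Calibration versus conservatism

The neighbor-pruning rule only ever *removes* supra-threshold points, so it
can only push the type-I error of the procedure below nominal — on this
sparse 13-channel montage it does so drastically (null clusters essentially
never form with the rule active). The suite therefore checks two separate
properties: (i) *calibration* of the permutation machinery — type-I error
within a binomial band around 0.05 and super-uniform cluster p-values —
measured with `min_neighbor_channels = 0`, where clusters form freely; and
(ii) *correctness of the pruning rule itself* against brute-force
reimplementations on toy grids. Power with the full default procedure is
checked by the effect-recovery suite.

## Confirmatory window tests

`window_mean()` extracts per-subject, per-condition means (default Fz,
160-180 ms); `kruskal_wallis()` applies the tie-corrected rank H test, and
`tukey_kramer_posthoc()` compares group mean ranks with the
studentized-range distribution (infinite df, tie-corrected rank variance) —
the standard nonparametric follow-up to a Kruskal-Wallis rejection.

## Problem sizes used by the test and acceptance runs

The full study design (20 subjects, 135 epochs per cell, 20,000
permutations) is the package default and is what `run_study()` executes out
of the box. The replicate-based suites use scaled designs chosen so that
hundreds of complete pipeline runs remain cheap while every stage still
executes: 10 subjects, 40 epochs per cell, 250-500 permutations; the
exhaustive permutation oracle uses 3 subjects, where the within-subject
null has exactly (4!)^3 = 13,824 partitions. The planted slope remains
detectable at these sizes (the effect-recovery suite demands >= 80% of
replicates recover a significant frontocentral negative cluster overlapping
120-200 ms at Fz), and the type-I band is the binomial band around the
nominal 0.05.

## Known limitations

* Channel-independent noise understates spatial correlation; real cluster
  extents over electrodes will behave differently than simulated ones.
* The joint-probability rejection reimplements the cited behavior from its
  description; bin-level agreement with the original tool is not claimed.
* The montage is a fixed 13-channel set; other montages can be supplied as
  `montage` objects but have no packaged coordinates.
* Reading vendor EEG formats is out of scope; the epoch container is the
  entry point for real data.

## A minimal session

```{r example, eval = FALSE}
cfg <- study_config(
  simulation = simulation_config(n_subjects = 10, n_epochs_per_type = 40),
  permutation = permutation_config(n_permutations = 500),
  master_seed = 42
)
rep <- run_study(cfg, out_dir = "study_results")
print(rep)
rep$analyses$D$table
```
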