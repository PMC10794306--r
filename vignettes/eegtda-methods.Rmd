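---
title: "Topological EEG features for cognitive screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological EEG features for cognitive screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegtda)
```

## The problem

Mild cognitive impairment (MCI) is cognitive decline beyond normal aging but
below the dementia threshold. A low-cost EEG marker of MCI would allow
screening and monitoring outside the clinic. One candidate family of markers
treats the joint dynamics of all EEG channels geometrically: each time
sample of an 8-channel recording is a point in $\mathbb{R}^8$, a 2-s epoch
is a cloud of 500 such points, and the *shape* of that cloud — in
particular, how strongly it organizes into cycles — reflects how richly the
brain moves through its state space. Healthy cognitive aging is associated
with larger, cleaner cyclic excursions during a working-memory task;
impairment with smaller, noisier ones.

`eegtda` implements this analysis end to end: an oddball-paradigm EEG
simulator, preprocessing (band-pass, epoching, empirical-mode-decomposition
artifact rejection), Vietoris–Rips persistent homology with six scalar
features per epoch, rank-based group statistics, unsupervised 2-D
projections, and leave-one-subject-out (LOSO) random-forest classification
of MCI and regression of MoCA (Montreal Cognitive Assessment, 0–30) scores.

## The oddball design

Each participant completes 8 sessions. A session shows one *cue* display
(the image to memorize), then a stream of 8 interior-photograph displays —
4 reminiscent (childhood-themed) and 4 contemporary identities in random
order — in which the cued image reappears exactly once (the *target*); the
other displays are *ignored* distractors. All 9 displays are epoched, giving
$8 \times 9 = 72$ epochs per participant. Downstream analyses split epochs
into TGT (cue + target by default, 16 per participant; a flag can exclude
cues), IGN (56), and ALL.

## The synthetic generator

Real oddball EEG of this kind is not shareable, so the package ships a
generator whose statistical structure matches what the analysis assumes,
and every stage is exercised against it.

* **Background**: per-channel pink (1/f) noise, SD 6 µV — a realistic
  resting EEG floor.
* **Stimulus response**: at each display onset, a damped alpha burst
  (centre 10 Hz, SD 0.6 Hz across events, envelope decay 0.45 s, support
  1.6 s, peak 22 µV for a fully healthy subject, ×1.25 for cue/target).
  Channel $c$ receives the burst with a fixed phase offset
  $2\pi c/8$, so a coherent burst traces an ellipse — a genuine loop — in
  channel space.
* **Impairment dial**: each subject has a latent severity
  $s \in [0,1]$ (healthy $\sim U(0, 0.25)$, MCI $\sim U(0.35, 1)$). With the
  study-level `effect_size` $e$, the burst gain is $g = 1 - s e$: amplitude
  shrinks toward an 8% floor and per-channel phase jitter
  $\mathcal{N}(0, (\pi(1-g))^2)$ destroys the loop's coherence. At
  $e = 0$ the two cohorts are statistically exchangeable (the calibration
  null); at $e = 1$ separation is strong.
* **MoCA**: a noisy decreasing function of severity, clipped to the
  standard cutoff convention (healthy ≥ 26, MCI < 26).
* **Artifacts**: Poisson eye-blink-like Gaussian bumps (SD 0.15 s, so
  essentially all energy below 5 Hz), peak 200 µV on Fz with an
  anterior-to-posterior topography falloff.
* **Ages**: $\mathcal{N}(70.7, 5.32^2)$ clipped to [60, 90]; metadata only.

What the generator does *not* emulate: realistic ERP morphology (there is
no P300), volume conduction, channel-specific spectra, within-subject
nonstationarity, or psychometrics of individual MoCA items. One consequence
worth knowing: the *count* features (`total_cycles`, `max_cycles`) are
dominated by the many small noise cycles every 8-D cloud has, so the
cohorts separate mainly through the amplitude-linked features
(`max_persistence`, ratio features) rather than through cycle counts.
Passing tests therefore demonstrate that the pipeline recovers the kind of
structure it is designed for — not that these six features behave
identically on clinical EEG.

## Preprocessing

The order is fixed: filter → epoch → clean.

* **Band-pass 1–40 Hz**: 4th-order Butterworth applied forward and
  backward (`signal::filtfilt`), i.e. zero phase, preserving latencies.
* **Epoching**: half-open windows $[t_{onset}, t_{onset} + 2\,\mathrm{s})$,
  exactly 500 samples at 250 Hz. Epochs overrunning the recording are
  dropped and counted.
* **EMD cleaning**: each channel of each epoch is decomposed into
  intrinsic mode functions (IMFs) by sifting with cubic-spline envelopes
  (outermost extrema mirrored past the ends; Cauchy-type stop at relative
  squared change $< 0.05$, at most 10 sifting iterations and 10 IMFs —
  common defaults). Any component (IMF or residual trend) whose maximum
  absolute amplitude exceeds 100 µV is discarded; the epoch is rebuilt from
  the survivors. Components exactly at the threshold are kept. Because each
  IMF is subtracted from the running residual, reconstruction is exact to
  floating point, which the tests assert at $10^{-8}$. Cleaning is applied
  per channel per epoch (a continuous-data variant would also be
  defensible; the per-epoch reading keeps the rejection local).

## Topological features

Each cleaned epoch becomes a point cloud (one point per sample, one
coordinate per channel; no delay embedding, no normalization by default — a
`zscore` flag exists for sensitivity analyses). The Vietoris–Rips
filtration over Euclidean distances with $\mathbb{Z}/2$ coefficients is
computed in dimensions 0 and 1 by a C++ engine using persistent cohomology
with clearing; the filtration is truncated at the enclosing radius
$\min_i \max_j d(i,j)$, which provably changes no interval and removes
essential 1-cycles. The engine is validated exactly (to $10^{-9}$) against
a brute-force boundary-matrix reduction on hundreds of small random clouds.

From the dimension-1 intervals with lifetimes $\ell_i$:

| feature | definition |
|---|---|
| `total_cycles` | number of dimension-1 intervals |
| `max_cycles` | peak of the Betti-1 curve (most cycles alive at once) |
| `max_persistence` | $\max_i \ell_i$ |
| `npe` | $-\sum_i p_i \log p_i / \log k$, $p_i = \ell_i / \sum \ell_j$; 0 when $k \le 1$ |
| `max_persistence_ratio` | $\max_i\, death_i / birth_i$ |
| `median_persistence_ratio` | $\mathrm{median}_i\, death_i / birth_i$ |

Conventions that were genuinely open and are fixed here: "maximum number
of cycles" is the Betti-1 peak (simultaneously alive cycles);
"persistence ratio" is death/birth per interval — the only dimensionless
per-interval ratio, which makes both ratio features scale-invariant (the
tests assert scale equivariance of the whole feature vector); normalized
persistence entropy is Shannon entropy of the lifetime distribution over
$\log(\text{count})$. With no cycles all six features are 0. The ratio
convention is isolated in one function, so death/birth could be swapped for
lifetime/birth without touching anything else.

## Group statistics

For each feature × condition (TGT/IGN/ALL), healthy vs MCI distributions
are compared with the two-sided Wilcoxon rank-sum test (midranks, normal
approximation with tie and continuity correction), reported with the
Mann–Whitney $U$, the common-language effect size
$\mathrm{CLES} = P(X > Y) + \tfrac12 P(X = Y)$, the single-feature ROC AUC,
and Shapiro–Wilk normality p-values per group (on at most 500 evenly spaced
values). CLES, AUC and $U/(n_1 n_2)$ are the same number; the package
computes them by three independent routes (pair counting, the rank-sum
statistic, and `pROC`) and the tests assert agreement to $10^{-12}$.

Tests run at epoch level by default, matching the per-epoch feature table.
**Epochs within a subject are not independent**, so epoch-level p-values
describe distributions, not subject-level inference; a per-subject median
aggregation is available. No multiple-testing correction is applied across
the 18 panels; p-values are reported raw.

## Projection and evaluation

UMAP (neighbors 15, min_dist 0.1) or t-SNE (perplexity 30) embeds the
z-scored six-feature table in 2-D, per condition; labels are never passed
to the projector. Method defaults are used deliberately — the point is
qualitative separability, not tuned clustering.

Classification (healthy vs MCI) and MoCA regression use random forests with
200 trees (other settings at package defaults, seeded) under
leave-one-subject-out cross-validation: each fold trains on all epochs of
all other subjects and predicts every epoch of the held-out subject; a
leakage assertion runs in every fold. Scoring is at epoch level. Per-fold
accuracy/f1/recall/precision are summarized as the median with a
95-percentile interval across folds; AUC is computed on the pooled held-out
class probabilities, because a held-out subject has a single true class and
fold-wise AUC is undefined. f1/recall/precision are support-weighted
averages by default (well-defined under imbalance; macro and
positive-class variants are available). Regression reports pooled $r^2$,
MSE, MAE and MAPE over held-out epochs, plus per-fold
$|\mathrm{median\ prediction} - \mathrm{true\ MoCA}|$. The chance level is
the rounded majority-class percentage — 70% for a 16 MCI / 7 healthy
cohort.

## Calibration and recovery properties, and the sizes used

The package's testable claims are property-based, at sizes chosen for a
single CPU (all stated here as the package's own choices):

* **Effect recovery**: a 10 healthy / 13 MCI study, one session per
  subject, 250 Hz, `effect_size = 1`, fixed seed. Median LOSO accuracy must
  beat the cohort's chance level, and pooled regression MAE must undercut
  the cohort's MoCA standard deviation.
* **Rank-sum type-I calibration**: 100 seeds of a balanced 3 + 3-subject
  null study (`effect_size = 0`, 100 Hz, 2 sessions); the fraction of the
  18 panels rejecting at $\alpha = 0.05$ must sit near 5%.
* **Classifier null baseline**: 100 seeds of an 18 MCI / 5 healthy null
  study (100 Hz, 1 session); the 100-seed mean of pooled LOSO accuracy must
  sit within 5 points of the majority-class rate.

The null-baseline cohort is deliberately *imbalanced*. Under LOSO with a
small **balanced** cohort, the held-out subject's class is always the
minority of the training fold, so a null classifier is pushed *away* from
the truth and pooled accuracy falls far **below** 50% — the familiar
pessimistic bias of leave-one-out under the null.
The majority-class rate is only the right null reference when the training
majority is stable across folds, i.e. under strong imbalance; that regime
is where the check is run. This phenomenon is worth remembering when
interpreting any LOSO study with few subjects per class.

The acceptance script (`scripts/acceptance.R`) runs the full pipeline —
artifacts injected and EMD-cleaned — on a 16 MCI / 7 healthy cohort with
two sessions per subject at 250 Hz.

## Numerical notes and limitations

* The Rips engine's tie-break order is (diameter, dimension, vertex
  index); any refinement of the filtration yields the same diagram, and
  zero-persistence pairs are dropped.
* Runtime is dominated by the cohomology reduction on 500-point clouds
  (roughly a second per epoch for strongly coherent signals); the
  100-seed calibrations therefore run at 100 Hz sampling (200-point
  clouds), which changes none of the calibration logic.
* `segment_epochs` never fabricates samples: each epoch is a contiguous
  slice of the recording, and the tests assert it.
* Degenerate inputs: constant signals have no IMFs; clouds with a single
  point have one essential component and no cycles; diagrams without
  cycles map to the zero feature vector; AUC on single-class truth is
  reported `NA` with a warning.
* Epoch-level scoring inflates the apparent sample size relative to the
  number of subjects; the per-subject aggregation options exist for more
  conservative readings.
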