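---
title: "Generalised scalp-EEG seizure detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalised scalp-EEG seizure detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizepipe)
```

## The problem

Most automated seizure detectors are patient-specific: a classifier is
trained and tested on the same person, implicitly learning which channels the
seizure focus projects to. `seizepipe` implements the alternative,
*generalised* (cross-patient) formulation: 60-second multichannel scalp-EEG
blocks, labelled ictal or interictal, are pooled across subjects, and a
classifier must separate the classes using features from the whole scalp,
with no prior knowledge of seizure focus. The pipeline is

1. repair of missing samples,
2. Butterworth decomposition of every channel into broadband (0.5--30 Hz)
   plus the classical delta, theta, alpha and beta bands,
3. per-(channel, band) feature extraction,
4. feature ranking and selection (whole-brain and per scalp region),
5. optional SMOTE oversampling of both classes,
6. nine reference classifiers behind one fit/score interface, evaluated by
   repeated stratified holdout and k-fold cross-validation with sensitivity,
   specificity, ROC/AUC, mean error and its standard deviation.

The clinical recordings such a pipeline was designed for (23 bipolar
channels, 256 Hz, 16-bit) cannot ship with a package, so a seeded synthetic
generator reproduces the statistical structure the method relies on; every
stage is tested against it.

## The synthetic generator

No generative model for ictal EEG is given in the detection literature the
pipeline follows; the generator is therefore built around the three
signatures that motivate the features:

* **Background** (nonseizure): `1/f^alpha` Gaussian noise (`alpha = 1`),
  scaled to `noise_sd = 20` uV, plus a weak 10 Hz alpha rhythm at 0.4 x
  `noise_sd` amplitude with random phase per channel. A `1/f` spectrum and
  ~20 uV amplitudes are the textbook description of resting scalp EEG, and
  the alpha rhythm gives the spectrum a feature outside the delta/theta
  range.
* **Ictal activity**: an amplitude-modulated 3 Hz oscillation with a weaker
  (0.4 x) second harmonic at 6 Hz, at `seizure_amplitude_gain = 3` times
  `noise_sd`, superimposed on the background of one randomly chosen scalp
  region's channels (focal seizures can arise anywhere, so the focus region
  is drawn per record). The envelope is a Hann window over the block times a
  slow (0.25 Hz) waxing-and-waning modulation. This produces, by
  construction, (i) a dominant cyclic spectral peak, (ii) an elevated
  delta+theta share of signal energy, and (iii) a drop in signal entropy --
  energy concentrates in mid-block bursts. The 3 Hz default keeps the
  fundamental inside the delta band's flat response and the harmonic inside
  theta; the published account quantifies neither ictal amplitude nor
  spectral gain, so the gain default is a tuning choice of this package,
  fixed once (it yields roughly a four-fold power increase on focus
  channels, comfortably inside the range of visually obvious ictal EEG).
* **Missing data**: runs of exact zeros (1--16 samples, Poisson-many per
  record at `missing_run_rate = 1`) emulate the dashed/zeroed samples found
  in archived recordings and exercise the repair stage.

All randomness flows from one integer seed per call; datasets derive
per-block sub-seeds from it. What the generator does *not* emulate:
inter-patient variability, artefacts (ocular, muscle, ECG, line noise),
non-stationary background, or realistic seizure morphology. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that the
protocol behaves sanely on data with the assumed structure -- not that the
published accuracy figures transfer, which requires the clinical recordings.

## Preprocessing choices

* **Zero repair.** Every exact-zero or explicitly missing sample is replaced
  by the mean of the non-missing samples within `window/2 = 128` samples on
  each side (window truncated at record edges). The source description of
  this rule is garbled ("a 256-point window, 50% on either side"); the
  reading implemented here -- half the window before, half after -- is the
  only symmetric one. Runs are repaired sample-by-sample from originally
  non-missing neighbours, so results do not depend on repair order; a run
  longer than the window is a degenerate input and raises an error rather
  than silently inventing data.
* **Filtering.** Second-order Butterworth bandpasses, applied
  forward-and-backward (`signal::filtfilt`), so band signals stay
  phase-aligned with annotations; the effective magnitude response is the
  squared one-pass response. Band edges: broadband 0.5--30, delta 0.5--4,
  theta 4--8, alpha 8--12, beta 12--25 Hz. Published feature tables in this
  literature sometimes print the beta band as 12--30 Hz; the edge is a
  parameter (`band_specs(beta_high = 30)`), and note that with the 25 Hz
  default the four sub-bands deliberately do *not* tile the broadband range
  (the 25--30 Hz strip, ~17% of white-noise broadband energy, is uncovered).
* **Block cutting.** Seizure blocks anchor at the annotated onset rather
  than being centred, because ictal periods frequently exceed the 60 s block
  length; an onset too near the record end shifts the window left so it
  fits. Nonseizure blocks are placed uniformly at random subject to not
  intersecting any annotated seizure interval.

## Features

Per (channel, band) signal, the default seven features are RMS, unbiased
variance, skewness, kurtosis, peak frequency, median frequency and signal
entropy: 23 channels x 5 band signals x 7 = 805 columns. Signal energy and
correlation dimension are implemented and selectable but excluded from the
default set, which mirrors the canonical seven-feature summary table of the
protocol (805 = 23 x 5 x 7 only works with exactly these seven).

* **Spectral estimation.** The power spectrum is a Welch average of
  Hann-windowed 4-second segments with 50% overlap (the source is silent on
  the estimator; segment length is configurable). Normalisation is
  Parseval-consistent -- bin powers sum to the signal variance -- so band
  powers read as uV^2. Peak frequency is the argmax bin (ties to the lowest
  frequency; an all-zero spectrum returns 0 Hz with a degenerate flag);
  median frequency is the smallest grid frequency where cumulative power
  reaches half the total. The summation-balance definition of the median
  and this cumulative-half rule differ only at bin granularity.
* **Entropy.** The printed entropy-style feature (a raw
  `sum(x_i * log(x_i^2))`) is neither sign- nor scale-normalised and is not
  a standard sample entropy. It is implemented here as the Shannon entropy
  of the normalised energy distribution `p_i = x_i^2 / sum(x^2)`, which
  matches the printed form up to sign and normalisation, lies in
  `[0, log N]`, and exhibits the required ictal *drop*. The literal printed
  sum is exposed as `signal_entropy_literal()` for audit.
* **Moments.** Skewness and kurtosis use population moments (the
  expectations as written; kurtosis non-excess, normal = 3); the standalone
  variance feature uses the unbiased `n - 1` convention.
* **Correlation dimension.** Grassberger--Procaccia: delay embedding
  (defaults m = 5, delay = 4 samples; the source gives none), correlation
  integral by pair counting over at most 400 evenly subsampled delay
  vectors, slope of `log C(r)` vs `log r` over radii log-spaced between the
  5th and 50th percentile of pairwise distances.
* Features that are degenerate on a particular block (e.g. moments of an
  all-zero band signal) are imputed by the column's finite mean, with a
  message, so the assembled matrix is always finite.

## Feature selection

Nine ranking criteria are provided: two-sample Welch p-values and their
Benjamini--Hochberg q-values; absolute PC1 /
PC2 / max-of-both loadings from covariance PCA; a per-feature Fisher
discriminant ratio (independent search); greedy sequential forward and
backward searches maximising the multivariate Fisher criterion
`d' W^{-1} d` on the pooled within-class covariance (ridge-regularised when
singular, which it necessarily is when features outnumber observations); and
Gram--Schmidt orthogonal forward regression on the class indicator. Design
notes:

* PCA ranks on **unstandardised** (centred) covariance: class separation
  inflates a feature's variance, which is exactly what makes PCA informative
  here; on standardised data a single informative feature is invisible to
  PCA. PC2 ranks the component *orthogonal* to PC1, so when one direction
  carries the class signal, PC2 by construction cannot recover it --
  the planted-feature recovery property holds for every method except
  `pca_pc2`.
* The sequential searches use the Fisher criterion because the source names
  the searches but not their objective; backward elimination uses the
  rank-one deletion identity on `W^{-1}` (O(p) per candidate), forward uses
  the bordered inverse, capped at `min(p, 60)` greedy steps with the
  remainder ranked by marginal ratio.
* Whole-brain selection walks a ranking keeping features whose absolute
  Pearson correlation with everything already kept is at most
  `max_abs_corr`; the threshold behind "uncorrelated" is unspecified in the
  source, so it defaults to 0.9 and is configurable.
* Region-wise selection restricts columns to each of five scalp regions and
  takes the top 5 per region (5 x 5 = 25) under the backward search, the
  criterion reported to rank best. The shipped region map applies two label
  normalisations, both flagged: `P7-O7` (not a montage channel; evidently
  `P7-O1`) and `T8-FT10` (the montage spells the same derivation
  `FT10-T8`). The map covers 21 of the 23 montage channels; the central
  `P7-T7` and the disambiguated duplicate `T8-P8-2` stay outside regional
  quotas and are reported.
* Ties in every ranking break by ascending column index; constant columns
  are ranked last with a warning.

## SMOTE

Both classes are oversampled: each synthetic observation is
`seed + u * (neighbour - seed)`, `u ~ U[0, 1]`, with the neighbour drawn
from the seed's `k = 5` same-class nearest neighbours (the original SMOTE
convention; the source gives no k). At the default 100%, 171/171 becomes
342/342. Where SMOTE enters the protocol is genuinely ambiguous in the
source: `run_experiment()` defaults to the literal reading -- oversample the
whole dataset, then evaluate (`smote.mode = "pre_split"`), which is what
makes the oversampled arms report 684 observations and an expected error of
342/684. This lets synthetic points built from test-fold originals leak into
training folds, so held-out errors in the SMOTE arms are optimistic;
`smote.mode = "train_only"` (or the `smote` argument of
`holdout_evaluate()` / `kfold_evaluate()`) confines oversampling to the
training portion of each split for a leakage-free comparison.

## Classifiers

All nine share one interface (`fit_classifier()` / `score()`), standardise
features with training statistics inside the fit, and return a continuous
seizure score (posterior probability, vote fraction, or logistic-mapped SVM
decision value) plus a label at the 0.5 / zero-decision threshold. LDC, QDC
and UDC are Gaussian discriminants with pooled, class-specific, and
class-specific-diagonal covariance respectively; near-singular covariances
get a diagonal ridge `1e-6 * trace(S)/d` (escalated tenfold until
well-conditioned) with a warning. POLYC appends squared features before a
pooled-covariance discriminant. LOGLC is `stats::glm` logistic regression;
KNNC is `class::knn` with k chosen by inner 5-fold validation over
{1, 3, 5, 7, 9} (the source never states k); TREEC is an `rpart` impurity
tree; PARZENC is a product-Gaussian kernel density per class with a common
bandwidth chosen by inner validation around a normal-reference value; SVC is
`e1071::svm`, linear kernel by default. Exact hyperparameters behind the
published tables are nowhere stated, so numeric agreement with them is not
claimed anywhere in this package.

## Evaluation protocol

Holdout: `reps` stratified random 80/20 splits (train size rounded up per
class: 342 observations split 274/68); per-repetition sensitivity,
specificity (at the default threshold) and AUC are averaged over
repetitions, and the global error's mean and SD are reported -- the source
does not state its averaging order, so the simple
mean-over-repetitions is used. K-fold: stratified folds (342 observations
give fold sizes 68 or 69), every observation tested exactly once per
repetition; SD is over repetition means (over folds when `reps = 1`). AUC is
the normalised Mann--Whitney statistic with midranks, which equals
trapezoidal ROC integration under ties. `run_experiment()` executes the
2 x 2 grid {whole-brain top-20, region 5 x 5} x {original, SMOTE} over all
nine classifiers and emits one report row per (arm, classifier) plus pooled
ROC points.

## Problem sizes and numerical notes

The packaged tests and the acceptance script run the full-scale protocol:
342 blocks of 23 channels x 15360 samples, the 805-column matrix, and the
complete 2 x 2 x 9 grid at 100 holdout repetitions per cell. Property checks
use reduced sizes: 4-channel, 4-second blocks for I/O and preprocessing
properties, and a 200 x 101 matrix for planted-feature recovery. Smaller
sizes are stated inline in the tests.

Numerical edge cases are handled explicitly rather than by NaN propagation:
all-zero signals (entropy, median frequency: degenerate errors; peak
frequency: 0 Hz with a flag), constant features (worst rank, warning),
singular covariances (ridge, warning), exact score ties (midrank AUC), and
missing-data runs longer than the repair window (error).

## Known limitations

* Synthetic EEG is deliberately minimal; see the generator section for what
  it omits. Reproduction of clinical-data accuracy figures is out of scope.
* The EDF codec writes and reads signals and labels only (16-bit
  quantisation over an 8-character physical range; EDF+ annotations are not
  parsed). Tabular text and a CSV annotation sidecar are the lossless route.
* `lda_forward` ranks beyond its greedy cap by the marginal Fisher ratio;
  for matrices wider than a few hundred columns the backward search is the
  intended whole-matrix criterion.
* The PARZENC inner bandwidth search and KNNC inner k search are small
  grids, not full optimisations; they exist to avoid unstated magic
  constants, not to maximise accuracy.
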