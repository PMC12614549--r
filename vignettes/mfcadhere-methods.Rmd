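---
title: "Methods: baseline-referenced MFC analysis and adherence scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline-referenced MFC analysis and adherence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcadhere)
```

# The measurement model

One walking session yields an ordered series of Minimum Foot Clearance
(MFC) heights, one scalar per stride, in millimetres. The baseline session
is the per-patient reference: it defines the biofeedback target band
(mean + SD) ± 0.5·SD (`target_range()`), and every later session is
described by how far it has moved away from the baseline series. The
package never works with marker trajectories or gait kinematics; MFC
extraction is upstream of it.

## Preprocessing

Two steps precede every metric, in this order:

1. **Amplitude normalization** (`amplitude_normalize()`): min–max rescaling
   of each series to [0, 1]. The alternatives considered were z-scoring
   (exposed as `normalization = "zscore"`) and no normalization; min–max is
   the default because it makes the "normalized distances lie in [0, 1]"
   bound of ED and MD attainable and tight — the all-ones/all-zeros pair
   attains exactly 1. A constant series maps to all 0.5 by convention: after
   normalization its location carries no information, and 0.5 avoids
   manufacturing an artificial extreme. Min–max removes *linear* amplitude
   effects only; distribution-shape differences between sessions survive it
   (this matters below).
2. **Zero-padding** (`zero_pad()`) to a fixed length L = 200, the nominal
   stride count of a session. Shorter series get trailing zeros, and the
   real length is recorded; longer series keep their first 200 strides
   (`truncate_policy = "head"`), preserving early-session behaviour. The
   order — normalize, then pad — is a documented convention: it guarantees
   the pad entries are exact zeros in [0, 1] space. Metrics are computed on
   the padded vectors including the pad zeros; when a series is much
   shorter than 200 strides this biases all six metrics (both vectors share
   a run of zeros), which is accepted as part of the procedure rather than
   corrected, and is why the generator's default stride count equals the
   pad length.

## The six metrics

`similarity_profile()` computes, between the processed baseline X and
session Y of common padded length n:

| metric | definition | range on [0,1] inputs |
|---|---|---|
| `ed` | sqrt(Σ(Xᵢ−Yᵢ)²/n) | [0, 1] |
| `md` | Σ|Xᵢ−Yᵢ|/n | [0, 1] |
| `dtw` | D(n,n)/n, D(i,j) = |Xᵢ−Yⱼ| + min(D(i−1,j), D(i,j−1), D(i−1,j−1)) | ≥ 0 |
| `xcrd` | (1 − XCR(0)²) / Σₖ₌₁..₂₀ (1 − XCR(k)²) | ≥ 0 |
| `cc` | Pearson correlation | [−1, 1] |
| `cs` | Σ XᵢYᵢ / (‖X‖‖Y‖) | [−1, 1] |

Numerical choices that were genuinely open:

- The normalized Euclidean distance is typeset ambiguously in the
  literature (sqrt(Σd²)/n vs sqrt(Σd²/n)); the RMS form is the default
  because only it attains the advertised upper bound of 1, and the other
  reading stays available as `ed_form = "sum_over_n"`.
- The DTW local cost is |Xᵢ−Yⱼ| by default (`dtw_local_cost = "sq"` for the
  squared alternative); the recurrence is evaluated over the full warping
  grid in compiled code (`src/dtw.cpp`) with O(n) memory. The diagonal path
  is one admissible warping, so `dtw ≤ md` always — asserted in the tests.
- XCRD uses one-sided lags k = 1..`max_lag` of Y relative to X, each
  correlation Pearson-normalized on the overlapping support. The default
  `max_lag = 20` (10% of the padded length) balances sensitivity to
  delayed correlations against the shrinking support at high lags. The
  one-sided convention makes XCRD the only asymmetric metric; this is
  asserted, not hidden. XCRD is undefined for constant inputs and when all
  lagged correlations are ±1; both raise errors.
- Cosine similarity is clamped to [−1, 1] against floating-point spill so
  downstream range contracts hold exactly.

# Outcome prediction

The prediction setting is deliberately early: features come from the
*second* training session (the first is discarded as an adaptation
session). With 15 patients (11 improved, 4 unimproved) the evaluation
design, not the classifier, is the hard part:

- **Stratified 5-fold CV** (`stratified_cv_eval()`): per-class counts
  differ by at most one across folds and class remainders are dealt to the
  smallest folds, so 11/4 over 5 folds gives per-fold class counts
  (3, 0), (2, 1), (2, 1), (2, 1), (2, 1) — one fold necessarily has no
  minority sample. Metrics are the arithmetic mean of per-fold values;
  a per-fold ratio with zero denominator (e.g. specificity in the
  minority-free fold) is undefined and *excluded* from the mean rather
  than zeroed. The degenerate all-improved predictor pins both
  conventions: it must yield exactly (73.33, 100.00, 0.00, 84.00) for
  (ACC, SENS, SPEC, F1) on the 11/4 cohort — pooled aggregation would give
  F1 = 84.62 instead, and zeroing the undefined specificity would not
  change SPEC here but would change the exclusion semantics the tests
  check. The positive class is `improved`.
- **Repeated undersampling** (`undersample_eval()`): 3 training samples
  per class, the rest tested, 200 repetitions averaged.
- **SMOTE CV** (`smote_cv_eval()`): minority oversampling with 2 nearest
  neighbours applied *inside training folds only*; synthetic points are
  convex combinations of a minority sample and one of its true minority
  neighbours, so they never leave the minority convex hull, and no
  synthetic sample ever reaches a test fold.

Classifier families (`model_spec()`, `model_grid()`): SVM (e1071; linear,
RBF, polynomial degree 3; cost 0.1–10000), random forest (randomForest;
min leaf 1/5/10, 5–100 trees), bagged decision trees (rpart bootstrap
ensemble), AdaBoost.M1 (rpart stumps, learning rate 0.001–0.1, 15–30
learners), and a single-hidden-layer perceptron (nnet; 10–50 nodes,
ridge decay 0.01, 1000 epochs, logistic activations). The perceptron's
BFGS optimizer stands in for gradient/conjugate-gradient backpropagation
variants; optimizer-level parity is explicitly out of scope, capacity
parity is not.

## Feature selection

`mrmr_rank()` implements greedy minimum-redundancy maximum-relevance
ranking with mutual information estimated after rank-based equal-frequency
3-bin discretization — at this sample size the smallest scheme that keeps
bins populated per class, and rank-based so the ranking is invariant to
strictly monotone transformations of any feature (a property test). The
difference form (MID) is the default, the quotient (MIQ) available. A
constant feature carries no information and is always ranked last; scores
are rounded to 10 decimals before ordering so mathematically tied
candidates fall back to relevance, then name, instead of floating-point
noise. Rankings are computed once per stratified fold (on the training
portion, so each ranking sees both classes) for both 5 and 3 folds, and
`vote_select()` keeps features ranked in the top k = 4 of a strict majority
of folds, ordering candidates by votes, then mean rank, then name, and
capping the subset at k.

# Adherence scoring (GPS_MFC)

For each training session, each chosen dissimilarity measure yields an MFC
Variation Score against the patient's processed baseline, and the session
score is their root mean square:

GPS_MFC = sqrt((1/N) Σₘ MVSₘ²), ΔGPS_MFC(i+1) = GPS_MFC(i+1) − GPS_MFC(i).

The default measure set is {1−CS, XCRD}; any subset of
{ed, md, dtw, xcrd, 1−cc, 1−cs} is accepted, with similarities converted by
1 − value whenever a distance measure is present so all components read in
the same direction. Since CC and CS live in [−1, 1], 1 − value can reach 2;
values are deliberately not clamped — a negative correlation genuinely is
further from baseline than a zero one, and clamping would hide it.

Ten sessions give nine deltas, which telescope exactly:
Σ deltas = GPS_MFC(10) − GPS_MFC(1); this identity is tested to machine
precision. Sessions lost to capture failure make GPS undefined; both
adjacent deltas are reported as 0 with `zeroed_by_missing = TRUE`, so plots
carry the zero convention while statistics (per-patient means,
`cohort_gps_correlation()`) exclude unavailable sessions instead of
absorbing zeros. Group differences per session are tested with the
two-sided Mann–Whitney U test (`session_group_test()`): exact for untied
samples at these sizes, tie-corrected normal approximation otherwise, and
p = 1 by definition when all pooled values are identical.

# Alternative feature spaces

For the comparison of derived-feature pathways, `alt_feature_profiles()`
computes CC/CS/XCRD between baseline and session *feature vectors* in two
spaces: descriptive statistics plus tone–entropy, and wavelet multiscale
log-variances.

- The percentage index PI is computed on the raw millimetre series (percent
  change of a min–max-normalized series is ill-defined at 0); tone is its
  mean, entropy the Shannon entropy over a fixed 1-percentage-point
  histogram (configurable; the binning of the original tone–entropy work is
  not recoverable here).
- The wavelet pathway uses a hand-implemented periodized Daubechies-6
  (12-tap) analysis filter bank over 8 levels — no DWT package is a
  dependency of this package. Per level the "variance" is the mean squared
  detail coefficient (energy about zero), which stays defined at the
  deepest levels where only one or two coefficients survive; the
  least-squares slope of log2-energy against level is appended as a
  multiscale exponent. Periodized boundaries (odd lengths wrapped to even)
  are an approximation accepted so that 8 levels are computable from 200
  samples. White noise gives a near-flat profile, a low-frequency sinusoid
  concentrates energy at coarse levels — both Monte-Carlo-tested. How many
  scalar features per decomposition the original comparison used is not
  recoverable; this package emits 8 + 1 and the classifier pathway is
  length-generic, so the choice does not affect the comparison machinery.

# The synthetic cohort

`simulate_cohort()` is first-class, tested code, not a fixture. It encodes
the study conditions: 11 improved / 4 unimproved patients, one baseline
plus ten training sessions of 200 strides, 5% session loss.

- **Baseline**: stationary AR(1) around 20 mm with SD 4 mm and lag-1
  autocorrelation 0.3 — the minimal model with stride-to-stride dependence,
  which the delayed-correlation metric presupposes. Per-patient mean and SD
  are jittered (10% relative SD). Values are floored at 0.5 mm.
- **Adherence** α ∈ [0, 1] acts three ways: the session mean moves to
  μ + α·σ (towards the target centre μ + σ), the SD shrinks by factor
  (1 − 0.5α) (the clinical goals: raise clearance, reduce variability), and
  the stride pattern decorrelates from baseline — the session's
  standardized deviations are (1 − α)·z_baseline blended with independent
  AR(1) innovations at weight sqrt(1 − (1 − α)²), so the expected
  correlation with the baseline pattern is 1 − α. The blending is the load-
  bearing choice: min–max normalization makes pure mean/SD changes
  invisible to the metrics, so a generator with fully independent session
  innovations would make *both* archetypes equally baseline-decorrelated
  and no metric could separate them. Low adherence must literally mean
  "stays baseline-like".
- **Schedules**: improved patients ramp linearly 0.3 → 0.9 over sessions
  1–10; unimproved patients draw a per-session level uniformly from
  [0, 0.15]. Effect sizes are unknowable from published material; these
  defaults are chosen once so the qualitative findings (class
  recoverability, session-wise CS/XCRD ordering, GPS_MFC group difference)
  hold robustly, and the negative control — both groups on the identical
  schedule — drops classification to the chance band.
- **Amplitude-shape jitter**: each session's marginal distribution is
  warped by a random monotone power map (log-uniform exponent, half-width
  0.5). This emulates the subject- and day-specific amplitude-distribution
  variation that motivates amplitude normalization in the first place:
  min–max removes linear amplitude effects but not shape changes, so
  pointwise metrics (ED, MD) acquire adherence-independent variation while
  rank-preserving metrics (CC, CS, XCRD) are barely touched. Without it
  every metric is a near-perfect proxy of the single latent adherence
  dimension, mutual-information relevance saturates, and the observed
  mRMR ordering (CS/XCRD/CC/DTW above ED/MD) cannot emerge from
  redundancy alone.
- **Data loss**: training sessions (never baselines) are dropped
  independently at the configured rate.

What the generator does *not* emulate: real biomechanics (joint kinematics,
double support), non-stationary within-session fatigue, floor/ceiling
effects of the treadmill protocol, and the true effect-size distribution of
a clinical cohort. Passing tests on this cohort therefore show that the
pipeline recovers the structure it assumes when that structure is present —
they are internal-consistency evidence, not clinical validation.

# Problem sizes and determinism

Every stochastic component takes an explicit seed, and the pipeline
(`run_experiment()`) derives per-stage seeds from one global seed, so
outputs reproduce byte-for-byte. The test suite and acceptance script use
the cohort at its study-condition size (15 patients × 11 sessions × 200
strides), 200 undersampling repetitions, Monte-Carlo checks at 100–500
replicates, and brute-force DTW enumeration up to length 6 — sizes chosen
so each suite documents the behaviour at the scale the method targets.

# Known limitations

- Metrics computed on padded vectors are biased when the real stride count
  is far below 200 (shared zero runs inflate similarity); the bias is part
  of the specified procedure and documented rather than corrected.
- XCRD's lag convention (one-sided, per-lag Pearson) is one defensible
  reading of a formula whose normalization is not fully specified in the
  literature it comes from; it is validated against an internal
  definitional oracle only.
- 1−CC/1−CS components of GPS_MFC can exceed 1 for anti-correlated
  sessions; downstream consumers comparing GPS values across measure sets
  should keep the measure set fixed.
- The exact Mann–Whitney test switches to the tie-corrected normal
  approximation under ties; at n = 15 with continuous metrics ties are
  measure-zero, but CSV round-trips at reduced precision could introduce
  them.
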