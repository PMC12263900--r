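---
title: "Electrode reduction for speech-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode reduction for speech-imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegreduce)
```

## The problem

Speech-imagery brain-computer interfaces decode silently imagined words from
multi-channel EEG. Laboratory systems use 64-channel caps; practical systems
cannot. `eegreduce` implements a wrapper-style evaluation loop that starts
from a full montage, removes one electrode per iteration, records the
held-out decoding accuracy of every surviving set, and then picks an
operating point that trades accuracy against electrode economy. Because each
stage (feature family, classifier family, reduction rule) interacts with the
others, the package keeps all of them behind uniform interfaces so that any
combination can be run factorially.

The package operates on epoched data: a `trials x channels x samples` tensor
with one class label per trial (`EpochedData`), cut from continuous
recordings (`ContinuousRecording`) that are band-pass filtered 0.5-60 Hz and
notch filtered at 50 Hz before epoching into 2-s windows starting at the
event marker.

A central discipline throughout: the train/test split (`SplitSpec`) is drawn
once per subject and frozen. Every elimination step, every feature re-fit
and every classifier evaluation reuses that same partition, so accuracy
series along a reduction trace are comparable.

## Montage

The reference layout (`standardMontage()`) is a 64-channel extended 10-20
cap: 29 left, 29 right and 6 midline electrodes (Fz, Cz, CPz, Pz, POz, Oz),
including the inferior rows F9/F10 and FT9/FT10. Three anatomical comparison
subsets are registered: `broca_wernicke` — the 18 electrodes covering F7 and
P3 plus their immediate neighbours (F7, AF7, AF3, F5, F9, F3, FT9, FT7, FC5,
CP5, CP3, CPz, P5, P1, P3, PO3, PO8, POz) — and the hemispheric subsets
`left` and `right`, 35 labels each. Midline electrodes belong to both
hemispheric subsets; with 6 midline sites on a 64-channel cap this is the
only assignment that yields 35 + 35. Channel-name comparison is
case-sensitive exact matching: silently aliasing between naming conventions
(T7 vs T3) causes worse bugs than a loud lookup failure.

## Filtering

The band edges are the scientific contract; the filter realization is a
choice. We use a 4th-order Butterworth band-pass plus an RBJ biquad notch
with quality factor 30, both applied forward-backward (zero phase, so event
alignment survives filtering). The normative surface is attenuation: a tone
at the notch frequency loses more than 20 dB RMS, a mid-band tone stays
within 1 dB. Any realization meeting those contracts is interchangeable.

## Feature families

**wav** — each channel's epoch is summarized by its maximum, minimum, mean
and standard deviation plus the relative wavelet energy (RWE) of a 4-level
bior2.2 decomposition: the fraction of total subband energy carried by the
approximation and each detail band (9 values per channel). The wavelet bank
is implemented in the package (decimated pyramid, symmetric boundary
extension). Symmetric padding matters: with it, the zero-sum high-pass taps
annihilate constant signals *exactly* in double precision, which the test
suite asserts bit-wise. RWE sums to 1 by construction.

**featvec** — 20 scalars per channel spanning the classical time/frequency
families: power spectral intensity and relative intensity ratio over delta
(0.5-4), theta (4-8), alpha (8-13), beta (13-30) and gamma (30-60 Hz) —
edges chosen to tile the filtered band; Petrosian and Higuchi fractal
dimensions; Hjorth mobility and complexity; band spectral entropy; skewness;
Fisher information of a delay embedding; approximate entropy; the
detrended-fluctuation exponent; and the Hurst exponent. Parameters the
literature leaves open are fixed as: Higuchi `kmax = 8`; approximate entropy
`m = 2`, `r = 0.2 sd`; DFA over dyadic window lengths 4 to N/4 with
least-squares detrending; Hurst by rescaled range over dyadic windows;
Fisher information from a dimension-20, lag-2 embedding's normalized
singular values. All are exposed as arguments. Zero-variance inputs return
defined sentinels (0 for variance-normalized quantities) rather than NaN,
so downstream classifiers remain total functions.

**csp / cspwav / cspfv** — supervised spatial filtering. For two classes the
filters solve the generalized eigenproblem of the class covariances via
whitening; for more classes the per-class mean covariances are approximately
jointly diagonalized (Pham's algorithm) and the filters ranked by an
information criterion on the projected per-class variances, with a pooled
one-vs-rest eigen fallback if the AJD does not converge. Per-trial
covariances are trace-normalized; a ridge of `1e-10 * trace/channels` keeps
low-rank toys non-singular. Filter signs are fixed (largest coefficient
positive) so results are reproducible and permutation-equivariant. `csp`
features are the log-variances of the top 4 source signals; `cspwav` and
`cspfv` push each source signal through the wav / featvec extractor instead.

Per-channel feature families are concatenated in channel order, and the
`FeatureMatrix` carries a block map from every column back to its source
channel (or CSP component). That layout is what makes channel removal
meaningful for wav/featvec — dropping a channel removes exactly its block
and leaves other channels' columns bit-identical, a property the reduction
loop exploits as a cache and the test suite asserts.

## Classifiers

Four families under one deterministic contract (`trainEval`): features are
standardized with training-set statistics only, all stochastic components
derive from the spec seed, and identical inputs give bit-identical accuracy.

* **xgb** — gradient boosting, softmax objective, mean-error metric, early
  stopping after 10 stagnant rounds on a stratified 20% validation carve-out
  of the training set, at most 200 rounds, depth 6, learning rate 0.3,
  exact greedy splits (midpoint thresholds; at these matrix sizes the
  histogram approximation buys nothing and puts thresholds at bin edges).
* **rf** — random forest, 100 trees, unlimited depth.
* **svm** — RBF kernel, C = 1, `gamma = 1/(n_features * var)`.
* **nn** — a multilayer perceptron implemented in the package: hidden widths
  256-128-64-32-16 with alternating ReLU/tanh activations, inverted dropout
  0.3, softmax output trained with categorical cross-entropy and Adam,
  patience-5 early stopping on a 20% validation carve-out. A sigmoid output
  is incoherent with categorical cross-entropy for more than two classes, so
  the output layer is softmax. Batch normalization is deliberately omitted:
  at the trial counts this pipeline sees (tens of training examples per
  class) batch statistics are noisy, and leaving it out keeps the optimizer
  small and exactly reproducible.

Early-stopping validation folds are carved from training data only; the
held-out test trials never influence fitting. The wrapper loop, however,
*scores* candidate subsets on the held-out set (below).

## Reduction algorithms

All four reducers remove exactly one channel per iteration; the outer loop
(`runReduction`) runs them from the full montage to a single channel,
re-fitting features on the survivors' training trials and recording held-out
accuracy at every step (`ReductionTrace`).

* **gwo** — greedy wrapper backward elimination: every surviving channel is
  left out in turn, the full pipeline is re-run, and the channel whose
  exclusion yields the highest accuracy is rejected. Accuracy ties remove
  the candidate earliest in montage order (deterministic and auditable).
  The per-candidate accuracy table is returned for audit, and the winner's
  accuracy doubles as the post-removal trace value (it is the identical
  computation). Scoring on the frozen held-out set follows the evaluated
  pipeline design; its selection-optimism implications are discussed below.
* **csp_rank** — fits multiclass CSP on the training epochs, extracts the
  two extreme filter vectors, sums absolute coefficients per channel across
  them, and rejects the channel with the smallest combined magnitude. The
  narrative descriptions of this rule in the literature conflict
  (extreme-L1-norm vectors vs the vectors carrying "the most common
  information"). The L1 reading fails on the analytic 4-channel toy: with
  the generalized-eigenvector scaling `w' C w = 1`, small-variance noise
  directions need *large* coefficients, so the largest-L1 filter is a noise
  filter and the rule would reject an informative electrode. The
  implemented resolution therefore takes the two most class-informative
  filters — the eigenvalue extremes for two classes, the top two
  separation-ranked filters otherwise — and rejects the electrode least
  represented in them; this is scale-invariant, total, and reproduces the
  toy.
* **ocsp_rank** — one-vs-all variant: for each class a two-class CSP of
  class-vs-rest contributes its largest- and smallest-eigenvalue
  eigenvectors to a pool; channels are then selected by repeated global
  argmax of absolute pooled coefficients (masking each selected channel)
  until a single unselected channel remains, which is rejected.
* **ica_score** — FastICA (symmetric, logcosh; implemented in the package,
  seeded) on the concatenated training epochs. Non-convergence triggers one
  automatic retry with a fresh seed; if the retry also fails the final
  iterate is used under a warning — on data whose noise subspace is close
  to Gaussian the FastICA contrast is rotation-invariant there, so strict
  convergence can be unattainable while the loading ranking remains
  deterministic and usable. Each component votes for the channel holding its maximum
  loading: 2 points if the component belongs to L, the
  `max(1, round(0.13 N))` components with the largest back-projection norm
  (the "13% largest" rule; boundary ties by component index), 1 point
  otherwise. Ties inside a component go to the lowest channel index; ties at
  the minimum score remove the channel latest in montage order. The
  lowest-scoring channel is rejected.

## Operating-point selection

A Mamdani fuzzy inference system (`fisScore`) turns each step of a trace
into a scalar: accuracy is fuzzified on `[0, subject maximum accuracy]`
(low / medium / high trapezoids with corner fractions {0,0,.5,.7},
{.5,.7,.8,.9}, {.8,.9,1,1}), electrodes removed on `[0, C-1]` (few / medium
/ many at {0,0,.3,.5}, {.3,.5,.6,.8}, {.6,.8,1,1}); nine rules fire with
min-conjunction into four output levels (poor / acceptable / good /
excellent trapezoids on [0,1]); aggregation is max and defuzzification is
the centroid, computed with trapezoid quadrature on a fixed 20001-point
grid (agreeing with a 200001-point oracle to 1e-6 in the tests). Bounding
the accuracy domain by the subject's *maximum* accuracy, rather than an
error-rate bound, keeps the system from over-rewarding channel economy when
accuracy drops. The membership breakpoints are package defaults with the
correct qualitative behavior — monotone in accuracy at fixed removal,
maximal at (max accuracy, max removal) — and are fully config-overridable;
they are not claimed to reproduce any published rule base. `selectTopSet`
evaluates the score at every step and returns the argmax, breaking ties
toward more electrodes removed.

Decoding significance uses the dataset-size-adjusted binomial rule: with
`p0 = 1/nClasses`,

    threshold = ceil(n * (p0 + z_{1-alpha/2} * sqrt(p0 (1-p0) / n))) / n * 100

rounded up to an attainable integer trial count and reported in percent.
For the three study-scale datasets this gives 24.29% (350 trials, 5
classes), 14.44% (360, 9) and 24.00% (400, 5). Whether the original
computation used total or test trials is not documented; total trials
reproduces all three printed values and is adopted.

## Position analysis

`electrodeOccurrence` counts, per channel, the percentage of top sets
retaining it (with a configurable 80% highlight level in the plot).
`clusterRemovedCounts` clusters removed-electrode counts with 1-D k-means
(k-means++ seeding, 25 restarts, best SSE kept) for k = 1..10 and picks the
elbow as the interior k maximizing the discrete second difference of the
log-SSE curve — on the raw SSE curve the first drop always dominates the
curvature and the rule would collapse to k = 2; the log scale locates the
last large relative drop, which is what "the elbow" means visually. On 1-D
data the k-means solutions are validated in the tests against an exact
dynamic-programming oracle. `anatomicalBenchmark` reruns
the feature/classifier pipeline restricted to a registered subset under the
same frozen split.

## The synthetic generator

`generateDataset` emulates the statistical skeleton of a speech-imagery
recording session: a 10-20 cap, 2-s epochs, balanced classes in randomized
order, 1/f background noise (spectrally shaped white noise, independent per
channel, 10 uV RMS), a common 50 Hz line component (5 uV RMS), and optional
frontal blink transients (0.3-4 Hz positive half-waves, off by default).
Class information is carried by band-limited oscillatory sources: each
class has a distinct center frequency spread over 8-30 Hz, a Hann amplitude
envelope, random phase per trial, center-frequency jitter (sd 1.2 Hz) and
Rayleigh-distributed amplitude (unit mean) per trial. The `snr` parameter
is the ratio of source RMS to noise RMS on informative channels; `snr = 0`
generates pure noise.

Two generator design points deserve emphasis because they decide what the
recovery experiments can mean:

* *Trial-to-trial variability is not optional.* With clean constant-
  amplitude sinusoids, decoding saturates at ceiling for any reasonable
  channel subset, and a greedy wrapper degenerates into its tie-breaking
  rule. The jitter and amplitude variability keep accuracy responsive to
  channel loss, as it is in real recordings where imagery strength varies.
* *Each class projects onto one informative channel* (round-robin), and
  classes beyond the channel capacity remain unmodulated (rest-like). The
  rest class is what makes the informative set identifiable in principle:
  without it, removing a channel leaves its class recognizable by the mere
  absence of any source pattern, so that channel carries no unique
  information and no selection method can be expected to keep it.

What the generator does **not** emulate: real imagined-speech
neurophysiology (spatial source mixing by volume conduction, broadband
desynchronization, cross-channel correlated noise), recording artifacts
beyond blinks, non-stationarity across a session, or block-design label
leakage. Passing the recovery tests therefore demonstrates that the
pipeline's machinery is correct and sensitive under a known ground truth —
not that any particular accuracy level will be attained on real data.

Presets: `tiny` (4 channels, 2 classes, 20 trials, 128 Hz), `small` (16
channels of which 4 informative, 5 classes, 100 trials, 128 Hz),
`study-like` (full 64-channel montage, 5 classes, 350 trials, 250 Hz).

## Numerical and reproducibility choices

All randomness flows from explicit integer seeds through a local RNG scope
(`withSeed`), never the global stream; derived stream seeds stay inside the
32-bit integer range. Covariances get a relative ridge of 1e-10; CSP and
ICA outputs are sign-fixed; greedy and score ties have fixed documented
directions; degenerate signals produce sentinels, not NaN; the FIS centroid
grid is fixed at 20001 points. Classifier parallelism is disabled
(`nthread = 1`) so results do not depend on scheduling.

## Selection optimism

Because the wrapper scores candidate subsets on the frozen held-out set,
every recorded trace value is the winner of an argmax over candidates, and
the maximum of a trace is effectively a maximum over on the order of a
hundred correlated evaluations. On pure-noise data this maximum
concentrates near the upper edge of — and with a few percent probability
per trace exceeds — the 99% binomial band of a *single* 20-trial
evaluation. This is the textbook optimism of test-set-scored selection, not
signal; applications that need unbiased operating-point accuracies should
re-evaluate the selected subset on data never touched by the selection
loop.

## Problem sizes used in the validation experiments

The parameter-recovery experiment runs 20 seeded greedy traces and the null
calibration 10 traces on the `small` preset with the wav features and the
random-forest classifier — the fastest feature/tree-ensemble combination,
chosen so the whole validation suite stays desk-scale. The `study-like`
preset exercises full-montage shapes without the factorial sweep.

## Limitations

* The FIS membership geometry is a qualitative default, not a published
  rule base; conclusions about specific operating points depend on it.
* The greedy wrapper is O(C^2) pipeline evaluations per trace; for 64
  channels with CSP-based features this is hours, not minutes, per combo.
* The multiclass CSP component ordering (information criterion on projected
  variances) is one of several defensible conventions; filter *sets* are
  stable but individual component ranks near the decision boundary may
  differ between conventions.
* Readers cover multiplexed binary BrainVision (float32/int16) and
  fixed-rate 16-bit EDF with a marker channel; exotic variants are out of
  scope.
```
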