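---
title: "Multi-objective EEG channel selection for biometric identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective EEG channel selection for biometric identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegselect)
```

## The problem

EEG recordings carry subject-specific structure that can serve as a
biometric: a system enrolls a group of subjects, later accepts or rejects a
claimed identity (authentication), and — for accepted instances — decides
*which* enrolled subject is present (identification). High-density montages
make this accurate but impractical; a deployable headset wants as few
electrodes as possible. Those goals pull in four directions at once:

1. minimize the number of channels,
2. maximize multi-class identification accuracy,
3. maximize the true acceptance rate (TAR): genuine instances accepted,
4. maximize the true rejection rate (TRR): intruder instances rejected
   (the false acceptance rate is `1 - TRR` by construction).

`eegselect` implements the whole pipeline — preprocessing, feature
extraction, two-layer classification, and an NSGA-II / NSGA-III search over
channel subsets and classifier parameters — together with a synthetic EEG
generator with known ground truth so every stage is testable without any
external recordings.

## Signal model and preprocessing

Input data are epoch sets: fixed-length multi-channel epochs (channels x
samples, microvolts, 200 Hz by default) indexed by subject and session,
with an ordered montage of channel labels. Each epoch is re-referenced to
the common average,

$$V_i^{CAR}[t] = V_i[t] - \frac{1}{n}\sum_{j=1}^{n} V_j[t],$$

which removes the component common to all electrodes. Two choices matter
here and are deliberate:

* CAR always uses **all** recorded electrodes, *before* any channel
  selection. Per-channel features can then be cached once and served for
  every candidate mask; computing CAR over a selected subset would make
  cached features mask-dependent and invalidate the cache-and-reuse
  workflow.
* CAR is applied **per epoch** rather than over a concatenated recording —
  the data model is epoch-wise throughout, and per-epoch referencing keeps
  epochs independent.

A config flag (`car = FALSE`) disables referencing for ablation.

## Per-channel features

Each (already re-referenced) channel series is decomposed by empirical
mode decomposition (EMD): iterative sifting with cubic-spline envelopes
through the local extrema, mirrored extrema extension at the boundaries
(two extrema reflected about each endpoint), a Cauchy-type stopping
criterion on the relative change between sifting iterations (threshold
0.2), at most 50 sifting iterations per mode and at most 10 modes.
Extraction stops when the residual has fewer than two maxima or minima. By
construction the modes and residual sum back to the input exactly;
constant or too-short series yield zero modes with the residual equal to
the input, and downstream code handles that fallback explicitly.

Sifting can produce redundant modes whose shape and frequency content
differ strongly from the raw signal; these sit at large Minkowski distance
from it. The **two IMFs closest to the original signal** (Minkowski order
`p = 2` by default; the order is configurable since nothing forces the
Euclidean choice) are kept, and each is summarised by four features:

* **instantaneous energy** — `log10` mean squared amplitude;
* **Teager energy** — `log10` mean absolute Teager-Kaiser operator
  `x[n]^2 - x[n-1] x[n+1]`, sensitive to joint amplitude-frequency
  modulation;
* **Higuchi fractal dimension** — slope of `log L(k)` vs `log k` for the
  standard curve-length construction, `k_max = 10` by default;
* **Petrosian fractal dimension** — from the number of sign changes of the
  first difference, with zero differences carrying the previous sign.

Both energies are reported on a `log10` scale: raw mean-square energies
span orders of magnitude across channels and would otherwise dominate any
kernel distance. The floor `log_floor = 1e-12` guards `log10(0)` for
zero-energy modes. When sifting yields a single mode its four features are
duplicated, so the per-channel block is always exactly 8 values —
classifiers require fixed dimension. Blocks for all channels of all epochs
are computed once into a **feature cache** (a tidy table with provenance:
feature order, EMD settings, Minkowski order, CAR flag, montage); any
candidate channel mask is then served by column selection.

## Two-layer classification

Authentication is a one-class SVM with RBF kernel, trained on the pooled
instance vectors of all enrolled subjects from the training session. `nu`
upper-bounds the fraction of training errors (and lower-bounds the support
vector fraction); `gamma` sets kernel locality. Acceptance uses the
decision function's natural zero boundary — no offset is tuned. One global
model is used, not per-subject models. Identification is a linear
multi-class SVM (regularization constant 1.0, configurable); its quality
is measured by stratified k-fold cross-validation (10-fold by default)
over the enrolled subjects' training-session instances, which matches the
training flow: the identification layer never sees intruders. The deployed
decision composes the layers: an instance is identified only if first
accepted.

Two numerical notes. The underlying libsvm solver cannot fit the
degenerate `nu = 1` problem, so `nu` is clamped to `[1e-6, 1 - 1e-6]` at
fit time while the requested value is reported unchanged. And boundary
support vectors land numerically just below zero decision value, so the
nominal "training error fraction at most nu" bound holds only up to the
boundary-SV fraction; tests allow for that slack.

## The search space and the genetic search

A candidate is a binary chromosome of `n_channels + 8` genes: one gene per
montage channel, then a 4-bit field indexing `nu` and a 4-bit field
indexing `gamma` (most-significant bit first) in a shared 16-entry lookup
table `{1e-6, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
0.7, 0.8, 0.9, 1.0}`. With the full 56-channel montage that is the
64-gene chromosome of the search. Embedding the classifier parameters in
the chromosome replaces a per-candidate grid search, which would be far
too slow inside an evolutionary loop.

Every candidate is scored on the four objectives; maximized rates are
negated internally (`1 - accuracy`, `1 - TAR`, `1 - TRR`) so all four are
minimized, and reports re-invert them. An all-zero channel mask is
penalized with a sentinel worst vector (`n_channels + 1`, 1, 1, 1 in the
minimization image) rather than repaired: repair would inject channels the
search never chose, and the penalty keeps evaluation total. A failed SVM
fit is penalized the same way. Cross-validation reuses one fixed fold
assignment per run, so objective noise across candidates reflects channels
and parameters, not fold shuffling.

The search follows the study configuration: population 30, at most 500
generations, and a termination check every 10 generations against an
objective-space tolerance of 1e-4. The movement metric (left open by the
source configuration) is the mean distance from each current front point
to its nearest counterpart of the previous checkpoint, after normalizing
both fronts by the ideal and nadir of their union. Genetic operators were
also left open; the package uses standard binary-GA defaults, all
configurable: binary tournament mating, two-point crossover with
probability 0.9, per-gene bit-flip mutation with probability `1/n_genes`.
NSGA-II survival uses fast non-dominated sorting with crowding distance;
NSGA-III replaces crowding with reference-point niching on the normalized
hyperplane (systematic Das-Dennis placement, 4 divisions over 4 objectives
= 35 points, at least the population size; intercepts from
achievement-scalarizing extreme points with a range fallback for
degenerate fronts).

**Archive-based fronts.** The returned front is the non-dominated set of
*all* candidates evaluated during a run, not only of the final
population. With a fixed-size population, crowding or niching truncation
can displace genuinely non-dominated members once the front outgrows the
population — observed directly on the 8-channel benchmark, whose true
front (40 members) exceeds the default population. The archive never
forgets an evaluated candidate, so on exhaustively enumerable instances
the returned front converges to the true Pareto front, which is exactly
what the test suite verifies. Evaluations are memoised by chromosome
(evaluators are deterministic), so archive bookkeeping costs nothing.

## Synthetic data: what it emulates, and what it does not

The generator emulates the gross structure of an ERP-style recording:
per-subject oscillatory signatures (random carrier frequencies in 6-30 Hz,
subject-specific channel loadings) confined to a known informative channel
subset, an ERP-like Gaussian bump about 300 ms after epoch onset on those
channels, `1/f` background noise on every channel (spectral exponent 1 —
EEG-like spectra stress EMD far more realistically than white noise), and
a multiplicative log-normal session-to-session amplitude jitter.
Full-scale defaults mirror the study conditions: 26 subjects, 56 channels,
2 sessions, 25 epochs per session, 200 Hz, 1-s epochs.

It does **not** attempt biophysical realism: no volume conduction or
forward modeling, no artifacts (blinks, EMG), no non-stationarity within
an epoch, and subject differences are purely spectral/loading differences.
Passing tests on this generator therefore demonstrate that the pipeline's
machinery is correct and that selection recovers channels that truly carry
identity information — not that any particular accuracy transfers to real
recordings.

The informative-channel set is the testing hook: real data has no ground
truth for "the right channels", so synthetic ground truth is the only way
to test selection behaviour. Two frozen benchmark instances are provided.
The `easy` instance (6 subjects, 16 channels of which 6 informative, 20
epochs/session, strong signatures, low noise, 2% session jitter) is
designed so the pipeline approaches perfect metrics; the `hard` instance
draws carriers from a shared 3-frequency pool with weak amplitudes, strong
noise and 30% jitter, so authentication stays clearly imperfect. Their
parameters were calibrated once, when the instances were designed, and
then frozen.

## Problem sizes used by the tests and the acceptance script

All checks run on reduced instances chosen to keep the whole suite in the
minutes range while leaving every mechanism intact: the enumeration oracle
uses 4 subjects x 8 channels x 8 epochs/session (255 non-empty masks,
frozen `nu`/`gamma`), the easy/hard benchmarks 6 subjects x 16 channels x
20 epochs/session, and search runs use populations of 16-48 over 8-60
generations. The full-scale 26 x 56 configuration runs through exactly the
same code paths.

## Other decisions worth recording

* **Instances per session.** The source material states both 60 recorded
  and 25 usable instances per session; the generator treats
  `epochs_per_session` as configuration (default 25) rather than guessing
  which figure is authoritative.
* **Identification pool.** Which epoch pool feeds the k-fold
  identification accuracy is configurable; the default is the
  training-session non-intruder pool, matching the training flow.
* **Channel indexing.** Montage positions are 1-based inside the R API
  (R-idiomatic); reports always print montage labels, never indices, so
  no off-by-one ambiguity can leak out.
* **Default montage.** The full 56-label extended 10-20 list is a
  documented stand-in (the source names only a subset of labels); all
  logic is label-agnostic.
* **TAR/TRR counting.** Per instance (epoch), not per subject — reported
  rates are finer than subject counts would allow.
* **Tie-breaks.** IMF-selection ties break toward the lower mode index;
  tournament ties break uniformly at random under the run's seed.
* **Determinism.** Every source of randomness (generator, fold
  assignment, GA) flows from explicit seeds; identical seeds reproduce
  datasets, fronts and reports bit for bit.

## Known limitations

* EMD is implemented with the standard but not unique sifting choices;
  different envelope or stopping conventions change individual features
  (not the pipeline's structure). Mode mixing on noisy channels is the
  main driver of session-to-session feature drift.
* The one-class layer is a single pooled model; per-subject authentication
  models are out of scope.
* NSGA-III niching uses the common simplified normalization (ASF extreme
  points with range fallback) rather than the full original
  linear-program intercept handling of degenerate cases.
* Report files store doubles at full precision (`%.17g`) and round-trip
  exactly, but are not compact; the format favours inspectability.
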