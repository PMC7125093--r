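# eegselect

Multi-objective EEG channel selection for biometric identification and
intruder detection.

## What this is for

EEG signals carry subject-specific structure that can act as a biometric:
a system enrolls a set of subjects and must later (a) reject probes from
people who are not enrolled — authentication — and (b) name the subject
for probes it accepts — identification. Dense electrode montages make
this accurate but impractical to wear; the engineering question is **which
small subset of channels preserves performance**. That is a genuinely
multi-objective problem, and `eegselect` treats it as one, searching for
channel subsets and classifier parameters that jointly optimize four
objectives:

| objective | direction |
|---|---|
| number of channels | minimize |
| identification accuracy (multi-class, k-fold CV) | maximize |
| TAR — true acceptance rate of genuine instances | maximize |
| TRR — true rejection rate of intruder instances (FAR = 1 − TRR) | maximize |

## The pipeline

1. **Common average reference.** Each epoch is re-referenced:
   `V_i ← V_i − mean_j(V_j)` at every sample, always over the full
   montage so cached per-channel features stay valid for any mask.
2. **EMD features.** Each channel series is decomposed by empirical mode
   decomposition; the two intrinsic mode functions closest to the raw
   signal (Minkowski distance, p = 2) are each summarised by four
   features — instantaneous energy, Teager energy, Higuchi fractal
   dimension, Petrosian fractal dimension — giving an 8-value block per
   channel, cached once per dataset.
3. **Two-layer classification.** A one-class RBF SVM (parameters `nu`,
   `gamma`) authenticates instances; a linear multi-class SVM identifies
   accepted ones.
4. **NSGA search.** Candidates are 64-gene binary chromosomes (with a
   56-channel montage): 56 channel genes plus two 4-bit fields indexing
   `nu` and `gamma` in a 16-entry lookup table. NSGA-II
   (crowding-distance survival) or NSGA-III (reference-point niching)
   evolves them under the four objectives; the result is a Pareto front
   of configurations, reported as a table of channel count, accuracy,
   TAR, TRR, `nu`, `gamma` and channel labels.

A synthetic EEG generator (subject-specific oscillatory signatures on a
known informative channel subset, ERP-like bump at 300 ms, 1/f noise,
session-to-session jitter) provides ground truth for testing everything,
including whether channel selection recovers the channels that truly
carry identity information.

## Worked example

```r
library(eegselect)

bm <- make_benchmark_instance("easy", seed = 7)
bm$epochs
#> <epoch_set> 6 subjects, 240 epochs, 16 channels x 200 samples @ 200 Hz

cache <- build_feature_cache(bm$epochs)   # CAR + EMD features, cached once

front <- run_nsga(
  make_evaluator(cache, bm$split),
  n_genes = length(bm$epochs$montage) + 8,
  config = ga_config("nsga2", population_size = 24,
                     max_generations = 30, seed = 5),
  montage = bm$epochs$montage
)
glance(front)
#> # A tibble: 1 × 9
#>   variant front_size n_generations converged n_evaluations min_channels ...
#> 1 nsga2           16            30 FALSE               744            1 ...

print(tidy(front), n = 5)
#> # A tibble: 16 × 7
#>   n_channels accuracy   tar   trr    nu    gamma channels
#> 1          1        1 0     1     0.01  0.000001 <chr [1]>
#> 2          1        1 0.617 0.933 0.1   0.0001   <chr [1]>
#> 3          1        1 0.683 0.783 0.3   0.005    <chr [1]>
#> 4          1        1 0.967 0.667 0.005 0.3      <chr [1]>
#> 5          1        1 0.85  0.75  0.1   0.2      <chr [1]>
```

Each row is one non-dominated configuration: with a single channel the
identification accuracy is already 1.0 on this easy synthetic instance,
but no single channel authenticates well. Picking the member with the
best joint operating point:

```r
td <- tidy(front)
best <- td[which.max(pmin(td$accuracy, td$tar, td$trr)), ]
#> best operating point: 4 channels (CH03, CH12, CH14, CH16),
#> accuracy 1.000, TAR 0.983, TRR 1.000, nu 0.9, gamma 1e-06
```

Three of those four channels are in the instance's ground-truth
informative set (`bm$informative`). `autoplot(front)` plots the rates
against channel count; `write_pareto_report(front, "pareto.tsv")` writes
the table above as TSV.

The staged command-line workflow (`simulate` → `extract-features` →
`optimize` → `evaluate`, mirroring the cache boundary between feature
extraction and search) is available both as R functions (`cmd_simulate()`
and friends, driven by a YAML run config) and as a thin CLI script at
`inst/cli/eegselect`.

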