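# Shared fixtures, built lazily once per test session. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# tiny 4-subject set for IO and feature-cache tests
fx_tiny <- function() fx("tiny", function() {
  spec <- synthetic_spec(
    n_subjects = 4, n_sessions = 2, epochs_per_session = 3,
    n_channels = 5, n_informative = 2, seed = 42
  )
  list(spec = spec, epochs = generate_epochset(spec))
})

# reduced 8-channel instance used for exhaustive-enumeration oracles
fx_mini <- function() fx("mini", function() {
  spec <- synthetic_spec(
    n_subjects = 4, n_sessions = 2, epochs_per_session = 8,
    n_channels = 8, n_informative = 4, signature_amplitude = 8,
    noise_level = 4, session_jitter = 0.1, seed = 11
  )
  es <- generate_epochset(spec)
  list(
    spec = spec, epochs = es,
    cache = build_feature_cache(es),
    split = subject_split(c("S01", "S02"), c("S03", "S04")),
    ecfg = eval_config(cv_folds = 4)
  )
})

# all 255 non-empty masks of the mini instance at frozen nu/gamma
# (nu index 5 -> 0.01, gamma index 6 -> 0.1)
fx_mini_enum <- function() fx("mini_enum", function() {
  mini <- fx_mini()
  dplyr::bind_rows(lapply(1:255, function(code) {
    mask <- which(as.integer(intToBits(code))[1:8] == 1L)
    evaluate_configuration(mask, 0.01, 0.1, mini$cache, mini$split,
                           mini$ecfg)
  }))
})

fx_easy <- function() fx("easy", function() {
  bm <- make_benchmark_instance("easy", seed = 7)
  bm$cache <- build_feature_cache(bm$epochs)
  bm
})

fx_hard <- function() fx("hard", function() {
  bm <- make_benchmark_instance("hard", seed = 7)
  bm$cache <- build_feature_cache(bm$epochs)
  bm
})

# one NSGA-II run on the easy instance, reused by recovery and
# end-to-end tests
fx_easy_front <- function() fx("easy_front", function() {
  bm <- fx_easy()
  run_nsga(
    make_evaluator(bm$cache, bm$split),
    n_genes = 24,
    config = ga_config("nsga2", population_size = 24, max_generations = 30,
                       seed = 5),
    montage = bm$epochs$montage
  )
})

# sorted, rounded minimization images for front-equality comparisons
front_key <- function(tb) {
  m <- unique(round(minimization_image(tb), 10))
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

# Monte Carlo hypervolume estimate (minimization, fixed reference box)
hv_estimate <- function(points, ref, n = 20000, seed = 99) {
  withr::with_seed(seed, {
    samples <- matrix(runif(n * length(ref)), n) %*% diag(ref)
    covered <- vapply(seq_len(n), function(i) {
      any(apply(points, 1L, function(p) all(p <= samples[i, ])))
    }, logical(1))
    mean(covered) * prod(ref)
  })
}
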