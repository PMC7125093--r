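short_run <- function(variant = "nsga2", seed = 3, gens = 8, pop = 16) {
  mini <- fx_mini()
  run_nsga(
    make_evaluator(mini$cache, mini$split, mini$ecfg),
    n_genes = 16,
    config = ga_config(variant, population_size = pop,
                       max_generations = gens, seed = seed)
  )
}

test_that("the returned front is unchanged by the brute-force filter", {
  front <- fx("short2", function() short_run("nsga2"))
  filtered <- pareto_filter(front$members[c("n_channels", "accuracy",
                                            "tar", "trr")])
  expect_equal(nrow(filtered), nrow(front$members))
  expect_equal(front_key(filtered), front_key(front$members))
})

test_that("exactly population_size candidates are evaluated per generation", {
  front <- fx("short2", function() short_run("nsga2"))
  per_gen <- table(front$evaluations$generation)
  expect_true(all(per_gen == 16))
  # one summary line per generation with front size and per-objective bests
  expect_equal(front$generations$generation,
               0:front$n_generations)
  expect_true(all(c("front_size", "min_channels", "max_accuracy",
                    "max_tar", "max_trr") %in% names(front$generations)))
})

test_that("identical seeds give identical fronts; different seeds explore differently", {
  f1 <- fx("short2", function() short_run("nsga2"))
  f2 <- short_run("nsga2")
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$evaluations, f2$evaluations)
})

test_that("NSGA-III survival runs and honours the population contract", {
  front <- short_run("nsga3", gens = 6)
  expect_s3_class(front, "pareto_front")
  per_gen <- table(front$evaluations$generation)
  expect_true(all(per_gen == 16))
  filtered <- pareto_filter(front$members[c("n_channels", "accuracy",
                                            "tar", "trr")])
  expect_equal(nrow(filtered), nrow(front$members))
})

test_that("frozen genes stay fixed through the whole run", {
  mini <- fx_mini()
  freeze <- list(positions = 9:16,
                 values = c(0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L))
  front <- run_nsga(
    make_evaluator(mini$cache, mini$split, mini$ecfg), n_genes = 16,
    config = ga_config(population_size = 8, max_generations = 4, seed = 2),
    freeze = freeze
  )
  for (key in front$evaluations$chromosome) {
    genes <- as.integer(strsplit(key, "")[[1]])
    expect_identical(genes[9:16], freeze$values)
  }
})

test_that("hypervolume of the evaluated archive never decreases", {
  front <- fx("short2", function() short_run("nsga2"))
  ev <- front$evaluations
  ref <- c(9, 1, 1, 1) + 0.01
  hv <- vapply(sort(unique(ev$generation)), function(g) {
    pts <- minimization_image(ev[ev$generation <= g, ])
    hv_estimate(pts[pareto_keep(pts), , drop = FALSE], ref, n = 4000)
  }, numeric(1))
  expect_true(all(diff(hv) >= -1e-12))
})

test_that("early termination fires when the front stops moving", {
  mini <- fx_mini()
  # constant evaluator: front is immobile from the start
  ev <- function(genes) {
    tibble::tibble(n_channels = max(1, sum(genes[1:8])),
                   accuracy = 0.5, tar = 0.5, trr = 0.5,
                   nu = 0.1, gamma = 0.1)
  }
  cfg <- ga_config(population_size = 8, max_generations = 200,
                   tolerance = 1e-4, tolerance_check_period = 5, seed = 1)
  front <- run_nsga(ev, n_genes = 16, config = cfg)
  expect_true(front$converged)
  expect_lte(front$n_generations, 15)
})

test_that("invalid GA configurations are rejected", {
  expect_error(ga_config(population_size = 2), "population_size")
  expect_error(ga_config(tolerance = 0), "tolerance")
  expect_error(ga_config(variant = "spea2"))
})
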