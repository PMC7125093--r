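fake_front <- function() {
  tibble::tibble(
    n_channels = c(8, 3), accuracy = c(0.9, 0.7), tar = c(0.8, 0.95),
    trr = c(0.85, 0.9), nu = c(0.01, 0.1), gamma = c(0.9, 0.2),
    channels = list(sprintf("C%d", 1:8), c("FP1", "FP2", "CZ"))
  )
}

test_that("pareto reports sort by channel count and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pareto_report(fake_front(), path)
  back <- read_pareto_report(path)
  expect_equal(back$n_channels, c(3, 8))      # ascending
  expect_equal(back$channels[[1]], c("FP1", "FP2", "CZ"))
  expect_equal(back$accuracy, c(0.7, 0.9))
  expect_equal(back$nu, c(0.1, 0.01))
  expect_equal(back$gamma, c(0.2, 0.9))

  one <- fake_front()[1, ]
  write_pareto_report(one, path)
  expect_equal(nrow(read_pareto_report(path)), 1L)

  expect_error(write_pareto_report(fake_front()[0, ], path), "empty front")
})

test_that("channel overlap summary tallies membership counts", {
  out <- channel_overlap_summary(list(c("A", "B"), c("B", "C")))
  expect_equal(out$channel, c("B", "A", "C"))
  expect_equal(out$n_subsets, c(2L, 1L, 1L))

  same <- channel_overlap_summary(list(c("A", "B"), c("A", "B"),
                                       c("B", "A")))
  expect_true(all(same$n_subsets == 3L))

  withr::with_seed(8, {
    labels <- sprintf("L%02d", 1:10)
    subsets <- lapply(1:3, function(i) sample(labels, sample(3:7, 1)))
    out <- channel_overlap_summary(subsets)
    for (k in seq_len(nrow(out))) {
      brute <- sum(vapply(subsets, function(s) out$channel[k] %in% s,
                          logical(1)))
      expect_equal(out$n_subsets[k], brute)
    }
    expect_setequal(out$channel, unique(unlist(subsets)))
  })

  expect_error(channel_overlap_summary(list(c("A"))), "at least 2")
})

test_that("split summaries average front members per channel count", {
  f1 <- fake_front()
  f2 <- fake_front()
  f2$accuracy <- c(0.8, 0.9)
  out <- summarize_split_fronts(list(f1, f2))
  row3 <- out[out$n_channels == 3, ]
  expect_equal(row3$mean_accuracy, mean(c(0.7, 0.9)))
  expect_equal(row3$sd_accuracy, sd(c(0.7, 0.9)))
  expect_equal(row3$n_members, 2L)
})

test_that("tidy, glance and autoplot expose the front", {
  front <- fx("short2", function() {
    mini <- fx_mini()
    run_nsga(make_evaluator(mini$cache, mini$split, mini$ecfg),
             n_genes = 16,
             config = ga_config("nsga2", population_size = 16,
                                max_generations = 8, seed = 3))
  })
  td <- tidy(front)
  expect_true(all(c("n_channels", "accuracy", "tar", "trr", "nu",
                    "gamma", "channels") %in% names(td)))
  gl <- glance(front)
  expect_equal(gl$front_size, nrow(td))
  expect_s3_class(autoplot(front), "ggplot")
  expect_s3_class(plot_search_progress(front), "ggplot")
})
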