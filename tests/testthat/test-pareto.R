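obj_tbl <- function(...) {
  m <- rbind(...)
  tibble::tibble(n_channels = m[, 1], accuracy = m[, 2],
                 tar = m[, 3], trr = m[, 4])
}

test_that("the minimization image negates the maximized objectives", {
  tb <- obj_tbl(c(3, 0.9, 0.8, 0.7))
  M <- minimization_image(tb)
  expect_equal(unname(M[1, ]), c(3, 0.1, 0.2, 0.3))
})

test_that("pareto_filter keeps exactly the non-dominated candidates", {
  single <- obj_tbl(c(5, 0.5, 0.5, 0.5))
  expect_equal(pareto_filter(single), single)

  # fewer channels with equal rates dominates
  two <- obj_tbl(c(2, 0.7, 0.8, 0.8), c(3, 0.7, 0.8, 0.8))
  kept <- pareto_filter(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_channels, 2)

  expect_error(pareto_filter(two[0, ]), "empty")
})

test_that("pareto_filter agrees with explicit pairwise brute force", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      tb <- tibble::tibble(
        n_channels = sample(1:10, 20, replace = TRUE),
        accuracy = round(runif(20), 2),
        tar = round(runif(20), 2),
        trr = round(runif(20), 2)
      )
      M <- minimization_image(tb)
      dominated <- vapply(1:20, function(i) {
        any(vapply(1:20, function(j) {
          j != i && all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])
        }, logical(1)))
      }, logical(1))
      brute <- M[!dominated, , drop = FALSE]
      brute <- brute[!duplicated(brute), , drop = FALSE]
      kept <- minimization_image(pareto_filter(tb))
      o <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
      expect_equal(unname(o(kept)), unname(o(brute)))
    }
  })
})

test_that("duplicate objective vectors collapse to one representative", {
  tb <- obj_tbl(c(2, 0.5, 0.5, 0.5), c(2, 0.5, 0.5, 0.5),
                c(1, 0.9, 0.2, 0.2))
  kept <- pareto_filter(tb)
  expect_equal(nrow(kept), 2L)
})

test_that("random subject splits are disjoint 50/50 partitions", {
  ids <- sprintf("S%02d", 1:26)
  splits <- random_subject_splits(ids, n_splits = 10, seed = 4)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_length(sp$non_intruders, 13L)
    expect_length(sp$intruders, 13L)
    expect_length(intersect(sp$non_intruders, sp$intruders), 0L)
    expect_setequal(c(sp$non_intruders, sp$intruders), ids)
  }
  # odd counts put the extra subject with the non-intruders
  odd <- random_subject_splits(ids[1:5], n_splits = 2, seed = 4)
  expect_length(odd[[1]]$non_intruders, 3L)
  expect_length(odd[[1]]$intruders, 2L)
  # determinism
  again <- random_subject_splits(ids, n_splits = 10, seed = 4)
  expect_identical(splits, again)
  expect_error(random_subject_splits("S01"), "at least 2")
})

test_that("reference points lie on the unit simplex and count C(d+m-1, m-1)", {
  Z <- reference_points(4, 4)
  expect_equal(nrow(Z), choose(4 + 4 - 1, 4 - 1))  # 35
  expect_equal(rowSums(Z), rep(1, nrow(Z)))
  expect_true(all(Z >= 0))
  expect_equal(nrow(unique(Z)), nrow(Z))
})
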