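make_cloud <- function(n, d = 4, centre = 0, sd = 1, seed = 10) {
  withr::with_seed(seed, matrix(rnorm(n * d, centre, sd), n, d))
}

test_that("one-class training respects the nu error-bound contract", {
  x <- make_cloud(80)
  for (nu in c(0.2, 0.5)) {
    m <- train_one_class(x, nu = nu, gamma = 0.1)
    # training rejection fraction is bounded by nu, up to the boundary
    # support vectors that land numerically just outside
    expect_lte(mean(!predict(m, x)), nu + 0.15)
  }
})

test_that("rejection of training data is monotone in nu", {
  x <- make_cloud(60, seed = 11)
  rej <- vapply(c(0.05, 0.2, 0.5, 0.8), function(nu) {
    mean(!predict(train_one_class(x, nu, gamma = 0.1), x))
  }, numeric(1))
  expect_true(all(diff(rej) >= -0.05))
})

test_that("a far outlier is rejected and dimension mismatches error", {
  x <- make_cloud(50, seed = 12)
  m <- train_one_class(x, nu = 0.1, gamma = 0.1)
  far <- matrix(100, 1, 4)           # ~100 sd away from the cloud
  expect_false(predict(m, far))
  expect_error(predict(m, matrix(0, 1, 5)), "dimension mismatch")
  expect_error(train_one_class(x, nu = 0, gamma = 0.1), "nu")
  expect_error(train_one_class(x, nu = 0.5, gamma = -1), "gamma")
  expect_error(train_one_class(x[1, , drop = FALSE], 0.5, 0.1),
               "2 training instances")
})

test_that("nu = 1.0 from the lookup table still trains", {
  x <- make_cloud(30, seed = 13)
  m <- train_one_class(x, nu = 1.0, gamma = 0.1)
  expect_s3_class(m, "auth_model")
  expect_equal(m$nu, 1.0)
})

test_that("authentication metrics count instances and satisfy FAR = 1 - TRR", {
  x <- make_cloud(50, seed = 14)
  m <- train_one_class(x, nu = 0.05, gamma = 0.05)

  # constructed separable case: intruders far away
  genuine <- make_cloud(10, seed = 15)
  intruders <- make_cloud(12, centre = 60, seed = 16)
  met <- evaluate_authentication(m, genuine, intruders)
  expect_equal(met$far, 1 - met$trr)
  expect_equal(met$tar, met$genuine_accepted / met$n_genuine)
  expect_equal(met$trr, met$intruder_rejected / met$n_intruder)
  expect_equal(met$trr, 1)           # far intruders all rejected
  expect_error(evaluate_authentication(m, genuine[0, ], intruders),
               "genuine")
  expect_error(evaluate_authentication(m, genuine, intruders[0, ]),
               "intruder")
})

test_that("hand-counted acceptance outcomes give TAR 0.8 and TRR 0.75", {
  # stub model with a known acceptance region: accept iff coordinate < 0
  stub <- structure(list(), class = "acceptance_stub")
  assign("predict.acceptance_stub",
         function(object, newdata, ...) as.logical(newdata[, 1] < 0),
         envir = globalenv())
  withr::defer(rm("predict.acceptance_stub", envir = globalenv()))
  genuine <- matrix(c(rep(-1, 8), rep(1, 2)), ncol = 1)    # 8/10 accepted
  intruder <- matrix(c(rep(-1, 3), rep(1, 9)), ncol = 1)   # 3/12 accepted
  met <- evaluate_authentication(stub, genuine, intruder)
  expect_equal(met$tar, 0.8)
  expect_equal(met$trr, 0.75)
  expect_equal(met$far, 0.25)

  # a model accepting everything: perfect TAR, zero TRR
  assign("predict.acceptance_stub",
         function(object, newdata, ...) rep(TRUE, nrow(newdata)),
         envir = globalenv())
  met_all <- evaluate_authentication(stub, genuine, intruder)
  expect_equal(met_all$tar, 1)
  expect_equal(met_all$trr, 0)
})

test_that("identification CV is perfect on a wide-margin separable problem", {
  set.seed(17)
  labels <- rep(c("a", "b", "c"), each = 20)
  x <- cbind(rep(c(0, 10, 20), each = 20) + rnorm(60, sd = 0.1),
             rnorm(60))
  res <- crossval_identification(x, labels, k = 10)
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$sd_accuracy, 0)
})

test_that("identification CV is at chance for permuted labels", {
  set.seed(18)
  c_classes <- 4
  x <- matrix(rnorm(120 * 3), 120, 3)
  labels <- sample(rep(letters[1:c_classes], each = 30))
  res <- crossval_identification(x, labels, k = 5)
  # permutation baseline: accuracy ~ Binomial(n, 1/c) / n
  p <- 1 / c_classes
  se <- sqrt(p * (1 - p) / 120)
  expect_lt(abs(res$mean_accuracy - p), 3 * se + 0.05)
  expect_gte(res$mean_accuracy, 0)
  expect_lte(res$mean_accuracy, 1)
  expect_gte(res$sd_accuracy, 0)
})

test_that("CV errors when a class has fewer instances than folds", {
  x <- matrix(rnorm(24), 12, 2)
  labels <- c(rep("a", 9), rep("b", 3))
  expect_error(crossval_identification(x, labels, k = 5), "smaller k")
})

test_that("CV is deterministic under a fixed fold seed", {
  set.seed(19)
  x <- matrix(rnorm(40 * 4), 40, 4)
  labels <- rep(c("a", "b"), each = 20)
  r1 <- crossval_identification(x, labels, k = 4, seed = 3)
  r2 <- crossval_identification(x, labels, k = 4, seed = 3)
  expect_identical(r1, r2)
})

test_that("the two-layer flow identifies only accepted instances", {
  set.seed(20)
  enrolled <- rbind(make_cloud(20, centre = 0, seed = 21),
                    make_cloud(20, centre = 8, seed = 22))
  labels <- rep(c("a", "b"), each = 20)
  auth <- train_one_class(enrolled, nu = 0.1, gamma = 0.1)
  ident <- train_identifier(enrolled, labels)
  probe <- rbind(enrolled[c(1, 21), ], matrix(100, 2, 4))
  out <- authenticate_identify(auth, ident, probe)
  expect_true(all(is.na(out$identity[!out$accepted])))
  expect_true(all(!is.na(out$identity[out$accepted])))
  expect_false(any(out$accepted[3:4]))   # far outliers never identified
})
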