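test_that("instantaneous energy matches its closed form and scaling law", {
  expect_equal(instantaneous_energy(rep(1, 10)), 0)
  expect_equal(instantaneous_energy(c(1, 2, 3, 4)), log10(7.5))
  x <- rnorm(100)
  expect_equal(instantaneous_energy(7 * x),
               instantaneous_energy(x) + 2 * log10(7), tolerance = 1e-12)
  expect_equal(instantaneous_energy(rep(0, 10), log_floor = 1e-12), -12)
  expect_error(instantaneous_energy(numeric(0)), "empty")
})

test_that("Teager energy matches closed forms for ramp, constant and sine", {
  expect_equal(teager_energy(as.numeric(1:50)), 0)   # operator == 1
  expect_equal(teager_energy(rep(5, 50), log_floor = 1e-12), -12)
  n <- 0:2999
  expect_equal(teager_energy(sin(pi * n / 4)), log10(0.5), tolerance = 1e-3)
  expect_error(teager_energy(c(1, 2)), "3 samples")
})

test_that("Higuchi dimension is ~1 for a line, ~2 for white noise, affine-invariant", {
  line <- seq(0, 1, length.out = 1000)
  expect_gt(higuchi_fd(line, 10), 0.95)
  expect_lt(higuchi_fd(line, 10), 1.05)
  set.seed(4)
  noise <- rnorm(1000)
  fd <- higuchi_fd(noise, 10)
  expect_gt(fd, 1.8)
  expect_lt(fd, 2.05)
  expect_equal(higuchi_fd(3 * noise - 11, 10), fd, tolerance = 1e-10)
  expect_error(higuchi_fd(rnorm(15), 10), "too short")
  expect_equal(higuchi_fd(rep(2, 100), 10), 1)  # flat-curve fallback
})

test_that("Petrosian dimension counts sign changes of the difference series", {
  expect_equal(petrosian_fd(as.numeric(1:100)), 1)
  alt <- rep(c(1, -1), 50)
  # brute-force count: every interior difference flips sign
  n_delta <- 98
  expect_equal(petrosian_fd(alt),
               log10(100) / (log10(100) + log10(100 / (100 + 0.4 * n_delta))))
  x <- cumsum(rnorm(200))
  expect_equal(petrosian_fd(2.5 * x), petrosian_fd(x))
  # zeros in the difference carry the previous sign: a staircase is monotone
  stair <- c(1, 1, 2, 2, 3, 3, 4)
  expect_equal(petrosian_fd(stair), 1)
})

test_that("channel blocks have fixed length 8 and match manual recomposition", {
  t <- (0:199) / 200
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 23 * t) + rnorm(200, sd = 0.1)
  cfg <- feature_config()
  block <- extract_channel_features(x, cfg)
  expect_length(block, 8L)
  expect_true(all(is.finite(block)))

  d <- emd_decompose(x, cfg)
  sel <- select_imfs_minkowski(d, cfg$minkowski_p)
  manual <- unlist(lapply(sel, function(i) {
    imf <- d$imfs[[i]]
    c(instantaneous_energy(imf, cfg$log_floor),
      teager_energy(imf, cfg$log_floor),
      higuchi_fd(imf, cfg$higuchi_kmax),
      petrosian_fd(imf))
  }))
  expect_equal(unname(block), manual)
})

test_that("a single-IMF signal duplicates its features to keep dimension 8", {
  t <- (0:199) / 200
  x <- sin(2 * pi * 5 * t)       # one oscillatory mode
  d <- emd_decompose(x)
  expect_length(d$imfs, 1L)
  block <- extract_channel_features(x)
  expect_length(block, 8L)
  expect_equal(unname(block[1:4]), unname(block[5:8]))
})

test_that("constant signals fall back to finite features, never NaN", {
  block <- extract_channel_features(rep(1.5, 200))
  expect_length(block, 8L)
  expect_true(all(is.finite(block)))
})

test_that("feature extraction is deterministic", {
  set.seed(5)
  x <- rnorm(200)
  expect_identical(extract_channel_features(x), extract_channel_features(x))
})
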