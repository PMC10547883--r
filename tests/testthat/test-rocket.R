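test_that("sampled kernel banks satisfy the sampling rules", {
  bank <- sample_kernel_bank(1000, 300, 68, seed = 7)
  expect_length(bank$kernels, 1000)
  lens <- vapply(bank$kernels, `[[`, integer(1), "length")
  dils <- vapply(bank$kernels, `[[`, integer(1), "dilation")
  biases <- vapply(bank$kernels, `[[`, numeric(1), "bias")
  expect_true(all(lens %in% c(7L, 9L, 11L)))
  expect_setequal(unique(lens), c(7L, 9L, 11L))
  expect_true(all(dils >= 1L))
  expect_true(all((lens - 1L) * dils <= 299L))
  expect_true(all(biases >= -1 & biases <= 1))
  expect_true(all(vapply(bank$kernels, function(k) {
    max(abs(rowMeans(k$weights))) < 1e-12 &&
      anyDuplicated(k$channels) == 0 &&
      all(k$channels >= 1 & k$channels <= 68) &&
      nrow(k$weights) == length(k$channels)
  }, logical(1))))
  # dilation admissibility for l_k = 9 at input length 100: d in 1..12
  bank2 <- sample_kernel_bank(500, 100, 3, seed = 21)
  d9 <- vapply(Filter(function(k) k$length == 9L, bank2$kernels),
               `[[`, integer(1), "dilation")
  expect_gt(length(d9), 0)
  expect_true(all(d9 %in% 1:12))
})

test_that("kernel banks are deterministic given the seed", {
  b1 <- sample_kernel_bank(50, 120, 5, seed = 99)
  b2 <- sample_kernel_bank(50, 120, 5, seed = 99)
  expect_identical(b1, b2)
  b3 <- sample_kernel_bank(50, 120, 5, seed = 100)
  expect_false(identical(b1$kernels, b3$kernels))
})

test_that("sampling rejects invalid inputs", {
  expect_error(sample_kernel_bank(10, 11, 4, seed = 1), class = "rocketfp_invalid_input")
  expect_error(sample_kernel_bank(10, 100, 0, seed = 1), class = "rocketfp_invalid_input")
  expect_error(sample_kernel_bank(0, 100, 4, seed = 1), class = "rocketfp_invalid_input")
})

make_kernel <- function(weights, dilation = 1L, bias = 0, padding = FALSE,
                        channels = seq_len(nrow(weights))) {
  list(length = ncol(weights), dilation = as.integer(dilation),
       weights = weights, bias = bias, padding = padding, channels = channels)
}

test_that("the sliding dot product matches hand-computed cases", {
  x <- matrix(1:5, 1)
  k <- make_kernel(matrix(c(1, 0, -1), 1))
  expect_equal(rocket_convolve(x, k), c(-2, -2, -2))

  # dilation 2 spans x_t - x_{t+4}
  x7 <- matrix(1:7, 1)
  k2 <- make_kernel(matrix(c(1, 0, -1), 1), dilation = 2L)
  expect_equal(rocket_convolve(x7, k2), c(-4, -4, -4))

  # degenerate all-zero kernel returns the bias everywhere
  kb <- make_kernel(matrix(0, 1, 3), bias = 0.7)
  expect_equal(rocket_convolve(x7, kb), rep(0.7, 5))

  # too-short input without padding errors
  k3 <- make_kernel(matrix(c(1, 0, -1), 1), dilation = 4L)
  expect_error(rocket_convolve(matrix(1:5, 1), k3), class = "rocketfp_invalid_input")
})

test_that("output length obeys the padded/unpadded law", {
  set.seed(5)
  trial <- matrix(rnorm(3 * 60), 3)
  bank <- sample_kernel_bank(40, 60, 3, seed = 13)
  for (k in bank$kernels) {
    n_out <- length(rocket_convolve(trial, k))
    if (k$padding) {
      expect_identical(n_out, 60L)
    } else {
      expect_identical(n_out, 60L - (k$length - 1L) * k$dilation)
    }
  }
})

test_that("pooling operators follow their definitions", {
  expect_equal(global_max(c(-2, -2, -2)), -2)
  expect_equal(global_max(c(0.1, 5, -3)), 5)
  expect_equal(global_max(3.2), 3.2)
  expect_error(global_max(numeric(0)), class = "rocketfp_invalid_input")

  expect_equal(ppv(c(-1, 0, 2, 3)), 0.5) # zero is not positive
  expect_equal(ppv(c(-1, -5)), 0)
  expect_equal(ppv(c(1, 2, 3)), 1)
  expect_error(ppv(numeric(0)), class = "rocketfp_invalid_input")

  # negation identity when no output value is exactly zero
  set.seed(8)
  for (i in 1:20) {
    cvec <- rnorm(50)
    expect_equal(ppv(-cvec), 1 - ppv(cvec))
  }
})

test_that("transform emits two features per kernel in bank order", {
  ts <- random_trialset(20, 4, 64, seed = 3)
  bank <- sample_kernel_bank(500, 64, 4, seed = 4)
  f <- rocket_transform(ts, bank)
  expect_identical(dim(f), c(20L, 1000L))
  expect_identical(colnames(f)[1:4], c("k1_ppv", "k1_max", "k2_ppv", "k2_max"))
  ppv_cols <- f[, seq(1, 999, by = 2)]
  expect_true(all(ppv_cols >= 0 & ppv_cols <= 1))

  # zero-weight kernel with positive bias gives constant-positive output
  bank1 <- sample_kernel_bank(1, 64, 4, seed = 1)
  bank1$kernels[[1]]$weights[] <- 0
  bank1$kernels[[1]]$bias <- 1
  f1 <- rocket_transform(random_trialset(1, 4, 64, seed = 2), bank1)
  expect_equal(unname(f1[1, ]), c(1, 1))
})

test_that("vectorized transform equals the naive per-placement oracle", {
  set.seed(17)
  for (i in 1:25) {
    nc <- sample(1:4, 1)
    ns <- sample(12:64, 1)
    nk <- sample(1:20, 1)
    ts <- random_trialset(sample(1:4, 1), nc, ns, seed = 1000 + i)
    bank <- sample_kernel_bank(nk, ns, nc, seed = 2000 + i)
    expect_lt(max(abs(rocket_transform(ts, bank) - naive_rocket_transform(ts, bank))),
              1e-9)
  }
})

test_that("transform rejects shape mismatches and is seed-stable", {
  ts <- random_trialset(3, 4, 64, seed = 3)
  bank <- sample_kernel_bank(5, 32, 4, seed = 4)
  expect_error(rocket_transform(ts, bank), class = "rocketfp_invalid_input")
  bank2 <- sample_kernel_bank(5, 64, 4, seed = 4)
  expect_identical(rocket_transform(ts, bank2), rocket_transform(ts, bank2))
})

test_that("kernel banks survive a JSON round trip", {
  ts <- random_trialset(4, 3, 40, seed = 5)
  bank <- sample_kernel_bank(12, 40, 3, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_kernel_bank(bank, path)
  bank2 <- read_kernel_bank(path)
  expect_equal(bank2$seed, bank$seed)
  expect_equal(rocket_transform(ts, bank2), rocket_transform(ts, bank))
})
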