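test_that("the fixed pattern set enumerates all 84 three-of-nine kernels", {
  pats <- minirocket_patterns()
  expect_identical(dim(pats), c(84L, 9L))
  expect_true(all(pats %in% c(-1, 2)))
  expect_equal(rowSums(pats == 2), rep(3, 84))
  expect_equal(rowSums(pats), rep(0, 84)) # 3*2 + 6*(-1)
  expect_false(anyDuplicated(pats) > 0)
  expect_equal(pats[1, ], c(2, 2, 2, -1, -1, -1, -1, -1, -1))
})

test_that("fitting distributes the feature budget and respects the dilation cap", {
  ts <- random_trialset(8, 5, 150, seed = 2)
  fit <- minirocket_fit(ts, minirocket_config(840, seed = 9))
  expect_identical(nrow(fit$feature_table), 840L)
  expect_equal(sum(fit$combos$n_features), 840L)
  # every pattern participates
  used <- fit$combos$pattern_id[fit$combos$n_features > 0]
  expect_setequal(used, 1:84)
  # dilation cap and receptive-field admissibility
  per_pattern <- table(fit$combos$pattern_id)
  expect_true(all(per_pattern <= 32))
  expect_true(all(8 * fit$combos$dilation <= 149))
  # budget spread is even to within one feature
  expect_lte(diff(range(fit$combos$n_features)), 1L)
  expect_true(all(is.finite(fit$feature_table$bias)))
})

test_that("fitting is deterministic and validates its inputs", {
  ts <- random_trialset(5, 3, 60, seed = 4)
  f1 <- minirocket_fit(ts, minirocket_config(100, seed = 5))
  f2 <- minirocket_fit(ts, minirocket_config(100, seed = 5))
  expect_identical(f1, f2)
  expect_error(minirocket_config(50), class = "rocketfp_invalid_input")
  expect_error(minirocket_config(840, max_dilations_per_kernel = 40),
               class = "rocketfp_invalid_input")
})

test_that("all-zero training signals give zero biases and zero features", {
  arr <- array(0, c(4, 3, 60))
  ts <- fp_trialset(arr, rep(c("a", "b"), 2), 0.6, 100)
  fit <- minirocket_fit(ts, minirocket_config(100, seed = 1))
  expect_equal(fit$feature_table$bias, rep(0, 100))
  f <- minirocket_features(ts, fit)
  expect_equal(unname(f), matrix(0, 4, 100), ignore_attr = TRUE) # 0 > 0 is FALSE
})

test_that("features lie in [0,1] with the contracted shape", {
  ts <- random_trialset(30, 6, 120, seed = 6)
  fit <- minirocket_fit(ts, minirocket_config(840, seed = 7))
  f <- minirocket_features(ts, fit)
  expect_identical(dim(f), c(30L, 840L))
  expect_true(all(f >= 0 & f <= 1))
  expect_identical(minirocket_features(ts, fit), f) # deterministic
  short <- random_trialset(3, 6, 60, seed = 8)
  expect_error(minirocket_features(short, fit), class = "rocketfp_invalid_input")
})

test_that("inverted-kernel features obey pnv = 1 - ppv on tie-free inputs", {
  ts <- random_trialset(6, 4, 80, seed = 10)
  fit <- minirocket_fit(ts, minirocket_config(168, seed = 11))
  f <- minirocket_features(ts, fit)
  ft <- fit$feature_table
  inv_rows <- which(ft$inverted)
  expect_gt(length(inv_rows), 0)
  for (r in inv_rows[seq(1, length(inv_rows), by = 7)]) {
    ci <- ft$combo[r]
    w <- fit$patterns[fit$combos$pattern_id[ci], ]
    for (i in seq_len(dim(ts$trials)[1])) {
      cmat <- rocketfp:::minirocket_conv(ts$trials[i, , , drop = FALSE], w,
                                         fit$combos$dilation[ci],
                                         fit$combos$padding[ci],
                                         fit$channel_sets[[ci]])
      # continuous data: no convolution value ties the bias
      expect_equal(unname(f[i, ft$feature[r]]), 1 - mean(cmat > -ft$bias[r]))
    }
  }
})

test_that("single-convolution features equal the explicit two-pass oracle", {
  set.seed(23)
  for (i in 1:15) {
    nc <- sample(1:4, 1)
    ns <- sample(16:64, 1)
    ts <- random_trialset(3, nc, ns, seed = 3000 + i)
    fit <- minirocket_fit(ts, minirocket_config(sample(84:120, 1), seed = 4000 + i))
    expect_lt(max(abs(minirocket_features(ts, fit) -
                        naive_minirocket_features(ts, fit))), 1e-9)
  }
})

test_that("fitted transforms survive a JSON round trip", {
  ts <- random_trialset(5, 4, 90, seed = 12)
  fit <- minirocket_fit(ts, minirocket_config(120, seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_minirocket_fit(fit, path)
  fit2 <- read_minirocket_fit(path)
  expect_equal(minirocket_features(ts, fit2), minirocket_features(ts, fit))
})
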