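co <- tiny_cohort(n_subjects = 5, seed = 33)
cfg <- tiny_config()

test_that("derived seeds are deterministic, distinct and 32-bit safe", {
  s1 <- derive_seed(1, 2, 3)
  expect_identical(s1, derive_seed(1, 2, 3))
  expect_false(s1 == derive_seed(1, 3, 2))
  for (i in 1:50) {
    s <- derive_seed(2147480000, i, i * 7)
    expect_true(s >= 0 && s < 2^31)
  }
})

test_that("leave-one-subject-out yields one report per subject over n-1 classes", {
  lo <- loom_evaluate(co, cfg, seed = 2)
  expect_length(lo$reports, 5)
  for (rep in lo$reports) {
    expect_identical(nrow(rep$per_class), 4L)
  }
  expect_identical(nrow(lo$summary), 4L)
  lo2 <- loom_evaluate(co, cfg, seed = 2)
  expect_equal(lo$summary, lo2$summary)
  expect_error(loom_evaluate(tiny_cohort(n_subjects = 2), cfg, 1),
               class = "rocketfp_invalid_input")
})

test_that("parameter sweeps report ordered statistics per grid value", {
  sw <- parameter_sweep(co, "num_kernels", c(84, 200), cfg, n_repeats = 3, seed = 3)
  expect_identical(nrow(sw$summary), 2L)
  expect_true(all(sw$summary$min_accuracy <= sw$summary$mean_accuracy))
  expect_true(all(sw$summary$mean_accuracy <= sw$summary$max_accuracy))
  expect_identical(nrow(sw$runs), 6L)
  # repeats use distinct seeds: not all runs identical
  expect_gt(length(unique(sw$runs$accuracy)) +
              length(unique(sw$runs$repetition)), 2)
  td <- tidy(sw)
  expect_identical(td$axis[1], "num_kernels")
  expect_error(parameter_sweep(co, "duration", numeric(0), cfg, 2, 1),
               class = "rocketfp_invalid_input")
})

test_that("the cross-over design fills all nine ordered cells", {
  xo <- crossover_experiment(co, run_config(num_kernels = 100, n_trials = 4,
                                            trial_duration = 1),
                             n_repeats = 2, seed = 4)
  expect_identical(dim(xo$matrix), c(3L, 3L))
  expect_false(anyNA(xo$matrix))
  expect_identical(nrow(xo$summary), 9L)
  expect_identical(nrow(xo$runs), 18L)
  expect_true(all(xo$runs$accuracy >= 0 & xo$runs$accuracy <= 1))
  # missing session triggers a clear error
  broken <- co
  broken$recordings$S001$empty <- NULL
  expect_error(crossover_experiment(broken, cfg, 1, 1),
               class = "rocketfp_invalid_input")
})

test_that("chance helpers agree with the analytic level", {
  expect_equal(chance_level(124), 1 / 124)
  draws <- chance_null(10, 2, n_draws = 2000, seed = 5)
  expect_length(draws, 2000)
  se <- sqrt(0.1 * 0.9 / (20 * 2000))
  expect_lt(abs(mean(draws) - 0.1), 4 * se)
})

test_that("metric reports expose tidy and glance views", {
  m <- fingerprint_sessions(co, "rs1", "rs2", cfg, seed = 6)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 5L)
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$accuracy, m$accuracy)
})
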