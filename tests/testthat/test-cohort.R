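test_that("signatures are deterministic, distinct and band-limited", {
  cfg <- cohort_config(n_subjects = 5, n_regions = 6, seed = 3)
  s1 <- make_signature(cfg, 1)
  expect_identical(make_signature(cfg, 1), s1)
  s2 <- make_signature(cfg, 2)
  expect_false(identical(s1$frequencies, s2$frequencies))
  for (s in list(s1, s2)) {
    expect_true(all(s$frequencies >= 1 & s$frequencies <= 40))
    expect_true(all(is.finite(s$mixing)))
  }
})

test_that("recordings have the configured shape and cohorts are bit-identical", {
  cfg <- cohort_config(n_subjects = 3, n_regions = 7, sampling_rate = 80,
                       duration_rs1 = 9, duration_rs2 = 9, duration_empty = 11,
                       seed = 8)
  co <- generate_cohort(cfg)
  expect_identical(co$subjects, c("S001", "S002", "S003"))
  rec <- co$recordings$S002$rs1
  expect_identical(dim(rec$data), c(7L, 720L))
  expect_identical(dim(co$recordings$S002$empty$data), c(7L, 880L))
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
})

test_that("same-subject sessions are spectrally closer than other subjects at high snr", {
  cfg <- cohort_config(n_subjects = 4, n_regions = 8, sampling_rate = 100,
                       duration_rs1 = 20, duration_rs2 = 20, duration_empty = 10,
                       snr = 50, session_perturbation = 0, seed = 12)
  co <- generate_cohort(cfg)
  log_spec <- function(rec) {
    sp <- apply(rec$data, 1, function(x) {
      stats::spec.pgram(x, spans = 9, plot = FALSE, taper = 0)$spec
    })
    log(sp)
  }
  specs <- lapply(co$subjects, function(s) {
    list(rs1 = log_spec(co$recordings[[s]]$rs1),
         rs2 = log_spec(co$recordings[[s]]$rs2))
  })
  dist2 <- function(a, b) mean((a - b)^2)
  for (i in seq_along(specs)) {
    within <- dist2(specs[[i]]$rs1, specs[[i]]$rs2)
    for (j in seq_along(specs)) {
      if (i == j) next
      expect_lt(within, dist2(specs[[i]]$rs1, specs[[j]]$rs2))
    }
  }
})

test_that("empty sessions share the day component but carry no subject signature", {
  cfg <- cohort_config(n_subjects = 3, n_regions = 6, sampling_rate = 100,
                       duration_rs1 = 8, duration_rs2 = 8, duration_empty = 12,
                       empty_day_structure = 2, seed = 15)
  co <- generate_cohort(cfg)
  e <- lapply(co$subjects, function(s) as.vector(co$recordings[[s]]$empty$data))
  # the shared day structure induces strong cross-subject correlation...
  expect_gt(cor(e[[1]], e[[2]]), 0.3)
  expect_gt(cor(e[[2]], e[[3]]), 0.3)
  # ...while resting sessions of different subjects are uncorrelated
  r <- lapply(co$subjects, function(s) as.vector(co$recordings[[s]]$rs1$data))
  expect_lt(abs(cor(r[[1]], r[[2]])), 0.1)
  # with the day amplitude at zero, empties of different subjects decorrelate
  cfg0 <- cohort_config(n_subjects = 3, n_regions = 6, sampling_rate = 100,
                        duration_rs1 = 8, duration_rs2 = 8, duration_empty = 12,
                        empty_day_structure = 0, seed = 15)
  co0 <- generate_cohort(cfg0)
  e0 <- lapply(co0$subjects, function(s) as.vector(co0$recordings[[s]]$empty$data))
  expect_lt(abs(cor(e0[[1]], e0[[2]])), 0.1)
})

test_that("pipeline accuracy rises with snr and is at chance for snr = 0", {
  accs <- vapply(c(0, 1, 5), function(snr) {
    cfg <- cohort_config(n_subjects = 5, n_regions = 10, sampling_rate = 100,
                         duration_rs1 = 12, duration_rs2 = 12, duration_empty = 6,
                         snr = snr, seed = 21)
    co <- generate_cohort(cfg)
    mean(vapply(1:3, function(r) {
      fingerprint_sessions(co, "rs1", "rs2",
                           run_config(num_kernels = 120, n_trials = 5,
                                      trial_duration = 1),
                           seed = derive_seed(100, r))$accuracy
    }, numeric(1)))
  }, numeric(1))
  # monotone non-decreasing within a small sampling margin
  expect_gte(accs[2], accs[1] - 0.1)
  expect_gte(accs[3], accs[2] - 0.1)
  expect_gt(accs[3], accs[1]) # identifiability dial actually moves
  # snr = 0: mean accuracy of 3 runs x 25 trials inside the 99% chance band
  band <- qbinom(c(0.005, 0.995), 75, 1 / 5) / 75
  expect_gte(accs[1], band[1])
  expect_lte(accs[1], band[2])
})

test_that("subset_cohort validates and keeps requested subjects", {
  co <- tiny_cohort(n_subjects = 4)
  sub <- subset_cohort(co, c("S001", "S003"))
  expect_identical(sub$subjects, c("S001", "S003"))
  expect_error(subset_cohort(co, "S999"), class = "rocketfp_invalid_input")
})
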