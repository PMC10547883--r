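# programmatic fixtures shared across test files

random_trialset <- function(n_trials, n_regions, n_samp, seed,
                            labels = rep("s1", n_trials),
                            duration = n_samp / 100, sampling_rate = 100) {
  set.seed(seed)
  fp_trialset(array(rnorm(n_trials * n_regions * n_samp),
                    c(n_trials, n_regions, n_samp)),
              labels, duration, sampling_rate)
}

# small, clearly identifiable cohort for fast pipeline tests
tiny_cohort <- function(n_subjects = 4, seed = 11, snr = 5,
                        n_regions = 8, fs = 100, dur = 16) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, n_regions = n_regions, sampling_rate = fs,
    duration_rs1 = dur, duration_rs2 = dur, duration_empty = dur,
    snr = snr, n_oscillators = 4, seed = seed))
}

tiny_config <- function(...) {
  run_config(num_kernels = 120, n_trials = 5, trial_duration = 1, ...)
}
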