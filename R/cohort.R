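#' Configuration of a synthetic multi-session cohort
#'
#' The generator emulates the statistical structure the fingerprinting
#' analysis assumes in region-level source time courses: each subject owns a
#' stable spectral/spatial signature (band-limited oscillators mixed into
#' regions) that persists across resting-state sessions, every session adds
#' fresh broadband 1/f noise, and "empty-room" sessions contain noise plus a
#' day-specific component shared across subjects — structured, but carrying
#' no subject information.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_regions number of regions per recording (default 68, one per
#'   cortical atlas label).
#' @param sampling_rate sampling rate in Hz.
#' @param duration_rs1,duration_rs2,duration_empty session durations in
#'   seconds.
#' @param snr ratio of signature power to noise power in resting sessions;
#'   0 produces pure-noise "resting" sessions (the null cohort).
#' @param session_perturbation fraction of the oscillator signature redrawn
#'   between rs1 and rs2, modelling day-to-day state changes.
#' @param noise_exponent spectral slope of the 1/f^a session noise.
#' @param empty_day_structure amplitude (relative to unit noise power) of
#'   the subject-shared day component in empty sessions.
#' @param n_oscillators oscillators per subject signature.
#' @param seed master seed; all subject/session streams derive from it.
#' @return a list of class `fp_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 25, n_regions = 68, sampling_rate = 250,
                          duration_rs1 = 40, duration_rs2 = 40, duration_empty = 40,
                          snr = 3, session_perturbation = 0.1,
                          noise_exponent = 1, empty_day_structure = 1,
                          n_oscillators = 6, seed = 1) {
  assert_count(n_subjects, "n_subjects", min = 2L)
  assert_count(n_regions, "n_regions")
  assert_count(n_oscillators, "n_oscillators")
  assert_scalar_positive(sampling_rate, "sampling_rate")
  for (d in c(duration_rs1, duration_rs2, duration_empty)) {
    assert_scalar_positive(d, "duration")
  }
  if (!is.numeric(snr) || length(snr) != 1L || snr < 0) {
    invalid_input("`snr` must be a single non-negative number.")
  }
  if (session_perturbation < 0 || session_perturbation > 1) {
    invalid_input("`session_perturbation` must lie in [0, 1].")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
         sampling_rate = as.numeric(sampling_rate),
         durations = c(rs1 = as.numeric(duration_rs1), rs2 = as.numeric(duration_rs2),
                       empty = as.numeric(duration_empty)),
         snr = as.numeric(snr),
         session_perturbation = as.numeric(session_perturbation),
         noise_exponent = as.numeric(noise_exponent),
         empty_day_structure = as.numeric(empty_day_structure),
         n_oscillators = as.integer(n_oscillators), seed = as.integer(seed)),
    class = "fp_cohort_config"
  )
}

#' Draw a subject's oscillatory signature
#'
#' A signature is the subject-stable part of the generative model: a set of
#' oscillator frequencies in the 1-40 Hz band, per-oscillator amplitudes,
#' a regions x oscillators spatial mixing matrix and phase offsets.
#' Distinct subject indices yield distinct signatures with probability 1;
#' the draw is deterministic given `(seed, subject_index)`.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return a list of class `fp_signature`.
#' @export
make_signature <- function(config, subject_index) {
  stopifnot(inherits(config, "fp_cohort_config"))
  assert_count(subject_index, "subject_index")
  with_seed(derive_seed(config$seed, 1L, subject_index), {
    k <- config$n_oscillators
    structure(
      list(subject_index = as.integer(subject_index),
           frequencies = runif(k, 1, 40),
           amplitudes = runif(k, 0.5, 1.5),
           mixing = matrix(rnorm(config$n_regions * k), config$n_regions, k),
           phases = runif(k, 0, 2 * pi)),
      class = "fp_signature"
    )
  })
}

# Redraw a fraction of the oscillators (frequency, amplitude, mixing column,
# phase) to model session-to-session signature drift.
perturb_signature <- function(signature, fraction, config, seed) {
  k <- length(signature$frequencies)
  n_redraw <- round(fraction * k)
  if (n_redraw == 0L) return(signature)
  with_seed(seed, {
    idx <- sample.int(k, n_redraw)
    signature$frequencies[idx] <- runif(n_redraw, 1, 40)
    signature$amplitudes[idx] <- runif(n_redraw, 0.5, 1.5)
    signature$mixing[, idx] <- rnorm(config$n_regions * n_redraw)
    signature$phases[idx] <- runif(n_redraw, 0, 2 * pi)
  })
  signature
}

# Power-law (1/f^a) noise via spectral shaping of white noise; unit sd.
one_over_f_noise <- function(n, exponent) {
  x <- rnorm(n)
  xf <- stats::fft(x)
  k <- seq_len(n) - 1L
  k <- pmin(k, n - k) # two-sided frequency index
  h <- c(0, k[-1L]^(-exponent / 2))
  y <- Re(stats::fft(xf * h, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

#' Synthesize one subject-session recording
#'
#' Resting sessions are the subject's mixed oscillators (with a fraction of
#' the signature redrawn for rs2 and fresh phases each session) plus fresh
#' per-region 1/f noise, with the oscillatory part rescaled so its power is
#' `snr` times the noise power. Empty sessions are 1/f noise plus the
#' day-specific component, whose realization is shared by every subject in
#' the cohort and therefore carries no subject information.
#'
#' @param signature a [make_signature()].
#' @param session `"rs1"`, `"rs2"` or `"empty"`.
#' @param config the [cohort_config()] the signature was drawn under.
#' @return an [fp_recording()].
#' @export
make_recording <- function(signature, session, config) {
  stopifnot(inherits(signature, "fp_signature"), inherits(config, "fp_cohort_config"))
  session <- match.arg(session, c("rs1", "rs2", "empty"))
  fs <- config$sampling_rate
  n <- round(config$durations[[session]] * fs)
  idx <- signature$subject_index
  session_code <- match(session, c("rs1", "rs2", "empty"))

  noise <- with_seed(derive_seed(config$seed, 2L, idx, session_code), {
    t(vapply(seq_len(config$n_regions),
             function(r) one_over_f_noise(n, config$noise_exponent),
             numeric(n)))
  })

  if (session == "empty") {
    day <- with_seed(derive_seed(config$seed, 3L, session_code), {
      k <- config$n_oscillators
      f <- runif(k, 1, 40)
      a <- runif(k, 0.5, 1.5)
      mix <- matrix(rnorm(config$n_regions * k), config$n_regions, k)
      ph <- runif(k, 0, 2 * pi)
      tt <- seq_len(n) / fs
      osc <- a * sin(outer(2 * pi * f, tt) + ph)
      mix %*% osc
    })
    p_day <- mean(day^2)
    if (p_day > 0 && config$empty_day_structure > 0) {
      day <- day * sqrt(config$empty_day_structure / p_day)
    } else {
      day <- day * 0
    }
    data <- noise + day
  } else {
    sig <- signature
    if (session == "rs2") {
      sig <- perturb_signature(sig, config$session_perturbation, config,
                               derive_seed(config$seed, 4L, idx))
    }
    osc <- with_seed(derive_seed(config$seed, 5L, idx, session_code), {
      tt <- seq_len(n) / fs
      ph <- sig$phases + runif(length(sig$phases), 0, 2 * pi)
      sig$amplitudes * sin(outer(2 * pi * sig$frequencies, tt) + ph)
    })
    signal <- sig$mixing %*% osc
    p_sig <- mean(signal^2)
    p_noise <- mean(noise^2)
    scale <- if (p_sig > 0 && config$snr > 0) sqrt(config$snr * p_noise / p_sig) else 0
    data <- scale * signal + noise
  }
  fp_recording(sprintf("S%03d", idx), session, data, fs)
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return an object of class `fp_cohort`: per subject, recordings for the
#'   three sessions rs1, rs2 and empty; bit-identical under a fixed seed.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "fp_cohort_config"))
  subjects <- sprintf("S%03d", seq_len(config$n_subjects))
  recordings <- lapply(seq_len(config$n_subjects), function(i) {
    sig <- make_signature(config, i)
    list(rs1 = make_recording(sig, "rs1", config),
         rs2 = make_recording(sig, "rs2", config),
         empty = make_recording(sig, "empty", config))
  })
  names(recordings) <- subjects
  structure(list(recordings = recordings, subjects = subjects, config = config),
            class = "fp_cohort")
}

#' @export
print.fp_cohort <- function(x, ...) {
  cat(sprintf("<fp_cohort> %d subjects x 3 sessions (%d regions @ %g Hz, snr %g, seed %d)\n",
              length(x$subjects), x$config$n_regions, x$config$sampling_rate,
              x$config$snr, x$config$seed))
  invisible(x)
}

#' Keep a subset of subjects
#'
#' @param cohort an [generate_cohort()] cohort.
#' @param subjects subject ids to keep.
#' @return the reduced `fp_cohort`.
#' @export
subset_cohort <- function(cohort, subjects) {
  stopifnot(inherits(cohort, "fp_cohort"))
  missing <- setdiff(subjects, cohort$subjects)
  if (length(missing)) {
    invalid_input(paste("unknown subject(s):", paste(missing, collapse = ", ")))
  }
  cohort$recordings <- cohort$recordings[subjects]
  cohort$subjects <- subjects
  cohort
}
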