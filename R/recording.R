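#' Construct a continuous multivariate recording
#'
#' A recording holds one subject-session continuous source time course as a
#' regions x samples matrix, together with its sampling rate and a session
#' tag (`"rs1"`, `"rs2"` resting-state sessions or `"empty"` for a
#' subject-free noise recording).
#'
#' @param subject_id subject identifier (scalar character).
#' @param session one of `"rs1"`, `"rs2"`, `"empty"`.
#' @param data numeric matrix, regions in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `fp_recording`.
#' @export
fp_recording <- function(subject_id, session, data, sampling_rate) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    invalid_input("`subject_id` must be a single string.")
  }
  session <- match.arg(session, c("rs1", "rs2", "empty"))
  if (!is.matrix(data) || !is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L) {
    invalid_input("`data` must be a numeric matrix with >= 1 region and >= 1 sample.")
  }
  if (anyNA(data)) invalid_input("`data` must not contain missing values.")
  assert_scalar_positive(sampling_rate, "sampling_rate")
  structure(
    list(subject_id = subject_id, session = session,
         data = data, sampling_rate = as.numeric(sampling_rate)),
    class = "fp_recording"
  )
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> subject %s, session %s: %d regions x %d samples @ %g Hz\n",
              x$subject_id, x$session, nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

#' Z-score each region's continuous time course
#'
#' Normalizes every region of the continuous recording to mean 0 and
#' standard deviation 1 before any segmentation into trials, so that trial
#' features reflect waveform shape rather than per-region signal scale.
#' A zero-variance region is centred to all zeros and a warning is issued.
#'
#' @param recording an [fp_recording()].
#' @return the z-scored `fp_recording`.
#' @export
znormalize <- function(recording) {
  stopifnot(inherits(recording, "fp_recording"))
  x <- recording$data
  mu <- rowMeans(x)
  centred <- x - mu
  # denominator n-1 as in stats::sd
  s <- sqrt(rowSums(centred^2) / max(1L, ncol(x) - 1L))
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    warn(sprintf("%d zero-variance region(s) left at 0 after centering.", sum(zero)))
    s[zero] <- 1
  }
  recording$data <- centred / s
  recording
}

#' Cut a recording into fixed-duration trials
#'
#' Consecutive non-overlapping windows are taken from the start of the
#' recording; a trailing remainder shorter than one trial is dropped.
#'
#' @param recording an [fp_recording()].
#' @param duration trial duration in seconds.
#' @return an [fp_trialset()] whose labels all equal the recording's subject.
#' @export
segment <- function(recording, duration) {
  stopifnot(inherits(recording, "fp_recording"))
  assert_scalar_positive(duration, "duration")
  spt <- round(duration * recording$sampling_rate)
  if (spt < 2) invalid_input("`duration` must span at least 2 samples.")
  n <- ncol(recording$data)
  n_trials <- n %/% spt
  if (n_trials < 1L) {
    invalid_input(sprintf(
      "recording of %d samples is shorter than one %d-sample trial.", n, spt))
  }
  n_regions <- nrow(recording$data)
  trials <- array(0, dim = c(n_trials, n_regions, spt))
  for (i in seq_len(n_trials)) {
    trials[i, , ] <- recording$data[, ((i - 1L) * spt + 1L):(i * spt)]
  }
  fp_trialset(trials, rep(recording$subject_id, n_trials),
              duration = duration, sampling_rate = recording$sampling_rate)
}

#' Split a recording into first and second halves
#'
#' Used by the cross-over design when training and testing draw from the
#' same session: trials for training come from the first half and trials for
#' testing from the second, so the two sets never share samples.
#'
#' @param recording an [fp_recording()].
#' @return a list with elements `first` and `second`, both `fp_recording`s.
#' @export
split_halves <- function(recording) {
  stopifnot(inherits(recording, "fp_recording"))
  n <- ncol(recording$data)
  if (n < 4L) invalid_input("recording must have >= 4 samples to split.")
  h <- n %/% 2L
  first <- recording
  first$data <- recording$data[, seq_len(h), drop = FALSE]
  second <- recording
  second$data <- recording$data[, (h + 1L):n, drop = FALSE]
  list(first = first, second = second)
}
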