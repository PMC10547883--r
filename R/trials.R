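#' Construct a trial set
#'
#' A trial set is the unit of classification: fixed-duration windows cut
#' from continuous recordings, stored as an `n_trials x regions x samples`
#' array with one subject label per trial.
#'
#' @param trials 3-d numeric array `[trial, region, sample]`.
#' @param labels character vector of subject ids, one per trial.
#' @param duration trial duration in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `fp_trialset`.
#' @export
fp_trialset <- function(trials, labels, duration, sampling_rate) {
  if (!is.array(trials) || length(dim(trials)) != 3L) {
    invalid_input("`trials` must be a 3-d array [trial, region, sample].")
  }
  if (length(labels) != dim(trials)[1L]) {
    invalid_input("`labels` must have one entry per trial.")
  }
  assert_scalar_positive(duration, "duration")
  assert_scalar_positive(sampling_rate, "sampling_rate")
  structure(
    list(trials = trials, labels = as.character(labels),
         duration = as.numeric(duration), sampling_rate = as.numeric(sampling_rate)),
    class = "fp_trialset"
  )
}

#' @export
print.fp_trialset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<fp_trialset> %d trials x %d regions x %d samples (%g s @ %g Hz), %d subject(s)\n",
              d[1L], d[2L], d[3L], x$duration, x$sampling_rate,
              length(unique(x$labels))))
  invisible(x)
}

n_trials <- function(ts) dim(ts$trials)[1L]
n_regions <- function(ts) dim(ts$trials)[2L]
n_samples <- function(ts) dim(ts$trials)[3L]

#' Concatenate trial sets
#'
#' @param ... `fp_trialset` objects with identical region count, trial
#'   length, duration and sampling rate.
#' @return a single combined `fp_trialset`.
#' @export
bind_trialsets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "fp_trialset")) {
    sets <- sets[[1L]]
  }
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, logical(1), "fp_trialset")))
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (n_regions(s) != n_regions(ref) || n_samples(s) != n_samples(ref) ||
        s$duration != ref$duration || s$sampling_rate != ref$sampling_rate) {
      invalid_input("all trial sets must share shape, duration and sampling rate.")
    }
  }
  total <- sum(vapply(sets, n_trials, integer(1)))
  out <- array(0, dim = c(total, n_regions(ref), n_samples(ref)))
  labels <- character(total)
  at <- 0L
  for (s in sets) {
    k <- n_trials(s)
    if (k > 0L) {
      out[at + seq_len(k), , ] <- s$trials
      labels[at + seq_len(k)] <- s$labels
    }
    at <- at + k
  }
  fp_trialset(out, labels, ref$duration, ref$sampling_rate)
}

#' Sample a balanced subset of trials per subject
#'
#' Draws exactly `n_per_subject` trials per subject without replacement, so
#' every class is equally represented (the balanced-design requirement of
#' the fingerprinting protocol). Reproducible from `seed`.
#'
#' @param trials an [fp_trialset()].
#' @param n_per_subject trials to keep per subject.
#' @param seed integer seed for the draw.
#' @return a balanced `fp_trialset`.
#' @export
sample_trials <- function(trials, n_per_subject, seed) {
  stopifnot(inherits(trials, "fp_trialset"))
  assert_count(n_per_subject, "n_per_subject")
  subjects <- sort(unique(trials$labels))
  counts <- table(trials$labels)
  short <- subjects[counts[subjects] < n_per_subject]
  if (length(short) > 0L) {
    invalid_input(sprintf(
      "subject(s) %s have fewer than %d trials.",
      paste(short, collapse = ", "), n_per_subject))
  }
  keep <- with_seed(seed, {
    unlist(lapply(subjects, function(s) {
      idx <- which(trials$labels == s)
      sort(sample(idx, n_per_subject))
    }))
  })
  fp_trialset(trials$trials[keep, , , drop = FALSE], trials$labels[keep],
              trials$duration, trials$sampling_rate)
}
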