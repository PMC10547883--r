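#' Default run configuration for fingerprinting experiments
#'
#' Defaults follow the reference operating point of the method: 3,500
#' kernels (for MiniRocket this is the pooled-feature budget), 15 trials
#' per subject and a 1.5 s trial duration, with 10 repeats for the
#' randomized designs.
#'
#' @param transform `"minirocket"` or `"rocket"`.
#' @param num_kernels kernel count (ROCKET) or feature budget (MiniRocket).
#' @param n_trials trials sampled per subject and session.
#' @param trial_duration trial duration in seconds.
#' @param n_repeats repeats for sweeps and cross-over cells.
#' @param seed master seed.
#' @param paths optional named list of file paths carried along for reports.
#' @return a list of class `fp_run_config`.
#' @export
run_config <- function(transform = c("minirocket", "rocket"),
                       num_kernels = 3500, n_trials = 15,
                       trial_duration = 1.5, n_repeats = 10,
                       seed = 1, paths = NULL) {
  transform <- match.arg(transform)
  problems <- character(0)
  chk <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      problems <<- c(problems, sprintf("`%s` must be a single positive number", name))
    }
  }
  chk(num_kernels, "num_kernels"); chk(n_trials, "n_trials")
  chk(trial_duration, "trial_duration"); chk(n_repeats, "n_repeats")
  if (length(problems)) {
    abort(c("invalid run configuration:", problems), class = "rocketfp_invalid_config")
  }
  structure(
    list(transform = transform, num_kernels = as.integer(num_kernels),
         n_trials = as.integer(n_trials), trial_duration = as.numeric(trial_duration),
         n_repeats = as.integer(n_repeats), seed = as.integer(seed), paths = paths),
    class = "fp_run_config"
  )
}

# Fit the configured transform on training trials only, then featurize both
# sets. Returns list(train, test) feature matrices plus the fitted object.
fit_and_transform <- function(train, test, config, seed) {
  if (config$transform == "minirocket") {
    fitted <- minirocket_fit(train, minirocket_config(
      num_features = max(84L, config$num_kernels), seed = seed))
    list(train = minirocket_features(train, fitted),
         test = minirocket_features(test, fitted), fitted = fitted)
  } else {
    bank <- sample_kernel_bank(config$num_kernels, n_samples(train),
                               n_regions(train), seed)
    list(train = rocket_transform(train, bank),
         test = rocket_transform(test, bank), fitted = bank)
  }
}

#' Run one train/test fingerprinting evaluation
#'
#' Fits the transform on the training trials only (MiniRocket bias fitting
#' never sees test data), trains the ridge classifier on the transformed
#' training features, and scores the test trials.
#'
#' @param train,test [fp_trialset()]s sharing region count and trial length.
#' @param config an [run_config()]; only `transform` and `num_kernels` are
#'   used here.
#' @param seed integer seed (expanded internally into transform and
#'   classifier streams).
#' @return an `fp_metrics` report on the test set.
#' @export
run_fingerprint <- function(train, test, config = run_config(), seed = 1) {
  stopifnot(inherits(train, "fp_trialset"), inherits(test, "fp_trialset"))
  if (n_regions(train) != n_regions(test) || n_samples(train) != n_samples(test)) {
    invalid_input("train and test trials must share region count and trial length.")
  }
  if (!any(test$labels %in% train$labels)) {
    invalid_input("train and test label sets do not overlap.")
  }
  feats <- fit_and_transform(train, test, config, derive_seed(seed, 1L))
  model <- fit_classifier(feats$train, train$labels, derive_seed(seed, 2L))
  pred <- predict(model, feats$test)
  metrics <- compute_metrics(test$labels, pred, model$class_list)
  attr(metrics, "alpha") <- model$alpha
  metrics
}

# Z-score, (optionally) half-split and segment every subject's recording of
# one session. Deterministic, so repeated designs (sweeps, cross-over
# repeats) can reuse the result through an environment cache.
segmented_session <- function(cohort, session, duration, half = NULL,
                              cache = NULL) {
  key <- paste(session, duration, half %||% "full", sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sets <- lapply(cohort$subjects, function(s) {
    rec <- cohort$recordings[[s]][[session]]
    if (is.null(rec)) invalid_input(sprintf("subject %s lacks session %s.", s, session))
    if (!is.null(half)) rec <- split_halves(rec)[[half]]
    segment(znormalize(rec), duration)
  })
  out <- bind_trialsets(sets)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# Assemble one session's balanced trial set: per subject z-score the
# continuous course, cut trials, then draw n_per_subject of them.
session_trialset <- function(cohort, session, duration, n_per_subject, seed,
                             half = NULL, subjects = cohort$subjects,
                             cache = NULL) {
  all_trials <- segmented_session(cohort, session, duration, half, cache)
  if (!identical(subjects, cohort$subjects)) {
    keep <- all_trials$labels %in% subjects
    all_trials <- fp_trialset(all_trials$trials[keep, , , drop = FALSE],
                              all_trials$labels[keep], all_trials$duration,
                              all_trials$sampling_rate)
  }
  sample_trials(all_trials, n_per_subject, seed)
}

#' Fingerprint one session pair of a cohort
#'
#' Draws a balanced trial set from each session (per-recording z-scoring,
#' segmentation, balanced sampling) and runs [run_fingerprint()]. When the
#' training and test sessions coincide, the continuous recording is split
#' into halves first: training trials come from the first half and test
#' trials from the second.
#'
#' @param cohort an [generate_cohort()] cohort (or any `fp_cohort`).
#' @param train_session,test_session session tags.
#' @param config an [run_config()].
#' @param seed integer seed for trial selection and kernel initialization.
#' @return an `fp_metrics` report.
#' @export
fingerprint_sessions <- function(cohort, train_session = "rs1", test_session = "rs2",
                                 config = run_config(), seed = 1,
                                 subjects = cohort$subjects, cache = NULL) {
  stopifnot(inherits(cohort, "fp_cohort"))
  same <- identical(train_session, test_session)
  train <- session_trialset(cohort, train_session, config$trial_duration,
                           config$n_trials, derive_seed(seed, 3L),
                           half = if (same) "first", subjects = subjects,
                           cache = cache)
  test <- session_trialset(cohort, test_session, config$trial_duration,
                           config$n_trials, derive_seed(seed, 4L),
                           half = if (same) "second", subjects = subjects,
                           cache = cache)
  run_fingerprint(train, test, config, seed)
}

#' Subject-level leave-one-out evaluation
#'
#' Each subject is excluded from both the training and the test set once;
#' the remaining cohort is evaluated train-session vs test-session, giving
#' one metrics report per left-out subject (over `n - 1` classes). The
#' summary is the mean and standard deviation of each metric across the
#' reports, measuring how stable identification is under cohort
#' composition.
#'
#' @param cohort an `fp_cohort` with at least 3 subjects.
#' @param config an [run_config()].
#' @param seed integer seed.
#' @param train_session,test_session session tags (default rs1 -> rs2).
#' @return an object of class `fp_loom` with elements `reports` (named list
#'   of `fp_metrics`) and `summary` (tibble of mean/sd per metric).
#' @export
loom_evaluate <- function(cohort, config = run_config(), seed = 1,
                          train_session = "rs1", test_session = "rs2") {
  stopifnot(inherits(cohort, "fp_cohort"))
  if (length(cohort$subjects) < 3L) {
    invalid_input("leave-one-out evaluation needs at least 3 subjects.")
  }
  cache <- new.env(parent = emptyenv())
  reports <- lapply(seq_along(cohort$subjects), function(i) {
    fingerprint_sessions(cohort, train_session, test_session, config,
                         derive_seed(seed, 6L, i),
                         subjects = setdiff(cohort$subjects, cohort$subjects[i]),
                         cache = cache)
  })
  names(reports) <- cohort$subjects
  per_run <- dplyr::bind_rows(lapply(reports, glance.fp_metrics), .id = "left_out")
  summary <- tidyr::pivot_longer(
    per_run, c("accuracy", "macro_precision", "macro_recall", "macro_f1"),
    names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value), sd = sd(.data$value),
                              .groups = "drop")
  structure(list(reports = reports, per_run = per_run, summary = summary,
                 seed = seed, config = config),
            class = "fp_loom")
}

#' @export
print.fp_loom <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("<fp_loom> %d left-out runs: accuracy %.4f +/- %.4f\n",
              length(x$reports), acc$mean, acc$sd))
  invisible(x)
}

#' Accuracy sweep over kernels, trials or duration
#'
#' Repeats the rs1 -> rs2 fingerprinting evaluation over a grid of one
#' parameter while the other two stay at their configured values, with
#' fresh trial selections and kernel seeds per repeat, and reports the
#' mean, minimum and maximum accuracy per grid value.
#'
#' @param cohort an `fp_cohort`.
#' @param axis `"num_kernels"`, `"num_trials"` or `"duration"`.
#' @param grid numeric vector of grid values.
#' @param config an [run_config()] providing the fixed settings.
#' @param n_repeats repeats per grid value.
#' @param seed integer seed.
#' @return an object of class `fp_sweep` with per-run accuracies (`runs`)
#'   and the per-value summary (`summary`).
#' @export
parameter_sweep <- function(cohort, axis = c("num_kernels", "num_trials", "duration"),
                            grid, config = run_config(), n_repeats = 10, seed = 1) {
  stopifnot(inherits(cohort, "fp_cohort"))
  axis <- match.arg(axis)
  if (length(grid) < 1L) invalid_input("`grid` must be non-empty.")
  cache <- new.env(parent = emptyenv())
  runs <- purrr::map_dfr(seq_along(grid), function(gi) {
    cfg <- config
    if (axis == "num_kernels") cfg$num_kernels <- as.integer(grid[gi])
    if (axis == "num_trials") cfg$n_trials <- as.integer(grid[gi])
    if (axis == "duration") cfg$trial_duration <- grid[gi]
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      m <- fingerprint_sessions(cohort, "rs1", "rs2", cfg,
                                derive_seed(seed, 7L, gi, r), cache = cache)
      tibble::tibble(value = grid[gi], repetition = r, accuracy = m$accuracy)
    })
  })
  summary <- dplyr::summarise(dplyr::group_by(runs, .data$value),
                              mean_accuracy = mean(.data$accuracy),
                              min_accuracy = min(.data$accuracy),
                              max_accuracy = max(.data$accuracy),
                              .groups = "drop")
  structure(list(axis = axis, runs = runs, summary = summary,
                 n_repeats = as.integer(n_repeats), config = config, seed = seed),
            class = "fp_sweep")
}

#' @export
print.fp_sweep <- function(x, ...) {
  cat(sprintf("<fp_sweep> axis %s, %d values x %d repeats\n",
              x$axis, nrow(x$summary), x$n_repeats))
  print(x$summary)
  invisible(x)
}

#' Cross-over experiment over rs1, rs2 and empty-room sessions
#'
#' Trains and tests the fingerprinting model for all 9 ordered combinations
#' of the three sessions. Off-diagonal cells draw training trials from one
#' session and test trials from another; diagonal cells split the
#' continuous recording into halves and sample training trials from the
#' first half and test trials from the second, so the sets never share
#' samples. Each cell is the mean accuracy over `n_repeats` runs with fresh
#' trial selections and kernel seeds. Comparing rest-vs-rest cells with
#' rest-vs-empty cells isolates how much day-specific background noise
#' contributes to identification.
#'
#' @param cohort an `fp_cohort` in which every subject has all 3 sessions.
#' @param config an [run_config()]; the reference design uses 10 trials per
#'   subject of 1.5 s.
#' @param n_repeats repeats per cell.
#' @param seed integer seed.
#' @return an object of class `fp_crossover` with per-run accuracies
#'   (`runs`), the mean-accuracy `matrix` (train session x test session)
#'   and a long-format `summary` tibble.
#' @export
crossover_experiment <- function(cohort, config = run_config(n_trials = 10),
                                 n_repeats = 10, seed = 1) {
  stopifnot(inherits(cohort, "fp_cohort"))
  sessions <- c("rs1", "rs2", "empty")
  for (s in cohort$subjects) {
    if (!all(sessions %in% names(cohort$recordings[[s]]))) {
      invalid_input(sprintf("subject %s is missing a session.", s))
    }
  }
  cells <- expand.grid(train_session = sessions, test_session = sessions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())
  runs <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      m <- fingerprint_sessions(cohort, cells$train_session[ci],
                                cells$test_session[ci], config,
                                derive_seed(seed, 8L, ci, r), cache = cache)
      tibble::tibble(train_session = cells$train_session[ci],
                     test_session = cells$test_session[ci],
                     repetition = r, accuracy = m$accuracy)
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(runs, .data$train_session, .data$test_session),
    mean_accuracy = mean(.data$accuracy), .groups = "drop")
  mat <- matrix(NA_real_, 3L, 3L, dimnames = list(train = sessions, test = sessions))
  for (i in seq_len(nrow(summary))) {
    mat[summary$train_session[i], summary$test_session[i]] <- summary$mean_accuracy[i]
  }
  structure(list(runs = runs, summary = summary, matrix = mat,
                 n_repeats = as.integer(n_repeats), config = config, seed = seed),
            class = "fp_crossover")
}

#' @export
print.fp_crossover <- function(x, ...) {
  cat(sprintf("<fp_crossover> mean accuracy over %d repeats:\n", x$n_repeats))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Chance level of balanced subject identification
#'
#' For `n_classes` equally represented subjects a uniform-random classifier
#' has expected accuracy `1 / n_classes` (about 0.81% for a 124-subject
#' cohort).
#'
#' @param n_classes number of classes.
#' @return the chance accuracy.
#' @export
chance_level <- function(n_classes) {
  assert_count(n_classes, "n_classes", min = 2L)
  1 / n_classes
}

#' Monte Carlo null accuracies of a uniform-random classifier
#'
#' Simulates a balanced test set (`n_per_class` trials for each of
#' `n_classes` subjects) and a classifier that guesses uniformly at random,
#' returning one accuracy per draw. Used to place empirical chance
#' intervals around [chance_level()].
#'
#' @param n_classes number of classes.
#' @param n_per_class test trials per class.
#' @param n_draws Monte Carlo draws.
#' @param seed integer seed.
#' @return numeric vector of `n_draws` accuracies.
#' @export
chance_null <- function(n_classes, n_per_class = 1, n_draws = 10000, seed = 1) {
  assert_count(n_classes, "n_classes", min = 2L)
  assert_count(n_per_class, "n_per_class")
  assert_count(n_draws, "n_draws")
  n <- n_classes * n_per_class
  y_true <- rep.int(seq_len(n_classes), n_per_class)
  with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      mean(sample.int(n_classes, n, replace = TRUE) == y_true)
    }, numeric(1))
  })
}
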