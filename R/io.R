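#' Load a run configuration from JSON or YAML
#'
#' Missing fields are filled with the reference defaults (3,500 kernels,
#' 15 trials, 1.5 s duration, 10 repeats); invalid fields are reported
#' together in one validation error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return an [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) invalid_input(sprintf("config file `%s` not found.", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  known <- c("transform", "num_kernels", "n_trials", "trial_duration",
             "n_repeats", "seed", "paths")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(c("invalid run configuration:",
            sprintf("unknown field `%s`", unknown)),
          class = "rocketfp_invalid_config")
  }
  defaults <- list(transform = "minirocket", num_kernels = 3500, n_trials = 15,
                   trial_duration = 1.5, n_repeats = 10, seed = 1, paths = NULL)
  args <- utils::modifyList(defaults, raw[lengths(raw) > 0])
  do.call(run_config, args)
}

#' Save a run configuration
#'
#' @param config an [run_config()].
#' @param path destination path; format chosen by extension as in
#'   [load_run_config()]. The round trip is lossless.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "fp_run_config"))
  x <- unclass(config)
  x$paths <- x$paths %||% NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Hash of a configuration for provenance stamps
#'
#' @param config any configuration object.
#' @return a short character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Write result tables and a JSON summary
#'
#' Writes a tidy tab-delimited table (one row per run/condition) and a JSON
#' summary next to it; both embed the seed and the configuration hash so
#' every artifact is traceable. Supported results: `fp_metrics`,
#' `fp_sweep`, `fp_crossover`, `fp_loom`.
#'
#' @param results a result object.
#' @param path base path without extension; `<path>.tsv` and `<path>.json`
#'   are written.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  seed <- results$seed %||% attr(results, "seed")
  cfg <- results$config
  # summary: mean/min/max rows for sweeps and cells, mean/sd for LOOM,
  # one-row macro summary for a single metrics report
  tbl <- switch(class(results)[1L],
                fp_loom = generics::glance(results),
                fp_metrics = generics::glance(results),
                generics::tidy(results))
  long <- switch(class(results)[1L],
                 fp_sweep = results$runs,
                 fp_crossover = results$runs,
                 fp_loom = results$per_run,
                 generics::tidy(results))
  tsv <- paste0(path, ".tsv")
  utils::write.table(long, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  summary <- list(result_class = class(results)[1L],
                  seed = seed,
                  config_hash = if (!is.null(cfg)) config_hash(cfg) else NULL,
                  config = if (!is.null(cfg)) unclass(cfg) else NULL,
                  summary = tbl)
  json <- paste0(path, ".json")
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(c(tsv, json))
}

# kernel bank / fitted transform serialization --------------------------------

#' Serialize a ROCKET kernel bank to JSON
#'
#' All sampled parameters (lengths, dilations, per-channel weights, biases,
#' padding flags, channel subsets) plus the generating seed are stored, so
#' a bank can be reloaded bit-identically for reproducibility.
#'
#' @param bank a [sample_kernel_bank()].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_kernel_bank <- function(bank, path) {
  stopifnot(inherits(bank, "rocket_bank"))
  x <- list(type = "rocket_bank", input_length = bank$input_length,
            n_channels = bank$n_channels, seed = bank$seed,
            kernels = lapply(bank$kernels, function(k) {
              list(length = k$length, dilation = k$dilation,
                   weights = apply(k$weights, 1L, identity, simplify = FALSE),
                   bias = k$bias, padding = k$padding, channels = k$channels)
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized ROCKET kernel bank
#'
#' @param path a path written by [write_kernel_bank()].
#' @return a `rocket_bank`.
#' @export
read_kernel_bank <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$type, "rocket_bank")) invalid_input("not a kernel bank file.")
  kernels <- lapply(x$kernels, function(k) {
    w <- do.call(rbind, lapply(k$weights, function(row) as.numeric(unlist(row))))
    list(length = as.integer(k$length), dilation = as.integer(k$dilation),
         weights = w, bias = as.numeric(k$bias),
         padding = as.logical(k$padding),
         channels = as.integer(unlist(k$channels)))
  })
  structure(list(kernels = kernels, input_length = as.integer(x$input_length),
                 n_channels = as.integer(x$n_channels), seed = as.integer(x$seed)),
            class = "rocket_bank")
}

#' Serialize a fitted MiniRocket transform to JSON
#'
#' Stores combos (pattern id, dilation, padding), channel subsets and the
#' per-feature bias table in the same JSON dialect as kernel banks.
#'
#' @param fitted a [minirocket_fit()].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_minirocket_fit <- function(fitted, path) {
  stopifnot(inherits(fitted, "minirocket_fit"))
  x <- list(type = "minirocket_fit", input_length = fitted$input_length,
            n_channels = fitted$n_channels, num_features = fitted$num_features,
            seed = fitted$seed,
            combos = fitted$combos,
            channel_sets = fitted$channel_sets,
            feature_table = fitted$feature_table)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a serialized MiniRocket transform
#'
#' @param path a path written by [write_minirocket_fit()].
#' @return a `minirocket_fit`.
#' @export
read_minirocket_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "minirocket_fit")) invalid_input("not a MiniRocket fit file.")
  combos <- as.data.frame(x$combos)
  ft <- as.data.frame(x$feature_table)
  structure(
    list(patterns = minirocket_patterns(), combos = combos,
         channel_sets = lapply(x$channel_sets, as.integer),
         feature_table = ft,
         input_length = as.integer(x$input_length),
         n_channels = as.integer(x$n_channels),
         num_features = as.integer(x$num_features), seed = as.integer(x$seed)),
    class = "minirocket_fit"
  )
}

# cohort container -------------------------------------------------------------

#' Write a cohort to a directory of delimited matrices
#'
#' One tab-delimited regions x samples matrix per subject-session plus a
#' JSON manifest recording the generator configuration, seed and layout.
#'
#' @param cohort an `fp_cohort`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    for (ses in names(cohort$recordings[[s]])) {
      rec <- cohort$recordings[[s]][[ses]]
      utils::write.table(rec$data, file.path(dir, sprintf("%s_%s.tsv", s, ses)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  cfg_out <- unclass(cohort$config)
  cfg_out$durations <- as.list(cfg_out$durations)
  manifest <- list(subjects = cohort$subjects,
                   sessions = names(cohort$recordings[[cohort$subjects[1L]]]),
                   sampling_rate = cohort$config$sampling_rate,
                   config = cfg_out,
                   config_hash = config_hash(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the per-subject TSV matrices and
#'   `manifest.json`.
#' @return an `fp_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfgl <- manifest$config[setdiff(names(manifest$config), "durations")]
  cfgl$duration_rs1 <- manifest$config$durations[["rs1"]]
  cfgl$duration_rs2 <- manifest$config$durations[["rs2"]]
  cfgl$duration_empty <- manifest$config$durations[["empty"]]
  cfg <- do.call(cohort_config, cfgl)
  recordings <- lapply(manifest$subjects, function(s) {
    out <- lapply(manifest$sessions, function(ses) {
      m <- as.matrix(utils::read.table(file.path(dir, sprintf("%s_%s.tsv", s, ses)),
                                       sep = "\t"))
      dimnames(m) <- NULL
      fp_recording(s, ses, m, manifest$sampling_rate)
    })
    names(out) <- manifest$sessions
    out
  })
  names(recordings) <- manifest$subjects
  structure(list(recordings = recordings, subjects = manifest$subjects,
                 config = cfg),
            class = "fp_cohort")
}
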