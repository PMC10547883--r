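#' Enumerate the fixed MiniRocket kernel patterns
#'
#' MiniRocket replaces ROCKET's random weights with a fixed set of length-9
#' kernels whose weights take only the two values -1 and 2, with exactly
#' three 2s per kernel (so every kernel sums to zero and is insensitive to
#' the input's mean level). All `choose(9, 3) = 84` such patterns are
#' enumerated in lexicographic order of the positions of the 2s.
#'
#' @return an 84 x 9 numeric matrix, one pattern per row.
#' @export
minirocket_patterns <- function() {
  pos <- utils::combn(9L, 3L)
  out <- matrix(-1, ncol(pos), 9L)
  for (i in seq_len(ncol(pos))) out[i, pos[, i]] <- 2
  out
}

#' MiniRocket configuration
#'
#' @param num_features total pooled-feature budget (the "number of kernels"
#'   axis of the method); must be at least the 84 base patterns.
#' @param max_dilations_per_kernel cap on dilations assigned to each
#'   pattern (the method fixes this at 32).
#' @param seed integer seed driving channel-subset draws and bias fitting.
#' @return a list of class `minirocket_config`.
#' @export
minirocket_config <- function(num_features = 3500, max_dilations_per_kernel = 32, seed = 1) {
  assert_count(num_features, "num_features")
  assert_count(max_dilations_per_kernel, "max_dilations_per_kernel")
  if (num_features < 84L) {
    invalid_input("`num_features` must be at least the 84 base patterns.")
  }
  if (max_dilations_per_kernel > 32L) {
    invalid_input("`max_dilations_per_kernel` must be <= 32.")
  }
  structure(list(num_features = as.integer(num_features),
                 max_dilations_per_kernel = as.integer(max_dilations_per_kernel),
                 seed = as.integer(seed)),
            class = "minirocket_config")
}

#' Fit the MiniRocket transform on training trials
#'
#' Assigns each of the 84 fixed patterns a set of dilations (at most 32,
#' geometrically spaced so the dilated receptive field of 9 taps fits the
#' trial length), distributes the feature budget as evenly as possible over
#' the (pattern, dilation) combinations, gives each combination a random
#' channel subset and a deterministic alternating padding flag, and fits
#' each feature's bias to a quantile of the combination's convolution
#' output on one uniformly drawn training trial. Quantile levels follow a
#' golden-ratio low-discrepancy sequence over (0, 1) so biases tile the
#' output distribution evenly. Feature slots alternate (in global feature
#' order) between the kernel and its sign-inverted twin, so half the budget
#' measures inverted-kernel prevalence; inverted-kernel biases are fitted
#' on the negated output. Biases are fitted on training
#' data only — test trials never influence the transform.
#'
#' @param training an [fp_trialset()] of training trials.
#' @param config a [minirocket_config()].
#' @return an object of class `minirocket_fit`.
#' @export
minirocket_fit <- function(training, config) {
  stopifnot(inherits(training, "fp_trialset"), inherits(config, "minirocket_config"))
  nt <- n_trials(training)
  if (nt < 1L) invalid_input("training set must contain at least one trial.")
  L <- n_samples(training)
  nch <- n_regions(training)
  if (L < 9L) invalid_input("trials must have >= 9 samples for the fixed 9-tap kernels.")

  patterns <- minirocket_patterns()
  n_pat <- nrow(patterns)

  # geometrically spaced dilations, receptive field 8*d must fit the trial
  d_max <- max(1L, (L - 1L) %/% 8L)
  n_dil_target <- min(config$max_dilations_per_kernel,
                      max(1L, config$num_features %/% n_pat))
  dilations <- unique(pmax(1L, as.integer(floor(
    2^seq(0, log2(d_max), length.out = n_dil_target)))))

  combos <- expand.grid(dilation = dilations, pattern_id = seq_len(n_pat),
                        KEEP.OUT.ATTRS = FALSE)[, c("pattern_id", "dilation")]
  n_combos <- nrow(combos)
  combos$padding <- (seq_len(n_combos) %% 2L) == 0L

  # spread the budget as evenly as possible over combos
  base <- config$num_features %/% n_combos
  rem <- config$num_features %% n_combos
  combos$n_features <- base + as.integer(seq_len(n_combos) <= rem)

  phi <- (sqrt(5) - 1) / 2
  cap <- min(9L, nch)

  fitted <- with_seed(config$seed, {
    channel_sets <- lapply(seq_len(n_combos), function(i) {
      s <- min(cap, max(1L, as.integer(floor(2^runif(1, 0, log2(cap + 1))))))
      sort(sample.int(nch, s))
    })
    feat <- vector("list", n_combos)
    f_global <- 0L
    for (i in seq_len(n_combos)) {
      k <- combos$n_features[i]
      if (k == 0L) { feat[[i]] <- NULL; next }
      w <- patterns[combos$pattern_id[i], ]
      slots <- seq_len(k)
      inverted <- ((f_global + slots) %% 2L) == 0L
      q <- ((f_global + slots) * phi) %% 1
      trial_idx <- sample.int(nt, k, replace = TRUE)
      bias <- numeric(k)
      for (j in slots) {
        cvec <- minirocket_conv(
          training$trials[trial_idx[j], , , drop = FALSE],
          w, combos$dilation[i], combos$padding[i], channel_sets[[i]])
        cvec <- as.numeric(cvec)
        bias[j] <- if (inverted[j]) {
          as.numeric(quantile(-cvec, q[j], names = FALSE))
        } else {
          as.numeric(quantile(cvec, q[j], names = FALSE))
        }
      }
      feat[[i]] <- data.frame(combo = i, slot = slots, inverted = inverted,
                              q = q, bias = bias, train_trial = trial_idx)
      f_global <- f_global + k
    }
    list(channel_sets = channel_sets, feature_table = do.call(rbind, feat))
  })
  ft <- fitted$feature_table
  ft$feature <- seq_len(nrow(ft))

  structure(
    list(patterns = patterns, combos = combos,
         channel_sets = fitted$channel_sets, feature_table = ft,
         input_length = L, n_channels = nch,
         num_features = config$num_features, seed = config$seed),
    class = "minirocket_fit"
  )
}

#' @export
print.minirocket_fit <- function(x, ...) {
  cat(sprintf(
    "<minirocket_fit> %d features over %d (pattern, dilation) combos; input %d channels x %d samples (seed %d)\n",
    nrow(x$feature_table), nrow(x$combos), x$n_channels, x$input_length, x$seed))
  invisible(x)
}

# One combo's convolution for all trials: the same 9-tap pattern applies to
# every channel in the subset, so channels are summed first and a single
# univariate dilated convolution follows (compiled, on the sample-major
# permutation of the array). Returns trials x n_out.
minirocket_conv <- function(trials_arr, w9, dilation, padding, channels) {
  span <- 8L * dilation
  pad <- if (padding) span %/% 2L else 0L
  if (dim(trials_arr)[3L] + 2L * pad - span < 1L) {
    invalid_input("trial too short for this dilation's receptive field.")
  }
  arr_t <- aperm(trials_arr, c(3L, 1L, 2L))
  t(mr_conv_cpp(arr_t, dim(arr_t), as.numeric(w9),
                as.integer(dilation), isTRUE(padding), as.integer(channels)))
}

#' Compute MiniRocket features for a trial set
#'
#' For each fitted (pattern, dilation, channel subset) combination one
#' convolution is computed per trial; every feature of that combination is
#' then a thresholded proportion of it. Regular slots emit
#' `ppv = mean(C > bias)`; inverted slots emit the proportion of values the
#' sign-inverted kernel would drive above its bias, obtained from the same
#' convolution as `mean(C < -bias)` — the "pnv = 1 - ppv" trick, which
#' avoids a second convolution pass and agrees with the explicit inverted
#' convolution exactly whenever no output value ties the bias.
#'
#' @param trials an [fp_trialset()] matching the fitted input shape.
#' @param fitted a [minirocket_fit()].
#' @return a numeric feature matrix (trials x features), all values in
#'   `[0, 1]`, with a `transform_tag` attribute of `"minirocket"`.
#' @export
minirocket_features <- function(trials, fitted) {
  stopifnot(inherits(trials, "fp_trialset"), inherits(fitted, "minirocket_fit"))
  if (n_samples(trials) != fitted$input_length || n_regions(trials) != fitted$n_channels) {
    invalid_input(sprintf(
      "trial shape (%d x %d) does not match fitted transform (%d x %d).",
      n_regions(trials), n_samples(trials), fitted$n_channels, fitted$input_length))
  }
  nt <- n_trials(trials)
  ft <- fitted$feature_table
  out <- matrix(0, nt, nrow(ft))
  arr_t <- aperm(trials$trials, c(3L, 1L, 2L)) # sample-major for the C kernel
  dims <- dim(arr_t)
  for (i in unique(ft$combo)) {
    rows <- which(ft$combo == i)
    w <- fitted$patterns[fitted$combos$pattern_id[i], ]
    out[, ft$feature[rows]] <- mr_features_cpp(
      arr_t, dims, as.numeric(w), fitted$combos$dilation[i],
      isTRUE(fitted$combos$padding[i]),
      as.integer(fitted$channel_sets[[i]]),
      ft$bias[rows], ft$inverted[rows])
  }
  colnames(out) <- sprintf("f%04d", seq_len(nrow(ft)))
  attr(out, "transform_tag") <- "minirocket"
  out
}
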