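#' Sample a bank of random convolutional kernels
#'
#' Draws `num_kernels` random kernels following the ROCKET sampling rules:
#' length uniform over \{7, 9, 11\}; per-channel weights standard normal then
#' mean-centred within each channel; bias uniform on `[-1, 1]`; dilation
#' `d = floor(2^x)` with `x ~ U(0, A)` and `A = log2((l_input - 1)/(l_k - 1))`,
#' so that the dilated receptive field `(l_k - 1) d` always fits inside the
#' input; padding a fair coin flip. For multivariate inputs each kernel also
#' carries a random channel subset (its "sixth parameter"): the subset size
#' is `floor(2^u)` with `u ~ U(0, log2(n_channels + 1))`, favouring small
#' subsets while allowing large ones, and that many distinct channels are
#' drawn uniformly.
#'
#' @param num_kernels number of kernels to sample.
#' @param input_length trial length in samples the bank will be applied to
#'   (must be >= 12 so the smallest kernel admits a dilation).
#' @param n_channels number of input channels (regions).
#' @param seed integer seed; the bank is fully reproducible from it.
#' @return an object of class `rocket_bank`: a list of kernels plus
#'   `input_length`, `n_channels` and `seed`.
#' @export
sample_kernel_bank <- function(num_kernels, input_length, n_channels, seed) {
  assert_count(num_kernels, "num_kernels")
  assert_count(n_channels, "n_channels")
  assert_count(input_length, "input_length", min = 2L)
  if (input_length < 12L) {
    invalid_input("`input_length` must be >= 12 so the smallest kernel admits a dilation.")
  }
  kernels <- with_seed(seed, {
    lapply(seq_len(num_kernels), function(i) {
      l_k <- sample(c(7L, 9L, 11L), 1L)
      A <- log2((input_length - 1) / (l_k - 1))
      d <- max(1L, as.integer(floor(2^runif(1, 0, A))))
      n_sel <- min(n_channels,
                   max(1L, as.integer(floor(2^runif(1, 0, log2(n_channels + 1))))))
      channels <- sort(sample.int(n_channels, n_sel))
      w <- matrix(rnorm(n_sel * l_k), nrow = n_sel)
      w <- w - rowMeans(w)
      list(length = l_k, dilation = d, weights = w,
           bias = runif(1, -1, 1), padding = runif(1) < 0.5,
           channels = channels)
    })
  })
  structure(
    list(kernels = kernels, input_length = as.integer(input_length),
         n_channels = as.integer(n_channels), seed = as.integer(seed)),
    class = "rocket_bank"
  )
}

#' @export
print.rocket_bank <- function(x, ...) {
  cat(sprintf("<rocket_bank> %d kernels for %d-channel inputs of %d samples (seed %d)\n",
              length(x$kernels), x$n_channels, x$input_length, x$seed))
  invisible(x)
}

#' Dilated sliding dot product of one kernel with one trial
#'
#' Computes `C_t = sum_c sum_j X[c, t + j d] w[c, j] + b` over the kernel's
#' channel subset, with the single bias added once per output sample. With
#' padding, `(l_k - 1) d / 2` zeros are implicitly prepended and appended per
#' channel so that the output has the same length as the input; without
#' padding the output has `n - (l_k - 1) d` samples.
#'
#' @param trial numeric matrix, channels x samples.
#' @param kernel one kernel from a [sample_kernel_bank()].
#' @return numeric vector of convolution values.
#' @export
rocket_convolve <- function(trial, kernel) {
  stopifnot(is.matrix(trial))
  l_k <- kernel$length
  d <- kernel$dilation
  span <- (l_k - 1L) * d
  if (max(kernel$channels) > nrow(trial)) {
    invalid_input("kernel channel subset exceeds trial channel count.")
  }
  x <- trial[kernel$channels, , drop = FALSE]
  if (kernel$padding) {
    pad <- matrix(0, nrow(x), span %/% 2L)
    x <- cbind(pad, x, pad)
  }
  n_out <- ncol(x) - span
  if (n_out < 1L) invalid_input("trial too short for this kernel's receptive field.")
  out <- rep(kernel$bias, n_out)
  for (ci in seq_along(kernel$channels)) {
    for (j in 0:(l_k - 1L)) {
      out <- out + x[ci, (1L + j * d):(n_out + j * d)] * kernel$weights[ci, j + 1L]
    }
  }
  out
}

#' Global max pooling of a convolution output
#'
#' @param output numeric vector of convolution values.
#' @return the maximum value.
#' @export
global_max <- function(output) {
  if (length(output) < 1L) invalid_input("empty convolution output.")
  max(output)
}

#' Proportion of positive values (ppv) pooling
#'
#' The fraction of convolution output samples that are strictly positive;
#' zeros do not count as positive.
#'
#' @param output numeric vector of convolution values.
#' @return a proportion in `[0, 1]`.
#' @export
ppv <- function(output) {
  if (length(output) < 1L) invalid_input("empty convolution output.")
  mean(output > 0)
}

#' Transform trials into pooled random-kernel features
#'
#' Applies every kernel of the bank to every trial and pools each
#' convolution output into two features, `ppv` then `max`, in bank order —
#' exactly `2 * num_kernels` columns. Column `k<i>_ppv` / `k<i>_max` comes
#' from kernel `i`.
#'
#' @param trials an [fp_trialset()] whose shape matches the bank.
#' @param bank a [sample_kernel_bank()].
#' @return a numeric feature matrix (trials x features) with a
#'   `transform_tag` attribute of `"rocket"`.
#' @export
rocket_transform <- function(trials, bank) {
  stopifnot(inherits(trials, "fp_trialset"), inherits(bank, "rocket_bank"))
  if (n_samples(trials) != bank$input_length || n_regions(trials) != bank$n_channels) {
    invalid_input(sprintf(
      "trial shape (%d x %d) does not match bank (%d x %d).",
      n_regions(trials), n_samples(trials), bank$n_channels, bank$input_length))
  }
  nt <- n_trials(trials)
  nk <- length(bank$kernels)
  out <- matrix(0, nt, 2L * nk)
  arr_t <- aperm(trials$trials, c(3L, 1L, 2L)) # sample-major for the C kernel
  dims <- dim(arr_t)
  for (k in seq_len(nk)) {
    ker <- bank$kernels[[k]]
    cmat <- rocket_conv_cpp(arr_t, dims, ker$weights, ker$length,
                            ker$dilation, ker$bias, isTRUE(ker$padding),
                            as.integer(ker$channels)) # n_out x trials
    out[, 2L * k - 1L] <- colMeans(cmat > 0)
    out[, 2L * k] <- apply(cmat, 2L, max)
  }
  colnames(out) <- as.vector(rbind(paste0("k", seq_len(nk), "_ppv"),
                                   paste0("k", seq_len(nk), "_max")))
  attr(out, "transform_tag") <- "rocket"
  out
}

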