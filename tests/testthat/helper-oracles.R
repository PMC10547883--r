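# Independent reference implementations used as oracles. These follow the
# defining formulas literally (explicit loops over placements, channels and
# taps) and deliberately share no code with the package's vectorized paths.

# dilated sliding dot product, one kernel x one trial, by direct enumeration
naive_convolve <- function(trial, kernel) {
  l_k <- kernel$length
  d <- kernel$dilation
  x <- trial[kernel$channels, , drop = FALSE]
  if (kernel$padding) {
    p <- (l_k - 1L) * d / 2L
    x <- cbind(matrix(0, nrow(x), p), x, matrix(0, nrow(x), p))
  }
  n_out <- ncol(x) - (l_k - 1L) * d
  out <- numeric(n_out)
  for (t in seq_len(n_out)) {
    acc <- 0
    for (ci in seq_len(nrow(x))) {
      for (j in 0:(l_k - 1L)) {
        acc <- acc + x[ci, t + j * d] * kernel$weights[ci, j + 1L]
      }
    }
    out[t] <- acc + kernel$bias
  }
  out
}

naive_rocket_transform <- function(trials, bank) {
  nt <- dim(trials$trials)[1L]
  nk <- length(bank$kernels)
  out <- matrix(0, nt, 2L * nk)
  for (i in seq_len(nt)) {
    trial <- trials$trials[i, , , drop = FALSE]
    dim(trial) <- dim(trials$trials)[2:3]
    for (k in seq_len(nk)) {
      cvec <- naive_convolve(trial, bank$kernels[[k]])
      out[i, 2L * k - 1L] <- sum(cvec > 0) / length(cvec)
      out[i, 2L * k] <- max(cvec)
    }
  }
  out
}

# explicit two-pass MiniRocket oracle: inverted-kernel features convolve -w
# for real instead of reusing the regular convolution output
naive_minirocket_features <- function(trials, fitted) {
  nt <- dim(trials$trials)[1L]
  ft <- fitted$feature_table
  out <- matrix(0, nt, nrow(ft))
  for (i in seq_len(nt)) {
    trial <- trials$trials[i, , , drop = FALSE]
    dim(trial) <- dim(trials$trials)[2:3]
    for (r in seq_len(nrow(ft))) {
      ci <- ft$combo[r]
      w <- fitted$patterns[fitted$combos$pattern_id[ci], ]
      if (ft$inverted[r]) w <- -w
      channels <- fitted$channel_sets[[ci]]
      kernel <- list(length = 9L, dilation = fitted$combos$dilation[ci],
                     weights = matrix(rep(w, each = length(channels)),
                                      nrow = length(channels)),
                     bias = 0, padding = fitted$combos$padding[ci],
                     channels = channels)
      cvec <- naive_convolve(trial, kernel)
      out[i, ft$feature[r]] <- mean(cvec > ft$bias[r])
    }
  }
  out
}

# confusion-matrix metrics by direct counting
brute_metrics <- function(y_true, y_pred, class_list) {
  prec <- rec <- f1 <- numeric(length(class_list))
  for (i in seq_along(class_list)) {
    cl <- class_list[i]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(accuracy = mean(y_true == y_pred), macro_precision = mean(prec),
       macro_recall = mean(rec), macro_f1 = mean(f1))
}
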