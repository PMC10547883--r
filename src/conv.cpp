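#include <Rcpp.h>
using namespace Rcpp;

// Dilated 9-tap convolution of the channel-summed signal, all trials at
// once. trials is a sample-major [n_samples x n_trials x n_regions] array
// (aperm of the trial-set array), so each trial-channel time course is
// contiguous; channels are 1-based. Padding prepends/appends span/2
// implicit zeros (span = 8*d) so the output length equals the input
// length. Returns n_out x n_trials (one contiguous column per trial).
// [[Rcpp::export]]
NumericMatrix mr_conv_cpp(NumericVector trials, IntegerVector dims,
                          NumericVector w9, int dilation, bool padding,
                          IntegerVector channels) {
  const int ns = dims[0], nt = dims[1];
  const int span = 8 * dilation;
  const int pad = padding ? span / 2 : 0;
  const int n_out = ns + 2 * pad - span;
  if (n_out < 1) stop("trial too short for this dilation's receptive field");
  NumericMatrix out(n_out, nt);
  std::vector<double> y(ns);
  const double *a = trials.begin();
  const int d = dilation;
  // interior rows: all 9 taps fall inside the unpadded signal, i.e.
  // t0 = t - pad in [0, ns - 1 - 8d]
  const int mid_lo = std::min(pad, n_out);
  const int mid_hi = std::max(mid_lo, std::min(n_out, ns - 8 * d + pad));
  const int n_s = std::max(0, ns - 8 * d); // valid t0 count

  // two-valued {-1, 2} patterns admit C = 3 * (sum of the three "2" taps)
  // - (sum of all 9 taps); the all-tap sum slides with step d
  int pos2[3], n2 = 0;
  bool two_valued = true;
  for (int j = 0; j < 9; ++j) {
    if (w9[j] == 2.0) { if (n2 < 3) pos2[n2] = j; ++n2; }
    else if (w9[j] != -1.0) two_valued = false;
  }
  two_valued = two_valued && n2 == 3;
  std::vector<double> S(two_valued ? n_s : 0);

  for (int i = 0; i < nt; ++i) {
    std::fill(y.begin(), y.end(), 0.0);
    for (int ci = 0; ci < channels.size(); ++ci) {
      const int c = channels[ci] - 1;
      const double *base = a + (R_xlen_t)ns * (i + (R_xlen_t)nt * c);
      for (int t = 0; t < ns; ++t) y[t] += base[t];
    }
    double *col = &out(0, i);
    // edge rows: only the taps inside the signal contribute
    auto edge = [&](int t) {
      const int t0 = t - pad;
      const int jlo = t0 < 0 ? (-t0 + d - 1) / d : 0;
      const int jhi = std::min(8, (ns - 1 - t0) / d);
      double acc = 0.0;
      const double *p = y.data() + t0;
      for (int j = jlo; j <= jhi; ++j) acc += p[j * d] * w9[j];
      col[t] = acc;
    };
    for (int t = 0; t < mid_lo; ++t) edge(t);
    if (two_valued && mid_hi > mid_lo) {
      // sliding 9-tap sums per residue class mod d
      for (int r = 0; r < d && r < n_s; ++r) {
        double acc = 0.0;
        for (int j = 0; j < 9; ++j) acc += y[r + j * d];
        S[r] = acc;
        for (int t0 = r + d; t0 < n_s; t0 += d) {
          acc += y[t0 + 8 * d] - y[t0 - d];
          S[t0] = acc;
        }
      }
      const int o0 = pos2[0] * d, o1 = pos2[1] * d, o2 = pos2[2] * d;
      const double *p = y.data() + (mid_lo - pad);
      const double *s = S.data() + (mid_lo - pad);
      double *c0 = col + mid_lo;
      const int m = mid_hi - mid_lo;
      for (int t = 0; t < m; ++t) { // unit-stride, auto-vectorizable
        c0[t] = 3.0 * (p[t + o0] + p[t + o1] + p[t + o2]) - s[t];
      }
    } else {
      const double w0 = w9[0], w1 = w9[1], w2 = w9[2], w3 = w9[3],
                   w4 = w9[4], w5 = w9[5], w6 = w9[6], w7 = w9[7],
                   w8 = w9[8];
      const double *p = y.data() + (mid_lo - pad);
      for (int t = mid_lo; t < mid_hi; ++t, ++p) {
        const double acc1 = p[0] * w0 + p[2 * d] * w2 + p[4 * d] * w4 +
                            p[6 * d] * w6 + p[8 * d] * w8;
        const double acc2 = p[d] * w1 + p[3 * d] * w3 + p[5 * d] * w5 +
                            p[7 * d] * w7;
        col[t] = acc1 + acc2;
      }
    }
    for (int t = mid_hi; t < n_out; ++t) edge(t);
  }
  return out;
}

// Per-feature ppv pooling against biases: regular slots count C > bias,
// inverted slots count C < -bias (the single-convolution pnv trick).
// conv is n_out x n_trials; returns n_trials x n_features.
// [[Rcpp::export]]
NumericMatrix ppv_pool_cpp(NumericMatrix conv, NumericVector biases,
                           LogicalVector inverted) {
  const int n_out = conv.nrow(), nt = conv.ncol(), nf = biases.size();
  NumericMatrix out(nt, nf);
  for (int f = 0; f < nf; ++f) {
    const double b = biases[f];
    const bool inv = inverted[f];
    for (int i = 0; i < nt; ++i) {
      const double *col = &conv(0, i);
      int cnt = 0;
      for (int t = 0; t < n_out; ++t) {
        const double v = col[t];
        if (inv ? (v < -b) : (v > b)) ++cnt;
      }
      out(i, f) = (double)cnt / n_out;
    }
  }
  return out;
}

// Multivariate dilated convolution with per-channel weights (random-kernel
// transform): C_t = sum_c sum_j X[c, t + j*d] w[c, j] + bias. trials is
// the sample-major [n_samples x n_trials x n_regions] permutation; returns
// n_out x n_trials.
// [[Rcpp::export]]
NumericMatrix rocket_conv_cpp(NumericVector trials, IntegerVector dims,
                              NumericMatrix weights, int l_k, int dilation,
                              double bias, bool padding,
                              IntegerVector channels) {
  const int ns = dims[0], nt = dims[1];
  const int span = (l_k - 1) * dilation;
  const int pad = padding ? span / 2 : 0;
  const int n_out = ns + 2 * pad - span;
  if (n_out < 1) stop("trial too short for this kernel's receptive field");
  NumericMatrix out(n_out, nt);
  const double *a = trials.begin();
  for (int i = 0; i < nt; ++i) {
    double *col = &out(0, i);
    for (int t = 0; t < n_out; ++t) col[t] = bias;
    for (int ci = 0; ci < channels.size(); ++ci) {
      const int c = channels[ci] - 1;
      const double *base = a + (R_xlen_t)ns * (i + (R_xlen_t)nt * c);
      for (int t = 0; t < n_out; ++t) {
        double acc = 0.0;
        const int t0 = t - pad;
        for (int j = 0; j < l_k; ++j) {
          const int idx = t0 + j * dilation;
          if (idx >= 0 && idx < ns) acc += base[idx] * weights(ci, j);
        }
        col[t] += acc;
      }
    }
  }
  return out;
}

// Fused transform for one fitted combo: convolve (two-valued fast path as
// in mr_conv_cpp) and pool every feature of the combo in a single pass,
// without materializing the convolution matrix. biases/inverted give the
// combo's feature slots; returns n_trials x n_features of proportions.
// [[Rcpp::export]]
NumericMatrix mr_features_cpp(NumericVector trials, IntegerVector dims,
                              NumericVector w9, int dilation, bool padding,
                              IntegerVector channels, NumericVector biases,
                              LogicalVector inverted) {
  const int ns = dims[0], nt = dims[1];
  const int span = 8 * dilation;
  const int pad = padding ? span / 2 : 0;
  const int n_out = ns + 2 * pad - span;
  if (n_out < 1) stop("trial too short for this dilation's receptive field");
  const int nf = biases.size();
  NumericMatrix out(nt, nf);
  const int d = dilation;
  const int mid_lo = std::min(pad, n_out);
  const int mid_hi = std::max(mid_lo, std::min(n_out, ns - 8 * d + pad));
  const int n_s = std::max(0, ns - 8 * d);

  int pos2[3], n2 = 0;
  bool two_valued = true;
  for (int j = 0; j < 9; ++j) {
    if (w9[j] == 2.0) { if (n2 < 3) pos2[n2] = j; ++n2; }
    else if (w9[j] != -1.0) two_valued = false;
  }
  two_valued = two_valued && n2 == 3;

  // per-slot threshold in "c" units: regular counts c > b, inverted c < -b
  std::vector<double> thr(nf);
  for (int f = 0; f < nf; ++f) thr[f] = inverted[f] ? -biases[f] : biases[f];

  std::vector<double> y(ns), S(two_valued ? n_s : 0), cbuf(n_out);
  const double *a = trials.begin();
  for (int i = 0; i < nt; ++i) {
    std::fill(y.begin(), y.end(), 0.0);
    for (int ci = 0; ci < channels.size(); ++ci) {
      const int c = channels[ci] - 1;
      const double *__restrict__ base =
          a + (R_xlen_t)ns * (i + (R_xlen_t)nt * c);
      double *__restrict__ yp = y.data();
      for (int t = 0; t < ns; ++t) yp[t] += base[t];
    }
    double *__restrict__ cb = cbuf.data();
    auto edge = [&](int t) {
      const int t0 = t - pad;
      const int jlo = t0 < 0 ? (-t0 + d - 1) / d : 0;
      const int jhi = std::min(8, (ns - 1 - t0) / d);
      double acc = 0.0;
      const double *p = y.data() + t0;
      for (int j = jlo; j <= jhi; ++j) acc += p[j * d] * w9[j];
      cb[t] = acc;
    };
    for (int t = 0; t < mid_lo; ++t) edge(t);
    if (two_valued && mid_hi > mid_lo) {
      for (int r = 0; r < d && r < n_s; ++r) {
        double acc = 0.0;
        for (int j = 0; j < 9; ++j) acc += y[r + j * d];
        S[r] = acc;
        for (int t0 = r + d; t0 < n_s; t0 += d) {
          acc += y[t0 + 8 * d] - y[t0 - d];
          S[t0] = acc;
        }
      }
      const int o0 = pos2[0] * d, o1 = pos2[1] * d, o2 = pos2[2] * d;
      const double *__restrict__ p = y.data() + (mid_lo - pad);
      const double *__restrict__ s = S.data() + (mid_lo - pad);
      double *__restrict__ c0 = cb + mid_lo;
      const int m = mid_hi - mid_lo;
      for (int t = 0; t < m; ++t)
        c0[t] = 3.0 * (p[t + o0] + p[t + o1] + p[t + o2]) - s[t];
    } else if (mid_hi > mid_lo) {
      const double w0 = w9[0], w1 = w9[1], w2 = w9[2], w3 = w9[3],
                   w4 = w9[4], w5 = w9[5], w6 = w9[6], w7 = w9[7],
                   w8 = w9[8];
      const double *p = y.data() + (mid_lo - pad);
      for (int t = mid_lo; t < mid_hi; ++t, ++p) {
        const double acc1 = p[0] * w0 + p[2 * d] * w2 + p[4 * d] * w4 +
                            p[6 * d] * w6 + p[8 * d] * w8;
        const double acc2 = p[d] * w1 + p[3 * d] * w3 + p[5 * d] * w5 +
                            p[7 * d] * w7;
        cb[t] = acc1 + acc2;
      }
    }
    for (int t = mid_hi; t < n_out; ++t) edge(t);
    for (int f = 0; f < nf; ++f) { // pool each slot over the buffered row
      const double b = thr[f];
      int cnt = 0;
      if (inverted[f]) {
        for (int t = 0; t < n_out; ++t) cnt += cb[t] < b;
      } else {
        for (int t = 0; t < n_out; ++t) cnt += cb[t] > b;
      }
      out(i, f) = (double)cnt / n_out;
    }
  }
  return out;
}
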