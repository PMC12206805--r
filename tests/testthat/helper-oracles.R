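# Independent brute-force oracles shared across test files.

# Brute-force Otsu oracle: for every possible histogram cut, compute the
# between-class variance directly from the bin-quantised pixel values and
# keep the lowest maximising cut.
otsu_oracle <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
  vq <- centers[idx]  # values as the histogram sees them
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(nbins - 1L)) {
    lower <- idx <= k
    if (!any(lower) || all(lower)) next
    w0 <- mean(lower); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(vq[lower]) - mean(vq[!lower]))^2
    if (sb > best + 1e-15) { best <- sb; best_k <- k }
  }
  lo + best_k * (hi - lo) / nbins
}

# Independent scalar recomputation of the one-vs-rest metrics for class k.
metrics_oracle <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / sum(cm),
       precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Enumeration oracle for the convolution output length: count the valid
# kernel placements on an explicitly padded axis.
conv_len_oracle <- function(L, k, s, p) {
  padded <- L + 2 * p
  starts <- seq(1, padded - k + 1, by = s)
  length(starts)
}
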