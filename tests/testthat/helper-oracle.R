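# Brute-force oracle: exact Bayes updates of a binned posterior over the
# unit interval, written independently of the piecewise-CDF decoder. The
# bin straddling the split point receives a mass-weighted likelihood.
grid_bayes <- function(bits, f0, f1, n_bins = 4096) {
  p <- rep(1 / n_bins, n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1)
  for (b in bits) {
    cum <- cumsum(p)
    j <- which(cum >= 0.5)[1]
    prev <- if (j > 1) cum[j - 1] else 0
    m <- edges[j] + (0.5 - prev) / p[j] * (edges[j + 1] - edges[j])
    frac_left <- pmin(pmax((m - edges[-(n_bins + 1)]) * n_bins, 0), 1)
    like <- if (b == 0) {
      frac_left * (1 - f0) + (1 - frac_left) * f1
    } else {
      frac_left * f0 + (1 - frac_left) * (1 - f1)
    }
    p <- p * like
    p <- p / sum(p)
  }
  p
}

# bin masses of a decoder's posterior on the same grid
decoder_bin_masses <- function(dec, n_bins = 4096) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  diff(horstein:::pw_eval(dec$cdf, edges))
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
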