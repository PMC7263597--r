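# Internal piecewise-linear CDF primitives.
#
# A posterior over the unit interval is held as ordered breakpoints `x`
# (x[1] = 0, x[n] = 1) and cumulative values `Fx` (Fx[1] = 0, Fx[n] = 1).
# The density is constant on each segment (a mixture of uniforms). These
# functions are the hot path of the decoder and operate on plain lists.

MERGE_EPS <- 1e-12

pw_uniform <- function() {
  list(x = c(0, 1), Fx = c(0, 1))
}

# masses over equal-width consecutive intervals
pw_from_masses <- function(masses) {
  if (any(masses <= 0)) stop("prior masses must be positive")
  masses <- masses / sum(masses)
  n <- length(masses)
  list(x = seq(0, 1, length.out = n + 1), Fx = c(0, cumsum(masses)))
}

pw_eval <- function(cdf, x) {
  stats::approx(cdf$x, cdf$Fx, xout = x, method = "linear",
                ties = "ordered", rule = 2)$y
}

# Quantile with the plateau-midpoint rule: a zero-density segment containing
# the quantile (possible only with a configured flip probability of exactly 0)
# maps to the plateau midpoint. q = 0 and q = 1 return the endpoints.
pw_quantile <- function(cdf, q) {
  stopifnot(q >= 0, q <= 1)
  if (q <= 0) return(0)
  if (q >= 1) return(1)
  Fx <- cdf$Fx
  x <- cdf$x
  hi <- which(Fx >= q)[1]
  if (Fx[hi] > q) {
    # strictly inside segment hi-1
    j <- hi - 1
    x[j] + (q - Fx[j]) * (x[j + 1] - x[j]) / (Fx[j + 1] - Fx[j])
  } else {
    # q hits a breakpoint value; detect a plateau of equal cumulative values
    lo <- hi
    while (lo > 1 && Fx[lo - 1] == q) lo <- lo - 1
    last <- hi
    while (last < length(Fx) && Fx[last + 1] == q) last <- last + 1
    if (last > lo || lo < hi) (x[lo] + x[last]) / 2 else x[hi]
  }
}

pw_median <- function(cdf) pw_quantile(cdf, 0.5)

# differential entropy in bits of the mixture-of-uniforms density
pw_entropy <- function(cdf) {
  m <- diff(cdf$Fx)
  w <- diff(cdf$x)
  pos <- m > 0
  -sum(m[pos] * log2(m[pos] / w[pos]))
}

# insert a breakpoint, merging with an existing one closer than MERGE_EPS
pw_insert <- function(cdf, pt) {
  x <- cdf$x
  j <- findInterval(pt, x)
  if (j >= 1 && pt - x[j] < MERGE_EPS) return(cdf)
  if (j < length(x) && x[j + 1] - pt < MERGE_EPS) return(cdf)
  Fpt <- x[j] + 0 # placeholder to keep numeric type
  Fpt <- cdf$Fx[j] + (pt - x[j]) * (cdf$Fx[j + 1] - cdf$Fx[j]) / (x[j + 1] - x[j])
  list(
    x = c(x[seq_len(j)], pt, x[seq(j + 1, length(x))]),
    Fx = c(cdf$Fx[seq_len(j)], Fpt, cdf$Fx[seq(j + 1, length(x))])
  )
}

# Scale the posterior mass of the regions delimited by `cuts` by `factors`
# (length(cuts) + 1 values), then renormalise to total mass 1. This is the
# single Bayes-update primitive: binary, trisection and q-ary updates are all
# region scalings with likelihood factors.
pw_scale_regions <- function(cdf, cuts, factors) {
  for (ct in cuts) cdf <- pw_insert(cdf, ct)
  x <- cdf$x
  m <- diff(cdf$Fx)
  # region index of each segment by its midpoint
  mid <- (x[-1] + x[-length(x)]) / 2
  reg <- findInterval(mid, cuts) + 1L
  m <- m * factors[reg]
  tot <- sum(m)
  if (tot <= 0) stop("update annihilated all posterior mass")
  Fx <- c(0, cumsum(m) / tot)
  Fx[length(Fx)] <- 1
  list(x = x, Fx = Fx)
}
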