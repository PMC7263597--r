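#' Decoder configuration
#'
#' Parameters of a posterior-matching (Horstein) block decoder. The decoder
#' selects one of `2^k` symbols laid out on the unit interval, consuming noisy
#' binary inputs until the posterior entropy has dropped by `k + beta` bits.
#'
#' `f0` and `f1` are the flip probabilities the decoder is *configured* for
#' (written f0', f1' in the channel-coding literature); `headroom` is added on
#' top, so passing calibration estimates plus a positive headroom yields a
#' deliberately pessimistic decoder. Configured probabilities are capped just
#' below 0.5, since a configured rate of 0.5 or more makes an input
#' uninformative or inverted.
#'
#' @param k symbol length in bits (positive integer).
#' @param beta confirmation overhead in bits; non-negative, may be fractional.
#' @param f0 configured probability that an intended 0 is received as 1.
#' @param f1 configured probability that an intended 1 is received as 0;
#'   defaults to `f0`.
#' @param headroom extra pessimism added to both configured probabilities.
#' @param prior optional non-uniform prior over targets: positive masses
#'   (normalised to sum to 1) over consecutive equal-width intervals. `NULL`
#'   means a uniform prior over `2^k` targets.
#' @return An object of class `decoder_config`.
#' @examples
#' decoder_config(k = 6, beta = 0, f0 = 0.17)
#' decoder_config(k = 2, beta = 2.3, f0 = 0.06, f1 = 0.35)
#' @export
decoder_config <- function(k, beta = 0, f0 = 0, f1 = f0, headroom = 0,
                           prior = NULL) {
  stopifnot(length(k) == 1, k >= 1, k == floor(k))
  stopifnot(length(beta) == 1, beta >= 0)
  f0p <- f0 + headroom
  f1p <- f1 + headroom
  if (f0p < 0 || f1p < 0) stop("configured flip probabilities must be >= 0")
  cap <- 0.5 - 1e-6
  f0p <- min(f0p, cap)
  f1p <- min(f1p, cap)
  if (!is.null(prior)) {
    if (any(prior <= 0)) stop("prior widths must be positive")
    if (abs(sum(prior) - 1) > 1e-9) stop("prior masses must sum to 1")
  }
  structure(
    list(k = as.integer(k), beta = beta, f0 = f0p, f1 = f1p,
         headroom = headroom, prior = prior,
         n_targets = if (is.null(prior)) as.integer(2^k) else length(prior)),
    class = "decoder_config"
  )
}

#' @export
print.decoder_config <- function(x, ...) {
  cat(sprintf("<decoder_config> k = %d, beta = %g, f0' = %g, f1' = %g%s\n",
              x$k, x$beta, x$f0, x$f1,
              if (is.null(x$prior)) "" else
                sprintf(", prior over %d targets", x$n_targets)))
  invisible(x)
}

# posterior left-of-median mass after observing bit 0 / bit 1
bayes_p <- function(f0, f1) (1 - f0) / ((1 - f0) + f1)
bayes_q <- function(f0, f1) (1 - f1) / ((1 - f1) + f0)

#' Initialise a posterior-matching decoder
#'
#' Starts from a uniform prior (a single unit-density segment, differential
#' entropy 0 bits) or, with a non-uniform prior, from a piecewise CDF whose
#' equal-width target intervals carry the prior masses.
#'
#' @param config a [decoder_config()].
#' @param store_history if `TRUE` (default) a snapshot of the CDF and entropy
#'   is kept at every step, enabling [decoder_undo()]; batch simulations turn
#'   this off for speed.
#' @return An object of class `horstein_decoder`.
#' @examples
#' dec <- init_decoder(decoder_config(k = 6, f0 = 0.15))
#' decoder_median(dec)
#' @export
init_decoder <- function(config, store_history = TRUE) {
  stopifnot(inherits(config, "decoder_config"))
  cdf <- if (is.null(config$prior)) pw_uniform() else pw_from_masses(config$prior)
  ent <- pw_entropy(cdf)
  dec <- list(
    cdf = cdf,
    config = config,
    n_inputs = 0L,
    entropy = ent,
    H0 = ent,
    history = if (store_history) {
      list(list(cdf = cdf, entropy = ent, cuts = NULL, factors = NULL))
    } else NULL
  )
  class(dec) <- "horstein_decoder"
  dec
}

#' @export
print.horstein_decoder <- function(x, ...) {
  cat(sprintf(
    "<horstein_decoder> k = %d, beta = %g | %d inputs, entropy %.3f bits, median %.4f%s\n",
    x$config$k, x$config$beta, x$n_inputs, x$entropy, decoder_median(x),
    if (is_terminated(x)) " [terminated]" else ""
  ))
  invisible(x)
}

#' Posterior median and quantiles
#'
#' `decoder_median()` returns the point `m` with `F(m) = 0.5` by linear
#' interpolation inside the containing segment; `decoder_quantile()`
#' generalises to any probability. A quantile falling on a zero-density
#' plateau (possible only when a configured flip probability is exactly 0)
#' returns the plateau midpoint.
#'
#' @param dec a `horstein_decoder`.
#' @param q probability in \[0, 1\].
#' @return A point in \[0, 1\].
#' @export
decoder_median <- function(dec) pw_median(dec$cdf)

#' @rdname decoder_median
#' @export
decoder_quantile <- function(dec, q) pw_quantile(dec$cdf, q)

#' Posterior entropy
#'
#' Differential entropy of the mixture-of-uniforms posterior in bits:
#' `-sum_j m_j log2(d_j)` over segments with mass `m_j` and density `d_j`.
#' The uniform prior has entropy 0; every informative input makes it more
#' negative.
#'
#' @param dec a `horstein_decoder`.
#' @return Entropy in bits (<= 0 for a uniform prior).
#' @export
decoder_entropy <- function(dec) dec$entropy

#' Has the decoder accumulated enough information to terminate?
#'
#' Termination occurs when the entropy has dropped by at least `k + beta`
#' bits from the prior entropy: `H_0 - H_i >= k + beta`. `beta` may be
#' fractional.
#'
#' @param dec a `horstein_decoder`.
#' @return Logical.
#' @export
is_terminated <- function(dec) {
  (dec$H0 - dec$entropy) >= (dec$config$k + dec$config$beta) - 1e-9
}

# shared worker: apply a region-scaling step and bookkeeping
apply_step <- function(dec, cuts, factors) {
  cdf <- pw_scale_regions(dec$cdf, cuts, factors)
  dec$cdf <- cdf
  dec$entropy <- pw_entropy(cdf)
  dec$n_inputs <- dec$n_inputs + 1L
  if (!is.null(dec$history)) {
    dec$history[[length(dec$history) + 1L]] <-
      list(cdf = cdf, entropy = dec$entropy, cuts = cuts, factors = factors)
  }
  dec
}

#' Bayesian median-split update
#'
#' The core posterior-matching step. The posterior is split at its current
#' median `m`; observing bit `b = 0` (the user indicated the target lies left
#' of `m`) leaves posterior mass `p = (1 - f0') / ((1 - f0') + f1')` on the
#' left side, and `b = 1` leaves `q = (1 - f1') / ((1 - f1') + f0')` on the
#' right side. Total mass is renormalised to 1 and one breakpoint is inserted
#' at the old median.
#'
#' @param dec a `horstein_decoder`.
#' @param bit observed input bit, 0 (left) or 1 (right).
#' @return The updated decoder.
#' @examples
#' dec <- init_decoder(decoder_config(k = 4, f0 = 0.1))
#' dec <- decoder_update(dec, 0)
#' decoder_entropy(dec) # about -0.531 bits
#' @export
decoder_update <- function(dec, bit) {
  decoder_update_weighted(dec, bit, dec$config$f0, dec$config$f1)
}

#' Reliability-weighted update
#'
#' As [decoder_update()] but with per-decision flip probabilities replacing
#' the configured ones for this step only — e.g. when a probabilistic
#' classifier reports its own confidence for each decision.
#'
#' @inheritParams decoder_update
#' @param f0,f1 per-decision flip probabilities in \[0, 0.5\]; 0.5 makes the
#'   input uninformative (the state is unchanged apart from bookkeeping).
#' @return The updated decoder.
#' @export
decoder_update_weighted <- function(dec, bit, f0, f1) {
  stopifnot(inherits(dec, "horstein_decoder"))
  if (!(length(bit) == 1 && bit %in% c(0, 1))) {
    stop("`bit` must be 0 or 1")
  }
  stopifnot(f0 >= 0, f0 <= 0.5, f1 >= 0, f1 <= 0.5)
  m <- pw_median(dec$cdf)
  # likelihood of the observed bit for targets left/right of the median
  factors <- if (bit == 0) c(1 - f0, f1) else c(f0, 1 - f1)
  apply_step(dec, m, factors)
}

#' Trisection update
#'
#' For interfaces splitting into an inner and outer region rather than
#' left/right: the posterior is trisected at its 25% and 75% quantiles (each
#' side of the split holds prior mass 0.5) and the observed `"inner"` or
#' `"outer"` input scales the central versus flanking mass by the same Bayes
#' factors as [decoder_update()] (an `"inner"` input plays the role of bit 0).
#'
#' @param dec a `horstein_decoder`.
#' @param region `"inner"` or `"outer"`.
#' @return The updated decoder.
#' @export
decoder_trisect <- function(dec, region) {
  stopifnot(inherits(dec, "horstein_decoder"))
  region <- match.arg(region, c("inner", "outer"))
  f0 <- dec$config$f0
  f1 <- dec$config$f1
  q1 <- pw_quantile(dec$cdf, 0.25)
  q3 <- pw_quantile(dec$cdf, 0.75)
  factors <- if (region == "inner") c(f1, 1 - f0, f1) else c(1 - f1, f0, 1 - f1)
  apply_step(dec, c(q1, q3), factors)
}

#' q-ary update
#'
#' Generalises the median split to a q-way split at the `1/q ... (q-1)/q`
#' quantiles. The segment matching the received symbol is scaled by its
#' probability of correct reception `1 - f_sym[j]`; every other segment by
#' its confusion likelihood `f_sym[j] / (q - 1)` (errors spread uniformly
#' over the other symbols). Reduces exactly to [decoder_update()] when
#' `q = 2` and `f_sym = c(f0', f1')`.
#'
#' @param dec a `horstein_decoder`.
#' @param symbol received symbol in `0 ... q - 1`.
#' @param q arity, >= 2.
#' @param f_sym per-symbol error probabilities (recycled to length `q`):
#'   `f_sym[j]` is the probability that intended symbol `j - 1` is corrupted.
#' @return The updated decoder.
#' @export
decoder_qary <- function(dec, symbol, q, f_sym = dec$config$f0) {
  stopifnot(inherits(dec, "horstein_decoder"), q >= 2, q == floor(q))
  if (!(length(symbol) == 1 && symbol %in% 0:(q - 1))) {
    stop("`symbol` must lie in 0 ... q - 1")
  }
  f_sym <- rep_len(f_sym, q)
  stopifnot(all(f_sym >= 0), all(f_sym <= 1))
  cuts <- vapply(seq_len(q - 1) / q, function(p) pw_quantile(dec$cdf, p),
                 numeric(1))
  # likelihood of receiving `symbol` given the target lies in region j
  factors <- f_sym / (q - 1)
  factors[symbol + 1] <- 1 - f_sym[symbol + 1]
  apply_step(dec, cuts, factors)
}

#' Decode the selected symbol
#'
#' Returns the symbol whose half-open interval `[s 2^-k, (s+1) 2^-k)`
#' contains the posterior median (under the uniform layout,
#' `s = floor(2^k m)` clamped to `2^k - 1`). With a non-uniform prior the
#' equal-width target interval containing the median is returned. Typically
#' called at termination, though this is not enforced.
#'
#' @param dec a `horstein_decoder`.
#' @return Symbol index in `0 ... n_targets - 1`.
#' @export
decode_symbol <- function(dec) {
  n <- dec$config$n_targets
  min(floor(n * pw_median(dec$cdf)), n - 1)
}

#' Information-metered undo
#'
#' Removes (approximately) `h_r` bits of accumulated information: the decoder
#' rewinds to the most recent snapshot whose accumulated information
#' (`H_0 - H_j`) does not exceed the current accumulated information minus
#' `h_r`, then re-applies a *partial* final step — interpolating the last
#' split's likelihood factors toward uniform — so that exactly `h_r` bits
#' (within 1e-6) are removed. Requires `store_history = TRUE` at
#' initialisation.
#'
#' @param dec a `horstein_decoder` with history.
#' @param h_r bits of reversal information, >= 0. Values larger than the
#'   accumulated information reset to the prior.
#' @return The rewound decoder. `n_inputs` counts full steps only; after a
#'   fractional undo the current CDF sits between snapshots.
#' @export
decoder_undo <- function(dec, h_r) {
  stopifnot(inherits(dec, "horstein_decoder"), h_r >= 0)
  if (is.null(dec$history)) stop("decoder was initialised without history")
  if (h_r == 0) return(dec)
  acc <- dec$H0 - dec$entropy
  target <- max(acc - h_r, 0) # accumulated information to keep
  ents <- vapply(dec$history, `[[`, numeric(1), "entropy")
  accs <- dec$H0 - ents
  j <- max(which(accs <= target + 1e-9))
  nxt <- if (j < length(dec$history)) dec$history[[j + 1]] else NULL
  snap <- dec$history[[j]]
  dec$history <- dec$history[seq_len(j)]
  dec$cdf <- snap$cdf
  dec$entropy <- snap$entropy
  dec$n_inputs <- j - 1L
  remainder <- target - accs[j]
  if (remainder > 1e-9 && !is.null(nxt)) {
    # Partial reverse step: re-apply the following step with its likelihood
    # factors tempered toward uniform, factors^alpha, choosing alpha so the
    # entropy lands exactly on the target information level.
    ent_at <- function(alpha) {
      pw_entropy(pw_scale_regions(snap$cdf, nxt$cuts, nxt$factors^alpha))
    }
    target_ent <- dec$H0 - target
    sol <- stats::uniroot(function(a) ent_at(a) - target_ent,
                          lower = 0, upper = 1, tol = 1e-9)
    dec$cdf <- pw_scale_regions(snap$cdf, nxt$cuts, nxt$factors^sol$root)
    dec$entropy <- pw_entropy(dec$cdf)
  }
  dec
}
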