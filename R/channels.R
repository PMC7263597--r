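#' Binary entropy function
#'
#' `H(f) = -f log2(f) - (1-f) log2(1-f)`, with the limit `x log2(x) -> 0`
#' taken at the endpoints.
#'
#' @param f vector of probabilities in \[0, 1\].
#' @return Entropy in bits, same length as `f`.
#' @export
binary_entropy <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  -xlx(f) - xlx(1 - f)
}

#' Memoryless binary channel specification
#'
#' A binary channel that flips an intended 0 to 1 with probability `f0` and an
#' intended 1 to 0 with probability `f1`. Derived quantities follow the usual
#' decomposition into a mean error rate `f = (f0 + f1) / 2`, an absolute bias
#' `f_delta` with `f0 = f + f_delta`, `f1 = f - f_delta`, and a relative bias
#' `b = f_delta / f` (undefined for a noise-free channel).
#'
#' @param f0 probability of a 0 -> 1 flip.
#' @param f1 probability of a 1 -> 0 flip; defaults to `f0` (symmetric channel).
#' @return An object of class `binary_channel`.
#' @examples
#' binary_channel(0.05, 0.45)
#' @export
binary_channel <- function(f0, f1 = f0) {
  stopifnot(length(f0) == 1, length(f1) == 1)
  if (is.na(f0) || is.na(f1) || f0 < 0 || f0 > 1 || f1 < 0 || f1 > 1) {
    stop("flip probabilities `f0` and `f1` must lie in [0, 1]")
  }
  f <- (f0 + f1) / 2
  structure(
    list(
      f0 = f0, f1 = f1, f = f,
      f_delta = (f0 - f1) / 2,
      bias = if (f > 0) (f0 - f1) / (2 * f) else NA_real_
    ),
    class = "binary_channel"
  )
}

#' @export
print.binary_channel <- function(x, ...) {
  cat(sprintf(
    "<binary_channel> f0 = %g, f1 = %g (mean f = %g, bias f_delta = %g)\n",
    x$f0, x$f1, x$f, x$f_delta
  ))
  invisible(x)
}

#' Capacity of the binary symmetric channel
#'
#' `c(f) = 1 - H(f)` bits per input, where `H` is the binary entropy function.
#' Symmetric about `f = 0.5`, zero at `f = 0.5`.
#'
#' @param f vector of flip probabilities in \[0, 1\].
#' @return Capacity in bits per input symbol.
#' @examples
#' capacity_bsc(c(0, 0.15, 0.5))
#' @export
capacity_bsc <- function(f) {
  1 - binary_entropy(f)
}

# Relabel 0/1 on input and/or output so that f0 <= f1 and f0 + f1 <= 1; the
# closed-form asymmetric capacity requires this canonical orientation and
# relabelling does not change capacity.
canonicalise_flips <- function(f0, f1) {
  if (f0 + f1 > 1) {
    f0 <- 1 - f0
    f1 <- 1 - f1
  }
  if (f0 > f1) {
    tmp <- f0
    f0 <- f1
    f1 <- tmp
  }
  c(f0 = f0, f1 = f1)
}

capacity_bac_scalar <- function(f0, f1) {
  if (is.na(f0) || is.na(f1) || f0 < 0 || f0 > 1 || f1 < 0 || f1 > 1) {
    stop("flip probabilities must lie in [0, 1]")
  }
  fc <- canonicalise_flips(f0, f1)
  f0 <- fc[["f0"]]
  f1 <- fc[["f1"]]
  # degenerate: output independent of input
  if (abs(1 - f0 - f1) < 1e-12) {
    return(0)
  }
  if (abs(f0 - f1) < 1e-12) {
    return(capacity_bsc(f0))
  }
  fd <- 1 - f0 - f1
  h0 <- binary_entropy(f0)
  h1 <- binary_entropy(f1)
  (f0 / fd) * h1 - ((1 - f1) / fd) * h0 + log2(1 + 2^((h0 - h1) / fd))
}

#' Capacity of the binary asymmetric channel
#'
#' Closed-form capacity of a binary channel with unequal flip probabilities
#' (a generalised Z channel). Labels are canonically swapped internally so
#' that the formula's orientation conditions hold; callers never see
#' relabelled bits. Reduces exactly to [capacity_bsc()] when `f0 = f1`, and
#' for a fixed mean error rate is minimised at zero bias.
#'
#' @param channel a [binary_channel()], or a numeric `f0` when `f1` is given.
#' @param f1 optional second flip probability when `channel` is numeric.
#' @return Capacity in bits per input symbol.
#' @examples
#' capacity_bac(binary_channel(0.05, 0.45))
#' capacity_bac(0.15, 0.15) == capacity_bsc(0.15)
#' @export
capacity_bac <- function(channel, f1 = NULL) {
  if (inherits(channel, "binary_channel")) {
    capacity_bac_scalar(channel$f0, channel$f1)
  } else {
    if (is.null(f1)) f1 <- channel
    stopifnot(length(channel) == length(f1))
    vapply(seq_along(channel), function(i) {
      capacity_bac_scalar(channel[i], f1[i])
    }, numeric(1))
  }
}

#' Theoretical decisions per error-free bit
#'
#' The reciprocal of the asymmetric channel capacity: the minimum number of
#' binary inputs a user must generate per error-free output bit. Returns
#' `Inf` for channels with zero capacity.
#'
#' @inheritParams capacity_bac
#' @return Decisions per error-free bit (>= 1, possibly `Inf`).
#' @examples
#' rate_bound(binary_channel(0.25)) # ~5.30 decisions/bit
#' @export
rate_bound <- function(channel, f1 = NULL) {
  cap <- capacity_bac(channel, f1)
  ifelse(cap > 0, 1 / cap, Inf)
}

#' Transmit bits through a memoryless binary channel
#'
#' Each intended bit is independently flipped with probability `f0` (when the
#' intended bit is 0) or `f1` (when it is 1).
#'
#' @param channel a [binary_channel()].
#' @param bits integer vector of intended bits in `{0, 1}`.
#' @return Observed bits, same length as `bits`.
#' @export
transmit <- function(channel, bits) {
  stopifnot(inherits(channel, "binary_channel"), all(bits %in% c(0L, 1L)))
  flip_prob <- ifelse(bits == 0L, channel$f0, channel$f1)
  flipped <- stats::runif(length(bits)) < flip_prob
  ifelse(flipped, 1L - as.integer(bits), as.integer(bits))
}

#' Gilbert-Elliott bursty channel specification
#'
#' A two-state Markov error process: a good state with flip probability
#' `f_good` and a bad state with flip probability `f_bad`. The chain enters
#' the bad state with per-step probability `p_b` and leaves it with
#' probability `p_g`. The model is parameterised by a target mean error rate
#' `f` and a burstiness `t > 1`: `p_b = 1 / t` and `p_g` is solved from the
#' stationary distribution so that the long-run flip rate equals `f`
#' (for the default `f_good = 0`, `f_bad = 1`, `p_g = p_b (1 - f) / f`).
#'
#' @param f target mean error rate, strictly inside (0, 1).
#' @param t burstiness, > 1; `1/t` is the per-step probability of entering
#'   the bad state, so the mean gap between bursts is `t` steps and burst
#'   length scales with `t` at fixed mean error. The
#'   process is memoryless at `t = (f_bad - f_good) / (f - f_good)`
#'   (`1/f` for the defaults) and increasingly bursty (positively
#'   autocorrelated errors) beyond it. Values below the feasibility floor
#'   `(1 - f) / f` (where the good-state exit probability would exceed 1)
#'   are clamped to the floor, preserving the mean error rate.
#' @param f_good,f_bad flip probabilities in the good and bad states.
#' @return An object of class `gilbert_elliott`.
#' @examples
#' gilbert_elliott_channel(0.15, t = 10)
#' @export
gilbert_elliott_channel <- function(f, t, f_good = 0, f_bad = 1) {
  stopifnot(length(f) == 1, length(t) == 1)
  if (!(f > 0 && f < 1)) stop("`f` must lie strictly inside (0, 1)")
  if (!(t > 1)) stop("burstiness `t` must exceed 1")
  stopifnot(f_good >= 0, f_good <= 1, f_bad >= 0, f_bad <= 1)
  if (f_bad <= f_good) stop("`f_bad` must exceed `f_good`")
  if (f <= f_good || f >= f_bad) {
    stop("`f` must lie between `f_good` and `f_bad` for a stationary mean of `f`")
  }
  p_b <- 1 / t
  # stationary bad-state occupancy pi_B solving pi_B f_bad + (1-pi_B) f_good = f
  pi_b <- (f - f_good) / (f_bad - f_good)
  p_g <- p_b * (1 - pi_b) / pi_b
  # Feasibility: p_g <= 1 requires t >= (1 - pi_B) / pi_B. Smaller requested
  # burstiness is clamped to that floor (mean error is preserved). Note the
  # memoryless point sits at t = 1/pi_B; between the floor and that point the
  # error process is anti-bursty (negatively autocorrelated).
  if (p_g > 1) {
    p_g <- 1
    p_b <- pi_b / (1 - pi_b)
    t <- 1 / p_b
  }
  structure(
    list(f = f, t = t, p_b = p_b, p_g = p_g, f_good = f_good, f_bad = f_bad),
    class = "gilbert_elliott"
  )
}

#' @export
print.gilbert_elliott <- function(x, ...) {
  cat(sprintf(
    "<gilbert_elliott> f = %g, t = %g (p_b = %g, p_g = %g, f_G = %g, f_B = %g)\n",
    x$f, x$t, x$p_b, x$p_g, x$f_good, x$f_bad
  ))
  invisible(x)
}

#' Initial state of a Gilbert-Elliott channel
#'
#' Draws the Markov state from the stationary distribution so that finite
#' transmissions are unbiased.
#'
#' @param channel a [gilbert_elliott_channel()].
#' @return `"good"` or `"bad"`.
#' @export
ge_init_state <- function(channel) {
  stopifnot(inherits(channel, "gilbert_elliott"))
  pi_b <- channel$p_b / (channel$p_b + channel$p_g)
  if (stats::runif(1) < pi_b) "bad" else "good"
}

#' Single step of a Gilbert-Elliott channel
#'
#' The Markov state transitions first; the bit is then flipped with the flip
#' probability of the state occupied *after* the transition. This pre/post
#' convention is fixed and documented; burst statistics differ negligibly
#' between the two conventions.
#'
#' @param channel a [gilbert_elliott_channel()].
#' @param state current state, `"good"` or `"bad"`.
#' @param bit intended bit in `{0, 1}`.
#' @return A list with `bit` (observed) and `state` (post-transition).
#' @export
ge_step <- function(channel, state, bit) {
  stopifnot(inherits(channel, "gilbert_elliott"), state %in% c("good", "bad"),
            bit %in% c(0L, 1L))
  u <- stats::runif(2)
  state <- if (state == "good") {
    if (u[1] < channel$p_b) "bad" else "good"
  } else {
    if (u[1] < channel$p_g) "good" else "bad"
  }
  fp <- if (state == "good") channel$f_good else channel$f_bad
  out <- if (u[2] < fp) 1L - as.integer(bit) else as.integer(bit)
  list(bit = out, state = state)
}

#' Transmit a bit sequence through a Gilbert-Elliott channel
#'
#' Vectorised convenience wrapper around [ge_step()]: simulates the Markov
#' state path and applies state-dependent flips.
#'
#' @param channel a [gilbert_elliott_channel()].
#' @param bits integer vector of intended bits.
#' @param state starting state; defaults to a stationary draw.
#' @return A list with `bits` (observed), `states` (post-transition state per
#'   bit) and `state` (final state, for chaining).
#' @export
ge_transmit <- function(channel, bits, state = ge_init_state(channel)) {
  stopifnot(inherits(channel, "gilbert_elliott"), all(bits %in% c(0L, 1L)))
  n <- length(bits)
  states <- character(n)
  u_trans <- stats::runif(n)
  u_flip <- stats::runif(n)
  bad <- state == "bad"
  for (i in seq_len(n)) {
    bad <- if (bad) u_trans[i] < 1 - channel$p_g else u_trans[i] < channel$p_b
    states[i] <- if (bad) "bad" else "good"
  }
  fp <- ifelse(states == "bad", channel$f_bad, channel$f_good)
  out <- ifelse(u_flip < fp, 1L - as.integer(bits), as.integer(bits))
  list(bits = out, states = states, state = if (n) states[n] else state)
}

#' Serialise a channel specification to JSON
#'
#' @param channel a [binary_channel()] or [gilbert_elliott_channel()].
#' @return A JSON string, e.g. `{"f0": 0.05, "f1": 0.45}` or
#'   `{"f": 0.15, "t": 10, "model": "gilbert_elliott"}`.
#' @export
channel_to_json <- function(channel) {
  if (inherits(channel, "binary_channel")) {
    jsonlite::toJSON(list(f0 = channel$f0, f1 = channel$f1), auto_unbox = TRUE)
  } else if (inherits(channel, "gilbert_elliott")) {
    jsonlite::toJSON(
      list(f = channel$f, t = channel$t, model = "gilbert_elliott",
           f_good = channel$f_good, f_bad = channel$f_bad),
      auto_unbox = TRUE
    )
  } else {
    stop("not a channel object")
  }
}

#' Deserialise a channel specification from JSON
#'
#' @param json a JSON string or parsed list as produced by [channel_to_json()].
#' @return A channel object.
#' @export
channel_from_json <- function(json) {
  x <- if (is.character(json)) jsonlite::fromJSON(json) else json
  if (!is.null(x$model) && x$model == "gilbert_elliott") {
    gilbert_elliott_channel(
      x$f, x$t,
      f_good = if (is.null(x$f_good)) 0 else x$f_good,
      f_bad = if (is.null(x$f_bad)) 1 else x$f_bad
    )
  } else {
    binary_channel(x$f0, if (is.null(x$f1)) x$f0 else x$f1)
  }
}
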