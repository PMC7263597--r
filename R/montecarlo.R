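# Monte Carlo simulation harness: an oracle user drives the decoder through a
# noisy channel; batches aggregate rate and error metrics.

# Fast inner loop. Operates directly on breakpoint/cumulative vectors rather
# than the S3 decoder to keep batch simulation cheap: one median lookup, one
# breakpoint insertion and one O(segments) entropy recomputation per input.
#
# Returns c(inputs, decoded_symbol, correct, n0, n1, aborted).
sim_trial_core <- function(k, beta, f0p, f1p, theta, n_targets, budget,
                           f0 = NULL, f1 = NULL, ge = NULL,
                           h_switch = NULL, x_delta = 0,
                           extra_error = 0, record = FALSE) {
  x <- c(0, 1)
  Fx <- c(0, 1)
  need <- k + beta
  ent <- 0
  inputs <- 0L
  n0 <- 0L
  n1 <- 0L
  switched <- is.null(h_switch)
  ge_bad <- if (!is.null(ge)) stats::runif(1) < ge$p_b / (ge$p_b + ge$p_g) else FALSE
  rec_int <- if (record) integer(0) else NULL
  rec_obs <- if (record) integer(0) else NULL

  while (-ent < need - 1e-9) {
    if (inputs >= budget) {
      m <- fast_median(x, Fx)
      return(list(inputs = inputs, symbol = min(floor(n_targets * m), n_targets - 1),
                  correct = FALSE, n0 = n0, n1 = n1, aborted = TRUE,
                  intended = rec_int, observed = rec_obs))
    }
    m <- fast_median(x, Fx)
    b_int <- if (theta < m) 0L else 1L
    if (extra_error > 0 && stats::runif(1) < extra_error) b_int <- 1L - b_int
    # channel corruption
    if (is.null(ge)) {
      fp <- if (b_int == 0L) f0 else f1
      b_obs <- if (stats::runif(1) < fp) 1L - b_int else b_int
    } else {
      u <- stats::runif(2)
      ge_bad <- if (ge_bad) u[1] >= ge$p_g else u[1] < ge$p_b
      fp <- if (ge_bad) ge$f_bad else ge$f_good
      b_obs <- if (u[2] < fp) 1L - b_int else b_int
    }
    if (record) {
      rec_int <- c(rec_int, b_int)
      rec_obs <- c(rec_obs, b_obs)
    }
    if (b_obs == 0L) n0 <- n0 + 1L else n1 <- n1 + 1L
    # split at the median and rescale the two sides
    w_left <- if (b_obs == 0L) bayes_p(f0p, f1p) else 1 - bayes_q(f0p, f1p)
    j <- findInterval(m, x)
    insert <- m - x[j] >= MERGE_EPS && (j >= length(x) || x[j + 1] - m >= MERGE_EPS)
    if (insert) {
      x <- c(x[seq_len(j)], m, x[seq(j + 1, length(x))])
      Fx <- c(Fx[seq_len(j)], 0.5, Fx[seq(j + 1, length(Fx))])
    }
    scale_l <- 2 * w_left
    scale_r <- 2 * (1 - w_left)
    left <- Fx <= 0.5
    Fx <- ifelse(left, Fx * scale_l, 1 - (1 - Fx) * scale_r)
    Fx[length(Fx)] <- 1
    # entropy of the mixture of uniforms
    ms <- diff(Fx)
    ws <- diff(x)
    pos <- ms > 0
    ent <- -sum(ms[pos] * log2(ms[pos] / ws[pos]))
    inputs <- inputs + 1L
    # change of heart: switch targets once entropy first crosses the threshold
    if (!switched && ent < h_switch) {
      switched <- TRUE
      cand <- if (theta + x_delta <= 1) theta + x_delta else theta - x_delta
      s_new <- min(max(round(cand * n_targets - 0.5), 0), n_targets - 1)
      theta <- (s_new + 0.5) / n_targets
    }
  }
  m <- fast_median(x, Fx)
  s_dec <- min(floor(n_targets * m), n_targets - 1)
  s_true <- min(floor(n_targets * theta), n_targets - 1)
  list(inputs = inputs, symbol = s_dec, correct = s_dec == s_true,
       n0 = n0, n1 = n1, aborted = FALSE,
       intended = rec_int, observed = rec_obs)
}

fast_median <- function(x, Fx) {
  j <- findInterval(0.5, Fx)
  if (Fx[j] < 0.5) {
    x[j] + (0.5 - Fx[j]) * (x[j + 1] - x[j]) / (Fx[j + 1] - Fx[j])
  } else {
    # 0.5 falls on a breakpoint or plateau (configured noise of exactly 0)
    lo <- j
    while (lo > 1 && Fx[lo - 1] == 0.5) lo <- lo - 1
    hi <- j
    while (hi < length(Fx) && Fx[hi + 1] == 0.5) hi <- hi + 1
    (x[lo] + x[hi]) / 2
  }
}

default_budget <- function(config) {
  cap <- capacity_bac(config$f0, config$f1)
  ceiling(50 * (config$k + config$beta) / max(cap, 1e-6))
}

ge_params <- function(channel) {
  if (inherits(channel, "gilbert_elliott")) {
    channel[c("p_b", "p_g", "f_good", "f_bad")]
  } else NULL
}

#' Simulate one oracle-driven selection
#'
#' Runs a single closed-loop selection: an oracle user emits bit 0 whenever
#' the target lies left of the decoder's median, the channel corrupts the
#' bit, and the decoder updates until the entropy has dropped by `k + beta`
#' bits. An optional change-of-heart specification switches the intended
#' target to a symbol centre at separation `x_delta` the first time the
#' entropy crosses `-lambda (k + beta)` bits.
#'
#' @param config a [decoder_config()].
#' @param channel a [binary_channel()] or [gilbert_elliott_channel()].
#' @param target target symbol index in `0 ... 2^k - 1`, or `NULL` to draw
#'   uniformly at random.
#' @param change_of_heart optional list with `lambda` (switchpoint fraction
#'   in \[0, 1\]) and `x_delta` (target separation in the unit interval).
#' @param extra_error additional oracle-side error rate applied to the
#'   intended bit before the channel (default 0: a perfect oracle).
#' @param budget maximum inputs before the trial is aborted and flagged
#'   incorrect; defaults to `50 (k + beta) / capacity` of the configured
#'   channel.
#' @param record if `TRUE`, per-step intended and observed bits are returned.
#' @return A one-row tibble: `inputs`, `symbol` (decoded), `target` (final
#'   intended symbol), `correct`, `aborted`, `n0`, `n1` (observed bit
#'   counts) and, when recorded, list-columns `intended` and `observed`.
#' @examples
#' set.seed(1)
#' run_selection(decoder_config(k = 6), binary_channel(0)) # 6 inputs, correct
#' @export
run_selection <- function(config, channel, target = NULL,
                          change_of_heart = NULL, extra_error = 0,
                          budget = default_budget(config), record = FALSE) {
  stopifnot(inherits(config, "decoder_config"))
  n_t <- config$n_targets
  if (is.null(target)) target <- sample.int(n_t, 1) - 1L
  stopifnot(target >= 0, target < n_t)
  theta <- (target + 0.5) / n_t
  ge <- ge_params(channel)
  h_switch <- NULL
  x_delta <- 0
  if (!is.null(change_of_heart)) {
    stopifnot(change_of_heart$lambda >= 0, change_of_heart$lambda <= 1,
              change_of_heart$x_delta >= 0, change_of_heart$x_delta <= 1)
    h_switch <- -change_of_heart$lambda * (config$k + config$beta)
    x_delta <- change_of_heart$x_delta
  }
  res <- sim_trial_core(
    config$k, config$beta, config$f0, config$f1, theta, n_t, budget,
    f0 = if (is.null(ge)) channel$f0 else NULL,
    f1 = if (is.null(ge)) channel$f1 else NULL,
    ge = ge, h_switch = h_switch, x_delta = x_delta,
    extra_error = extra_error, record = record
  )
  out <- tibble::tibble(
    inputs = res$inputs, symbol = res$symbol, target = target,
    correct = res$correct, aborted = res$aborted,
    n0 = res$n0, n1 = res$n1
  )
  if (record) {
    out$intended <- list(res$intended)
    out$observed <- list(res$observed)
  }
  out
}

#' Simulate a batch of selections
#'
#' Runs `n` independent oracle selections of uniformly random targets (or
#' prior-weighted targets under a non-uniform prior) and aggregates the
#' standard design metrics: mean decisions per bit `R = total inputs / (n k)`
#' (inputs of incorrect trials included; the error rate is reported
#' separately), the uncorrected symbol error rate `e_k`, and the
#' backspace-corrected decisions per error-free bit `R'` obtained by applying
#' [backspace_corrected_rate()] to the batch's own `R` and `e_k`.
#'
#' @inheritParams run_selection
#' @param n number of trials.
#' @param t_input optional seconds per binary decision; when given, the
#'   symbol entry time projection `T_k = R k t_input` is reported.
#' @param seed optional integer; when given, seeds the RNG for a
#'   reproducible batch.
#' @param ... passed to [run_selection()] (e.g. `change_of_heart`,
#'   `extra_error`, `budget`).
#' @return A one-row tibble: decoder and channel parameters, `n`, `R_mean`,
#'   `R_sd`, `e_k`, `R_prime`, `T_k`, `aborted_frac`, `seed`.
#' @examples
#' set.seed(42)
#' run_batch(decoder_config(k = 6), binary_channel(0), n = 10) # R = 1, e_k = 0
#' @export
run_batch <- function(config, channel, n, t_input = NA_real_, seed = NULL, ...) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_t <- config$n_targets
  probs <- if (is.null(config$prior)) rep(1 / n_t, n_t) else config$prior
  targets <- sample.int(n_t, n, replace = TRUE, prob = probs) - 1L
  inputs <- integer(n)
  correct <- logical(n)
  aborted <- logical(n)
  for (i in seq_len(n)) {
    tr <- run_selection(config, channel, target = targets[i], ...)
    inputs[i] <- tr$inputs
    correct[i] <- tr$correct
    aborted[i] <- tr$aborted
  }
  k <- config$k
  R <- sum(inputs) / (n * k)
  e_k <- mean(!correct)
  is_ge <- inherits(channel, "gilbert_elliott")
  tibble::tibble(
    k = k, beta = config$beta,
    f0 = if (is_ge) channel$f else channel$f0,
    f1 = if (is_ge) channel$f else channel$f1,
    f0_dec = config$f0, f1_dec = config$f1,
    model = if (is_ge) "gilbert_elliott" else "bernoulli",
    t = if (is_ge) channel$t else NA_real_,
    n = n,
    R_mean = R,
    R_sd = stats::sd(inputs / k),
    e_k = e_k,
    R_prime = backspace_corrected_rate(R, e_k, k),
    T_k = R * k * t_input,
    aborted_frac = mean(aborted),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Simulate a data frame of conditions
#'
#' Data-frame-first wrapper over [run_batch()]: each row describes one
#' condition (`k`, `beta`, true `f0`/`f1`, configured `f0_dec`/`f1_dec`,
#' optionally `t` for a Gilbert-Elliott channel and `t_input` for timing) and
#' the result rows are bound into one tibble.
#'
#' @param conditions a data frame; missing `f1` defaults to `f0`, missing
#'   `f0_dec`/`f1_dec` default to the true values (a matched decoder),
#'   missing `beta` defaults to 0.
#' @param n trials per condition.
#' @param ... passed to [run_batch()].
#' @return A tibble with one row per condition.
#' @export
simulate_conditions <- function(conditions, n = 1000, ...) {
  stopifnot(is.data.frame(conditions), "k" %in% names(conditions))
  rows <- purrr::map(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, ]
    f0 <- cond$f0
    f1 <- if ("f1" %in% names(cond) && !is.na(cond$f1)) cond$f1 else f0
    beta <- if ("beta" %in% names(cond) && !is.na(cond$beta)) cond$beta else 0
    f0d <- if ("f0_dec" %in% names(cond) && !is.na(cond$f0_dec)) cond$f0_dec else f0
    f1d <- if ("f1_dec" %in% names(cond) && !is.na(cond$f1_dec)) cond$f1_dec else f1
    t_in <- if ("t_input" %in% names(cond) && !is.na(cond$t_input)) cond$t_input else NA_real_
    channel <- if ("t" %in% names(cond) && !is.na(cond$t)) {
      gilbert_elliott_channel(f0, cond$t)
    } else {
      binary_channel(f0, f1)
    }
    cfg <- decoder_config(k = cond$k, beta = beta, f0 = f0d, f1 = f1d)
    out <- run_batch(cfg, channel, n = n, t_input = t_in, ...)
    if ("condition" %in% names(cond)) {
      out <- dplyr::bind_cols(tibble::tibble(condition = cond$condition), out)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Bisect the confirmation overhead for a target error rate
#'
#' Finds the smallest `beta` (within `tol` bits) whose batch uncorrected
#' error rate does not exceed `e_target`, by monotone bisection on
#' `beta` in `[0, beta_max]`. The error rate is a Monte Carlo estimate, so
#' `n` controls the resolution of the search.
#'
#' @param config a [decoder_config()]; its `beta` is ignored.
#' @param channel the true channel.
#' @param e_target tolerated uncorrected symbol error rate.
#' @param n trials per bisection evaluation.
#' @param beta_max upper end of the search interval.
#' @param tol termination tolerance on `beta`, in bits.
#' @param seed optional seed applied before each batch evaluation (common
#'   random numbers across the search stabilise the bisection).
#' @return A list with `beta`, `e_k` (error at the returned `beta`),
#'   `converged`, and `trace` (a tibble of evaluated points).
#' @export
bisect_beta <- function(config, channel, e_target, n = 1000, beta_max = 16,
                        tol = 0.05, seed = NULL) {
  eval_beta <- function(beta) {
    cfg <- config
    cfg$beta <- beta
    if (!is.null(seed)) set.seed(seed)
    run_batch(cfg, channel, n = n)$e_k
  }
  trace <- tibble::tibble(beta = numeric(0), e_k = numeric(0))
  note <- function(b, e) trace <<- dplyr::bind_rows(trace, tibble::tibble(beta = b, e_k = e))
  e_lo <- eval_beta(0)
  note(0, e_lo)
  if (e_lo <= e_target) {
    return(list(beta = 0, e_k = e_lo, converged = TRUE, trace = trace))
  }
  e_hi <- eval_beta(beta_max)
  note(beta_max, e_hi)
  if (e_hi > e_target) {
    return(list(beta = beta_max, e_k = e_hi, converged = FALSE, trace = trace))
  }
  lo <- 0
  hi <- beta_max
  e_at_hi <- e_hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    e_mid <- eval_beta(mid)
    note(mid, e_mid)
    if (e_mid <= e_target) {
      hi <- mid
      e_at_hi <- e_mid
    } else {
      lo <- mid
    }
  }
  list(beta = hi, e_k = e_at_hi, converged = TRUE, trace = trace)
}

#' Closed-form approximation of the uncorrected error rate
#'
#' Log-linear empirical fit of the uncorrected symbol error rate as a
#' function of the flip probability `f` and the confirmation overhead
#' `beta`: `e_k = exp(-0.28 (beta + 5.17)) f + exp(-1.19 (beta + 2.57))`.
#' Both the slope and the intercept decay exponentially with `beta`; the fit
#' does not depend on `k`.
#'
#' @param f flip probability in \[0, 0.5\].
#' @param beta confirmation overhead in bits, >= 0.
#' @return Predicted uncorrected symbol error rate (vectorised).
#' @examples
#' predict_error_rate(0.15, beta = 0) # about 0.082
#' @export
predict_error_rate <- function(f, beta) {
  stopifnot(all(f >= 0 & f <= 0.5), all(beta >= 0))
  exp(-0.28 * (beta + 5.17)) * f + exp(-1.19 * (beta + 2.57))
}

#' Interleaved ("diffused") multi-decoder batch
#'
#' Interleaves `n_decoders` independent decoders, each selecting its own
#' uniformly random target, with the next input requested from a uniformly
#' random unterminated decoder. Diffusing inputs across decoders spreads
#' bursts of channel errors so each decoder sees noise closer to independent
#' draws; with a memoryless channel it is statistically equivalent to
#' running the decoders separately. Correctness is scored per decoder.
#'
#' @inheritParams run_batch
#' @param n_decoders number of interleaved decoders per group.
#' @param n_groups number of independent groups to simulate.
#' @return A tibble with one row per decoder: `group`, `decoder`, `inputs`,
#'   `correct`, `aborted`.
#' @export
run_batch_diffused <- function(config, channel, n_decoders, n_groups = 1,
                               budget = default_budget(config)) {
  stopifnot(n_decoders >= 1, n_groups >= 1)
  is_ge <- inherits(channel, "gilbert_elliott")
  ge <- ge_params(channel)
  n_t <- config$n_targets
  need <- config$k + config$beta
  out <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    decs <- lapply(seq_len(n_decoders), function(i) {
      init_decoder(config, store_history = FALSE)
    })
    thetas <- (sample.int(n_t, n_decoders, replace = TRUE) - 0.5) / n_t
    inputs <- integer(n_decoders)
    aborted <- logical(n_decoders)
    ge_state <- if (is_ge) ge_init_state(channel) else NULL
    active <- rep(TRUE, n_decoders)
    while (any(active)) {
      i <- if (sum(active) == 1) which(active) else sample(which(active), 1)
      m <- decoder_median(decs[[i]])
      b_int <- if (thetas[i] < m) 0L else 1L
      if (is_ge) {
        st <- ge_step(channel, ge_state, b_int)
        ge_state <- st$state
        b_obs <- st$bit
      } else {
        b_obs <- transmit(channel, b_int)
      }
      decs[[i]] <- decoder_update(decs[[i]], b_obs)
      inputs[i] <- inputs[i] + 1L
      if (is_terminated(decs[[i]])) active[i] <- FALSE
      if (inputs[i] >= budget) {
        active[i] <- FALSE
        aborted[i] <- TRUE
      }
    }
    correct <- vapply(seq_len(n_decoders), function(i) {
      !aborted[i] && decode_symbol(decs[[i]]) == floor(thetas[i] * n_t)
    }, logical(1))
    out[[g]] <- tibble::tibble(
      group = g, decoder = seq_len(n_decoders),
      inputs = inputs, correct = correct, aborted = aborted
    )
  }
  dplyr::bind_rows(out)
}
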