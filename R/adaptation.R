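# Online adaptation of channel statistics between symbols: a count-based
# rule for symmetric channels and a replicate-simulation heuristic for
# biased channels.

clamp_fprime <- function(f) pmin(pmax(f, 0), 0.499)

#' Count-based adaptation for symmetric channels
#'
#' After each decoded symbol, compares the number of inputs `n` actually
#' consumed with the number expected under the configured statistics,
#' `n_p = (k + beta) / c(f0', f1')` (the termination budget divided by the
#' configured channel capacity, so both counts are per symbol). The
#' configured rate moves by a fixed step when the relative deviation
#' `(n - n_p) / n_p` leaves the dead-band `[-eps_n, eps_n]`:
#' more inputs than expected means the channel is noisier than configured
#' (raise `f'`); fewer means the decoder is pessimistic (lower `f'`).
#'
#' @param f_prime current configured flip probability.
#' @param n inputs consumed by the symbol that just terminated.
#' @param k,beta decoder parameters.
#' @param eps_n dead-band half-width on the relative deviation.
#' @param delta_n adaptation step size.
#' @return Updated configured flip probability, clamped to \[0, 0.499\].
#' @export
adapt_symmetric <- function(f_prime, n, k, beta, eps_n = 0.01, delta_n = 0.005) {
  stopifnot(n >= 0, eps_n >= 0, delta_n >= 0)
  n_p <- (k + beta) / capacity_bac(f_prime, f_prime)
  rel <- (n - n_p) / n_p
  out <- if (rel > eps_n) {
    f_prime + delta_n
  } else if (rel < -eps_n) {
    f_prime - delta_n
  } else {
    f_prime
  }
  clamp_fprime(out)
}

#' Replicate-simulation adaptation for biased channels
#'
#' For biased channels there is no closed-form expected input count, so the
#' decoder's own simulator is used as the reference: the symbol just decoded
#' is re-selected in `replicates` simulations that use the *configured*
#' probabilities as the true noise, and the averaged observed bit counts
#' `n0'`, `n1'` are compared with the counts `n0`, `n1` actually observed.
#' The configured rates move by `eps_n (n0 - n0') / k` and
#' `eps_n (n1 - n1') / k`. When the configured values match the truth the
#' expected update is zero, making the truth a fixed point.
#'
#' @param f0_prime,f1_prime current configured flip probabilities.
#' @param n0,n1 observed counts of 0 and 1 input bits for the last symbol.
#' @param target the symbol that was decoded (the replicates re-select it).
#' @param k,beta decoder parameters.
#' @param eps_n adaptation gain.
#' @param replicates number of replicate simulations to average.
#' @return A list with updated `f0_prime` and `f1_prime`, clamped to
#'   \[0, 0.499\].
#' @export
adapt_biased <- function(f0_prime, f1_prime, n0, n1, target, k, beta,
                         eps_n = 5e-4, replicates = 4) {
  stopifnot(replicates >= 1, n0 >= 0, n1 >= 0)
  cfg <- decoder_config(k = k, beta = beta, f0 = f0_prime, f1 = f1_prime)
  chan <- binary_channel(f0_prime, f1_prime)
  n0r <- numeric(replicates)
  n1r <- numeric(replicates)
  for (r in seq_len(replicates)) {
    tr <- run_selection(cfg, chan, target = target)
    n0r[r] <- tr$n0
    n1r[r] <- tr$n1
  }
  list(
    f0_prime = clamp_fprime(f0_prime + eps_n * (n0 - mean(n0r)) / k),
    f1_prime = clamp_fprime(f1_prime + eps_n * (n1 - mean(n1r)) / k)
  )
}

#' Run a sequence of selections with online symmetric adaptation
#'
#' Simulates `n_symbols` consecutive selections against a fixed true
#' symmetric channel, adapting the configured rate with [adapt_symmetric()]
#' between symbols (never mid-symbol).
#'
#' @param f_true true symmetric flip probability.
#' @param f_start initial configured flip probability.
#' @param k,beta decoder parameters.
#' @param n_symbols number of symbols to decode.
#' @param eps_n,delta_n adaptation parameters, see [adapt_symmetric()].
#' @return A tibble trace with one row per symbol: `symbol`, `f_prime` (the
#'   value used for that symbol), `inputs`, `correct`, `f_true`.
#' @export
run_adaptation <- function(f_true, f_start, k = 8, beta = 8, n_symbols = 150,
                           eps_n = 0.01, delta_n = 0.005) {
  chan <- binary_channel(f_true)
  f_prime <- f_start
  rows <- vector("list", n_symbols)
  for (s in seq_len(n_symbols)) {
    cfg <- decoder_config(k = k, beta = beta, f0 = f_prime)
    tr <- run_selection(cfg, chan)
    rows[[s]] <- tibble::tibble(
      symbol = s, f_prime = f_prime, inputs = tr$inputs,
      correct = tr$correct, f_true = f_true
    )
    f_prime <- adapt_symmetric(f_prime, tr$inputs, k, beta, eps_n, delta_n)
  }
  dplyr::bind_rows(rows)
}

#' Run a sequence of selections with online biased adaptation
#'
#' Simulates consecutive selections against a (possibly step-changing)
#' biased channel, adapting both configured rates with [adapt_biased()]
#' between symbols.
#'
#' @param f0_true,f1_true true flip probabilities; vectors are recycled to
#'   `n_symbols`, so a step change is expressed by e.g.
#'   `rep(c(0.1, 0.3), c(100, 200))`.
#' @param f0_start,f1_start initial configured values.
#' @param k,beta decoder parameters.
#' @param n_symbols number of symbols.
#' @param eps_n adaptation gain.
#' @param replicates replicate simulations per update.
#' @return A tibble trace: `symbol`, `f0_prime`, `f1_prime`, `f0_true`,
#'   `f1_true`, `inputs`, `correct`.
#' @export
run_adaptation_biased <- function(f0_true, f1_true, f0_start, f1_start,
                                  k = 8, beta = 8, n_symbols = 300,
                                  eps_n = 5e-4, replicates = 4) {
  f0_true <- rep_len(f0_true, n_symbols)
  f1_true <- rep_len(f1_true, n_symbols)
  f0p <- f0_start
  f1p <- f1_start
  rows <- vector("list", n_symbols)
  for (s in seq_len(n_symbols)) {
    cfg <- decoder_config(k = k, beta = beta, f0 = f0p, f1 = f1p)
    chan <- binary_channel(f0_true[s], f1_true[s])
    tr <- run_selection(cfg, chan)
    rows[[s]] <- tibble::tibble(
      symbol = s, f0_prime = f0p, f1_prime = f1p,
      f0_true = f0_true[s], f1_true = f1_true[s],
      inputs = tr$inputs, correct = tr$correct
    )
    upd <- adapt_biased(f0p, f1p, tr$n0, tr$n1, tr$symbol, k, beta,
                        eps_n = eps_n, replicates = replicates)
    f0p <- upd$f0_prime
    f1p <- upd$f1_prime
  }
  dplyr::bind_rows(rows)
}
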