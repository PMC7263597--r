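# Backspace/undo reference code: Monte Carlo simulation of symbol entry with
# a reserved backspace symbol, the closed-form Gamma approximation, and the
# concatenation formula for error-free throughput.

delta_k <- function(k) 2^k / (2^k - 1)

#' Closed-form backspace throughput approximation
#'
#' Approximates the decisions per correct bit of backspace-corrected symbol
#' entry on a binary symmetric channel:
#' `R_b(k, f) ~ delta_k (Gamma(2 p_k - 1) + 1 - p_k)` with
#' `delta_k = 2^k / (2^k - 1)` (the cost of reserving one symbol for
#' backspace) and `p_k = (1 - f)^k` (the probability of entering one k-bit
#' symbol without error). Where `2 p_k - 1 <= 0` the backspace process does
#' not converge and the rate is `+Inf`.
#'
#' @param k bits per symbol, >= 2 (vectorised).
#' @param f flip probability in \[0, 1\] (vectorised).
#' @return Decisions per correct bit, possibly `Inf`.
#' @examples
#' approx_backspace_rate(2, 0)    # 4/3: pure alphabet-reservation overhead
#' approx_backspace_rate(4, 0.3)  # Inf: correction cascade regime
#' @export
approx_backspace_rate <- function(k, f) {
  stopifnot(all(k >= 2), all(k == floor(k)), all(f >= 0 & f <= 1))
  p_k <- (1 - f)^k
  arg <- 2 * p_k - 1
  out <- rep(Inf, length(arg))
  ok <- arg > 0
  dk <- rep_len(delta_k(k), length(arg))
  p_k <- rep_len(p_k, length(arg))
  val <- dk[ok] * (gamma(arg[ok]) + 1 - p_k[ok])
  val[val < 0] <- Inf
  out[ok] <- val
  out
}

#' Backspace-corrected rate of a concatenated decoder
#'
#' Given an inner code with rate `R` decisions per bit and residual symbol
#' error rate `e_k`, concatenating a backspace code to drive the error to
#' zero costs `R' = R delta_k (Gamma(2 (1 - e_k) - 1) + e_k)`. Returns
#' `Inf` when `e_k >= 0.5` (the Gamma argument reaches 0) or the expression
#' is negative: the correction cascade never terminates.
#'
#' @param R decisions per (uncorrected) bit.
#' @param e_k residual symbol error rate in \[0, 1).
#' @param k bits per symbol.
#' @return Decisions per error-free bit, possibly `Inf`.
#' @examples
#' backspace_corrected_rate(1, 0, k = 6)    # just the reservation overhead
#' backspace_corrected_rate(4.07, 0.08, 10) # about 4.9
#' @export
backspace_corrected_rate <- function(R, e_k, k) {
  stopifnot(all(e_k >= 0 & e_k < 1))
  arg <- 2 * (1 - e_k) - 1
  out <- rep(Inf, max(length(R), length(e_k)))
  R <- rep_len(R, length(out))
  e_k <- rep_len(e_k, length(out))
  arg <- rep_len(arg, length(out))
  k <- rep_len(k, length(out))
  ok <- arg > 0
  val <- R[ok] * delta_k(k[ok]) * (gamma(arg[ok]) + e_k[ok])
  val[val < 0] <- Inf
  out[ok] <- val
  out
}

#' Monte Carlo simulation of backspace-corrected symbol entry
#'
#' Simulates perfect-strategy entry of `n_symbols` terminal symbols from a
#' `2^k` alphabet with one symbol reserved for backspace. Each entry takes
#' `k` binary decisions, each flipped independently with probability `f`, so
#' the committed symbol is the intended one with probability `(1 - f)^k` and
#' otherwise uniform over the other `2^k - 1` symbols — including backspace,
#' which deletes the previous committed symbol. The perfect-strategy user
#' enters backspace if and only if the last committed symbol is wrong.
#' Replications are simulated as a vectorised Markov chain over the count of
#' correct prefix symbols and wrong symbols stacked on top.
#'
#' The rate charges the alphabet-reservation overhead: at `f = 0` entry of
#' `n` symbols takes `n k` decisions and the rate is exactly
#' `delta_k = 2^k / (2^k - 1)` decisions per correct bit.
#'
#' @param k bits per symbol, >= 2 (the alphabet needs at least 3 terminals
#'   plus backspace).
#' @param f flip probability in \[0, 0.5).
#' @param n_symbols length of the intended symbol sequence.
#' @param n_reps number of replications.
#' @param budget maximum symbol entries per replication before it is flagged
#'   as failed (a correction cascade); the default mirrors a decision budget
#'   of `1e4 * n_symbols * k`.
#' @return A one-row tibble: `k`, `f`, `n_symbols`, `n_reps`, `R_mean`,
#'   `R_sd` (decisions per correct bit over completed replications, `Inf`
#'   when none complete), `failed_frac`.
#' @examples
#' simulate_backspace(2, 0, n_symbols = 32, n_reps = 3) # R = 4/3 exactly
#' @export
simulate_backspace <- function(k, f, n_symbols = 32, n_reps = 1000,
                               budget = 1e4 * n_symbols) {
  stopifnot(k >= 2, k == floor(k), f >= 0, f < 0.5, n_symbols >= 1)
  p_k <- (1 - f)^k
  n_alpha <- 2^k
  # probability that an entry comes out as one specific *other* symbol
  p_other <- (1 - p_k) / (n_alpha - 1)
  correct <- integer(n_reps) # correct prefix length
  wrong <- integer(n_reps)   # wrong symbols stacked on top
  entries <- integer(n_reps)
  active <- rep(TRUE, n_reps)
  while (any(active)) {
    idx <- which(active)
    u <- stats::runif(length(idx))
    w <- wrong[idx]
    cc <- correct[idx]
    # intending a terminal symbol (w == 0) or backspace (w > 0):
    # outcome "as intended" with prob p_k; corrupted to backspace with prob
    # p_other (only relevant when intending a terminal); otherwise a wrong
    # terminal is appended.
    as_intended <- u < p_k
    to_backspace <- !as_intended & (u < p_k + p_other)
    terminal <- w == 0L
    # intended terminal, entered correctly -> prefix grows
    cc <- cc + as.integer(terminal & as_intended)
    # intended terminal, corrupted to backspace -> pops a correct symbol
    cc <- cc - as.integer(terminal & to_backspace & cc > 0L)
    # intended terminal, corrupted to another terminal -> wrong on top
    w <- w + as.integer(terminal & !as_intended & !to_backspace)
    # intended backspace, entered correctly -> pops the wrong symbol
    w <- w - as.integer(!terminal & as_intended)
    # intended backspace, corrupted: the entry comes out as one of the
    # 2^k - 1 terminal symbols, all wrong while a wrong symbol sits on top
    w <- w + as.integer(!terminal & !as_intended)
    correct[idx] <- cc
    wrong[idx] <- w
    entries[idx] <- entries[idx] + 1L
    done <- cc == n_symbols & w == 0L
    over <- entries[idx] >= budget
    active[idx[done | over]] <- FALSE
  }
  failed <- entries >= budget & !(correct == n_symbols & wrong == 0L)
  rates <- delta_k(k) * (entries[!failed] * k) / (n_symbols * k)
  tibble::tibble(
    k = k, f = f, n_symbols = n_symbols, n_reps = n_reps,
    R_mean = if (length(rates)) mean(rates) else Inf,
    R_sd = if (length(rates) > 1) stats::sd(rates) else NA_real_,
    failed_frac = mean(failed)
  )
}

#' Simulate backspace entry over a grid of conditions
#'
#' Data-frame-first wrapper around [simulate_backspace()].
#'
#' @param grid a data frame with columns `k` and `f`.
#' @param ... passed to [simulate_backspace()].
#' @return A tibble with one row per grid cell.
#' @export
simulate_backspace_grid <- function(grid, ...) {
  stopifnot(is.data.frame(grid), all(c("k", "f") %in% names(grid)))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    simulate_backspace(grid$k[i], grid$f[i], ...)
  })
}
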