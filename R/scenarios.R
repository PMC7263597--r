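# Design-scenario evaluator: predict rate, error and timing metrics for
# hypothetical interface designs before any human trial.

#' Built-in design scenarios
#'
#' Three worked design studies for assistive interfaces, expressed as rows
#' of decoder/channel parameters:
#'
#' * **A** — wheelchair control: 4 directional commands (`k = 2`) driven by a
#'   heavily biased BCI (`f0 = 0.01`, `f1 = 0.30`), decoder configured with
#'   0.05 headroom to `(0.06, 0.35)`; `beta` bisected for `e_k <= 0.01`
#'   (case `a`), then the same decoder on a degraded channel
#'   `(0.10, 0.40)` (case `b`). 0.3 s per decision.
#' * **B** — word selection from 1000 common requests (`k = 10`) with an
#'   accurately calibrated eyebrow switch at `f = 0.2`; `beta = 0` relying
#'   on backspace (case `a`) versus `beta = 7` to nearly eliminate undo
#'   (case `b`). 0.5 s per decision.
#' * **C** — choosing among three classifiers to dial 1 of 200 contacts
#'   (`k = 8`, headroom 0.03): fast/unreliable/biased (case `a`,
#'   `beta = 3`), moderate (case `b`, `beta = 2`), slow/reliable (case `c`,
#'   `beta = 1`).
#'
#' @param scenario `"A"`, `"B"`, `"C"` or a vector of these; default all.
#' @return A tibble with columns `scenario`, `case`, `k`, `beta` (`NA` when
#'   bisected), `e_target`, `f0`, `f1`, `f0_dec`, `f1_dec`, `t_input`.
#' @export
scenario_presets <- function(scenario = c("A", "B", "C")) {
  scenario <- match.arg(scenario, several.ok = TRUE)
  all <- tibble::tribble(
    ~scenario, ~case, ~k, ~beta, ~e_target, ~f0, ~f1, ~f0_dec, ~f1_dec, ~t_input,
    "A", "a", 2L, NA_real_, 0.01, 0.01, 0.30, 0.06, 0.35, 0.3,
    "A", "b", 2L, NA_real_, 0.01, 0.10, 0.40, 0.06, 0.35, 0.3,
    "B", "a", 10L, 0, NA_real_, 0.20, 0.20, 0.20, 0.20, 0.5,
    "B", "b", 10L, 7, NA_real_, 0.20, 0.20, 0.20, 0.20, 0.5,
    "C", "a", 8L, 3, NA_real_, 0.15, 0.40, 0.18, 0.43, 0.15,
    "C", "b", 8L, 2, NA_real_, 0.10, 0.10, 0.13, 0.13, 0.3,
    "C", "c", 8L, 1, NA_real_, 0.01, 0.06, 0.04, 0.09, 1.5
  )
  all[all$scenario %in% scenario, ]
}

#' Evaluate design scenarios by simulation
#'
#' Data-frame-first scenario evaluator. Each row of `spec` describes a
#' decoder (`k`, and either `beta` or an `e_target` to bisect `beta` for), a
#' true channel (`f0`, `f1`), configured statistics (`f0_dec`, `f1_dec`) and
#' a seconds-per-decision `t_input`. Runs [run_batch()] (after
#' [bisect_beta()] when `e_target` is given) and reports the decisions per
#' bit `R_mean`, uncorrected error `e_k`, backspace-corrected `R_prime` and
#' the per-symbol entry time `T_k = R k t_input`.
#'
#' A scenario sharing a bisected decoder with an earlier row (same
#' `scenario`, `beta` missing in both) reuses the `beta` found for the first
#' row, matching the "same decoder, degraded channel" design question.
#'
#' @param spec a data frame as from [scenario_presets()].
#' @param n trials per batch.
#' @param n_bisect trials per bisection evaluation (defaults to `n`).
#' @param ... passed to [run_batch()].
#' @return A tibble: the `spec` columns with `beta` filled in, plus
#'   `R_mean`, `R_sd`, `e_k`, `R_prime`, `T_k`.
#' @examples
#' \donttest{
#' set.seed(1)
#' evaluate_scenario(scenario_presets("B")[1, ], n = 200)
#' }
#' @export
evaluate_scenario <- function(spec, n = 2000, n_bisect = n, ...) {
  stopifnot(is.data.frame(spec), all(c("k", "f0") %in% names(spec)))
  beta_cache <- list()
  rows <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    f1 <- if ("f1" %in% names(row) && !is.na(row$f1)) row$f1 else row$f0
    f0d <- if ("f0_dec" %in% names(row) && !is.na(row$f0_dec)) row$f0_dec else row$f0
    f1d <- if ("f1_dec" %in% names(row) && !is.na(row$f1_dec)) row$f1_dec else f1
    t_in <- if ("t_input" %in% names(row) && !is.na(row$t_input)) row$t_input else NA_real_
    beta <- if ("beta" %in% names(row)) row$beta else NA_real_
    key <- if ("scenario" %in% names(row)) as.character(row$scenario) else as.character(i)
    if (is.na(beta)) {
      if (!is.null(beta_cache[[key]])) {
        beta <- beta_cache[[key]]
      } else {
        stopifnot(!is.na(row$e_target))
        cfg0 <- decoder_config(k = row$k, beta = 0, f0 = f0d, f1 = f1d)
        bis <- bisect_beta(cfg0, binary_channel(row$f0, f1),
                           e_target = row$e_target, n = n_bisect)
        beta <- bis$beta
        beta_cache[[key]] <- beta
      }
    }
    cfg <- decoder_config(k = row$k, beta = beta, f0 = f0d, f1 = f1d)
    res <- run_batch(cfg, binary_channel(row$f0, f1), n = n, t_input = t_in, ...)
    keep <- intersect(c("scenario", "case"), names(row))
    rows[[i]] <- dplyr::bind_cols(
      row[, keep, drop = FALSE],
      tibble::tibble(k = row$k, beta = beta, f0 = row$f0, f1 = f1,
                     f0_dec = f0d, f1_dec = f1d),
      res[, c("R_mean", "R_sd", "e_k", "R_prime", "T_k")]
    )
  }
  dplyr::bind_rows(rows)
}

#' Change-of-heart batch
#'
#' Simulates selections in which the intended target switches to a symbol at
#' separation `x_delta` once the decoder entropy first crosses
#' `-lambda (k + beta)` bits, and reports the fraction of trials that
#' acquire the *switched* target.
#'
#' @inheritParams run_batch
#' @param lambda switchpoint fraction in \[0, 1\].
#' @param x_delta target separation on the unit interval.
#' @return A one-row tibble: parameters plus `acquired_frac` (fraction
#'   decoding the new target), `R_mean` and `n`.
#' @export
run_change_of_heart <- function(config, channel, lambda, x_delta, n = 250,
                                seed = NULL) {
  res <- run_batch(config, channel, n = n, seed = seed,
                   change_of_heart = list(lambda = lambda, x_delta = x_delta))
  tibble::tibble(
    k = config$k, beta = config$beta, lambda = lambda, x_delta = x_delta,
    n = n, acquired_frac = 1 - res$e_k, R_mean = res$R_mean
  )
}
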