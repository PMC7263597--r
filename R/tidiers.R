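#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decoder's posterior into segments
#'
#' One row per piecewise-uniform segment of the posterior.
#'
#' @param x a `horstein_decoder`.
#' @param ... unused.
#' @return A tibble: `lower`, `upper`, `width`, `mass`, `density`,
#'   `cum_lower`, `cum_upper`.
#' @method tidy horstein_decoder
#' @export
tidy.horstein_decoder <- function(x, ...) {
  cdf <- x$cdf
  n <- length(cdf$x)
  tibble::tibble(
    lower = cdf$x[-n],
    upper = cdf$x[-1],
    width = diff(cdf$x),
    mass = diff(cdf$Fx),
    density = diff(cdf$Fx) / diff(cdf$x),
    cum_lower = cdf$Fx[-n],
    cum_upper = cdf$Fx[-1]
  )
}

#' One-row summary of a decoder
#'
#' @param x a `horstein_decoder`.
#' @param ... unused.
#' @return A tibble: `k`, `beta`, `inputs`, `entropy`, `info_bits`
#'   (accumulated entropy drop), `median`, `symbol`, `terminated`,
#'   `segments`.
#' @method glance horstein_decoder
#' @export
glance.horstein_decoder <- function(x, ...) {
  tibble::tibble(
    k = x$config$k,
    beta = x$config$beta,
    inputs = x$n_inputs,
    entropy = x$entropy,
    info_bits = x$H0 - x$entropy,
    median = decoder_median(x),
    symbol = decode_symbol(x),
    terminated = is_terminated(x),
    segments = length(x$cdf$x) - 1L
  )
}

#' Plot a decoder's posterior density and CDF
#'
#' @param object a `horstein_decoder`.
#' @param ... unused.
#' @return A ggplot showing the piecewise-uniform density with the median
#'   marked.
#' @method autoplot horstein_decoder
#' @export
autoplot.horstein_decoder <- function(object, ...) {
  seg <- tidy(object)
  m <- decoder_median(object)
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = 0, ymax = .data$density),
      fill = "steelblue", colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::geom_vline(xintercept = m, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "unit interval", y = "posterior density",
      title = sprintf("Posterior after %d inputs (%.2f bits accumulated)",
                      object$n_inputs, object$H0 - object$entropy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot batch simulation results
#'
#' Convenience plot of decisions per bit against the mean channel error
#' rate for a tibble of batch results (as from [simulate_conditions()]),
#' with the theoretical capacity bound overlaid.
#'
#' @param results a tibble with columns `f0`, `f1`, `R_mean` (and
#'   optionally `R_prime`).
#' @return A ggplot.
#' @export
plot_rate_vs_noise <- function(results) {
  stopifnot(all(c("f0", "f1", "R_mean") %in% names(results)))
  results <- dplyr::mutate(
    results,
    f = (.data$f0 + .data$f1) / 2,
    bound = rate_bound(.data$f0, .data$f1)
  )
  p <- ggplot2::ggplot(results, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bound), linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(y = .data$R_mean), colour = "steelblue") +
    ggplot2::labs(x = "mean flip probability f", y = "decisions per bit",
                  title = "Simulated rate against the channel bound") +
    ggplot2::theme_minimal()
  if ("R_prime" %in% names(results)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$R_prime),
                                 colour = "firebrick", shape = 1)
  }
  p
}

#' Plot an adaptation trace
#'
#' @param trace a tibble from [run_adaptation()] (columns `symbol`,
#'   `f_prime`, `f_true`) or [run_adaptation_biased()].
#' @return A ggplot of the configured rate(s) against the truth over
#'   symbols.
#' @export
plot_adaptation <- function(trace) {
  if ("f_prime" %in% names(trace)) {
    long <- tidyr::pivot_longer(trace, c("f_prime", "f_true"),
                                names_to = "series", values_to = "value")
  } else {
    long <- tidyr::pivot_longer(
      trace, c("f0_prime", "f1_prime", "f0_true", "f1_true"),
      names_to = "series", values_to = "value"
    )
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$symbol, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "symbol", y = "flip probability",
                  title = "Online adaptation of configured channel statistics") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
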