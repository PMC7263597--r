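# Multi-dimensional decoding and display geometry: independent per-axis
# decoders with entropy scheduling, diagonal-split decision mapping, highest
# density posterior intervals, linear viewports and nonlinear display warps.

#' Multi-axis decoder
#'
#' Maintains one independent posterior-matching decoder per dimension. The
#' joint posterior over the hypercube is the product of the marginals;
#' selection terminates when every axis has met its own entropy-drop
#' criterion.
#'
#' @param k per-axis symbol length(s) in bits (recycled to `n_axes`).
#' @param beta per-axis confirmation overhead(s).
#' @param f0,f1 configured flip probabilities shared by all axes.
#' @param n_axes number of dimensions (default 2).
#' @return An object of class `multi_decoder`.
#' @examples
#' md <- multi_decoder(k = 6, f0 = 0.15, n_axes = 2)
#' schedule_axis(md)
#' @export
multi_decoder <- function(k, beta = 0, f0 = 0, f1 = f0, n_axes = 2) {
  stopifnot(n_axes >= 1)
  k <- rep_len(k, n_axes)
  beta <- rep_len(beta, n_axes)
  axes <- lapply(seq_len(n_axes), function(i) {
    init_decoder(decoder_config(k = k[i], beta = beta[i], f0 = f0, f1 = f1),
                 store_history = FALSE)
  })
  structure(list(axes = axes), class = "multi_decoder")
}

#' @export
print.multi_decoder <- function(x, ...) {
  ents <- vapply(x$axes, decoder_entropy, numeric(1))
  cat(sprintf("<multi_decoder> %d axes, entropies: %s\n",
              length(x$axes), paste(sprintf("%.2f", ents), collapse = ", ")))
  invisible(x)
}

#' Entropy-based axis scheduling
#'
#' Returns the index of the unterminated axis with the largest remaining
#' entropy (the least accumulated information), ties broken by the lowest
#' index. Eliciting input for the most uncertain dimension is more efficient
#' than round-robin cycling, which wastes inputs on axes that are already
#' nearly certain.
#'
#' @param md a [multi_decoder()].
#' @return Axis index (1-based).
#' @export
schedule_axis <- function(md) {
  stopifnot(inherits(md, "multi_decoder"))
  open <- which(!vapply(md$axes, is_terminated, logical(1)))
  if (!length(open)) stop("all axes are terminated")
  ents <- vapply(md$axes, decoder_entropy, numeric(1))[open]
  open[which.max(ents)]
}

#' All axes terminated?
#'
#' @param md a [multi_decoder()].
#' @return Logical.
#' @export
md_terminated <- function(md) {
  all(vapply(md$axes, is_terminated, logical(1)))
}

#' Oracle decision for a diagonal-split display
#'
#' Chooses the scheduled axis and returns the oracle bit for that axis's
#' median: 0 when the target coordinate lies left of (below) the median. In
#' display coordinates the split is always rendered as a left/right divider
#' regardless of which axis is queried (the 45-degree rotation is a pure
#' display mapping; no decoder state changes here).
#'
#' @param md a [multi_decoder()].
#' @param target numeric vector of target coordinates in the unit hypercube.
#' @return A list with `axis` and `bit`.
#' @export
diagonal_decision <- function(md, target) {
  stopifnot(inherits(md, "multi_decoder"), length(target) == length(md$axes))
  ax <- schedule_axis(md)
  m <- decoder_median(md$axes[[ax]])
  list(axis = ax, bit = if (target[ax] < m) 0L else 1L)
}

#' Update one axis of a multi-axis decoder
#'
#' @param md a [multi_decoder()].
#' @param axis axis index.
#' @param bit observed bit.
#' @return The updated `multi_decoder`.
#' @export
md_update <- function(md, axis, bit) {
  stopifnot(inherits(md, "multi_decoder"))
  md$axes[[axis]] <- decoder_update(md$axes[[axis]], bit)
  md
}

#' Highest density posterior interval
#'
#' The shortest interval containing at least `coverage` posterior mass,
#' computed exactly over the piecewise-constant density: the interval length
#' as a function of its left endpoint is piecewise linear, so it suffices to
#' evaluate the candidate left endpoints at segment breakpoints and at
#' points whose right endpoint lands on a breakpoint. Ties are broken by the
#' leftmost interval.
#'
#' @param dec a `horstein_decoder`.
#' @param coverage posterior mass to cover, strictly inside (0, 1).
#' @return A named numeric vector `c(lower, upper)`.
#' @examples
#' dec <- init_decoder(decoder_config(k = 4, f0 = 0.1))
#' hdpi(dec, 0.5) # uniform: leftmost interval of length 0.5
#' @export
hdpi <- function(dec, coverage = 0.5) {
  stopifnot(inherits(dec, "horstein_decoder"), coverage > 0, coverage < 1)
  cdf <- dec$cdf
  qf <- function(p) pw_quantile(cdf, p)
  Ff <- function(x) pw_eval(cdf, x)
  # candidate left endpoints: breakpoints, and pre-images of breakpoints
  cands <- cdf$x
  f_at_break <- cdf$Fx
  pre <- vapply(f_at_break - coverage, function(p) {
    if (p < 0) NA_real_ else qf(p)
  }, numeric(1))
  cands <- sort(unique(c(cands, pre[!is.na(pre)])))
  Fc <- Ff(cands)
  feas <- Fc + coverage <= 1 + 1e-12
  cands <- cands[feas]
  Fc <- pmin(Fc[feas], 1 - coverage)
  uppers <- vapply(Fc + coverage, qf, numeric(1))
  lens <- uppers - cands
  best <- which(lens <= min(lens) + 1e-12)[1] # leftmost among the shortest
  c(lower = cands[best], upper = uppers[best])
}

#' Linear zoom viewport for a 2D decoder
#'
#' Computes the square viewport a linear zooming display would show: the
#' smallest axis-aligned square (aspect ratio 1) that spans the
#' `coverage`-HDPI of both axes, clamped to the unit square. The scale is
#' set by the longer of the two intervals.
#'
#' @param md a two-axis [multi_decoder()].
#' @param coverage HDPI mass per axis (default 0.5).
#' @return A list with `centre` (length-2), `half_width`, and the per-axis
#'   intervals `x` and `y`.
#' @export
linear_viewport <- function(md, coverage = 0.5) {
  stopifnot(inherits(md, "multi_decoder"), length(md$axes) == 2)
  hx <- hdpi(md$axes[[1]], coverage)
  hy <- hdpi(md$axes[[2]], coverage)
  half <- max(hx[2] - hx[1], hy[2] - hy[1]) / 2
  centre <- c(mean(hx), mean(hy))
  centre <- pmin(pmax(centre, half), 1 - half)
  list(
    centre = unname(centre), half_width = unname(half),
    x = c(centre[1] - half, centre[1] + half),
    y = c(centre[2] - half, centre[2] + half)
  )
}

#' Nonlinear display warp
#'
#' Maps a world coordinate to display space with the probability-integral
#' transform `F_i(x)`: each unit of display space carries equal posterior
#' mass, so high-density regions are stretched and unlikely regions are
#' squashed toward the edges. Monotone, with fixed endpoints, and maps the
#' median to the display centre 0.5.
#'
#' @param dec a `horstein_decoder`.
#' @param x world coordinates in \[0, 1\] (vectorised).
#' @return Display coordinates in \[0, 1\].
#' @export
nonlinear_warp <- function(dec, x) {
  stopifnot(inherits(dec, "horstein_decoder"), all(x >= 0 & x <= 1))
  pw_eval(dec$cdf, x)
}

#' Lay out targets on the unit interval
#'
#' Assigns consecutive half-open intervals to targets with widths
#' proportional to the (normalised) prior masses. The uniform prior with
#' `2^k` targets reproduces the `floor(2^k m)` decode rule.
#'
#' @param prior positive target masses.
#' @return A tibble: `symbol` (0-based), `lower`, `upper`, `width`.
#' @examples
#' layout_targets(c(3, 1)) # widths 0.75 and 0.25
#' @export
layout_targets <- function(prior) {
  if (any(prior <= 0) || !length(prior)) stop("target masses must be positive")
  w <- prior / sum(prior)
  bounds <- c(0, cumsum(w))
  bounds[length(bounds)] <- 1
  tibble::tibble(
    symbol = seq_along(w) - 1L,
    lower = bounds[-length(bounds)],
    upper = bounds[-1],
    width = w
  )
}

#' Which target interval contains a point?
#'
#' Decode rule under an arbitrary layout: intervals are half-open
#' `[lower, upper)` with the last closed at 1.
#'
#' @param layout a tibble from [layout_targets()].
#' @param x points in \[0, 1\].
#' @return Symbol indices (0-based).
#' @export
locate_target <- function(layout, x) {
  stopifnot(all(x >= 0 & x <= 1))
  idx <- findInterval(x, c(layout$lower, 1), rightmost.closed = TRUE)
  layout$symbol[pmin(idx, nrow(layout))]
}

#' Simulate a full multi-axis selection
#'
#' Runs the diagonal-split closed loop: at each step the axis with the most
#' remaining entropy is scheduled, the oracle answers for that axis's
#' median, the channel corrupts the answer, and the axis decoder updates.
#' A selection is correct iff every axis decodes its target symbol.
#'
#' @param md a [multi_decoder()] (freshly initialised).
#' @param channel a [binary_channel()].
#' @param targets integer vector of per-axis target symbols (0-based), or
#'   `NULL` for uniform random targets.
#' @param scheduler `"entropy"` (default) or `"roundrobin"`.
#' @param budget maximum total inputs.
#' @return A one-row tibble: `inputs`, `correct`, per-axis decoded symbols
#'   in a list-column `symbols`, `aborted`.
#' @export
run_selection_md <- function(md, channel, targets = NULL,
                             scheduler = c("entropy", "roundrobin"),
                             budget = 10000) {
  stopifnot(inherits(md, "multi_decoder"))
  scheduler <- match.arg(scheduler)
  n_axes <- length(md$axes)
  n_t <- vapply(md$axes, function(d) d$config$n_targets, integer(1))
  if (is.null(targets)) {
    targets <- vapply(n_t, function(m) sample.int(m, 1) - 1L, integer(1))
  }
  theta <- (targets + 0.5) / n_t
  inputs <- 0L
  rr <- 0L
  aborted <- FALSE
  while (!md_terminated(md)) {
    if (inputs >= budget) {
      aborted <- TRUE
      break
    }
    ax <- if (scheduler == "entropy") {
      schedule_axis(md)
    } else {
      open <- which(!vapply(md$axes, is_terminated, logical(1)))
      rr <- rr + 1L
      open[((rr - 1L) %% length(open)) + 1L]
    }
    m <- decoder_median(md$axes[[ax]])
    b <- transmit(channel, if (theta[ax] < m) 0L else 1L)
    md <- md_update(md, ax, b)
    inputs <- inputs + 1L
  }
  symbols <- vapply(md$axes, decode_symbol, numeric(1))
  tibble::tibble(
    inputs = inputs,
    correct = !aborted && all(symbols == targets),
    symbols = list(symbols),
    aborted = aborted
  )
}
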