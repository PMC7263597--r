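test_that("initialisation produces the documented priors and entropies", {
  dec <- init_decoder(decoder_config(k = 6))
  expect_equal(decoder_median(dec), 0.5)
  expect_equal(decoder_entropy(dec), 0)
  expect_false(is_terminated(dec))
  # equal-mass prior over two targets is identical to uniform
  dec2 <- init_decoder(decoder_config(k = 1, prior = c(0.5, 0.5)))
  expect_equal(decoder_entropy(dec2), 0)
  expect_equal(decoder_median(dec2), 0.5)
  # closed-form entropy of a two-segment mixture of uniforms
  dec3 <- init_decoder(decoder_config(k = 1, prior = c(0.75, 0.25)))
  expect_equal(decoder_entropy(dec3),
               -(0.75 * log2(1.5) + 0.25 * log2(0.5)),
               tolerance = 1e-12)
  expect_error(decoder_config(k = 2, prior = c(0.5, -0.1, 0.6)), "positive")
})

test_that("median and quantiles interpolate the piecewise CDF", {
  dec <- decoder_update(init_decoder(decoder_config(k = 4, f0 = 0.1)), 0)
  # left mass 0.9 at density 1.8: solve F(x) = 0.5
  expect_equal(decoder_median(dec), 0.5 / 1.8, tolerance = 1e-12)
  expect_equal(decoder_quantile(dec, 0), 0)
  expect_equal(decoder_quantile(dec, 1), 1)
  expect_equal(decoder_quantile(dec, 0.9), 0.5, tolerance = 1e-12)
  # plateau rule: with f' = 0 the dead half has zero density
  dec0 <- decoder_update(init_decoder(decoder_config(k = 4, f0 = 0)), 0)
  expect_equal(decoder_quantile(dec0, 1 - 1e-9), 0.5, tolerance = 1e-6)
})

test_that("updates leave the Bayes posterior mass on each side of the split", {
  # symmetric: p = 0.9
  dec <- decoder_update(init_decoder(decoder_config(k = 4, f0 = 0.1)), 0)
  expect_equal(horstein:::pw_eval(dec$cdf, 0.5), 0.9, tolerance = 1e-12)
  expect_equal(decoder_entropy(dec),
               -(0.9 * log2(1.8) + 0.1 * log2(0.2)), tolerance = 1e-12)
  # asymmetric plug-in: left mass 0.95 / (0.95 + 0.45)
  deca <- decoder_update(init_decoder(decoder_config(k = 4, f0 = 0.05, f1 = 0.45)), 0)
  expect_equal(horstein:::pw_eval(deca$cdf, 0.5), 0.95 / (0.95 + 0.45),
               tolerance = 1e-12)
  # bit = 1 leaves mass q on the right
  decb <- decoder_update(init_decoder(decoder_config(k = 4, f0 = 0.05, f1 = 0.45)), 1)
  q <- 0.55 / (0.55 + 0.05)
  expect_equal(1 - horstein:::pw_eval(decb$cdf, 0.5), q, tolerance = 1e-12)
  expect_error(decoder_update(dec, 2), "0 or 1")
})

test_that("mass is conserved and expected entropy drop never exceeds 1 bit", {
  # A single surprising input can drop (or raise) entropy by more than 1
  # bit, but the drop averaged over the decoder's own predictive
  # distribution for the next bit is the mutual information of one binary
  # observation, hence at most 1 bit.
  set.seed(404)
  ok_mass <- TRUE
  ok_drop <- TRUE
  ok_bayes <- TRUE
  n_updates <- 0L
  for (rep in 1:40) {
    f0 <- runif(1, 0, 0.45)
    f1 <- runif(1, 0, 0.45)
    dec <- init_decoder(decoder_config(k = 8, beta = 2, f0 = f0, f1 = f1),
                        store_history = FALSE)
    while (!is_terminated(dec) && dec$n_inputs < 60) {
      h_prev <- decoder_entropy(dec)
      d0 <- decoder_update(dec, 0)
      d1 <- decoder_update(dec, 1)
      # predictive probability of observing 0 when the split is at the median
      pr0 <- 0.5 * (1 - f0) + 0.5 * f1
      e_drop <- pr0 * (h_prev - decoder_entropy(d0)) +
        (1 - pr0) * (h_prev - decoder_entropy(d1))
      ok_drop <- ok_drop && e_drop <= 1 + 1e-9
      dec <- if (runif(1) < pr0) d0 else d1
      ok_mass <- ok_mass && abs(dec$cdf$Fx[length(dec$cdf$Fx)] - 1) < 1e-9
      n_updates <- n_updates + 1L
    }
    # left-of-split mass matches the Bayes factor at an arbitrary state
    m <- decoder_median(dec)
    dec2 <- decoder_update(dec, 0)
    p <- (1 - f0) / ((1 - f0) + f1)
    ok_bayes <- ok_bayes && abs(horstein:::pw_eval(dec2$cdf, m) - p) < 1e-9
  }
  expect_gt(n_updates, 400)
  expect_true(ok_mass)
  expect_true(ok_drop)
  expect_true(ok_bayes)
})

test_that("noise-free bisection selects any target in exactly k + ceiling(beta) inputs", {
  for (k in c(3, 6)) {
    for (beta in c(0, 0.5)) {
      cfg <- decoder_config(k = k, beta = beta, f0 = 0)
      for (target in c(0, 1, 2^k - 1, sample(0:(2^k - 1), 3))) {
        dec <- init_decoder(cfg, store_history = FALSE)
        theta <- (target + 0.5) / 2^k
        n <- 0
        while (!is_terminated(dec)) {
          dec <- decoder_update(dec, as.integer(theta >= decoder_median(dec)))
          n <- n + 1
        }
        expect_equal(n, k + ceiling(beta))
        expect_equal(decode_symbol(dec), target)
      }
    }
  }
})

test_that("entropy accumulates exactly under noise-free splits", {
  dec <- init_decoder(decoder_config(k = 6, f0 = 0))
  for (i in 1:3) dec <- decoder_update(dec, 0)
  expect_equal(decoder_entropy(dec), -3)
})

test_that("termination respects fractional beta", {
  cfg <- decoder_config(k = 6, beta = 0.5, f0 = 0)
  dec <- init_decoder(cfg)
  for (i in 1:6) dec <- decoder_update(dec, 0)
  expect_false(is_terminated(dec)) # 6 bits < 6.5
  dec <- decoder_update(dec, 0)
  expect_true(is_terminated(dec))
})

test_that("decode_symbol maps the median to the containing interval with clamping", {
  dec <- init_decoder(decoder_config(k = 8))
  dec$cdf <- list(x = c(0, 0.71875 - 1e-4, 0.71875 + 1e-4, 1),
                  Fx = c(0, 0.49, 0.51, 1))
  expect_equal(decode_symbol(dec), 184) # floor(256 * 0.71875)
  dec$cdf <- list(x = c(0, 1 - 1e-9, 1), Fx = c(0, 0.4999999, 1))
  k4 <- init_decoder(decoder_config(k = 4))
  k4$cdf <- dec$cdf
  expect_equal(decode_symbol(k4), 15) # boundary clamp
  k4$cdf <- list(x = c(0, 1e-9, 1), Fx = c(0, 0.6, 1))
  expect_equal(decode_symbol(k4), 0)
})

test_that("weighted updates use per-decision probabilities", {
  cfg <- decoder_config(k = 4, f0 = 0.1)
  a <- decoder_update(init_decoder(cfg), 0)
  b <- decoder_update_weighted(init_decoder(cfg), 0, 0.1, 0.1)
  expect_equal(a$cdf, b$cdf)
  # f = 0.5 is uninformative: posterior unchanged
  u <- decoder_update_weighted(init_decoder(cfg), 0, 0.5, 0.5)
  expect_equal(decoder_entropy(u), 0, tolerance = 1e-12)
  expect_equal(horstein:::pw_eval(u$cdf, 0.5), 0.5, tolerance = 1e-12)
  # alternating weighted updates match step-by-step Bayes-factor evaluation
  dec <- init_decoder(cfg)
  dec <- decoder_update_weighted(dec, 0, 0.1, 0.3)
  p1 <- 0.9 / (0.9 + 0.3)
  expect_equal(horstein:::pw_eval(dec$cdf, 0.5), p1, tolerance = 1e-12)
  m2 <- decoder_median(dec)
  dec <- decoder_update_weighted(dec, 1, 0.3, 0.1)
  q2 <- 0.9 / (0.9 + 0.3)
  expect_equal(1 - horstein:::pw_eval(dec$cdf, m2), q2, tolerance = 1e-12)
})

test_that("posterior equals the brute-force grid oracle for short input sequences", {
  set.seed(505)
  for (rep in 1:6) {
    f0 <- runif(1, 0.02, 0.45)
    f1 <- runif(1, 0.02, 0.45)
    n_bits <- sample(1:3, 1)
    bits <- sample(0:1, n_bits, replace = TRUE)
    dec <- init_decoder(decoder_config(k = 6, f0 = f0, f1 = f1))
    for (b in bits) dec <- decoder_update(dec, b)
    oracle <- grid_bayes(bits, f0, f1)
    mine <- decoder_bin_masses(dec)
    expect_true(max(abs(oracle - mine)) < 1e-6)
  }
})

test_that("mirroring the interval with swapped inputs and rates mirrors the state", {
  set.seed(606)
  bits <- sample(0:1, 12, replace = TRUE)
  a <- init_decoder(decoder_config(k = 5, f0 = 0.1, f1 = 0.3))
  b <- init_decoder(decoder_config(k = 5, f0 = 0.3, f1 = 0.1))
  for (bit in bits) {
    a <- decoder_update(a, bit)
    b <- decoder_update(b, 1L - bit)
  }
  # b's CDF is the mirror image of a's: F_b(x) = 1 - F_a(1 - x)
  xs <- seq(0, 1, by = 0.01)
  expect_equal(horstein:::pw_eval(b$cdf, xs),
               1 - horstein:::pw_eval(a$cdf, 1 - xs),
               tolerance = 1e-9)
  expect_equal(decoder_entropy(a), decoder_entropy(b), tolerance = 1e-9)
})

test_that("trisection scales inner versus outer mass by the Bayes factors", {
  cfg <- decoder_config(k = 4, f0 = 0.1)
  dec <- decoder_trisect(init_decoder(cfg), "inner")
  inner_mass <- horstein:::pw_eval(dec$cdf, 0.75) - horstein:::pw_eval(dec$cdf, 0.25)
  expect_equal(inner_mass, 0.9, tolerance = 1e-12)
  # noise-free inner input keeps prior mass 0.5 on half the support: -1 bit
  dec0 <- decoder_trisect(init_decoder(decoder_config(k = 4, f0 = 0)), "inner")
  expect_equal(decoder_entropy(dec0), -1, tolerance = 1e-12)
  # uninformative configured rate leaves masses unchanged
  cfg5 <- decoder_config(k = 4, f0 = 0.5) # capped just below 0.5
  dec5 <- decoder_trisect(init_decoder(cfg5), "outer")
  expect_equal(decoder_entropy(dec5), 0, tolerance = 1e-5)
})

test_that("q-ary updates reduce to binary and quarter the support when error-free", {
  set.seed(707)
  # q = 2 reduction: identical state trajectories over random sequences
  for (rep in 1:20) {
    f0 <- runif(1, 0, 0.4)
    f1 <- runif(1, 0, 0.4)
    bits <- sample(0:1, 8, replace = TRUE)
    a <- init_decoder(decoder_config(k = 5, f0 = f0, f1 = f1))
    b <- init_decoder(decoder_config(k = 5, f0 = f0, f1 = f1))
    for (bit in bits) {
      a <- decoder_update(a, bit)
      b <- decoder_qary(b, bit, q = 2, f_sym = c(f0, f1))
    }
    expect_equal(a$cdf$x, b$cdf$x, tolerance = 1e-12)
    expect_equal(a$cdf$Fx, b$cdf$Fx, tolerance = 1e-12)
  }
  # error-free q = 4: exactly 2 bits per input
  dec <- init_decoder(decoder_config(k = 6, f0 = 0))
  dec <- decoder_qary(dec, 2, q = 4, f_sym = 0)
  expect_equal(decoder_entropy(dec), -2, tolerance = 1e-12)
  # uniform confusion (error 3/4 spread over 3 others) is uninformative
  dec2 <- decoder_qary(init_decoder(decoder_config(k = 6, f0 = 0.1)),
                       1, q = 4, f_sym = 3 / 4)
  expect_equal(decoder_entropy(dec2), 0, tolerance = 1e-12)
  expect_error(decoder_qary(init_decoder(decoder_config(k = 4)), 4, q = 4),
               "0 ... q")
})

test_that("undo removes the requested information exactly", {
  cfg <- decoder_config(k = 6, f0 = 0)
  dec <- init_decoder(cfg)
  for (i in 1:3) dec <- decoder_update(dec, 0)
  # no-op
  expect_equal(decoder_undo(dec, 0)$cdf, dec$cdf)
  # exact snapshot restore
  undone <- decoder_undo(dec, 1)
  expect_equal(decoder_entropy(undone), -2, tolerance = 1e-9)
  expect_equal(undone$n_inputs, 2L)
  expect_equal(length(undone$history), 3L)
  ref <- init_decoder(cfg)
  for (i in 1:2) ref <- decoder_update(ref, 0)
  expect_equal(undone$cdf, ref$cdf)
  # full reset when h_r exceeds accumulated information
  reset <- decoder_undo(dec, 99)
  expect_equal(decoder_entropy(reset), 0)
  expect_equal(reset$n_inputs, 0L)
  # fractional undo: partial reverse of the last split
  cfgn <- decoder_config(k = 6, f0 = 0.1)
  decn <- init_decoder(cfgn)
  for (i in 1:4) decn <- decoder_update(decn, 0)
  acc <- -decoder_entropy(decn)
  part <- decoder_undo(decn, 0.7)
  expect_equal(-decoder_entropy(part), acc - 0.7, tolerance = 1e-6)
  expect_equal(part$n_inputs, length(part$history) - 1L)
})

test_that("configured probabilities are capped below one half", {
  cfg <- decoder_config(k = 4, f0 = 0.7)
  expect_lt(cfg$f0, 0.5)
  expect_error(decoder_config(k = 4, f0 = -0.1), ">= 0")
})

test_that("decoder round-trips through JSON serialisation", {
  dec <- init_decoder(decoder_config(k = 5, f0 = 0.2, f1 = 0.3))
  for (b in c(0, 1, 1)) dec <- decoder_update(dec, b)
  back <- decoder_from_json(decoder_to_json(dec))
  expect_equal(back$cdf$x, dec$cdf$x)
  expect_equal(back$cdf$Fx, dec$cdf$Fx)
  expect_equal(back$n_inputs, dec$n_inputs)
  expect_equal(decoder_entropy(back), decoder_entropy(dec), tolerance = 1e-12)
})

test_that("tidiers summarise the decoder state consistently", {
  dec <- decoder_update(init_decoder(decoder_config(k = 4, f0 = 0.1)), 0)
  td <- tidy(dec)
  expect_equal(sum(td$mass), 1, tolerance = 1e-12)
  expect_equal(td$mass / td$width, td$density)
  gl <- glance(dec)
  expect_equal(gl$inputs, 1L)
  expect_equal(gl$entropy, decoder_entropy(dec))
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
})
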