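test_that("noise-free selection is exact bisection", {
  set.seed(901)
  cfg <- decoder_config(k = 6, beta = 0, f0 = 0)
  for (target in c(0L, 31L, 63L)) {
    tr <- run_selection(cfg, binary_channel(0), target = target)
    expect_equal(tr$inputs, 6L)
    expect_true(tr$correct)
    expect_equal(tr$symbol, target)
  }
  b <- run_batch(cfg, binary_channel(0), n = 20)
  expect_equal(b$R_mean, 1)
  expect_equal(b$e_k, 0)
})

test_that("a pessimistic decoder on a clean channel pays an input overhead", {
  set.seed(902)
  cfg <- decoder_config(k = 6, beta = 0, f0 = 0.02)
  tr <- run_selection(cfg, binary_channel(0), target = 10L)
  expect_gt(tr$inputs, 6)
  expect_true(tr$correct)
})

test_that("batch metrics respect their accounting identities", {
  set.seed(903)
  cfg <- decoder_config(k = 5, beta = 1, f0 = 0.15)
  b <- run_batch(cfg, binary_channel(0.1), n = 60, t_input = 0.5)
  # at least one input per bit of the termination budget per decoded bit
  expect_gte(b$R_mean, (cfg$k + cfg$beta) / cfg$k - 1e-9)
  expect_true(b$e_k >= 0 && b$e_k <= 1)
  expect_equal(b$R_prime, backspace_corrected_rate(b$R_mean, b$e_k, 5))
  expect_gte(b$R_prime, b$R_mean)
  expect_equal(b$T_k, b$R_mean * 5 * 0.5)
  # zero seconds per decision projects zero entry time
  b0 <- run_batch(cfg, binary_channel(0.1), n = 5, t_input = 0)
  expect_equal(b0$T_k, 0)
})

test_that("per-step bit records are consistent with the counts", {
  set.seed(904)
  tr <- run_selection(decoder_config(k = 4, f0 = 0.2), binary_channel(0.2),
                      record = TRUE)
  obs <- tr$observed[[1]]
  expect_length(obs, tr$inputs)
  expect_equal(sum(obs == 0L), tr$n0)
  expect_equal(sum(obs == 1L), tr$n1)
  expect_length(tr$intended[[1]], tr$inputs)
})

test_that("rate grows with true noise for a matched decoder", {
  set.seed(905)
  res <- simulate_conditions(
    data.frame(k = 6, f0 = c(0.05, 0.15, 0.25)), n = 150
  )
  expect_true(all(diff(res$R_mean) > 0))
})

test_that("headroom is asymmetric: optimism explodes errors, pessimism costs rate", {
  set.seed(906)
  f <- 0.2
  matched <- run_batch(decoder_config(k = 8, f0 = f), binary_channel(f), n = 120)
  optimist <- run_batch(decoder_config(k = 8, f0 = 0.08), binary_channel(f), n = 120)
  pessimist <- run_batch(decoder_config(k = 8, f0 = 0.3), binary_channel(f), n = 120)
  expect_gt(optimist$e_k, matched$e_k + 0.1) # cliff edge
  expect_gt(pessimist$R_mean, matched$R_mean) # gentle rate penalty
  expect_lte(pessimist$e_k, matched$e_k + 0.05)
})

test_that("the input budget aborts pathological runs and flags them incorrect", {
  set.seed(907)
  cfg <- decoder_config(k = 6, f0 = 0.4)
  tr <- run_selection(cfg, binary_channel(0.4), budget = 3)
  expect_equal(tr$inputs, 3L)
  expect_true(tr$aborted)
  expect_false(tr$correct)
})

test_that("beta bisection finds the smallest sufficient confirmation overhead", {
  set.seed(908)
  # noise-free: already error-free at beta = 0
  cfg <- decoder_config(k = 4, f0 = 0)
  out <- bisect_beta(cfg, binary_channel(0), e_target = 0.01, n = 40)
  expect_equal(out$beta, 0)
  expect_true(out$converged)
  # noisy: returns a beta achieving the target, tight to ~tol
  cfg2 <- decoder_config(k = 6, f0 = 0.15)
  out2 <- bisect_beta(cfg2, binary_channel(0.15), e_target = 0.02, n = 250,
                      seed = 42)
  expect_true(out2$converged)
  expect_lte(out2$e_k, 0.02)
  expect_gt(out2$beta, 0.5) # beta = 0 sits near e_k ~ 0.06 at this noise
  # the search trace is consistent: error at the returned beta meets target
  expect_true(all(out2$trace$beta >= 0 & out2$trace$beta <= 16))
})

test_that("the closed-form error fit evaluates and vanishes for large beta", {
  expect_equal(predict_error_rate(0.15, 0),
               exp(-0.28 * 5.17) * 0.15 + exp(-1.19 * 2.57),
               tolerance = 1e-12)
  expect_lt(predict_error_rate(0.5, 40), 1e-4)
  expect_equal(predict_error_rate(0, 1e6), 0, tolerance = 1e-12)
})

test_that("simulated e_k tracks the closed-form fit at moderate noise", {
  set.seed(909)
  # scaled-down regression-quality audit of the log-linear fit
  for (case in list(c(0.1, 0), c(0.2, 2), c(0.15, 4))) {
    f <- case[1]
    beta <- case[2]
    b <- run_batch(decoder_config(k = 8, beta = beta, f0 = f),
                   binary_channel(f), n = 400)
    expect_close(b$e_k, predict_error_rate(f, beta), 0.06)
  }
})

test_that("change of heart recovers the switched target given enough confirmation", {
  set.seed(910)
  cfg <- decoder_config(k = 8, beta = 2, f0 = 0.25)
  out <- run_change_of_heart(cfg, binary_channel(0.15), lambda = 0.5,
                             x_delta = 0.25, n = 120)
  expect_gt(out$acquired_frac, 0.9)
  # a late switch with no confirmation budget mostly fails
  cfg0 <- decoder_config(k = 8, beta = 0, f0 = 0.17)
  late <- run_change_of_heart(cfg0, binary_channel(0.15), lambda = 0.95,
                              x_delta = 0.25, n = 60)
  expect_lt(late$acquired_frac, out$acquired_frac)
})

test_that("diffused decoders decode independently with per-decoder correctness", {
  set.seed(911)
  cfg <- decoder_config(k = 4, beta = 1, f0 = 0.1)
  out <- run_batch_diffused(cfg, binary_channel(0.1), n_decoders = 3,
                            n_groups = 8)
  expect_equal(nrow(out), 24)
  expect_true(all(out$inputs >= 4))
  expect_gt(mean(out$correct), 0.7)
  # interleaving spreads a bursty channel's errors across decoders
  ge <- gilbert_elliott_channel(0.15, t = 12)
  out_ge <- run_batch_diffused(cfg, ge, n_decoders = 4, n_groups = 6)
  expect_equal(nrow(out_ge), 24)
})

test_that("scenario evaluation wires bisection, batches and timing together", {
  set.seed(912)
  spec <- scenario_presets("B")[1, ]
  out <- evaluate_scenario(spec, n = 120)
  expect_equal(out$beta, 0)
  expect_equal(out$T_k, out$R_mean * 10 * 0.5)
  expect_true(out$R_mean > 3 && out$R_mean < 5)
  # bisected beta is cached across cases of the same scenario
  specA <- scenario_presets("A")
  outA <- evaluate_scenario(specA, n = 80, n_bisect = 80)
  expect_equal(outA$beta[1], outA$beta[2])
  expect_gt(outA$R_mean[2], outA$R_mean[1]) # degraded channel costs rate
})
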