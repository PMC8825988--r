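# Reference frequencies, closest-pair differences, normalized
# distributions.

test_that("reference frequency is the mean and sd of echo CF2", {
  ec <- data.frame(channel_bat_id = "b1", cf2 = rep(68500, 12))
  rf <- reference_frequency(ec)
  expect_equal(rf$mean_cf2, 68500)
  expect_equal(rf$sd_cf2, 0)
  expect_equal(rf$n_echoes, 12L)
  expect_false(rf$flagged)

  rf0 <- reference_frequency(data.frame(channel_bat_id = character(0),
                                        cf2 = numeric(0)), bat_id = "b9")
  expect_true(rf0$flagged)
  expect_true(is.na(rf0$mean_cf2))
})

test_that("a full-DSC flight holds the echo spread below one CF2 bin", {
  sim <- sim_single()
  ev <- sim$analysis$events
  rf <- reference_frequency(ev[ev$kind == "own_echo", ])
  expect_lte(rf$sd_cf2, 500000 / 16384)
  # and lands on the bat's true reference frequency
  expect_lt(abs(rf$mean_cf2 - sim$scene$profiles[[1]]$reference_frequency),
            500000 / 16384)
})

test_that("without compensation the echo spread widens", {
  pr_off <- vocal_profile(compensation_gain = 0)
  sc <- simulation_scene("narrow", n_bats = 1, duration_s = 5, seed = 3,
                         profiles = list(pr_off))
  sim <- simulate_scene(sc)
  aa <- analyze_audio(sim$waveforms, sc$sample_rate)
  ev <- aa$events
  rf_off <- reference_frequency(ev[ev$kind == "own_echo", ])
  sim_on <- sim_single()
  rf_on <- reference_frequency(
    sim_on$analysis$events[sim_on$analysis$events$kind == "own_echo", ])
  expect_gt(rf_off$sd_cf2, rf_on$sd_cf2)
  expect_gt(rf_off$sd_cf2, 100)   # uncompensated Doppler spreads widely
})

test_that("delta RF finds the closest pair", {
  rfs <- data.frame(bat_id = c("b1", "b2", "b3"),
                    mean_cf2 = c(68000, 68400, 69500))
  d <- delta_rf(rfs)
  expect_equal(d$delta_rf, 400)
  expect_setequal(d$pair, c("b1", "b2"))
  expect_equal(d$per_bat$delta_signed[d$per_bat$bat_id == "b1"], 400)

  # identical reference frequencies: zero difference
  d0 <- delta_rf(data.frame(bat_id = c("a", "b", "c"),
                            mean_cf2 = rep(68500, 3)))
  expect_equal(d0$delta_rf, 0)

  # two bats: their plain difference
  d2 <- delta_rf(data.frame(bat_id = c("a", "b"),
                            mean_cf2 = c(68000, 68250)))
  expect_equal(d2$delta_rf, 250)

  expect_error(delta_rf(data.frame(bat_id = "a", mean_cf2 = 68000)),
               "at least two")
})

test_that("delta RF is invariant to bat ordering", {
  rfs <- data.frame(bat_id = c("b1", "b2", "b3"),
                    mean_cf2 = c(68000, 68400, 69500))
  d1 <- delta_rf(rfs)
  d2 <- delta_rf(rfs[c(3, 1, 2), ])
  expect_equal(d1$delta_rf, d2$delta_rf)
  expect_setequal(d1$pair, d2$pair)
})

test_that("normalization centres own echoes at zero by construction", {
  sim <- sim_single()
  ev <- sim$analysis$events
  echo_cf2 <- ev$cf2[ev$kind == "own_echo"]
  rf <- mean(echo_cf2)
  nh <- normalize_and_histogram(echo_cf2, numeric(0), rf)
  own <- nh$samples$value[nh$samples$source == "own_echo"]
  expect_equal(mean(own), 0, tolerance = 1e-9)      # definitional identity
  expect_gte(mean(abs(own) < 100), 0.95)            # closed-loop property
  # empty estimates: zero-count histogram, no error
  expect_equal(nrow(nh$estimate_hist), 0L)
  expect_equal(nh$spread$n[2], 0L)
})
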