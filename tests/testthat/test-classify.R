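# Cross-channel event classification and spectral own-echo recovery.

test_that("group-scene classification agrees with ground truth for strong events", {
  sim <- sim_group()
  ev <- label_events_with_truth(sim$analysis$events, sim$arrivals)
  strong <- !is.na(ev$true_source) & ev$level_abs > -30 &
    ev$kind != "unknown"
  expect_gt(sum(strong), 100)
  expect_gte(mean(ev$kind[strong] == ev$true_source[strong]), 0.95)
})

test_that("a lone bat never yields other-pulse labels", {
  sim <- sim_single()
  expect_false("other_pulse" %in% sim$analysis$events$kind)
})

test_that("echo extraction can be disabled via the echo window", {
  sim <- sim_single()
  det <- list(bat01 = detect_events(sim$waveforms[[1]],
                                    sim$scene$sample_rate,
                                    channel_bat_id = "bat01"))
  ev <- classify_events(det, sim$waveforms, sim$scene$sample_rate,
                        echo_window_ms = c(0, 0))
  expect_false("own_echo" %in% ev$kind)
})

test_that("missing synchronization offsets are an error", {
  sim <- sim_single()
  det <- list(bat01 = detect_events(sim$waveforms[[1]],
                                    sim$scene$sample_rate,
                                    channel_bat_id = "bat01"))
  expect_error(
    classify_events(det, sim$waveforms, sim$scene$sample_rate,
                    offsets_s = c(other = 0)),
    "offsets missing")
})

test_that("no own echo precedes its channel's first focal pulse", {
  for (sim in list(sim_single(), sim_group())) {
    ev <- sim$analysis$events
    for (ch in unique(ev$channel_bat_id)) {
      e <- ev[ev$channel_bat_id == ch, ]
      first_fp <- min(e$onset[e$kind == "focal_pulse"])
      echoes <- e$onset[e$kind == "own_echo"]
      if (length(echoes)) expect_true(all(echoes > first_fp))
    }
  }
})

test_that("recovered echo frequencies sit within a bin of the rendered echoes", {
  sim <- sim_single()
  ev <- label_events_with_truth(sim$analysis$events, sim$arrivals)
  ec <- ev[ev$kind == "own_echo" & !is.na(ev$true_cf2), ]
  expect_gt(nrow(ec), 40)
  expect_gte(mean(abs(ec$cf2 - ec$true_cf2) < 500000 / 16384), 0.95)
})
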