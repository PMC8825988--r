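# Acoustic rendering: waveform contract, ground-truth Doppler bookkeeping,
# amplitude model.

test_that("waveforms have exactly duration x sample_rate samples", {
  sim <- sim_single()
  n_exp <- round(sim$scene$duration_s * sim$scene$sample_rate)
  for (w in sim$waveforms) expect_length(w, n_exp)
})

test_that("ground-truth echo frequencies follow two-way Doppler exactly", {
  sim <- sim_single()
  gt <- sim$arrivals
  sch <- sim$schedule
  ec <- gt[gt$source == "own_echo", ]
  m <- match(ec$pulse_id, sch$pulse_id)
  expect_equal(ec$cf2_arrival,
               sch$cf2_emit[m] * doppler_two_way(sch$closing_speed[m]),
               tolerance = 1e-9)
  # echo delay equals the two-way wall distance over C, within one sample
  expect_equal(ec$t_arrival - sch$t_emit[m],
               2 * sch$wall_distance_m[m] / 343.5,
               tolerance = 1 / sim$scene$sample_rate)
  # every arrival maps to an emitted pulse and arrives after emission
  expect_true(all(gt$t_arrival >= sch$t_emit[match(gt$pulse_id, sch$pulse_id)]))
})

test_that("disabling wall reflections leaves only own pulses on a lone bat's channel", {
  sc <- simulation_scene("narrow", n_bats = 1, duration_s = 3, seed = 5,
                         wall_loss_db = Inf)
  sim <- simulate_scene(sc)
  expect_setequal(unique(sim$arrivals$source), "own_pulse")
})

test_that("rendering is deterministic under a fixed seed", {
  sc <- simulation_scene("narrow", n_bats = 2, duration_s = 2, seed = 23)
  s1 <- simulate_scene(sc)
  s2 <- simulate_scene(sc)
  expect_identical(s1$waveforms, s2$waveforms)
  expect_identical(s1$arrivals, s2$arrivals)
})

test_that("arrivals past the waveform end are truncated with a warning", {
  sc <- simulation_scene("narrow", n_bats = 1, duration_s = 2, seed = 5)
  tr <- simulate_trajectories(sc)
  sch <- simulate_vocalizations(sc, tr)
  sch$t_emit[nrow(sch)] <- sc$duration_s - 0.005   # pulse overruns the end
  expect_warning(render_telemetry_waveforms(sc, tr, sch), "truncated")
})

test_that("conspecific arrivals carry one-way Doppler consistent with geometry", {
  sim <- sim_group()
  gt <- sim$arrivals
  ot <- gt[gt$source == "other_pulse", ]
  sch <- sim$schedule
  key <- paste(sch$bat_id, sch$pulse_id)
  m <- match(paste(ot$emitter, ot$pulse_id), key)
  ratio <- ot$cf2_arrival / sch$cf2_emit[m]
  # shifts are bounded by the worst-case closing speed of two 3 m/s bats
  expect_true(all(ratio > (343.5 - 6) / 343.5 & ratio < 343.5 / (343.5 - 6)))
  # and are not systematically one-sided
  expect_gt(sum(ratio > 1), 50)
  expect_gt(sum(ratio < 1), 50)
})
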