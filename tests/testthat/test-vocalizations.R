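# Sonar-sound-group schedules and their DSC-governed emitted frequencies.

test_that("fixed inter-group intervals give exactly the configured silent times", {
  pr <- vocal_profile(pulses_per_group_probs = c(`1` = 1),
                      inter_group_interval_ms = c(52, 0),
                      intra_group_interval_ms = c(20, 0))
  sc <- simulation_scene("narrow", n_bats = 1, duration_s = 8, seed = 4,
                         profiles = list(pr))
  tr <- simulate_trajectories(sc)
  sch <- simulate_vocalizations(sc, tr)
  # single-pulse groups: every offset->onset gap is the 52 ms silent time
  gaps <- diff(sch$t_emit) - pr$pulse_duration_ms / 1000
  expect_true(all(abs(gaps - 0.052) < 1e-9))
})

test_that("doublet groups alternate intra- and inter-group gaps", {
  pr <- vocal_profile(pulses_per_group_probs = c(`2` = 1),
                      inter_group_interval_ms = c(52, 0),
                      intra_group_interval_ms = c(20, 0))
  sc <- simulation_scene("narrow", n_bats = 1, duration_s = 8, seed = 4,
                         profiles = list(pr))
  sch <- simulate_vocalizations(sc, simulate_trajectories(sc))
  gaps <- (diff(sch$t_emit) - pr$pulse_duration_ms / 1000) * 1000
  odd <- gaps[seq(1, length(gaps), by = 2)]     # within-group gaps
  even <- gaps[seq(2, length(gaps), by = 2)]    # between-group gaps
  expect_true(all(abs(odd - 20) < 1e-6))
  expect_true(all(abs(even - 52) < 1e-6))
  expect_true(all(diff(sch$group_id) %in% c(0L, 1L)))
})

test_that("schedules are deterministic under a fixed seed", {
  sc <- simulation_scene("narrow", n_bats = 2, duration_s = 5, seed = 17)
  tr <- simulate_trajectories(sc)
  expect_identical(simulate_vocalizations(sc, tr),
                   simulate_vocalizations(sc, tr))
})

test_that("emitted CF2 implements full DSC toward the wall ahead", {
  sim <- sim_single()
  sch <- sim$schedule
  pr <- sim$scene$profiles[[1]]
  # emitted = RF (C - v)/(C + v): echo off the approached wall returns at RF
  expect_equal(sch$cf2_emit,
               pr$reference_frequency *
                 (343.5 - sch$closing_speed) / (343.5 + sch$closing_speed),
               tolerance = 1e-9)
  echo_cf2 <- sch$cf2_emit * doppler_two_way(sch$closing_speed)
  expect_true(all(abs(echo_cf2 - pr$reference_frequency) < 0.01))
})
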