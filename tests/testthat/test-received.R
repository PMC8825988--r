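# Trajectory-based estimates of the frequencies at which each bat hears
# its group mates.

test_that("a lone bat yields an empty estimate table", {
  sim <- sim_single()
  sm <- list(bat01 = fit_polynomials(sim$trajectories[[1]]))
  fp <- sim$analysis$events
  fp <- fp[fp$kind == "focal_pulse", ]
  fp$t_emit <- fp$core_onset
  rec <- estimate_received_series(fp, sm)
  expect_equal(nrow(rec), 0L)
})

test_that("every ordered pair contributes one estimate per emitted pulse", {
  sim <- sim_group()
  sm <- lapply(sim$trajectories, fit_polynomials)
  pulses <- data.frame(channel_bat_id = sim$schedule$bat_id,
                       t_emit = sim$schedule$t_emit,
                       cf2 = sim$schedule$cf2_emit)
  rec <- estimate_received_series(pulses, sm)
  n_skip <- attr(rec, "n_skipped")
  expect_equal(nrow(rec) + n_skip, 2L * nrow(pulses))
  expect_equal(sort(unique(paste(rec$listener, rec$emitter))),
               sort(as.vector(outer(sim$scene$bat_ids, sim$scene$bat_ids,
                                    function(a, b) ifelse(a == b, NA,
                                                          paste(a, b)))
                              [!diag(3) == 1])))
})

test_that("signed-mode estimates match rendered arrivals within one CF2 bin", {
  sim <- sim_group()
  sm <- lapply(sim$trajectories, fit_polynomials, segment_len_s = 1.25)
  ev <- sim$analysis$events
  pulses <- ev[ev$kind == "focal_pulse" & !is.na(ev$cf2), ]
  pulses$t_emit <- pulses$core_onset
  rec <- estimate_received_series(pulses, sm, mode = "signed",
                                  sub_frame = TRUE, velocity = "exact3d")
  scored <- received_errors_vs_truth(rec, sim$arrivals)
  expect_gt(nrow(scored), 500)
  expect_gte(mean(abs(scored$error) <= 500000 / 16384), 0.95)
})

test_that("the published magnitude mode only ever up-shifts", {
  sim <- sim_group()
  sm <- lapply(sim$trajectories, fit_polynomials)
  pulses <- data.frame(channel_bat_id = sim$schedule$bat_id,
                       t_emit = sim$schedule$t_emit,
                       cf2 = sim$schedule$cf2_emit)
  rec <- estimate_received_series(pulses, sm, mode = "as_printed")
  expect_true(all(rec$cf2_ba >= rec$cf2_b))
  expect_identical(unique(rec$mode), "as_printed")
})

test_that("pulses outside trajectory coverage are skipped, not errors", {
  sim <- sim_group()
  sm <- lapply(sim$trajectories, fit_polynomials)
  pulses <- data.frame(channel_bat_id = "bat01",
                       t_emit = c(0.005, 1e6), cf2 = c(68500, 68500))
  rec <- estimate_received_series(pulses, sm)
  expect_equal(attr(rec, "n_skipped"), 4L)   # 2 listeners x 2 bad pulses
})
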