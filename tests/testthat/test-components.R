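# Terminal/initial FM measurement and pulse duration.

test_that("tFM bandwidth and duration are recovered across seeded pulses", {
  set.seed(5)
  n_cases <- 40
  bw_err <- dur_err <- pd_err <- numeric(n_cases)
  for (k in seq_len(n_cases)) {
    bw <- runif(1, 10000, 20000)
    td <- runif(1, 1.5, 3)
    pd <- runif(1, 20, 27)
    cf2 <- runif(1, 68000, 69200)
    se <- synth_event(cf2 = cf2, duration_ms = pd, tfm_duration_ms = td,
                      tfm_bandwidth_hz = bw, ifm = runif(1) < 0.5)
    mc <- measure_components(se$event, se$wave, se$fs)
    bw_err[k] <- mc$tfm_bandwidth - bw
    dur_err[k] <- mc$tfm_duration - td
    pd_err[k] <- mc$pulse_duration - pd
  }
  expect_lt(median(abs(bw_err)), 500)
  expect_lt(median(abs(dur_err)), 0.2)
  expect_lt(median(abs(pd_err)), 0.2)
  # and the large majority of individual pulses stay within tolerance
  expect_gt(mean(abs(bw_err) < 500), 0.8)
  expect_gt(mean(abs(dur_err) < 0.2), 0.8)
})

test_that("a pulse without a terminal sweep reports zero tFM and a flag", {
  se <- synth_event(tfm_duration_ms = 0, tfm_bandwidth_hz = 0, ifm = FALSE)
  mc <- measure_components(se$event, se$wave, se$fs)
  expect_equal(mc$tfm_duration, 0)
  expect_equal(mc$tfm_bandwidth, 0)
  expect_identical(mc$flag, "no_tfm")
})

test_that("iFM detection follows the synthesized component", {
  se_no <- synth_event(ifm = FALSE)
  expect_false(measure_components(se_no$event, se_no$wave, se_no$fs)$ifm_detected)
  se_yes <- synth_event(ifm = TRUE, ifm_bandwidth_hz = 10000,
                        ifm_duration_ms = 1.5)
  expect_true(measure_components(se_yes$event, se_yes$wave, se_yes$fs)$ifm_detected)
})

test_that("simulator focal pulses recover the profile's component values", {
  sim <- sim_single()
  pr <- sim$scene$profiles[[1]]
  fp <- sim$analysis$events[sim$analysis$events$kind == "focal_pulse", ]
  expect_lt(median(abs(fp$tfm_bandwidth - pr$tfm_bandwidth_hz), na.rm = TRUE), 500)
  expect_lt(median(abs(fp$tfm_duration - pr$tfm_duration_ms), na.rm = TRUE), 0.2)
  expect_lt(median(abs(fp$pulse_duration - pr$pulse_duration_ms), na.rm = TRUE), 0.2)
})
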