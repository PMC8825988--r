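# Envelope detection and the spectrogram front end.

test_that("spectrogram localizes tones and sweeps", {
  fs <- 500000
  tone <- sin(2 * pi * 68000 * (1:25000) / fs)
  sg <- spectrogram(tone, fs)
  ridge <- sg$freq[apply(sg$mag, 2, which.max)]
  expect_true(all(abs(ridge - 68000) <= sg$df))

  # silence: nothing above an absolute floor
  sg0 <- spectrogram(numeric(4096), fs)
  expect_true(all(sg0$mag < 1e-12))

  # linear 80 -> 66 kHz sweep over 2 ms: ridge slope -7 kHz/ms
  n <- round(0.002 * fs)
  f <- seq(80000, 66000, length.out = n)
  sweep <- sin(2 * pi * cumsum(f) / fs)
  sgs <- spectrogram(c(numeric(500), sweep, numeric(500)), fs,
                     window_len = 256, overlap = 0.75)
  rd <- sonarjam:::ridge_track(sgs, band = c(40000, 120000))
  ok <- !is.na(rd$f) & rd$level_db > -10
  fit <- stats::lm(rd$f[ok] ~ rd$t[ok])
  expect_lt(abs(coef(fit)[2] / 1e6 - (-7)), 1.2)   # kHz/ms, +- bin effects

  expect_error(spectrogram(numeric(100), fs, window_len = 1024), "longer")
})

test_that("every rendered pulse is detected on a clean channel", {
  sim <- sim_single()
  det <- detect_events(sim$waveforms[[1]], sim$scene$sample_rate,
                       channel_bat_id = "bat01")
  expect_equal(nrow(det), nrow(sim$schedule))
  # onsets align with the schedule to sub-millisecond accuracy
  expect_lt(max(abs(sort(det$onset) - sort(sim$schedule$t_emit))), 1e-3)
})

test_that("pure noise yields no events", {
  set.seed(1)
  det <- detect_events(rnorm(500000, 0, 1e-4), 500000)
  expect_equal(nrow(det), 0L)
})

test_that("events separated by less than the merge gap fuse into one", {
  fs <- 500000
  burst <- sin(2 * pi * 68000 * (1:2500) / fs)       # 5 ms tone
  gap <- numeric(round(0.0005 * fs))                 # 0.5 ms apart
  w <- c(numeric(5000), burst, gap, burst, numeric(5000))
  det <- detect_events(w, fs, min_dur_ms = 3)
  expect_equal(nrow(det), 1L)

  gap2 <- numeric(round(0.004 * fs))                 # 4 ms apart
  w2 <- c(numeric(5000), burst, gap2, burst, numeric(5000))
  expect_equal(nrow(detect_events(w2, fs, min_dur_ms = 3)), 2L)
})
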