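# Shared simulated fixtures, built once per test run and cached.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .scene_cache)) {
    assign(name, builder(), envir = .scene_cache)
  }
  get(name, envir = .scene_cache)
}

# clean single-bat narrow-space flight: the closed-loop DSC fixture
sim_single <- function() cached("sim_single", function() {
  sc <- simulation_scene("narrow", n_bats = 1, duration_s = 5, seed = 3)
  sim <- simulate_scene(sc)
  sim$analysis <- analyze_audio(sim$waveforms, sc$sample_rate)
  sim
})

# three-bat narrow-space group flight: classification / received-frequency
# fixture
sim_group <- function() cached("sim_group", function() {
  sc <- simulation_scene("narrow", n_bats = 3, duration_s = 10, seed = 7)
  sim <- simulate_scene(sc)
  sim$analysis <- analyze_audio(sim$waveforms, sc$sample_rate)
  sim
})

# a single synthesized CF-FM pulse wrapped as a detected event
synth_event <- function(fs = 500000, cf2 = 68500, duration_ms = 24,
                        tfm_duration_ms = 2, tfm_bandwidth_hz = 16000,
                        ifm = TRUE, ifm_duration_ms = 1,
                        ifm_bandwidth_hz = 8000, pad_s = 0.005, ...) {
  w <- sonarjam:::synth_cf_fm_pulse(fs, cf2, duration_ms, tfm_duration_ms,
                         tfm_bandwidth_hz, ifm, ifm_duration_ms,
                         ifm_bandwidth_hz, ...)
  wave <- c(numeric(round(pad_s * fs)), w, numeric(round(pad_s * fs)))
  ev <- data.frame(channel_bat_id = "b", onset = pad_s,
                   offset = pad_s + duration_ms / 1000,
                   core_onset = pad_s, core_offset = pad_s + duration_ms / 1000,
                   kind = "focal_pulse", peak_level = 0)
  list(wave = wave, event = ev, fs = fs)
}
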