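# CF-FM pulse synthesis and per-channel telemetry rendering.
#
# A pulse is synthesized as a phase-continuous frequency trajectory of the
# fundamental: linear iFM up-sweep -> CF plateau at cf2/2 -> linear tFM
# down-sweep; harmonics are summed with the configured levels (CF2
# dominant). Doppler on an arrival scales the whole frequency trajectory by
# the arrival/emission frequency ratio.

synth_cf_fm_pulse <- function(fs, cf2, duration_ms, tfm_duration_ms,
                              tfm_bandwidth_hz, ifm, ifm_duration_ms,
                              ifm_bandwidth_hz, harmonics = c(`1` = -20, `2` = 0),
                              doppler_factor = 1, taper_ms = 0.2,
                              phase0 = 0) {
  n <- round(duration_ms / 1000 * fs)
  t <- seq_len(n) / fs
  f2 <- rep(cf2, n)                       # CF2 (second harmonic) trajectory
  if (ifm && ifm_duration_ms > 0) {
    ni <- round(ifm_duration_ms / 1000 * fs)
    ni <- min(ni, n)
    f2[seq_len(ni)] <- cf2 - ifm_bandwidth_hz * (1 - (seq_len(ni) - 1) / ni)
  }
  if (tfm_duration_ms > 0) {
    nt <- round(tfm_duration_ms / 1000 * fs)
    nt <- min(nt, n)
    idx <- (n - nt + 1L):n
    f2[idx] <- cf2 - tfm_bandwidth_hz * (seq_len(nt) / nt)
  }
  f1 <- f2 / 2 * doppler_factor           # Doppler scales every harmonic
  phase <- phase0 + 2 * pi * cumsum(f1) / fs
  wave <- numeric(n)
  for (h in names(harmonics))
    wave <- wave + db_to_amp(harmonics[[h]]) * sin(as.numeric(h) * phase)
  wave <- wave / sum(db_to_amp(unlist(harmonics)))   # unit peak envelope
  nr <- max(2L, round(taper_ms / 1000 * fs))
  if (2L * nr < n) {                       # raised-cosine onset/offset ramps
    ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    wave[seq_len(nr)] <- wave[seq_len(nr)] * ramp
    wave[(n - nr + 1L):n] <- wave[(n - nr + 1L):n] * rev(ramp)
  }
  wave
}

#' Render per-bat telemetry-microphone waveforms
#'
#' Builds, for each bat's animal-borne microphone channel: the bat's own
#' pulses at full level; its own first-order wall echoes (image source off
#' the wall it is flying toward) delayed by the two-way travel time,
#' up-shifted by the two-way Doppler factor and attenuated by spherical
#' spreading plus a flat wall-reflection loss; and the other bats' pulses
#' with one-way Doppler set by the instantaneous radial velocity between
#' the pair at emission and 1/r spreading loss. Every rendered arrival is
#' logged in the ground-truth table, the oracle for all recovery tests.
#'
#' @param scene A [simulation_scene()].
#' @param trajectories From [simulate_trajectories()].
#' @param schedule From [simulate_vocalizations()].
#' @return List with \code{waveforms} (list of numeric vectors, one per
#'   bat, exactly \code{duration_s * sample_rate} samples), \code{emitted}
#'   (the schedule) and \code{arrivals}: data frame with \code{channel},
#'   \code{source} (\code{own_pulse}/\code{own_echo}/\code{other_pulse}),
#'   \code{emitter}, \code{pulse_id}, \code{t_arrival} (s),
#'   \code{cf2_arrival} (Hz), \code{level_db} (re the full pulse level),
#'   \code{wall}.
#' @export
render_telemetry_waveforms <- function(scene, trajectories, schedule) {
  stopifnot(inherits(scene, "simulation_scene"))
  fs <- scene$sample_rate
  n_samp <- round(scene$duration_s * fs)
  C <- scene$sound_speed
  r0 <- 0.1                               # reference distance for 1/r, m
  waves <- lapply(seq_len(scene$n_bats), function(i) numeric(n_samp))
  names(waves) <- scene$bat_ids
  arr <- vector("list", 1000L); na <- 0L
  truncated <- 0L

  add_arrival <- function(ch, wave_pulse, t_arr, rec) {
    k0 <- round(t_arr * fs) + 1L
    if (k0 > n_samp) { truncated <<- truncated + 1L; return(invisible()) }
    k1 <- min(k0 + length(wave_pulse) - 1L, n_samp)
    if (k1 < k0 + length(wave_pulse) - 1L) truncated <<- truncated + 1L
    waves[[ch]][k0:k1] <<- waves[[ch]][k0:k1] + wave_pulse[seq_len(k1 - k0 + 1L)]
    na <<- na + 1L
    arr[[na]] <<- rec
    invisible()
  }

  phases <- with_seed(stage_seed(scene$seed, "render"),
                      stats::runif(nrow(schedule), 0, 2 * pi))
  for (r in seq_len(nrow(schedule))) {
    p <- schedule[r, ]
    i <- match(p$bat_id, scene$bat_ids)
    base_args <- list(fs = fs, cf2 = p$cf2_emit, duration_ms = p$duration_ms,
                      tfm_duration_ms = p$tfm_duration_ms,
                      tfm_bandwidth_hz = p$tfm_bandwidth_hz, ifm = p$ifm,
                      ifm_duration_ms = p$ifm_duration_ms,
                      ifm_bandwidth_hz = p$ifm_bandwidth_hz,
                      harmonics = scene$harmonics, phase0 = phases[r])

    # own pulse, full level
    w <- do.call(synth_cf_fm_pulse, c(base_args, doppler_factor = 1))
    add_arrival(i, w, p$t_emit, data.frame(
      channel = p$bat_id, source = "own_pulse", emitter = p$bat_id,
      pulse_id = p$pulse_id, t_arrival = p$t_emit, cf2_arrival = p$cf2_emit,
      level_db = 0, wall = NA_character_))

    # first-order wall echo
    if (is.finite(scene$wall_loss_db) && p$wall != "none") {
      dfac <- doppler_two_way(p$closing_speed, C)
      amp <- db_to_amp(-scene$wall_loss_db) * r0 / pmax(2 * p$wall_distance_m, r0)
      we <- do.call(synth_cf_fm_pulse, c(base_args, doppler_factor = dfac))
      add_arrival(i, amp * we, p$t_emit + 2 * p$wall_distance_m / C, data.frame(
        channel = p$bat_id, source = "own_echo", emitter = p$bat_id,
        pulse_id = p$pulse_id, t_arrival = p$t_emit + 2 * p$wall_distance_m / C,
        cf2_arrival = p$cf2_emit * dfac, level_db = amp_to_db(amp),
        wall = p$wall))
    }

    # conspecific arrivals on every other channel
    if (scene$n_bats > 1L) {
      sb <- fine_state(trajectories[[i]], p$t_emit)
      for (j in setdiff(seq_len(scene$n_bats), i)) {
        sa <- fine_state(trajectories[[j]], p$t_emit)
        d <- c(sb$x - sa$x, sb$y - sa$y, sb$z - sa$z)   # listener -> emitter
        r_ab <- sqrt(sum(d^2)); u <- d / r_ab
        dfac <- doppler_one_way(
          v_listener_along = sum(c(sa$vx, sa$vy, sa$vz) * u),
          v_emitter_along = sum(c(sb$vx, sb$vy, sb$vz) * u), C)
        amp <- db_to_amp(scene$conspecific_pickup_db) * r0 / pmax(r_ab, r0)
        wo <- do.call(synth_cf_fm_pulse, c(base_args, doppler_factor = dfac))
        add_arrival(j, amp * wo, p$t_emit + r_ab / C, data.frame(
          channel = scene$bat_ids[j], source = "other_pulse",
          emitter = p$bat_id, pulse_id = p$pulse_id,
          t_arrival = p$t_emit + r_ab / C, cf2_arrival = p$cf2_emit * dfac,
          level_db = amp_to_db(amp), wall = NA_character_))
      }
    }
  }
  if (truncated > 0L)
    warning(sprintf("%d arrival(s) extended beyond the waveform end and were truncated",
                    truncated), call. = FALSE)
  if (is.finite(scene$noise_db)) {
    noise <- with_seed(stage_seed(scene$seed, "noise"),
                       lapply(waves, function(w)
                         stats::rnorm(length(w), 0, db_to_amp(scene$noise_db))))
    waves <- Map(`+`, waves, noise)
  }
  list(waveforms = waves, emitted = schedule,
       arrivals = do.call(rbind, arr[seq_len(na)]))
}

#' Simulate a complete scene
#'
#' Convenience wrapper chaining [simulate_trajectories()],
#' [simulate_vocalizations()] and [render_telemetry_waveforms()].
#'
#' @param scene A [simulation_scene()].
#' @return List: \code{scene}, \code{trajectories}, \code{schedule},
#'   \code{waveforms}, \code{arrivals} (the ground truth).
#' @export
simulate_scene <- function(scene) {
  tr <- simulate_trajectories(scene)
  sch <- simulate_vocalizations(scene, tr)
  rd <- render_telemetry_waveforms(scene, tr, sch)
  list(scene = scene, trajectories = tr, schedule = sch,
       waveforms = rd$waveforms, arrivals = rd$arrivals)
}
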