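#' Per-bat vocal profile
#'
#' Describes one bat's CF-FM call repertoire and its Doppler-shift
#' compensation (DSC) behaviour. The emitted call is a long constant
#' frequency (CF) plateau whose dominant second harmonic (CF2, about
#' 68--70 kHz in Japanese horseshoe bats) is preceded by a brief upward
#' initial FM sweep (iFM, often weak or absent) and followed by a brief
#' downward terminal FM sweep (tFM). Pulses are emitted in sonar sound
#' groups: clusters with short intra-group intervals separated by longer
#' silent times.
#'
#' @param reference_frequency Individual reference frequency, Hz: the echo
#'   CF2 that full DSC holds constant.
#' @param pulse_duration_ms Total call duration, ms.
#' @param tfm_duration_ms,tfm_bandwidth_hz Terminal-FM sweep duration (ms)
#'   and its depth below CF2 (Hz).
#' @param ifm_duration_ms,ifm_bandwidth_hz Initial-FM sweep duration (ms)
#'   and rise toward CF2 (Hz).
#' @param ifm_present Probability that a given pulse carries a detectable
#'   iFM component.
#' @param pulses_per_group_probs Named numeric vector of probabilities over
#'   group sizes 1, 2, 3, ...
#' @param inter_group_interval_ms,intra_group_interval_ms Length-2 vectors
#'   \code{c(mean, sd)} in ms of the silent time between groups (offset of
#'   one group's last pulse to onset of the next group) and of the
#'   interpulse gap within a group.
#' @param source_level_rolloff_db Level of the fundamental (CF1) relative to
#'   CF2 in dB (CF2 is the dominant harmonic).
#' @param compensation_gain DSC gain in \code{[0, 1]}; 1 = full
#'   compensation, 0 = none (always emit at the reference frequency).
#' @return An object of class \code{"vocal_profile"}.
#' @export
vocal_profile <- function(reference_frequency = 68500,
                          pulse_duration_ms = 24,
                          tfm_duration_ms = 2.0,
                          tfm_bandwidth_hz = 16000,
                          ifm_duration_ms = 1.0,
                          ifm_bandwidth_hz = 8000,
                          ifm_present = 0.7,
                          pulses_per_group_probs = c(`1` = 0.4, `2` = 0.45,
                                                     `3` = 0.15),
                          inter_group_interval_ms = c(52, 5),
                          intra_group_interval_ms = c(20, 3),
                          source_level_rolloff_db = -20,
                          compensation_gain = 1) {
  stopifnot_scalar(reference_frequency, "reference_frequency")
  stopifnot_scalar(pulse_duration_ms, "pulse_duration_ms")
  stopifnot_scalar(tfm_duration_ms, "tfm_duration_ms")
  stopifnot_scalar(tfm_bandwidth_hz, "tfm_bandwidth_hz")
  stopifnot_scalar(ifm_duration_ms, "ifm_duration_ms")
  stopifnot_scalar(ifm_bandwidth_hz, "ifm_bandwidth_hz")
  if (ifm_present < 0 || ifm_present > 1)
    stop("`ifm_present` is a probability", call. = FALSE)
  if (compensation_gain < 0 || compensation_gain > 1)
    stop("`compensation_gain` must lie in [0, 1]", call. = FALSE)
  if (tfm_duration_ms + ifm_duration_ms >= pulse_duration_ms)
    stop("FM components exceed the pulse duration", call. = FALSE)
  p <- pulses_per_group_probs / sum(pulses_per_group_probs)
  structure(list(
    reference_frequency = reference_frequency,
    pulse_duration_ms = pulse_duration_ms,
    tfm_duration_ms = tfm_duration_ms,
    tfm_bandwidth_hz = tfm_bandwidth_hz,
    ifm_duration_ms = ifm_duration_ms,
    ifm_bandwidth_hz = ifm_bandwidth_hz,
    ifm_present = ifm_present,
    pulses_per_group_probs = p,
    inter_group_interval_ms = inter_group_interval_ms,
    intra_group_interval_ms = intra_group_interval_ms,
    source_level_rolloff_db = source_level_rolloff_db,
    compensation_gain = compensation_gain
  ), class = "vocal_profile")
}

# chamber presets: the full experimental chamber and the two partitioned
# flight spaces (m)
chamber_presets <- list(
  full   = c(9, 4.5, 2.4),
  wide   = c(6, 4.5, 2.4),
  narrow = c(2, 4.5, 2.4)
)

default_speed_bands <- list(narrow = c(1.9, 2.5), wide = c(2.4, 3.0),
                            full = c(2.4, 3.0))

#' Define a group-flight simulation scene
#'
#' A scene bundles the flight-space geometry, the bats' kinematic and vocal
#' parameters, the acoustic constants and the RNG seed that fixes every
#' stochastic draw downstream (trajectories, vocalisation schedules,
#' waveform noise).
#'
#' @param preset Flight-space preset: \code{"narrow"} (2 x 4.5 x 2.4 m),
#'   \code{"wide"} (6 x 4.5 x 2.4 m) or \code{"full"} (9 x 4.5 x 2.4 m).
#'   Ignored if \code{chamber_dims} is given.
#' @param n_bats Number of bats (>= 1).
#' @param duration_s Flight duration, s.
#' @param seed Integer seed fixing all stochastic draws for this scene.
#' @param chamber_dims Optional explicit chamber dimensions, m (length 3).
#' @param frame_rate Trajectory frame rate, Hz.
#' @param sample_rate Audio sampling rate, Hz.
#' @param sound_speed Speed of sound in air, m/s (about 20 C air by
#'   default; exposed because every Doppler quantity depends on it).
#' @param speed_band Length-2 flight-speed band \code{c(lo, hi)} in m/s;
#'   per-bat cruise speeds are spaced across it (mean about 2.2 m/s in the
#'   narrow space, 2.7 m/s in the wide space by default). A degenerate band
#'   (\code{lo == hi}) produces constant-speed flight.
#' @param profiles Optional list of \code{n_bats} [vocal_profile()] objects.
#'   By default, per-bat reference frequencies are drawn uniformly within a
#'   1.2 kHz colony band centred on 68.6 kHz (individual differences in a
#'   colony span up to about 1.2 kHz) and other call parameters take the
#'   profile defaults.
#' @param wall_loss_db Level loss at each wall reflection, dB (>= 0).
#'   \code{Inf} disables wall echoes.
#' @param conspecific_pickup_db Extra reception loss applied to other bats'
#'   pulses on a listener's channel, dB (<= 0). The animal-borne telemetry
#'   microphone points into its carrier's own sound field; conspecific
#'   pulses arrive body-shadowed and off-axis, so they are recorded well
#'   below their free-field level (and in the real experiments were scarce
#'   enough that received conspecific frequencies had to be estimated from
#'   trajectories). \code{0} disables the loss.
#' @param noise_db RMS level of the additive microphone noise floor, dB
#'   relative to the full pulse amplitude; \code{-Inf} for noise-free.
#' @param harmonics Named numeric vector of harmonic levels in dB relative
#'   to CF2; names are harmonic numbers of the fundamental. Default:
#'   fundamental (CF1) at -20 dB, CF2 at 0 dB.
#' @return An object of class \code{"simulation_scene"}.
#' @examples
#' sc <- simulation_scene("narrow", n_bats = 3, duration_s = 10, seed = 7)
#' sc
#' @export
simulation_scene <- function(preset = c("narrow", "wide", "full"),
                             n_bats = 3, duration_s = 20, seed = 1,
                             chamber_dims = NULL, frame_rate = 30,
                             sample_rate = 500000, sound_speed = 343.5,
                             speed_band = NULL, profiles = NULL,
                             wall_loss_db = 6, conspecific_pickup_db = -25,
                             noise_db = -70,
                             harmonics = c(`1` = -20, `2` = 0)) {
  if (is.null(chamber_dims)) {
    preset <- match.arg(preset)
    chamber_dims <- chamber_presets[[preset]]
  } else {
    preset <- "custom"
    if (length(chamber_dims) != 3L || any(chamber_dims <= 0))
      stop("`chamber_dims` must be three positive lengths (m)", call. = FALSE)
  }
  if (n_bats < 1L) stop("`n_bats` must be >= 1", call. = FALSE)
  stopifnot_scalar(duration_s, "duration_s")
  stopifnot_scalar(frame_rate, "frame_rate")
  stopifnot_scalar(sample_rate, "sample_rate")
  stopifnot_scalar(sound_speed, "sound_speed")
  if (is.null(speed_band))
    speed_band <- default_speed_bands[[if (preset %in% names(default_speed_bands))
      preset else "full"]]
  if (length(speed_band) != 2L || speed_band[1] > speed_band[2] ||
      speed_band[1] <= 0)
    stop("`speed_band` must be c(lo, hi) with 0 < lo <= hi", call. = FALSE)
  if (is.null(profiles)) {
    profiles <- with_seed(stage_seed(seed, "profiles"), {
      rf <- stats::runif(n_bats, 68000, 69200)   # <= 1.2 kHz colony spread
      lapply(rf, function(f) vocal_profile(reference_frequency = f))
    })
  }
  if (length(profiles) != n_bats ||
      !all(vapply(profiles, inherits, TRUE, "vocal_profile")))
    stop("`profiles` must be a list of n_bats vocal_profile objects",
         call. = FALSE)
  # Nyquist guard for the highest synthesized harmonic of the highest RF
  hmax <- max(as.integer(names(harmonics)))
  fmax <- max(vapply(profiles, `[[`, 0, "reference_frequency")) / 2 * hmax * 1.1
  if (sample_rate <= 2 * fmax)
    stop("`sample_rate` must exceed twice the highest synthesized harmonic",
         call. = FALSE)
  structure(list(
    preset = preset, chamber_dims = chamber_dims, n_bats = as.integer(n_bats),
    duration_s = duration_s, frame_rate = frame_rate,
    sample_rate = sample_rate, sound_speed = sound_speed,
    seed = as.integer(seed), speed_band = speed_band, profiles = profiles,
    wall_loss_db = wall_loss_db,
    conspecific_pickup_db = conspecific_pickup_db,
    noise_db = noise_db, harmonics = harmonics,
    bat_ids = sprintf("bat%02d", seq_len(n_bats))
  ), class = "simulation_scene")
}

#' @exportS3Method base::print
print.simulation_scene <- function(x, ...) {
  cat(sprintf(
    "Simulation scene [%s]: %.1f x %.1f x %.1f m, %d bat(s), %.1f s, seed %d\n",
    x$preset, x$chamber_dims[1], x$chamber_dims[2], x$chamber_dims[3],
    x$n_bats, x$duration_s, x$seed))
  cat(sprintf("audio %g Hz, frames %g fps, C = %g m/s, speeds %.2f-%.2f m/s\n",
              x$sample_rate, x$frame_rate, x$sound_speed,
              x$speed_band[1], x$speed_band[2]))
  rf <- vapply(x$profiles, `[[`, 0, "reference_frequency")
  cat("reference frequencies (Hz):", paste(round(rf, 1), collapse = ", "), "\n")
  invisible(x)
}
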