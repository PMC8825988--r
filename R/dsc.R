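#' Doppler-shift-compensated emitted CF2
#'
#' Horseshoe bats lower the constant-frequency second harmonic (CF2) of their
#' emitted pulses while flying so that the two-way Doppler-shifted echo from
#' an object ahead returns at a fixed, individual-specific reference
#' frequency (the centre of the auditory fovea). With compensation gain
#' \code{g}, the emitted CF2 is
#' \deqn{f_e = RF \left(\frac{C - v}{C + v}\right)^g}
#' where \code{v} is the closing speed toward the reflector (positive when
#' approaching) and \code{C} the sound speed. \code{g = 1} is full
#' compensation: the echo, up-shifted by the two-way factor
#' \eqn{(C+v)/(C-v)}, returns exactly at \code{RF}. \code{g = 0} means the
#' bat emits at its reference frequency regardless of flight speed.
#'
#' @param reference_frequency Reference frequency in Hz (per bat).
#' @param closing_speed Closing speed toward the reflector in m/s; positive
#'   when approaching. Vectorised.
#' @param compensation_gain Compensation gain in \code{[0, 1]}.
#' @param sound_speed Speed of sound in air, m/s.
#' @return Emitted CF2 in Hz (vector matching \code{closing_speed}).
#' @examples
#' dsc_emitted_cf2(68500, 3, 1)                      # lowered when approaching
#' dsc_emitted_cf2(68500, 0, 1)                      # no motion: emits at RF
#' f <- dsc_emitted_cf2(68500, 3, 1)
#' f * doppler_two_way(3)                            # echo back at RF
#' @seealso [doppler_two_way()], [doppler_one_way()]
#' @export
dsc_emitted_cf2 <- function(reference_frequency, closing_speed,
                            compensation_gain = 1, sound_speed = 343.5) {
  stopifnot_scalar(reference_frequency, "reference_frequency")
  stopifnot_scalar(sound_speed, "sound_speed")
  if (compensation_gain < 0 || compensation_gain > 1)
    stop("`compensation_gain` must lie in [0, 1]", call. = FALSE)
  if (any(abs(closing_speed) >= sound_speed))
    stop("|closing_speed| must be below the sound speed", call. = FALSE)
  reference_frequency *
    ((sound_speed - closing_speed) / (sound_speed + closing_speed))^
      compensation_gain
}

#' Two-way Doppler factor for an echo from a stationary reflector
#'
#' A source approaching a stationary wall at closing speed \code{v} receives
#' its own echo up-shifted by \eqn{(C+v)/(C-v)}.
#'
#' @inheritParams dsc_emitted_cf2
#' @param closing_speed Closing speed toward the reflector, m/s (positive
#'   approaching).
#' @return Multiplicative frequency factor.
#' @export
doppler_two_way <- function(closing_speed, sound_speed = 343.5) {
  if (any(abs(closing_speed) >= sound_speed))
    stop("|closing_speed| must be below the sound speed", call. = FALSE)
  (sound_speed + closing_speed) / (sound_speed - closing_speed)
}

#' One-way Doppler factor between two moving bats
#'
#' Frequency factor for a pulse emitted by bat B and heard by bat A, both
#' moving: \eqn{(C + u_A)/(C + u_B)} where \eqn{u_A} is A's speed component
#' toward B and \eqn{u_B} is B's speed component away from A (both signed
#' projections on the unit vector from A to B).
#'
#' @param v_listener_along Listener velocity component along the
#'   listener-to-emitter unit vector, m/s.
#' @param v_emitter_along Emitter velocity component along the same unit
#'   vector, m/s.
#' @param sound_speed Speed of sound, m/s.
#' @return Multiplicative frequency factor (received / emitted).
#' @export
doppler_one_way <- function(v_listener_along, v_emitter_along,
                            sound_speed = 343.5) {
  if (any(abs(v_listener_along) >= sound_speed) ||
      any(abs(v_emitter_along) >= sound_speed))
    stop("speeds must be below the sound speed", call. = FALSE)
  (sound_speed + v_listener_along) / (sound_speed + v_emitter_along)
}
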