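#' Frame-wise flight directions from a smoothed trajectory
#'
#' Computes, for frames \code{n}, the azimuth \eqn{\theta} (x--y plane), the
#' inclination \eqn{\varphi} (x--z plane) and the speed of a bat from
#' backward finite differences of its polynomial-smoothed positions:
#' \eqn{\theta_n = \mathrm{atan2}(y_n - y_{n-1},\; x_n - x_{n-1})} and
#' \eqn{\varphi_n = \mathrm{atan2}(z_n - z_{n-1},\; x_n - x_{n-1})}. The
#' azimuth uses the full-quadrant inverse tangent (a ratio arctangent would
#' lose the heading quadrant, and the cosine-difference terms of the
#' relative-velocity decomposition make quadrants consequential). The
#' inclination \eqn{\varphi} is the ratio arctangent of the z-displacement
#' over the magnitude of the x-displacement, confined to
#' \eqn{(-\pi/2, \pi/2]}: the x-heading quadrant is already carried by
#' \eqn{\theta}, and a full-quadrant \eqn{\varphi} would double-count the
#' x-sign in the double-cosine decomposition of [relative_velocity()]
#' (motion along \eqn{-x} would come out with a spuriously positive
#' projection, breaking the planar identity with the vector oracle).
#'
#' @param smoothed A smoothed trajectory from [fit_polynomials()].
#' @param n Integer frame indices (0-based, as in the trajectory table);
#'   must be >= 1 so that frame \code{n - 1} exists. Defaults to all frames
#'   from 1.
#' @return A data frame with columns \code{bat_id}, \code{frame},
#'   \code{theta} (radians in \eqn{(-\pi, \pi]}), \code{phi} (radians in
#'   \eqn{(-\pi/2, \pi/2]}), \code{v} (m/s)
#'   and \code{degenerate} (TRUE where the displacement was exactly zero and
#'   the previous frame's direction was carried forward).
#' @export
flight_directions <- function(smoothed, n = NULL) {
  stopifnot(inherits(smoothed, "smoothed_trajectory"))
  fr <- smoothed$frame_rate
  if (is.null(n)) n <- seq.int(1L, smoothed$n_frames - 1L)
  if (any(n < 1L)) stop("frame indices must be >= 1", call. = FALSE)
  p1 <- predict(smoothed, frame = n)
  p0 <- predict(smoothed, frame = n - 1L)
  dx <- p1$x - p0$x; dy <- p1$y - p0$y; dz <- p1$z - p0$z
  theta <- atan2(dy, dx)
  phi <- atan2(dz, abs(dx))
  v <- sqrt(dx^2 + dy^2 + dz^2) * fr
  degen <- dx == 0 & dy == 0 & dz == 0
  if (any(degen)) {
    for (i in which(degen)) {           # carry forward previous direction
      if (i > 1L) { theta[i] <- theta[i - 1L]; phi[i] <- phi[i - 1L] }
    }
  }
  data.frame(bat_id = smoothed$bat_id, frame = n, theta = theta, phi = phi,
             v = v, degenerate = degen)
}

#' Inter-bat bearing angles and separation
#'
#' Bearings from a focal listener A to an emitter B at given frames:
#' \eqn{\theta_{AB} = \mathrm{atan2}(y_B - y_A,\; x_B - x_A)},
#' \eqn{\varphi_{AB} = \mathrm{atan2}(z_B - z_A,\; x_B - x_A)}, plus the
#' Euclidean separation. Swapping the pair flips the bearing by \eqn{\pi}
#' (mod \eqn{2\pi}).
#'
#' @param smoothed_a,smoothed_b Smoothed trajectories ([fit_polynomials()])
#'   of listener A and emitter B.
#' @param n Integer frame indices (0-based); default all common frames.
#' @return Data frame with \code{frame}, \code{theta_ab}, \code{phi_ab}
#'   (radians), \code{separation} (m).
#' @export
inter_bat_geometry <- function(smoothed_a, smoothed_b, n = NULL) {
  stopifnot(inherits(smoothed_a, "smoothed_trajectory"),
            inherits(smoothed_b, "smoothed_trajectory"))
  if (is.null(n)) n <- seq.int(0L, min(smoothed_a$n_frames,
                                       smoothed_b$n_frames) - 1L)
  pa <- predict(smoothed_a, frame = n)
  pb <- predict(smoothed_b, frame = n)
  dx <- pb$x - pa$x; dy <- pb$y - pa$y; dz <- pb$z - pa$z
  sep <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(sep == 0))
    stop("coincident positions: bearing undefined at frame(s) ",
         paste(n[sep == 0], collapse = ", "), call. = FALSE)
  data.frame(frame = n, theta_ab = atan2(dy, dx),
             phi_ab = atan2(dz, abs(dx)), separation = sep)
}

#' Relative radial velocity of emitter B with respect to listener A
#'
#' Angle-decomposed relative velocity along the A-to-B bearing:
#' \deqn{v_{BA} = v_B \cos(\theta_B - \theta_{AB}) \cos(\varphi_B -
#'   \varphi_{AB}) - v_A \cos(\theta_A - \theta_{AB}) \cos(\varphi_A -
#'   \varphi_{AB}).}
#' Positive values mean the separation is increasing (the pair recedes)
#' under this decomposition. For planar (constant-z) motion it reduces
#' exactly to the vector projection
#' \eqn{(\mathbf{v}_B - \mathbf{v}_A) \cdot \hat{u}_{AB}}; for fully 3-D
#' motion the double-cosine form is an approximation tied to the x-based
#' inclination convention (see [flight_directions()]).
#'
#' @param dir_a,dir_b Rows of [flight_directions()] output for listener A
#'   and emitter B (recycled; must be frame-aligned with \code{geom}).
#' @param geom Matching rows of [inter_bat_geometry()] output.
#' @return Numeric vector \code{v_ba} in m/s.
#' @export
relative_velocity <- function(dir_a, dir_b, geom) {
  stopifnot(nrow(dir_a) == nrow(geom), nrow(dir_b) == nrow(geom))
  dir_b$v * cos(dir_b$theta - geom$theta_ab) * cos(dir_b$phi - geom$phi_ab) -
    dir_a$v * cos(dir_a$theta - geom$theta_ab) * cos(dir_a$phi - geom$phi_ab)
}

#' CF2 of another bat's pulse as audible to a focal bat
#'
#' Doppler-shifts the emitted CF2 of bat B by the relative radial velocity
#' \code{v_ba} between the pair. Two modes are provided and the mode is
#' recorded on the result:
#' \describe{
#'   \item{\code{"as_printed"}}{\eqn{CF2_{BA} = CF2_B \cdot C /(C -
#'     |v_{BA}|)}: the magnitude of the relative velocity is used, so every
#'     estimate is an up-shift (or no shift). This is the published form of
#'     the estimator.}
#'   \item{\code{"signed"}}{\eqn{CF2_{BA} = CF2_B \cdot C /(C + v_{BA})}
#'     with \code{v_ba > 0} receding: physically directional one-way Doppler
#'     (to first order in \eqn{v/C}), used to validate the estimator against
#'     waveform-level ground truth.}
#' }
#'
#' @param cf2_b Emitted CF2 of bat B, Hz (vectorised).
#' @param v_ba Relative radial velocity from [relative_velocity()], m/s.
#' @param sound_speed Speed of sound, m/s.
#' @param mode \code{"as_printed"} (default) or \code{"signed"}.
#' @return Numeric vector of received-CF2 estimates in Hz, with the mode in
#'   attribute \code{"mode"}.
#' @export
received_cf2 <- function(cf2_b, v_ba, sound_speed = 343.5,
                         mode = c("as_printed", "signed")) {
  mode <- match.arg(mode)
  if (any(cf2_b <= 0)) stop("`cf2_b` must be > 0", call. = FALSE)
  if (any(abs(v_ba) >= sound_speed))
    stop("|v_ba| must be below the sound speed", call. = FALSE)
  out <- if (mode == "as_printed") {
    cf2_b * sound_speed / (sound_speed - abs(v_ba))
  } else {
    cf2_b * sound_speed / (sound_speed + v_ba)
  }
  attr(out, "mode") <- mode
  out
}
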