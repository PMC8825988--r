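#' Simulate looping group-flight trajectories
#'
#' Bats in confined flight rooms typically circle the space; the generator
#' therefore flies each bat on a smoothly perturbed ellipse spanning the
#' chamber footprint, with harmonic modulation of loop radius and flight
#' height and a per-bat phase offset so that inter-bat distances vary
#' through each revolution. This is a kinematic, not behavioural, model:
#' only the resulting speed/distance statistics matter downstream.
#'
#' The path is integrated at 1 ms resolution with arc-length
#' parameterisation so that the total speed tracks the per-bat target; the
#' vertical velocity is subtracted from the horizontal speed budget, which
#' makes a degenerate speed band (\code{lo == hi}) produce constant-speed
#' flight. Per-bat cruise speeds are spaced evenly across the scene's speed
#' band.
#'
#' Flight speed follows the per-bat cruise target except where the loop
#' curvature would demand more lateral acceleration than \code{a_max}:
#' through the tight turns of a narrow space the bat slows to
#' \eqn{\sqrt{a_{max}/\kappa}}, as real bats do — confined-space flight
#' shows wide speed spreads with lower speeds in smaller rooms. In a wide
#' space the limit never binds and flight is at the cruise speed.
#'
#' @param scene A [simulation_scene()].
#' @param margin Wall clearance of the loop, m.
#' @param a_max Maximum lateral (centripetal) acceleration, m/s^2; about
#'   1 g by default.
#' @return A list of per-bat trajectory data frames (\code{bat_id},
#'   \code{frame}, \code{t_s}, \code{x_m}, \code{y_m}, \code{z_m}), one per
#'   bat, with the fine-grid path attached as attribute \code{"fine"}
#'   (positions at 1 kHz, used by the acoustic renderer for instantaneous
#'   velocities).
#' @export
simulate_trajectories <- function(scene, margin = 0.4, a_max = 10) {
  stopifnot(inherits(scene, "simulation_scene"))
  dims <- scene$chamber_dims
  ax <- dims[1] / 2 - margin
  ay <- dims[2] / 2 - margin
  if (ax < 0.3 || ay < 0.3)
    stop(sprintf(
      "chamber %.1f x %.1f m too small for the loop turn radius (need >= %.1f m semi-axis after %.1f m wall margin)",
      dims[1], dims[2], 0.3, margin), call. = FALSE)
  cx <- dims[1] / 2; cy <- dims[2] / 2; cz <- dims[3] / 2
  n <- scene$n_bats
  lo <- scene$speed_band[1]; hi <- scene$speed_band[2]
  v_base <- if (n == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = n)
  wobble <- min(1, (hi - lo) / 0.4)   # degenerate band -> rigid loop

  dt <- 1 / (100 * scene$frame_rate)   # nests frame times exactly
  tt <- seq(0, scene$duration_s, by = dt)
  out <- with_seed(stage_seed(scene$seed, "trajectories"), {
    lapply(seq_len(n), function(i) {
      phase0 <- 2 * pi * (i - 1) / n + stats::runif(1, -0.3, 0.3)
      f_rho <- stats::runif(1, 0.15, 0.25)   # radius modulation, Hz
      f_z <- stats::runif(1, 0.2, 0.3)       # height modulation, Hz
      ph_rho <- stats::runif(1, 0, 2 * pi)
      ph_z <- stats::runif(1, 0, 2 * pi)
      a_rho <- 0.05 * wobble
      a_z <- 0.3 * wobble

      z <- cz + a_z * sin(2 * pi * f_z * tt + ph_z)
      vz <- a_z * 2 * pi * f_z * cos(2 * pi * f_z * tt + ph_z)
      rho <- 1 + a_rho * sin(2 * pi * f_rho * tt + ph_rho)

      integrate_loop <- function(v_cruise) {
        alpha <- numeric(length(tt)); alpha[1] <- phase0
        for (k in seq_len(length(tt) - 1L)) {
          g2 <- ax^2 * sin(alpha[k])^2 + ay^2 * cos(alpha[k])^2
          ds_dalpha <- rho[k] * sqrt(g2)
          # curvature-limited speed through tight turns (smooth blend)
          kappa <- ax * ay / (rho[k] * g2^1.5)
          v_lim <- sqrt(a_max / kappa)
          v_eff <- v_cruise / (1 + (v_cruise / v_lim)^4)^0.25
          vh <- sqrt(pmax(v_eff^2 - vz[k]^2, 0.25))
          alpha[k + 1L] <- alpha[k] + vh * dt / ds_dalpha
        }
        alpha
      }
      # calibrate the cruise speed so the realized mean speed matches the
      # target despite turn slowdowns
      v_cruise <- v_base[i]
      alpha <- integrate_loop(v_cruise)
      if (is.finite(a_max)) {
        for (it in 1:2) {
          xs <- ax * rho * cos(alpha); ys <- ay * rho * sin(alpha)
          m <- mean(sqrt(diff(xs)^2 + diff(ys)^2 + diff(z)^2)) / dt
          if (m >= v_base[i] * 0.99) break
          v_cruise <- min(v_cruise * v_base[i] / m, v_base[i] * 1.8)
          alpha <- integrate_loop(v_cruise)
        }
      }
      x <- cx + ax * rho * cos(alpha)
      y <- cy + ay * rho * sin(alpha)

      fr_t <- seq(0, scene$duration_s, by = 1 / scene$frame_rate)
      fr_t <- fr_t[fr_t <= scene$duration_s - 1 / scene$frame_rate + 1e-9]
      idx <- round(fr_t / dt) + 1L
      tr <- data.frame(bat_id = scene$bat_ids[i],
                       frame = seq_along(fr_t) - 1L, t_s = fr_t,
                       x_m = x[idx], y_m = y[idx], z_m = z[idx])
      attr(tr, "fine") <- list(t = tt, x = x, y = y, z = z, dt = dt)
      tr
    })
  })
  names(out) <- scene$bat_ids[seq_len(n)]
  out
}

# Instantaneous position and velocity at arbitrary times from the fine grid
# (central differences at 1 ms; far finer than any manoeuvre timescale).
fine_state <- function(trajectory, t) {
  f <- attr(trajectory, "fine")
  if (is.null(f)) stop("trajectory lacks fine-grid attribute", call. = FALSE)
  k <- pmin(pmax(round(t / f$dt) + 1L, 2L), length(f$t) - 1L)
  vx <- (f$x[k + 1L] - f$x[k - 1L]) / (2 * f$dt)
  vy <- (f$y[k + 1L] - f$y[k - 1L]) / (2 * f$dt)
  vz <- (f$z[k + 1L] - f$z[k - 1L]) / (2 * f$dt)
  list(x = f$x[k], y = f$y[k], z = f$z[k], vx = vx, vy = vy, vz = vz)
}

# First wall hit by the ray from position p along velocity v, among the six
# chamber walls; returns the wall name, perpendicular distance to that wall
# and the closing speed (velocity component toward the wall, m/s).
nearest_wall_ahead <- function(p, v, dims) {
  walls <- list(
    xlo = list(axis = 1, pos = 0),       xhi = list(axis = 1, pos = dims[1]),
    ylo = list(axis = 2, pos = 0),       yhi = list(axis = 2, pos = dims[2]),
    zlo = list(axis = 3, pos = 0),       zhi = list(axis = 3, pos = dims[3]))
  pv <- c(p$x, p$y, p$z); vv <- c(v$vx, v$vy, v$vz)
  best <- NULL; best_s <- Inf
  for (w in names(walls)) {
    ax <- walls[[w]]$axis; pos <- walls[[w]]$pos
    dv <- vv[ax]
    if (abs(dv) < 1e-12) next
    s <- (pos - pv[ax]) / dv            # ray parameter to the wall plane
    if (s <= 0 || s >= best_s) next
    best_s <- s
    best <- list(wall = w, distance = abs(pos - pv[ax]),
                 closing_speed = abs(dv))
  }
  if (is.null(best))                    # stationary: compensate to nothing
    best <- list(wall = "none", distance = min(pv, dims - pv),
                 closing_speed = 0)
  best
}
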