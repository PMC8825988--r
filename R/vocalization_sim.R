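#' Simulate Doppler-shift-compensated vocalisation schedules
#'
#' Lays out each bat's emissions as sonar sound groups (clusters of pulses
#' at short intra-group intervals, separated by longer silent times drawn
#' from the profile's distributions) and assigns every pulse its emitted
#' CF2 via [dsc_emitted_cf2()]: at each emission the bat's instantaneous
#' closing speed toward the first wall ahead of it (the reflector it
#' compensates to) lowers the emitted CF2 so the wall echo returns at the
#' bat's reference frequency.
#'
#' @param scene A [simulation_scene()].
#' @param trajectories Output of [simulate_trajectories()] for the scene.
#' @return Data frame (one row per emitted pulse): \code{bat_id},
#'   \code{pulse_id}, \code{group_id}, \code{t_emit} (s), \code{cf2_emit}
#'   (Hz), \code{duration_ms}, \code{tfm_duration_ms},
#'   \code{tfm_bandwidth_hz}, \code{ifm} (logical), \code{ifm_duration_ms},
#'   \code{ifm_bandwidth_hz}, \code{wall}, \code{wall_distance_m},
#'   \code{closing_speed} (m/s toward the reflector).
#' @export
simulate_vocalizations <- function(scene, trajectories) {
  stopifnot(inherits(scene, "simulation_scene"))
  rows <- with_seed(stage_seed(scene$seed, "vocalizations"), {
    lapply(seq_len(scene$n_bats), function(i) {
      pr <- scene$profiles[[i]]
      tr <- trajectories[[i]]
      dur_s <- pr$pulse_duration_ms / 1000
      t_max <- scene$duration_s - dur_s - 0.02
      t <- 0.05 + stats::runif(1, 0, 0.03)
      emit <- numeric(0); gid <- integer(0)
      g <- 0L
      sizes <- as.integer(names(pr$pulses_per_group_probs))
      while (t < t_max) {
        g <- g + 1L
        k <- sizes[sample.int(length(sizes), 1L,
                              prob = pr$pulses_per_group_probs)]
        for (j in seq_len(k)) {
          if (t >= t_max) break
          emit <- c(emit, t); gid <- c(gid, g)
          gap <- if (j < k)
            rnorm_trunc(1, pr$intra_group_interval_ms[1],
                        pr$intra_group_interval_ms[2], lower = 5) / 1000
          else
            rnorm_trunc(1, pr$inter_group_interval_ms[1],
                        pr$inter_group_interval_ms[2], lower = 10) / 1000
          t <- t + dur_s + gap
        }
      }
      np <- length(emit)
      if (np == 0L) return(NULL)
      st <- fine_state(tr, emit)
      wall <- character(np); wd <- numeric(np); cs <- numeric(np)
      for (k2 in seq_len(np)) {
        w <- nearest_wall_ahead(
          list(x = st$x[k2], y = st$y[k2], z = st$z[k2]),
          list(vx = st$vx[k2], vy = st$vy[k2], vz = st$vz[k2]),
          scene$chamber_dims)
        wall[k2] <- w$wall; wd[k2] <- w$distance; cs[k2] <- w$closing_speed
      }
      data.frame(
        bat_id = scene$bat_ids[i], pulse_id = seq_len(np), group_id = gid,
        t_emit = emit,
        cf2_emit = dsc_emitted_cf2(pr$reference_frequency, cs,
                                   pr$compensation_gain, scene$sound_speed),
        duration_ms = pr$pulse_duration_ms,
        tfm_duration_ms = pr$tfm_duration_ms,
        tfm_bandwidth_hz = pr$tfm_bandwidth_hz,
        ifm = stats::runif(np) < pr$ifm_present,
        ifm_duration_ms = pr$ifm_duration_ms,
        ifm_bandwidth_hz = pr$ifm_bandwidth_hz,
        wall = wall, wall_distance_m = wd, closing_speed = cs)
    })
  })
  do.call(rbind, rows)
}
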