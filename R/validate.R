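# Validation utilities against simulator ground truth: label detected
# events with the arrival that dominates them, and score received-CF2
# estimates against the rendered arrivals.

#' Label detected events with their dominant ground-truth arrival
#'
#' Envelope detection cannot split temporally overlapping sounds, so a
#' detected event is credited to the loudest ground-truth arrival that
#' overlaps it on its channel (own echoes, which are recovered spectrally
#' and linked to their parent pulse, are matched to the echo arrival of
#' that pulse instead).
#'
#' @param events Classified events ([classify_events()] output).
#' @param arrivals Ground-truth arrivals from [simulate_scene()].
#' @param pulse_duration_s Nominal pulse duration used to span arrivals, s.
#' @return \code{events} with columns \code{true_source} (the simulator
#'   label, translated to the classifier's vocabulary: \code{focal_pulse},
#'   \code{other_pulse}, \code{own_echo}, or \code{NA} when nothing
#'   overlaps), \code{true_cf2} (the arrival's CF2) and \code{true_level}.
#' @export
label_events_with_truth <- function(events, arrivals,
                                    pulse_duration_s = 0.024) {
  kind_map <- c(own_pulse = "focal_pulse", other_pulse = "other_pulse",
                own_echo = "own_echo")
  events$true_source <- NA_character_
  events$true_cf2 <- NA_real_
  events$true_level <- NA_real_
  for (i in seq_len(nrow(events))) {
    ch <- events$channel_bat_id[i]
    if (identical(events$kind[i], "own_echo") &&
        !is.na(events$parent_pulse[i])) {
      par <- events[events$event_id == events$parent_pulse[i], ]
      a <- arrivals[arrivals$channel == ch & arrivals$source == "own_echo", ]
      if (nrow(a) == 0L || nrow(par) == 0L) next
      j <- which.min(abs(a$t_arrival - par$onset[1]))
      if (abs(a$t_arrival[j] - par$onset[1]) > 0.02) next
      events$true_source[i] <- "own_echo"
      events$true_cf2[i] <- a$cf2_arrival[j]
      events$true_level[i] <- a$level_db[j]
      next
    }
    a <- arrivals[arrivals$channel == ch & arrivals$source != "own_echo", ]
    ov <- a$t_arrival <= events$offset[i] &
      a$t_arrival + pulse_duration_s >= events$onset[i]
    if (!any(ov)) next
    a <- a[ov, ]
    j <- which.max(a$level_db)
    events$true_source[i] <- kind_map[[a$source[j]]]
    events$true_cf2[i] <- a$cf2_arrival[j]
    events$true_level[i] <- a$level_db[j]
  }
  events
}

#' Score received-CF2 estimates against rendered ground truth
#'
#' Matches each trajectory-based estimate of a conspecific pulse's
#' received frequency to the rendered arrival of that pulse on the
#' listener's channel and returns the frequency errors.
#'
#' @param received Output of [estimate_received_series()].
#' @param arrivals Ground-truth arrivals from [simulate_scene()].
#' @param max_lag_s Maximum |emission time - arrival time| for a match, s.
#' @return \code{received} with columns \code{cf2_true} and \code{error}
#'   (estimate minus truth, Hz); unmatched rows are dropped.
#' @export
received_errors_vs_truth <- function(received, arrivals, max_lag_s = 0.02) {
  a <- arrivals[arrivals$source == "other_pulse", ]
  out <- received
  out$cf2_true <- NA_real_
  for (i in seq_len(nrow(out))) {
    ai <- a[a$channel == out$listener[i] & a$emitter == out$emitter[i], ]
    if (nrow(ai) == 0L) next
    j <- which.min(abs(ai$t_arrival - out$t[i]))
    if (abs(ai$t_arrival[j] - out$t[i]) > max_lag_s) next
    out$cf2_true[i] <- ai$cf2_arrival[j]
  }
  out <- out[!is.na(out$cf2_true), ]
  out$error <- out$cf2_ba - out$cf2_true
  out
}
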