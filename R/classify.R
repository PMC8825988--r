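#' Classify detected events across synchronized channels
#'
#' Assigns each detected event one of the three source kinds, using the
#' cross-channel power and timing differences that arise from the spatial
#' arrangement of the bats:
#' \describe{
#'   \item{\code{focal_pulse}}{the channel where the event's level is
#'     maximal among time-overlapping events across channels (the
#'     animal-borne microphone picks up its carrier's own emissions at full
#'     level).}
#'   \item{\code{other_pulse}}{an event whose onset follows a stronger
#'     focal pulse on another channel within the arrival-lag window
#'     \code{other_lag_ms} (propagation across the chamber delays
#'     conspecific arrivals by r/C).}
#'   \item{\code{own_echo}}{wall echoes overlap their own 20--27 ms pulse
#'     (two-way delays here are 3--16 ms) and never appear as separate
#'     envelope events; they do, however, outlast the pulse by the two-way
#'     delay. Echoes are therefore recovered spectrally from the pulse
#'     tail: the dominant peak within \code{echo_band_hz} of the pulse CF2
#'     in the spectrum of the span just after the pulse core, with level
#'     above \code{echo_min_db}, becomes an own-echo event. A persistence
#'     filter then drops isolated outliers against the running median of
#'     each channel's echo-CF2 series (compensated echoes vary slowly;
#'     sporadic conspecific energy in the tail does not). Setting
#'     \code{echo_window_ms} to zero (or \code{echo_band_hz} to zero)
#'     disables echo extraction.}
#' }
#' Events matching nothing stay \code{unknown}.
#'
#' @param events_by_channel Named list (channel bat id -> event data frame
#'   from [detect_events()]).
#' @param waveforms Named list of channel waveforms (same names).
#' @param fs Sampling rate, Hz.
#' @param offsets_s Named numeric: declared synchronization offset of each
#'   channel, s (0 when channels share a clock). Required; an error is
#'   raised if a channel's offset is missing.
#' @param other_lag_ms Arrival-lag window (min, max) after another
#'   channel's focal-pulse onset for \code{other_pulse}, ms.
#' @param echo_window_ms Echo-delay window (min, max) after the focal
#'   pulse onset, ms; bounds the echo search and is reported with the
#'   events.
#' @param echo_band_hz Own-echo spectral search half-width around the
#'   pulse CF2, Hz.
#' @param echo_min_db Minimum echo peak level, dB re channel max.
#' @param sound_speed Speed of sound, m/s (used to turn echo-delay trends
#'   into wall closing speeds for echo-frequency prediction).
#' @return One data frame of events over all channels with \code{kind}
#'   assigned, CF2 fields filled for focal pulses and own echoes
#'   (\code{cf2}, \code{cf2_raw}, \code{cf2_bin_width}, \code{cf2_padded})
#'   and \code{parent_pulse} linking each own echo to its pulse's row id.
#' @export
classify_events <- function(events_by_channel, waveforms, fs,
                            offsets_s = NULL,
                            other_lag_ms = c(0, 20),
                            echo_window_ms = c(3, 60),
                            echo_band_hz = 2000, echo_min_db = -60,
                            sound_speed = 343.5) {
  chans <- names(events_by_channel)
  if (is.null(chans) || is.null(names(waveforms)))
    stop("channels must be named", call. = FALSE)
  if (is.null(offsets_s)) offsets_s <- stats::setNames(rep(0, length(chans)), chans)
  if (!all(chans %in% names(offsets_s)))
    stop("synchronization offsets missing for channel(s): ",
         paste(setdiff(chans, names(offsets_s)), collapse = ", "),
         call. = FALSE)

  ev <- do.call(rbind, lapply(chans, function(ch) {
    e <- events_by_channel[[ch]]
    if (nrow(e) == 0L) return(NULL)
    e$channel_bat_id <- ch
    e$onset <- e$onset + offsets_s[[ch]]
    e$offset <- e$offset + offsets_s[[ch]]
    e
  }))
  if (is.null(ev) || nrow(ev) == 0L)
    return(data.frame())
  ev$event_id <- seq_len(nrow(ev))
  ev$kind <- "unknown"
  ev$cf2 <- NA_real_; ev$cf2_raw <- NA_real_
  ev$cf2_bin_width <- NA_real_; ev$cf2_padded <- NA
  ev$parent_pulse <- NA_integer_

  # absolute level comparison requires a common scale: use per-channel
  # peak envelope amplitude to re-reference event levels to the global max
  ch_peak <- vapply(chans, function(ch) max(abs(waveforms[[ch]])), 0)
  ev$level_abs <- ev$peak_level + amp_to_db(ch_peak[ev$channel_bat_id],
                                            max(ch_peak))

  # focal pulses: the carrier's own emissions dominate its channel, so a
  # focal pulse must be near its channel's loudest events AND must not be
  # clearly outshone by a time-overlapping event on another channel (the
  # same sound heard at its emitter's microphone; two bats genuinely
  # calling at once are both focal on their own channels, hence the margin)
  ch_ev_max <- tapply(ev$level_abs, ev$channel_bat_id, max)
  for (i in seq_len(nrow(ev))) {
    if (ev$level_abs[i] < ch_ev_max[[ev$channel_bat_id[i]]] - 15) next
    ov <- ev$onset <= ev$offset[i] & ev$offset >= ev$onset[i] &
      ev$channel_bat_id != ev$channel_bat_id[i]
    if (!any(ov) || all(ev$level_abs[ov] < ev$level_abs[i] + 6))
      ev$kind[i] <- "focal_pulse"
  }
  # other pulses: onset lags a stronger focal pulse on another channel
  lag <- other_lag_ms / 1000
  for (i in which(ev$kind == "unknown")) {
    fp <- ev$kind == "focal_pulse" & ev$channel_bat_id != ev$channel_bat_id[i]
    dl <- ev$onset[i] - ev$onset[fp]
    hit <- dl >= lag[1] & dl <= lag[2] &
      ev$level_abs[fp] > ev$level_abs[i]
    if (any(hit)) ev$kind[i] <- "other_pulse"
  }

  # CF2 for every focal pulse first (echo disambiguation below needs the
  # emitted CF2 of all channels)
  for (i in which(ev$kind == "focal_pulse")) {
    est <- estimate_cf2(ev[i, ], waveforms[[ev$channel_bat_id[i]]], fs)
    ev$cf2[i] <- est$cf2; ev$cf2_raw[i] <- est$cf2_raw
    ev$cf2_bin_width[i] <- est$bin_width; ev$cf2_padded[i] <- est$padded
  }

  # Spectral own-echo extraction from the pulse tail (see extract_echoes)
  do_echo <- echo_window_ms[2] > echo_window_ms[1] && echo_band_hz > 0
  if (do_echo) {
    ech <- extract_echoes(ev, waveforms, fs, echo_window_ms, echo_band_hz,
                          echo_min_db, sound_speed)
    if (nrow(ech) > 0L) {
      ech$event_id <- nrow(ev) + seq_len(nrow(ech))
      ech <- echo_persistence_filter(ech)
      ev <- rbind(ev, ech)
    }
  }
  ev <- ev[order(ev$channel_bat_id, ev$onset), ]
  rownames(ev) <- NULL
  ev
}

# Own-echo extraction. A wall echo overlaps its 20-27 ms pulse (two-way
# delays 3-16 ms) but outlasts it by the delay, so the span just after the
# pulse core holds the echo's CF plateau nearly alone (the animal-borne
# microphone scarcely picks up other bats' pulses, so the echo dominates
# there). Per pulse: the envelope-event offset marks the echo end and
# estimates the delay; the tail window stops short of the echo's own
# terminal sweep; the echo is the dominant spectral peak of that window in
# the physically admissible band around the pulse CF2 (echoes from the
# wall being approached are up-shifted, hence the asymmetric band).
extract_echoes <- function(ev, waveforms, fs, echo_window_ms, echo_band_hz,
                           echo_min_db, sound_speed = 343.5) {
  fp_idx <- which(ev$kind == "focal_pulse" & !is.na(ev$cf2))
  echoes <- list(); ne <- 0L
  for (ch in unique(ev$channel_bat_id[fp_idx])) {
    idx <- fp_idx[ev$channel_bat_id[fp_idx] == ch]
    idx <- idx[order(ev$onset[idx])]
    core_off <- ifelse(is.na(ev$core_offset[idx]), ev$offset[idx],
                       ev$core_offset[idx])
    d_hat <- ev$offset[idx] - core_off
    d_rob <- if (length(idx) >= 5L) stats::runmed(d_hat, 5L) else d_hat
    for (k in seq_along(idx)) {
      i <- idx[k]
      band <- c(ev$cf2[i] - min(300, echo_band_hz),
                ev$cf2[i] + min(1800, echo_band_hz))
      tail0 <- core_off[k] + 3e-4
      tail1 <- min(core_off[k] + d_rob[k] - 0.0025,
                   ev$onset[i] + echo_window_ms[2] / 1000,
                   length(waveforms[[ch]]) / fs)
      nxt <- ev$onset[ev$channel_bat_id == ch & ev$onset > core_off[k]]
      if (length(nxt)) tail1 <- min(tail1, min(nxt))
      if ((tail1 - tail0) < 0.0015) next        # echo tail unresolvable
      pk <- tail_band_peak(waveforms[[ch]], fs, tail0, tail1, band)
      if (is.null(pk)) next
      lvl <- amp_to_db(pk$amp, max(abs(waveforms[[ch]])))
      if (lvl < echo_min_db) next
      ne <- ne + 1L
      echoes[[ne]] <- data.frame(
        channel_bat_id = ch, onset = tail0, offset = tail1,
        core_onset = tail0, core_offset = tail1, kind = "own_echo",
        peak_level = lvl, event_id = NA_integer_,
        cf2 = pk$freq, cf2_raw = pk$freq_raw,
        cf2_bin_width = fs / 16384, cf2_padded = TRUE,
        parent_pulse = ev$event_id[i], level_abs = lvl)
    }
  }
  if (ne == 0L) return(data.frame())
  do.call(rbind, echoes)
}

# Dominant spectral peak of the post-pulse tail within a frequency band:
# Hann taper, zero-pad to 16384 points, parabolic interpolation.
tail_band_peak <- function(wave, fs, t0, t1, band, n_fft = 16384) {
  i0 <- max(1L, round(t0 * fs) + 1L); i1 <- min(length(wave), round(t1 * fs))
  if (i1 - i0 < 64L) return(NULL)
  x <- wave[i0:i1]
  win <- 0.5 - 0.5 * cos(2 * pi * seq_along(x) / (length(x) + 1))
  amp <- sqrt(2 * mean((x * win)^2) / mean(win^2))   # tone amplitude est.
  x <- c(x * win, numeric(max(0L, n_fft - length(x))))
  nf <- length(x) %/% 2L + 1L
  sp <- Mod(stats::fft(x))[seq_len(nf)]
  freq <- (seq_len(nf) - 1L) * fs / length(x)
  cand <- which(freq >= band[1] & freq <= band[2])
  if (length(cand) < 3L) return(NULL)
  pk <- interp_peak(freq, sp, cand[which.max(sp[cand])])
  pk$amp <- amp
  pk
}

# Echoes returned by Doppler-shift compensation vary slowly pulse-to-pulse;
# sporadic contamination (an overlapping conspecific pulse in the tail
# window) shows up as isolated outliers against a running median of the
# per-channel echo CF2 series and is dropped.
echo_persistence_filter <- function(echoes, outlier_hz = 400, k = 5L) {
  keep <- rep(TRUE, nrow(echoes))
  for (ch in unique(echoes$channel_bat_id)) {
    idx <- which(echoes$channel_bat_id == ch)
    if (length(idx) < k) next
    o <- idx[order(echoes$onset[idx])]
    med <- stats::runmed(echoes$cf2[o], k, endrule = "median")
    keep[o] <- abs(echoes$cf2[o] - med) <= outlier_hz
  }
  echoes[keep, ]
}
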