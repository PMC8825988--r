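# Event detection on a telemetry channel: band-limited envelope over a
# rolling noise floor.

#' Band-pass a telemetry channel to the analysis band
#'
#' 4th-order Butterworth band-pass (zero-phase, forward-backward) over the
#' receiver analysis band, 10--200 kHz by default.
#'
#' @param wave Numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 band edges, Hz.
#' @return Filtered waveform.
#' @export
bandpass_channel <- function(wave, fs, band = c(10000, 200000)) {
  if (band[2] >= fs / 2) band[2] <- fs / 2 * 0.999
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, wave)
}

# RMS envelope at a decimated hop (seconds grid attached).
envelope_rms <- function(wave, fs, win_ms = 0.2, hop_ms = 0.1) {
  w <- max(8L, round(win_ms / 1000 * fs))
  hop <- max(1L, round(hop_ms / 1000 * fs))
  cs <- cumsum(c(0, wave^2))
  starts <- seq(1L, length(wave) - w + 1L, by = hop)
  env <- sqrt((cs[starts + w] - cs[starts]) / w)
  list(env = env, t = (starts + (w - 1) / 2) / fs, hop_s = hop / fs)
}

#' Detect sound events on one channel
#'
#' Events are maximal runs where the band-limited RMS envelope exceeds a
#' threshold for at least \code{min_dur_ms}; runs separated by less than
#' 1 ms are merged. The threshold is \code{threshold_db} (default -40 dB)
#' relative to the channel maximum, but never less than 10 dB above the
#' rolling-median noise floor.
#'
#' @param wave Channel waveform (raw; band-passed internally).
#' @param fs Sampling rate, Hz.
#' @param threshold_db Detection threshold, dB relative to channel max.
#' @param min_dur_ms Minimum event duration, ms.
#' @param merge_gap_ms Merge events separated by less than this, ms.
#' @param band Analysis band, Hz.
#' @param channel_bat_id Channel label carried into the events.
#' @return Data frame of events with \code{channel_bat_id}, \code{onset},
#'   \code{offset} (s, threshold crossings), \code{core_onset},
#'   \code{core_offset} (s, the span within 20 dB of the event peak: for a
#'   pulse trailed by its weaker wall echo this delimits the pulse itself),
#'   \code{kind = "unknown"}, \code{peak_level} (dB re channel max); zero
#'   rows if nothing exceeds threshold.
#' @export
detect_events <- function(wave, fs, threshold_db = -40, min_dur_ms = 3,
                          merge_gap_ms = 1, band = c(10000, 200000),
                          channel_bat_id = "ch1") {
  xf <- bandpass_channel(wave, fs, band)
  ev <- envelope_rms(xf, fs)
  peak <- max(ev$env)
  empty <- data.frame(channel_bat_id = character(0), onset = numeric(0),
                      offset = numeric(0), kind = character(0),
                      peak_level = numeric(0))
  if (peak <= 0) return(empty)
  env_db <- amp_to_db(ev$env, peak)
  # rolling noise floor: 10th percentile per 100-ms block (robust to the
  # high duty cycle of sonar sound groups), median-smoothed across blocks
  blk <- max(1L, round(0.1 / ev$hop_s))
  bi <- ceiling(seq_along(env_db) / blk)
  bq <- tapply(env_db, bi, stats::quantile, probs = 0.1, names = FALSE)
  if (length(bq) >= 3L) bq <- stats::runmed(bq, 3L, endrule = "median")
  floor_db <- bq[bi]
  thr <- pmax(threshold_db, floor_db + 10)
  above <- env_db > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]; off_i <- ends[r$values]
  # merge runs separated by < merge_gap_ms
  if (length(on_i) > 1L) {
    gaps <- ev$t[on_i[-1L]] - ev$t[off_i[-length(off_i)]]
    keep <- gaps >= merge_gap_ms / 1000
    on_i <- on_i[c(TRUE, keep)]
    off_i <- off_i[c(keep, TRUE)]
  }
  dur_ok <- (ev$t[off_i] - ev$t[on_i]) * 1000 >= min_dur_ms
  on_i <- on_i[dur_ok]; off_i <- off_i[dur_ok]
  if (length(on_i) == 0L) return(empty)
  lvl <- numeric(length(on_i))
  core_on <- numeric(length(on_i)); core_off <- numeric(length(on_i))
  for (i in seq_along(on_i)) {
    idx <- on_i[i]:off_i[i]
    lvl[i] <- max(env_db[idx])
    # core: the span within 20 dB of the event peak — for a pulse whose
    # weaker echo tail extends past its end, this is the pulse itself
    strong <- idx[env_db[idx] >= lvl[i] - 20]
    core_on[i] <- ev$t[min(strong)]
    core_off[i] <- ev$t[max(strong)]
  }
  data.frame(channel_bat_id = channel_bat_id,
             onset = ev$t[on_i] - ev$hop_s / 2,
             offset = ev$t[off_i] + ev$hop_s / 2,
             core_onset = core_on - ev$hop_s / 2,
             core_offset = core_off + ev$hop_s / 2,
             kind = "unknown", peak_level = lvl)
}
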