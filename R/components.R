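#' Measure FM components and duration of a CF-FM pulse
#'
#' Tracks the spectrogram frequency ridge of the event and measures the
#' terminal-FM (tFM) sweep and initial-FM (iFM) presence against the CF2
#' plateau:
#' \itemize{
#'   \item the tFM region starts at the first ridge frame after the CF
#'     plateau that drops more than \code{tfm_drop_hz} (1 kHz) below CF2,
#'     and ends at the last ridge frame above \code{ridge_floor_db}
#'     (-20 dB re event peak);
#'   \item because ridge frames near the pulse edge average the sweep over
#'     the analysis window, a straight line is fitted to the ridge inside
#'     the tFM region and extrapolated: \code{tfm_bandwidth} = CF2 minus
#'     the line at the envelope offset, \code{tfm onset} = the line's
#'     crossing of CF2, \code{tfm_duration} = offset minus that crossing;
#'   \item iFM is flagged if a rising ridge at least \code{ifm_drop_hz}
#'     (2 kHz) below CF2 precedes the plateau;
#'   \item \code{pulse_duration} = envelope offset minus onset (any iFM
#'     component is part of the pulse).
#' }
#'
#' @param event One-row event data frame with \code{onset}, \code{offset}.
#' @param wave Channel waveform.
#' @param fs Sampling rate, Hz.
#' @param cf2 The event's CF2 (Hz), from [estimate_cf2()]; measured here
#'   if missing.
#' @param tfm_drop_hz tFM boundary: drop below CF2 marking the sweep, Hz.
#' @param ifm_drop_hz iFM detection depth below CF2, Hz.
#' @param ridge_floor_db Ridge-end threshold, dB re event peak.
#' @param window_len,overlap Ridge-tracking STFT parameters.
#' @return List: \code{tfm_bandwidth} (Hz), \code{tfm_duration} (ms),
#'   \code{tfm_onset} (s), \code{ifm_detected}, \code{pulse_duration} (ms),
#'   \code{flag} (\code{NA}, \code{"no_tfm"} or \code{"ridge_untrackable"}).
#' @export
measure_components <- function(event, wave, fs, cf2 = NULL,
                               tfm_drop_hz = 1000, ifm_drop_hz = 2000,
                               ridge_floor_db = -20, window_len = 256,
                               overlap = 0.875) {
  on <- if (!is.null(event$core_onset) && !is.na(event$core_onset))
    event$core_onset else event$onset
  off <- if (!is.null(event$core_offset) && !is.na(event$core_offset))
    event$core_offset else event$offset
  seg <- extract_segment(wave, fs, on, off)
  out <- list(tfm_bandwidth = NA_real_, tfm_duration = NA_real_,
              tfm_onset = NA_real_, ifm_detected = NA,
              pulse_duration = (off - on) * 1000,
              flag = NA_character_)
  if (length(seg) < window_len) { out$flag <- "ridge_untrackable"; return(out) }
  sg <- spectrogram(seg, fs, window_len, overlap)
  rd <- ridge_track(sg, floor_db = ridge_floor_db)
  ok <- which(!is.na(rd$f))
  if (length(ok) < 5L) { out$flag <- "ridge_untrackable"; return(out) }
  if (is.null(cf2)) {
    est <- estimate_cf2(event, wave, fs)
    cf2 <- est$cf2
    if (is.na(cf2)) { out$flag <- "ridge_untrackable"; return(out) }
  }

  dur_s <- off - on
  plateau <- ok[abs(rd$f[ok] - cf2) < tfm_drop_hz / 2]
  if (length(plateau) == 0L) { out$flag <- "ridge_untrackable"; return(out) }
  pl_end <- max(plateau)

  # iFM: rising ridge well below CF2 before the plateau
  pre <- ok[ok < min(plateau)]
  pre <- pre[rd$f[pre] < cf2 - ifm_drop_hz]
  out$ifm_detected <- length(pre) >= 2L &&
    stats::cor(rd$t[pre], rd$f[pre]) > 0

  # tFM: dropping ridge after the plateau
  tfm <- ok[ok > pl_end & rd$f[ok] < cf2 - tfm_drop_hz]
  tfm <- tfm[rd$t[tfm] > rd$t[pl_end]]
  if (length(tfm) < 3L) {
    out$tfm_bandwidth <- 0; out$tfm_duration <- 0; out$flag <- "no_tfm"
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, rd$t[tfm]), rd$f[tfm])
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0) {
    out$tfm_bandwidth <- 0; out$tfm_duration <- 0; out$flag <- "no_tfm"
    return(out)
  }
  f_end <- unname(fit$coefficients[1] + slope * dur_s)  # line at pulse offset
  t_cross <- unname((cf2 - fit$coefficients[1]) / slope)  # line crosses CF2
  out$tfm_bandwidth <- cf2 - f_end
  out$tfm_onset <- on + t_cross
  out$tfm_duration <- (dur_s - t_cross) * 1000
  out
}
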