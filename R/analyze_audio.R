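#' Full sound analysis of a set of telemetry channels
#'
#' Runs detection, cross-channel classification, CF2 estimation and
#' component measurement on every channel of a recording (or simulated
#' scene), then forms sonar sound groups and silent times per channel.
#'
#' @param waveforms Named list of channel waveforms (names are bat ids).
#' @param fs Sampling rate, Hz.
#' @param threshold_db Detection threshold, dB re channel max.
#' @param gap_threshold_ms Sonar-sound-group gap threshold, ms.
#' @param ... Further arguments passed to [classify_events()].
#' @return List of class \code{"audio_analysis"}: \code{events} (all
#'   channels, with kinds, CF2 and component measures), \code{groups}
#'   (per-channel group table), \code{silent_times} (data frame
#'   \code{channel_bat_id}, \code{silent_time_s}) and \code{summary}
#'   (per-channel means of the headline features).
#' @export
analyze_audio <- function(waveforms, fs, threshold_db = -40,
                          gap_threshold_ms = 30, ...) {
  stopifnot(is.list(waveforms), !is.null(names(waveforms)))
  det <- lapply(names(waveforms), function(ch)
    detect_events(waveforms[[ch]], fs, threshold_db = threshold_db,
                  channel_bat_id = ch))
  names(det) <- names(waveforms)
  ev <- classify_events(det, waveforms, fs, ...)
  if (nrow(ev) == 0L)
    return(structure(list(events = ev, groups = NULL,
                          silent_times = NULL, summary = NULL),
                     class = "audio_analysis"))

  ev$tfm_bandwidth <- NA_real_; ev$tfm_duration <- NA_real_
  ev$tfm_onset <- NA_real_; ev$ifm_detected <- NA
  ev$pulse_duration <- NA_real_; ev$component_flag <- NA_character_
  for (i in which(ev$kind == "focal_pulse")) {
    mc <- measure_components(ev[i, ], waveforms[[ev$channel_bat_id[i]]], fs,
                             cf2 = ev$cf2[i])
    ev$tfm_bandwidth[i] <- mc$tfm_bandwidth
    ev$tfm_duration[i] <- mc$tfm_duration
    ev$tfm_onset[i] <- mc$tfm_onset
    ev$ifm_detected[i] <- mc$ifm_detected
    ev$pulse_duration[i] <- mc$pulse_duration
    ev$component_flag[i] <- mc$flag
  }

  grp <- list(); sil <- list()
  for (ch in names(waveforms)) {
    fp <- ev[ev$kind == "focal_pulse" & ev$channel_bat_id == ch, ]
    # group on the pulse cores: the envelope event runs on to the end of
    # the trailing wall echo, which is not part of the emission pattern
    if (nrow(fp) > 0L) {
      fp$onset <- ifelse(is.na(fp$core_onset), fp$onset, fp$core_onset)
      fp$offset <- ifelse(is.na(fp$core_offset), fp$offset, fp$core_offset)
    }
    g <- group_and_silent_times(fp, gap_threshold_ms)
    if (nrow(g$groups) > 0L) {
      g$groups$channel_bat_id <- ch
      grp[[ch]] <- g$groups
    }
    if (length(g$silent_times) > 0L)
      sil[[ch]] <- data.frame(channel_bat_id = ch,
                              silent_time_s = g$silent_times)
  }
  groups <- if (length(grp)) do.call(rbind, grp) else NULL
  silent <- if (length(sil)) do.call(rbind, sil) else NULL

  smry <- do.call(rbind, lapply(names(waveforms), function(ch) {
    fp <- ev[ev$kind == "focal_pulse" & ev$channel_bat_id == ch, ]
    ec <- ev[ev$kind == "own_echo" & ev$channel_bat_id == ch, ]
    st <- if (!is.null(silent))
      silent$silent_time_s[silent$channel_bat_id == ch] else numeric(0)
    data.frame(
      channel_bat_id = ch,
      n_pulses = nrow(fp), n_echoes = nrow(ec),
      pulse_duration_ms = mean(fp$pulse_duration, na.rm = TRUE),
      tfm_bandwidth_hz = mean(fp$tfm_bandwidth, na.rm = TRUE),
      tfm_duration_ms = mean(fp$tfm_duration, na.rm = TRUE),
      silent_time_ms = if (length(st)) mean(st) * 1000 else NA_real_,
      cf2_mean_hz = mean(fp$cf2, na.rm = TRUE))
  }))
  structure(list(events = ev, groups = groups, silent_times = silent,
                 summary = smry),
            class = "audio_analysis")
}

#' @exportS3Method base::print
print.audio_analysis <- function(x, ...) {
  cat("Audio analysis:", nrow(x$events), "events\n")
  if (nrow(x$events)) print(table(x$events$kind))
  if (!is.null(x$summary)) { cat("\nPer-channel summary:\n"); print(x$summary) }
  invisible(x)
}
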