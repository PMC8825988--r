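#' Per-flight reference frequency
#'
#' The reference frequency of a bat is the mean CF2 of the echoes its own
#' telemetry microphone recorded during a flight — the operational
#' estimate of its Doppler-shift-compensation set-point. The spread
#' (sample s.d.) of those echo CF2s measures how tightly the bat holds its
#' echoes at the set-point.
#'
#' @param echo_events Data frame of one bat's classified \code{own_echo}
#'   events for one flight, with \code{cf2} set.
#' @param bat_id,flight_id,condition,space Metadata carried through.
#' @return One-row data frame: \code{bat_id}, \code{flight_id},
#'   \code{condition}, \code{space}, \code{mean_cf2}, \code{sd_cf2} (Hz),
#'   \code{n_echoes}, \code{flagged} (TRUE when no usable echoes were
#'   available and no estimate is made).
#' @export
reference_frequency <- function(echo_events, bat_id = NULL,
                                flight_id = NA_character_,
                                condition = NA_character_,
                                space = NA_character_) {
  cf <- echo_events$cf2[!is.na(echo_events$cf2)]
  if (is.null(bat_id))
    bat_id <- if (nrow(echo_events)) echo_events$channel_bat_id[1] else NA_character_
  if (length(cf) == 0L)
    return(data.frame(bat_id = bat_id, flight_id = flight_id,
                      condition = condition, space = space,
                      mean_cf2 = NA_real_, sd_cf2 = NA_real_,
                      n_echoes = 0L, flagged = TRUE))
  data.frame(bat_id = bat_id, flight_id = flight_id, condition = condition,
             space = space, mean_cf2 = mean(cf),
             sd_cf2 = if (length(cf) > 1L) stats::sd(cf) else 0,
             n_echoes = length(cf), flagged = FALSE)
}

#' Closest-pair reference-frequency difference within a group
#'
#' The headline group statistic: the difference in mean reference
#' frequency between the two group members closest in reference frequency.
#' Also reports, per bat, the signed difference to its nearest neighbour.
#' Ties in the closest-pair search are broken toward lower bat id.
#'
#' @param rfs Data frame from [reference_frequency()] rows (2--3 bats, one
#'   flight condition).
#' @return List: \code{delta_rf} (Hz, absolute closest-pair difference),
#'   \code{delta_rf_signed} (higher-id member minus lower-id member),
#'   \code{pair} (the two bat ids), \code{per_bat} (data frame
#'   \code{bat_id}, \code{nearest}, \code{delta_signed}).
#' @export
delta_rf <- function(rfs) {
  rfs <- rfs[!is.na(rfs$mean_cf2), ]
  if (nrow(rfs) < 2L)
    stop("need at least two reference-frequency estimates", call. = FALSE)
  rfs <- rfs[order(rfs$bat_id), ]
  ids <- rfs$bat_id; f <- rfs$mean_cf2
  n <- length(f)
  per <- data.frame(bat_id = ids, nearest = NA_character_,
                    delta_signed = NA_real_)
  best <- c(NA_integer_, NA_integer_); best_d <- Inf
  for (i in seq_len(n)) {
    d <- abs(f - f[i]); d[i] <- Inf
    j <- which.min(d)                      # ties -> lower bat_id (sorted)
    per$nearest[i] <- ids[j]
    per$delta_signed[i] <- f[j] - f[i]
    for (j2 in seq_len(n)) if (j2 > i && d[j2] < best_d) {
      best_d <- d[j2]; best <- c(i, j2)
    }
  }
  list(delta_rf = abs(f[best[2]] - f[best[1]]),
       delta_rf_signed = f[best[2]] - f[best[1]],
       pair = ids[best], per_bat = per)
}

#' Reference-normalized frequency samples and histograms
#'
#' Normalizes a listener's own-echo CF2s and its estimates of other bats'
#' pulse frequencies by subtracting the listener's reference frequency,
#' then histograms both — the distribution comparison at the heart of the
#' jamming question: a bat's echoes pile up at zero (its auditory fovea)
#' while conspecific pulses scatter widely.
#'
#' @param echo_cf2 Numeric vector: the listener's own-echo CF2s, Hz.
#' @param estimate_cf2 Numeric vector: received-frequency estimates of the
#'   other bats' pulses at this listener, Hz.
#' @param rf The listener's reference frequency, Hz.
#' @param echo_bin_hz,estimate_bin_hz Histogram bin widths, Hz.
#' @return List of class \code{"normalized_frequencies"}: \code{samples}
#'   (data frame \code{source}, \code{value}), \code{spread} (per-source
#'   sd and IQR), \code{echo_hist}, \code{estimate_hist} (data frames
#'   \code{mid}, \code{count}; zero-count histograms when a source is
#'   empty).
#' @export
normalize_and_histogram <- function(echo_cf2, estimate_cf2, rf,
                                    echo_bin_hz = 50, estimate_bin_hz = 200) {
  stopifnot_scalar(rf, "rf")
  echo_v <- echo_cf2[!is.na(echo_cf2)] - rf
  est_v <- estimate_cf2[!is.na(estimate_cf2)] - rf
  samples <- rbind(
    if (length(echo_v)) data.frame(source = "own_echo", value = echo_v),
    if (length(est_v)) data.frame(source = "other_pulse_estimate",
                                  value = est_v))
  if (is.null(samples)) samples <- data.frame(source = character(0),
                                              value = numeric(0))
  hist1 <- function(v, bw) {
    if (length(v) == 0L)
      return(data.frame(mid = numeric(0), count = integer(0)))
    br <- seq(floor(min(v) / bw) * bw, ceiling(max(v) / bw) * bw + bw, by = bw)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  spread <- data.frame(
    source = c("own_echo", "other_pulse_estimate"),
    n = c(length(echo_v), length(est_v)),
    sd = c(if (length(echo_v) > 1) stats::sd(echo_v) else NA_real_,
           if (length(est_v) > 1) stats::sd(est_v) else NA_real_),
    iqr = c(if (length(echo_v)) stats::IQR(echo_v) else NA_real_,
            if (length(est_v)) stats::IQR(est_v) else NA_real_))
  structure(list(samples = samples, spread = spread,
                 echo_hist = hist1(echo_v, echo_bin_hz),
                 estimate_hist = hist1(est_v, estimate_bin_hz),
                 rf = rf),
            class = "normalized_frequencies")
}

#' @exportS3Method base::print
print.normalized_frequencies <- function(x, ...) {
  cat(sprintf("Normalized frequencies (reference %0.1f Hz):\n", x$rf))
  print(x$spread)
  invisible(x)
}
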