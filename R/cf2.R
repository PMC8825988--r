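#' Estimate the CF2 frequency of a detected event
#'
#' Reproduces the standard CF2 measurement for CF-FM calls: a segment
#' around the constant-frequency plateau is transformed with a
#' 16 384-point FFT (frequency resolution \code{fs / 16384}, about 31 Hz
#' at 500 kHz) and the spectral peak taken as CF2. The plateau is
#' auto-selected as the longest run of ridge frames whose
#' instantaneous-frequency slope stays below 1 kHz/ms; segments shorter
#' than 16 384 samples are Hann-tapered and zero-padded (flagged), longer
#' ones are cropped to their centre. The peak is refined by parabolic
#' interpolation on the peak bin and its neighbours; the raw bin-resolution
#' estimate is reported alongside.
#'
#' @param event One-row event data frame (needs \code{onset},
#'   \code{offset} in seconds).
#' @param wave The event's channel waveform.
#' @param fs Sampling rate, Hz.
#' @param n_fft Transform length (16 384 by default).
#' @param slope_thresh CF-plateau slope threshold, Hz per ms.
#' @param band Analysis band, Hz.
#' @return List: \code{cf2} (interpolated, Hz), \code{cf2_raw} (peak bin),
#'   \code{bin_width} (\code{fs/n_fft}), \code{padded} (flag),
#'   \code{cf_start}, \code{cf_end} (s), \code{spectrum} (data frame
#'   \code{freq}, \code{mag} over \code{band}, for secondary-peak
#'   searches). \code{cf2} is \code{NA} with \code{flag = "no_cf_plateau"}
#'   if no plateau is found.
#' @export
estimate_cf2 <- function(event, wave, fs, n_fft = 16384,
                         slope_thresh = 1000, band = c(10000, 200000)) {
  on <- if (!is.null(event$core_onset) && !is.na(event$core_onset))
    event$core_onset else event$onset
  off <- if (!is.null(event$core_offset) && !is.na(event$core_offset))
    event$core_offset else event$offset
  seg <- extract_segment(wave, fs, on, off)
  cf <- cf_plateau(seg, fs, slope_thresh, band)
  out <- list(cf2 = NA_real_, cf2_raw = NA_real_, bin_width = fs / n_fft,
              padded = NA, cf_start = NA_real_, cf_end = NA_real_,
              spectrum = NULL, flag = NA_character_)
  if (is.null(cf)) { out$flag <- "no_cf_plateau"; return(out) }
  x <- seg[cf$i0:cf$i1]
  padded <- length(x) < n_fft
  if (padded) {
    win <- 0.5 - 0.5 * cos(2 * pi * seq_along(x) / (length(x) + 1))
    x <- c(x * win, numeric(n_fft - length(x)))
  } else {
    mid <- length(x) %/% 2L
    x <- x[(mid - n_fft %/% 2L + 1L):(mid + n_fft %/% 2L)]
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_fft) / (n_fft + 1))
    x <- x * win
  }
  sp <- Mod(stats::fft(x))[seq_len(n_fft %/% 2L + 1L)]
  freq <- (seq_len(n_fft %/% 2L + 1L) - 1L) * fs / n_fft
  sel <- freq >= band[1] & freq <= band[2]
  pk <- interp_peak(freq[sel], sp[sel])
  out$cf2 <- pk$freq; out$cf2_raw <- pk$freq_raw
  out$padded <- padded
  out$cf_start <- on + (cf$i0 - 1L) / fs
  out$cf_end <- on + cf$i1 / fs
  out$spectrum <- data.frame(freq = freq[sel], mag = sp[sel])
  out
}

extract_segment <- function(wave, fs, onset, offset) {
  i0 <- max(1L, round(onset * fs) + 1L)
  i1 <- min(length(wave), round(offset * fs))
  if (i1 <= i0) stop("empty event segment", call. = FALSE)
  wave[i0:i1]
}

# Longest ridge run with |df/dt| < slope_thresh (Hz/ms): sample indices
# within the segment. Uses a short-window STFT so the plateau boundary is
# resolved at sub-ms scale.
cf_plateau <- function(seg, fs, slope_thresh = 1000, band = c(10000, 200000),
                       window_len = 256, overlap = 0.75) {
  if (length(seg) < window_len) return(NULL)
  sg <- spectrogram(seg, fs, window_len, overlap)
  rd <- ridge_track(sg, band, floor_db = -25)
  ok <- !is.na(rd$f)
  slope <- c(Inf, abs(diff(rd$f)) / (diff(rd$t) * 1000))   # Hz per ms
  flat <- ok & c(ok[-1], FALSE) & slope < slope_thresh
  flat[is.na(flat)] <- FALSE
  if (!any(flat)) return(NULL)
  r <- rle(flat)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  k0 <- starts[best]; k1 <- ends[best]
  if (k1 - k0 < 2L) return(NULL)
  i0 <- max(1L, round(rd$t[k0] * fs - window_len / 2))
  i1 <- min(length(seg), round(rd$t[k1] * fs + window_len / 2))
  list(i0 = i0, i1 = i1, f_med = stats::median(rd$f[k0:k1], na.rm = TRUE))
}
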