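#' Spectrogram of an ultrasound waveform
#'
#' Short-time Fourier magnitude with a Hann taper. Defaults (1024-sample
#' window, 87.5\% overlap) give 0.26-ms frame spacing at 500 kHz so that
#' even a 2-ms terminal-FM sweep spans several frames.
#'
#' @param wave Numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param window_len Window length, samples.
#' @param overlap Fractional overlap in \code{[0, 1)}.
#' @return List of class \code{"sonar_spectrogram"}: \code{mag} (frequency
#'   x time magnitude matrix, Parseval-consistent window scaling),
#'   \code{freq} (Hz), \code{time} (s, frame centres), \code{df}, \code{dt}
#'   (bin spacings).
#' @export
spectrogram <- function(wave, fs, window_len = 1024, overlap = 0.875) {
  if (window_len > length(wave))
    stop("window longer than the signal", call. = FALSE)
  hop <- max(1L, round(window_len * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / (window_len + 1))
  starts <- seq(1L, length(wave) - window_len + 1L, by = hop)
  nf <- window_len %/% 2L + 1L
  mag <- matrix(0, nf, length(starts))
  scale <- sqrt(sum(win^2))            # Parseval-consistent
  for (k in seq_along(starts)) {
    seg <- wave[starts[k]:(starts[k] + window_len - 1L)] * win
    sp <- stats::fft(seg)[seq_len(nf)]
    mag[, k] <- Mod(sp) / scale
  }
  structure(list(mag = mag,
                 freq = (seq_len(nf) - 1L) * fs / window_len,
                 time = (starts + (window_len - 1) / 2) / fs,
                 df = fs / window_len, dt = hop / fs),
            class = "sonar_spectrogram")
}

# Frequency ridge (peak per frame, parabolically interpolated) restricted
# to a band; frames whose peak magnitude is below `floor_db` relative to
# the strongest frame get NA.
ridge_track <- function(sg, band = c(10000, 200000), floor_db = -30) {
  sel <- which(sg$freq >= band[1] & sg$freq <= band[2])
  m <- sg$mag[sel, , drop = FALSE]
  pk <- apply(m, 2, which.max)
  pmag <- m[cbind(pk, seq_along(pk))]
  ok <- amp_to_db(pmag, max(pmag)) >= floor_db
  fr <- numeric(length(pk))
  for (k in seq_along(pk)) {
    i <- pk[k]
    if (i > 1L && i < nrow(m)) {
      a <- m[i - 1L, k]; b <- m[i, k]; cc <- m[i + 1L, k]
      den <- a - 2 * b + cc
      d <- if (den != 0) 0.5 * (a - cc) / den else 0
      d <- max(min(d, 0.5), -0.5)
    } else d <- 0
    fr[k] <- sg$freq[sel[1]] + (i - 1 + d) * sg$df
  }
  fr[!ok] <- NA_real_
  list(t = sg$time, f = fr, level_db = amp_to_db(pmag, max(pmag)))
}

# parabolic-interpolated peak of a magnitude spectrum
interp_peak <- function(freq, mag, i = which.max(mag)) {
  if (i > 1L && i < length(mag)) {
    a <- mag[i - 1L]; b <- mag[i]; cc <- mag[i + 1L]
    den <- a - 2 * b + cc
    d <- if (den != 0) 0.5 * (a - cc) / den else 0
    d <- max(min(d, 0.5), -0.5)
  } else d <- 0
  df <- freq[2] - freq[1]
  list(freq = freq[i] + d * df, freq_raw = freq[i], mag = mag[i])
}
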