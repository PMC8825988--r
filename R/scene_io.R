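# Scene persistence: one WAV per bat channel, trajectories / ground truth
# as TSV, scene config as a flat key = value text file.
#
# The WAV reader/writer below handles canonical RIFF PCM (16-bit) and IEEE
# float (32-bit) mono files, which is all the pipeline needs.

#' Write a mono WAV file
#'
#' @param wave Numeric vector in \code{[-1, 1]}.
#' @param path Output path.
#' @param fs Sampling rate, Hz.
#' @param bits 32 (IEEE float, default: lossless for the simulator) or 16
#'   (integer PCM).
#' @export
write_wav <- function(wave, path, fs, bits = 32) {
  stopifnot(bits %in% c(16, 32))
  con <- file(path, "wb"); on.exit(close(con))
  n <- length(wave)
  bytes_per <- bits / 8
  data_len <- n * bytes_per
  fmt <- if (bits == 32) 3L else 1L       # IEEE float / PCM
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(as.numeric(wave), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(wave, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path WAV path (16-bit PCM or 32-bit float, mono).
#' @return List \code{wave} (numeric, floats in \code{[-1, 1]} for PCM) and
#'   \code{fs}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; fs <- NULL; bits <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      nch <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (nch != 1L) stop("only mono WAV is supported", call. = FALSE)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (len > 16) readBin(con, "raw", len - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt == 3L && bits == 32L) {
        wave <- readBin(con, "numeric", len / 4, size = 4, endian = "little")
      } else if (fmt == 1L && bits == 16L) {
        wave <- readBin(con, "integer", len / 2, size = 2, signed = TRUE,
                        endian = "little") / 32767
      } else stop("unsupported WAV encoding", call. = FALSE)
    } else {
      readBin(con, "raw", len)
    }
    if (!is.null(wave)) break
  }
  if (is.null(wave)) stop("no data chunk in ", path, call. = FALSE)
  list(wave = wave, fs = fs)
}

# flat key = value config serialization (plain text, diff-able)
write_flat_config <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(" *= *", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    vals <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[trimws(p[1])]] <- if (!anyNA(num)) num else trimws(vals)
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write a simulated scene to disk
#'
#' Layout under \code{outdir}: \code{<bat_id>.wav} per channel (float WAV,
#' sample rate in the header), \code{trajectories.tsv}
#' (\code{bat_id frame t_s x_m y_m z_m}), \code{schedule.tsv},
#' \code{arrivals.tsv} (ground truth) and \code{scene.cfg} (flat
#' key = value).
#'
#' @param sim Output of [simulate_scene()].
#' @param outdir Output directory (created if missing).
#' @return \code{outdir}, invisibly.
#' @export
write_scene <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- sim$scene
  for (b in names(sim$waveforms))
    write_wav(sim$waveforms[[b]], file.path(outdir, paste0(b, ".wav")),
              sc$sample_rate)
  write_tsv(do.call(rbind, lapply(sim$trajectories, as.data.frame)),
            file.path(outdir, "trajectories.tsv"))
  write_tsv(sim$schedule, file.path(outdir, "schedule.tsv"))
  write_tsv(sim$arrivals, file.path(outdir, "arrivals.tsv"))
  pr <- sim$scene$profiles
  cfg <- list(
    preset = sc$preset, chamber_dims = sc$chamber_dims, n_bats = sc$n_bats,
    duration_s = sc$duration_s, frame_rate = sc$frame_rate,
    sample_rate = sc$sample_rate, sound_speed = sc$sound_speed,
    seed = sc$seed, speed_band = sc$speed_band,
    wall_loss_db = sc$wall_loss_db,
    conspecific_pickup_db = sc$conspecific_pickup_db,
    noise_db = sc$noise_db,
    harmonics_db = unname(unlist(sc$harmonics)),
    harmonic_numbers = as.integer(names(sc$harmonics)),
    bat_ids = sc$bat_ids,
    reference_frequency = vapply(pr, `[[`, 0, "reference_frequency"),
    compensation_gain = vapply(pr, `[[`, 0, "compensation_gain"),
    pulse_duration_ms = vapply(pr, `[[`, 0, "pulse_duration_ms"),
    tfm_duration_ms = vapply(pr, `[[`, 0, "tfm_duration_ms"),
    tfm_bandwidth_hz = vapply(pr, `[[`, 0, "tfm_bandwidth_hz"))
  write_flat_config(cfg, file.path(outdir, "scene.cfg"))
  invisible(outdir)
}

#' Read a scene directory written by [write_scene()]
#'
#' Fails hard if a WAV header's sample rate disagrees with the scene
#' config.
#'
#' @param outdir Scene directory.
#' @return List with \code{config}, \code{waveforms}, \code{fs},
#'   \code{trajectories} (single data frame), \code{schedule},
#'   \code{arrivals}.
#' @export
read_scene <- function(outdir) {
  cfg <- read_flat_config(file.path(outdir, "scene.cfg"))
  waves <- list()
  for (b in cfg$bat_ids) {
    w <- read_wav(file.path(outdir, paste0(b, ".wav")))
    if (w$fs != cfg$sample_rate)
      stop(sprintf("WAV sample rate %d != scene config %g for %s",
                   w$fs, cfg$sample_rate, b), call. = FALSE)
    waves[[b]] <- w$wave
  }
  list(config = cfg, waveforms = waves, fs = cfg$sample_rate,
       trajectories = read_tsv(file.path(outdir, "trajectories.tsv")),
       schedule = read_tsv(file.path(outdir, "schedule.tsv")),
       arrivals = read_tsv(file.path(outdir, "arrivals.tsv")))
}
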