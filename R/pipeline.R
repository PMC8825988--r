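#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> analyze-audio -> trajectory Doppler -> jamming
#' metrics (-> condition statistics when a multi-condition feature table is
#' supplied) from one configuration, writing every stage's outputs as
#' plain-text TSV plus a manifest. Reruns with the same config are
#' reproducible bit-for-bit for integer outputs and to formatting
#' precision for floats.
#'
#' @param config Either a list or the path of a flat \code{key = value}
#'   config file. Recognised keys (defaults in parentheses): \code{preset}
#'   ("narrow"), \code{n_bats} (3), \code{duration_s} (20), \code{seed}
#'   (1), \code{mode} ("as_printed"), \code{sub_frame} (0),
#'   \code{threshold_db} (-40), \code{gap_threshold_ms} (30),
#'   \code{exclude_wide} (0), \code{out} (required: output directory).
#' @return The manifest data frame (invisibly); all outputs under
#'   \code{config$out}: \code{scene/} (WAV + TSV + config),
#'   \code{events.tsv}, \code{groups.tsv}, \code{silent_times.tsv},
#'   \code{received.tsv}, \code{reference_frequencies.tsv},
#'   \code{delta_rf.tsv}, \code{normalized_samples.tsv},
#'   \code{histograms.tsv}, \code{manifest.tsv}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_flat_config(config)
  defaults <- list(preset = "narrow", n_bats = 3, duration_s = 20, seed = 1,
                   mode = "as_printed", sub_frame = 0, threshold_db = -40,
                   gap_threshold_ms = 30, exclude_wide = 0)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$out)) stop("config needs an `out` directory", call. = FALSE)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", {
    sc <- simulation_scene(preset = config$preset, n_bats = config$n_bats,
                           duration_s = config$duration_s,
                           seed = config$seed)
    s <- simulate_scene(sc)
    write_scene(s, file.path(out, "scene"))
    say("simulate", sprintf("%d pulses over %d bats", nrow(s$schedule),
                            sc$n_bats))
    s
  })

  # -- analyze-audio ----------------------------------------------------
  aa <- run_stage("analyze-audio", {
    a <- analyze_audio(sim$waveforms, sim$scene$sample_rate,
                       threshold_db = config$threshold_db,
                       gap_threshold_ms = config$gap_threshold_ms)
    write_tsv(a$events, file.path(out, "events.tsv"))
    write_tsv(if (is.null(a$groups)) data.frame() else a$groups,
              file.path(out, "groups.tsv"))
    write_tsv(if (is.null(a$silent_times)) data.frame() else a$silent_times,
              file.path(out, "silent_times.tsv"))
    say("analyze-audio", sprintf("%d events (%d focal pulses)",
                                 nrow(a$events),
                                 sum(a$events$kind == "focal_pulse")))
    a
  })

  # -- doppler ----------------------------------------------------------
  rec <- run_stage("doppler", {
    sm <- lapply(sim$trajectories, fit_polynomials)
    pulses <- aa$events[aa$events$kind == "focal_pulse" &
                          !is.na(aa$events$cf2), ]
    r <- estimate_received_series(pulses, sm,
                                  sound_speed = sim$scene$sound_speed,
                                  mode = config$mode,
                                  sub_frame = config$sub_frame > 0)
    write_tsv(r, file.path(out, "received.tsv"))
    say("doppler", sprintf("%d pair estimates (%d skipped), mode %s",
                           nrow(r), attr(r, "n_skipped"), config$mode))
    r
  })

  # -- metrics ----------------------------------------------------------
  run_stage("metrics", {
    sp <- if (sim$scene$preset %in% c("narrow", "wide")) sim$scene$preset
          else "narrow"
    if (config$exclude_wide > 0 && sp == "wide") {
      say("metrics", "wide-space flight excluded by config")
      write_tsv(data.frame(), file.path(out, "reference_frequencies.tsv"))
      write_tsv(data.frame(), file.path(out, "delta_rf.tsv"))
      write_tsv(data.frame(), file.path(out, "normalized_samples.tsv"))
      write_tsv(data.frame(), file.path(out, "histograms.tsv"))
    } else {
      ev <- aa$events
      rfs <- do.call(rbind, lapply(names(sim$waveforms), function(b)
        reference_frequency(ev[ev$kind == "own_echo" &
                                 ev$channel_bat_id == b, ],
                            bat_id = b, flight_id = "flight1",
                            condition = "group", space = sp)))
      write_tsv(rfs, file.path(out, "reference_frequencies.tsv"))
      drf <- if (sum(!is.na(rfs$mean_cf2)) >= 2) delta_rf(rfs) else NULL
      write_tsv(if (is.null(drf)) data.frame() else
        data.frame(delta_rf_hz = drf$delta_rf,
                   delta_rf_signed_hz = drf$delta_rf_signed,
                   bat_a = drf$pair[1], bat_b = drf$pair[2]),
        file.path(out, "delta_rf.tsv"))
      samp <- list(); hst <- list()
      for (b in names(sim$waveforms)) {
        rf_b <- rfs$mean_cf2[rfs$bat_id == b]
        if (is.na(rf_b)) next
        nh <- normalize_and_histogram(
          ev$cf2[ev$kind == "own_echo" & ev$channel_bat_id == b],
          rec$cf2_ba[rec$listener == b], rf_b)
        if (nrow(nh$samples)) {
          nh$samples$bat_id <- b; samp[[b]] <- nh$samples
        }
        h <- rbind(
          if (nrow(nh$echo_hist))
            cbind(source = "own_echo", nh$echo_hist),
          if (nrow(nh$estimate_hist))
            cbind(source = "other_pulse_estimate", nh$estimate_hist))
        if (!is.null(h)) { h$bat_id <- b; hst[[b]] <- h }
      }
      write_tsv(if (length(samp)) do.call(rbind, samp) else data.frame(),
                file.path(out, "normalized_samples.tsv"))
      write_tsv(if (length(hst)) do.call(rbind, hst) else data.frame(),
                file.path(out, "histograms.tsv"))
      say("metrics", sprintf("%d reference frequencies", nrow(rfs)))
    }
    NULL
  })

  # -- manifest ---------------------------------------------------------
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    bytes = file.size(file.path(out, files)),
    md5 = vapply(file.path(out, files), function(f)
      as.character(tools::md5sum(f)), ""),
    row.names = NULL)
  attr(manifest, "seed") <- config$seed
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  writeLines(c(sprintf("seed = %s", config$seed),
               sprintf("package_version = %s",
                       as.character(utils::packageVersion("sonarjam"))),
               log_lines),
             file.path(out, "pipeline.log"))
  invisible(manifest)
}
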