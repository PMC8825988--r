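Package: sonarjam
Title: Echo Reception and Jamming Analysis for Group-Flying CF-FM Bats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses group flight of Doppler-shift-compensating
    CF-FM bats (e.g. Japanese horseshoe bats). Generates physically consistent
    synthetic scenes: looping 3-D flight trajectories, sonar sound groups of
    CF-FM pulses whose emitted CF2 is governed by Doppler shift compensation,
    and per-bat telemetry-microphone waveforms carrying own pulses, wall
    echoes with two-way Doppler and conspecific pulses with one-way Doppler.
    Detects and segments pulses and echoes, measures CF2 (16384-point
    transform with parabolic peak interpolation), terminal-FM bandwidth and
    duration, pulse duration, sonar sound groups and silent times. Implements
    trajectory-based estimation of the Doppler-shifted frequencies at which
    each bat hears conspecific pulses (polynomial trajectory smoothing,
    flight-direction angles, relative radial velocity), per-flight reference
    frequencies and their spread, closest-pair reference-frequency
    differences, and reference-normalized frequency distributions of own
    echoes versus conspecific-pulse estimates. Condition comparisons use
    linear mixed models with Wald chi-square tests and Tukey-adjusted
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    car,
    emmeans,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
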