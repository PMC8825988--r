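---
title: "Echo reception and mutual jamming in group-flying CF-FM bats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo reception and mutual jamming in group-flying CF-FM bats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonarjam)
```

## The scientific problem

Horseshoe bats (and other CF-FM echolocators) emit calls built around a
long constant-frequency plateau whose dominant second harmonic (CF2, about
68--70 kHz in Japanese horseshoe bats) is individually stereotyped. In
flight they perform Doppler shift compensation (DSC): the emitted CF2 is
lowered by exactly the amount needed for the two-way Doppler-shifted wall
echo to return at a fixed individual set-point, the *reference frequency*
(RF), where the cochlear auditory fovea concentrates its extreme frequency
resolution.

When several such bats fly together, each also hears the others' pulses,
Doppler-shifted by the pair's relative motion. The question this package
operationalises: do a bat's own echoes and the conspecific pulses it
receives overlap at the auditory fovea, or does the combination of
individual RF differences and relative-motion Doppler scatter the
conspecific energy away from it?

Because each bat's acoustic world is only observable with an animal-borne
(telemetry) microphone, and the conspecific pulses *as heard by a given
bat* are scarcely recorded by it, the received conspecific frequencies
must be *estimated from the flight trajectories*: smooth the 30-fps 3-D
tracks, differentiate to flight directions, project onto the inter-bat
bearing to get the relative radial velocity $v_{BA}$, and shift the
emitter's measured CF2:

$$\mathrm{CF2}_{BA} = \mathrm{CF2}_{B}\cdot\frac{C}{C - |v_{BA}|}.$$

The package implements this estimator exactly as published (mode
`"as_printed"`), plus a physically directional variant
($C/(C+v_{BA})$, mode `"signed"`) used to validate the chain against
waveform-level ground truth. Neither silently corrects the other; outputs
carry their mode label. The magnitude form can only ever up-shift — it
cannot represent receding pairs — and whether that is intended or a typo
in the source method is undecidable, which is precisely why both modes
exist side by side.

## The synthetic-data generator

No recordings of this kind are publicly deposited, so the package's first
module generates complete, physically consistent group-flight scenes with
known ground truth. A scene fixes the flight-space geometry (presets:
the full 9 x 4.5 x 2.4 m chamber, a "wide" 6 m and a "narrow" 2 m
partition), the per-bat vocal profiles, the acoustic constants and one RNG
seed that determines every stochastic draw.

**Trajectories.** Bats in confined rooms circle the space, so each bat
flies a smoothly perturbed ellipse spanning the chamber footprint
(harmonic modulation of loop radius and height, per-bat phase offsets),
integrated at 1 ms resolution with arc-length parameterisation. Flight
speed follows a per-bat cruise target drawn across the scene's speed band
(defaults centred on 2.2 m/s in the narrow space and 2.7 m/s in the wide
space, the regime reported for this species in these rooms), except where
loop curvature would demand more than `a_max` (default 10 m/s^2, about
1 g) of lateral acceleration: there the bat slows to
$\sqrt{a_{max}/\kappa}$. This curvature limit is what produces the wide
within-flight speed spreads seen in real confined flight, and the cruise
speed is re-calibrated so the realized mean still matches the target.
This is a kinematic model, not a behavioural one: no obstacle avoidance,
no interaction between bats, no landing. Only the resulting speed,
distance and relative-velocity statistics matter downstream, and those
are the quantities the tests pin.

**Vocalisations.** Pulses are laid out in sonar sound groups: group sizes
drawn from a configurable distribution (default mixing singles, doublets
and triplets), intra-group gaps of 20 +/- 3 ms and inter-group silent
times of 52 +/- 5 ms (offset-to-onset, matching the observed ~51 ms
silent times). Each pulse's emitted CF2 comes from the DSC law with
configurable gain $g$:

$$f_e = \mathrm{RF}\left(\frac{C - v}{C + v}\right)^{g},$$

where $v$ is the instantaneous closing speed toward the first wall ahead
along the velocity vector (the reflector the bat compensates to). With
$g = 1$ the two-way echo returns exactly at RF; with $g = 0$ the bat
emits at RF regardless of flight. Per-bat reference frequencies default
to uniform draws within a 1.2 kHz colony band (68.0--69.2 kHz), the span
reported for colony-mates of this species.

**Rendering.** Calls are synthesized as phase-continuous frequency
trajectories of the fundamental (linear iFM up-sweep, CF plateau at
CF2/2, linear tFM down-sweep; default 24 ms duration, 16 kHz tFM depth
over 2 ms), with CF1 at -20 dB relative to the dominant CF2. Each
channel receives: its own pulses at full level; its own first-order
image-source echo off the wall ahead (delay $2d/C$, two-way Doppler,
spherical spreading plus a flat -6 dB wall loss — higher-order
reflections are deliberately omitted because wall echoes only serve the
RF estimate); and the other bats' pulses with one-way Doppler from the
instantaneous pair geometry at emission (pulse durations are far below
manoeuvre timescales), 1/r spreading, and a *conspecific pickup loss*
(default -25 dB). That last parameter encodes a documented property of
animal-borne telemetry microphones in this preparation: they scarcely
record the other bats' pulses (which is the very reason received
frequencies must be estimated from trajectories), yet close passes remain
visible on spectrograms. No absolute source or echo levels are reported
for this system, so all amplitude constants are free, documented
parameters. Gaussian microphone noise sits at -70 dB by default;
atmospheric absorption is not modelled.

**What passing tests on these scenes do and do not show.** The generator
shares the real data's structure — DSC-governed frequencies, true Doppler
on every path, realistic timing, three synchronized channels — but it is
noise-poor, reverberation-poor (first-order echoes only) and
behaviourally sterile. Recovery tolerances met here bound the algorithmic
error of the pipeline, not its robustness to real telemetry artefacts
(FM-radio dropouts, wingbeat modulation, overlapping clutter echoes).

## Sound analysis

The source method measured everything by manual spectrogram inspection;
this package replaces that with declared automatic criteria, all
configurable:

* **Detection**: 4th-order Butterworth band-pass 10--200 kHz (the
  receiver chain's band), RMS envelope (0.2 ms window, 0.1 ms hop),
  events where the envelope exceeds -40 dB re channel max (never less
  than 10 dB above a rolling 10th-percentile noise floor) for >= 3 ms,
  runs closer than 1 ms merged. Each event also carries a *core* span
  (within 20 dB of its peak): a pulse trailed by its much weaker wall
  echo ends where the core ends.
* **CF2**: the constant-frequency plateau is auto-selected as the longest
  ridge run with instantaneous-frequency slope < 1 kHz/ms; a 16 384-point
  transform (bin width $f_s/16384 \approx 31$ Hz at 500 kHz; Hann taper,
  zero-padding flagged when the segment is shorter) and parabolic
  interpolation of the peak give the estimate, with the raw bin-resolution
  value alongside.
* **Components**: the spectrogram ridge frames inside the terminal sweep
  are fitted with a straight line, extrapolated to the envelope offset
  (tFM bandwidth = CF2 minus the line there) and to the CF2 crossing (tFM
  onset). The extrapolation matters: ridge frames near the pulse edge
  average the sweep over the analysis window and would otherwise bias the
  bandwidth by ~2 kHz. iFM is flagged when a rising ridge >= 2 kHz below
  CF2 precedes the plateau. Pulse duration is the core envelope span and
  includes any iFM.
* **Classification** uses the cross-channel power and timing differences
  that the three synchronized telemetry channels provide: focal pulses
  dominate their own channel (within 15 dB of its loudest events, not
  outshone by >6 dB by an overlapping event elsewhere — two bats genuinely
  calling at once are both focal); conspecific pulses lag a stronger
  focal pulse on another channel by the 0--20 ms propagation delay.
* **Own echoes** overlap their own 20--27 ms pulse (two-way delays here
  are 3--16 ms) and are never separate envelope events; but they *outlast*
  the pulse by the delay. The envelope-event offset marks the echo end,
  which estimates the delay; the span between the pulse core's end and the
  echo's own terminal sweep is transformed and the dominant peak within
  the physically admissible band (CF2 - 0.3 kHz to CF2 + 1.8 kHz — echoes
  off the approached wall are up-shifted) is the echo CF2. A persistence
  filter drops isolated outliers against the running median of the
  channel's echo series: compensated echoes vary slowly, sporadic
  conspecific energy does not. Echoes with less than ~4 ms of usable tail
  (walls closer than ~0.7 m) are skipped rather than guessed.
* **Sonar sound groups**: pulses whose offset-to-onset gap is below 30 ms
  share a group (the concept is defined in the field; the threshold is
  ours); silent time is the gap between consecutive groups.

## Trajectory smoothing and the two analysis configurations

The published procedure fits each 5-s half of a 10-s flight with
order-10 polynomials per coordinate and differentiates frame to frame.
On rescaled per-segment time this is numerically benign, and
`fit_polynomials()` keeps those defaults. But an order-10 polynomial over
5 s cannot follow a ~4-s narrow-space loop with ~0.2--0.5 m turn radii:
fit residuals reach centimetres and velocity errors ~0.3 m/s, i.e.
~60 Hz of Doppler at 68.5 kHz. That error is a property of the published
settings in tight spaces, and the vignette's point is to make it visible,
not to hide it.

The package therefore distinguishes two configurations:

* **Fidelity configuration** (defaults): 5-s segments, order 10,
  backward frame differences, angle-decomposed relative velocity, mode
  `"as_printed"`. This is what `run_pipeline()` uses and what mirrors the
  published analysis.
* **Validation configuration**: 1.25-s segments (order 10), centred
  sub-frame differences, exact 3-D vector projection (`velocity =
  "exact3d"`), mode `"signed"`. The shorter segments resolve the
  manoeuvre timescale of narrow-space flight (chosen so fit residuals are
  millimetres, well below the centimetre scale that one 31-Hz CF2 bin
  corresponds to); the vector projection avoids a pathology of the
  angle-decomposed form described next. Under this configuration the
  trajectory-based received-frequency estimates match the rendered
  ground-truth arrivals within one CF2 analysis bin for >= 95% of pulses
  (the acceptance suite re-measures this on every run).

**Angle conventions.** The azimuth uses the full-quadrant inverse tangent
of $(\Delta y, \Delta x)$ — a ratio arctangent would lose the heading
quadrant, and the cosine-difference decomposition makes quadrants
consequential. The inclination is the *ratio* arctangent of
$\Delta z / |\Delta x|$, confined to $(-\pi/2, \pi/2]$: the x-heading
sign is already carried by the azimuth, and a full-quadrant inclination
would double-count it (motion along $-x$ would project with the wrong
sign, breaking the exact planar identity between the decomposition and
the vector projection, which the worked examples and the acceptance
geometry oracle both pin down). Even so, the double-cosine decomposition
is exact only for planar motion: when a heading is nearly perpendicular
to the x axis ($\Delta x \to 0$), its x-based inclination saturates at
$\pm\pi/2$ regardless of how shallow the climb is, which is why the
`exact3d` option exists and is used for physical validation.

## Jamming metrics

The per-flight reference frequency is the mean CF2 of a bat's extracted
own echoes, its s.d. the tightness of compensation. In clean single-bat
scenes with full DSC the closed loop holds the spread below one CF2 bin;
in three-bat scenes residual conspecific interference in the echo tails
raises it to tens of hertz — a realistic magnitude (narrow-space flights
of this species show RF spreads of roughly 80--90 Hz).

Delta-RF is the difference in mean RF between the two group members
closest in RF (signed and absolute are both reported, since the published
figure does not disambiguate; ties break toward the lower bat id). The
normalized-distribution comparison subtracts each listener's RF from its
own echo CF2s and from its estimates of the others' pulse frequencies;
histograms default to 50 Hz bins for echoes and 200 Hz for estimates
(the published figure's bins are unreadable, so both are configurable).
The qualitative finding this reproduces on synthetic scenes: conspecific
estimates spread far wider than own echoes whenever the group members'
speeds differ by more than ~0.5 m/s.

## Condition comparisons

The statistical stage is deliberately a thin, validated layer over
established tooling: `lme4::lmer` fits
`response ~ condition * space + (1 | bat_id)` (condition-only per space
for the RF s.d., whose distributions differ strongly between spaces),
`car::Anova` provides type II Wald chi-square tests, and `emmeans`
Tukey-adjusted pairwise contrasts. The package's own content is the data
model (one row per bat x flight, per-flight means as the analysis unit;
the observation unit is ambiguous in the source, and per-flight means are
the conservative choice), the per-space split, and a simulation harness:
`condition_test_rejection_rate()` simulates feature tables from the
random-intercept model and reports how often a Tukey-adjusted
group-vs-single contrast comes out significant. With no true effect this
empirical type-I error sits just below the nominal 0.05 (the "any group
contrast" family covers two of the three Tukey contrasts); with a +3 kHz
group effect on tFM bandwidth (sigma_bat 0.5, sigma_res 1, nine bats)
power is essentially 1. Residual diagnostics are a compact normality /
spread summary rather than a full simulation-based residual workflow,
which is outside this package's scope.

## Numerical choices and degenerate inputs

* Sound speed defaults to 343.5 m/s (about 20 C air) and is exposed
  everywhere a Doppler quantity is computed; the source never states it.
* Zero displacement between frames carries the previous flight direction
  forward and flags the frame; coincident bat positions make the bearing
  undefined and raise an error.
* Pulses outside trajectory coverage are skipped and counted, not errors.
* An event without a CF plateau, or with an untrackable ridge, is
  flagged with its fields unset rather than guessed.
* The supersonic guard (|v| >= C) raises a domain error in every Doppler
  function.
* `read_scene()` fails hard when a WAV header's sample rate disagrees
  with the scene config. 32-bit float WAV round-trips to ~1e-7 (IEEE
  single precision); all TSV floats round-trip to 1e-9.
* Problem sizes in the test and acceptance suites: a 20-s three-bat
  narrow-space scene (about 950 pulses, 500 kHz channels) for the
  physical-recovery checks, 10-s scenes for the spread-ordering property,
  500 + 200 replicates for the statistical harness, 10 000 random planar
  configurations for the geometry oracle.

## Known limitations

* The echo extractor needs the echo to outlast the pulse by >= ~4 ms and
  so discards close-wall pulses; with three bats it additionally loses
  echoes to conspecific interference. Yields of 30--60% of pulses are
  normal and unbiased for RF estimation.
* Conspecific arrivals weaker than the detection threshold (most, at the
  default pickup loss) are not individually detected — exactly as in the
  real preparation, where they are estimated from trajectories instead.
* The generator's loops are kinematic; nothing about behavioural
  interaction, task structure, or landing is represented.
* Received-frequency estimates inherit whatever error the trajectory
  smoothing leaves; with the published 5-s/order-10 settings in a narrow
  space that error is tens of hertz and is quantified, not corrected,
  by this package.
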