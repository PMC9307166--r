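---
title: "Models and methods behind magstimkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magstimkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magstimkit)
```

`magstimkit` models the full chain needed to deliver and verify
well-defined magnetic stimuli inside a space-constrained physiology
recording setup: the coil physics, the miniature magnetometer used to
verify the stimulus, the in-situ calibration of the coil system, the
current driver electronics, and the separation of magnetic induction
artifacts from biological spikes in multielectrode recordings. This
vignette explains each model, its assumptions, the parameters that
matter, and the choices made where the design was genuinely open.

## Coordinate and unit conventions

Geometry is expressed in meters in right-handed setup coordinates with
the origin at the nominal specimen position; magnetic fields are in
microtesla (the closed-form Helmholtz midpoint function returns tesla, as
its result is commonly quoted that way). The multielectrode module uses
micrometers for electrode positions, microvolts for waveforms, and
seconds for time. Keeping one convention per module avoids the unit
mistakes that mixed millimeter/microtesla bookkeeping invites.

## Coil fields

Fields of square loops are computed segment-wise with the Biot--Savart
closed form for a straight conductor (the Hanson--Hirshman formulation,
which is numerically stable near the segment ends); circular loops are
discretized into polygons. The default of 3600 segments keeps the
polygon approximation error at the Helmholtz midpoint near 2.5e-7
relative, comfortably below the 1e-6 agreement demanded of the
closed-form cross-check; convergence is verified by segment doubling in
the tests. Evaluation closer than 1e-4 of the loop size to a conductor
is refused rather than returned, because field values that close to an
idealized filament are numerically meaningless.

A coil pair in the `anti_serial` state -- the double-wrapped sham wiring
-- contributes exactly zero field by construction, not by numerical
cancellation: the sham condition of a double-wrapped coil is an exact
physical null, and modeling it as such keeps sham comparisons free of
spurious numerical residue.

The optimal spacing of a square pair is found by root-bracketing the
central-difference second axial derivative of the pair's on-axis field
at the midpoint. The criterion yields `d/a ~ 0.5445`. The ratio usually
quoted for square Helmholtz pairs is 0.5452; the two differ by about
0.13 %. We implement the zero-second-derivative criterion and report its
root rather than hard-coding the quoted constant, and document the
discrepancy here: over a central region that is small against the coil,
the field profile is so flat near the optimum that the 0.13 % difference
in spacing has no practical effect on homogeneity.

Distortion sources are point dipoles. Hard sources carry a fixed moment.
Soft sources model linear soft-iron material: the induced moment is
`m = chi_V B_applied / mu0`, where `chi_V` is an effective
susceptibility volume (m^3) and `B_applied` is the total field at the
source from coils, ambient field and hard sources -- a single-scattering
approximation that excludes the source's own field and any
dipole--dipole self-consistency. Linear induced magnetization is an
excellent approximation for mild steel below 200 uT; hysteresis,
saturation and finite-element magnetostatics are out of scope.

## Magnetometer model and ellipsoid calibration

The sensor forward model is
`V_raw = V_bias + (1/g_mag) W B + noise`, rounded to integer counts and
clipped to the signed 16-bit range. `V_bias` collects bridge offsets and
hard-iron fields; `W` collects soft-iron distortion, per-axis gain
mismatch and cross-axis sensitivity; `g_mag` (default 7.85 nT/LSB) is
the scale at the sensor's most sensitive range. The per-axis noise
default of 0.54 uT is the noise floor at 64x internal oversampling; the
oversampling model `base_std * sqrt(64/k)` is plain white-noise
averaging and reproduces the published ladder 0.54/0.39/0.27/0.19 uT
for 64x--512x.

Rotating such a sensor in a uniform field traces an offset ellipsoid in
count space. The calibration fits the general 10-parameter quadric by
direct algebraic least squares (unit-norm constraint, solved by
eigendecomposition of the normal matrix) -- deterministic, with no
initialization, unlike iterative geometric fitting. The ellipsoid center
gives `V_bias`; the symmetric-positive-definite square root of the
quadratic form gives `W_inv` up to scale.

Two identifiability facts shape the interface:

* Rotation data determine `W` only up to a left orthogonal factor. The
  calibration resolves this by convention, returning a symmetric-PD
  `W_inv`. For symmetric-PD ground truths the recovery is exact; for
  general ground truths `W_inv W` is orthogonal, which is equally valid
  (both undo the distortion of the sphere).
* Only the product `g_mag * W_inv` is identifiable, so `W_inv` is
  normalized to unit determinant and the overall scale lives in
  `g_mag`, fixed by the known reference field magnitude.

Trajectories confined to a plane leave the quadric rank-deficient; the
fit refuses them with a rank error instead of returning a silently
ill-conditioned calibration. Synthetic trajectories come in two modes:
`uniform` (independent uniform rotations, via random unit quaternions)
and `smooth` (a bounded-step random walk emulating hand rotation). All
generators take explicit seeds; the package default is 20220722.

Magnitude residuals `|B| - reference` are the default residual
statistic. With the 64x noise floor on a 49 uT field, per-axis noise
projects onto the magnitude almost unchanged, so a 3-minute, 200 Hz
simulated rotation yields a residual std of ~0.55 uT; this is the
noise-dominated part of what a real calibrated sensor shows, and the
simulation makes no claim about slowly varying calibration error on real
hardware. With noise off, residuals sit at the rounding floor
`g_mag/sqrt(12)` per axis (~2.3 nT).

## Coil-system calibration

At a fixed position the measured field is affine in the control
voltages, `B = B_const + D U`: all hard- and soft-iron distortions of
coil and ambient fields collapse into the nine entries of `D` and the
three of `B_const`. Calibration fits each Cartesian component by
ordinary least squares over a set of voltage triplets; commanding a
target inverts the fit, `U = D^-1 (B_target - B_const)`. Because the
true response is affine, calibrate-then-command is exact up to
measurement noise -- the tests verify the round trip to 1e-9 uT -- and
any linear distortion introduced later (a steel bar near the chamber) is
absorbed completely at the calibrated point by refitting. What a linear
recalibration cannot remove is the position dependence of a nearby
dipole's field, which is why the off-center inhomogeneity grows after
placing the bar even though the center error returns to the noise floor.

Design choices:

* Calibration voltages form a deterministic Fibonacci-lattice sphere
  (reproducible without seeds, near-uniform coverage). The default
  amplitude is 2 V -- a mid-range drive for a gain of tens of uT/V --
  and the default design size is 162 vectors, with 44-vector spheres at
  50 uT as verification probes.
* `B_const` is estimated jointly as the regression intercept by
  default; a measured zero-voltage field can be supplied instead. The
  intercept is in the design matrix either way.
* Inversion refuses a `D` with condition number above 1e6: inverting a
  near-singular gain matrix commands meaninglessly large voltages.
* Verification probes are held out from the calibration design by
  default (different sphere sizes), though nothing forbids evaluating on
  the calibration vectors themselves.

The homogeneity scan commands the probe sphere, via a calibration fitted
at the center, at every node of a 5 x 5 grid with 500 um pitch and
reports each position's mean Euclidean error as a percentage of the
probe magnitude. For the ideal reference geometry (square pairs of 223,
400 and 162 mm side at the optimal spacing, 32/53/19 turns) the worst
position stays below 1e-5 %, far under the 1 % acceptance bound -- the
grid spans ~1/200 of the smallest coil.

## Driver model

The static transfer `I = divider * U / R_shunt` is exactly linear inside
the compliance window set by the current limit (3 A) and the voltage
compliance `(supply - dropout)/R_coil`, with a 4 V dropout default. The
worked power budget follows directly: 1 A into 5 ohm with 4 V dropout
needs at least 9 V rails, and the amplifier dissipates
`(supply - |U_coil|) |I|` at steady state, so supply power splits
exactly into coil plus amplifier dissipation.

The closed loop is abstracted as a canonical second-order system in
`(zeta, omega_n)` with an added slew ceiling `di/dt <= (supply -
dropout)/L`. The real amplifier's loop order with its adjustable
compensation network is not public, so this is a stated approximation,
not a claim about the hardware: `zeta` plays the role of the
compensation trimmer, and the defaults (`zeta = 0.517`, `omega_n` tuned
for a 400 us 2 %-band settling) reproduce the observed behavior of ~15 %
overshoot with steady state well below 500 us. The 2 % settling band is
our definition; the hardware description says only "steady state". The
underdamped overshoot obeys `exp(-pi zeta / sqrt(1 - zeta^2))`, which
the tests check to 0.5 % across `zeta` in [0.2, 0.9].

Sham blanking switches the double-wrapped winding anti-serial: the
current, resistance and dissipated power are unchanged while the field
scale factor drops to exactly zero, leaving only the ambient field --
the control condition that separates electrically induced from
field-induced effects.

## Multielectrode artifact laboratory

The synthetic recording emulates a 512-electrode planar array covering
1890 x 900 um (hexagonally packed; the commercial array's exact site
map is not public) sampled at 20 kHz -- a rate of our choosing that
safely exceeds twice the 2 kHz band edge. Spikes are biphasic kernels
(dominant narrow lobe, opposite shallow lobe, zero integral) with
somatic amplitude decaying as `1/(1 + (d/lambda)^2)`, `lambda = 30 um`,
plus an attenuated axonal contribution delayed by arc length over a
1 m/s conduction velocity; these values are free parameters chosen to
produce the qualitative structure of real electrical images (a compact
soma footprint with increasing latency along the axon), not a fitted
retinal model.

The magnetic stimulus switches among the 12 vertices of a regular
icosahedron at 50 uT every 200 ms, consecutive segments always
differing. Each field transition adds an induction artifact:
simultaneously on all electrodes, with peak amplitude `(c . dB)` times a
per-electrode scale (default uniform, as no routing dependence was
apparent in the hardware this emulates), and a temporal kernel equal to
the derivative of a smooth step -- a Gaussian pulse of 0.3 ms width --
standing in for a dB/dt transient band-limited by the recording chain.
Traces are band-pass filtered 80--2000 Hz with a second-order
Butterworth applied forward--backward (zero phase), so planted peak
latencies survive filtering within a sample.

Because everything downstream of the field step is linear, the
transition-triggered average images are exactly linear in `dB`:
reversed transitions give exactly opposite images, and regressing the
signed peak amplitude (read at a common reference electrode and common
peak sample) on the three `dB` components through the origin recovers
the coupling axis with R^2 = 1 in the noise-free model. The default
planted axis is `[-0.74, 0.67, 0.07]`, normalized -- an in-plane
coupling consistent with pickup dominated by the planar array and
headstage geometry.

Spike/artifact separation uses two statistics per image: the *spread
index* (fraction of electrodes whose peak exceeds 30 % of the maximum)
and the *latency dispersion* (std of peak latencies over those
electrodes, in ms). An image is an artifact if spread > 0.5 and
dispersion < 0.2 ms. These thresholds are this package's definition of
the spatiotemporal separation idea -- the statistic used in the original
hardware analysis is not specified -- and they are exposed as arguments.
A deliberate boundary case is retained: an artifact visible on a single
electrode is labeled "spike", documenting that on one electrode an
induction artifact can genuinely resemble a biological waveform; the
classifier's power comes from the array, not the waveform.

The benchmark scenario draws 367 spike-like and 144 artifact-like
images (the population sizes of the reference dataset) with residual
averaging noise of 2 uV; artifact amplitudes are drawn from 50--200 uV,
above the noise floor, so separation is by construction and the
expected outcome is zero misclassification and ROC area 1.0 -- which
the tests check over 200 seeds. Passing this says the statistics
separate the *modeled* populations perfectly; it does not certify
performance on real recordings, where overlapping spikes, drifting
electrodes and sub-noise artifacts occur.

Event-triggered stimulus averages use a frame-based binary noise
stimulus at 120 Hz: spike times of a visually driven cell recover the
planted temporal kernel, while artifact times average flat at the
stimulus mean -- the control that confirms artifacts carry no visual
signature.

## Numerical and testing choices

Problem sizes in the tests are chosen to finish quickly while leaving
Monte-Carlo margins comfortable: 1500--36000-sample trajectories for
calibration checks, 16--32-electrode layouts for recording-level tests
(the full 512-site default is exercised by the classification
benchmark), 3 x 3 grids for monotonicity checks with the full 5 x 5
scan in the end-to-end suite. Fixed seeds make every stochastic test
reproducible; none of the tolerances were derived from the observed
values they check, but from the noise model (e.g. 3 standard errors, or
the sqrt(64/k) prediction within 5 %).

Known limitations, beyond those noted per module: no temperature
drift anywhere; no closed-loop stimulation; no real spike sorting
(ground-truth labels stand in for it); and the magnetometer emulation
covers rate, oversampling and range semantics of the sensor class, not
its register map.
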