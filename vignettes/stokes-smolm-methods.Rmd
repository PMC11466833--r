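---
title: "Methods: Stokes-based single-molecule orientation imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Stokes-based single-molecule orientation imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stokescam)
```

This vignette records the models, numerical choices and known limitations
behind `stokescam`, at the level of detail a user needs to judge what the
package's results do and do not establish.

## Physical model

### Dipole emission and the four-channel estimator

A fluorophore with a dominant emission dipole moment radiates with
intensity proportional to $\sin^2\eta$, where $\eta$ is the angle between
the observation direction and the dipole axis. Behind an objective of
numerical aperture NA in immersion medium $n_{\mathrm{imm}}$ (half
collection angle $\alpha = \arcsin(\mathrm{NA}/n_{\mathrm{imm}})$), the
total intensity transmitted by an ideal linear analyzer at angle $\eta_a$
is, for a dipole at azimuth $\phi$ and polar angle $\theta$,

$$I(\eta_a) \propto A + B\sin^2\theta + C\sin^2\theta\cos 2(\phi-\eta_a),$$

with the angular constants

$$A = \tfrac16 - \tfrac14\cos\alpha + \tfrac1{12}\cos^3\alpha,\quad
  B = \tfrac18(\cos\alpha - \cos^3\alpha),\quad
  C = \tfrac7{48} - \tfrac{\cos\alpha}{16} - \tfrac{\cos^2\alpha}{16}
      - \tfrac{\cos^3\alpha}{48}.$$

`fourkas_constants()` evaluates these closed forms; the test suite
verifies them to $10^{-6}$ relative against an independent numerical
quadrature of the dipole far field over the collection cone. Rewriting the
four channel intensities as Stokes parameters
($S_0 = (I_0+I_{45}+I_{90}+I_{-45})/2$, $S_1 = I_0 - I_{90}$,
$S_2 = I_{45} - I_{-45}$) gives the two estimators the whole package rests
on: $\phi = \tfrac12\mathrm{atan2}(\langle S_2\rangle,\langle S_1\rangle)$
(the angle of linear polarization) and
$\theta = \arcsin\sqrt{Ap/(C-Bp)}$ with the net degree of linear
polarization $p = \sqrt{\langle S_1\rangle^2 + \langle
S_2\rangle^2}/\langle S_0\rangle$. Under this parameterization $\theta$ is
the polar angle from the optical axis: an axial molecule has $p = 0$ and
$\theta = 0$, an in-plane molecule maximizes $p$. That convention makes the
inversion self-consistent (its alternative, $\theta$ as elevation above the
sample plane, would put $\theta=0$ at maximal polarization, contradicting
the formula), and it is what the package uses throughout.

The $\phi$ estimator is robust — it needs only the signs and ratio of two
differences of large numbers. The $\theta$ estimator is exact only for a
rotationally immobilized emitter, an index-matched sample, a region of
interest that captures the whole dipole image, and no noise; every
violation biases it. The package reports $\theta$ with a validity flag
(clamped inversion argument) rather than hiding the failure modes.

### Vectorial image formation

`dsf_basis()` / `simulate_dipole_channels()` implement image formation for
a dipole near the coverglass: the s- and p-polarized far-field amplitudes
of the dipole in the sample medium, Fresnel-transmitted through the
sample/glass interface, collimated with the aplanatic $1/\sqrt{\cos}$
apodization, and propagated to the image plane by FFT. Above the critical
angle the sample-side cosine is continued as $+i\sqrt{\sin^2-1}$, which
captures supercritical-angle fluorescence for emitters at the interface
(the default $z = 0$). The model is two-media (glass = immersion); a full
stratified three-media stack is out of scope. With $n_s = n_{\mathrm{imm}}$
and the aplanatic apodization, the simulated channel energies reproduce the
closed-form $A, B, C$ integrals exactly — this is checked in the tests, as
is recovery of $(\phi,\theta)$ from simulated channel sums to within 2°.

Because detected intensity is a quadratic form in the dipole unit vector,
a wobbling molecule's time-averaged image depends on its orientation
distribution only through the second moments
$\langle\mu\mu^\top\rangle$. For the uniform cone these moments have an
exact closed form ($\mathrm{diag}(a,a,b)$ in the cone frame with
$b = (1+c+c^2)/3$, $c = \cos\delta$), which the simulator uses directly;
a stratified Monte-Carlo average over $10^4$ cone orientations agrees with
it to better than $10^{-3}$ relative RMS in the tests. The scalar
rotational-constraint parameter is defined from the same second moment,
$\gamma = (3\langle\cos^2\beta\rangle - 1)/2 = \cos\delta(1+\cos\delta)/2$,
spanning 1 (immobilized) to 0 (free). One subtlety the Monte-Carlo
cross-check exposed: a wobbling molecule emits at constant power, so the
photons each instantaneous orientation delivers to the camera scale with
that orientation's coupling to the collection cone; an average of
per-orientation images individually normalized to equal detected photons
differs from the correct average by about 1%.

### Photon bookkeeping and the camera

`dipole_emitter(photons =)` counts photons arriving at the analyzer plane
over the whole image plane. Ideal analyzers transmit half of an
unpolarized field, so the mosaic detects on average 50% of those photons —
the test suite and the acceptance script verify 50% ± 2% by Monte-Carlo
over random orientations. High-NA dipole images have $r^{-3}$ intensity
tails, so a finite simulation grid never captures quite all the energy;
energy statements are therefore checked as transmitted/incident ratios
within the rendered plane.

The CMOS model (`camera_noise_model()`) is
$\mathrm{ADU} = \mathrm{round}(g\,e) + \mathrm{offset}$ with
$e \sim \mathrm{Poisson}(\mathrm{QE}\,(\mathrm{signal}+\mathrm{bg})) +
\mathcal N(0,\sigma_r)$, clamped to the bit depth. Defaults — QE 0.7,
gain 1 ADU/e⁻, offset 100 ADU, read noise 2 e⁻ RMS, 16 bit, 10 background
photons/pixel/frame — describe a current micropolarizer camera: QE near
0.7 (below scientific CMOS), a few electrons of read noise, and a
background level typical of single-molecule experiments. "Background" is
counted per pixel at the detector (after the analyzer). All noise flows
through an explicit seed and restores the caller's RNG state.

## Demosaicking

The 2 × 2 analyzer pattern turns one raw frame into amplitude-modulated
Stokes components: $S_0$ at baseband, $S_1$ and $S_2$ on the Nyquist
carriers. `demosaic_fourier()` demodulates against the four pixel-parity
carriers and solves the small linear system that any 2 × 2 analyzer
permutation induces, so the tile order is configuration, not code. The
low-pass window is a radial raised cosine with default cutoff 0.25
cycles/pixel and transition half-width 0.02: at the optimal pixel pitch
the measured spectral supports leave only a narrow gap (roughly 0.235 to
0.265 cycles/pixel) between baseband and carriers, and a filter that rolls
off across that gap leaks neither band (a wider transition visibly
corrupts single-molecule Stokes maps — this failure mode is what fixed the
default). `demosaic_spline()` is the alternative route: split the mosaic
into its four quarter-resolution channels and upsample each with separable
cubic splines honouring its half-pixel lattice offset. The two routes
agree within 3% RMS on simulated molecules at the deployed pitch, and the
spline route beats nearest-neighbour and bilinear recovery on the same
input; both facts are tested. Background that varies slowly in time is
removed by a per-pixel temporal running median (default window 101
frames), which preserves blinking molecules; applied to raw stacks it acts
per polarized channel automatically since each pixel keeps its analyzer.

## The intensity-only pipeline

Per frame: ADU → photons via the global gain/offset/QE (per-pixel camera
calibration is out of scope); demosaic; subtract the frame-median of
$S_0$ (the ambient level of a sparse single-molecule field — $S_1$ and
$S_2$ are left untouched because an unpolarized background cancels in the
channel differences, and subtracting an estimate there would only add
noise); detect with a difference-of-Gaussians bandpass (scale 2 px at the
57.5-nm pitch) and a robust MAD threshold at $k = 5$, merging candidates
closer than one ROI; localize on a 9 × 9-pixel ROI by intensity centroid
or least-squares rotated asymmetric Gaussian (non-convergence falls back
to the centroid, flagged); estimate orientation from unweighted ROI Stokes
means. The detection threshold was calibrated on simulated blank frames
(≤1% of blanks yield any candidate) while keeping single-emitter detection
at ~100% for ≥500 detected photons, with no dependence on $\phi$ — the
detection image $S_0$ is polarization-blind by construction.

Choices worth recording:

* **ROI size 9 × 9 px** (~520 nm) suits $\phi$, avgDoLP and localization.
  The $\theta$ inversion, by contrast, is written for *total* channel
  intensities; restricting to 9 × 9 excludes low-polarization skirt pixels
  and biases netDoLP upward (≈ +6° at $\theta=60°$). Tests and examples
  that exercise $\theta$ therefore evaluate `estimate_orientation()` on a
  generous ROI (33 px) covering the dipole image; with it, noiseless
  index-matched recovery is within 2–5° over $\theta \in [20°, 80°]$. In
  water ($n_s = 1.33$) the same inversion is biased low (e.g. 60° → ~58°,
  90° → ~80°) — reported, not corrected, matching the estimator's stated
  domain of validity.
* **avgDoLP** is implemented as a *mean* of per-pixel DoLP (a sum over ROI
  pixels would leave $[0,1]$ and could not be thresholded at 0.4). The
  mean runs over pixels inside the spot's half-maximum support, with
  per-pixel values clipped to 1: outside the support the ratio is a
  quotient of near-zero numbers and measures noise, not mobility. With
  this definition immobilized in-plane molecules at 500–1000 detected
  photons sit near 0.9 and isotropic emitters near 0.26 (every simulated
  isotropic repeat falls below the 0.4 cut), so the threshold separates
  the regimes it is meant to separate.
* **Photometry**: the reported photons are the background-corrected ROI
  sum of $S_0$ divided by two (the mosaic detects half the incident
  intensity). The 9 × 9 window cannot hold the dipole tails, so this
  underestimates the true detected photons by a roughly constant factor
  (~0.65–0.75) — linear across brightness, which is what the ≥500-photon
  filter relies on; the tests pin the linearity, not an absolute match.
* **Axial statistics**: $\phi$ is 180°-periodic, so means and standard
  deviations use the angle-doubling method, avoiding wrap bias at ±90°.
* **Repeat linking** for precision benchmarks is deterministic greedy
  nearest-neighbour in frame order; groups are truncated to their first 40
  and discarded below 12 repeats before binning by photons and fitting the
  power law $\sigma = aN^b$.

Precision under the default noise model (immobilized in-plane molecule,
10 background photons/pixel, 200 repeats): $\sigma_\phi \approx 5.3°$ at
500 detected photons and $\approx 3.0°$ at 1000; lateral precision
~15 nm at 500 detected photons. With near-zero background the fitted
power-law exponent is −0.5 ± 0.1, the shot-noise signature; with 10
background photons/pixel the low-photon end is background-dominated and
falls faster, which is expected and not an error.

Drift correction subtracts the running-median-smoothed mean displacement
of fiducial tracks (linear interpolation over frames without fiducials);
a synthetic 0.5 nm/frame drift is recovered within 5%. Fourier ring
correlation splits the table randomly (seeded), renders two histograms and
takes the fixed-1/7-threshold crossing of the ring correlation; with a
densely labeled line pair at known $\sigma = 10$ nm it lands between
$2\sigma$ and $3\sigma$.

## Pixel-size design

Artifact-free demodulation requires the $S_0$ baseband and the $S_1/S_2$
carrier bands not to overlap. `stokes_spectral_overlap()` measures the
bands on simulated noiseless frames over a worst-case orientation set
(in-plane at 0°, 22.5°, 45°; axial; isotropic — spanning the modulation
extremes) as the radius enclosing 99.9% of each component's spectral
energy, and reports the signed gap $0.5 - r_{S_0} - r_{S_1/S_2}$
cycles/pixel. Sampled dipole images are not strictly band-limited, so
supports are measured rather than set to the optical cutoff $2\mathrm{NA}/\lambda$.
The energy fraction is the one tunable of this criterion: 99% yields
65 nm, 99.5% 62.5 nm and 99.9% ~61 nm for the 1.4-NA / 650-nm / aqueous
reference configuration. The package uses 99.9% — the faint outer part of
the dipole spectrum still carries polarization modulation, and the
stricter fraction reproduces the ~60-nm design point this criterion is
known to give for that configuration, which also certifies the deployed
57.5-nm pitch (3.45 µm / 60). `optimal_pixel_size()` sweeps pitches
(default 2.5-nm steps) and interpolates the margin's zero crossing; the
margin is monotone decreasing in pixel size, so the crossing is unique.

## Simulation scope and problem sizes

The simulator emulates: vectorial dipole images at a glass/sample
interface (in focus by default), wobble cones, the analyzer mosaic with
optional finite extinction, and pixel-wise CMOS noise. It does not
emulate: spatial QE/gain non-uniformity or defective micropolarizer
pixels, optical aberrations beyond defocus, chromatic effects, sample
drift during a frame, or fluorophore photophysics (blinking is imposed by
the scene, not emergent). Passing tests therefore certify the estimator
chain under an ideal-but-noisy camera, not robustness to instrument
non-idealities — the latter needs per-pixel calibration, which is out of
scope here.

Default problem sizes keep the whole suite comfortably interactive:
32 × 32-pixel frames for single-molecule scenes (64–48 px where tails
matter), 128 pupil samples across the aperture embedded in a ≥512-point
FFT (≥4× padding; no aliasing at 57.5-nm pixels), 200 repeats for
precision estimates, 2.5-nm design-sweep steps. All are arguments, not
constants.

## Known limitations

* $\theta$ from netDoLP is usable only near its assumptions; the package
  flags rather than fixes violations. Dipole-image **shape** fitting,
  which handles mobility and index mismatch, is deliberately not included.
* No $S_3$: a linear-analyzer mosaic cannot measure circular polarization.
* No 3D (z) localization; defocus is a forward-model parameter only.
* The Fourier demodulation assumes a spatially uniform, ideal mosaic;
  real micropolarizer arrays need per-pixel calibration for best results.
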