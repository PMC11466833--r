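# stokescam

Single-molecule orientation imaging with a polarization camera, in R.

## The problem

Fluorophores emit like oscillating electric dipoles, so the polarization of
their fluorescence encodes the orientation of the molecule. Single-molecule
orientation localization microscopy (SMOLM) exploits this, but most
implementations need beam-splitting optics and slow dipole-spread-function
fitting. A division-of-focal-plane *polarization camera* — a sensor whose
pixels carry a repeating 2 × 2 mosaic of linear micropolarizers at 0°, 45°,
90° and −45° — measures four polarized channels in a single shot on an
unmodified wide-field microscope. `stokescam` provides the computational
side of that experiment for people building or analyzing such instruments:

* a **vectorial dipole-spread-function simulator** (back-focal-plane fields
  of a dipole at a coverglass interface, Fresnel transmission including
  supercritical-angle fluorescence, wobble-cone averaging, the analyzer
  mosaic, and a CMOS camera noise model),
* **Stokes demosaicking** of raw mosaic frames by Fourier demodulation or
  cubic-spline channel interpolation,
* the **fast intensity-only SMOLM pipeline**: detection on the recovered
  incident intensity, centroid or rotated-Gaussian localization, in-plane
  and out-of-plane orientation and rotational-mobility estimation, photon
  and mobility filtering, fiducial drift correction, precision
  benchmarking, Fourier ring correlation,
* **pixel-size design**: the largest sample-plane pixel that still permits
  artifact-free Stokes recovery, from the Fourier-domain carrier-overlap
  criterion,
* polarization-resolved **rendering** (HSV composites, orientation-coded
  rod maps).

## The estimator

With the four co-registered channel intensities the first three Stokes
parameters are

    S0 = (I0 + I45 + I90 + I-45) / 2,   S1 = I0 − I90,   S2 = I45 − I-45.

Averaging over a small region of interest around one molecule (angle
brackets), the in-plane dipole azimuth is the angle of linear polarization

    phi = ½ · atan2(⟨S2⟩, ⟨S1⟩)  (the AoLP),

and the polar angle of a rotationally immobilized molecule follows from the
net degree of linear polarization
p = sqrt(⟨S1⟩² + ⟨S2⟩²) / ⟨S0⟩ through

    theta = asin( sqrt( A·p / (C − B·p) ) ),

where A, B, C are angular integration constants of the objective's
collection cone (half angle α = asin(NA / n_imm)); `stokescam` evaluates
them in closed form and verifies them against numerical quadrature of the
dipole far field. The per-pixel degree of linear polarization averaged over
the molecule's image (avgDoLP) serves as a rotational-mobility proxy: free
rotors depolarize and fall below the conventional 0.4 threshold.

## Worked example

Simulate 50 frames of one immobilized in-plane molecule (ϕ = 30°,
θ = 90°, 2000 photons at the analyzer plane ⇒ ~1000 detected) on the
1.4-NA / ×60 / 3.45-µm configuration and run the intensity-only pipeline:

```r
library(stokescam)

optics <- optical_config()             # NA 1.4 oil, x60, 630 nm
fourkas_constants(collection_half_angle(optics))
#> Angular constants (alpha = 1.1739 rad): A = 0.074841, B = 0.041099, C = 0.111131

pitch <- sample_pitch_nm(optics)       # 57.5 nm virtual pixels
grid  <- image_grid(32, 32, pitch)
mol   <- dipole_emitter(x_nm = 15 * pitch, y_nm = 15 * pitch,
                        phi_deg = 30, theta_deg = 90, photons = 2000)
sim <- simulate_stack(scene_repeats(mol, 50), optics, grid, seed = 42)
res <- pipeline_localize(sim$stack, optics, noise = camera_noise_model())
res
#> SMOLM result: 50 localizations from 50 frames (50 candidates)
phi_mean(res$table$phi_deg); phi_sd(res$table$phi_deg)
#> 30.24      # degrees: unbiased in-plane angle
#> 2.56       # degrees: precision at ~1000 detected photons
```

Every frame is detected once (no orientation is preferentially missed),
the recovered in-plane angle is unbiased with ~2.6° spread at this photon
level, the mean lateral position error is ~9 nm, and the mobility proxy
(mean avgDoLP 0.95) correctly reports an immobilized molecule. Dropping
`cone_deg = 90` into the emitter instead yields avgDoLP below 0.4 — the
standard cut for "too rotationally free to orient".

Designing the camera sampling for a different instrument:

```r
opt <- optical_config(numerical_aperture = 1.4, wavelength_nm = 650, n_sample = 1.33)
optimal_pixel_size(opt)$optimal_nm     # largest artifact-free pixel, ~61 nm
```

A thin command-line front end over the same functions ships in
`inst/cli/stokescam.R`
(`simulate | design | process | localize | filter | drift | frc | render | benchmark`).

## Conventions

* Image frame: x right (columns), y down (rows); 0-based pixel indices
  with the pixel-centre convention; positions in nm, pixel `(0,0)` at
  `(0,0)` nm.
* ϕ ∈ (−90°, 90°] measured from +x toward +y; 180°-periodic (axial)
  statistics via angle doubling.
* θ ∈ [0°, 90°] measured from the optical axis: θ = 90° is in-plane,
  θ = 0° is along the optical axis (netDoLP 0).
* "Detected photons" are photons reaching the sensor; the analyzers absorb
  on average half of the photons arriving at the mosaic.
* `dipole_emitter(photons = …)` counts photons at the analyzer plane, so
  ~`photons/2` are detected.

See the methods vignette (`vignettes/stokes-smolm-methods.Rmd`) for the
model, its assumptions, parameter choices and limitations.
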