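---
title: "Methods: FPM simulation, phase retrieval and the multi-scale lacunarity dose assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FPM simulation, phase retrieval and the multi-scale lacunarity dose assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fpmfa` implements a complete *in silico* version of a copper-pollution
assay that uses chain-forming marine diatoms as optical bio-probes. The
pipeline has three scientific layers, each exposed as ordinary R
functions: a Fourier Ptychographic Microscopy (FPM) image-formation model
and its inverse (iterative phase retrieval with embedded pupil recovery),
fractal and texture descriptors of the retrieved phase-contrast map, and a
two-step calibration/classification scheme that converts a descriptor pair
into one of seven copper dose intervals.

## 1. Image formation and retrieval

### Forward model

A thin, pure-phase sample `o(r) = exp(i phi(r))` is illuminated by a
quasi-plane wave from LED *n*, which multiplies the field by
`exp(i 2 pi nu_n . r)` and therefore shifts the sample spectrum `O(nu)` by
the carrier frequency `nu_n = sin(theta_n) / lambda`. The objective passes
the band inside its pupil `P(nu)`, a circle of radius `NA_MO / lambda`
whose phase encodes aberrations, and the camera records

```
I_n(r) = | IFT{ O(nu - nu_n) P(nu) } |^2 .
```

`forward_acquire()` evaluates this model exactly on sampled grids. Two
numerical conventions matter and are used identically in the simulator and
the reconstruction, so the pair is self-consistent:

* **Centered spectra, integer shifts.** All spectra are stored DC-centered
  and `nu_n` is rounded to the nearest spectral sample. Sub-sample spectral
  interpolation is deliberately omitted; with the LED geometries used here
  the rounding error is below the spectral sample spacing and identical on
  both sides of the pipeline.
* **Shared spectral pitch.** The high-resolution (object) grid is an even
  integer factor `f = ceil((NA_MO + lambda max|nu_n|) / NA_MO)` larger than
  the detector grid, so both spectral grids share one sample spacing and
  band extraction is pure cropping.

The synthetic LED array is a 15 x 15 matrix truncated to a disk of radius
7.3 pitches, which keeps 177 LEDs — the on-axis LED first, the rest ordered
center-outward so bright-field information is always processed before
dark-field shells.

### Inverse model

`reconstruct()` runs the sequential Gerchberg-Saxton-Fienup retrieval. Per
LED visit: simulate the detector field from the current estimates, replace
its modulus by `sqrt(I_n)` (keeping `sqrt(I_n)` at zero phase where the
modulus vanishes), transform back, and apply gradient-style corrections to
the object band and the pupil. The object step is weighted by
`|P| P* / (max|P| (|P|^2 + delta1))` and the pupil step by the analogous
expression in the shifted object band, with `delta1 = delta2 = 1e-4`
*relative to* `max|P|^2` and `max|O|^2`; the relative scaling makes the
defaults meaningful regardless of the physical scale of the spectra. Both
maxima are evaluated on the pre-update estimates, once per LED visit. After
every pupil step the pupil is re-projected onto its circular support.
`J = 20` outer loops with an optional early stop (relative amplitude misfit
below `1e-6`) are the default; there is no universally agreed stopping
rule for this family of algorithms, and on the noiseless fixtures used in
the tests the misfit falls monotonically by more than an order of
magnitude.

Convergence is overlap-driven: with a 5 x 5 array at 2.5 mm pitch and
28 mm height (roughly 80% pupil overlap between neighbouring LEDs) the
phase RMSE on a noiseless 64 x 64 acquisition reaches ~0.01 rad within 20
loops, while a 4 mm pitch (sparser overlap) needs about 50 loops for
0.05 rad. The acceptance suite uses the former geometry.

No phase unwrapping is performed: the synthetic scenes keep peak phase
below pi, and `extract_phase_map()` warns if 1% or more of pixels sit near
+/- pi. Optional background flattening fits a quadratic surface to the
lower 60% phase quantile (background-dominated pixels) and subtracts it.

## 2. The synthetic diatom scene generator

`synth_diatom_scene()` is first-class, tested code — it defines the study
conditions for every claim the test suite makes. It renders chains of
elliptical phase domes (frustule full axes 7 x 3.2 um, peak phase 1.6 rad,
mean chain length 4 cells) placed uniformly at an areal density derived
from the culture conditions being emulated: 190,000 cells/ml spread as a
0.9 ml film across a 40 mm dish, i.e. ~136 cells/mm^2. The cell budget per
field is deterministic (the emulated protocol *controls* density by
dilution or re-concentration before acquisition, so Poisson inoculum noise
is not a feature of the experiment); randomness enters through placement,
orientation, chain lengths and the damage draws.

Copper stress is a single severity `s` in [0, 1] that drives three
morphological effects, in the direction observed for real dosed
populations: peak phase scales by `1 - 0.55 s` (degraded, optically
thinner frustules); each chain junction fragments with probability
`0.5 s`; and each cell lyses with probability `0.75 s^0.7`, leaking
cytoplasm as 1-2 um Gaussian halos (peak 0.25-0.55 rad) scattered around
the cell. The concave lysis exponent makes a sensitive subpopulation
respond already at low severities — the dose range where the assay needs
its finest resolution and where the entropy descriptor is observed to be
most discriminative. The dose-severity bridge is linear in dose,
`s = d/60` for the 72 h exposure (T3) and `s = d/120` for 48 h (T2): both
exposures share the control state at dose 0 and differ only in growth
rate, which is what makes the dual-exposure congruence check meaningful.

What the generator does *not* emulate: real frustule micro-ornamentation,
focus drift, illumination miscalibration, debris unrelated to the probes,
and optical absorption (scenes are pure phase). Tests passing on these
scenes therefore validate the machinery and its dose-response logic, not
performance on real micrographs.

## 3. Fractal and texture descriptors

The analysis substrate is the phase-contrast map. It is binarized —
default Otsu for exploratory use, but a **fixed threshold per experiment**
(0.2 rad here) for any calibration series, so that dose-driven loss of
phase contrast shows up in the masks instead of being re-normalized away
image by image.

Lacunarity is computed with the gliding-box (Allain-Cloitre) algorithm:
an `r x r` box slides with unit step over every fully-inside position, and
`Lambda(r) = E[m^2] / E[m]^2` over the box masses `m`. Fully-inside
positions keep the statistic bit-reproducible; the residual edge effect is
a box-phase weighting imbalance that vanishes as the field grows. Three
summaries feed the assay:

* **GL**, the global lacunarity: the geometric mean of `Lambda(r)` over
  the dyadic ladder `r = 2, 4, ..., min(dim)/4`. `Lambda` spans decades
  across that ladder, so the geometric mean is the scale-symmetric
  ensemble summary (arithmetic aggregation is available as an option).
* **LL**, the local lacunarity: `Lambda(r_local)` at a single probe-sized
  scale. `select_local_scale()` uses the rounded median equivalent
  diameter of the mask's connected components; in a calibration series the
  scale is chosen once (6 px at the 1 um analysis pitch, the scale of a
  single diatom) and held fixed, as an instrument parameter.
* **MSL = GL / LL**, the dose descriptor: the ratio contrasts
  population-scale gappiness, which grows as damage clumps and disperses
  material, against single-probe-scale gappiness.

The texture descriptor Delta-s is the *range* (max - min across the four
Haralick directions at distance 1 px) of the gray-level co-occurrence
matrix entropy, with Q = 64 levels. Quantization uses the full observed
phase range: realistic fields are more than 99% background, so an inner
percentile range (1st-99th) collapses to zero width and erases the
descriptor — this failure mode was verified empirically and is why the
robust-percentile variant, although available through `glcm_spec()`, is
not the default.

## 4. Calibration and the two-step dose call

MSL versus dose is fitted with `y = a exp(b x) + c`, `b > 0`
(`minpack.lm::nlsLM`); the three-parameter form lets independently fitted
exposure series share the dose-0 intercept, which is the congruence
property that distinguishes the fractal descriptor from ordinary texture
features. Delta-s versus dose is fitted with a least-squares cubic over
the low-dose domain only. Measured values are inverted to dose estimates
(closed form for the exponential, root bracketing on the monotone
restriction for the cubic; out-of-range values clamp to the domain ends
and are flagged) and binned in *dose space*: step 1 against
`{17.5, 22.5, 30}` uM, and — only when the step-1 estimate falls below
17.5 uM — step 2 against `{2.5, 7.5, 12.5}` uM inside `[0, 17.5)`. That
yields seven half-open intervals, boundary values assigning upward; the
lower-slope 48 h variant uses `{30, 42.5}` uM and no second step (three
intervals). Binning in dose space rather than raw descriptor space makes
the decision table reusable across recalibrations; the raw-threshold view
is recoverable by mapping the boundaries through the fitted curves.

## 5. Study sizes and numerical tolerances used by the tests

* Reconstruction checks: 64 x 64 detector grid, 25 LEDs, upsampling
  factor 2, J = 20, noiseless; phase RMSE compared after removing the
  global phase offset (piston), which retrieval cannot and need not fix.
* Resolution check: two 1.2 um-separated phase points — between the
  synthetic-aperture two-point limit (~0.8 um) and the objective-only
  limit (~1.5 um); a >= 20% profile dip counts as resolved.
* Descriptor monotonicity: 5 severities x 10 seeds on 1 mm^2 fields
  (1024 px at 1 um); medians across seeds must rise strictly with
  severity.
* End-to-end assay: 3.3 mm^2 fields (1820 px at 1 um — the full
  field of view of the emulated instrument, rendered at half its optical
  resolution to keep the suite fast), 3 calibration and 3 held-out fields
  per dose in {0, 5, 10, 15, 25, 35, 50} uM; at least 80% of held-out
  fields must receive the interval containing their true dose.
* Oracle equivalences (forward model, retrieval update, lacunarity, GLCM)
  are asserted at 1e-12; fixed-point invariance of the update at 1e-9;
  both on small grids where direct summation/enumeration is exact.

Descriptor-level studies run on the generator's ground-truth phase maps;
the optical round trip (simulate, acquire, retrieve) is exercised by the
reconstruction and resolution checks and by the pipeline smoke tests, and
behaves as an additional smoothing that leaves the dose trends intact.

## 6. Known limitations

* The gliding-box variant, the geometric-mean aggregation of GL, the
  median-diameter local scale, and the full-range GLCM quantization are
  this package's explicit definitions; alternative conventions exist and
  are configurable, and absolute descriptor values are only comparable
  within one convention set.
* The severity axis is synthetic; mapping it to real doses requires a
  recalibration on real specimens.
* LED positional miscalibration, multiplexed illumination and thick
  samples are out of scope; reconstruction assumes the nominal geometry.
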