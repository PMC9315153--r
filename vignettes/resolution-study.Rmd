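---
title: "How imaging resolution shapes Mueller-matrix-derived polarization properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How imaging resolution shapes Mueller-matrix-derived polarization properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(muellerscope)
```

## The question

A transmission Mueller matrix microscope measures, at every pixel, the full
4×4 linear response of a thin sample to polarized light. Polar decomposition
of that matrix yields three parameter images with direct physical meaning
for fibrous tissue: diattenuation *D* (polarization-dependent transmittance,
sensitive to fiber caliber), linear retardance *δ* (birefringent phase
delay, radians, tracking fiber density and orientation), and depolarization
*Δ* (loss of degree of polarization from multiple scattering).

Objective choice trades resolution against field of view and speed: a
4×/NA 0.10 objective images a wide field quickly at coarse resolution, a
60×/NA 0.80 objective the reverse. The question this package studies is
*which* polarization-derived structural information survives that trade —
quantified with first-order moments, co-occurrence texture features and
cross-magnification correlations — and *why* the diattenuation channel
behaves differently from retardance and depolarization, explained at the
photon level with exact cylinder-scattering physics and a polarized Monte
Carlo model.

Because no measured tissue stacks ship with the package, a seeded synthetic
generator of collagen-like fibrous regions stands in for the sample panel;
everything downstream of the generator is the same code a measured stack
would flow through.

## The polarimeter model and reconstruction

The instrument model is the dual-rotating quarter-wave-plate scheme:
horizontal polarizer and rotating QWP before the sample (angle θ),
rotating QWP and horizontal polarizer after it (angle 5θ), with 30 equal
steps of 6° spanning 180°. The detected intensity is

I(θ) = a₀ + Σₙ (aₙ cos 2nθ + bₙ sin 2nθ),  n = 1…12,

a trigonometric polynomial in ψ = 2θ whose 25 free harmonics
over-determine the 16 Mueller elements. `reconstruct_mueller()` inverts the
30×16 measurement matrix built from the known generator/analyzer states by
linear least squares; an equivalent route through the discrete Fourier
harmonics of the trace (`method = "fourier"`) is provided and agrees to
machine precision at ideal settings. Least squares was preferred as the
default because it is robust to step-count changes.

Two conventions are fixed once, here and in the code: Stokes components are
(s₀, s₁, s₂, s₃) = (intensity, H−V, +45°−(−45°), R−L circular), angles
counterclockwise looking toward the source; and the ideal waveplate with
fast axis at 0° maps (1, 0, 1, 0) to (1, 0, 0, −1). Whether the 30 steps
span 180° or 360° is a free configuration (`span_deg`); 180° is the default
since the ideal-element intensity is periodic with that period.

```{r}
M <- random_physical_mueller()
max(abs(reconstruct_mueller(simulate_measurement(M)) - M))
```

Forward-simulating the classical calibration standards (air, polarizers at
0°/45°/90°, quarter-wave retarders at 0°/30°) and reconstructing yields
maximum normalized element errors at machine precision — comfortably inside
the 1% bound a real calibrated instrument achieves.

## Polar decomposition

`lu_chipman()` factors an M11-normalized matrix as M = M_Δ · M_R · M_D:
the diattenuator is built from the first row, the depolarizer block is the
signed principal square root of m′m′ᵀ (sign of det m′), and the retarder is
what remains. The scalar maps are

* D = √(M₁₂² + M₁₃² + M₁₄²) / M₁₁ — computed on the normalized matrix so it
  is scale invariant;
* δ = arccos{√[(M_R(2,2)+M_R(3,3))² + (M_R(3,2)−M_R(2,3))²] − 1} — the
  standard linear-retardance magnitude. (A widely circulated typeset variant
  of this formula repeats the (3,2) element and flips a sign; that variant
  contradicts the quarter-wave sanity value δ = π/2, so the standard form is
  implemented.)
* Δ = 1 − |tr(M_Δ) − 1|/3.

Numerical choices: arccos arguments are clamped to [−1, 1] and pixels whose
clamping exceeds 10⁻⁶ are flagged rather than silently accepted; eigenvalues
of m′m′ᵀ in (−10⁻⁹, 0) are clipped to zero, more negative ones flag the
pixel; the ideal-polarizer limit D → 1 switches to a pseudo-inverse branch.
`decompose_image()` applies the identical algorithm per pixel in compiled
code (the scalar R implementation is the reference; tests assert agreement)
and returns a validity mask alongside the three maps.

## Texture quantification

Parameter maps are normalized to gray values [0, 255] (affine map, half-up
rounding; a constant map under the automatic range becomes all zeros). Mean
and Entropy are computed on the 256-level image; the co-occurrence matrix
re-quantizes to Ng = 64 levels and accumulates symmetric pixel pairs at
displacement d, with Contrast, Correlation, Energy and Homogeneity in their
standard forms (level indices 1…Ng enter Correlation's products).

Configuration decisions, each exposed as an argument:

* **Displacement per magnification** is fixed at d = 1, 3, 5, 11, 15 for
  4×, 10×, 20×, 40×, 60×, compensating the field-of-view differences.
* **Direction handling**: features are computed per direction over
  {0°, 45°, 90°, 135°} and averaged — the common Haralick practice, which
  removes fiber-orientation bias; a single-direction override exists.
* **Normalization range**: the per-image min–max default of
  `normalize_to_gray()` is standard for single images, but the study
  pipeline defaults to the fixed physical ranges (D, Δ ∈ [0,1];
  δ ∈ [0,π]) because cross-magnification comparisons of the Mean are only
  meaningful on a common scale.
* Mean/Entropy use the 256-level image; only the GLCM uses Ng = 64. Both
  levels are supported if the other reading is wanted.

## Cylinder scattering and phase functions

Collagen fibers are modeled as infinite dielectric cylinders (index 1.43)
in a host of index 1.35 at 633 nm. `cylinder_coefficients()` implements the
classical cylindrical-harmonic series for oblique incidence at zenith angle
ζ (ζ = 90° is normal incidence), with coefficients from Bessel-function
boundary conditions, truncated at N = ⌈x + 4x^(1/3) + 2⌉ (x the size
parameter) and extended until the trailing term falls below 10⁻¹² of the
leading one; far past convergence the Neumann functions overflow and the
series is cut just before the first non-finite order. The thin-wire limit
reproduces the two-term Rayleigh closed form (isotropic parallel channel;
cos²Θ perpendicular channel) to better than 1% at x ≈ 0.07, and the
single-scattering Mueller matrix obtained by the coherency transformation is
pure (Gil–Bernabeu depolarization index 1) — both are tested.

`phase_function()` integrates to 1 on a 1° azimuthal grid (per-degree
density, trapezoid rule); the unpolarized mode averages the parallel and
perpendicular incident channels. `forward_fraction()` then expresses the
study's central geometric fact: at 633 nm the fraction of scattered light
within the 15° acceptance cone of the 10× objective rises strictly from
100 nm through 200 nm and 1 µm to 1.5 µm radius — coarse fibers scatter
forward, thin fibers broadly. `acceptance_half_angle(NA)` = arcsin(NA)
links objectives to cones: 14.48° (≈15°) for NA 0.25, 53.13° for NA 0.80.

## The polarized Monte Carlo

`run_simulation()` transports photons along +z through a 6 µm slab with
scattering coefficient 200 cm⁻¹ (optical thickness 0.12 — a predominantly
single-scattering regime). Cylinder axes are drawn per event from a
Gaussian orientation distribution: mean along x, σ = 30° tilts about the y
axis (out of plane) and the z axis (in plane). These two orthogonal
fluctuation planes are the package's definition of "orientations fluctuate
around both axes" — note that for a mean-x axis a rotation *about* x would
be a no-op, so it cannot carry one of the fluctuations. The quoted spread
is interpreted as a standard deviation of 30° per rotation axis.

Each event preserves the photon's direction component along the cylinder
axis (the specular cone of an infinite cylinder); the cone azimuth is drawn
by inverse CDF from the polarization-resolved single-scattering intensity
on a 1° grid (series coefficients cached per 0.1° of incidence angle), the
Stokes vector is rotated into the incidence frame, multiplied by the event
Mueller matrix, and renormalized so s₀ is carried unchanged — there is no
absorption, so transmitted + backscattered (+ capped) weight equals
launched weight exactly, not just in expectation. Transmitted photons are
binned by exit polar angle (1° bins) with their Stokes vectors rotated to a
fixed detector frame (component 1 along the projection of lab x); the
per-bin Mueller matrix is estimated by least squares over a six-state input
basis (H, V, ±45°, R, L — over-determination reduces Monte Carlo noise
bias; a four-state basis is available).

Decisions worth stating:

* **Ballistic light.** At optical thickness 0.12 about 89% of photons exit
  unscattered at exactly 0° with identity Mueller response. A
  scattering-angle sweep that includes them is dominated by this constant
  background, so `d_vs_angle()` analyzes scattered light by default;
  `include_ballistic = TRUE` restores the full beam (used for the
  empty-medium identity check, where the slab must reproduce the identity
  matrix).
* **Cumulative vs annular.** The default sweep is cumulative (a high-NA
  cone also collects everything a low-NA cone sees); annular rings are an
  option. With cumulative scattered light at 10⁵ photons per state the
  model reproduces the three qualitative diattenuation findings: thin
  (100 nm) cylinders show larger D at 5° than coarse (1.5 µm) ones; thin-
  cylinder D falls from 5° to 55° (negative fitted slope at 95% bootstrap
  confidence over accumulation batches); and the coarse-cylinder change is
  much smaller in magnitude.
* One scattering coefficient serves all polarizations; polarization enters
  through the per-event Mueller matrix only, and polarization-dependent
  extinction of the ballistic beam is not modeled. Slab boundaries are
  index-matched (no Fresnel refraction).

## The synthetic tissue generator

`generate_fiber_map()` draws fibers as correlated random walks with
Gaussian cross profiles; radii come from a two-component mixture (thin
100–200 nm, coarse 1–1.5 µm) echoing the scatterer sizes above. The
rendered Mueller image composes, per pixel, exactly M_Δ · M_R · M_D with

* δ = 1.1 · density (radians), axis = local fiber tangent,
* D = d(radius) · density with d(r) = 0.02 + 0.10/(1 + (r/400 nm)²) —
  monotone decreasing, so thin fibers carry more diattenuation, the same
  direction the cylinder physics predicts,
* Δ = floor + 0.25 · density, the floor drawn per region from
  U(0.03, 0.10).

Because the composition order equals the decomposition order, recovery at
native resolution is exact — the generator provides known ground truth, not
merely plausible images. The density coupling of Δ plants a δ–Δ
correlation across regions whose recovery the pipeline must demonstrate; a
decoupled variant (`coupled = FALSE`) keeps only the random floor and must
yield near-zero correlation. No quantitative per-pixel optical coefficients
for real skin exist to copy, so these defaults are explicitly configuration
chosen for plausibility (retardance up to ~1.1 rad and depolarization up to
~0.35 for dense collagen at 6 µm), not measured values.

`degrade_resolution()` models the objective as a Gaussian point-spread
function of sample-plane width σ = 0.21·λ/NA (the standard widefield
approximation of the Airy core, one tunable constant) applied to all 16
element maps, followed by area averaging to the camera-limited pitch
3.45 µm / magnification. Both steps are positive-weight averages, so every
output pixel is a convex combination of physical Mueller matrices and stays
physical. All magnifications render the same centered region, as in an
experiment that switches objectives without moving the slide.

What the generator does *not* emulate: radiometric noise, optical-depth
dependent depolarization, out-of-plane fiber tilt, spatially varying
refractive index, or any coupling between the image-domain degradation and
the photon-level Monte Carlo — the two are deliberately separate
explanatory layers. Passing tests therefore demonstrate the pipeline's
internal correctness and the direction of resolution effects on known
ground truth, not quantitative agreement with any particular tissue.

## The study pipeline

`run_study()` chains generator → degradation → decomposition → texture into
a tidy table (region × magnification × parameter × statistic), box-plot
summaries, per-parameter Pearson correlation matrices across magnifications
and the per-magnification δ–Δ correlation. Everything is deterministic per
master seed. Correlations are computed on per-region means by default;
p-values are not adjusted (the analysis reports R descriptively).

```{r, eval = FALSE}
study <- run_study(study_config(n_regions = 27, seed = 2026))
glance(study)
autoplot(study, parameter = "D")
```

Problem sizes were chosen so the full suite runs on a laptop-class single
core: 240×240 native pixels per region (13.8 µm field at the 60× pitch of
57.5 nm), 27 regions, five magnifications, 10⁵ photons per input state and
200 bootstrap resamples in the Monte Carlo analyses. The structural claims
tested at these sizes (correlation directions, trend signs) are stable well
below them.

## Known limitations

* The retarder in the polarimeter model is an exact quarter-wave plate;
  component imperfections and wavelength dependence are out of scope.
* The decomposition is the polar (Lu–Chipman) factorization only;
  differential and symmetric decompositions, and circular retardance, are
  not implemented.
* Cylinders are infinite, homogeneous and lossless; no finite-length or
  coated scatterers, no sphere–cylinder mixtures, no birefringent host.
* The Monte Carlo targets thin-slab transmission; reflection geometries and
  index-mismatched boundaries would need the Fresnel branch it deliberately
  omits.
* Synthetic regions share one noise-free image model; conclusions about
  real stained or unstained tissue require measured stacks, for which the
  pipeline's input format (per-pixel 4×4 arrays with pitch/NA metadata) is
  the only contract.
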