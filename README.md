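# muellerscope

Tools for studying how objective magnification and numerical aperture (NA)
shape the polarization properties derived from transmission Mueller matrix
microscopy of fibrous, collagen-like media.

A Mueller matrix microscope records a 4×4 matrix **M** per pixel — the
complete linear polarization response of the sample. The polar (Lu–Chipman)
decomposition **M** = **M**<sub>Δ</sub> **M**<sub>R</sub> **M**<sub>D</sub>
yields three parameter images:

* diattenuation D = √(M₁₂² + M₁₃² + M₁₄²)/M₁₁ ∈ [0, 1],
* linear retardance δ = arccos{√[(M<sub>R</sub>(2,2)+M<sub>R</sub>(3,3))² +
  (M<sub>R</sub>(3,2)−M<sub>R</sub>(2,3))²] − 1} ∈ [0, π] rad,
* depolarization Δ = 1 − |tr(**M**<sub>Δ</sub>) − 1|/3 ∈ [0, 1].

The package implements the full analysis chain around that decomposition:

* **Polarimeter forward model + reconstruction** — dual-rotating
  quarter-wave-plate scheme (30 steps, 5:1 rate ratio), intensity traces,
  and Mueller reconstruction by least squares or Fourier harmonics
  (`simulate_measurement()`, `reconstruct_mueller()`).
* **Per-pixel polar decomposition** (`lu_chipman()`, `decompose_image()`;
  the pixel loop runs in compiled code).
* **Texture quantification** — Mean/Entropy on 256 gray levels, GLCM
  (Ng = 64) Contrast/Correlation/Energy/Homogeneity with per-magnification
  displacements d = 1, 3, 5, 11, 15 (`texture_summary()`).
* **Exact cylinder optics** — infinite-cylinder scattering series at
  oblique incidence, phase functions, forward fractions, single-scattering
  Mueller matrices (`phase_function()`, `forward_fraction()`).
* **Polarized Monte Carlo** — photon transport through a slab of oriented
  cylinders (µs = 200 cm⁻¹, 6 µm, 633 nm, σ = 30° orientation spread),
  angle-resolved transmission Mueller matrices, and the
  diattenuation-versus-collection-angle analysis (`run_simulation()`,
  `d_vs_angle()`, `d_trend()`).
* **Synthetic fibrous tissue** — seeded generator of collagen-like regions
  whose per-pixel ground truth is exactly recoverable, plus an
  NA-dependent degradation model (Gaussian PSF σ = 0.21·λ/NA, area
  averaging to camera pitch 3.45 µm/mag) covering 4×/0.10 through 60×/0.80
  (`generate_region_set()`, `degrade_resolution()`).
* **Study pipeline** — tidy texture tables, box-plot summaries,
  cross-magnification Pearson correlation matrices and δ–Δ correlations
  (`run_study()`, with `tidy()`, `glance()`, `autoplot()` methods).

## Worked example

```r
library(muellerscope)

# a sample with known properties, measured by the simulated polarimeter
M <- mueller_depolarizer(0.4) %*% mueller_retarder(1.0, 20) %*%
  mueller_diattenuator(0.2, 0)
trace <- simulate_measurement(M)          # 30-step intensity trace
Mhat <- reconstruct_mueller(trace)
max(abs(Mhat - M))
#> [1] 2.498002e-16

tidy(lu_chipman(Mhat))
#> # A tibble: 1 × 6
#>       D delta Delta  axis flag     resid
#>   <dbl> <dbl> <dbl> <dbl> <chr>    <dbl>
#> 1   0.2 1.000 0.400 0.349 ""    1.11e-16
```

The reconstructed matrix is exact to machine precision, and the
decomposition returns the planted D = 0.2, δ = 1.0 rad, Δ = 0.4 with the
retarder axis at 20° (0.349 rad).

```r
# why diattenuation behaves differently: scattering geometry of fibers
sapply(c(100, 200, 1000, 1500), function(r)
  forward_fraction(phase_function(cylinder_spec(r), medium_spec()), 15))
#> [1] 0.2286077 0.4220478 0.9654080 0.9757388
```

The fraction of scattered light inside the 15° acceptance cone of a
10×/NA 0.25 objective (`acceptance_half_angle(0.25)` = 14.48°) grows
strictly with fiber radius: coarse fibers scatter forward, thin fibers
broadly — which is why thin-fiber diattenuation fades as the collection
angle widens.

```r
# the full synthetic study (a few minutes)
study <- run_study(study_config(n_regions = 27, seed = 2026))
glance(study)
#> # A tibble: 1 × 4
#>   n_regions n_magnifications min_adjacent_r_delta min_delta_Delta_r
#>       <dbl>            <int>                <dbl>             <dbl>
#> 1        27                5                0.996             0.705
```

Per-region mean retardance correlates above 0.99 between adjacent
magnifications (fiber-density information survives resolution loss), and
the generator's planted coupling between retardance and depolarization is
recovered with R >= 0.7 at every magnification.

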