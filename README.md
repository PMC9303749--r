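# canopysphere

Estimate forest canopy structure — gap fraction, plant area index (PAI)
and vertical plant area density (PAD) profiles — from 360° spherical
photographs, and cross-check the profiles against an airborne laser
scanning (ALS) transmission proxy.

## The problem

Digital hemispherical photography (DHP) estimates canopy structure from
the ground by measuring the gap fraction *P*(θ), the probability that a
ray at zenith angle θ passes through the canopy unobstructed. Under the
Beer's-law turbid-medium model,

    P(θ) = exp( −G(θ) · Ω(θ) · PAI / cos θ )

where G is the foliage projection function (0.5 for a spherical leaf
angle distribution) and Ω the clumping index. A camera that can move
*vertically* through a canopy gap — e.g. a small drone shooting a
spherical panorama at a series of heights — turns the single ground-based
estimate into a vertical profile: since PAI measured at height *z*
integrates everything above *z*, the density of the layer between two
consecutive capture heights is

    PAD ≈ (PAI_i − PAI_j) / (z_j − z_i)     (i below j).

`canopysphere` implements the full measurement chain:

1. **Reprojection** — equirectangular panoramas (azimuth on x, zenith on
   y) are resampled to upward-looking hemispherical images with a
   configurable lens function (equidistant by default).
2. **Segmentation** — gamma linearization (`(v/255)^2.2`) and automatic
   Ridler–Calvard (isodata) thresholding into sky and plant pixels.
3. **Inversion** — gap fractions on five 15° zenith annuli, inverted to
   PAI with the discretized Miller integral
   `PAI = 2 Σᵢ (−ln Pᵢ) cos θᵢ sin θᵢ Δθ / C`, where `C = 1 − cos θ_max`
   renormalizes the truncated zenith range; optional shoot-clumping
   correction divides PAI by 4·STAR (silhouette-to-total-area ratio,
   e.g. 0.147 for Scots pine, 0.161 for Norway spruce).
4. **Profiles** — replicate aggregation per height, layer PAD, and the
   replicate range-deviation statistic.
5. **ALS proxy** — canopy transmission `T(z) = 1 − N_c(z)/N_t` from
   return counts in a 10 m cylinder (1.5 m ground cut, 50 levels),
   extinction coefficient *k* fitted through the origin to the
   photographic PAI (`T = exp(−k·PAI)`), and PAD-profile comparison.
6. **Statistics** — OLS with relative standard error
   `RSE = SE/ȳ · 100`, Welch's t-test from group summaries, and a
   blue-band exposure metric.
7. **Synthetic ground truth** — slab canopies with closed-form *P*(θ),
   Bernoulli-dithered panorama rendering, and attenuated point-cloud
   simulation, so every stage is testable without field data.

## Worked example

A uniform slab canopy with PAD 1 m² m⁻³ from 0 to 6 m (true PAI 6 at the
ground) is rendered, reprojected, segmented and inverted:

```r
library(canopysphere)

canopy <- slab_canopy(0, 6, 1.0)                     # PAD 1 over 0-6 m, G = 0.5
pano   <- render_panorama(canopy, render_config(camera_height = 0,
                                                pano_height = 500, seed = 1))
hemi   <- reproject_to_hemisphere(pano, out_size = 1000,
                                  interpolation = "nearest")
mask   <- segment_image(hemi)                        # gamma 2.2 + isodata
gap_fractions(mask)
#> <gap_profile>
#>   theta_mid      P
#> 1       7.5 0.0468
#> 2      22.5 0.0370
#> 3      37.5 0.0226
#> 4      52.5 0.0072
#> 5      67.5 0.0007
miller_pai(gap_fractions(mask), star = 0.147)
#> <pai_estimate> PAI_raw = 5.8968 m2/m2, clumping-corrected = 10.0286 (STAR 0.147)
```

The raw PAI lands within 2% of the generating value of 6 (the annuli see
`exp(−3/cos θ)`, dropping from 0.047 near the zenith to under 0.001 at
67.5°). The clumping-corrected value is larger by 1/(4·0.147): on this
synthetic canopy no shoot clumping was simulated, so the corrected number
simply illustrates the STAR rescaling.

A full vertical profile — three replicate panoramas at each of 0, 2, 4
and 6 m, run through the whole chain:

```r
sim <- simulate_uas_profile(canopy, c(0, 2, 4, 6),
                            render_config(pano_height = 500, seed = 1))
height_profile(sim)
#> <height_profile>
#>   height   pai deviation_pct
#> 1      0 5.921           1.3
#> 2      2 3.997           0.7
#> 3      4 2.022           0.5
#> 4      6 0.000           0.0
#> layers:
#>   midpoint   pad
#> 1        1 0.962
#> 2        3 0.987
#> 3        5 1.011
```

Each layer density recovers the generating 1 m² m⁻³ within a few
percent, and the layer sums telescope exactly back to
PAI(0 m) − PAI(6 m).

A thin command-line wrapper with subcommands (`reproject`, `segment`,
`analyze`, `profile`, `als`, `compare`, `welch`, `simulate`) is installed
at `inst/cli/canopysphere.R`.

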