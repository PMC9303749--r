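---
title: "Methods: canopy structure from spherical photography and a laser transmission proxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy structure from spherical photography and a laser transmission proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopysphere)
```

## The measurement model

All of the photographic machinery rests on the turbid-medium gap-fraction
model. For a horizontally homogeneous canopy viewed from below at zenith
angle $\theta$,

$$P(\theta) = \exp\!\left(-\,\frac{G(\theta)\,\Omega(\theta)\,\mathrm{PAI}}{\cos\theta}\right),$$

where $P$ is the probability that a ray clears the canopy, $G$ the
projection of unit foliage area onto the plane normal to the ray (0.5
for a spherical leaf-angle distribution), and $\Omega$ a clumping index.
Miller's theorem integrates $G$ out:

$$\mathrm{PAI} = 2\int_0^{\pi/2} -\ln P(\theta)\,\cos\theta\,\sin\theta\,d\theta,$$

so PAI can be recovered from gap fractions alone without knowing the
leaf-angle distribution. The package discretizes this integral over
contiguous zenith annuli (default five rings of 15°, midpoint rule) and
renormalizes for the truncated 75–90° band (below). Assumptions
inherited from the model: foliage elements are small relative to the
annuli, dispersion within an annulus is random (residual shoot-level
clumping is handled only through the 4·STAR division, stand-level
clumping not at all), and the canopy is horizontally homogeneous at the
scale of the image footprint.

A camera that ascends through a canopy gap measures $\mathrm{PAI}(z)$ —
the plant area above the camera — at each height. Layer densities follow
by downward differencing,
$\mathrm{PAD} \approx (\mathrm{PAI}_i - \mathrm{PAI}_j)/(z_j - z_i)$,
which telescopes: the sum of $\mathrm{PAD}\cdot\Delta z$ over layers
equals the difference between the lowest and highest PAI, exactly, as
long as negative layers are not clipped.

The laser-scanning module uses the same physics read in reverse:
transmission estimated from return counts, $T(z) = 1 - N_c(z)/N_t$,
obeys $T = \exp(-k\,\mathrm{PAI})$, so a single extinction coefficient
$k$ converts the count profile into a PAI profile. $k$ is fitted against
the photographic PAI by least squares through the origin — the model
forces $\mathrm{PAI}=0$ at $T=1$, so an intercept would absorb signal
into a physically meaningless offset (an intercept variant is available
behind a flag for diagnostic use).

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| gamma | 2.2 | – | stored JPEG/PNG imagery is gamma-encoded; linearize as $(v/255)^{2.2}$ before thresholding |
| channel mode | rgb mean | – | all three bands weighted equally; blue-only retained because sky/foliage contrast peaks there |
| annuli | 5 × 15° | degrees | standard ring layout; covers 0–75°, leaving the distortion- and obstruction-prone near-horizon band unused |
| lens | equidistant, $\theta_{max}=90°$ | – | matches the built-in reprojection of panorama software; calibrated polynomials accepted |
| hemispherical size | 2000–4000 px | pixels | radius = size/2; analyses use the inside-disc mask, never the fill value |
| STAR | none; 0.147 pine / 0.161 spruce | – | shoot silhouette-to-total-area ratio; PAI is divided by 4·STAR, identity at the spherical value 0.25; broadleaves uncorrected |
| truncation factor | on | – | $C = 1-\cos\theta_{max}$, exact for spherical canopies (see below) |
| height step | 2 m | m | typical capture increment; arbitrary ascending grids accepted |
| cylinder radius | 10 m | m | laser returns are restricted to a vertical cylinder around the profile location |
| ground cut | 1.5 m | m | returns below it are ground; they count in $N_t$ only, never in $N_c$ |
| levels | 50 | – | equal-width level boundaries from the ground cut to the highest return (≈0.5 m spacing in a 25 m stand) |

## Numerical choices

**Midpoint rule and log-of-mean.** Each annulus contributes one gap
fraction — the sky-pixel proportion over the whole ring — evaluated at
the ring's midpoint angle. This is "log of the mean", not "mean of the
log": it matches how one gap fraction per ring is computed in practice,
and sub-ring (Lang–Xiang) averaging is out of scope. The midpoint rule's
discretization error for a spherical canopy is 0.29% at 15° rings and
under 0.01% at 1° rings; the test suite checks both. Within-ring
curvature of $P(\theta)$ adds a small bias (the ring mean is
area-weighted toward the outer edge); at the default geometry the
end-to-end recovery stays within a few percent.

**Truncation.** With rings covering only $[0°, 75°]$, the Miller
integral is incomplete. For a spherical canopy $-\ln P\cos\theta$ is
constant, so the missing band contributes exactly the fraction
$1 - (1-\cos 75°)$ of the integral; dividing by $C = 1-\cos\theta_{max}$
restores it. The correction is exact only in that case, which is also
the case the synthetic generator produces; for real canopies it is an
approximation, and it is on by default.

**Gap-fraction floor.** A ring with zero sky pixels would send
$-\ln P$ to infinity. Gap fractions are floored at one pixel out of the
ring's pixel count — the smallest observable non-zero proportion — a
simple convention documented in the estimate; with no pixel counts
available a zero gap fraction is an error instead.

**Isodata thresholding.** The Ridler–Calvard recurrence
$t \leftarrow (\mu_{<t} + \mu_{\ge t})/2$ starts from the global mean
(the classic initialization) and stops when the step falls below
$10^{-4}$ on the $[0,1]$ scale. If one side of the split empties, that
side's mean is taken as the current threshold. A constant image is a
degenerate histogram and errors; the pipeline wrapper falls back to the
manual threshold (0.5), which classifies an all-sky view correctly. The
main path works in continuous intensities; a 256-bin quantized
exhaustive scan exists only as the test oracle.

**Resampling kernel.** `reproject_to_hemisphere` defaults to bilinear
sampling, which is the right choice for real photographs: it avoids
aliasing along high-contrast edges before thresholding. The synthetic
profile simulator instead defaults to nearest-neighbour. Its renderer
dithers the canopy per pixel (Bernoulli sky/plant draws), and averaging
a dithered field before thresholding votes mixed pixels toward the
locally dominant class, biasing gap fractions away from 0.5; copying
single source pixels preserves the Bernoulli statistics and keeps the
closed-form expectations exact. This is a property of dithered imagery,
not of real scenes.

**Lens inversion.** Polynomial lens functions are inverted by monotone
bisection (50 halvings, interval below $10^{-15}$); monotonicity is
checked at construction. The linear lens inverts in closed form.

**Boundary conventions.** The cylinder filter keeps points exactly at
the radius; transmission levels are closed at the top (a level above the
highest return has $T=1$); the last annulus includes its outer edge;
laser levels are layer *boundaries*, with PAD assigned to the layer
between consecutive boundaries; photographic heights are matched to the
nearest laser level and dropped beyond one layer width. Each return
counts once — echo-number weighting is not modeled.

## The synthetic generator: what it does and does not show

`slab_canopy` + `render_panorama` + `simulate_point_cloud` produce data
whose ground truth is known in closed form: slab canopies give
$P(\theta) = \exp(-g\,\mathrm{PAI}_{above}/\cos\theta)$, panoramas are
per-pixel Bernoulli dithers of that field, and laser pulses descend
vertically with survival $\exp(-k\,\mathrm{PAI}_{above}(z))$, ground
returns landing below the 1.5 m cut. All generators are deterministic
under a fixed seed.

What this validates: the geometry of the reprojection, the thresholding,
the Miller inversion including its truncation handling, the profile
differencing, and the transmission/extinction chain — i.e. that the
pipeline inverts its own forward model without bias at realistic sample
sizes. What it deliberately does not emulate: crown geometry and
stand-level clumping, mixed pixels and penumbra, exposure variation and
stitching artifacts, sensor noise, off-nadir laser scan angles, and
multiple echoes per pulse. Passing tests therefore demonstrate
correctness of the estimators, not field accuracy of the method; the
dominant real-world error sources (exposure, stitching) enter upstream
of this package's inputs.

Problem sizes used in the validation suite: panoramas of 1000 × 2000 px
reprojected at 2000 px with three replicates per height for the
end-to-end slab recovery (PAI at ground within 5%, layer PAD within
10%), 50 000 pulses for extinction recovery (k within 10%), and smaller
rasters (60–300 px) wherever an exhaustive per-pixel oracle is compared
bit for bit. These sizes keep the whole suite under a minute while
leaving Monte-Carlo error well inside the asserted tolerances.

## Replicates and summary statistics

Replicate PAIs at a height are combined by arithmetic mean (computing
PAI per image and averaging, rather than averaging gap fractions first),
and their spread is reported as $(\max-\min)/\mathrm{mean}\times 100$%.
Method comparison uses OLS with the relative standard error
$\mathrm{RSE} = \mathrm{SE}/\bar y \times 100$,
$\mathrm{SE} = \sqrt{\mathrm{SSR}/(N-2)}$ (hence $N \ge 3$), and
Welch's unequal-variance t-test computed directly from group means,
variances and sizes with Welch–Satterthwaite degrees of freedom — the
form needed when only published summaries are available.

## Known limitations

- Gap fractions assume the segmentation is unbiased; systematic exposure
  differences shift the isodata threshold and propagate directly into
  PAI. The blue-band `exposure_metric` quantifies but does not correct
  this.
- Woody and green elements are not separated: all estimates are plant
  (not leaf) area.
- The truncation factor and the clumping division are exact only under
  the spherical assumptions stated above.
- LAS reading is limited to uncompressed files and x/y/z; LAZ and
  echo-level attributes are unsupported.
- Negative PAD layers are reported, not suppressed, by default — they
  are a truthful signal of drift or replicate noise.
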