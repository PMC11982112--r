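---
title: "Methods: under-ice phytoplankton imaging, classification and mixing diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: under-ice phytoplankton imaging, classification and mixing diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underice)
```

`underice` turns two data streams from a moored under-ice imaging
flow cytometer deployment into interpretable science: grayscale
particle images into per-taxon biovolume time series, and CTD /
irradiance profiles into a stratification-and-convection chronology.
This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## The biovolume estimator

A particle's 3-D volume must be inferred from a single 2-D silhouette.
We treat the shape as locally a solid of revolution about its medial
axis. For a pixel at distance $D$ from the mask boundary and distance
$M$ from the medial axis, the local half-width is $w = D + M$ and the
pixel sits at radius $s = M$ off the axis. Revolving the local
cross-section assigns the pixel a chord of length

$$2\sqrt{w^2 - s^2} \;=\; 2\sqrt{D\,(D + 2M)},$$

and the biovolume is the chord sum over the mask times
$(\text{µm/px})^3$. The identity is exact for the two generative
solids of the synthetic taxa: for a circular cylinder the medial axis
is the centre line ($D + M = w$ identically), and for a sphere it
collapses to the disc centre ($D + M = R$ along every radius). Tests
verify a rasterized $r = 20$ px sphere and a $100 \times 10$ px
cylinder to within 5% of the analytic volumes, and spheroids to within
10% of a brute-force voxelization oracle.

Numerics: the distance transform measures centre-to-centre pixel
distances, so the true boundary lies half a pixel beyond the nearest
background centre; we use $D - 0.5$ (floored at 0.05 px). The medial
axis is a Zhang–Suen thinning skeleton; for masks that thin to
nothing (single pixels) every pixel is treated as on-axis. Colony
images violate the solid-of-revolution assumption at junctions; their
biovolume is reported per image, not per cell — the instrument cannot
count cells within a colony, and no attempt is made to.

## Features and segmentation

Upstream IFCB processing chains extract several hundred features; we
implement a documented subset of ~15 (area, perimeter, equivalent
diameter, principal-axis lengths from second moments, elongation,
solidity against the pixel-corner convex hull, bounding-box extent,
blob count and area, and mean/variance/entropy of the masked
intensities, plus the biovolume). The subset is sufficient to separate
the six synthetic morphotypes (out-of-bag error below 1%); it does not
attempt bit-compatibility with any upstream feature file. The feature
order is fixed and version-stamped (`feature_version()`).

Segmentation is Otsu's threshold with a configurable floor (default
0.3) against near-blank frames, followed by a 3-px disc closing. The
floor matters only for images with no particle, where Otsu's
between-class criterion is unstable.

## The classifier selection protocol

The classifier is a random forest (bagged CART trees via the
`randomForest` package); the protocol around it is the contribution:

* **Balancing.** Every category must bring between `min_n` and `max_n`
  training images; under-represented categories are excluded and
  reported, over-represented ones are subsampled reproducibly by seed.
  The catch-all `Other` category is never trained on.
* **Unclassified contract.** An image is accepted only if its winning
  vote fraction reaches `vote_threshold` (default 0.5 — the natural
  majority point; the choice is exposed because no principled value
  exists without a cost model). Ties break to the lexicographically
  first category.
* **Grid selection.** The canonical grid crosses minima
  {200..500 by 100} with maxima {300..900 by 100} and tree counts
  {25, 50}: 28 ranges, 56 candidates. Degenerate pairs
  (`max_n < min_n`) are enumerated — the printed counts require it —
  but recorded as failed candidates rather than trained.
* **Scoring.** Candidates are ranked by accepted-classification error
  rate, with ties broken by unclassified fraction, then training-set
  size, then tree count: exactly the two metrics reported for a
  selection winner, made deterministic. Evaluation uses a stratified
  80/20 hold-out fixed by seed; the upstream protocol is not
  documented, and a fixed split keeps the whole grid comparable.

## Water-column physics

Density uses a limnological-range polynomial equation of state
(Chen–Millero type): a degree-6 pure-water polynomial in temperature,
a linear volumetric-salinity term, and a secant-bulk-modulus pressure
correction. Its zero-salinity maximum sits at 3.98 °C (4.0 at one
decimal), the anchor of winter inverse stratification. Volumetric
salinity (g L⁻¹) sums the eight major ions, carbonate species
partitioned from DIC by pH (two-pK equilibrium, pK₁ = 6.35,
pK₂ = 10.33), and H⁺/OH⁻; profiles scale this reference salinity along
the conductivity profile. Thermal expansibility is a central finite
difference of the EOS (step 0.01 °C); specific heat is the standard
pure-water polynomial (~4.2 kJ kg⁻¹ °C⁻¹ in the winter range).

**Potential density.** Stability work uses potential density (the
pressure term zeroed). At lake depths the compressibility contribution
to the in-situ gradient (~0.005 kg m⁻⁴) is of the same order as the
stability threshold yet represents no stratification; leaving it in
systematically inflates $N^2$ by two orders of magnitude in
near-isothermal columns and makes radiative convection undetectable.
`density_profile(potential = FALSE)` restores in-situ values.

**Stable surface layer.** Density is resampled to 0.5-m intervals from
the first valid depth; an interval is stable iff
$\partial\rho/\partial z > 0.01$ kg m⁻⁴ (threshold configurable). The
layer thickness $h$ is the maximal contiguous stable run starting at
the first interval; if the first interval already fails, no layer is
diagnosed — consistent with the convention that an unstable first
valid measurement means no detectable stable surface layer.

**Convection test.** At the layer base (the convective test depth):
scalar irradiance $Q$ = trapezoid-integrated planar PAR
(398.76–700.04 nm, µW cm⁻² nm⁻¹ → W m⁻²) divided by 0.75; buoyancy
flux $b = g\,\alpha\,Q/(\rho c_p)$, signed so that heating water below
the density maximum ($\alpha < 0$) gives $b > 0$; convective velocity
$w_* = (b\,h)^{1/3}$ for $b > 0$; $N^2 = (g/\rho)\,
\partial\rho/\partial z$ from the first interval *below* the layer
base, floored at zero; and $R_i = N^2 h^2 / w_*^2$ ($\infty$ when
$w_* = 0$). Convection is diagnosed iff $R_i \le 1$ and $b > 0$.

Evaluating $N^2$ below the layer base was a genuinely open design
point: the candidate reading "within the stable layer" is
self-defeating, because a diagnosed layer has
$\partial\rho/\partial z > 0.01$ kg m⁻⁴ by construction
($N^2 \gtrsim 10^{-4}$ s⁻²), which no realistic under-ice radiative
forcing can bring to $R_i \le 1$ (it would require
$Q \sim 10^4$ W m⁻²). Convective mixed layers form *beneath* the
stable surface layer, in the weakly stratified water the convection
must erode; that gradient is the physically meaningful numerator, and
with it realistic clear-ice forcing (50–70 W m⁻²) crosses the
threshold while snow-covered forcing (< 3 W m⁻²) never does. Whether
$Q$ should instead be the flux *absorbed within* the layer remains
unstated upstream; flux at the test depth is used, and the choice is
isolated in one place.

Constants: $g = 9.81$ m s⁻², freshwater carbonate constants at 25 °C.

## Sections

Profiles are first QC'd (empty, non-monotone-depth, or out-of-range
profiles dropped with logged reasons). Irradiance gaps within a
profile are filled by regressing $\ln E_d$ on depth — exact for
exponentially attenuated light, and exactly geometric interpolation in
the two-point case (100 at 1 m, missing at 2 m, 1 at 3 m → 10).
Observed values are never overwritten.

Gridding is depth-then-time: each profile is linearly interpolated to
the 0.1-m axis (0–18.5 m, 186 rows) within its observed depth range,
snapped to the nearest 20-min grid time (origin: midnight UTC of the
first profile day), then interpolated linearly in time per depth
between consecutive profiles no more than 6 h apart. The 6-h cap is
read strictly — no bridging across longer winch outages, no
extrapolation before the first or after the last profile; a lone
profile occupies exactly its nearest grid time.

## The synthetic-data generator

The generator emulates the *structure* of a winter deployment, not any
particular lake's values:

* **Morphotypes.** Star colonies (4–7 rods joined at one end), ribbon
  colonies (rods stacked side-by-side), needles, zigzag chains,
  chloroplast-shedding cylinders, and discs — the canonical shapes of
  the six target taxa, rendered as flat-shaded primitives plus
  Gaussian noise on a dim background. No optical/PSF model: the
  contracts being tested (segmentation area, feature separability,
  biovolume recovery) do not require one.
* **Abundance trajectories** are expected image counts per 5-mL sample
  at 2 m, splined through six seasonal knots with 5–8× early-winter to
  spring declines (the magnitude reported for real winter diatom
  populations) and peaks of 22–32 images per sample — tens of images
  of a dominant taxon per 5-mL winter sample is realistic for a
  mesotrophic lake. Depth attenuation is exponential (e-folding 8 m,
  referenced to 2 m). These defaults were fixed by a design-time power
  analysis: at 40 samples per depth they give ground-truth Spearman
  trajectory recovery with 5th percentile ≥ 0.82 for every taxon.
* **The frustule-loss artifact.** With probability `frustule_loss_prob`
  a cylinder taxon renders only 2–3 small chloroplast discs (< 61 µm³
  by construction) while its ground-truth biovolume remains the full
  cylinder. The mid-deployment flash-lamp step multiplies the
  *fragment capture rate* — full-frustule captures are unaffected,
  matching a lamp change that adds small detections rather than
  removing large ones.
* **Scheduling.** Samples recur per depth from the campaign start;
  a final sample whose period does not fit before the campaign end is
  dropped (1 day at 25 min → 57 samples). Defaults sample 2/4/10 m
  every 75 min and 15 m every 375 min (the ~5× shallow bias at a
  ~25-min overall cadence).
* **Scenarios.** `stable_winter` (inverse stratification, snow-covered
  light), `clear_ice_heating` (sharp thin surface layer over
  near-isothermal water, strong light), `isothermal_autumn` (uniform
  column) are constructed so the convection diagnosis exercises both
  of its outcomes and its no-layer branch. Profiles are deterministic;
  the diel cycle enters only through irradiance.

What passing tests show — and what they do not: recovery of imposed
trajectories demonstrates that the pipeline's plumbing (counting,
classification, filtering, normalisation, smoothing) preserves
abundance signal under Poisson sampling and the fragment artifact. It
does not validate the classifier against real morphological variation
(real images vary in focus, orientation and decoration far beyond flat
shading), nor the biovolume estimator against irregular cell shapes,
nor the physics against a real CTD record.

## Problem sizes in the tests

The end-to-end suite uses a 30-day campaign at 3 depths × 40 samples
(~8,000 images), a training database of 150 images per class plus 60
catch-all images, and a 2×2×2 selection grid; smaller fixtures cover
each operation's contract. These sizes were chosen as the smallest at
which the statistical acceptance properties (trajectory recovery
ρ ≥ 0.8, hold-out error ≤ 15%) are comfortably away from their noise
floors.

## Known limitations

* Colony biovolume is per image; junction overlaps make it a mild
  overestimate relative to the sum of member cylinders.
* The EOS is a freshwater polynomial: fine for g/L-scale salinities,
  not for brackish systems.
* The 61-µm³ filter is applied post-classification to the named class
  only; whether it should precede other corrections is not
  determinable from the upstream description.
* The interface is R functions and this vignette; there is no shell
  CLI. `write_campaign()`, `write_biovolume_records()` and the config
  YAML round-trip cover file-based interoperability.
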