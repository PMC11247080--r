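---
title: "cropsight: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cropsight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropsight)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline has four scientific stages —
pan-sharpening, HSV green-area segmentation, rule-based crop
recommendation, and evaluation against a dominant-crop reference — plus a
seeded synthetic-data stage that makes all of them testable offline.

## Raster model and resampling

Images are arrays of intensities in $[0,1]$ (8/16-bit files are rescaled on
read and quantized on write), row-major with the origin top-left. Working in
a continuous intensity domain makes the fusion arithmetic below well-defined
regardless of file bit depth. Grayscale conversion uses the ITU-R BT.601
luminance weights $0.299R + 0.587G + 0.114B$ — a standard model of the eye's
channel sensitivity, and a convex combination, so outputs stay in range.

Resampling supports nearest-neighbour, bilinear and cubic interpolation
under a pixel-centre convention (destination centre $i+\tfrac12$ maps to
source coordinate $(i+\tfrac12)\,s-\tfrac12$). Cubic uses the Keys
convolution kernel with $a=-0.5$, the common default where the method is
named without a kernel. Three numerical choices worth stating: border
samples are replicated for interpolation, out-of-range interpolants are
clipped to $[0,1]$ (cubic can overshoot), and all three methods reproduce
constant images exactly — a property the tests assert rather than assume.

## Pan-sharpening

Two fusions are implemented.

**High-pass-filter fusion.** With $M$ the grayscale multispectral image and
$P$ the (resampled) panchromatic band,
$$\mathrm{sharpened} = \mathrm{clip}\bigl(M + \lambda F(P)\bigr),$$
where $F$ is a zero-sum high-pass kernel: the 3×3 four-neighbour Laplacian
$[[0,-1,0],[-1,4,-1],[0,-1,0]]$ or a Difference of Gaussians with
$\sigma = (1, 2)$ by default. Convolution uses reflective padding (folded
periodically, so kernels wider than the image remain defined). $\lambda$
defaults to 1 and is fully configurable; at $\lambda = 0$, or for a constant
$P$, the operation is the identity — both are tested invariants.

**Brovey transform.** Per pixel and band $k \in \{R,G,B\}$:
$$Y_k = \frac{X_k\, X_p}{\max(X_R + X_G + X_B,\ \varepsilon)} .$$
The denominator is the sum over the three multispectral bands — the standard
three-band Brovey definition. $\varepsilon = 10^{-6}$ guards the
all-black-pixel division and pins its output to zero. Two identities
characterize the transform and are asserted to $10^{-9}$: the fused band sum
equals $X_p$ wherever the denominator is unguarded (intensity modulation),
and the transform is 1-homogeneous in the pan band. Whether to clip,
rescale or allow overflow after fusion is an open design point in most
descriptions of the method; this package clips, consistent with its global
intensity domain.

The full pipeline upsamples the multispectral image onto the panchromatic
grid (bilinear by default) and then fuses. An optional *HSV route*
(`hsv_route = TRUE`) re-injects the fused luminance as the V channel of the
upsampled multispectral image in HSV space, preserving hue and saturation
while taking sharpness from the fusion. Descriptions of HSV-mediated
sharpening are typically algorithmically underspecified; this is one
explicit reading, shipped off by default and labelled as an interpretation.

## Green-area segmentation and acreage

RGB→HSV follows the max-branch formulas: $V=\max(R,G,B)$,
$S=(\max-\min)/\max$ with $S=0$ at $V=0$, and hue in degrees from whichever
channel attains the maximum, wrapped by +360° when negative. The formulas
leave hue undefined for achromatic pixels ($\max=\min$); the package sets
$H=0$ there, and the saturation floor below makes the choice inconsequential
for masking. The inverse conversion is also provided; round-tripping is
exact to $10^{-6}$, which the suite checks against an independent
`grDevices::rgb2hsv` oracle.

A pixel is vegetation iff $H \in [h_{lo}, h_{hi}]$ (closed interval, no
wrap-around — green never straddles 0°) **and** $S \ge s_{min}$, $V \ge
v_{min}$. Defaults: hue 70–170°, $s_{min}=0.15$, $v_{min}=0.10$. Published
workflows of this kind rarely print their thresholds; these four values are
explicit engineering choices (the hue pair brackets the green band of the
hue circle generously; the floors reject gray roofs/asphalt and deep shadow,
whose hue is numerically arbitrary) and all are user-settable. No
morphological clean-up is applied by default — the method is pure
thresholding — but a `min_blob_px` speckle filter is available.

Acreage uses a map-scale convention: a scale of $y$ yards of ground per
on-screen centimetre at $d$ px/cm gives $y \cdot 0.9144/d$ metres per pixel
(defaults $y=126$, $d=37.795$, i.e. 96 dpi, ≈3.048 m/px — the screen
density is deliberately configuration, not a guess, since acreage scales
with its square), and
$$\text{acres} = n_{green}\cdot(\text{m/px})^2 / 4046.8564224 .$$

## Attribute categorization and the crop rule engine

Environmental records carry temperature (°C), relative humidity (%), wind
(km/h), precipitation (mm/day), UV index, volumetric soil moisture
(fraction) and terrain (plain/hilly). The units are declared package
conventions. Categorization maps these onto discrete levels: temperature
above 30 °C is *hot* ("exceeds 30 °C" read strictly, so the boundary is
moderate), 20–30 °C *moderate*, below *cool*; humidity low/moderate/high at
40/70 %; wind, precipitation, UV and soil moisture are two-level (≥ 20 km/h,
≥ 10 mm/day, ≥ 6 — the WHO "high UV" convention — and ≥ 0.30 VWC). Only the
temperature cut-points come from the decision narrative the engine
transcribes; the others are documented defaults, all configurable — the
engine's *logic*, not the cut-points, is the scientifically fixed part.

The narrative itself describes branch outcomes (which crops each weather
condition suggests) but no combination scheme. The package's scheme,
chosen for determinism and transparency:

- every *additive* rule whose condition holds contributes its weight
  (default 1) to each of its crops — the temperature/humidity branches, the
  precipitation branches, and the soil-moisture branches;
- *restrictive* stages (high wind, high UV) multiply the score of crops
  outside their tolerant set by 0.5 rather than deleting them, encoding
  "prefer tolerant crops" without violating totality;
- ranking is by score, ties broken by a canonical crop order (order of
  first appearance in the narrative), truncated to top-$k$.

The wind-resistant set {Millets, Ragi, Sugarcane, Groundnut} and UV-tolerant
set {Millets, Groundnut, Sunflower, Cotton, Sugarcane} are editorial: the
narrative names the *properties*, not the memberships. Both ship as data in
the rulebase, which round-trips through YAML so users can edit rules without
code. Conditions colder than 20 °C have no rules in the narrative; rather
than return nothing, the engine falls back to the broad moderate-band list
with a warning. With the full default rulebase the precipitation and soil
stages vote on every combination, so the fallback is only reachable with
reduced rulebases — the totality test enumerates all
$3\times3\times2^4\times2 = 288$ level combinations and asserts a non-empty,
duplicate-free ranking for each.

## Evaluation

Predictions are scored against a dominant-crop reference by the top-1
convention: a record counts as a match iff the first-ranked crop equals the
reference crop. The confusion matrix counts (truth, top-1) pairs; the
report computes per-class precision, recall and F1 with the 0/0 ≡ 0
convention, and overall accuracy as the diagonal fraction. F1 uses the
standard $2PR/(P+R)$; a printed variant of these formulas omitting the
factor 2 is inconsistent with its own reference rows (a class with
$P=R=0.80$ and printed $F1=0.80$ requires the factor), so the standard form
is used. A separate top-$k$ hit rate reports how often the reference crop
appears anywhere in the ranked list; it is never folded into accuracy.

The packaged 20-row district fixture is a transcription of a published
predicted-vs-dominant comparison. Recomputing from those rows gives 15/20
top-1 matches (75 %), Wheat recall 0.80 (4 of 5) and support 5, perfect rows
for Chickpea, Cotton, Groundnut and Mustard, zero rows for Maize and
Soybean, and Rice support 8. Three printed companion numbers are *not*
derivable from the same rows and are deliberately not reproduced: a Rice
row of 0.70/0.88 (the rows give 6/9 and 6/8), a Wheat precision of 0.80
(the rows give 4/6), and a narrative accuracy of "80 %" (the rows give
75 %). The package reproduces what the records imply and documents the
discrepancies; its own report is verified against a brute-force per-class
tally oracle on hundreds of random record sets instead.

## Synthetic data: what it emulates and what it does not

`generate_scene()` emulates the *geometry and colour statistics* that the
segmentation and fusion stages care about: a tan soil background, warm-gray
building rectangles, dark road strips, and elliptical vegetation patches
painted last (so the recorded ground-truth mask reflects final pixel
ownership), plus optional additive Gaussian noise. The palette is designed
from a noise-propagation argument fixed before any testing: every
non-vegetation element gets a warm hue (20–40°) with saturation ≥ 0.2 and
vegetation hues are drawn in [80°, 150°] with S ≥ 0.55, V ≥ 0.45, so that
noise of σ = 0.02 — a few grey levels — cannot move any pixel across the
70°/170° window edges or the S/V floors. Under these conditions noise-free
recovery is exact and the suite requires ≤ 2 % relative area error across 20
seeded noisy scenes. The panchromatic band is the scene's grayscale; the
low-resolution multispectral input is a σ = 1.5 Gaussian blur followed by
factor-4 decimation, enough degradation that fusion has visible work to do.

What the generator does **not** emulate: sensor point-spread functions,
atmospheric haze, spatially correlated noise, mixed soil–canopy pixels, or
non-green vegetation (senescent crops, conifers in shadow). Passing tests
therefore demonstrate algorithmic correctness under controlled conditions,
not field-ready segmentation accuracy on real satellite products.

`generate_attribute_suite()` emits one record per reachable rule branch
(hot/dry, hot/humid, hot with middling humidity, moderate on plain and
hills, cool, and both levels of wind, precipitation, UV and soil moisture),
with values drawn uniformly inside each band. Both generators take explicit
seeds and restore the RNG state, so no global state leaks.

Problem sizes used by the test suite and the acceptance script — 96×96
scenes, 20 noise seeds, 50 random image pairs for the conservation check,
200 random record sets for the report oracle — were chosen as the smallest
sizes at which each property is non-trivial (masks of thousands of pixels,
multi-class confusion matrices) while keeping the suite quick to run.

## Known limitations

- No georeferencing: scale is a single isotropic metres-per-pixel number;
  no CRS, no reprojection, no area distortion handling.
- The hue window approach cannot separate cropland from any other green
  surface (parks, backyards, forest); that distinction is out of scope.
- The rule engine is a faithful transcription of a prose decision
  narrative, not a calibrated agronomic model; its thresholds and tolerant
  sets are configuration, and an LLM or other backend can replace it only
  upstream of the evaluation interfaces.
- Only 1- and 3-band rasters are supported; true multispectral (> 3 band)
  products and NDVI-style indices are out of scope.
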