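---
title: "Methods: object-based mTOR recruitment and compartmentalized P-pS6 quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based mTOR recruitment and compartmentalized P-pS6 quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lequant)
```

## Scope and model

`lequant` quantifies two readouts of neuronal mTORC1 signalling from
multi-channel 2D fluorescence micrographs:

1. **Recruitment of mTOR to late endosomes (LEs).** LAMP1-positive
   puncta are segmented in dendrites and the mean background-subtracted
   mTOR intensity inside them (IN) is divided by the mean in a ring of
   nearby cytoplasm (OUT). The ratio is 1 under no recruitment and grows
   as mTOR concentrates on LE membranes.
2. **Spatial distribution of mTORC1 activity**, via P-pS6
   immunofluorescence: whole-field neuronal mean, somatic vs dendritic
   split, per-soma distributions (with a percentile-shift description of
   population heterogeneity), and intensity profiles along dendrites
   with discrete hot-spot detection.

Both readouts operate on masks transferred between channels of the same
field, so registration is assumed perfect (channels acquired on one
microscope without stage movement). Images are processed in floating
point regardless of file bit depth; coordinates are 1-based (row, col)
and pixel-centered, the native R convention.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| rolling-ball diameter, P-pS6 | 50 | px | protocol value for activity images |
| rolling-ball diameter, mTOR/LAMP1 | 75 | px | protocol value for recruitment images |
| LE minimum area | 25 (strict `>`) | px | ≈ 350 nm equivalent diameter at 65 nm/px; removes sub-resolution specks |
| ring gap | 6 | px | distance from LE boundary to ring inner edge |
| ring width | 4 | px | local-background annulus thickness |
| MAP2 threshold | mean | — | named protocol choice for the dendrite mask |
| other thresholds | isodata | — | intermeans fixed point; the common ImageJ default family |
| minimum soma area | 200 | px | separates somata from dendritic fragments at large-field pixel sizes |
| percentile for shift analysis | 75 | % | upper-quartile threshold of the control distribution |

The rolling-ball parameter is a **diameter** (ball radius = diameter/2)
so the protocol's printed numbers can be used literally. The subtraction
is implemented as grayscale opening with a spherical-cap structuring
element $B(\delta) = \sqrt{r^2-\lVert\delta\rVert^2}$: an exact,
oracle-testable definition (the test suite compares it pixel-for-pixel
with a brute-force min-then-max scan). This is a deliberate dialect
difference from ImageJ's legacy shrink/interpolate approximation. One
consequence of the exact definition: an isolated single-pixel impulse is
preserved only up to the crown curvature of the discrete ball
($r-\sqrt{r^2-1}\approx0.02$ intensity units for $r=25$), which the
tests assert at $10^{-3}$ relative tolerance.

Ring (OUT) masks are defined by the exact Euclidean distance transform —
a pixel belongs to the ring iff its distance $d$ to the nearest object
pixel satisfies $\mathrm{gap} < d \le \mathrm{gap}+\mathrm{width}$ —
rather than by iterated binary dilation, giving an unambiguous, checkable
contract. Rings of neighbouring objects merge in the image-level mask
(each pixel counted once, matching the single IN/OUT ratio per image);
per-object mode assigns shared ring pixels to the nearest object, ties to
the lower id.

"Area above 25 pixels" is read as strictly greater than 25; the boundary
case (25 rejected, 26 retained) is pinned by tests. Segmentation of LE
puncta is isodata threshold + 8-connected components (+ optional
watershed splitting): the globally optimized region-competition
segmenters used interactively in FIJI are out of scope, and the module
interface accepts any labeling, so a different segmenter can be swapped
in upstream.

## The statistical decision tree

`compare_two()` uses a Welch t-test when both groups pass Shapiro-Wilk
normality at $\alpha=0.05$, otherwise a two-sided Mann-Whitney U test
(exact when both $n \le 8$ and there are no ties; normal approximation
with tie and continuity correction otherwise). `compare_many()` uses
one-way ANOVA + Tukey HSD when every group is normal and Bartlett's test
accepts variance homogeneity, otherwise Kruskal-Wallis + Dunn's test with
Bonferroni family correction. Welch rather than pooled-variance, and
Shapiro-Wilk as the normality gate, are the package's pinned choices
where the protocol is silent; Dunn-Bonferroni matches the reporting
convention of common GUI statistics software. Both functions accept a
`test =` argument to force a branch, because highly regular small samples
(e.g. `1:3` vs `4:6`) pass normality checks yet are natural examples for
the nonparametric path. Significance stars use strict thresholds
(`*` p < 0.05, `**` p < 0.01, `***` p < 0.001), and the
partial-inhibition flag is true only when the inhibited condition differs
from stimulated **and** control at strict p < 0.05.

The percentile-shift threshold uses R's type-7 quantile (linear
interpolation between order statistics); "above the percentile" is
strictly greater. For control = $\{1,\dots,100\}$ and $q=75$ the
threshold is 75.25. The unit of analysis (field, neuron, image) varies by
experiment; the tables carry `image_id` and `condition` columns and the
caller decides what constitutes a replicate — the package does not guess.

## The synthetic-data generator

`make_geometry()` places disk somata and unbranched piecewise-linear
dendrites with bounded turning (≤ 20° per ~10 px segment); dendrites that
would leave the field steer back toward the centre one bounded turn at a
time and are truncated only when cornered. LEs are disks (optionally
annuli, mimicking limiting-membrane staining) placed fully inside the
MAP2 region, non-overlapping by rejection sampling so per-object ring
backgrounds are unambiguous (an `allow_le_overlap` switch exists to
stress-test ring exclusion). `render()` builds channels additively:
background + optional shading plane + stain intensity, with the mTOR
channel multiplied by the per-object enrichment inside each LE and the
P-pS6 channel decaying exponentially along dendrite arclength with
optional Gaussian hot-spot bumps whose amplitude is a multiple of the
local baseline. Optional Gaussian PSF blur, Poisson shot noise and
Gaussian read noise follow. Per-pixel dendrite arclength is assigned from
the nearest rasterization stamp centre, so the along-path coordinate is
unbiased across the tube cross-section.

Default geometry (65 nm/px, 256×256 fields, two neurons, dendrites
80–150 px long and 5–8 px wide, ~30 LEs per 100 µm of dendrite of
3–6 px radius) represents a high-magnification dendritic crop scaled to
keep the full test suite fast; large-field somatic simulations use
~325 nm/px with 10–12 neurons per field. The 65 nm/px default makes a
25-px area correspond to ≈350 nm equivalent diameter; the acquisition
pixel size is a free parameter, not a constant. Field sizes, neuron
counts and replicate numbers used by the tests and the acceptance script
(e.g. 20 seeds × 4 enrichment levels on 256×256 fields; 8–10 neuron
large fields) are the package's chosen problem sizes: large enough for
stable means, small enough that the whole suite runs in minutes.

**What the generator does not emulate:** realistic dendritic arbors
(branching, spines), 3D structure, chromatic mis-registration,
camera-specific noise, autofluorescence texture, or biological
covariation between channels. Passing tests therefore demonstrate that
the *measurement pipeline* is correct and well calibrated on images with
the assumed statistical structure — not that the biological conclusions
drawn from any particular real dataset are robust to all of that
structure being violated.

## Numerical choices and degenerate inputs

* Isodata iterates $t \leftarrow (\mu_{\le t}+\mu_{>t})/2$ from the
  global mean to a $10^{-9}$ relative fixed point; constant images are an
  error for isodata and an empty mask for the mean threshold.
* Empty segmentations are empty results, not errors; invalid ratio
  results (no objects, no ring, zero background) are kept in output
  tables with a reason column so per-condition n remains auditable.
* The image-level IN/OUT ratio pools pixels (one IN mean, one OUT mean
  per image) rather than averaging per-object ratios.
* The clustering index defaults to the contrast form
  $(\max-\min)/\mathrm{mean}$ over a region; the literal
  $(\max/\min)/\mathrm{mean}$ variant (units 1/intensity, and undefined
  at $\min=0$) is available behind `variant = "literal"` and is never
  silently substituted.
* Hot-spot detection — local maxima with prominence above
  `min_prominence_factor` × median profile intensity, greedily thinned to
  `min_separation` — is this package's operationalization of visually
  scored dendritic spots; any reported result should state its
  parameters. A monotone decaying (control-like) profile yields none.
* All pipeline randomness flows from a single config seed; CSV outputs
  pin their floating-point format and embed version, parameter hash and
  seed, so reruns are byte-identical.

## Calibration results the test suite establishes

On noise-free, blur-free renders the recruitment pipeline recovers the
ground-truth enrichment within 1%. With Poisson shot noise (SNR ≥ 10 in
the cytoplasm), read noise and shading, the mean recovered ratio over 20
seeds stays within 5% of truth across enrichment 1.0–2.18 and is
strictly monotone in the ground truth. With PSF blur enabled the ratio
acquires a known **upward** bias at these scaled-down dendrite widths
(up to ~+20% at enrichment 1): ring pixels near the dendrite edge sample
blur-dimmed cytoplasm, depressing the OUT mean. Real dendrites are wide
relative to the PSF, so the effect is milder in practice, but it is the
reason background subtraction and mask placement must be reported with
any ratio, and why the recovery claims above are stated for the
noise-only conditions. Planted dendritic hot spots of amplitude ≥ 2× the
local baseline are recalled at ≥ 90% with ≤ 0.1 false detections per
dendrite; the two-group comparison holds its nominal 5% type-I rate
within ±1.5% over 2000 null simulations.

## Known limitations

* Threshold-based soma segmentation can merge adjacent somata bridged by
  bright proximal dendrites in crowded fields, and segmented soma blobs
  include proximal dendrite stubs; per-soma intensities are means over
  those blobs.
* The IN mask inherits threshold-edge pixels of the LAMP1 segmentation,
  producing a small downward bias of the recovered ratio (within the 5%
  envelope above) under noise.
* No automated dendrite tracing: profiles follow simulator centerlines
  or user-supplied polylines.
* Fields, not hierarchical units, are the statistical unit in the
  comparison helpers; nested designs (neurons within fields within
  cultures) need a mixed model outside this package's scope.
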