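---
title: "Methods: laser-referenced stem diameter measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laser-referenced stem diameter measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemspot)
```

## The measurement principle

A collimated laser mounted coaxially with a small panchromatic image sensor
projects a spot of known physical diameter $R$ (3.00–30.00 mm) onto a tree
trunk. Spot and trunk lie in the same object plane, so their pixel sizes
are proportional to their physical sizes and the stem diameter $S$ follows
from

$$\frac{S'}{S} = \frac{R'}{R}, \qquad \frac{h'}{R'} = \frac{h}{R},$$

with primes denoting pixel quantities and $h$ the measurement height. The
method assumes (i) the trunk cross-section is wide relative to the spot so
both lie at essentially the same depth; (ii) the small angle between sensor
axis and beam (nominally 91°) distorts the spot negligibly — no
rectification is applied; (iii) the trunk is approximately vertical in the
frame, so a per-row width is a meaningful diameter proxy. Everything
upstream of the final division is image analysis: find the spot
(centroid $\Omega^*$ and pixel diameter $R'$) and segment the trunk
(pixel width $S'$ at the measurement row).

All images are numeric matrices with intensities in $[0, 255]$, indexed
1-based as (row, col) from the top-left; crop intervals are closed pixel
ranges. This one convention is used everywhere, including serialized
records.

## Spot detection

The detector must separate one bright, roughly circular spot from uneven
illumination, bark texture and small bright clutter.

**Top-hat enhancement, twice.** A grayscale opening with a disk erases
bright structures that cannot contain the structuring element, so the
positive difference image (white top-hat) retains the spot and other
compact bright blobs — the circular structural elements among which the
spot must be found. Each pass ends with a central crop to 15/16 of each
linear dimension (margins split evenly, extra pixel to the top/left),
discarding clutter near the borders, and the cropped difference image is
the input of the next pass. Exactly two passes are run: more passes would
keep eroding genuine spot signal for little extra suppression. The crop
translation is accumulated exactly, so detected coordinates can be restored
to the original frame by a single vector addition — features are never
resampled, only translated.

The disk radius defaults to $\max(3, \min(H, W)/34)$ (about 32 px on a
1080-row frame, 8 px at the quarter-scale test size). The choice is driven
by the top-hat cap: for a radially decreasing spot the difference image is
a cap of the element's radius centred on the spot centroid, and a cap of
less than a few pixels radius has too small an area for stable
intensity-weighted centroiding. The cap mechanism also means the element
does **not** need to exceed the spot: any spot wider than the element still
leaves its full-strength cap.

**Component selection.** The difference image is binarised at its mean plus
three standard deviations — a robust cut that separates the cap (tens of
gray levels) from sensor-noise residue in the top-hat — and components
smaller than 9 px are dropped. Among the survivors the spot is the
component whose intensity-weighted centroid is closest to the frame centre;
the laser being coaxial with the sensor guarantees the spot is near the
optical centre, while clutter concentrates near the borders. Ties are
broken deterministically by larger area, then row-major centroid order.

**Centroid refinement.** The original image is thresholded at
$\eta/2 + \mu$ with $\eta = 255$ (pixels above the image mean plus half the
maximum gray level keep the label $\eta$, the rest become 0; $\eta = 255$
makes the rule a mean-shifted half-maximum and keeps the binary map in the
image alphabet). The core component nearest the top-hat centroid provides
an intensity-weighted refinement of $\Omega^*$; this separates the spot
from disturbing factors more precisely than the cap alone, whose support
can merge with clutter under noise.

**Edge ring and circle fit.** The spot's gray value decreases from centroid
to edge, so its rim is a ring of large intensity variation. 72 radial
spokes are cast from $\Omega^*$; along each, the Sobel gradient magnitude
is sampled every 0.25 px out to 1.5 core diameters and the maximum is
refined to sub-pixel accuracy by a three-point parabola. No Gaussian
pre-smoothing is applied by default (`smooth_sigma = 0`): the Sobel
operator's intrinsic smoothing suffices, the 72-spoke average suppresses
noise, and additional blurring measurably drags the detected ring inward on
small spots. Spokes whose peak gradient falls below half the median peak
are rejected, as are spokes whose maximum sits at the sampling boundary;
finally radii farther than $\max(2\,\mathrm{MAD}, 10\%, 1\,\mathrm{px})$
from the median radius are discarded — these are spokes that latched onto a
stronger nearby edge, typically the trunk contour when the spot sits close
to it. Relaxing the gradient-acceptance fraction towards zero grows the
accepted point count monotonically.

The diameter estimator is twice the mean Euclidean distance of the $k$
edge points to the centre. Because the estimator fixes the centre, one
refinement pass first re-estimates it by an algebraic least-squares (Kåsa)
circle fit; the centroid-anchored estimate is reported alongside. Fewer
than three edge points raise a classed error rather than a degenerate fit.
The estimator is validated in the test suite against a coarse-to-fine
grid search over (centre, radius) minimising the summed squared radial
deviation — an intentionally brute-force, independent oracle.

## Trunk segmentation

**Deterministic baseline.** A global Otsu threshold, choice of polarity
(trunk darker or brighter than background) by coverage of the central
columns, largest connected component, hole filling. It assumes a clear
trunk/background contrast and carries no learned knowledge; it exists so
the geometry pipeline can be exercised and validated end-to-end without
training, and is the default segmenter in `measure()`.

**Attention-augmented nested U-net.** The learned segmenter is a two-level
nested U-structure: six encoder stages and five decoder stages, each a
ReSidual U-block computing $U(F(x)) + F(x)$ where $F$ is a convolutional
weight layer and $U$ a small symmetric encoder–decoder over it. Encoder
stages become A-RSU blocks through an *Attach* module that injects
spot-local context: stage $m$ receives a crop of the input image centred on
the detected spot centroid (clamped inside the frame, input aspect ratio)
with area $m/n$ of the frame, $n = 6$ — tight context early, global
context last. Inside Attach, queries come from a 1×1 convolution of the
stage input and keys/values from two 1×1 convolutions of the local crop;
the affinity matrix (row-softmax of $QK^\top$, the usual non-local-block
normalisation — the construction prescribes the multiplications but no
normalisation, and an unnormalised product is scale-unstable) weights the
values, a fourth 1×1 convolution restores the channel count, and the
result is added to the stage input. The attention grid is pooled to at
most 8×8 before the product, keeping the affinity matrix small; with the
output projection zeroed the module is exactly the identity, a contract
the tests pin down. Side outputs from the five decoder stages and the
deepest encoder stage, plus a fused 1×1 combination, are all supervised:

$$L = \sum_{m=1}^{M} \omega^m_{side}\, l^m_{side}\, \varphi^m
      + \omega^m_{fuse}\, l^m_{fuse},$$

with $l$ the mean pixelwise binary cross-entropy and all $\omega = 1$. The
fuse term appearing inside the sum makes its effective weight $M$ — the
formula is implemented literally; since it is a constant rescaling it only
shifts the side/fuse balance. The coverage weight is
$\varphi^m = 1 - R(x'_m)/R(x)$ for a strict sub-window and 1 when local
and full maps coincide ($m = n$). $R(\cdot)$ is read as pixel *area*,
giving $\varphi^m = 1 - m/n$; the linear-dimension reading
($1 - \sqrt{m/n}$) is available as a configuration option. The condition
as printed in the source formulation ("$n < m$") is treated as a typo for
$m < n$, since $m \le n$ by construction.

The network is implemented on a small reverse-mode tape written for this
package (same-padding convolutions via im2col, dilation, 2×2 max pooling,
bilinear resize, channel concat, row softmax, BCE), with gradients
verified against finite differences in the tests. Two deliberate
departures from large-scale practice, stated as such: there are no
normalisation layers (plain conv + ReLU), and the default configuration is
small — 32×32 input with pooling after the first three stages, 6 output /
3 internal channels, RSU depth 2, dilation replacing pooling at the 4–8 px
stages. At this scale full-batch Adam (lr $10^{-3}$, betas (0.9, 0.999),
eps $10^{-8}$, weight decay 0 — the optimiser defaults of the underlying
training recipe) on 8 synthetic scenes reduces the loss within 50
iterations on one CPU, which is what the acceptance smoke run measures.
This demonstrates the architecture's trainability, not field-grade
generalisation: weights are initialised
He-style from a seeded draw (the Attach output projection near zero, so
training starts close to the attention-free network), training is
deterministic under the seed, and a non-finite loss aborts with the
iteration index.

**Mask to width.** `width_profile()` records, per image row, the length of
the contiguous foreground run containing the reference column (the spot
column); rows where the reference column is background get width 0. In
trunk mode the measurement row is the spot row. In sapling mode —
multi-stemmed or branching vegetation is measured below the lowest fork —
the profile is smoothed with a 9-row running mean and the bottom-most run
of rows with relative row-to-row change under 5% is located; the row just
below its smoothing transient is returned, or the spot row when it already
lies in that run. A profile with no stable run falls back to the spot row
with a warning.

## The synthetic scene generator

Scenes emulate the structure the device sees: a vertical trunk band of
known integer width over darker background; a smooth low-order polynomial
shading surface (uneven lighting; drawn coefficients, normalised to the
requested amplitude); a radially decaying spot; small bright blobs within
10% of the border (where field clutter concentrates and the detector's
crops operate); additive Gaussian sensor noise, clipped to $[0, 255]$.
Bright structures are composited with `pmax`, so the trunk band equals the
trunk intensity exactly wherever no spot/blob exceeds it. Identical
parameters and seed give bit-identical scenes; masks share the image
dimensions and use the \{0, 255\} alphabet with 255 as trunk foreground.

The spot profile is specified only qualitatively by the underlying method
(monotone decrease from centroid to edge), so the generator must choose
one, and the choice defines the ground-truth diameter. The profile used
is: a gentle cosine-eased core from `peak` at the centroid; a half-cosine
intensity step of half-width $0.25\,r$ centred exactly on the nominal
radius $r$, where the value is `edge`; a fast cosine-squared fade to zero
by $1.5\,r$. Two properties motivate it. First, an edge *step symmetric
about $r$* keeps its inflection — the point every gradient-based edge
detector localises — at $r$ under blurring; profiles whose gradient ramps
up to $r$ and collapses after it (e.g. a linear core) have their apparent
edge dragged inward by any smoothing, making the generator's own truth
unrecoverable in principle. Second, the step amplitude is set to
`edge − trunk_intensity` during compositing, so the visible part of the
step (above the trunk level) remains symmetric — a larger amplitude would
clip the lower shoulder at the trunk gray level and re-introduce the
asymmetry. Centroid placement defaults to the central 40–60% of the frame:
the laser is coaxial with the sensor, and the centre-distance selection
rule relies on exactly this property.

Default study conditions (used by `generate_dataset()` and the recovery
experiments): 480×270 frames (quarter scale of the 1920×1080 sensor, full
size available via `scene_params()`), trunk widths 60–160 px, trunk gray
70–95 over background 30–55, spot diameters 12–24 px, peak 230–255, edge
40–60 above trunk, up to 5 blobs of 3–9 px, shading amplitude up to 30,
noise σ 1–3. The end-to-end experiment uses 640×360 frames so that trunks
corresponding to 89 cm stems fit at a 14–18 px spot scale, with the spot's
physical size chosen as in field practice: 3 mm below 10 cm stems, 30 mm
otherwise.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: bark texture and specular structure, occlusion
by branches or foliage, non-vertical or non-cylindrical stems, defocus,
saturation blooming, multi-tree scenes, and the wavelength-dependent
response of the filtered sensor. Results on synthetic scenes bound the
algorithmic error of the pipeline, not field accuracy.

## Numerical choices and degenerate inputs

* Binarisation of saliency maps at 0.5; metrics accept \{0, 255\} or
  $[0, 1]$ maps and normalise internally.
* `error_metrics()` implements the relative error with the *measured*
  value in the denominator and $R^2$ with the measured mean in the total
  sum of squares, exactly as the device reports them; both have flags for
  the conventional forms. Samples with a zero denominator are flagged and
  excluded from RE rather than propagating infinities.
* The weighted F-measure needs, for every background pixel, the error at
  its nearest foreground pixel; the nearest-pixel map is computed by a
  vectorised chamfer wavefront propagation, with exact Euclidean distances
  from `EBImage::distmap()` for the decay weights. The tests compare the
  whole measure against a brute-force exact-nearest-neighbour reference on
  small images. The E-measure averages the enhanced alignment matrix with
  an exact mean so that identical maps score exactly 1.
* Empty CSE sets, empty thresholded cores, fewer than 3 edge points, empty
  foregrounds and empty truth masks raise classed errors
  (`stemspot_no_spot_error`, `stemspot_insufficient_edge_error`,
  `stemspot_no_trunk_error`, `stemspot_metric_error`) rather than returning
  sentinel values; `measure()` attaches stage labels and downgrades a spot
  outside the trunk foreground to a warning carried in the record.
* All randomness flows through explicit integer seeds; dataset generation
  draws per-scene seeds from the master seed so manifests are reproducible
  row-by-row.

## Limitations

The package measures one stem per image, from one image, with the spot as
the only scale reference: there is no distance estimation, no tree height,
no stand-level mapping, and no handling of leaning or buttressed stems.
The learned segmenter at the default scale is a verified-trainable
miniature, not a substitute for training at full resolution on real
imagery. Physical effects at the laser/bark interface (diffraction,
speckle, oblique incidence elongating the spot) are outside the synthetic
model; on real data they would bias $R'$ and hence $S$ multiplicatively.
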