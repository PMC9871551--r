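---
title: "Locating the next tapping cut on rubber-tree panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the next tapping cut on rubber-tree panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapline)
```

## The problem

Natural rubber is harvested by cutting a thin, sloped groove — the tapping
line — through the bark of *Hevea brasiliensis* trunks. Each harvest
removes a strip of bark below the previous cut, so after months of tapping
the trunk carries a conspicuous shaved region, the tapped area or panel,
whose lower-left boundary is the most recent cut. An autonomous tapping
machine must place the next cut a fixed bark-consumption distance `m`
below the existing one, following the same slope.

`tapline` decomposes this into: (i) rough segmentation of the panel in an
RGB trunk image, (ii) fine extraction of the existing line from the binary
panel mask, (iii) geometric construction of the new line, and (iv)
evaluation. Stages (ii)–(iii) are fully deterministic given the mask, and
the package can run them directly on ground-truth or externally produced
masks ("mask mode"), which is how the bundled tests exercise the geometry
without a trained network.

## Coordinates

All rasters are indexed `(r, c)`, 1-based, `r` increasing downwards. File
interfaces (Labelme-style JSON, exported line JSON/CSV) use `[x, y] =
[col, row]`, 0-based, matching the common annotation convention. Gradient
and edge rasters live on an `(H−1) × (W−1)` grid of 2 × 2 pixel
neighbourhoods; whenever edge positions are turned into line geometry the
half-pixel cell-centre offset is added back, so emitted coordinates are
unbiased estimates of the true boundary (a boundary between pixel columns
`c` and `c+1` is reported at `c + 0.5`).

## Fine segmentation of the existing line

The mask is smoothed with a 5 × 5 Gaussian (σ = 1.4 px), differentiated
with 2 × 2 averaged-difference operators,

$$G_x = \tfrac12\,(P_{r,c+1} - P_{r,c} + P_{r+1,c+1} - P_{r+1,c}),\qquad
  G_y = \tfrac12\,(P_{r,c} - P_{r+1,c} + P_{r,c+1} - P_{r+1,c+1}),$$

thinned by non-maximum suppression along the quantized gradient direction
(four 45° bins; plateau ties broken on the forward neighbour so ridges are
one pixel wide), and linked by double-threshold hysteresis. On a 0/255
mask the Gaussian spreads the step so that the peak gradient magnitude is
about 70 gray levels; the default thresholds 60/30 sit safely below that
peak while rejecting noise. (For grayscale input the thresholds are
derived from Otsu's criterion on the magnitude field instead.) A final
simple-point thinning pass removes the stair doublets that quantized
suppression leaves on arcs near the bin boundaries, restoring strict 1-px
thinness without breaking connectivity.

From the edge map, `A1` is the topmost edge pixel (ties: leftmost) and
`B1` the bottommost (ties: rightmost). The lower-left boundary trace emits
one extreme edge pixel per scanline between `B1` and `A1`. The scan axis
matters: one point per scanline is 8-connected only along the line's
*dominant* axis, and the subsequent step-distance constraint
(`d ≤ 1.5` px, just above the diagonal step √2) rejects anything less
connected. Panels are mostly wider than tall (bounding-box aspect ratios
1–2), i.e. lines shallower than 45°, for which a per-column scan
(maximum row per column) is the connected parameterization; steeper lines
need the per-row scan (minimum column per row). `extract_existing_line()`
therefore runs the full filter chain on both axes and keeps the longer
recovered line — the wrong axis truncates at the anchor and loses. Both
fixed conventions remain available through the `scan` argument.

The first 50 trace points are seeded into the line, and the 50th point is
the fixed anchor of the angle filter: a later point is kept if its chord
from the anchor stays within the forward quadrant, `0 ≤ a ≤ π/2`, with
`a` measured between the chord and the column axis. The angle is taken
unsigned by default (`|atan2(Δr, Δc)| ≤ π/2`): its role is to discard
chords that point *backwards* along the trace, and a signed version, also
available, would additionally discard chords dipping one pixel below the
anchor — something rasterized boundaries of 25–40° lines produce
constantly. The distance filter then walks the remaining points with an
advancing current point and stops at the first step exceeding 1.5 px;
the stopping point is the line start `C1`. The synthetic panels guarantee
such a gap at the line start: the top-left corner of a real panel
overhangs the start of the cut, so the boundary jumps left there by
several pixels (`corner_overhang_px ≥ 2`).

## Constructing the new line

Two left-edge points are sampled 30 and 60 rows above `C1` (minimum edge
column in those rows) and two right-edge points above `B1` (maximum
column); their midpoints `F1`, `F2` define the panel centre line, and its
downward unit vector `û` is the direction of bark consumption. Every
existing-line point moves by exactly `m·û` (`m = 8` px by default — the
bark consumed per cut at the working resolution of 652 × 552 px). Of the
two points at distance `m` on the centre-line direction, the one with
increasing row (down the trunk) is taken. One row of lookup jitter is
tolerated when sampling the side rows, since line coordinates carry the
half-pixel offset relative to the edge raster.

The displaced points `Q1` are smoothed by a cubic polynomial
`r = Σ_{k=0..3} a_k c^k`, fitted by a QR least-squares solve of the
Vandermonde system on a centred and scaled column variable for
conditioning; the solution is mathematically the normal-equations
solution, and the tests verify coefficient agreement with an independent
normal-equations solve and with `lm()`. The smoothed line `Q2` samples the
polynomial at every integer column of the fitted span (with exact values
retained and a half-pixel-rounded copy for rendering). Degenerate inputs —
fewer than `degree + 1` distinct columns, a zero-length centre line, a
panel shorter than the 60-row side offset, an empty mask — raise explicit
stage-tagged errors.

## The synthetic scene generator

Real tapped-area imagery is not publicly deposited, so every stage is
validated on generated scenes with exact ground truth. A scene is a
five-vertex panel polygon on a textured trunk band: the tapping line runs
from the bottom-right corner `B` up to `C` at a configurable tilt
(10–50°); one row above `C` the boundary jogs `corner_overhang_px` left
(default 3 px, emulating the overhanging top-left corner); the left edge
leans a further `panel_lean_px` left towards the top; the right edge is
vertical. The mask is the even-odd pixel-centre rasterization of this
polygon, and the ground-truth lines are carried analytically: the new line
is the existing line translated by `m` along the analytically computed
centre-line direction, so the offset invariant is exact by construction.

Three illumination modes emulate field conditions — `cloudy` (uniform),
`direct_sun` (global brightening plus a saturated highlight blob over the
panel) and `backlight` (strong contrast compression) — and panel heights
140/180/220 px emulate one/two/three years of cutting. Illumination and
pixel noise affect only the rendered image, never the mask or the ground
truth. All randomness flows from a single integer seed per scene, with
dataset seeds derived reproducibly from one master seed.

What the generator does *not* emulate: photorealistic bark texture,
partial occlusion, multiple panels per trunk, camera distortion, or
detector segmentation errors. Mask-mode results on these scenes therefore
validate the geometric chain under clean segmentation, not end-to-end
performance on field imagery.

Panel sizes default to the widest panel (capped at 340 px) that fits
vertically at the drawn tilt. This keeps the line's column span comfortably
above the 50-point seed at shallow tilts and mirrors the 1–2 aspect-ratio
statistic of real panels.

## Detection components and smoke training

The network components are implemented as forward-contracted operations on
`(C, H, W)` arrays: aggregated-residual blocks (explicit-branch and
grouped-convolution forms, tested for equivalence), parallel
channel/spatial attention (`F''' = M_C ⊗ F + M_S ⊗ F`, shared
one-hidden-layer MLP with reduction 16 for the channel gate, 7 × 7
convolution over channel-max/average maps for the spatial gate), top-down
pyramid fusion to five 256-channel levels at strides 4–64, anchors of
ratios 1 : 1.5 : 2 with equal areas per scale, and a mask head whose
fully-connected branch (two extra 3 × 3 convolutions, the second with half
the channels, then a flatten and a 784-way linear map reshaped to 28 × 28)
is summed with the convolutional branch. Parameter counting is analytic,
so configurations can be compared without instantiating weights.

Training a full instance-segmentation network is out of scope on a single
CPU; instead, the composite loss `L = L_cls + L_box + L_mask` is exercised
by a deliberately small differentiable detector: a per-pixel logistic mask
head over 4 × 4-block colour features, a logistic foreground/background
classifier over region colour statistics, and a linear box-refinement
head, trained jointly by full-batch gradient descent with analytic
gradients (default learning rate 1.0, 10 steps per epoch, 5 epochs on
16 scenes of 128 × 128 px). The loss curve decreases monotonically under
these settings, and the trained model segments held-out synthetic panels
well enough to drive the geometric pipeline in image mode. This smoke
detector is a reduced-capacity surrogate for exercising the contracts; it
makes no claim about the accuracy of the full architecture.

## Evaluation

Instance metrics follow the standard definitions: `P`, `R`, `F1` in
percent; average precision as the area under the monotonized
precision–recall curve (all-point interpolation by default, the 101-point
variant behind a flag) at IOU thresholds 0.5–0.95; pixel IOU
`M_TP/(M_TP+M_FP+M_FN)`. Location quality uses the rectangle error
`e_x = (|X_{min}−x_{min}| + |X_{max}−x_{max}|)/2`, `e_y` analogously, and
`e = \sqrt{(e_x^2+e_y^2)/2}`, with success declared at `e ≤ 10` px — the
fault tolerance of a tapping end effector. On synthetic data the reference
rectangle is the bounding box of the ground-truth new line.

## Problem sizes and runtime choices

The bundled tests run the full geometric chain on 20–100 seeded scenes at
the 652 × 552 working resolution (about 0.3 s per scene), oracle
equivalences on 50–100 random 64 × 64 rasters, and smoke training on 16
small scenes; the acceptance script repeats the 100-scene end-to-end run.
These sizes keep a complete run in the low minutes on one CPU while still
covering the tilt range and all illumination modes.

## Known limitations

* The trace assumes a single panel per image; multiple panels would need
  instance separation upstream.
* Tilts at exactly 45° sit on the boundary of both scan
  parameterizations; both work there, but lines beyond ~55° with very
  short column spans would degrade the per-column fallback.
* The angle/distance filters operate on rasterized boundaries; heavy mask
  fragmentation (e.g. from a poor detector) truncates the line early
  rather than bridging gaps, which is the conservative behaviour for a
  cutting robot.
* The smoke detector's colour features assume the panel is
  distinguishable from bark by colour statistics, which the generator
  guarantees but field imagery may not.
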