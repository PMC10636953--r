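---
title: "Estimating tangential-field lung exposure from CT surface markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tangential-field lung exposure from CT surface markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In whole-breast radiotherapy after breast-conserving surgery, opposed
tangential beams graze the chest wall, and the rind of ipsilateral lung
inside the field edge determines the risk of radiation pneumonitis. The
dosimetric quantity clinicians watch is lung V20 — the percentage of the
ipsilateral lung receiving at least 20 Gy — but it only becomes available
after treatment planning. Before the planning CT, the breast outline is
marked on the skin with a radio-opaque lead wire, which shows up as two
bright points on every axial slice through the breast: the medial and
lateral breast borders. Those two points define, per slice, the tangential
field edge.

`tangentfeat` implements a geometric *organ feature* computable at
simulation time from these two markers alone: per slice, the line through
the two wire points is translated 5 mm towards the lung (emulating the
planning-target-volume margin), the ipsilateral-lung area on the
superficial side of the shifted line is accumulated over slices, and the
sum is divided by the total ipsilateral-lung volume. The result is the
exposed lung volume fraction, a number in [0, 1] that rises with V20 and
can flag high-risk anatomy before any plan exists. The package also
implements the automatic detection of the wire points by heatmap
regression, the distance-tolerance precision/recall metrics used to score
such detectors, and a cohort-level correlation analysis between the
feature and V20.

Patient CTs of the kind this method targets are not redistributable, so the
package ships a parametric digital thorax phantom and a simplified
tangential dose simulator. Every claim the test suite makes is therefore a
claim about this synthetic system, exercised end to end.

## The phantom

A phantom slice is an elliptical body with two elliptical lungs, a thin
high-density rib rim around each lung, and a breast bulge on the
ipsilateral surface. The stack tapers smoothly cranio-caudally. Tissue HU
defaults are air −1000, lung −750, soft tissue 40, bone rim 700, lead wire
2500, with additive Gaussian noise (sd 10 HU). Default acquisition
geometry follows clinical practice for this setting: 5 mm slices, 1 mm
in-plane pixels.

The breast spans a surface arc; its two borders carry the wire markers,
placed exactly on the body contour and rendered as 1-voxel (optionally
3-voxel) lead-density points. The arc's lateral extent grows with a single
dimensionless knob, `marker_depth_frac`, so the chord through the two
markers — the field edge — cuts controllably deeper into the lung. The arc
constants were calibrated once so that the default cohort reproduces a
clinically typical V20 distribution under tangential fields (median ≈ 17%,
roughly 2–37% across anatomies) and feature values of roughly 0.02–0.35;
after that calibration they are fixed.

Cohorts draw anatomy (body and lung semiaxes, lung offset, breast radius
and position, marker depth) from uniform ranges inside the validity
envelope, with per-case seeds split deterministically from a master seed.
Annotations equal the true wire-voxel centroids plus Gaussian jitter
(default sd 3 mm), emulating manual labelling error at the scale a human
reader achieves on 1 mm pixels.

What the phantom does *not* emulate: heart and chest-wall substructures,
breathing motion, realistic CT texture, beam divergence and scatter. Tests
passing on phantoms therefore validate the geometry, supervision contract
and statistics of the method — not its performance on patient images.

Two problem sizes are used. The `"default"` cohort preset (1 mm pixels, 20
slices) drives the feature/dose/correlation studies. The `"compact"`
preset (2 mm pixels, 8 slices, no annotation jitter) is the detector
*training* condition: heatmap localization error scales with pixel
spacing, so this preset exercises the same learning problem at a size a
single CPU handles in minutes.

## Marker detection

Preprocessing clips CT values to [−140, 210] HU and rescales to [0, 1] — a
soft-tissue window in which skin, breast and wire are all visible — and
stacks each slice with its two neighbours as a 3-channel slab (edge slices
replicate). Supervision is one unnormalized Gaussian heatmap per marker
channel (medial, lateral; medial = nearer the midsagittal plane), peak 1
at the marker, width sigma = 5 mm by default, matching the scale of the
5 mm evaluation tolerance; slices without markers get zero targets.
Decoding takes the per-channel argmax (ties break to the lowest row, then
column), converts to patient mm, and suppresses channels whose peak is
below a confidence threshold (default 0.1).

The trainable network is deliberately compact: a two-scale convolutional
encoder–decoder (full-resolution 3×3 stage, pooled 3×3 stages, fusion by
upsample-and-add, 1×1 head) trained with Adam on mean-squared heatmap
error, keeping the parameters of the epoch with minimum validation loss.
Three design points matter:

* **Coordinate channels.** A convolution cannot tell two identical wire
  points apart. Normalized x/y coordinate maps are appended to the input
  and injected again at the fusion and output layers, letting the network
  gate its response by position and separate the medial from the lateral
  channel. The external contract (3-channel slab in, 2 heatmaps out) is
  unchanged.
* **Zero-initialized head.** With sparse targets, the natural starting
  point is the all-zero heatmap; initializing the output and coordinate
  projections at zero makes the first prediction exactly that baseline and
  stabilizes training dramatically at desk scale.
* **Desk-scale protocol.** Defaults are 50 epochs and learning rate 1e-4
  (the reference protocol); the shipped experiments use 25 epochs at 3e-3
  on 40 training / 10 validation phantoms, which reaches a mean held-out
  localization error under two pixel spacings in about six CPU-minutes.
  Learning rates an order of magnitude higher diverge.

A training-free *classical* detector — threshold at 1500 HU, connected
components, centroids, medial/lateral by x-extremity — is exact on
phantoms by construction (only the wire exceeds 1500 HU) and serves as the
oracle detector for every downstream test that should not depend on
training.

## Metrics

Localization error is the Euclidean in-plane distance between prediction
and ground truth of the same slice and channel, pooled over all pairs
where both exist — deliberately independent of any tolerance, so the
distance summary and the tolerance-based counts cannot interact. At each
tolerance t, a same-channel pair within t is a true positive; unmatched
predictions and truths are false positives and negatives;
AP = TP/(TP+FP), AR = TP/(TP+FN). Matching is channel-respecting by
default because the detector's channels are semantically identified — a
Hungarian mode is available to diagnose channel swaps. The standard
deviation is the sample (n−1) form. Undefined ratios (0/0) and empty
distance pools are reported as NA rather than silently coerced.

## The organ feature

Per marker-bearing slice: the field edge is the line through the two
markers; the inward unit normal points towards the slice's lung centroid;
the shifted edge is the marker line translated `shift` mm (default 5)
along it. "Inward" towards the lung was chosen because the margin
emulates the planning-target expansion that deepens the field edge, and
because the worked relationship — larger feature, larger V20 — only holds
under this orientation; the opposite reading would anti-correlate. The
exposed side of the shifted line is the superficial one (it contains the
marker line). Lung pixels are counted by their centres, centres exactly on
the line counting as exposed (a deterministic tie rule shared with the
brute-force oracle in the tests). The numerator sums exposed area × slice
thickness over marker slices; the denominator is the whole-volume
ipsilateral lung (a per-slice-restricted denominator is available behind a
flag). Degenerate slices — coincident markers, centroid on the line,
missing channel — contribute zero exposed area and are counted and
warned about, never silently dropped.

## The dose surrogate

The simulator assigns, on every marker-bearing slice, a logistic profile
of the signed distance d from the shifted field edge (positive on the
exposed side): dose = prescription / (1 + exp(−4d/w)), prescription 50 Gy,
penumbra scale w = 6 mm so that w approximately spans the 10–90% falloff.
Marker-free slices receive zero dose. This is the minimal model that makes
the feature–V20 relationship non-trivial — penumbra width, anatomical
variability and annotation jitter all decorrelate the two quantities —
while keeping a closed-form limit: as w → 0, V20 converges to 100 × the
organ feature computed from the same markers, which the tests verify to
within one percentage point. It is a surrogate, not a treatment planning
system: no divergence, obliquity, heterogeneity or fractionation.

Dose is simulated from the *true* wire centroids (the "plan"), while
features are computed from labeled or detected markers, so label jitter
and detector error attenuate the observed correlation exactly as reader
variability would.

## Statistics

Pearson's r with the two-sided t-transform p-value and a Fisher-z 95% CI,
reported with the conventional strength bands (|r| < 0.3 weak, 0.3–0.5
moderate, ≥ 0.5 correlated). The labeled- and detected-marker feature
vectors are compared with a two-sided paired t-test on the same case set.
Degenerate inputs fail loudly (constant vectors, n < 3) or follow stated
limits (all-zero differences: t = 0, p = 1).

One empirical subtlety the phantom exposed: because the exposed area is a
convex function of field-edge depth near the lung surface, symmetric
marker jitter biases the feature slightly upward. With very shallow
tangential cuts this bias is reliably detectable by a paired test at
n = 100; at clinically calibrated cut depths (the default cohort) it
shrinks to the order of the jitter-induced noise, so the paired
comparison is usually — though not at every seed — non-significant, in
line with reader-vs-detector comparisons reported for this class of
feature. A residual upward bias of a fraction of a percent of the feature
value remains a real property of the geometry, not an implementation
artifact.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 50 phantoms for the
brute-force feature-oracle equivalence (tolerance 1e-9 relative), 20
phantoms × 5 shifts for monotonicity, 1000 random marker pairs for the
encode/decode identity (bound: half a pixel diagonal), a 40/10/10 compact
cohort for detector training, and n = 100 default cohorts for the
correlation study. Seeds are explicit everywhere; phantom generation,
training and the full study are bit-reproducible for a fixed seed. All
geometry is computed in patient millimetres; voxel indices are 0-based in
all serialized artifacts, and the in-plane origin is the grid centre, so
x = 0 is the midsagittal plane.

## Known limitations

* The phantom's lungs are convex ellipses; real lungs are not, and the
  lung-centroid rule for orienting the inward normal could misbehave for
  strongly concave slices.
* The detector is validated at 2 mm training resolution; transferring a
  trained model across pixel spacings is warned about but not corrected.
* The dose surrogate shares its geometry with the feature by construction;
  the reported correlations on phantoms are therefore upper bounds, not
  estimates of clinical correlation strength.
* The classical detector's 1500 HU threshold assumes no metal other than
  the wire; clips or dense calcifications would need exclusion logic.
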