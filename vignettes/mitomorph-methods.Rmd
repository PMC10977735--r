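---
title: "Quantifying mitochondrial network morphology with mitomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology with mitomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mitochondria continuously fuse and divide, and the balance of those
processes — together with swelling, branching and repositioning of the
network — is a sensitive readout of cell health. `mitomorph` quantifies
this morphology in single adherent cells imaged live in 2D with three
vital dyes: a nuclear stain (blue), a plasma-membrane stain (green) and a
membrane-potential-dependent mitochondrial stain (red). For each cell the
package produces 31 morphometric descriptors spanning abundance, shape,
connectivity, size and density/texture, and summarizes condition-level
differences as normalized radar ("spider") profiles with per-feature
significance tiers and a compact rule-based morphospace code.

Flat cultured cells are well captured by a single optical section, which
is why the whole pipeline is 2D; z-stacks and stitched mosaics are
deliberately rejected at the reader.

## Five-stage segmentation

All geometry is computed in pixel units on row-major matrices (origin at
the top-left); the physical pixel size (default 0.108333 µm, a 60x
confocal configuration) is carried as metadata for reporting only. Every
stage is deterministic — there is no randomness anywhere in segmentation
— so re-running a stage reproduces its mask exactly.

1. **Nuclei.** The blue channel is band-passed with a difference of
   Gaussians (sigmas 3 and 12 px: the narrow blur removes sharp noise,
   subtracting the wide blur removes background), thresholded, cleaned of
   components below 2000 px, hole-filled, dilated by a 3 px disk, split
   with a watershed on the distance transform, and cleared of
   border-touching objects. Large nuclei at this magnification produce a
   band-pass response concentrated in an edge annulus — the hole-filling
   step is what recovers the solid nucleus from it.
2. **Cells.** The negated green channel is the watershed relief, with
   nucleus interiors forced below every other value so each nucleus seeds
   one catchment basin. Basins containing a nucleus take its label;
   remaining ("residual") basins merge iteratively into the adjacent cell
   whose shared boundary has the lowest mean green intensity (residuals
   processed in decreasing area, ties to the lower label). Finally pixels
   below the user-adjustable cell-marker floor become background. Cell
   label k always corresponds to nucleus label k.
3. **Mitochondrial clusters.** The red channel is band-passed (sigmas 1
   and 4 px), thresholded at mean + 1 SD of the filtered image,
   cleaned of components below 10 px, intersected with the cell
   foreground (clusters straddling a cell boundary are split per cell)
   and labeled with 8-connectivity.
4. **Skeleton branches.** Clusters are thinned to 1-px skeletons
   (Zhang–Suen two-subiteration thinning). Skeleton pixels with one
   8-neighbor (or none) are end points; pixels with three or more are
   junction points; a branch is a connected run of skeleton pixels
   bounded by end/junction points.
5. **Isolated mitochondria.** Each cluster is re-segmented by assigning
   every cluster pixel to its geodesically nearest skeleton branch
   (branch-seeded watershed on the negated distance-to-branch relief).
   By construction the isolated mask has exactly the cluster support —
   pixel conservation is asserted in the tests.

### Numerical choices worth knowing

* **Nuclei threshold guard.** The nuclei threshold is anchored at the
  median of the band-passed image and raised by `nuclei_mad_k` (default
  3) times its MAD. On a clean background the band-passed image is
  exactly zero away from structures, the MAD is zero, and the rule
  reduces to a plain median threshold. On any noisy background, however,
  a strict median cut passes roughly half of the background; because the
  band-pass correlates noise over a few pixels, those pixels percolate
  into a single background component of tens of thousands of pixels that
  survives the 2000 px filter, swallows the nuclei during hole-filling
  and shatters under the splitting watershed. The MAD guard is scale-free
  (it adapts to any intensity range), changes nothing in the noiseless
  limit, and `nuclei_mad_k = 0` restores the literal median rule.
* **Cell-stage watershed regularization.** Basin detection runs on the
  green channel lightly smoothed (`ws_smooth_sigma`, default 1.5 px) with
  a merging tolerance of 1 % of the relief range (`ws_tolerance`).
  Without this, shot noise seeds one basin per noise bump (tens of
  thousands on a 512^2 field), which multiplies the residual-merge
  workload a hundredfold without changing where boundaries fall. The
  boundary-intensity statistics of the merge and the final intensity
  floor always use the raw channel.
* **Residual merge and the background.** Watershed basins containing no
  pixel at or above the cell floor, and boundary contacts whose pixels
  lie below it, are excluded from the residual merge. In a confluent
  monolayer (the regime the aggregation rule is designed for) no such
  basin exists and the behaviour is identical; in sparse fields this
  prevents the dark background — always the largest residual — from
  bridging unrelated cells through dim contacts.
* **Cell floor default.** The floor is user-settable; when unset, an Otsu
  threshold of the green channel is used. Any automated batch tool needs
  a data-driven default, and Otsu separates the membrane-stained
  foreground from the dark surround cleanly at typical staining
  contrasts.
* **Nuclei split tolerance.** The touching-nuclei watershed uses a 2 px
  tolerance on the distance relief, ignoring sub-pixel maxima along
  necks that would otherwise oversplit wavy nuclei.
* **Connectivity conventions.** 8-connectivity for components and border
  tests, 4-connectivity for watershed boundary definition and for hole
  counting (so that the Euler number of an annulus is 0).
* **Degenerate skeletons.** Zhang–Suen thinning can delete a very
  compact blob entirely (a final 2x2 block satisfies both deletion
  subiterations); such clusters get a single medial skeleton pixel back
  (the distance-transform maximum) so every cluster owns at least one
  degenerate branch. Junction pixels that touch each other are merged
  into one junction node before counting, since thinning produces small
  junction clumps that would otherwise inflate the branch-point count.
* **Branch length.** Measured as the polygonal chain length over the
  branch's pixel adjacencies (1 per axial step, sqrt(2) per diagonal,
  dropping diagonal short-cuts across staircase corners). Steps through
  junction pixels are not attributed to any branch, a small systematic
  undercount of the per-cell skeleton length.

## The 31 descriptors

The full data dictionary ships at
`inst/extdata/feature_dictionary.csv`. Definitions follow the field's
regionprops conventions: ellipse axes from second central moments (with
the 1/12 px correction), perimeter as contour chain length, roundness as
`sqrt(4 A / pi) / (P / pi)` so a perfect circle scores 1, elongation and
compaction as reciprocal axis ratios (so their product is exactly 1 per
object), Euler number as components minus holes. Solidity here is the
convex-hull perimeter divided by the object perimeter — a perimeter
ratio, deliberately not the conventional area ratio.

**Aggregation to one row per cell:** areas and lengths are summed over
objects; every other per-object feature is arithmetically averaged;
counts are object counts. Cells without any mitochondrial signal are
still emitted with their cellular features, and all mitochondrial
features missing (`NA`, never 0 — zero is a valid feature value and
conflating the two would bias condition means).

**Fractal features.** The per-cell cluster-union mask, cropped to its
bounding box, is zero-padded to a `2^P x 2^P` square (P minimal);
occupied boxes are counted at sizes `2^0 .. 2^P` and the fractal
dimension vector is `-gradient(log N) / gradient(log R)` with central
differences in the interior and one-sided differences at the ends.
`Fractal2`, `Fractal8` and `Fractal32` are the values at box sizes 4, 16
and 64 px. When the padded side is smaller than a box size the value is
missing. The box counts are verified against a brute-force double loop
in the test suite; the filled square, the line and the point hit their
analytic dimensions (2, 1, 0) exactly.

**Localization.** For every skeleton pixel of cell k the Euclidean
distances to the cell boundary and to the envelope of nucleus k are
computed from distance transforms (the image border counts as membrane
for the cell distance; it never counts as nucleus). The ratio
`dN / (dM + dN)` is evaluated per pixel and then averaged, so it reads 0
at the nuclear envelope and 1 at the plasma membrane.

## Condition-level analysis

Feature means per condition are min–max normalized per feature,
`Vn = (Vp - Vmin) / (Vmax - Vmin)`, over the set of conditions being
compared; a feature constant across conditions is flagged degenerate and
pinned at 0.5. Significance is a two-sample t-test per feature against
the reference condition (Welch by default; Student's by flag), encoded as
`*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001) circles of increasing
size on the spider plot. The natural statistical unit is the independent
experiment: when a replicate column is supplied the test runs on
experiment means; testing per-cell values is supported but warns, because
cells within a field are not independent replicates.

The morphospace classifier maps significant feature changes to a
three-axis code: mitochondrial state (M1 reference, M2 fusion, M3
branching, M4 compaction, M5 dislocation, M6 fission, M7 swollen),
localization (I1 reference, I2 pericortical, I3 perinuclear) and cell
shape (C1 reference, C2 retraction, C3 spreading, C4 compaction, C5
star-like, C6 marker intensity). The fission rule requires a cluster
count increase with shorter and rounder/more compact mitochondria;
swelling keys on skeleton width; dislocation on reduced skeleton length
and branch points with raised cluster solidity. The M2 (fusion), M4
(mitochondrial compaction) and C6 (marker intensity) rules are this
package's own completions of the axis vocabulary: fusion as the mirror
image of fission (length up, count or end points down), compaction as a
significant compaction increase without the full fission pattern, and C6
as any significant cell-marker intensity change. Several rules may fire
on one axis — composite states are reported with a conflict flag rather
than silently picking one. Effect-size thresholds that would distinguish
"partial" from "total" states are not part of the rule set; the classifier
keys on significance and direction only.

## The synthetic generator

`generate_field()` emulates what the pipeline actually sees: smooth
cell-shaped blobs tiling part of the frame, one large elliptical nucleus
per cell (~120 px across, matching a real nucleus at 0.108 µm/px — the
scale matters, because the protocol's fixed 3 px nucleus dilation makes
sub-0.9 IoU geometrically unavoidable for small nuclei), a bright
membrane band at each cell boundary, and mitochondria drawn as
persistent random-walk tubules with optional branching. Three knobs move
the phenotype the way biological stressors do:

* `fragmentation` (0–1): tubule length shrinks from ~55 px to ~4 px while
  the total mitochondrial area budget (~1800 px per cell) is held, so the
  object count rises as fragments shrink and round up;
* `swelling` (0–1): tubule diameter `3 * (1 + 2 * swelling)` px;
* `perinuclear_bias` (0–1): radial placement is skewed toward the nuclear
  envelope by sampling the radial fraction as `u^(1 + 4 * bias)`.

Channels are rendered at 16-bit-like intensities (backgrounds 200–300,
nuclei ~12 000, cytoplasm ~2750 with a ~9250 membrane ridge,
mitochondria ~10 000 with per-tubule variation), blurred by a Gaussian
PSF (default sigma 1 px) and corrupted by Poisson shot noise
(`noise_level`, default 0.02, giving a few-percent relative fluctuation
at typical signal levels). One local RNG stream keyed by the seed makes
output bit-identical for identical parameters, and a series over one
knob shares all other randomness.

What the generator does **not** emulate: intracellular texture,
uneven illumination and vignetting, dye bleed-through between channels,
out-of-focus haze, photobleaching, cell-to-cell staining variability and
true 3D structure. Passing the recovery and monotonicity suites
therefore demonstrates that the algorithms are implemented correctly and
respond in the right direction at realistic geometry and noise — not
that segmentation quality on any particular microscope is guaranteed.

Ground truth records the label masks, per-cell component counts, the
end/branch-point counts of the true-mask skeleton (drawn tubes may merge,
so nominal per-tube counts would overstate the truth), centerline length
and mean width.

## Validation scope and problem sizes

The test suite runs entirely on synthetic or analytic inputs: fixture
geometry (bars, crosses, disks, ellipses, annuli), brute-force oracles
(dense 2D convolution for the band-pass, a double-loop box counter for
the fractal profile), invariance properties (pixel conservation,
elongation-compaction reciprocity, affine invariance of Vn, worker-count
invariance of the batch outputs) and phenotype recovery. Recovery and
monotonicity use 512^2 fields with 4 cells each: two noiseless fields for
ground-truth recovery (per-object IoU >= 0.9 for nuclei and cells,
cluster count within 10 %, skeleton end points within 20 %) and, per
knob, 5 levels x 5 fields = 20 cells per level at default noise for the
Spearman monotonicity checks (|rho| >= 0.9 across level means). These
sizes keep the full suite in the tens of minutes on one core while
satisfying the per-level cell counts the properties call for.

## Known limitations

* The pipeline is strictly 2D and single-plane; multi-page TIFFs are
  rejected rather than projected.
* The residual-merge rule assigns each bright inter-cell ridge wholly to
  one neighbor, so cell boundaries between touching cells track the
  ridge only to within the ridge's basin width.
* `Skel_Width` is a per-cell area/length quotient, not a per-tubule
  width distribution; heavily clustered mitochondria inflate it.
* The t-test follows the published display convention; no
  multiple-testing correction is applied by default (31 features), so
  per-feature tiers are descriptive annotations, not inferential claims.
* Table-style solidity (perimeter ratio) can exceed 1 for non-convex
  contours with smooth hulls; it is reported as defined, not clamped.
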