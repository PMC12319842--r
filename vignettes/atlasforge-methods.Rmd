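---
title: "Methods: hierarchical region-wise atlas registration in atlasforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical region-wise atlas registration in atlasforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atlasforge)
```

## The problem

Mouse-brain reference atlases couple a scalar anatomical volume (a
Nissl-stained reference brain, or a serial two-photon average template) with
an integer-labeled annotation volume whose voxel values are region ids drawn
from a hierarchical ontology (a structure graph: root, major divisions,
parents, leaf regions). Successive atlas versions differ in both the
template and the label set, so transferring the cell-level contrast of an
older Nissl reference into the coordinate space of a newer average template
requires more than a single whole-brain registration: region boundaries
carry most of the anatomical signal, the two modalities have very different
contrast, and the two annotation versions do not even share all leaf labels.

`atlasforge` implements a desk-scale version of the full construction
workflow:

1. **Ontology decomposition.** Leaves annotated in both versions are
   registered at leaf level; every other supported leaf is assigned, by
   walking strictly rootward, to the first ancestor with non-empty
   (descendant-aggregated) voxel support in both volumes. A parent's own
   voxels count as support, which matters when a dropped leaf's voxels are
   relabeled with the parent id itself.
2. **Global label-driven initialization.** The two annotation volumes are
   registered (affine, then nonlinear) on Gaussian-blurred per-label
   indicator channels; the transform is applied to the Nissl volume with
   linear interpolation and to its annotation with nearest-neighbor.
3. **Region-by-region multimodal registration.** For each leaf-level
   region, both volumes are cropped to the union bounding box of the region
   masks (5-voxel margin), masked, and registered affinely and then
   nonlinearly under the normalized-mutual-information metric. Warped
   tissue is written into the reconstruction strictly inside the
   fixed-space region mask; voxels still empty afterwards are filled from
   parent-level registrations and finally from the globally initialized
   volume, so coverage of the annotated domain is complete by construction.
4. **Dedicated cerebellar path.** The average-template modality carries no
   granular/molecular contrast inside cerebellar lobules, so intensity
   metrics are uninformative there. Each lobule is instead registered on
   its blurred annotation masks (affine, then an aggressive nonlinear
   variant: halved smoothing, doubled iterations, local-correlation
   forces), and the resulting transforms move the Nissl lobule tissue.
5. **Final whole-brain pass.** The piecewise reconstruction is a mosaic:
   adjacent regions were warped by different transforms, so seams and
   duplicated tissue can occur at region borders. One monomodal nonlinear
   registration maps the *continuous* globally-initialized volume onto the
   mosaic; the warped continuous volume is the final product. Composing the
   residual field with the initialization chain gives a single end-to-end
   mapping from the fixed grid back to the raw volume, which is what the
   fiducial evaluation inverts.

## The registration engine

The engine is a demons-style free-form displacement estimator with Gaussian
regularization, written for clarity and testability rather than raw speed:

* **Forces.** Classic fixed-image demons: `u += (f - m(p+u)) grad f /
  (|grad f|^2 + (f - m)^2)`, averaged over channels for multi-channel
  (label-indicator) registration.
* **Metrics.** `ssd` on jointly min-max-scaled images for monomodal pairs;
  `nmi` (64-bin joint histogram by default) for multimodal pairs, with
  forces computed on rank-normalized images so that any monotone intensity
  relation becomes quasi-monomodal; `lcc` (local correlation: images
  locally standardized with a 2-voxel Gaussian window) for same-stain pairs
  from *different* specimens, where a global intensity-gain mismatch would
  otherwise be absorbed into spurious deformation.
* **Monotone accept/reject.** Every candidate update is scored; steps that
  would decrease the metric are rejected and the step size halved, so the
  reported metric is non-decreasing over accepted iterations and the
  procedure is deterministic (no stochastic sampling anywhere).
* **Regularization.** The update is smoothed before composition (fluid
  sigma) and the accumulated field after (diffusion sigma), both defaulting
  to one fixed-grid voxel; the aggressive variant halves them.
* **Pyramid.** Block-mean levels x4, x2, x1 with 100/50/20 iterations by
  default; the affine optimizer seeds with an exhaustive coarse translation
  search, refines with Nelder-Mead per level, and ends with a
  full-resolution guard that never returns a transform scoring worse than
  its own starting point at native resolution (coarse-level optima can
  regress when brought back to full resolution).
* **Metric masks.** Similarity evaluation and forces can be restricted to a
  fixed-space mask. The tissue-extension workflow depends on this: both the
  donor and the truncated target carry an identical artificial edge where
  the truncation mask cuts them, and with that edge in the metric every
  registration is anchored to zero displacement at the cut.

Transforms follow the resampling convention (fixed-space point to
moving-space point). Affines compose in closed form; any transform realizes
as a dense displacement field on a chosen grid; fields invert by fixed-point
iteration.

## Tissue extension

A truncated volume is completed from a donor of the same stain: global
similarity registration (donor masked by the truncated annotation), crop to
the full-region bounding box, nonlinear registration of the masked donor
(local-correlation metric, metric mask excluding a 3-plane band around the
cut), application of the field to the *unmasked* donor, histogram matching
(256-bin monotone quantile mapping fitted on the shared tissue, applied to
all donor tissue including the extension), copy of the missing voxels
(never overwriting populated target tissue), and a three-voxel junction
averaging slab centered on the last originally-populated plane.

## Cerebellar layers

Within each lobule mask, Otsu's threshold (256-bin exhaustive
between-class-variance scan, lowest maximizing boundary on ties) splits the
Nissl intensities into the high-intensity granular and low-intensity
molecular layers; islands under 10 voxels are reassigned, and lobules whose
split leaves under 1% of voxels in a class are flagged in the QC table
rather than silently accepted (the stand-in for manual review). At fine
resolution (annotation block-replicated, one pass of 3x3x3 modal filtering)
the Purkinje layer is synthesized as the two-sided 6-adjacency interface:
one voxel from each side, hence exactly two voxels thick across any locally
planar interface — a symmetric, parameter-free reading of a "two-voxel
layer".

## Average template

The template accumulator registers every 2D section nonlinearly to its
anatomical plane of the *fixed* initialization average (not a progressively
updated one), which makes the result independent of section order and fully
deterministic. Warped intensities are summed and counts incremented only at
covered (non-background) voxels, so partial sections do not dilute voxels
they miss. Normalization is `(init + sum) / (1 + count)`: the
initialization counts as one contribution everywhere, and uncovered voxels
keep their initialization value.

## The phantom: what it emulates, and what it does not

All tests run on synthetic phantom brains with recorded ground truth. The
standard phantom ("mouse-64") is a 64 x 80 x 56 grid at 25 um with a
15-node ontology (root, 2 divisions, 4 parents, 8 leaves of which 4 are
cerebellar lobules). The newer-version annotation partitions a brain
ellipsoid into rostro-caudal territories split into leaves; the older
version is a known smooth sinusoidal warp (peak displacement 3 voxels,
wavelength 32 voxels) composed with a small affine jitter (1 degree, 2%
scale, sub-voxel shift), with two leaves merged into their parents. The
Nissl-like modality adds per-region mean intensities (50–200) and
speckle noise (sd 8); the template-like modality is contrast-compressed
(factor 0.45 about a gray level of 60), Gaussian-blurred (1.5 voxels), and
— deliberately — *uniform inside cerebellar lobules*, mirroring the absence
of granular/molecular contrast in the real average template that motivates
the dedicated cerebellar path. Lobule layering is concentric (granular
inner fraction 0.62), so the intensity structure follows lobule shape the
way cortical layers do.

The extension donor emulates another specimen: the complete volume under an
organ-scale smooth warp (one sinusoid period across the volume, 1.5-voxel
amplitude), a 15% intensity gain plus offset, and independent noise. An
earlier draft used a two-period warp; under such a warp the missing rostral
cap is geometrically unpredictable from the populated tissue and no method
could reconstruct it, which is not what specimen-scale shape differences
look like.

What the phantom does **not** emulate: real anatomical geometry, staining
artifacts and tears, section damage, the 500+ leaf regions of a real
ontology, and white-matter/gray-matter discrepancies between annotation
versions. Passing tests demonstrate that the machinery is correct and
well-behaved under controlled conditions, not that real-data accuracy
numbers transfer.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based in world arithmetic; world position of index i
  is `origin + i * voxel_size` (voxel-center convention). Index 0 of the
  rostro-caudal axis is the rostral end, so rostral padding shifts the
  origin negatively (14 slabs at 25 um gives -350 um).
* Majority-vote ties in label downsampling break toward the smallest label
  id; the modal smoothing filter does the same.
* Border-voxel cleanup defaults to 26-connectivity components with a
  5-voxel minimum at 25 um; a small component face-adjacent to a strictly
  larger same-label component survives.
* NMI uses base-2 logarithms internally (the ratio is base-invariant), 64
  bins min-max scaled per image over the mask, and excludes voxels where
  both images are background ("either-foreground" policy, configurable).
  Constant images over the mask are an explicit error, not a silent zero.
* Regions below 50 voxels are not registered independently; they defer to
  the first both-supported ancestor. Degenerate (constant) crops are
  likewise deferred rather than registered.
* Overlapping leaf claims in the reconstruction resolve first-writer in
  ascending region id and are counted; parent-level fills only ever write
  still-empty voxels and are not counted as conflicts.
* Annotation upsampling uses integer block factors; the exact physical
  voxel size is tracked in the grid metadata, and the 25-to-10 um
  deformation-field upsampling is continuous (linear interpolation of
  displacement components, magnitudes in micrometres preserved).

## Problem sizes

The shipped test-suite and reproduction sizes are chosen so a complete run
stays desk-scale: unit tests use a 36 x 44 x 32 reduced phantom; the
acceptance checks and the reproduction script run the full pipeline on the
standard 64 x 80 x 56 phantom, one known-warp recovery at full amplitude,
one tissue extension, a 40-section template-averaging study at spacing 16,
and the layer segmentation of all four lobules.

## Known limitations

* The nonlinear engine is a first-order demons variant, not a geodesic
  symmetric normalization; it recovers smooth warps of a few voxels (the
  regime the pipeline needs) but is not diffeomorphic by construction.
* In-plane (2D) section registration is weaker than the 3D case — flat
  region interiors are underdetermined in a single section — which is why
  the template builder leans on the averaging rather than per-section
  accuracy.
* Per-slice NMI series react to interpolation-induced smoothing differences
  as well as to alignment, so individual incidences can show small negative
  mean deltas even when whole-brain and per-region scores improve; the
  report exposes all three series rather than a single summary.
* Histogram matching assumes a globally monotone intensity relation between
  donor and target; stain-specific non-monotone differences would need a
  richer transfer model.
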