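---
title: "Measuring occlusal tooth wear by 3D superimposition when other surfaces changed too"
author: "occlusalWear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring occlusal tooth wear by 3D superimposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occlusalWear)
```

## The measurement model

Occlusal wear between a baseline scan T0 and a follow-up scan T1 of the same
tooth is a volume: the tooth substance removed from the biting surface. The
package measures it in three steps.

**Rigid superimposition.** The T1 model is registered onto T0 by a trimmed
iterative closest point (ICP) loop. Each iteration (i) takes the vertices of
a *reference area* on the T0 crown, (ii) finds for each the exact closest
point on the T1 surface (faces, edges and vertices are all candidate
features; a BVH-accelerated exact query, not an approximate vertex match),
(iii) keeps the fraction $f$ of pairs with the smallest distances — the
*estimated overlap of meshes* — and (iv) solves the point-to-plane
least-squares update in the small-angle linearisation, re-orthonormalising
the rotation through an SVD projection. Correspondences whose closest point
lies on an open boundary edge or vertex of the target are discarded when
*exclude overhangs* is on, so structure present in only one model cannot
attract the fit. A staged pipeline mirrors operator practice: a
landmark-based coarse alignment (the stand-in for on-screen manual
approximation), then — whenever the requested overlap is below 50 % — a
partial approximation at 100 % overlap, then the final setting. The trim is
annealed from 100 % down to the target fraction over the first iterations of
each ICP run; a hard jump to an aggressive trim (20 %) can lock onto a
spurious partial fit in which a fifth of the crown matches at the wrong
pose, while the annealed trim follows the same minimum that full-overlap
registration tracks and then sharpens it. Trimmed RMS remains non-increasing
under annealing because the mean over the $k' \le k$ smallest distances
never exceeds the mean over the $k$ smallest.

**Reference areas and techniques.** Eight technique definitions pair a
reference area with an overlap setting: the gold standard GS (adjacent
intact teeth plus alveolar band, 100 %), partial-crown techniques PC_A–PC_D
(buccal surface at 100 %; buccolingual or complete crown minus the composite
footprint at user-defined or 40 % overlap) and complete-crown techniques
CC_A–CC_C (40 %, user defined, 20 %). "User defined" is realised as a grid
search (0.05–1.00, step 0.05) minimising the RMS distance of known-intact
structures — possible only in a benchmark, which is precisely its role. GS
provides the true value; CC_C (complete crown, 20 %) is the setting usable
on clinical data, where no adjacent structure can be assumed stable.

**Slicing and volumetry.** After superimposition both crowns are cut with
identical planes. The gingival plane (normal along the occlusal axis) is
placed at a configurable offset (default 0.2 mm) below the occlusal changed
region, which is detected on *both* models as the connected component of
vertices with $|d| >$ 0.05 mm in the signed distance map that contains the
occlusally topmost changed point; detecting on both sides matters because a
ground facet contributes few off-surface sample points on the worn model
itself. Other changed regions — the retainer relief — must stay gingival to
the plane; if the two cannot be separated, or the wear reaches the gingival
boundary of the crown mask, the case is rejected rather than measured.
Along the cut line the two models must agree within the same 0.05 mm
threshold (the numeric analog of inspecting a colour-coded distance map);
violations confined to the proximal ends trigger mesial/distal auxiliary
planes. Triangles crossing a plane are split exactly on it; hole boundaries
spanning several planes are split into planar loops with chords along the
plane intersection lines, so both crowns receive *identical* caps; each
planar loop is closed by ear clipping. Wear is
$V(\text{T0 part}) - V(\text{T1 part})$ by the divergence theorem on the
watertight parts — positive for loss, and independent of the cap
triangulation because all cap triangles are coplanar.

## Tunable parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `overlapFraction` | technique | — | estimated overlap (trim fraction per iteration) |
| `matching` | point_to_plane | — | update metric; point-to-point is the Procrustes fallback |
| `samplingFraction` | 1.0 | — | fraction of reference vertices used (seeded subset below 1) |
| `excludeOverhangs` | TRUE | — | reject boundary-contact correspondences |
| `maxIterations` | 50 | — | ICP budget per stage |
| `convergenceTol` | 1e-7 | mm | stop when RMS changes less than this |
| `distanceThreshold` | 0.05 | mm | changed-region detection and cut-line verification |
| `planeOffset` | 0.2 | mm | gingival plane offset below the changed region |

The convergence tolerance is an addition: the workflow fixes only the
iteration budget, and a stationarity stop makes unchanged-pair registrations
terminate in a handful of iterations. The 0.05 mm threshold is an explicit
numeric stand-in for a visual check; it is far above scanner noise (5 µm)
and far below the smallest simulated wear depth (0.5 mm), so detection is
insensitive to its exact value within that window.

## The synthetic benchmark

The generator reproduces the validation design in silico: 18 incisor and 18
canine cases, vertical losses of ~0.5, 1 and 2 mm, symmetric (horizontal
facet) and asymmetric (tilted facet, default 15°, capped at 30°) grinding, a
0.3 mm lingual wire with a composite blob bonded during the observation
interval, scanner noise, and a random initial pose of T1 (rotation ≤ 15°,
translation ≤ 10 mm) so registration is always exercised.

Teeth are parametric, not anatomical scans: a superellipse cross-section
with a curved height profile, developmental lobes, cusp ridges (canines), a
lingual cingulum and a lingual fossa (incisors). These features matter: a
crown that is axially self-similar admits sliding fits under aggressive
trimming, which real crown anatomy — and this generator — excludes. Each
tooth, and the scalloped alveolar band, is a closed component, so arch
segments are watertight and volumes add; grinding slices only the test
tooth's component and reseals it, giving closed-form ground truth (a 6 × 7 mm
prism ground by 1 mm loses exactly 42 mm³). The retainer is modelled as a
displacement relief (wire ridge plus Gaussian composite blobs) on the
lingual vertices of the test tooth: lingual geometry changes by up to
~0.8 mm while buccal and occlusal vertices stay bit-identical and the mesh
remains watertight — the property the measurement actually depends on. The
adjacent teeth stay intact, which is what makes the gold-standard reference
valid. Scanner noise displaces vertices along their normals; its parameters
are the *repeated-scan* deviation budget (SD 2 µm, hard bound 5 µm between
any two scans), so each realisation draws SD $2/\sqrt2$ µm clamped at
2.5 µm.

Default problem sizes are desk-scale: ~8 000 triangles per tooth, ~30 000
per arch segment (the physical scans are 600 000–900 000 per arch; the
`resolution` argument scales up). The benchmark of record is 36 cases
measured with GS and CC_C; reproducibility re-measures ten cases with the
coarse-alignment landmarks jittered by 0.3 mm SD — the in-silico analog of
an operator re-approximating the models at a later session — and the
repeated-scan experiment measures ten unchanged single teeth across two
noise realisations at a random relative pose.

What passing these suites does and does not show: the generator emulates
wear facets, a retainer relief, scanner noise and pose variability, but not
real anatomical variation between patients, segmentation uncertainty of the
crown masks (masks are exact by construction), soft-tissue differences, or
scanner artefacts beyond i.i.d. normal-direction noise. Results on real
scans depend on those factors; the in-silico benchmark validates the
algorithmic chain, not the scanner or the operator.

## Numerical choices and degenerate inputs

* Exact-duplicate vertex welding only (1 nm tolerance) on STL import, so
  fine wire geometry can never be merged away; degenerate faces are dropped
  with a message.
* Slice vertices are projected exactly onto their plane (|signed distance|
  < 1e-9 mm); split points are cached per edge so the cut stays sewn.
* Cap orientation is fixed by the boundary-edge direction (each cap
  traverses a boundary edge opposite to its single incident face), which
  makes watertightness a checkable invariant rather than a convention.
* Ear clipping prefers strictly convex ears and falls back to collinear
  ears; self-intersecting cap polygons are a geometry error.
* Ties in distance-rank trimming break by source index, making every
  registration bit-reproducible for a given seed.
* Point-to-plane updates fall back to Procrustes when the normal equations
  are ill-conditioned (e.g. degenerate normals).
* All stochastic paths (sampling, noise, poses, jitter) draw from local
  seeded generators that never touch the session RNG state.

## Known limitations

* The retainer is a surface relief, not a separately meshed wire swept and
  unioned onto the crown; undercuts beneath the wire are therefore not
  represented. The measurement never looks at that region, but renderings
  of T1 are stylised.
* Automatic plane placement handles one gingival plane routinely and adds
  proximal planes only on cut-line violations; pathologies such as wear
  wrapping around the proximal surface are rejected as cannot-isolate
  errors instead of being measured badly.
* The "user defined" overlap search needs known-intact structures and is
  deliberately benchmark-only, as is the gold standard itself.
* Registration quality, and hence wear accuracy, degrades with mesh
  resolution; the desk-scale defaults keep single-tooth volume errors an
  order of magnitude below the smallest simulated wear volume, but
  sub-0.01 mm³ claims would require scan-resolution meshes.
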