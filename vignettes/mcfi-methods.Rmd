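---
title: "MRI-CT fusion imaging of capitellar OCD: models, rules and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-CT fusion imaging of capitellar OCD: models, rules and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capfuse)
```

## The problem and the method

Osteochondritis dissecans (OCD) of the humeral capitellum involves two
tissues that no single modality images well: articular cartilage
(delineated on traction MRI, where distracting the joint separates the
cartilage outline from the opposing radial head) and subchondral bone
(delineated on thin-slice CT). The fusion approach implemented here
segments each tissue from its best modality, reconstructs triangle-mesh
models, rigidly registers the MRI-derived humerus to the CT-derived
humerus, and hides the MRI bone so that the scene shows the CT bone
with the MRI cartilage draped over it. Because the cartilage model is
rigidly linked to the MRI bone model during registration, the
cartilage lands on the CT bone in the correct anatomical relationship,
and turning down the cartilage transparency reveals whether a
separated bone fragment lies directly beneath a cartilage lesion — the
key stability question.

The evaluation vocabulary is a small set of finding primitives:

* **ACF** (articular cartilage fissure): a low-signal line *within*
  the cartilage that penetrates, or is perpendicular to, the articular
  surface.
* **ACD** (articular cartilage defect): cartilage frankly absent.
* **ASD** (articular surface deformity): an irregular outer cartilage
  outline, recorded as protrusion or flattening.
* **SSB** (segmented subchondral bone): a fragment whose continuity
  with the parent bone is lost in *all three* orthogonal planes.
* **Sclerosis**: abnormally dense subchondral bone, relevant to
  drilling.

## Codified rules replacing operator judgment

The source workflow relied on an experienced surgeon's reading of the
fused scene. This package replaces each judgment with an explicit,
parameterized criterion; the parameters below are this package's
choices, validated on the phantom, not published constants.

* *Fissure criterion*: a connected low-intensity component inside the
  (morphologically closed) cartilage layer is an ACF when its
  principal axis is within `angle_tol = 30` degrees of the local
  surface normal **or** it spans at least `span_frac = 0.8` of the
  local cartilage thickness. A sub-surface slab parallel to the
  surface fails both and is rejected.
* *Deformity criterion*: a reference sphere is anchored at the
  capitellar centre (the anatomical-frame origin) with radius equal to
  the median radius of the outer cartilage boundary; contiguous
  patches with signed radial residual beyond `h_tol = 0.5` mm (about
  one MRI voxel) and at least `area_min = 10` mm&sup2; of projected area
  are ASDs. Fitting both centre and radius to a partial cap is
  ill-conditioned — centre depth and radius trade off, and the
  deformity itself drags a free fit — which is why the centre comes
  from the frame rather than from the data.
* *Defect criterion*: directions inside the cap (the convex hull of
  cartilage-bearing directions in the anteroposterior projection)
  whose radial cartilage thickness falls below `thickness_min = 0.5`
  mm over at least `area_min = 5` mm&sup2;.
* *Three-plane SSB criterion*: a candidate fragment is a 3D connected
  component (26-connectivity) disjoint from the largest bone
  component; it qualifies only if, in every axial, sagittal and
  coronal slice it occupies, it is 2D-disconnected (8-connectivity)
  from the main bone. A fragment bridged to the floor anywhere is
  rejected — the phantom's `ssb_cleft_planes = "bridge"` setting
  generates exactly this counterexample.
* *Sclerosis*: bone voxels above the 90th percentile of the bone
  intensity distribution, largest connected component retained (the
  percentile inevitably captures a scattered noise tail; the
  largest-component step removes it).

**Stability and ICRS class.** A lesion is unstable when a fissure or
deformity has the SSB underneath it, or when the cartilage is frankly
defective. The ICRS mapping is the package's codification: ACD → IV;
ACF or ASD with SSB underneath → III; ACF or ASD without separated
bone → II; no findings → I. Written this way, class III/IV coincides
exactly with the unstable call on every input — a findings-only
variant (`predict_icrs(..., use_ssb = FALSE)`, where ASD → III and a
lone ACF → II) exists for the packaged tables, which do not record the
SSB relationship per finding. Applied to the tabulated findings, the
findings-only rule reproduces the human assessors' predicted classes
in 16/16 cases, and disagrees with the intraoperative class only for
the case whose lesion detached between imaging and surgery.

**Quadrants and diameters.** The articular surface is treated as an
ellipse in the anteroposterior (AP) view — fitted by a direct
least-squares conic (Halir–Flusser formulation of the
ellipse-constrained fit, stable also when the data are exactly
elliptical) to the convex hull of the projected cartilage boundary.
The proximodistal and mediolateral axes through the ellipse centre cut
the surface into areas 1–4, clockwise from anteromedial; boundary
points take the lower-numbered adjacent area, and the medial axis is
defined by the frame so a left-side elbow mirrors consistently.
Diameters are straight-line extents of the AP-projected footprint
(vertical = proximodistal, horizontal = mediolateral), not geodesics —
matching caliper-style measurement on an AP view. When the footprint
points are voxel centres the extent under-covers the region by about
one voxel; `measure_diameters(..., voxel_correction_mm = )`
compensates.

## Registration

Stage one is landmark ("N-point") registration: a closed-form
least-squares rigid fit (Kabsch) over ordered, named corresponding
points — at least three, non-collinear; four well-spread points on
different planes is the working protocol. The rotation is forced to
determinant +1: a reflected solution would silently mirror anatomy.
Stage two is point-to-point iterative closest point between the two
bone meshes: nearest neighbours on a uniform spatial hash grid, rigid
update, stopping when the relative rmsd change falls below `1e-6` (a
convergence test on the objective, not on parameters) or after 50
iterations; the rmsd trace is non-increasing. The moving cloud is
uniformly subsampled (default ~1500–2000 vertices) for speed; no
trimming by default because phantom surfaces overlap fully — a
`trim_frac` parameter exists for partial-overlap real data. On
phantoms with landmark noise of 0.2 mm, landmark + ICP recovers the
true inter-modality transform to well under 1 degree and 0.1 mm.

## The phantom: what it emulates and what it does not

The phantom is a geometric stand-in, not an anatomical simulation. It
emulates: a capitellum-like spherical cap (bone radius 11 mm,
cartilage shell 2.2 mm, cap half-angle 60°) with a proximal shaft and
two epicondyle-like bosses that break rotational symmetry (a bare
sphere would leave ICP's rotation unconstrained); three MRI intensity
classes (background 0, bone 80, cartilage 200) and CT classes
(background 0, cartilage 30, bone 1000, sclerosis 1600) — synthetic
constants, deliberately not HU-calibrated, because clinical thresholds
were scanner-specific and operator-tuned; a lesion whose footprint is
an ellipse in the AP projection with semi-axes
$R_s \sin(\alpha/2)$ for angular extent $\alpha$, so the true
diameters $2 R_s \sin(\alpha/2)$ are closed-form; a fissure slab
(1 voxel thick, containing the surface normal — an ACF by
construction, with a tangential variant as a negative control);
flat-top protrusion/flattening; a full-thickness defect; a lens-shaped
subchondral fragment separated by a 1.2 mm cleft, with an optional
bone rod bridging the cleft as the three-plane-criterion
counterexample; a sclerotic rim beneath the cleft; additive Gaussian
noise (default sd 5, i.e. ≥ 20 sd of class separation); and ≥ 4 shared
landmarks exactly related by the configured rigid transform. Voxel
spacings default to 0.4 mm (MRI) and 0.5 mm (CT) isotropic, matching
thin-slice acquisition of a small joint.

It does **not** emulate: realistic elbow anatomy (trochlea, radius,
ulna, growth plates), MR pulse-sequence contrast, partial-volume
blur, bias fields, motion, or traction biomechanics (traction is a
metadata flag; its imaging benefit — a visible cartilage outline — is
implicit in the phantom having one). Passing the phantom suite
therefore demonstrates geometric and algorithmic correctness of the
pipeline, not clinical segmentation performance on real MRI.

Defaults were chosen once to represent the study conditions: the
default lesion (fissure + 1.2 mm protrusion + separated fragment +
sclerosis) is the modal class-III presentation, and the configurable
angular extents span lesion diameters of roughly 8–20 mm, the range
the per-case diameter table covers.

## Numerical choices

* Iso-surfacing is marching tetrahedra (six tetrahedra per cube around
  a fixed diagonal, so shared faces match and the mesh is watertight)
  at level 0.5 on the binary indicator, which is pre-smoothed with a
  small Gaussian (σ = 0.8 voxel) so linear interpolation places
  vertices sub-voxel-accurately; a voxelized 10 mm sphere comes back
  with surface area within a few percent of $4\pi r^2$. For masks so
  small that smoothing would erase them, the raw indicator is used.
* Mesh smoothing is Taubin λ/µ (0.33 / −0.34), which relaxes staircase
  noise while changing enclosed volume by well under 1% over 20
  iterations.
* Placement metrics are computed on rasters (default 0.2 mm), not by
  exact mesh booleans — robust against near-degenerate contacts. The
  graft silhouette uses the convex hull of projected vertices (valid
  because both graft shapes are convex); the test suite checks it
  against an independent brute-force voxel-counting oracle.
* Drilling is a zero-width segment by default; a physical drill
  diameter turns the breach test into a sampled capsule test.
* Ties and degenerate inputs: empty threshold masks warn rather than
  error (the caller decides); an empty lesion footprint yields absent
  diameters, mirroring the clinical case with nothing to measure; the
  area tie-break is always the lower-numbered area.
* The corresponding rate rounds half-away-from-zero to one decimal, so
  15/16 prints as 93.8 — the convention the published tables use.
* The Mann–Whitney default is the tie-corrected normal approximation
  without continuity correction, with a seeded permutation test (10^5
  resamples) as the distribution-free oracle; published p-values are
  checked with tolerance, never for exact equality, since the original
  software and convention are unknown. The published interquartile
  ranges are not reproducible under any single quartile convention, so
  the quartile type is a parameter (`median_iqr(..., convention = )`)
  and IQRs are reported but not asserted.

## Problem sizes used in the shipped tests

The default phantom grid is 80³ voxels (a 32 mm MRI field of view at
0.4 mm; 40 mm CT at 0.5 mm), generated in about a second; smaller
64³ phantoms with an 8 mm cap are used where only plumbing is under
test. The validation suite runs 20 seeded registration trials, 10
seeded lesion-recovery phantoms plus bridge counterexamples, and 50
randomized graft poses against the coverage oracle. These sizes were
chosen to exercise the estimators well past their asymptotic behaviour
while keeping a full run in the low minutes on a single CPU.

## Known limitations

* Flattening-type deformities are detected reliably, but their
  measured extent is conservative by up to a bin (0.6 mm) per side:
  boundary bins containing both flattened and intact surface take the
  intact (maximum) radius and drop out of the patch. Protrusion and
  defect footprints do not suffer from this.
* The defect detector reconstructs the crater on the fitted reference
  sphere; on a cap whose true surface deviates strongly from a sphere
  the reconstructed footprint (and hence localization) degrades.
* The stability rule deliberately ignores an SSB with no overlying
  cartilage finding; such a case is called stable/class I, which is
  faithful to the underneath-based definition but would miss a purely
  osseous lesion.
* Registration assumes the two volumes image the same rigid anatomy;
  there is no deformable component, and partial overlap requires
  setting `trim_frac`.
* The packaged tables are outcome summaries of 16 cases; statistics
  computed from them (medians, rank-sum p-values) inherit the rounding
  of the printed values.
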