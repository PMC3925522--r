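---
title: "Methods: zone mapping on the quadrilateral surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone mapping on the quadrilateral surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the geometric model implemented by `quadzone`, the
assumptions and numerical choices behind it, and what the synthetic
phantom does and does not establish about real anatomy.

## The model

A screw placed on the quadrilateral surface endangers the hip joint when
its axis passes too close to the acetabular articular surface. Two
stand-off distances bound the risk:

* the **absolute clearance**, `d_abs = 1.2 mm + 1.75 mm = 2.95 mm`
  (maximal subchondral bone thickness plus minimal screw radius), below
  which a screw necessarily violates subchondral bone; and
* the **margin clearance** of `6 mm`, kept as an explicit constant rather
  than recomputed as `2.95 + 3 = 5.95`: the margin figure in clinical use
  is the round 6 mm, described as allowing roughly a 3 mm insertion
  error. `offset_spec()` stores both and checks the derivation.

The articular surface is offset by each clearance ("shelled"). The offset
shell, not the bone, is then the occluder in a visibility computation:
the (modified) Stoppa incision is reduced to a straight skin-level
segment, viewpoints are sampled uniformly along it, and an entry point is
occluded from a viewpoint when the open segment between them intersects
the shell. A rigid straight instrument is assumed — the incision
constrains direction, soft-tissue deflection is ignored.

Zone labels use mixed quantifiers, which is the substantive modelling
decision in the pipeline:

* **absolute dangerous** — occluded by the 2.95 mm shell from *every*
  viewpoint. No admissible trajectory achieves the minimal clearance.
* **absolute safe** — clear of the 6 mm shell from *at least one*
  viewpoint.
* **relatively dangerous** — the remainder.

The all/some reading follows from how the brim landmarks are used: an
entry proximal to `E` is safe *when approached from the distal end* and
one distal to `F` *from the proximal end*, so danger persists only where
no direction works. A uniform "occluded from any viewpoint" reading is
nevertheless exposed (`quantifier = "union"` in `classify_zones()` /
`quadzone_config()`) because the alternative interpretation is
grammatically possible; with it the dangerous set is provably a superset
of the default's, which the tests assert.

Landmarks `E` and `F` are occlusion boundaries *on the brim curve* under
the single end viewpoints (distal for `E`, proximal for `F`),
disambiguated among boundary candidates by distance to the obturator
canal (farthest for `E`, nearest for `F`). `G` and `H` are the dangerous
points farthest from the canal and from the brim. The auxiliary points
(`K`, `M`, `P` perpendicular feet on the brim; `N`, `Q` brim-parallel
intersections with the foramen rim) are constructed in the best-fit plane
of the analysed region using the local brim tangent at the nearest brim
point: perpendicularity to a 3D space curve is otherwise underdetermined,
and the planar reading matches how such constructions are drawn on a 2D
view of the surface. Distances are straight-line 3D segment lengths in
centimetres, reported to two decimals; cohort cells are
`mean (min–max)`.

## Numerical choices

**Offsetting.** Shells are extracted as the iso-surface of the unsigned
distance field at level `d`, sampled on a voxel grid (default pitch
0.5 mm) and polygonised with marching tetrahedra. A distance-field offset
cannot self-intersect on concave regions and handles the *open* articular
cap uniformly: its offset is the closed shell wrapping the cap, which is
exactly the occluder the zone logic needs. The field is computed exactly
in a band of `d + 6` pitches around the input triangles; voxels outside
the band keep a sentinel far value, which cannot create spurious
crossings because the band exceeds the level by several voxel diagonals.
Marching tetrahedra welds iso-vertices exactly through shared grid-edge
keys, so closed iso-surfaces come out watertight; the output is
deliberately not re-welded or area-filtered afterwards, since dropping
sliver triangles would open cracks. The offset is accurate to well under
a voxel on smooth surfaces (the tests bound it by two voxels and observe
a median deviation an order of magnitude smaller); `d = 0` returns the
validated input, and a pitch coarser than `d` is refused.

**Occlusion.** Segment–mesh tests use exhaustive Möller–Trumbore
scanning below 4000 faces and a uniform-grid accelerator (3-DDA
traversal over conservatively binned triangle boxes) above; the tests
require the two paths to agree exactly. Hits within `1e-6` mm of either
segment end are discarded to avoid grazing self-hits. Inside/outside
queries (used by the shell-nesting checks) take ray-crossing parity with
a two-of-three vote over fixed skew directions.

**Landmark localisation.** `E`/`F` are bracketed on a brim densified at
0.1 mm and bisected to `1e-4` mm. `G`/`H` sit where a distance level set
is tangent to the dangerous-zone boundary, so the objective is nearly
flat along the boundary and a naive local search stalls unpredictably;
instead the boundary is probed along one-dimensional families on which
the objective is monotone — rays out of the canal for `G`, inward brim
normals for `H` — scanning coarsely and bisecting the outermost
dangerous point per probe to 0.003 mm. The analytic truth uses the same
constructions on the exact sphere predicate with finer steps, keeping the
two routes independent. Ties among equal extremal candidates resolve to
the first probe encountered, which is deterministic because mesh loading
and probe fans are deterministic.

**Meshes.** STL facets are welded at `1e-6` mm (STL stores each facet
independently); faces with repeated indices or area below `1e-12` mm²
are dropped at validation. Watertightness is defined as every edge
shared by exactly two faces, ignoring orientation.

## The phantom and its ground truth

`phantom_spec()` describes a canonical left hemipelvis in local
coordinates (plate plane `z = 0`, `x` anterior, `y` proximal, `z`
medial): a 24 mm spherical articular cup buried 2 mm below the plate, a
gently curved brim arc running obliquely above the cup from the
superomedial to the inferolateral corner, an elliptic obturator foramen
inferolateral of the cup with the canal point on its superolateral rim,
and a 90 mm longitudinal incision anterior and medial of the plate at
skin height 20 mm. The scale is plausible for an adult pelvis; none of
the numbers is a population value. The defaults were chosen once so that
the construction is well posed — both shells partially occlude the brim
from both incision ends (so `E` and `F` exist), the brim-parallel lines
through `G` and `H` intersect the foramen rim (so `N` and `Q` exist),
and all three zones are non-empty — and they produce the monotone shell
effect that motivates the measurements: enlarging the shell moves `E`
away from `K`, `F` toward it, and `G`/`H` away from foramen and brim.

The cup is modelled as a perfect sphere even though real acetabula are
not: sphericity buys a closed-form occlusion predicate (exact
segment–sphere distance), from which the truth derives shadow conics per
viewpoint (tangent-cone intersection with the plate plane), brim
boundary points by bisection, extremal points by monotone probing, and
all six distances by exact planar constructions. The articular cap spans
60° about the medial axis; every admissible sight line touches the
offset sphere on its plate-facing side well inside that span, so the cap
shell and the full offset sphere occlude identically (a property the
tests verify directly against the mesh pipeline). A `lumpy` mode applies
a seeded low-frequency radial perturbation for robustness testing; it
has no analytic truth and falls back to brute-force oracles.

Default discretisation: cap/slab target edge length 1.5 mm, entry grid
1.25 mm, voxel pitch 0.5 mm, 21 viewpoints. At these settings the
end-to-end landmark error against the analytic truth is a few tenths of
a millimetre, dominated by the faceting of the cap (whose footprint
boundary shift is amplified by the shallow crossing angle of the shell
through the plate, roughly `R/√(R²−depth²) ≈ 3.8×`); the edge length is
chosen so this stays comfortably below the 0.05 cm reporting precision.
Halving edge length, pitch and grid spacing roughly quarters the
faceting error, which is how the suite checks convergence. The
finer-resolution validation run uses a 0.75 mm cap mesh with 0.25 mm
pitch; cohort-level tests run coarser phantoms (2.5–3 mm) since they
exercise aggregation, not geometric accuracy.

What passing the phantom suite shows: the chain
offset → occlusion → quantifier logic → boundary landmarks →
plane constructions → aggregation is implemented correctly to sub-half-
millimetre accuracy. What it does not show: anything about segmentation
quality, non-spherical acetabula (beyond the lumpy smoke tests),
soft-tissue constraints on the real aperture, or population values of
the six distances — the phantom's distances are properties of its
synthetic anatomy only.

## Interfaces and scope decisions

* The pipeline requires exactly two offsets (absolute, margin); the zone
  semantics is defined for that pair. Sensitivity sweeps over more
  offsets can be scripted against `offset_surface()`/`classify_zones()`
  directly.
* Right-sided subjects are mirrored into the canonical left frame
  (`x → −x`, faces reversed), processed, and mirrored back, keeping one
  code path; the tests check mirror symmetry of landmarks and exact
  equality of distances.
* Subjects from files supply meshes (STL/PLY/OBJ) plus a landmark JSON;
  the analysed region is either an explicit entry-point set (phantoms) or
  an in-plane polygon lasso, from which only the incision-facing sheet of
  the inner surface is kept.
* PLY support is ASCII (read/write, with per-vertex integer `zone`
  overlays); binary PLY is refused with a clear error. Both STL dialects
  are read and written; the binary/ASCII choice is auto-detected from the
  record-count arithmetic, not the `solid` prefix.
* Per-subject failures in cohort runs are recorded and skipped; a cohort
  fails only when every subject does.

## Known limitations

* Occlusion is tested against the offset shells only; self-occlusion by
  other bone is deliberately not modelled, since the zone definition is a
  property of the shelled articular model, and bony-window feasibility is
  a separate surgical question.
* Trajectories are straight segments from the aperture; instrument
  diameter beyond the screw radius, soft-tissue deformation and retractor
  effects are out of scope.
* The best-fit-plane reading of "perpendicular/parallel to the brim" is
  one of several possible conventions; it is isolated behind
  `fit_reference_frame()` so an alternative frame could be substituted.
* Distances are Euclidean 3D segment lengths, not geodesics along bone;
  for the nearly planar quadrilateral region the difference is small but
  not zero.
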