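---
title: "Methods: localizing standardized head acupoints on surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing standardized head acupoints on surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Standardized acupuncture point locations on the head are defined partly by
anatomy (protuberances, canthi, auricular landmarks), partly by proportional
subdivision between anatomical landmarks, and partly only descriptively,
"along the curve between two other points". `acuhead` implements a partially
automated localization pipeline over triangulated head surfaces
reconstructed from axial image stacks: the 34 anatomical points are supplied
as a manual annotation, the 24 proportional points are computed from angle
ratios, and the 7 morphological points are transferred from a standard
source model by a distance-matching argument. With the three auxiliary
landmarks (Pupil, Yintang, TOP) this covers all 65 standard head points.

## Surface reconstruction

The input is a stack of 8-bit axial slices (one BMP per slice, 1 mm
spacing by default). Binarization uses inclusive intensity thresholds — 10
for skin, 110 for bone — so the printed values are meaningful as minima.
Enclosed cavities are then filled: background voxels not 26-connected to
the stack border become foreground (the skull interior must be solid for
the center of mass to be meaningful), optionally preceded by a 6-neighbour
morphological closing for genuinely perforated data. The closing count is a
free parameter because the source procedure names only a "dilation
subroutine" without an element or iteration count; on the clean synthetic
phantom closing is a no-op, and the default of one pass is retained.

Triangulation walks the marching-cubes cube grid, but each cube is split
into the six Kuhn tetrahedra sharing its main diagonal and the 0.5-level
surface is extracted per tetrahedron. This produces the same watertight
iso-surface a table-driven marching-cubes implementation would (vertices on
grid edges, here midpoints since the field is binary) while avoiding the
ambiguous cube configurations entirely; no pre-installed R package offers
marching cubes, so the primitive is implemented in the package and checked
against analytic oracles (sphere radius, cube area, Euler characteristic
2). Faces are oriented outward using the inside/outside corners of the
owning tetrahedron; vertex normals are the renormalized *unweighted* means
of incident face normals (area or angle weighting is a possible variant;
unweighted is declared and kept). Note that on a binary field the facets
are staircase-like, so individual face normals deviate substantially from
the smooth-surface normal; the averaging contract is therefore verified on
an analytic sphere mesh, not on voxelized output.

## Frames and planes

The model frame is `p' = alpha (p - CM)` with `alpha = 4/512` and `CM` the
mean foreground voxel index of the binarized head. The source formulation
writes the CM sums without the normalizing `1/N`; the mean is used because
an unnormalized sum does not produce a centering translation. Axis
convention: x left-right (subject's left negative, matching the sign
pattern of the standard-source coordinate table), y posterior-anterior,
z inferior-superior.

The midsagittal plane is fixed by Yintang, TOP and GV17 (normal
`(GV17-Yintang) x (TOP-Yintang)`), the coronal plane by the two TE20 points
and TOP, and a transverse plane at any level is perpendicular to the axis
shared by the two. The level point for the proportional hairline band is
GV24: the source leaves the level unstated, and GV24 is the one midline
point that the band's rules (ST8, GB13, BL3, BL4) are all measured from,
so its transverse plane is the natural carrier. On discrete surfaces exact
plane membership is replaced by a band of half-width `alpha/2` (half a
model-frame voxel pitch) by default.

## Proportional points

All angles share the vertex TE20CP, the midpoint of the two TE20 points.
`theta0` is the angle between the rays to Yintang and to GV17 and is worth
12.5 proportional units. A sagittal-ratio rule `r` selects skin vertices in
the midsagittal band whose ray makes angle `(r/12.5) theta0` with the GV17
ray, within a tolerance of 0.25 degrees (doubling up to four times if the
selection is empty — at 1 mm resolution on a 60 mm head the vertex spacing
is about one degree, so a fixed narrow interval alone would often select
nothing); the cosine is symmetric about the GV17 ray, so selection is
restricted to the cranial arc (positive component toward Yintang in the
plane), excluding the chin-side mirror solutions. Selected vertices are
averaged and the average snapped to the nearest mesh vertex, so every
output lies on the surface (the source leaves the averaged point possibly
off-surface; downstream curve construction needs on-surface points).
Transverse-ratio rules work identically in the GV24-level band with the
GV24 ray as reference, per side of the sagittal plane. GV24 is itself a
ratio output, so rule evaluation follows a fixed dependency order: the
sagittal chain (GV18..GV24, then the AUX helper at ratio 11/12.5), then
transverse rules, then coordinate rules.

Coordinate rules constrain one or two coordinates to (rational
combinations of) other points' coordinates and leave the remaining degree
of freedom to the surface; the residual hemisphere ambiguity is resolved by
a per-rule half-space (anterior for the forehead points GB14..GB17 and BL5,
superior for BL6..BL8, posterior for BL9, GB18, GB19 and BL10). SI19 is the
surface projection of the TE21/GB2 midpoint. One composite rule (BL9) has a
typographically ambiguous coefficient grouping in the source table; it is
encoded as `P_x = GV17_x - (1.3/1.5)(BL4_x - GV24_x)` and isolated in a
single catalog record so a correction never touches code. As encoded, a
same-side BL4 input lands the point across the midline; the left/right
pair remains mirror-consistent (the labels swap), and the record is the
single place to flip the sign should the grouping be resolved otherwise.

## Morphological points

A morphological rule carries two control points and the standard-source
coordinates of controls and targets (left and right) from the normal-man
model. On the target head a candidate curve joins the controls: mesh
vertices within one voxel pitch of the plane through the two controls and
the head centroid, chained by the shortest surface path (shorter arc of the
plane section). A geodesic construction independent of the section plane is
a possible alternative; the plane section is declared because the source
never defines the "curved line". For each target with source triple
(P, Q, R) and target controls (P', Q'), the solver minimizes

    L(X) = (|X - P'| - |R - P|)^2 + (|X - Q'| - |R - Q|)^2

exhaustively over the curve vertices (hundreds of vertices; ties break
toward the control-a end). The exact printed form of the functional is not
legible in the source; this sum-of-squared-distance-differences form is
declared, satisfies the stated self-consistency property (L = 0 when the
target reproduces the source distances, so running source = target returns
every standard coordinate exactly), is rigidly invariant, and is isolated
behind one function so absolute-difference or normalized variants can be
swapped. No head-size normalization of the source distances is applied
(none is stated); for strongly differently sized heads the minimizer of L
is *not* the similarity-mapped point, which is a known limitation of the
distance-matching form.

## The synthetic phantom

The generator emulates a two-shell head: an outer soft-tissue ellipsoid
(intensity 40, within the [10, 110) soft band) containing an ellipsoidal
bone shell (intensity 200, >= 110) over background 0, voxelized exactly via
quadratic forms so the conventional thresholds reproduce the construction
masks bit-for-bit. Defaults state the validation world used throughout the
tests: a spherical head of radius 60 mm centered in a 128^3 stack of 1 mm
voxels — the spherical-head idealization under which the angle-ratio
machinery has a closed-form great-circle oracle — with a 52 mm bone shell
6 mm thick. Landmarks sit at fixed (longitude, latitude) chart positions on
the skin surface, chosen once to mimic the qualitative arrangement on a
real head (Yintang 20 degrees above the anterior equator, GV17 10 degrees
above the posterior equator — hence theta0 = 150 degrees — ears exactly
lateral so that TE20CP falls on the center, etc.). Optional features:
radial asymmetry gradients, Gaussian protuberance bumps, and seeded
additive intensity noise (default 0 so intensity classes stay exact).

What a green phantom test does establish: the frame/plane algebra, the
selection-average-snap solver against closed-form spherical oracles (about
one voxel of agreement), bilateral mirror consistency, and end-to-end
plumbing. What it does not establish: behaviour on real anatomy — hairline
and auricular structure, non-convex surfaces (chin, ears), tissue
inhomogeneity, or the accuracy of manual annotation, none of which the
phantom emulates.

## Numerical choices

- Angle interval 0.25 degrees, doubling at most 4 times on empty
  selections; plane/coordinate bands half a voxel pitch with the same
  widening schedule. Shrinking the interval cannot move a result farther
  than the band width (selection is an average over the band).
- Iso-level fixed at 0.5 on the 0/1 mask; vertices at edge midpoints.
- Mesh files carry 6 significant decimals (sub-voxel at 1 mm).
- Degenerate inputs error early and name the offending entity (empty
  masks, collinear plane triples, coincident controls, missing landmarks).
- The bundled catalog is checksummed (31-ary rolling checksum) and
  re-validated on every load: category counts 34/24/7 (+3 auxiliary),
  referential integrity of every rule, mirror-sign sanity of the
  standard-source coordinates (|x_left + x_right| <= 0.05; the observed
  asymmetries up to ~0.04 are genuine in the source data and deliberately
  tolerated, not corrected).

## Known limitations

- Anatomical points are inputs, not detected; the phantom supplies them as
  ground truth, real data needs manual annotation.
- The morphological solver is scale-sensitive by design (see above).
- Binary-field triangulation quantizes vertex positions to half-voxels;
  sub-voxel surface accuracy would need grayscale interpolation, which the
  binarize-first procedure deliberately forgoes.
- DICOM input is out of scope (no reader available offline); BMP stacks
  with a JSON sidecar are the supported interchange format.
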