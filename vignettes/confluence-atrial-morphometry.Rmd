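---
title: "Quantifying 3D confluence-atrial morphology: methods and design"
author: "confluencemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D confluence-atrial morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

In supracardiac total anomalous pulmonary venous connection the four
pulmonary veins drain into a common confluence (PVC) behind the left
atrium (LA), and the repair anastomoses confluence to atrium.  The
package measures, from a labelled segmentation, geometry that bears on
how large and how well-apposed that anastomosis can be:

1. **Volumes.**  `voxelVolume()` counts label voxels and multiplies by
   the voxel volume; no partial-volume correction is applied, because
   the measurement is defined as a voxel count.  Volumes are indexed to
   body surface area (BSA): `iLA = V_LA/BSA`, `iPVC = V_PVC/BSA`,
   and `iTVLC` is computed as `iLA + iPVC` (not `(V_LA+V_PVC)/BSA`) so
   the identity `iTVLC = iLA + iPVC` holds to the last bit.  BSA is an
   input, never computed: charted BSA values are the reference and no
   single formula is canonical in infants.

2. **Confluence demarcation.**  Each venous structure gets its own
   centerline (below).  The confluence is the sub-polyline of the main
   channel between two *junction planes*: the plane where the right
   upper and inferior pulmonary veins join the channel, and the plane
   where the vertical vein and the left upper pulmonary vein join it.
   A junction plane is realized as the plane orthogonal to the local
   channel tangent at the junction node — the plane family is named by
   the anatomy but its orientation is not, and the orthogonal choice is
   the only one that is independent of the world frame.  For a
   right-sided vertical vein (type Ib) the rule mirrors left-right
   (LUPV∧LIPV and VV∧RUPV); the literature describes only the
   left-sided wording, so the mirror is an explicit package convention.

3. **Projection.**  The demarcated centerline is projected onto the LA
   surface.  "Projection by stereo geometry" is realized as *Euclidean
   closest-point projection onto the surface mesh*: it is well defined
   everywhere (normal-ray casting is not, on a voxelized surface), and
   on the phantoms it reproduces the closed forms (perpendicular foot
   on a plane; concentric arc shortened by R/(R+g) on a sphere).  This
   is the single most consequential interpretation in the package.

4. **CCL and mDBLC.**  The corresponding confluence length (CCL) is the
   arc length of the ordered projected polyline — a surface-following
   chordal path, not an exact geodesic; the difference vanishes with
   sampling density, and the centerline is resampled to at least 101
   stations before projection.  The projected curve is sampled at 100
   points `p_i` at equal arc-length intervals *including both
   endpoints* (station spacing CCL/99; the source description says only
   "equal intervals").  Each `p_i` is paired with the globally nearest
   point `q_i` on the confluence centerline — nearest-point is the only
   order-free reading of "the projection point identified for each
   sampling point".  `DBLC_i = |p_i − q_i|` is taken as an absolute
   distance (never signed), and `mDBLC` is the mean of the 100 values.

5. **Risk classes.**  `classifyRisk()` dichotomizes iTVLC at 20 cm³/m²
   and CCL/mDBLC at 7.7 (both `>=`, both configurable): two thresholds
   met → low, one → medium, none → high.  The thresholds are treated as
   fixed clinical constants; they are never re-derived from phantom
   data.

## Centerline extraction

The published pipeline uses flux-driven centerline extraction; this
package substitutes a simpler estimator with the same geometric
accuracy class on tubular labels, because the acceptance surface of the
method is geometric accuracy, not algorithm identity:

* build the 26-connected voxel graph of the label (6-connectivity is
  used for the "single connected component" precondition, matching the
  usual topology conventions);
* compute the exact Euclidean distance transform (EDT; separable
  lower-envelope algorithm in C++, anisotropic spacing supported);
* find the farthest voxel pair by graph distance and connect it with a
  minimal path whose edge costs are `length / EDT²`, which pins the
  path to the medial ridge;
* rebuild the geometry as the *moving centroid* of the label voxels
  over one-voxel arc-length bins along that path.  Interior bins are
  complete cross-sections, so their centroids lie on the medial axis by
  symmetry.
* Near each tip the minimal path reaches the boundary through a
  diagonal "dive" from a rim corner, which tilts the bin boundaries and
  biases centroids over roughly two tube radii.  Each endpoint is
  therefore re-estimated as the centroid of the outermost one-voxel
  slab of label support along the (stable) interior axis direction, the
  contaminated stretch is replaced by the chord to the first clean bin,
  and one orthogonal recentring pass restores any curvature.  A final
  3-point moving average smooths lattice jitter.

A label whose maximum EDT does not exceed one voxel (a 1-voxel-thick
line) is already its own skeleton; the minimal path is returned as-is,
so the degenerate case is exact.

Junction nodes are found from label adjacency (a vein label must touch
the main channel within the 26-neighbourhood, else a topology error
names the role) but *located* by the junction-side endpoint of the vein
centerline, which lies on the vein axis and therefore maps onto the
main channel more accurately than the adjacency-voxel centroid; the
centroid is the tie-breaking fallback.  Attachment stations closer than
`max(2 mm, 4 voxels)` are clustered into one junction node.

## Surface extraction and projection

The LA isosurface (level 0.5 between label and background) is extracted
by marching tetrahedra on the standard 6-tetrahedron decomposition of
each grid cube sharing the main diagonal, with vertices at midpoints of
sign-changing edges.  Adjacent cubes agree on shared faces, so the mesh
is watertight (the test suite checks every edge borders exactly two
triangles); every vertex is within half a voxel of the true boundary.

Closest-point queries prefilter triangles by centroid distance (bound:
nearest centroid distance + twice the largest triangle radius) before
the exact region-based point-triangle test.  The projected curve is
smoothed with a 7-point moving average (endpoints preserved) to
suppress the facet jitter a voxelized surface imprints on the
projections; the window spans under 2 mm of curve, far below any
anatomical curvature of interest, so CCL is unaffected beyond the voxel
scale.  A projection distance above 50 mm (configurable) triggers a
warning — in a correctly registered thorax the confluence sits within a
few mm of the atrium, so larger distances indicate a frame mismatch.

## Phantoms: what they emulate and what they do not

`makePhantom()` rasterizes analytic LA + confluence + vein geometries by
voxel-center thresholding, with ground truth taken from closed forms
only (never measured from the raster):

* **slab** — box LA, straight confluence at constant gap `d` from the
  face (truth: CCL = L, DBLC = d).  Because `d` is an integer number of
  voxels, face and tube axis share a lattice phase; the grid is aligned
  so both sit mid-phase (plane between voxel centers), and the tube is
  tilted within the face-parallel plane so its cross-sections sweep all
  lattice phases.  A straight tube locked at one phase can carry a
  cross-section bias of several percent; phase-sweeping reduces the
  volume bias below 1% without changing either truth value.
* **sphere_arc** — spherical LA, concentric equatorial arc at radius
  R + g (truth: CCL = R·θ after projection, DBLC = g, tube volume
  πr²(R+g)θ by Pappus).  The arc plane is aligned with a voxel-center
  plane; the default tube radius of 1.8 mm was chosen, under the
  constraint r < g, as the radius with adequate resolution (r ≥ 3.5
  voxels) and sub-percent lattice bias at 0.5 mm spacing.
* **ellipsoid_tree** — ellipsoidal LA; volume truth 4/3·π·abc; CCL and
  DBLC truths only in the equal-equatorial-axes case.

Vein stubs join the confluence ends per the type Ia layout (RUPV+RIPV
at one junction; LUPV, LIPV and the ascending VV at the other);
`vvSide = "right"` mirrors the roles.  Default test spacing is 0.5 mm
isotropic — the working CT resolution is not published, and 0.5 mm is a
typical value for pediatric cardiac CTA reconstructions.

The phantoms are tubes and boxes: they share with real anatomy the
features the metrics depend on (a tubular confluence near a large
chamber, junctions delimiting it, a measurable gap) but none of the
features that make real segmentations hard — trabeculation and the
atrial appendage, non-circular confluence cross-sections, wall contact,
segmentation noise, oblique acquisition.  Passing the phantom suite
therefore demonstrates that the geometric estimators are correct and
convergent on resolved tubular inputs, not that they are robust to
segmentation artefacts.

## Synthetic cohorts

`makeSyntheticCohort()` draws sphere-arc geometries from uniform
ranges — LA radius U(8.5, 12.5) mm, gap U(1.6, 2.5) mm, arc angle
U(0.9, 1.9) rad, BSA U(0.24, 0.34) m² — chosen once so that iTVLC spans
roughly 8–35 cm³/m² and the CCL/mDBLC ratio roughly 3–15, bracketing
the clinical thresholds (20 and 7.7) and the reported iTVLC median of
20 cm³/m².  No distributional description of real confluence shapes is
published; the uniform ranges are an explicit stand-in.  Event times
are exponential with hazard

    h_i = h0 · exp(β_iTVLC · iTVLC_i + β_ratio · ratio_i),    h0 = 0.6/month

so the generative coefficients are exact recovery targets.  Censoring
is independent uniform on (0, c_max) with c_max solved numerically so
the expected censored fraction equals `censorRate`; times are rounded
to 0.1 month, which produces the tied event times that month-scale
follow-up data show (and which Breslow tie handling is chosen for).
`prepvo` is drawn with probability decreasing in iTVLC — mirroring the
reported association between obstruction and smaller iTVLC — but has no
direct hazard effect, so adjusted and unadjusted fits share the same
estimand.  One caveat is deliberate: with a tube model, the confluence
volume compatible with a 1.5–2.5 mm gap is smaller than clinical iPVC
medians; the LA radius range compensates so that iTVLC (the marker the
simulations exercise) is on the clinical scale.

## Survival machinery: numerical choices

* **Cox fits** use the Breslow tie approximation (`survival::coxph`),
  which keeps the brute-force partial-likelihood oracle in the test
  suite a three-line formula.  Wald intervals; convergence failure
  within 100 iterations is an error reporting the final score norm.
* **Schoenfeld check**: scaled Schoenfeld residuals are correlated with
  the rank of the event times (the reported `rho`); the p-value is the
  rank-transform score test (`survival::cox.zph`).  Its size is
  verified by simulation in the acceptance suite.
* **Time-dependent ROC**: the cumulative-case/dynamic-control estimator
  with inverse-probability-of-censoring weights from the Kaplan–Meier
  estimate of the censoring distribution (left limits at case times).
  The published analysis names the method only by citation; this
  estimator is pinned by an exact property — with no censoring it
  equals pair counting of the binary outcome "event by the horizon" —
  and is rank-based, hence invariant under monotone marker transforms.
  Confidence intervals are a seeded percentile bootstrap (default 500
  resamples).
* **Spline hazard curves**: natural cubic spline of the marker with 4
  knots at the 5/35/65/95th percentiles, computed with
  linear-interpolation quantiles (R type 7) — knot placement depends on
  the quantile convention, so it is stated.  The curve is anchored at
  HR = 1 at the cohort median (the anchor used in the source analysis
  is not stated; the median is the conventional choice), with
  delta-method pointwise bands.
* **Backward selection**: univariable screen at p < 0.05, then repeated
  multivariable fits dropping the largest-p covariate until all remain
  below 0.05 — the mechanical reading of the described procedure.
* **No competing-risk analysis**, deliberately: in the motivating
  cohort all deaths occurred secondary to the event of interest.

## Degenerate inputs

Empty or disconnected venous labels, a vein that never touches the main
channel, coincident junction planes, a zero-length projection, a
constant covariate or marker, fewer than 2 (Cox) / 3 (Schoenfeld) / 5
(spline) events, negative times, and a censoring rate outside [0, 1)
are all rejected with errors naming the offending role, row or
quantity.  Oblique volume orientations are rejected at read time: the
world-coordinate contract is axis-aligned, and resampling belongs
upstream of this package.

## Problem sizes in the test and acceptance suites

The suites are sized to run comfortably on one CPU: two 0.5 mm
acceptance phantoms (about 1–2 s each to quantify), a doubled-scale
slab for the scale-equivariance check, 100 cohorts of n = 400 for Cox
recovery, 200 replicates of n = 150 for the Schoenfeld size, and 100
replicates of n = 500 for the null AUC.  These sizes give Monte-Carlo
standard errors well inside the asserted tolerances (the mean of 100
cohort estimates has standard error ≈ 0.001 on a coefficient of 0.15).

## Known limitations

* CCL is chordal-on-mesh, not geodesic; both agree on the phantoms and
  differ only at the sampling scale, but the choice is a convention.
* The type Ib demarcation rule is a mirrored convention, not a
  published definition.
* Closest-point projection can fold on strongly concave atrial
  surfaces (two centerline points mapping to the same surface point);
  the phantoms do not exercise this, and the projected-curve arc length
  would then undercount.  A warning-level diagnostic (projection
  distance bound) is the only guard.
* Voxel-center rasterization and voxel-count volumetry carry
  lattice-phase bias for thin structures; the phantom defaults are
  chosen to keep it below the tolerances, but under-resolved tubes
  (radius < 2 voxels) warn, and in strict mode error.
* The synthetic cohorts are geometric stand-ins; they validate the
  statistical machinery, not clinical effect sizes.
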