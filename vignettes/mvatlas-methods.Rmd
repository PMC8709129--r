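---
title: "Building synthetic mitral-valve atlases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building synthetic mitral-valve atlases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvatlas)
```

## The problem

Percutaneous edge-to-edge mitral repair (MitraClip) fastens the anterior and
posterior leaflet edges at a chosen station on the coaptation line. Studying
how placement affects the residual orifice across anatomies requires many
patient-like valve geometries in a common mesh topology — far more than any
single echo series provides. `mvatlas` generates such atlases from three
sources: an emulated multi-view key-point digitization pipeline, a
literature-percentile enumeration, and a PCA point-distribution shape model;
it then enumerates clip scenarios on every geometry and evaluates a
fiber-reinforced hyperelastic law for the leaflet tissue at material points.
Everything downstream of geometry (fluid–structure simulation, regurgitant
volumes, leaflet stress maps) is deliberately out of scope: those require a
full finite-element solver, and this package only prepares its inputs and
computes geometric surrogates.

## The parametric template

Six scalars parameterize a valve: the anterior leaflet depth `aml`, the three
posterior scallop depths `p1, p2, p3` (lateral, middle, medial), and the
aorto-mural and intercommissural annular diameters `d_am`, `d_ic`, all in
millimetres. The template places a **planar elliptical annulus** in z = 0
(intercommissural axis = x, aorto-mural = y, origin at the annulus centroid)
and extends each leaflet from the annulus toward the centerline along
straight columns dipping below the annulus plane (default dip 60°). The
posterior half is split into three equal annular arcs for P1/P2/P3; the
region depth profile interpolates linearly in arc angle between the four
region mid-columns, where it equals the prescribed depths exactly.

Because each measured column is a straight segment, the surface geodesic
from an annulus station to its free-edge tip *equals* the prescribed depth,
and since the graph geodesic between two vertices is bounded below by their
Euclidean distance, no mesh path can undercut it: `measure_parameters()`
(igraph shortest paths over the mesh edges) inverts `build_template()` to
machine precision at any resolution. A saddle-shaped annulus and leaflet
thickness are deliberately omitted; the planar-annulus convention is what
makes every atlas scalar directly realizable and measurable. Depth
measurement is geodesic by default with a chordal (straight base-to-tip)
mode; the two coincide on the straight-column template, and the chordal mode
is what a six-key-point reconstruction can observe.

Chordae tendineae are line (truss) elements from free-edge vertices to two
papillary anchor points 25 mm below the annulus plane; several chords may
share an attachment vertex, mimicking branching. The chord count is
configurable (default 4,971) and `prune_chordae()` removes a seeded random
subset — weakening tethering is how template-derived geometries are made
regurgitant — with the removal set a pure function of the seed.

## RBF morphing

All geometry creation is landmark-driven thin-plate-spline morphing
(`fit_rbf()`, kernel `φ(r) = r³` with a full affine term and the standard
side constraints; Gaussian and multiquadric kernels are available with a
shape parameter). With zero regularization the deformation interpolates the
control points to ~1e-12 mm; positive regularization is available for noisy
hand-digitized landmarks.

Two numerical points found while validating deserve note. First, six
landmarks under-constrain a 3-D TPS, so `morph_to_parameters()` uses the
named landmarks **plus** an 8-point annulus anchor ring and three interior
anchors along each region's measured column; without the column anchors the
morphed columns bow and the geodesic depth overshoots by up to ~0.14 mm,
with them the worst-case discrepancy over the default literature plan is
below 0.02 mm (the 0.1 mm manifest threshold follows from this). The anchor
stations are recorded in the deformation metadata. Second, for the cubic
kernel in 3-D the far-field deformation does *not* converge to its affine
part: the side constraints cancel the r³ and r² terms of the radial sum but
an O(r) term survives. The test suite asserts the true behavior (sub-
quadratic growth for TPS; exact affine far field for the decaying Gaussian
kernel).

## The emulated digitization pipeline

The patient pathway is emulated end to end so it can be tested without
images. Three mutually orthogonal view planes through the annulus centroid
(chosen because the geometry of the original multi-view acquisitions is not
part of the package's inputs, and orthogonality maximizes triangulation
conditioning) project six key points — `AM_ANT`, `AM_POST`, `COMM_A`,
`COMM_P`, `ANT_TIP`, `P2_TIP` — to pixel coordinates at 0.5 mm/px with
isotropic Gaussian click noise (default 1 px), the simplest defensible model
of manual digitization. `reconstruct_landmarks()` stacks the two in-plane
constraints per view and solves least squares; with zero noise and three
orthogonal views recovery is exact, and with 1 px noise the 3-D RMSE is
`sqrt(3·spacing²/2) ≈ 0.61 mm` because each world coordinate appears in
exactly two of the three views (the suite checks this against a Monte-Carlo
run).

Cohort truth is drawn from a normal distribution truncated at the parameter
admissibility bounds, centred on the template anatomy with a default 1.5 mm
per-parameter spread — a plausible single-center spread; no patient
distribution is shipped with the package, and the generator's defaults are
the declared study conditions. One identifiability limit is inherent to six
key points: the P1/P3 scallop depths have no observed base/tip pair, so the
reconstruction scales them from the recovered P2 depth by the base valve's
ratios. Consequently recovery error on P1/P3 has a floor set by anatomy
variation, not by click noise — the tests separate the two groups.

## Literature enumeration

Published morphometry enters as per-parameter normal distributions evaluated
at the 5th/50th/95th percentiles (`normal_percentiles()`, exact `qnorm`).
The default plan enumerates (a) the full 3⁴ = 81 factorial of the four
leaflet depths with diameters fixed at their first levels and (b) the 5 × 5
diameter grid with leaflet depths fixed at their 5th-percentile values,
106 sets in total. One combination (all depths at the 5th percentile,
diameters at the first levels) occurs in both arms; the default
`dedupe = "portion"` counts the arms separately, as enumeration studies
typically tally their sub-designs, while `dedupe = "all"` collapses the
coincidence to 105 unique sets. Each set is morphed and re-measured; the
manifest keeps requested values, measured values and the residual.

## The shape model

`fit_shape_model()` is a standard point-distribution model: shape vectors
(by default the 18 concatenated key-point coordinates; full-vertex mode
available) are averaged, the centered matrix is SVD-decomposed, and the
sample covariance spectrum uses the n − 1 denominator. Reconstruction is
`X = X̄ + Σ α_m √λ_m W_m`; `encode_shape()` is the orthogonal projection
`α_m = W_mᵀ(X − X̄)/√λ_m`. Eigenvector signs are fixed (largest-magnitude
entry positive) so fits are bit-reproducible. Virtual valves are sampled
with α i.i.d. standard normal truncated at ±3 — a conventional plausibility
box, recorded in output metadata since no sampling law is inherited from
data.

`simulate_shape_cohort()` is the ground-truth generator used for
validation: 180 vectors from a 3-mode orthogonal linear model (mode standard
deviations 8, 4, 2 mm — dominant annular size, conformation and a minor
mode) plus isotropic noise at 5% of the per-coordinate signal standard
deviation. Under these conditions three components explain ≈ 99.8% of the
variance and the fitted subspace aligns with the generating one to well
under 5°. The generator emulates linear low-rank anatomy variation only; it
has no nonlinear mode coupling, no landmark correspondence error and no
outliers, so passing tests certify the fitting machinery, not PCA's adequacy
for any particular clinical cohort.

## Clip scenarios and orifice metrics

A clip is a single node-pair tie: the anterior- and posterior-chain
free-edge vertices nearest to the chosen coaptation fraction s are moved to
their common midpoint and recorded as a tied pair — the pure-geometry
abstraction of tying leaflet edge nodes, with no device width and no
deformation under load. The default six stations are s = 0.20, 0.70, 0.35,
0.50, 0.62, 0.80 (stations 2 and 6 adjacent in the posterior-commissure
half); they are config values, not anatomical constants. Ties are
station-indexed, which makes re-application idempotent.

`orifice_area()` splits the free-edge loop at the tied pairs — k ties on one
loop give k + 1 openings — projects each sub-loop onto the best-fit annulus
plane and applies the shoelace formula with normalized orientation. A
self-intersecting projection (possible for deep leaflets on small annuli,
where the template's funnel crosses itself) is reported as the largest
simple sub-polygon and flagged. `scenario_sweep()` reports per-scenario
areas and reductions relative to the untreated valve; on these convex-ish
loops moving boundary vertices to an interior midpoint cannot grow the area,
so reductions are monotone in nested clip sets — the geometric surrogate the
suite asserts in place of solver-derived regurgitation numbers, which are
not reproducible at desk scale.

## The constitutive law

Leaflet tissue is the exponential fiber-reinforced hyperelastic model with
deviatoric part

Ψ_dev = a/(2b)·e^{b(Ī₁−3)} + Σ_{i∈{f,t}} a_i/(2b_i)·(e^{b_i(Ī₄ᵢ−1)²} − 1)
+ a_ft/(2b_ft)·(e^{b_ft Ī₈ft²} − 1)

and volumetric part Ψ_vol = (1/D)·((J²−1)/2 − ln J). Invariants are
evaluated on the isochoric tensor C̄ = J^(−2/3)C by default: the
deviatoric/volumetric naming only produces a stress-free reference
configuration under that split, which is also how solver material libraries
implement this family; a `split = "none"` flag evaluates plain C for
comparison (its reference state carries the isotropic term's stress). The
fiber terms use (I₄−1)² symmetrically — active in extension and compression
exactly as written; a tension-only switch is a known variant this package
does not apply by default. `D` is interpreted as 2/K (K the bulk modulus)
so 1/D carries stress units; the alternative reading D = 2K would make
Ψ_vol dimensionally inconsistent with Ψ_dev. A single trans-fiber direction
t0 orthogonal to f0 is assumed throughout.

The analytic Cauchy stress σ = (2/J)·dev[F̄(∂Ψ_dev/∂C̄)F̄ᵀ] + (1/D)(J−1/J)I
is verified everywhere against central finite differences of the energy with
respect to C (step 1e-6, relative tolerance 1e-5), and objectivity
Ψ(QF) = Ψ(F) against random rotations at 1e-10. No published constants for
this tissue parameterization are bundled; `demo_material()` is a clearly
labelled synthetic set in the range of exponential-model leaflet fits, for
demonstrations and verification sweeps only. Exponential overflow (exponent
arguments above 700) raises an error naming the offending term rather than
returning `Inf`.

## Numerical choices and degenerate inputs

* Duplicate RBF control points (distance < 1e-9 mm) are rejected by name
  before factorization; unsupported kernels list the supported set.
* Landmarks observed in fewer than two views, or in mutually parallel
  views, abort reconstruction naming the landmark.
* `J ≤ 0` (inverted state) is rejected in all constitutive entry points.
* Cross-portion enumeration duplicates are compared after rounding to
  1e-6 mm.
* All stochastic operations (cohort draws, chord pruning, click noise, PCA
  sampling) run under a locally scoped RNG: they are pure functions of
  their seed and never disturb the caller's RNG state.

## Problem sizes

The bundled defaults mirror the study scale: 29 digitized patients, 106
literature geometries, 20 PCA-sampled valves, 7 scenarios per geometry.
Tests exercise templates at resolution 4–8 (≈ 160–580 vertices), Monte-Carlo
checks at 1,000–10,000 draws, and the full 155-geometry atlas build runs in
well under a minute at resolution 4; resolution mainly affects mesh density,
not the landmark measurements, which are resolution-independent by
construction.

## Known limitations

* Planar annulus, uniform leaflet depth interpolation between region
  mid-columns, and straight chordae are simplifications; no claim is made
  that the template reproduces any specific anatomical mesh.
* Orifice areas are anatomic (projected geometric) areas on the *open*
  configuration — not effective orifice areas under flow, and not
  post-closure areas.
* The six-key-point pipeline cannot identify P1/P3 depths independently
  (see above).
* The PCA model is linear; strongly nonlinear anatomy variation would need
  more components or a nonlinear embedding, neither of which is provided.
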