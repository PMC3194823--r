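---
title: "Measuring territory size from intrusion experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring territory size from intrusion experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(territr)
```

## The problem

A territory — an area of intense, often exclusive use that an animal
announces and defends — is narrower than a home range, and mapping it
purely by observation is biased by the observer's chance of catching
peripheral interactions. Intrusion experiments measure the defended area
*actively*: a conspecific cue (for example, playback of an advertisement
call) is presented to the focal animal from a chosen compass direction, and
the animal's phonotactic approach is followed until it stops, which marks
the boundary of the area it is willing to defend in that direction. Twelve
trials at every 30° "span up" the territory with a tolerable amount of
disturbance.

The resulting point pattern is unusual: a tight clump of initial (calling)
positions in the centre and a ring of final (approach) positions along the
boundary, with almost nothing in between. `territr` implements the
estimators suited to such bimodal patterns, a simulation framework for
benchmarking them against territories of known area, and the
stretch-the-centre (STC) estimator that reshapes a central kernel onto the
trial endpoints.

## Virtual territories and simulated trials

A virtual territory is a nested pair of polygons: an outer defended region
normalised to a known true area, and a central area (display and resting
sites) obtained by shrinking the outer outline by a linear factor about its
centroid.

```{r}
tr <- make_virtual_territory("circle")   # true area 200.04
glance(tr)
```

Six built-in outlines span strictly convex (circle, ellipse, triangle) to
highly concave (star, angle, irregular) shapes, with benchmark true areas
of 200.04, 243.58, 88, 130.09, 155.63 and 395.11 arbitrary units. The
concave outlines are this package's own constructions — a 5-point star with
inner/outer radius ratio 0.5, an L-shape, and a fixed 12-vertex concave
polygon — chosen to reproduce the *shape classes*, not any particular
geometry. The L-shape uses an arm width of one half the arm length: with
thinner arms the polygon's centroid falls outside the polygon, and the
centroid is the origin for the equiangular edge-point construction below.
The central area defaults to a 0.3 linear scale of the outer region (no
canonical value exists; it is configurable), giving a central area 9% of
the outer one — the same order as the ratio between calling and defended
areas seen in territorial frogs.

A full simulated trial set places 360 uniform random points in the central
area (rejection sampling), 360 edge points at 1° bearing intervals about
the central centroid (bearings are geographic: 0° = north, clockwise;
concave boundaries use the outermost ray crossing, because trial endpoints
lie along the outer edge), and pairs them by a uniform random bijection:

```{r}
trials <- simulate_trials(tr, 360, seed = 1)
trials
```

Equiangular subsets of a trial set represent field designs with fewer
trials: for every trial count k dividing 360 there are 360/k distinct
subsets (one per angular offset), and over the divisor list 2…360 there
are exactly 810.

## Area estimators

* **MCP** (`mcp()`): the minimum convex polygon.
* **Detailed hull** (`detailed_hull()`): a characteristic (concave) hull.
  Starting from the Delaunay triangulation of the points, the longest
  exterior boundary edge longer than a threshold λ is peeled off
  iteratively, under a regularity guard (the apex of the peeled triangle
  must not already lie on the boundary, which keeps the boundary a simple
  polygon containing every point). `lambda = "auto"` sets λ to the mean
  plus one standard deviation of all Delaunay edge lengths; `lambda = Inf`
  reproduces the MCP exactly. This open, deterministic construction stands
  in for proprietary detailed-hull tools; it shares their defining
  property of collapsing to the convex hull on dense convex patterns while
  following concave outlines tightly. Ties between equally long edges are
  broken by the lexicographically smaller edge midpoint.
* **Kernel UDs** (`kde_density()`, `kde_isopleth()`): fixed and adaptive
  bivariate normal kernels. The reference bandwidth is the normal-reference
  rule h = sqrt((s_x² + s_y²)/2)·n^(−1/6); GIS plug-ins are known to
  disagree on this constant, so the package fixes the form explicitly and
  records it with every fit. LSCV minimises the least-squares
  cross-validation score, evaluated in closed form over pairwise distances,
  with a coarse log-grid scan plus golden-section refinement over
  [href/20, 2·href]; a minimiser on the search boundary is returned with
  `converged = FALSE` rather than an error, because that failure mode *is*
  the scientifically relevant behaviour on clumped intrusion patterns.
  Densities live on a 256×256 grid padded by 3.5 bandwidths and expanded
  automatically until at least 99% of the probability mass is captured;
  isopleths take the smallest density level set holding p% of the total
  mass (cells sorted by density, threshold contoured by marching squares
  with sub-cell linear interpolation, via `grDevices::contourLines`).
* **k-LoCoH** (`k_locoh()`): the union of each point's convex hull with its
  k−1 nearest neighbours, hulls sorted by ascending area; the p% isopleth
  is the union of the smallest hulls needed to cover p% of the points.
  Distance ties are broken by point index. Because the area ordering is
  only defined up to ties, the isopleth construction includes the *whole*
  group of numerically equal-area hulls whenever the coverage threshold
  falls inside one — equiangular boundary points produce exact ties, and
  without this rule the isopleth would depend on an arbitrary tie order
  (on the circle benchmark it would be a band cut open at a random
  position).

### Automated MSHC

The minimum-spurious-hole-covering rule selects the tuning parameter k as
the smallest value whose 100% isopleth carries no unjustified holes or
cutaways. `mshc_select_k()` automates this as a topological criterion: the
smallest k whose 100% isopleth has **no interior holes and a single
connected component**. Hole-freeness alone is not sufficient — at very
small k the union degenerates into many disconnected, individually
hole-free crumbs, which no analyst would accept; a fragmented union is the
extreme cutaway. Genuinely justified holes (say, a pond inside a
territory) are a judgement call the automation deliberately does not make:
it treats all holes as spurious, and the scan table it returns
(`$scanned`) lets the analyst override.

## The stretch-the-centre estimator

`stc_estimate()` fits a fixed kernel at the reference bandwidth to the
calling positions only — a bounded, roughly unimodal pattern on which such
kernels behave well — and then reshapes all of its isoclines to the
defended boundary with a piecewise-linear rubbersheet adjustment:

* one **correction link** per trial, from the intersection of the trial ray
  with the 99% isocline to the trial endpoint; for a non-responding trial
  the target is the calling position itself, pulling the boundary inwards
  along directions where the animal claimed no territory;
* one **identity link** (zero displacement) at every calling position.

A Delaunay TIN over the link sources interpolates the displacement field
barycentrically; every link source maps exactly onto its target (the link
sources are inserted as isocline vertices first, so the transformed 99%
isocline passes through every endpoint, not merely near it). For points
outside the TIN the field is evaluated at the nearest point of the
triangulation, interpolated linearly along the nearest edge. An affine
extension of the nearest triangle was considered and rejected: isocline
arcs bulge slightly outside the hull of link sources, and the affine
extension of a thin boundary triangle can amplify the displacement
severalfold there, throwing artefact lobes far outside the links. The
nearest-point rule is continuous, honours the links exactly, and is
bounded by the node displacements.

The transformation is applied to the isocline *polylines*, never to the
density raster — warping the raster is known to produce severe artefacts.
Piecewise-linear maps with strong non-uniform stretch can still fold:
transformed rings are checked for self-intersection (repaired by dropping
the smaller lobe, with a warning) and for nesting violations, which are
detected and reported (`$nesting_ok`, `$nesting_report`), not silently
accepted. Strong inward pulls from non-responses are the usual cause — a
real sensitivity of the method, not a numerical accident.

## Benchmarking machinery

`accumulation_table()` evaluates an estimator over every equiangular subset
at each trial count and summarises mean and SD; polygon estimators are
evaluated at their full extension, parametric kernels at the 95% isocline.
`rank_stability()` finds the smallest trial count from which the ordering
of units never changes again; `stepwise_change()` reports per-step
percentage changes and the last step above a threshold (default 2%);
`isopleth_coverage_stats()` gives the smallest isopleth level whose area
reaches a reference polygon and the smallest level that fully contains it
(containment is checked on a densified reference boundary, 200 probe
points by default).

On the six-territory benchmark with one logged seed, the detailed hull
reaches a stable shape ranking by twelve trials and changes by at most 2%
per step from twenty trials upward on the circle, while LSCV-selected
kernels fluctuate erratically with sample size — the pattern that motivates
using twelve equiangular trials with a detailed hull in the field.

## Numerical choices

* **Geometry** is planar Cartesian throughout (unitless in simulation,
  metres in the field); no geodesy.
* **Delaunay triangulation** (shared by the detailed hull and the
  rubbersheet TIN) is a Bowyer–Watson construction with all orientation and
  in-circle decisions taken as long-double determinants on coordinates
  normalised to the unit box. Field layouts are adversarial here: straight
  territory sides put hundreds of points exactly on a line and equiangular
  rings are nearly cocircular, so a deterministic jitter of about 10⁻⁶ of
  the data span enforces general position. The jitter affects the
  *topology* only — all downstream computations (edge lengths, hull rings,
  barycentric interpolation) use the original coordinates — and is far
  below every tolerance used in the package.
* **Unions of convex hulls** (LoCoH) are built from boundary fragments:
  every hull edge is clipped against the strict interiors of the other
  hulls, surviving fragments whose right-hand side is exterior to all hulls
  form the directed union boundary, and Green's theorem gives the exact
  area. Collinear shared edges (systematic when endpoints lie on straight
  territory sides) are deduplicated by hull priority; facing collinear
  edges are removed as interior. Rings are stitched gap-tolerantly
  (junctions computed from different hull pairs can differ by ~10⁻⁸),
  outer rings counter-clockwise and holes clockwise, which yields the hole
  and component counts that MSHC consumes. Slivers below 10⁻¹² of the
  squared extent are dropped.
* **Tolerances**: ray–boundary intersections are exact to 10⁻⁹ of a unit;
  STC link exactness is verified to 10⁻⁶; kernel isopleth areas are
  grid-limited (≈1% at the default grid).
* **Degenerate inputs**: fewer than three points or all-collinear input is
  a `territr_degenerate_input` error; zero-variance inputs fail the
  bandwidth rules explicitly; duplicate points are removed before hull
  construction; LSCV returns its boundary value with a flag instead of
  crashing.

## Problem sizes

The simulation study runs at its natural scale everywhere: 360 trials per
territory, all 810 equiangular subsets enumerated exhaustively (they are
cheap), six territories for the rank-order benchmark, and a 15-individual
synthetic cohort for the STC–LoCoH comparison. The MSHC scan on a
720-point pattern examines each k from 3 upward; on the circle benchmark
the first clean k is near 150, which is the single most expensive
computation in the package (about a minute).

## What the generator does and does not emulate

The synthetic cohort (`generate_fixture_individuals()`) reproduces the
*geometry* of a field campaign: non-overlapping territories in an arena,
twelve 30°-trials per individual scheduled semi-randomly
(`schedule_directions()`), calling positions confined to the central area,
endpoints on the outer boundary along the trial bearing, and occasional
non-responses (default probability 0.04, the order observed in field
campaigns of this design). It deliberately models no behaviour: no
movement paths, no detection error in mapping, no temporal drift of
territory boundaries, no directional bias in responsiveness. Passing tests
therefore demonstrate that the estimators recover known geometry from
ideal intrusion endpoints — not that any particular field dataset is free
of mapping error or behavioural complications.

## Known limitations

* The detailed hull is a characteristic-hull construction with an explicit
  λ; it is not bit-compatible with any proprietary implementation.
* Automated MSHC treats every hole and every disconnection as spurious;
  biologically justified exceptions need the analyst.
* The rubbersheet is piecewise linear; its behaviour between links is a
  modelling choice (TIN interpolation with nearest-point extension), and
  severe non-response pulls can fold isoclines — reported, not repaired
  away.
* Fixed-distance intrusion setups (intensity is varied at a fixed speaker
  position) are representable in `trial_plan()` but yield no reaction
  horizon without a calibration that must come from outside the package.
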