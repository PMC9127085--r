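---
title: "Modelling street-environment effects on pedestrian route choice"
author: "routewalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling street-environment effects on pedestrian route choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routewalk)
```

## The problem

When a pedestrian walks from home to a first destination, the route they
take is a choice among many feasible paths on the street network. If the
chosen route coincides with an "obvious" alternative — the shortest-distance
path, or the path with the least directional change — the street environment
tells us little: distance or legibility alone can explain the choice. It is
when the chosen route *deviates* from these alternatives that the
micro-level street environment (sidewalk quality, greenery, street walls,
shops, bins, benches) becomes informative about preference. routewalk
implements that analysis end to end:

1. generate the two labeled alternatives for every origin–destination (OD)
   pair;
2. measure how much each chosen route overlaps each alternative, and drop
   trips with 100% overlap (those choices are explained by distance or
   direction alone);
3. aggregate per-edge street-environment attributes to the route level;
4. estimate conditional logit (CL) models contrasting chosen and
   alternative routes — once for entire routes (habitual, planned-before-
   departure behaviour) and once for the deviated part-routes (en-route
   adjustment at decision points).

## Labeled alternatives

Choice-set generation uses the *labeling method*: one route per criterion
label rather than an enumeration of many paths. This matches short
utilitarian walking trips, where plausible alternatives are few.

**Shortest-distance route.** Minimises total length over the network.

**Least-directional-change route.** Minimises the summed angular deviation
over consecutive edges. The network is first converted to its *angular
segment graph* (the space-syntax dual): each street edge becomes a segment
node; each pair of edges meeting at an intersection becomes a link weighted
by the turn angle between them. We use the θ/90 weighting with θ ∈ [0°,
180°] measured against straight-ahead continuation: going straight costs 0,
a right angle costs 1, a full reversal costs 2. Any positive monotone
transform of θ yields the same minimising paths, so this convention is a
normalisation, not a substantive assumption. Bearings at an intersection are
taken from the polyline chords incident to that intersection, so gently
curved streets behave like their local tangents.

`angular_step_depth()` exposes the classical angular step-depth map
(cheapest cumulative angular cost from all segments incident to an origin,
computed on the segment graph), which is the quantity segment-analysis
software tabulates per origin.

### Why routes are not extracted by backtracking the depth map

The segment-level depth map treats each street segment as a single node, so
a cheapest "path" on it may enter and leave a segment at the *same*
intersection — a turn sequence no walker can execute. On jittered grids
such phantom continuations can even be strictly cheaper than every real
path. Route construction therefore runs a direction-aware search over
*arcs* (directed edge traversals): the state records which way the walker
is travelling, immediate reversal onto the same edge is not a transition,
and every returned route is a traversable, edge-simple path. On networks
small enough to enumerate, both labeled routes provably coincide with
exhaustive minimisation over all edge-simple paths (this is tested).

### Determinism and tie-breaking

Optimal routes are often non-unique, especially on regular grids. Among
equal-primary-cost paths the search prefers (1) the lower secondary cost —
total turn cost for the distance route, total length for the angular
route — then (2) the lexicographically smallest edge-id sequence. All cost
comparisons use a relative tolerance of 1e-9 so that floating-point
summation order cannot flip a tie. This makes every routing result
reproducible bit-for-bit.

## Overlap decomposition

For a chosen route C and an alternative A (same OD pair), the overlap ratio
is

> overlap(C, A) = length(edges of C shared with A) / length(C),

a chosen-route-centric definition (a symmetric variant is available via
`denominator = "symmetric"`). Sharing means identical edge ids — both
routes live on one network, so no geometric buffering is involved — and
*full overlap* is exact edge-set equality.

Trips that fully overlap an alternative are excluded from the model against
that alternative: their choice is already explained by distance or
direction. The remaining chosen routes are decomposed into maximal
sub-paths absent from the alternative (*deviated part-routes*), each
bounded by a divergence and a reconvergence node that both lie on the
alternative; the alternative's sub-path between those nodes is the
contrasting part-route. Shared edges plus deviated edges exactly partition
the chosen route, which is asserted property-style over thousands of
simulated trips. A deviation that loops back to a single node of the
alternative has no alternative-side counterpart; such trips are dropped
from the part-route model input (they cannot arise from labeled
alternatives, which never contain loops, but user-supplied GPS routes could
produce them).

For modelling, all deviated chosen edges of one trip are aggregated into a
single part-route observation (and likewise the alternative's sub-paths):
the models are per-pedestrian, not per-deviation-loop.

## Street-environment aggregation

Fifteen per-edge attributes in four functional categories (roadway
features, streetscape, pedestrian infrastructure, facilities) follow a
walkability-audit measurement scheme: continuous widths (m), a D/H
enclosure ratio, ordinal condition codes (on-street parking 1–3, sidewalk
walkability 1–3, green spaces 1–3, street walls 0–2), raw counts (signals,
garbage bins, streetlights, benches) and street-front facility proportions
in [0, 1]. Route-level values are

* **length-weighted means** for widths, D/H, ordinal codes and proportions:
  Σ(value × edge length)/Σ(edge length). Treating ordinal codes as interval
  quantities is a deliberate, flagged simplification — it mirrors how
  audit-based condition scores are aggregated in practice;
* **sums** for counts, since the audit records raw numbers per edge. An
  opt-in `counts_per_100m` flag normalises counts by route length for users
  who prefer densities.

## The conditional logit model

Each pedestrian n faces a choice set of routes j with attribute vectors
x_nj; utility is U_nj = β'x_nj + ε_nj with i.i.d. Gumbel(0, 1) errors, so

> P(n chooses i) = exp(β'x_ni) / Σ_j exp(β'x_nj).

Only within-set attribute differences matter (an attribute constant across
a pedestrian's alternatives contributes nothing; this invariance is
tested). The log-likelihood is globally concave; `fit_clogit()` maximises
it by Newton iteration with the analytic score and observed information,
starting from β = 0, with step halving. Convergence is declared when the
score max-norm drops below 1e-8 or the relative log-likelihood change below
1e-12. Standard errors are square roots of the diagonal of the inverse
observed information at the optimum; z = β/SE with two-sided normal
p-values.

Degenerate inputs are reported, not silently absorbed: attributes that
never vary within any choice set are refused by name; a likelihood drifting
to its supremum (|β| beyond 30 on these natural attribute scales, or every
chosen alternative perfectly predicted) raises an explicit separation
error; hitting the iteration cap flags the fit as unconverged, and
`model_table()` refuses to tabulate unconverged fits.

The engine is validated three independent ways: against a closed-form
binary-logit identity, against a one-dimensional brute-force search of the
likelihood, and against the matched conditional-logistic implementation in
the survival package.

`run_pipeline()` fits four models independently — {entire route, deviated
part-route} × {shortest, least angular} — mirroring the standard
presentation of this analysis rather than one joint three-alternative
model, which would require overlap corrections (e.g. path-size terms) that
are out of scope here. `attribute_presets()` ships the four attribute
subsets used in that presentation; no automatic attribute selection is
performed. With many attributes and few deviating trips, separation is
common and the pipeline records the refusal note per model instead of
failing.

## What the synthetic generator emulates

`synthetic_config()` defaults encode the study conditions the package
targets:

| parameter | default | meaning |
|---|---|---|
| `rows × cols` | 8 × 8 | residential-scale grid of intersections |
| `block_length_mean` | 100 m | old-town block size |
| `block_length_cv` | 0.15 | lognormal variation of block lengths |
| `jitter_sd` | 5 m | node jitter: streets not perfectly straight |
| `n_od` | 219 | cohort size (one trip per pedestrian) |
| `trip_length_target` | 350 m | short utilitarian walks; sampled trips lie in [0.5, 2]× this |
| `beta_true` | green_spaces 1.0, sidewalk_width −0.5 | generating utility |

Attributes are drawn independently per edge: lognormal widths (median 2 m
sidewalks, 7 m driveways, D/H around 1), categorical ordinal codes, Poisson
counts with per-meter rates (so longer blocks carry more bins and lights),
Beta-distributed facility proportions. OD pairs are sampled with a Gaussian
kernel around the target length so the mean trip length tracks the target.
Choices maximise β'x + Gumbel(0, 1) noise; Gumbel(0, 1) fixes the utility
scale on which `beta_true` is read. All randomness flows through one master
seed, with deterministic child streams per stage (network, OD sampling,
choice noise), so a seed fully determines a cohort.

In *pairwise* mode the choice set is exactly the two labeled routes, so the
estimation choice set equals the generation choice set and coefficient
recovery is a clean test of the whole pipeline (generation → routing →
aggregation → estimation). In *choice-set* mode random simple-path detours
are added at generation but not at estimation, which deliberately
demonstrates — without correcting — the misspecification incurred when the
true choice set is larger than the analyst's.

What the generator does **not** emulate: GPS measurement error and
map-matching artefacts; spatial correlation of attributes along fronts or
corridors (attributes are i.i.d. across edges); one-way streets or
multigraphs; heterogeneous pedestrians (a single β generates all trips);
destination choice (ODs are exogenous). Passing recovery tests therefore
shows the estimator and plumbing are correct under the stated model — not
that real audit data meet these assumptions.

Two modelling notes follow from the i.i.d.-attribute design. First, because
attributes are independent of network geometry, the attribute differences
between the two labeled routes are approximately symmetric about zero, so
the pipeline's conditional models (where, after the full-overlap exclusion,
the chosen route is by construction the non-alternative route) still centre
on the generating coefficients; with spatially structured attributes this
need not hold, and the package makes no such claim for real data. Second,
trips whose two labeled routes coincide carry no preference information and
are marked `coincident`, excluded from estimation.

## Problem sizes and numerical settings used in validation

The test-suite simulations use grids from 3×3 to 8×8, cohorts of 120–1000
trips, 200-replication coverage runs at 500 trips with the route-attribute
design held fixed across replications (fresh Gumbel noise each time), and
exhaustive path enumeration as the routing oracle on networks of up to 20
nodes — sizes at which enumeration is exact and fast while still exercising
non-trivial tie-breaking. The attribute-marginal calibration check uses a
~10,000-edge network. Tolerances: routing cost comparisons 1e-9 (relative);
length-vs-geometry validation 1e-6 (relative); node snapping on GeoJSON
import 1e-6 m; CL convergence as above; the scalar MLE is checked against a
brute-force search to 1e-6.

## Known limitations

* Origins and destinations live on intersections; trips starting mid-block
  are snapped upstream of this package.
* The angular route is unconstrained in length; no maximum-detour factor is
  imposed on the least-directional-change alternative.
* Conditional logit treats the two alternatives of a pair as uncorrelated;
  with heavily overlapping alternatives a path-size correction would be
  needed, and is deliberately not provided.
* Statistical inference on length differences between overlap groups is
  out of scope; `summarize_route_lengths()` reports means only.
* The part-route observation aggregates all of a trip's deviations; no
  per-deviation modelling or minimum-deviation-length filter is applied by
  default (a `min_part_length` option exists).
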