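---
title: "Judging transmembrane helix-bundle models against predicted contacts"
author: "tmbundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging transmembrane helix-bundle models against predicted contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbundle)
```

# Scope and model

`tmbundle` evaluates rough Cα-trace models of polytopic membrane
proteins against coevolution-predicted contacts.  It deliberately
ignores atomic detail: the working assumption is that any modern
construction method produces locally reasonable helices, so what must
be judged is the *fold* — which helices pack, in which orientation,
how compactly, and with which chirality.  The package therefore stops
at a scored, culled, fold-space-organised pool of models; synthesising
the pool into a single structure is a job for a modelling engine and
is out of scope, as is running any contact or topology predictor.

# Contact normalization

A raw reliability `p` is method-specific: some methods produce
near-uniform scores, others decay almost exponentially down the ranked
list.  Summing such scores across methods would let one method
dominate.  The rank transform

$$e = \exp(-r^2 \cdot 0.01 / L)$$

(`rankTransform()`; `r` = 1-based rank, `L` = protein length) maps
every method onto a common (0, 1] scale whose effective depth grows as
$\sqrt{L}$: exactly $10\sqrt{L}$ pairs sit at or above $e = e^{-1}$.
Ranks are 1-based so the transform stays strictly monotone; ties in
`p` break lexicographically by (i, j) for determinism.  A consensus
(`combineContactSets()`) sums `e` over the contributing sets (a
missing pair contributes 0), then re-ranks and re-transforms, so the
consensus lives on the same scale as its inputs.  Summation on the `e`
scale is the design choice here: the transform exists precisely to
equalise the methods, so the minimal faithful combination is a plain
sum — anything cleverer (rank aggregation, learned weights) would add
parameters the data cannot justify.

# Parsing helix packing from the map

Contacts between two aligned helices form stripes: along the diagonal
for parallel packing, orthogonal for antiparallel.  `orientationFit()`
fits both directions with **fixed slopes ±1** and a free intercept,
scoring a stripe as the e-weighted support
$\sum_k e_k \max(0, 1 - |d_k - c|/w)$ with half-width $w = 4$
residues.  Free-slope regression is ill-posed on the handful of
contacts a sparse block contains; fixed slopes make the
parallel/antiparallel discrimination well-defined, and the support
functional is piecewise linear in the intercept, so scanning its kinks
($c \in \{d_k, d_k \pm w\}$) finds the exact optimum.  A block needs at
least 3 supporting contacts to be assigned an orientation — two points
fit any line.  Equal strengths resolve to antiparallel, the dominant
geometry in membrane bundles.

Predicted TM segments rarely coincide with the packing stripes, since
helices often extend beyond the membrane.  `optimizeBoundaries()` lets
every segment start and end shift by up to `max_shift` (default 5)
residues and maximises the total winning strength over all segment
pairs, re-fitting each block under the candidate boundaries, subject
to segments staying ordered, disjoint and inside the chain.  Because a
non-adjacent block couples the boundary choices of two distant
segments, a dynamic programme whose state is only the previous
segment's boundaries is *not* exact for this objective.  The
implementation instead slides a window: the DP state carries the
boundary choices of the last `R` segments, with `R` the longest-range
pair that could ever attract enough contacts to score.  This is exact
whenever the window fits (always, for instances of a few helices with
small shifts — the regime the equality-versus-enumeration tests
cover).  When the implied state space would exceed `state_limit`, the
window is capped and the capped optimum polished by coordinate ascent;
the result is guarded never to fall below the unshifted segmentation.
Ties break by the smallest total absolute shift, then
lexicographically on the shift vector (encoded as one number while the
problem fits 52 bits, beyond which the lexicographic tie-break
degrades gracefully).

`packingGraph()` renders the parse as an igraph object (edges =
non-"none" blocks, labelled parallel/antiparallel, weighted by
strength) and `packingSummary()` as a one-line text cartoon such as
`"1-2 anti; 3-4 anti; 1-4 anti"`.

# Scoring models

`pseudoCentroids()` places a dummy atom 2 Å beyond each Cα along the
outward negative bisector of the adjacent virtual bonds — the
direction a Cβ points, away from the helix axis — because at Cα
resolution the two faces of a helix differ by only a few Å.  Terminal
residues copy their neighbour's offset so terminal contacts still
score; a locally straight chain leaves the centroid on the Cα.

A contact observed at centroid separation `d` scores

$$q(d) = \exp(-(d-5)^2/s^2)$$

maximal at the ideal 5 Å and with spread `s = 5` Å by default:
separations beyond 10 Å score under 0.37, beyond 15 Å essentially
zero, and `d = 0` is slightly penalised (also 0.37).  The symmetric
penalty below 5 Å is intentional — centroids closer than the native
minimum are as suspect as ones too far apart.  `scoreModel()` sums
`e · q(d)` over the top `n_top = 100` pairs at sequence separation
≥ 8 (two helical turns, so local contacts cannot dominate);
`e`, not the raw `p`, enters the product so that scores are comparable
across prediction methods.  Pairs touching residues missing from a
partial model contribute zero and are reported as a coverage
fraction.  Rankings are insensitive to doubling or halving `s` or
`n_top`, which the test suite asserts on fixtures.

# Bundle axis, compactness, chirality

Without an explicit membrane, compactness is judged about an average
bundle axis (`bundleAxis()`): each TM segment gets two 4-residue caps
(its two terminal residues plus the two beyond, sliding outward up to
10 positions when the prediction around the end is unreliable —
`assignCaps(extend = )`, an explicit parameter rather than an
auto-detected trigger), the cap midpoints give one axis sample per
helix, and samples are accumulated from the most widely separated pair
down as a running mean, flipping any sample that opposes the running
direction so antiparallel helices reinforce rather than cancel.  The
running mean with orientation flip is the minimal reading of
"accumulate, taking account of orientation", and it recovers the
generator's known axis to well under 5 degrees on ideal bundles.  The
RoG (`axialRog()`) is taken about the single infinite line through the
final mean point — one shared axis for all three weighting schemes,
which keeps the measure rotation-invariant and comparable across
schemes: `tm_only` (TM = 1), `tm_caps` (TM = 1, caps 0.5), `whole`
(TM = 2, caps 1, rest 0.5).  As operational guidance for typical
bundles, RoG > 15 Å almost always means a stray helix and RoG > 12 Å
deserves inspection (`flagCompactness()`); these thresholds drift
slightly with protein size.

Distance data cannot distinguish a fold from its mirror image.
`bundleHandedness()` projects helix midpoints onto the plane normal to
the axis and takes the sign of the cyclic cross-product sum, viewed
down the bundle with the first helix approaching (the axis is
sign-aligned against segment 1's N→C vector, then negated): +1 =
clockwise helix order, −1 = anticlockwise, 0 = collinear.  Mirroring
flips the sign while leaving the contact score bit-identical — the
chirality blind spot made explicit.

# Comparing and embedding ensembles

Whole-chain RMSD is easily dominated by long, badly modelled loops.
Since all models of one protein share a sequence there is no alignment
problem, and each residue's context can be summarised by its internal
distance profile: `environmentWeights()` weights residue `i` by
$\exp(-\Delta_i/\sigma)$ with $\Delta_i$ the mean absolute
discrepancy of `i`'s distances to all other residues between the two
models ($\sigma$ = 4 Å).  This is a deliberately simple,
fully-specified context weight with the contract the workflow needs —
continuous, in (0, 1], derived from the whole structure — and it is
documented as this package's own scheme, not a reimplementation of any
published environment-comparison program.  `weightedSuperpose()` then
solves the weighted least-squares superposition (Kabsch via SVD,
reflections excluded) and reports the weighted RMSD; `rmsdSuite()`
adds the three fixed schemes reusing the RoG weights.

`projectFoldspace()` embeds a pairwise RMSD matrix for visualisation.
Pairwise RMSDs form a consistent Euclidean metric only in n−1
dimensions, so a direct 2–3-dimensional MDS can distort badly.  The
projection instead (1) repairs triangle-inequality violations to their
tightest path bound (a Floyd–Warshall pass, tolerance 1e-9), (2)
starts from the exact classical-scaling configuration in n−1
dimensions, and (3) halves the dimension stage by stage down to the
target, re-minimising weighted stress by SMACOF majorization after
each cut (tolerance 1e-6 relative, ≤ 500 iterations per stage).
Distances are weighted $w = \min(1, 10/d)$ — inverse distance capped
at 1 — so reliable short distances anchor the layout and long,
unreliable ones are allowed to distort.  The seed only perturbs
coordinates infinitesimally before each stage to break symmetry ties;
stress is reported so exactness (zero stress) is verifiable.

# Selection

Plotting score (y) against RoG (x) puts the interesting models in the
upper left.  `topSlice()` slides the line `y = 10x + c` down until it
admits up to 20 models — provably the same set as ranking by the
margin `y − 10x`, with ties broken by score, then RoG, then id —
and `crossSliceCull()` keeps models appearing in at least 3 of the
per-contact-set slices.  The intercept is chosen per contact set; a
narrow-score ensemble can share a single line simply by calling
`topSlice()` once.  `balancePool()` evens the pool across construction
methods.  The slice gradient of 10 score-units per Å reflects the
relative dynamic ranges of the two axes for 100-pair scores and
bundle-scale RoGs.

# The synthetic generator

`makeBundle()` builds ideal helix bundles: textbook α-helix geometry
(1.5 Å rise, 100° twist, 2.3 Å Cα radius — defaults, not fitted),
helices on a circle of radius 10 Å alternating up/down, joined by
straight loops.  `oracleContacts()` lists centroid pairs within a
cutoff, scored by inverse squared distance, with a seeded fraction of
adjacent-rank swaps as rank noise; centroid (not Cα) distances ensure
the true structure can attain the scoring maximum.  `makeDecoys()`
produces the failure modes the workflow must detect: mirrors, stray
helices, swapped helices and Gaussian jitter.  These fixtures emulate
the *geometry* of real model sets, not their biology: real contact
predictions carry correlated errors, real loops are not straight, and
real bundles are neither equiangular nor ideally helical.  Passing
tests therefore demonstrate that the algorithms do what they claim on
known ground truth, not that any particular protein's prediction is
correct.

# Numerical choices and limitations

* Problem sizes in the shipped tests (95-residue bundles, ensembles of
  ~20 models, 3-helix boundary-optimisation instances at shifts ≤ 2,
  100 seeded trials) were chosen so the whole suite runs in about a
  minute while still exercising every code path, including the exact
  DP regime.
* The boundary DP is exact only while its state window covers the
  longest-range coupling; beyond that it is a guarded heuristic (see
  above).  `state_limit` trades exactness for memory.
* The stripe model assumes ideally aligned helices (slopes ±1); long
  kinked helices would need a free-slope extension.
* Cap-derived axes degrade when a segment sits at a chain terminus and
  its outer cap residues are clipped; the RoG error stays small but
  visible (tests allow ±0.4 Å there versus ±0.1 Å for interior
  segments).
* `topSlice()` assumes a positive gradient and higher-is-better
  scores; RoG enters in Å.
* The fold-space projection is deterministic given the seed but, like
  any stress minimiser, only locally optimal at low target dimensions;
  the reported stress is the honest summary of residual distortion.
* No in/out alternation is imposed on parsed orientations: forcing it
  would hide missing or re-entrant helices, and the consistency of the
  unforced assignments is itself a useful quality signal.
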