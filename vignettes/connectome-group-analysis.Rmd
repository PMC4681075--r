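---
title: "Methods: building and comparing structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and comparing structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractnet)
```

This vignette documents the models, conventions and design choices behind
`tractnet`. The package implements a complete group-comparison pipeline
for structural brain networks reconstructed from tractography, plus a
synthetic-data module that makes every stage testable without subject
data.

## From streamlines to networks

A subject's input is a set of streamlines (ordered 3D point sequences in
mm, world space) and a parcellation: an integer label grid with voxel
dimensions and a region table (id, name, hemisphere, volume). The
pipeline assumes streamlines and parcellation are already co-registered;
tractography itself (fiber-orientation estimation, seeding, stopping
rules) is upstream and out of scope — tracking parameters travel along
only as provenance metadata.

Construction proceeds in four steps:

1. **Length filter.** Streamlines shorter than `min_length_mm` are
   removed. The default is 50 mm, the common choice for whole-cerebrum
   studies that want to suppress spurious short association fibers. The
   threshold is *inclusive* (a 50.0 mm streamline is kept): stated
   minimum lengths are read as admissible values, and the choice is
   documented here because it is a genuine boundary convention rather
   than something the definition forces.
2. **Endpoint assignment.** Each terminal point maps to the label of the
   voxel containing it. World coordinates map to 0-based voxel indices by
   `floor(x / voxel_size)`, with half-open voxel intervals `[lo, hi)` so
   boundary points belong to exactly one voxel. Only terminal points
   count — a streamline passing through a region without ending there
   contributes nothing. This is the simplest rule consistent with
   "tracts between two nodes"; pass-through or dilated assignment
   variants could be added behind the same interface.
3. **Counting.** `F[i, j]` counts streamlines with one endpoint in region
   i and the other in region j. Streamlines with an endpoint in
   background or outside the grid, and streamlines with both endpoints in
   one region, are discarded; both discard categories are counted and
   attached to the result so the filtering is auditable.
4. **Networks.** The binary network has a link wherever `F[i, j] ≥ 1`
   (a single tract suffices). The density-weighted network divides the
   fiber count by the mean volume of the two regions,
   `W[i,j] = F[i,j] / ((V_i + V_j)/2)`, which compensates for larger
   regions capturing more endpoints. Volumes always come from the
   supplied parcellation (voxel count × voxel volume), so networks built
   in individual space use individual volumes. Zero or missing volumes
   are a hard validation error rather than a silent `Inf`.

## Graph measures and their conventions

All measures exist for binary and weighted networks. The conventions
below matter for comparability and are fixed package-wide:

* **Weight-to-length map.** Shortest paths on weighted networks use
  per-link lengths `l = 1/w`: strong connections are short. With
  density-weights of order 1e-4 this makes weighted path lengths of order
  1e4–1e5 and weighted global efficiencies of order 1e-6 — the natural
  scales for this weighting, and the inverse map used by the standard
  connectome toolboxes.
* **Characteristic path length** `L` averages shortest paths over ordered
  pairs with a *finite* distance. Unreachable pairs are excluded rather
  than imputed, and their count is attached to the result
  (`attr(, "n_infinite")`) so disconnectedness is never hidden. A network
  with no finite pair gives `NA` with a warning, not an error.
* **Global efficiency** averages `1/d` with `1/∞ = 0`, so it is always
  defined; a single-node network has efficiency 0 by convention.
* **Clustering.** Binary clustering is the triangle fraction
  `C_i = 2t_i / (k_i (k_i − 1))`, zero when `k_i < 2`. Weighted
  clustering is Onnela's geometric-mean form over neighbour-pair
  triangles with weights normalised by the network-wide maximum; it
  reduces exactly to the binary coefficient on uniform weights, and the
  max-normalisation makes the network-mean `C` invariant under global
  weight rescaling (which the normalized measures below rely on).
* **Betweenness centrality** is reported unnormalised over *ordered*
  source–target pairs (each unordered pair counted twice), endpoints
  excluded, computed with Brandes' dependency accumulation (Dijkstra
  inside for weighted networks). On 90-node networks this puts nodal
  values in the tens-to-hundreds range. Shortest-path ties in weighted
  networks are detected with a relative tolerance of 1e-12 on path sums;
  with continuous weights exact ties are measure-zero, and the tests
  verify the accumulation against exhaustive path enumeration.
* **Hubs** are nodes whose value exceeds mean + 2 standard deviations
  (strict inequality, sample SD with n − 1). With equal values the SD is
  0 and the hub set is empty, which the strict inequality makes
  well-defined.

## Null models and normalized measures

Normalized clustering (γ) and normalized path length (λ) divide the
observed network's `C` and `L` by ensemble means over randomized
reference networks:

* **Binary nulls** use Maslov–Sneppen double-edge swaps: two links with
  four distinct endpoints are rewired unless a duplicate link would
  arise. The degree sequence is preserved exactly and the graph stays
  simple. The attempt budget is `rewires_per_link × link count`; failed
  attempts consume budget, so runtime is bounded and a fixed seed gives a
  deterministic null.
* **Weighted nulls** randomize topology the same way with weights riding
  on the swapped links, then reassign the weight multiset across the new
  topology by greedy residual-strength matching: weights in descending
  order are placed on the free link whose endpoints have the largest
  product of residual target strengths. The weight multiset is preserved
  exactly, the degree sequence exactly, and the strength sequence
  approximately (Spearman correlation with the original above 0.8 on
  random 30-node networks at the defaults — a tolerance we chose and
  verify in the tests, not an external given). The published
  strength-preserving null has algorithmic variants; this is one faithful
  reading, and the reassignment step is isolated so alternatives can be
  swapped in.
* **Defaults**: 100 nulls × 10 rewires per link, both configurable. At 90
  nodes this is enough for stable ensemble means (the per-null values are
  returned for audit), and ensemble *means* — not medians — enter the
  ratios.

γ and λ are invariant under global weight multiplication (the tests
assert this numerically), so group differences in the normalized measures
are not artifacts of overall weight scale.

## Group comparison

`compare_cohort()` takes a cohort (manifest + one weighted connectome per
subject on a shared region table) and, per mode:

* computes per-subject **global** measures (mean degree/strength, γ, λ,
  global efficiency) and compares groups with two-sample t tests at
  α = 0.05, *uncorrected* — global tests are a small fixed family and are
  conventionally reported raw;
* computes per-subject **nodal** measures (degree/strength, clustering,
  local efficiency, betweenness) and tests each node, declaring
  significance at `p < α/N` (Bonferroni over the N nodes; with N = 90,
  p < 0.00056). Only the nodal family is corrected;
* builds **hub tables** from group-mean nodal values (not per-subject hub
  sets): group-mean betweenness for binary networks, group-mean strength
  for weighted ones;
* computes **laterality**: each global measure on the left and right
  hemispheric subnetworks gives a per-subject laterality index
  `(L − R)/(L + R)`, compared across groups with the same t test. All
  computed laterality p-values are emitted (uncorrected) so any post-hoc
  correction can be applied downstream.

The t test is the pooled-variance (Student) test with
`df = n_A + n_B − 2`; a Welch variant sits behind a config flag. The sign
convention is `t = (mean_A − mean_B)/se` with group A the first group in
the manifest. Zero pooled variance returns `t = 0, p = 1` for equal means
and `NA` with a warning otherwise. Null-ensemble seeds are derived from
the configured seed and each subject's *sorted-id rank*, which makes the
whole comparison bit-reproducible and exactly invariant to subject
reordering and group-label swaps.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes —
not brains. What it does model:

* a **parcellation** with the canonical 90-region, hemisphere-balanced
  layout: the grid splits into left/right halves along x, regions grow
  from random seed voxels by nearest-seed assignment (so they are
  spatially coherent and every region is non-empty), odd ids left and
  even ids right;
* **streamline sets realising a prescribed count matrix** exactly:
  endpoints sit at centres of voxels of the two target regions, and
  polylines shorter than the length threshold get a perpendicular
  midpoint detour that lifts them just past it (target 1.05 × threshold),
  so construction round-trips exactly even after filtering;
* **cohorts** on a distance-dependent random geometric base topology:
  node centroids are uniform in the unit cube, pair scores decay as
  `exp(−d/0.3)` times lognormal heterogeneity (sdlog 0.5), and each
  subject keeps the top `density` fraction of pairs by noisy score. The
  distance decay mimics the short-link bias of anatomical networks and
  the heterogeneity term produces the degree spread hub analysis needs.
  Weights are scaled so control-group mean strength sits near 7.3e-5 —
  the order of density-weighted strengths — which keeps formatting,
  tolerances and the 1/w length scale realistic.

Planted effects (patient group only): a global multiplicative weight
factor (default 0.9, a 10 % attenuation — the order suggested by reported
group strength means); attenuation of one node's incident weights
(default factor 0.8, applied *before* the density threshold so the node
can lose links as well as weight); and hub boosting by rerouting a
fraction (default 0.1) of links through the target node, each rerouted
link a–b becoming a–h and h–b carrying half the weight each, so the
subject's total weight is unchanged and the pure-attenuation closed form
(strength ratio = global factor) stays exact. Betweenness cannot be set
directly; rerouting raises it through the topology, which is also why the
default effect sizes are the package's own choices — the effects they
emulate are directions, not published effect sizes.

What the generator does *not* model: diffusion signal, tract geometry,
spatial autocorrelation of weights, inter-subject registration error, or
realistic between-subject variance structure (per-subject variation comes
from independent lognormal edge noise, default CV 0.4, so group-level
variances are much smaller than in real cohorts and t statistics on
planted effects are correspondingly large). Passing tests therefore
demonstrate correctness of the *pipeline*, not statistical power on real
data.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; child seeds stay within 32-bit range. The test suite
verifies the graph measures against independent brute-force oracles
(Floyd–Warshall distances, triple-loop triangle counting, exhaustive
shortest-path enumeration for betweenness) on 100 random graphs of up to
12 nodes at 1e-10, cross-checks against igraph, checks null-model
invariants per emitted null at full 90-node scale, calibrates the null
t test over 500 replicate 30-node cohorts, and verifies planted-effect
recovery over 20 study-sized cohorts (14 vs 19 subjects, 90 nodes) —
sizes chosen to exercise every code path at the scale the analysis
targets while keeping a full run in tens of seconds. The acceptance
script (`scripts/acceptance.R`) repeats the headline computations from a
single command-line seed.

## Known limitations

* Endpoint-only region assignment undercounts tracts whose termination
  falls in white matter just outside a labelled region; real pipelines
  often dilate labels. The assignment rule is isolated in
  `assign_endpoints()` for that reason.
* The weighted null's strength preservation is approximate by
  construction; studies for which exact strength sequences matter should
  increase `rewires_per_link`, inspect the returned ensembles, or swap
  the reassignment step.
* Bonferroni over nodes is conservative under the strong positive
  dependence of nodal measures; no FDR or permutation alternative is
  provided because the analysis this package implements uses Bonferroni
  only.
* Laterality assumes a hemisphere-balanced region table; cohorts lacking
  one hemisphere skip the laterality block.
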