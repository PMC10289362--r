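---
title: "Methods: geodesic pathtrees and likelihood landscapes in treespace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geodesic pathtrees and likelihood landscapes in treespace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathscape)
```

## Overview

`pathscape` explores the log-likelihood landscape of phylogenetic
treespace in a user-chosen area of interest. Trees with branch lengths are
points of the Billera–Holmes–Vogtmann (BHV) complex: one Euclidean orthant
per topology, coordinates given by the branch lengths of that topology's
splits, orthants glued along shared-split boundaries. Between any two
trees there is a unique shortest path (geodesic); sampling trees along
geodesics between the trees that bound the area of interest gives an
evenly spread set of "pathtrees" whose likelihoods, after per-topology
branch-length optimization, map the landscape.

This vignette records the model assumptions, the algorithmic and numerical
choices, and what the synthetic fixtures do and do not establish.

## Tree representation and splits

Trees are `ape::phylo` objects, rooted as read, with multifurcations
allowed and non-negative branch lengths in substitutions/site. All
distance computations operate on the *split decomposition*: each edge maps
to the bipartition of the leaf set it induces, encoded canonically as a
0/1 string over the sorted master taxon list, storing the side that does
not contain the first taxon. Two conventions matter:

* **Root handling.** Input trees are rooted, but BHV and Robinson–Foulds
  distances are defined on unrooted split sets. The two edges incident to
  a degree-2 root induce the same bipartition; their lengths are summed
  into one split weight. This makes every distance rooting-invariant and
  matches the convention used by standard wRF implementations (the
  package's tests cross-check against `phangorn::wRF.dist`).
* **Rooting of reconstructed trees.** Trees rebuilt from split sets
  (pathtrees, boundary trees) are emitted rooted at the attachment node of
  the first taxon. This is a serialization convention only; the split
  decomposition, and hence every distance and likelihood, is unaffected.

Zero-length edges are legal and preserved; `topology_key()` contracts
internal edges with length ≤ `tol` (default `1e-9`) before comparing
split sets, so trees sitting on orthant boundaries key like their
multifurcating contractions. The default exists because degenerate,
near-zero edges arise routinely both in pathtrees at boundaries and in
data sets containing identical sequences.

Newick output carries 15 significant digits. Twelve digits would not keep
a write/parse round trip within the package's 1e-12 absolute tolerance for
branch lengths above 1 substitution/site, so the higher precision is used
throughout.

## The geodesic (GTP) computation

For trees `T1`, `T2`, splits shared by both trees (always including
pendants) are *common* coordinates that interpolate linearly. A split of
one tree that is compatible with every split of the other is also treated
as common, with length 0 on the other side: the other tree lies on the
boundary of the enlarged orthant, and the coordinate simply shrinks to
zero. This preprocessing also removes the 0/0 ratio degeneracies that
empty support pairs would otherwise create. Tree-exclusive splits of
length ≤ `tol` are contracted first.

The remaining tree-exclusive splits are partitioned into support legs
`(A_1, B_1), …, (A_k, B_k)` by successive refinement. Because every
incompatible pair lies within one common-split subproblem, the bipartite
incompatibility graph decomposes into connected components that are solved
independently and merged by ratio order. Within a component, a leg
`(A, B)` is split whenever its incompatibility graph admits a vertex cover
`(C1 ⊆ A, C2 ⊆ B)` of weight `‖C1‖²/‖A‖² + ‖C2‖²/‖B‖² < 1`, into
`(C1, B∖C2)` followed by `(A∖C1, C2)`; the minimum-weight cover is found
by max-flow on the standard bipartite construction (igraph). Covers and
orderings are made deterministic by sorting all split encodings
lexicographically before graph construction, and ties between equal-ratio
legs keep lexicographic order (the path length is invariant to how
equal-ratio legs are arranged). Ratio and cover-weight comparisons use an
absolute tolerance of 1e-12.

The returned support satisfies, and the tests assert, the two conditions
that characterize realizable geodesics: non-decreasing leg ratios
`‖A_i‖/‖B_i‖`, and pairwise compatibility of every intermediate orthant's
split set `C ∪ B_1..B_i ∪ A_{i+1}..A_k`. The brute-force oracle used in
the tests enumerates *all* ordered partitions satisfying these two
conditions and minimizes the length formula directly; the ratio condition
is essential — dropping it admits supports whose formula value undercuts
any realizable path.

## Pathtrees

`tree_at()` evaluates the closed-form parameterization: the orthant index
at position λ is the largest `i` with `‖A_i‖/(‖A_i‖+‖B_i‖) ≤ λ` (0 if
none), so a λ exactly on a boundary belongs to the orthant it enters, with
the vanishing splits retained at length exactly 0. Eq-length values are
clamped at zero (they can only be negative by floating-point rounding,
checked to −1e-12). `sample_path()` places `m` trees at `λ_j = j/(m+1)`,
excluding endpoints: "equally spaced" is uniform in λ, which under this
parameterization is proportional to distance traveled along the geodesic,
and endpoint exclusion reproduces the published count arithmetic
(s starting trees give `m·s(s−1)/2` pathtrees).

## JC69 likelihood and optimization

The fitness function is the Jukes–Cantor (JC69) log-likelihood: equal base
frequencies (1/4), a single substitution rate, independent sites, no rate
heterogeneity. The simplicity is deliberate — the landscape machinery is
model-agnostic, and a one-parameter model avoids confounding the geometry
with parameter fitting. Felsenstein pruning runs over compressed site
patterns; gaps, `N` and ambiguity codes are fully missing (partial vector
of ones); per-pattern rescaling guards against underflow. Reversibility
makes the result independent of root placement (asserted to 1e-9 in the
tests). Reported values are plain pruning log-likelihoods with no
multinomial pattern constant, the convention of standard ML programs.

Branch lengths are optimized per topology by coordinate ascent: Brent's
method on `[1e-8, 10]` substitutions/site per edge (the lower bound clamps
zero-substitution edges, the upper is far beyond saturation for real
data), sweeping all edges until a sweep improves the log-likelihood by
less than `tol = 1e-6` or 50 sweeps. A proposed length is accepted only if
it improves the likelihood, so the sweep trace is non-decreasing by
construction. Multifurcating topologies are optimized as-is, because
boundary pathtrees are legitimately multifurcating. For a rooted binary
input only the sum of the two root-incident edge lengths is identifiable;
the split decomposition (where they merge) is the right scale on which to
read the result.

## Landscape: MDS, hull, interpolation

Classical (Torgerson) MDS is used rather than stress-minimizing SMACOF: it
is deterministic, has no random initialization, and its distortion is
exactly what the Shepard statistics quantify. BHV and wRF matrices are
generally non-Euclidean; negative eigenvalues are truncated and only the
top two positive components used. Each axis is flipped so its
largest-magnitude coordinate is positive, making embeddings reproducible
to the byte. Shepard validation reports Pearson, Spearman and Kendall
correlations between original and embedded distances over the strict
upper triangle.

Starting trees are the convex-hull vertices of the embedding
(counter-clockwise, with edge-interior and coincident points removed). The
hull in the 2-D projection approximates the hull in treespace; this is an
acknowledged approximation — no algorithm exists for the latter.

The likelihood surface is interpolated by exact (zero-smoothing) radial
basis functions with an affine drift term: the thin-plate kernel
`r² log r` (`tps`) or the cubic kernel `r³` (`cubic`, the scattered-data
member of the cubic-spline family; a triangulation-based Clough–Tocher
scheme was considered and rejected as it needs gradient estimation
machinery without changing any tested property). Both reproduce data
values at the sites and affine fields exactly; duplicate coordinates
(identical trees) are collapsed to their mean value before solving; cells
outside the hull polygon are masked. Collinear sites leave the 2-D
interpolation problem singular and are rejected with an error. The grid
default in the pipeline is 80×80 — figures are smooth at this resolution
while keeping the dense-grid kernel evaluation cheap; `interpolate_surface`
accepts any resolution.

Plots color all trees by log-likelihood (viridis), starting trees as black
triangles, selected/optimized trees on a purple spectrum rank-scaled by
log-likelihood (lighter = lower), and the best tree as a red square.

## Pipeline

Iteration 1 embeds the (optionally burned-in and thinned) input sample,
takes its hull vertices as starting trees, generates pathtrees, evaluates
likelihoods, selects the top `n`, optimizes one tree per topology, and
writes the landscape. Subsequent iterations zoom: the starting trees are
the hull vertices of the previous iteration's *optimized* trees in a fresh
MDS embedding, with the faster wRF metric by default. Selection uses the
*unoptimized* likelihoods (the algorithm's selection step precedes
optimization); optimized likelihoods drive reporting and coloring only.
When fewer than three distinct optimized trees exist the zoom hull is
degenerate; the pipeline then widens the zoom set to include the selected
trees, and failing that keeps the current starting trees — stopping a run
for lack of topological diversity would discard completed work.

Within a topology cluster the optimization start is the highest-likelihood
member (deterministic, best local start). Runs are deterministic given the
configuration: identical seeds produce byte-identical tree files and
tables. All stages log counts and settings to a JSON run log.

## Synthetic data

The fixture generator stands in for an MCMC tree sample and its alignment:

* `random_tree()` grows a rooted binary topology by sequential attachment
  to a uniformly chosen position (any edge or above the root), giving the
  uniform distribution over rooted binary labeled topologies; branch
  lengths are i.i.d. exponential (default mean 0.1 substitutions/site,
  typical of the short-to-moderate edges in empirical CytB-scale data) or
  uniform.
* `perturb_cloud()` emulates the local cloud of a converged MCMC sample:
  NNI moves (default 1) plus multiplicative log-normal length jitter
  (default sd 0.1) around a base tree.
* `simulate_alignment()` evolves i.i.d. uniform root states down the tree
  with the same JC69 transition matrices the likelihood uses; tests verify
  pairwise mismatch fractions against the closed form
  `(3/4)(1 − e^{−4t/3})`.

What these fixtures do **not** emulate: rate heterogeneity, base
composition bias, indels/missing-data structure, autocorrelated MCMC
samples, and the near-duplicate-sequence degeneracy of large population
data sets (beyond zero-length edges, which are covered). Passing tests
therefore establish the geometry, the likelihood machinery and the
pipeline contracts — not robustness to model misspecification.

The branch-length recovery check uses a fixed 6-leaf tree with lengths
0.1–0.5 substitutions/site and a 100,000-site simulated alignment. The
range is deliberate: edges near saturation inflate the sampling variance
of adjacent internal-edge estimates, and the check is meant to detect
optimizer defects at a tolerance (5% relative error) several standard
deviations above the sampling noise of every edge, from both the true and
a uniform (all edges 0.5) start.

## Problem sizes in the test suite

The suite runs on 4–8-leaf trees: geodesics are verified against an oracle
that enumerates ordered support partitions (feasible up to ~3 exclusive
splits per tree), likelihoods against exhaustive ancestral-state summation
(4^(internal nodes) terms), hulls against a 720-direction support-function
sweep, and the pipeline on a 15-tree, 300-site fixture with two zoom
iterations. These sizes keep the complete suite under a few minutes while
exercising every code path; the algorithms themselves are polynomial
(GTP is O(n⁴) in the leaf count) and run comfortably on hundreds of trees.

## Known limitations

* Distance matrices are computed serially; for `N` trees the BHV matrix
  needs `N(N−1)/2` geodesics, which dominates runtime for `N` in the
  thousands (the wRF metric is the practical choice there, as in the
  pipeline's zoom default).
* The convex hull is taken in the 2-D MDS projection, not in treespace;
  trees outside the projected hull can still be inside the treespace hull
  and vice versa. Shepard correlations should be inspected before trusting
  a landscape read off the embedding.
* The weighted Robinson–Foulds distance exceeds the BHV distance by a
  factor that grows with the number of differing coordinates (an L1 vs L2
  effect, up to √dimension for same-topology pairs); claims of a fixed
  factor-2 bound do not hold in general, and the acceptance machinery
  measures the empirical ratio rather than assuming it.
* Only JC69 without rate variation is implemented; the likelihood module's
  interface (alignment + tree → per-pattern log-likelihoods) is the
  extension point for richer models.
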