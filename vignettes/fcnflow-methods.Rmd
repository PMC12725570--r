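---
title: "Methods: fragmentation, habitat diversity, and temporal change in fish communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation, habitat diversity, and temporal change in fish communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcnflow` implements an analysis chain that asks whether the loss of river
network connectivity and habitat diversity explains where freshwater fish
communities changed between a historical and a current period. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the bundled synthetic data can and cannot show.

## The river network model

The unit of hydrography is the confluence-to-confluence stream reach. A
network is a forest of in-trees: each reach has at most one downstream
neighbour (`downstream_id`), and a reach with none is a terminus (an ocean
outlet or a hydrologic disconnect). Confluences are implicit — two or more
reaches sharing a downstream neighbour. Braided channels (multiple
downstream neighbours) are out of scope; input must be pre-resolved to a
dendritic topology.

Validation is strict on structure (unique ids, resolvable pointers, no
cycles, positive lengths and drainage areas — each failure is a distinct,
classed condition) and permissive on physics: drainage area decreasing in
the downstream direction is logged as a warning, not rejected, because
real hydrographic products contain such divergences. Missing condition
attributes propagate as `NA` through every summary; they are never
silently zero.

Reaches draining less than 2.5 km² are excluded before analysis
(`filter_small_reaches()`), evening out variable drainage density in the
source hydrography. Because drainage area accumulates downstream, the
removed set is upstream-closed in well-formed data; in data that triggered
the monotonicity warning, a retained reach pointing at a removed one is
converted to a terminus, with a warning, so the result is always a valid
network.

## Functionally connected networks

A passage barrier on reach *r* severs the connection between *r* and its
downstream neighbour, with *r* itself belonging to the upstream patch. The
maximal sets of mutually reachable reaches under the active barrier set
are the functionally connected networks (FCNs) — the habitat patches a
fish could traverse. Two scenario definitions mirror the study design:

* **historical** — natural fragmentation only: waterfalls that are
  complete barriers to passage;
* **current** — waterfalls plus dams of any passability class (complete,
  partial, or unknown).

Both scenarios drop barriers flagged as removed, off the routed network,
or with observed anadromous fish distribution upstream. Partial and
unknown *waterfalls* never count: the natural-barrier dataset convention
is that only complete waterfalls are treated as barriers in either period.

Three edge-case rules are deliberate: a barrier on a terminus reach cuts
nothing (logged no-op); several barriers on one reach collapse to one cut
(the severed edge is the same); FCN identifiers are derived from the
smallest member reach id, so output is independent of iteration order.
Delineation is a union–find pass over the retained edges, and the test
suite holds it equal to an independent connected-components oracle on a
thousand random trees.

## Physical habitat classes, richness and rarity

Each reach is classified by composable dimensions: stream size class from
drainage-area breaks, thermal class from August temperature breaks, and
any of the categorical pass-through attributes (gradient, flow regime,
valley confinement). The shipped break values are editable defaults, not
constants of the method — the upstream classification systems they stand
in for are inputs here. Waterbody classes (ocean/estuary, natural lake,
artificial lake) are standalone.

Within an FCN, a stream class is *present* when its summed length is at
least 1 km (inclusive bound); waterbody classes are present by mere
occurrence. Richness is the count of present classes. Rarity-weighted
richness (RWR) is `sum(1 / n_h)` over present classes, with `n_h` the
number of FCNs in the same scenario and ecoregion containing class *h*;
summed over FCNs it equals the number of classes present anywhere, an
identity the tests enforce exactly. Because fragmentation inflates the
network count and deflates each `n_h`-denominator share, raw RWR is not
comparable across periods; RWR is therefore z-scored within ecoregion
separately per period (sample, *n−1*, standard deviation; a zero-spread
group gets z = 0 with a warning), and the change in z-scores is the
comparable quantity. Z-scoring is a pragmatic normalization, not a perfect
one; it is the only option implemented.

Whether waterbody classes count toward richness is an open reading; they
are counted here, and the schema can exclude them by omitting the
waterbody reaches from classification.

## Linking networks to subwatersheds

Fish observations live at the HUC-12 subwatershed scale, and several FCNs
can cross one HUC-12. Each HUC-12 is characterized by the *longest*
(total stream km, not reach count) historical and current FCN
intersecting it, selected independently per period — no containment is
enforced between the two. Ties break to the smallest FCN id and are
logged.

Per habitat class, the predictors are the percent change in class length
from the historic to the current network (negative = loss) and a presence
change coded −1/0/+1, so loss and gain remain distinguishable. A class
absent historically has an undefined percent change (`NA`, logged); its
+1 presence change carries the gain signal. Before modelling, undefined
percent changes and class columns absent from both networks are imputed
to zero. Condition enters as the length-weighted mean of the habitat
condition index (HWI) and local hydrologic regulation over the HUC-12's
reaches (missing values skipped, weights renormalized), and as the dam
density/storage values of the HUC-12 outlet — the member reach with the
largest drainage area (ties to smallest reach id).

## Temporal beta-diversity

For each site, with `a` shared species, `b` species present only
historically and `c` present only currently, the Sorensen dissimilarity

$$D = \frac{b + c}{2a + b + c} = B + C, \qquad
  B = \frac{b}{2a+b+c},\; C = \frac{c}{2a+b+c}$$

decomposes change into loss (`B`) and gain (`C`). Sites empty in both
periods are undefined and excluded from means and the dominance test,
with a logged count.

Significance per site comes from a permutation null of "assemblages that
could have been observed at this site". The default scheme permutes each
species column independently across sites, separately in each period's
matrix, regenerating every site's `D` each round; an alternative joint
site permutation (one common row shuffle per matrix) is selectable, since
the exact scheme inside the referenced TBI implementation is not
specified by its description. P-values use the add-one estimator
`(1 + #{D_perm >= D_obs}) / (1 + n_perm)` — never zero — and permuted
values tying the observed one count as exceedances (conservative). The
test suite checks the estimator against an exact enumeration of the
column null on a small instance and verifies the empirical size at
α = 0.05 over a thousand null replicates.

Loss/gain dominance across sites is a sign-flip permutation of the
per-site differences `B − C` (two-sided). Per-species change uses a
paired *t* statistic on the site-wise occupancy differences with sign-flip
permutation and a Holm correction by default (Bonferroni and BH are
selectable). A species with no change at any site has p = 1 by
convention; a species changed identically at every occupied site has an
infinite *t*, and only the all-plus and all-minus flips tie it, so it
attains the minimum permutation p — the behaviour the occupancy tables
require for uniform extirpations.

## Spatial random forest attribution

Collinearity among the predictors is resolved before fitting: zero-
variance columns first, then pairwise correlations above 0.75 (within a
violating pair, the member less rank-correlated with the response is
dropped), then the worst variance inflation factor until all VIF ≤ 5.
The total-length percent change — the fragmentation hypothesis variable —
is protected through a preference order, as the spatial-RF tooling this
stage mirrors supports: a hypothesis variable should be pruned *for*,
never replaced by, a collinear proxy.

Spatial structure is diagnosed with Moran's I,
`I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, on row-normalized
inverse-distance weights truncated at a distance threshold, with
permutation p-values (one-sided for positive autocorrelation, the
direction that matters for residual diagnostics). The thresholds default
to the quartiles of the pairwise distance distribution; the values used
by any given study are data-dependent choices, so they are parameters
here. The expectation −1/(n−1) under the permutation null is verified in
the tests, as is agreement with an independent Moran implementation.

The forest of TBI on the pruned predictors is fit with library-default
hyperparameters (tuning was explored in the source analysis and judged
unnecessary). If out-of-bag residuals show significant Moran's I at any
threshold, Moran eigenvector maps — eigenvectors of the double-centred
symmetric weight matrix at the most-structured threshold, in decreasing
eigenvalue (= Moran) order — are added one at a time until residuals are
non-significant at every threshold or candidates (20 at most) run out, in
which case a warning is mandatory. The final model is refit 30 times
under different seeds; reported are the distribution of out-of-bag R²
(median and MAD) and of permutation importances, and partial dependence
curves computed by holding all other predictors at their 0.5 quantiles
and averaging predictions over all 30 fits. A 75/25 train/test evaluation
exists as an optional report, not as part of the main chain.

## The synthetic study system

The generator (`synth_config()`, `generate_dataset()`) emulates the
*structure* of the study inputs so every stage runs offline. Its defaults
are the package's study conditions, chosen once to echo the published
system's scale and then left alone:

* 4,000 reaches in one drainage (~9,000 km of stream; log-normal reach
  lengths with a ~2 km median), drainage area accumulated downstream so
  monotonicity holds by construction;
* 110 complete-barrier waterfalls and 66 dams. These counts reproduce the
  reported magnitude of fragmentation change — an FCN count increase near
  +59% with a mean-length change near −37%, and a historical mean FCN
  length near 84 km — so the synthetic system is stressed the way the
  real one was;
* dams placed with probability proportional to drainage area^0.5. The
  square-root bias puts dams preferentially on larger rivers (as real
  inventories show) while leaving some main-stem segments uncut, which
  keeps the per-site fractional length loss well spread instead of
  saturating near 1;
* ~500 HUC-12 subwatersheds carved as contiguous subtree blocks (so
  several FCNs can cross one HUC-12, reproducing the linkage ambiguity
  the longest-FCN rule resolves), with centroids from a planar embedding
  of the tree — which also gives nearby subwatersheds correlated
  attributes, the autocorrelation the spatial stage needs to have
  something to do;
* 40 species whose minimum-network-length requirements are drawn from
  the observed longest-FCN length distribution (longer networks host more
  species), occupancy thinned at a 0.9 observation rate;
* loss-only dynamics: a historically present species is lost with
  probability `plogis(-3.2 + 3.5 * frag - 1.5 * cond)`, where `frag` is
  the site's fractional loss of longest-network length and `cond` its
  length-weighted HWI. At these coefficients the mean site dissimilarity
  lands near 0.2, the upper end of the published ecoregion means, and
  sites with no fragmentation and good condition lose almost nothing. An
  optional `gain_rate` exists solely to exercise the gain branch of the
  dominance test.

What the generator does **not** emulate: real drainage geometry and flow
permanence (desert networks that are "connected" without water), species
interactions, detection error structured by survey effort, translocations,
and abundance. Passing tests on this system therefore show that the
machinery recovers a planted fragmentation→loss effect under realistic
network topology and sampling scale — not that the effect holds in any
real landscape.

## Numerical conventions and problem sizes

* Reported percent changes round half away from zero (base R rounds half
  to even), matching how summary tables are conventionally printed.
* All permutation p-values use the add-one estimator; ties count as
  exceedances.
* Every random step takes an explicit integer seed; repeated runs are
  identical bit for bit, including the forest stage (single-threaded
  fits).
* The test suite exercises: delineation against an oracle on 1,000 random
  trees (≤ 200 reaches); TBI identities on 10,000 random rows; test size
  over 1,000 null replicates of a 12-site × 6-species community at 999
  permutations; RWR conservation on 500 random instances; pruning on 100
  random tables; and effect recovery over 20 end-to-end seeded runs of the
  default 4,000-reach system with 30 forest repetitions each. These sizes
  were chosen so the full suite completes on a laptop in minutes while
  keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Probabilistic (partial-passability) connectivity is not modelled; a
  barrier either cuts or does not.
* The habitat-class thresholds shipped as defaults are illustrative; any
  real application must supply the classification system actually used.
* The MEM candidate pool comes from the single most-structured threshold
  rather than a multi-threshold union; in practice the leading
  eigenvectors at neighbouring thresholds are near-identical.
* HUC-12s whose longest current FCN lacks a historical habitat summary
  are dropped (logged), mirroring the listwise handling a real analysis
  would need to make explicit.
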