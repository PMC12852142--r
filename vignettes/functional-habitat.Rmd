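---
title: "Functional habitat delineation from fuzzy land-cover surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional habitat delineation from fuzzy land-cover surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fuzzyhab)
```

## The problem

Habitat mapping usually forces a choice between two representations that are
both wrong in different ways. A *patch* (Boolean) map partitions the
landscape into habitat and matrix, which supports area, isolation and
connectivity metrics but erases gradients, ecotones and matrix quality. A
*gradient* map keeps the continuity but provides no objects to measure
distances between. fuzzyhab implements a framework that keeps both: land
cover is carried as per-cell **type-1 fuzzy memberships** (one value in
[0, 1] per class per cell, the probabilities a classifier such as a Random
Forest emits), and the **uncertainty of those memberships** (type-2 fuzzy
representation) is carried alongside as a per-cell variance. Patches are
delineated by an α-cut *within each Monte-Carlo realization* of the
landscape, so every patch-based quantity — habitat amount, least-cost
distance, connectivity — comes back as a distribution rather than a single
number.

## The model, step by step

**Classifier fusion.** Tree-level class probabilities $P_1$ and the
row-normalized confusion-matrix diagonal $P_2$ carry overlapping
information. They are fused per tree with a power posterior,
$P_c \propto P_{1c} P_{2c}^{\alpha}$ with $\alpha = 1-|\rho|$ and $\rho$
the Pearson correlation between the two vectors: perfectly correlated
evidence is a pure repeat and is ignored, uncorrelated evidence enters as a
full Bayesian product. Trees are repeated estimates of the same quantity,
so fused vectors are averaged across trees (type-1 membership) and their
across-tree variance is the type-2 uncertainty — evidence is never
chain-multiplied across trees. When either vector is constant the
correlation is undefined; we define $\rho = 0$ there (full product), which
is inconsequential in practice because a constant $P_2$ rescales all
classes equally. Note one structural degeneracy: with exactly two classes,
any two non-constant probability vectors are perfectly correlated, so the
confusion-matrix evidence is inert for $K = 2$; fusion is only informative
from three classes up.

**Beta moment matching.** Each (mean, variance) pair becomes a Beta
distribution by the method of moments
($\nu = \mu(1-\mu)/\sigma^2 - 1$, $a = \mu\nu$, $b = (1-\mu)\nu$). Cells
with $\sigma^2 = 0$ or $\mu \in \{0, 1\}$ are point masses and sample as
constants. A variance at or above the feasible bound $\mu(1-\mu)$ cannot
come from a Beta distribution; we cap it at 0.95 of the bound and warn,
treating it as a data-quality problem rather than an error.

**Realization sampling.** One draw per cell per class, independently
(spatial correlation of classification error is not modelled — see
Limitations). The raw draws no longer sum to one within a cell, while the
downstream operators treat memberships as convex weights; we therefore
renormalize each cell's class memberships to sum to one by default. The
closure rule is a genuine design choice — sampling per class and leaving
the sums free is also defensible — so `sample_realization(renormalize =
FALSE)` exposes the raw draws for sensitivity checks. Renormalization is
skipped for single-class stacks, where closure is meaningless.

**Patches and habitat amount.** `alpha_cut_patches()` labels cells with
value ≥ α (default α = 0.5: above it, no other class can have a larger
membership) into queen-connected (8-neighbour) components. The fuzzy
habitat content of a patch is $pHab = \sum_c M_c$, the plain membership
sum; multiplied by the cell area $A$ it is a habitat *amount* in squared
map units — deliberately not the patch *area*, since membership weights
each cell's contribution. For Monte-Carlo amount distributions we track the
landscape-wide sum over all cells meeting the α-cut rather than per-patch
sums, because components split and merge freely across draws and per-patch
identities are not stable. Patch centroids are means of member-cell
centers, snapped to the nearest member cell when the mean falls outside a
concave patch, so they are always valid path endpoints.

**Multivariate habitat and neighbourhood effects.** Habitat suitability is
the membership-weighted sum $habitat_c = \sum_i M_{ci} H_i$, and foraging
suitability likewise with weights $F$. Two kernel-based neighbourhood terms
modify it:

* $nNeg_c = \sum_k P_{ck} \sum_i M_{ki}$ over deleterious classes — a
  negative-exponential edge effect, $P_{ck} = e^{-\alpha D_{ck}}$ with
  $\alpha = -\log(d)/maxD$, so the kernel is exactly the tail probability
  $d$ (default 0.01) at the maximum edge-effect distance. $D_{ck}$ is
  Euclidean, center-to-center; the window truncates at $maxD$ (the dropped
  tail is ≤ 0.01 per cell), giving $O(n\,w^2)$ cost.
* $nPos_c$ averages kernel-weighted foraging suitability over every cell
  reachable within the maximum foraging distance (default tail 0.05 at 100
  map units), where "reachable" is measured as *accumulated functional
  cost*, not straight-line distance — intervening hostile cover shrinks the
  accessible foraging neighbourhood. The normalizer $|C|$ is the size of
  exactly that reachable set (the same cells being summed); a Euclidean
  window would have been the other defensible reading.

Functional habitat is $fHab_c = habitat_c + nPos_c - nNeg_c$, clipped to
[0, 1]: the raw sum can leave the unit interval, while the α-cut and the
membership semantics require a bounded surface. The unclipped surface is
kept as an attribute for diagnostics.

**Cost surfaces and functional distances.** Movement cost is the
membership-weighted resistance $cost_c = \sum_i M_{ci} R_i$; the
*functional* cost adds kernel-weighted resistance contributions of nearby
deleterious memberships, so a tree line abutting a city costs more to
traverse than the same tree line in grassland. Least-cost paths run on the
8-connected grid graph with per-step cost the mean of the two endpoint
cells times the step length (diagonals × √2) — the convention that makes
cost distance equal Euclidean distance on a unit surface, so kernel
distances in map units remain directly comparable. Ties between equal-cost
paths are broken deterministically by the shortest-path backend under our
fixed edge-insertion order; which of several exactly-equal paths is
returned is not otherwise specified. Repeating the least-cost computation
across realizations and counting traversals per cell gives the
**path-density surface**; we report raw traversal frequencies rather than a
smoothed point-process density because the counts are the analysis-relevant
statistic and need no bandwidth parameter.

**Connectivity.** Each realization's patches form a complete graph with
node weights $pHab_p A$ and edge probabilities
$p_{pq} = e^{-\alpha_{disp}\, cd_{pq}}$, with $\alpha_{disp}$ calibrated
exactly like the other kernels from a dispersal distance and tail. The
reachability matrix $P^*_{pq}$ is the maximum product of edge
probabilities over any route, computed as a shortest path on $-\log p$
weights, with $P^*_{pp} = 1$ (self-pairs are included so a single patch
reduces cleanly). The headline metric is

$$RFH = \frac{\sqrt{\sum_p \sum_q pHab_p A \; pHab_q A \; P^*_{pq}}}{A_L}
\times 100,$$

a percentage of landscape area. `rfh_monte_carlo()` runs the whole chain
per iteration (realization → functional cost → habitat → neighbourhood
terms → fHab → patches → graph → RFH); mode `"rh"` is the single-class
baseline without neighbourhood effects, and `boolean_ehi()` is the crisp
arg-max baseline with patch area as the node weight.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha_cut` | 0.5 | — | patch inclusion threshold on membership / fHab |
| `H`, `F_` | (0.9, 0.1, 0, 0) / (0.8, 0.5, 0.3, 0.2) | — | habitat / foraging suitability per class (woodland, grassland, wetland, urban demo) |
| `R` | (1, 5, 8, 10) | cost per map unit | movement resistance per class |
| `maxD_edge`, `d_edge` | 10 map units, 0.01 | — | edge-effect reach and kernel tail |
| `maxD_forage`, `d_forage` | 100 map units, 0.05 | — | foraging reach (functional-cost distance) and tail |
| `dispersal_distance`, `dispersal_tail` | 200 map units, 0.05 | — | between-patch movement calibration |
| `variance_scale` | 0.2 | — | generator uncertainty level `s` in `s·μ(1−μ)` |

The demonstration weights are illustrative of a woodland species with
grassland foraging spillover and urban avoidance; in applications they
should come from expert elicitation or literature. The dispersal defaults
are the package's own choice of a mobile but not unlimited disperser at
the scale of the bundled 100 × 100-map-unit landscapes; they reuse the
kernel-tail calibration pattern so a single mechanism covers all three
distance parameters.

## What the synthetic generator does and does not emulate

`generate_landscape()` produces three study landscapes on a default
50 × 50 grid of 2-unit cells: a single compact patch with a wide (6-cell)
sigmoidal membership transition, the same patch with a hard (1-cell)
transition, and a four-class mosaic (two woodland regions flanking a
wetland band, urban strip along the bottom margin, grassland elsewhere).
Memberships sum to one per cell by construction; the variance surface is
$s\,\mu(1-\mu)$ — the framework requires only that uncertainty peaks
at intermediate membership, and this is the simplest form with that
property that also guarantees Beta-feasible moments for $0 < s < 1$. Blob
outlines get a small seeded Fourier wobble so patch shapes are not exactly
circular; the exact shapes are fixtures, not claims.

The generator emulates the *statistical structure* of classified
landscapes, not real ones: there is no spatial autocorrelation in the
uncertainty beyond what the membership gradient induces, no mixed-pixel
class confusion structure (e.g. wetland–grassland confusion being more
likely than wetland–urban), and no sensor artefacts. Passing tests
therefore demonstrate the correctness of the machinery and the qualitative
behaviour of the metrics (e.g. soft transitions widen habitat-amount
distributions), not the absolute values any real landscape would produce.
Reference absolute fixture values (habitat-amount means of ≈2440 and
≈1459 m², single-class reachable habitat ≈8.56%) depend on externally deposited reference rasters, whose grid size and
generation procedure are unavailable here; the corresponding check in `test-acceptance.R` runs only when
those rasters are dropped into `tests/testthat/fixtures/deposited_rasters/`
and is expected to fail (not skip) without them. The reachable-functional-
habitat distribution itself is compared only qualitatively (wider than the
single-class baseline) because the reference mean/min values for it are internally inconsistent
between the two places that report them.

## Numerical choices and degenerate inputs

* Kernel calibrations are closed-form and exact; tests pin the tails at
  1e-9.
* Per-cell operators (weighted sums, kernel windows, foraging means) match
  exhaustive double-loop oracles to 1e-10; grid least-cost distances match
  an independent array Dijkstra to 1e-10.
* Zero-variance (crisp) inputs short-circuit correctly end to end: amounts
  equal areas, Monte-Carlo distributions collapse to a point, the
  reachability metric equals the Boolean baseline, and the path density is
  the indicator of the single least-cost path.
* Empty patch sets are legal everywhere: zero patches give metric 0;
  habitat cells with an empty foraging neighbourhood get $nPos = 0$.
* Probability-vector inputs are validated to sum to 1 within 1e-6 (CSV
  round-off); internal renormalization then restores exact closure.
* TIFF storage is 32-bit float, scaled into [0, 1] with the scale recorded
  in a JSON sidecar; round-trips are exact to float32 resolution
  (relative ~1e-7). All internal arithmetic is float64.
* A single root seed drives every stochastic stage; per-iteration sub-seeds
  are drawn once from the root seed so any iteration is reproducible in
  isolation, and seeded sampling never perturbs the caller's RNG state.

Test problem sizes are deliberately small — oracle grids of 7–15 cells a
side, 20 × 20 cost surfaces, 100–1000-iteration Monte-Carlo runs on the
50 × 50 bundled landscapes — chosen so the full suite exercises every code
path in well under a minute while keeping Monte-Carlo comparisons stable
under their fixed seeds.

## Known limitations

* Per-cell independent sampling ignores spatial correlation of classifier
  error; real uncertainty is patchy, so our distributions are likely
  narrower than reality at fixed per-cell variance.
* A single edge-effect distance per profile: class-specific edge distances
  per deleterious cover type would be a straightforward extension.
* The negative-effect kernel uses Euclidean distance (the foraging kernel
  uses functional cost); whether edge effects should also propagate along
  cost surfaces is ecologically arguable, and `nNeg` is not
  count-normalized while `nPos` is — both choices are deliberate and
  symmetric alternatives would be easy to add.
* Circuit-theory or random-walk effective distances are deliberately out of
  scope; path redundancy here emerges from classification uncertainty, not
  from a movement model.
* Boolean-mode workflows assume the arg-max class is meaningful everywhere,
  which is exactly the assumption the fuzzy pipeline is designed to relax.

## A worked run

```{r example, fig.width = 6, fig.height = 4}
stack <- make_four_class(scenario_spec("four_class", seed = 7))
profile <- species_profile()

boolean_ehi(stack, profile)$value

mc_rh <- rfh_monte_carlo(stack, profile, n_iter = 50, seed = 11,
                         mode = "rh", collect_density = FALSE)
glance(mc_rh)

mc_rfh <- rfh_monte_carlo(stack, profile, n_iter = 50, seed = 11,
                          mode = "rfh", collect_density = FALSE)
glance(mc_rfh)

autoplot(mc_rfh, bins = 15)
```

The crisp baseline overstates connected habitat relative to both fuzzy
modes (it counts whole cells as habitat wherever woodland merely wins the
arg-max), and the functional-habitat distribution is wider than the
single-class one: neighbourhood effects move cells across the α-cut in
both directions, adding patch-configuration variability that a single
membership surface cannot express.
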