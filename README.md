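# fuzzyhab

Functional habitat delineation from fuzzy land-cover classifications, for
landscape ecologists working on fragmentation and connectivity.

Habitat analysis usually forces a choice between a *patch* map (crisp
habitat/matrix polygons — measurable, but blind to gradients and matrix
quality) and a *gradient* map (continuous suitability — faithful, but with
no objects to measure distances between). fuzzyhab keeps both. Land cover
enters as per-cell **type-1 fuzzy memberships** — one value in [0, 1] per
class, the probabilities a classifier such as a Random Forest produces —
together with their per-cell **classification uncertainty** (a type-2
representation: each membership is itself a Beta distribution). Patch
delineation happens *inside* a Monte-Carlo loop, once per sampled
landscape, so every patch-based quantity comes back as a distribution.

The pipeline, per Monte-Carlo iteration:

1. sample a landscape realization from the per-cell Beta distributions
   (moment-matched to the membership mean and variance);
2. contract memberships with species weights: habitat suitability
   `habitat_c = Σ M_ci H_i`, foraging suitability `forage_c = Σ M_ci F_i`,
   movement cost `cost_c = Σ M_ci R_i`;
3. apply negative-exponential neighbourhood kernels
   `P_ck = exp(−α D_ck)`, calibrated so `α = −log(d)/maxD` pins the kernel
   to its tail probability `d` at the maximum effect distance: an edge
   effect `nNeg_c` from deleterious cover (Euclidean distance, tail 0.01)
   and a foraging complement `nPos_c` (accumulated functional-cost
   distance, tail 0.05 at 100 map units);
4. form functional habitat `fHab_c = habitat_c + nPos_c − nNeg_c`
   (clipped to [0, 1]), α-cut it (default 0.5) into queen-connected
   patches with fuzzy content `pHab = Σ M_c`;
5. connect patches by least-cost paths into a probabilistic graph
   (`p_pq = exp(−α_disp · cd_pq)`), take max-product reachabilities
   `P*_pq`, and score **Reachable Functional Habitat**

   `RFH = 100 · sqrt(Σ_p Σ_q pHab_p A · pHab_q A · P*_pq) / A_L`.

Single least-cost paths are replaced by per-cell path-density surfaces
(the fraction of iterations whose least-cost path crosses a cell), and
core/edge structure by a core-frequency surface (the fraction of
iterations in which a cell meets the α-cut). A crisp arg-max baseline
(`boolean_ehi()`) and a single-class mode without neighbourhood effects
(`mode = "rh"`) are included for comparison. A synthetic-landscape
generator ships with the package, so the whole workflow runs without any
external data.

## A worked example

```r
library(fuzzyhab)

stack   <- make_four_class(scenario_spec("four_class", seed = 7))
profile <- species_profile()   # woodland species, urban-averse, 100-unit forager

boolean_ehi(stack, profile)$value
#> [1] 9.606052

glance(rfh_monte_carlo(stack, profile, n_iter = 50, seed = 11, mode = "rh"))
#>   metric            n_iter  mean   min   max    sd
#> 1 reachable_habitat     50  7.91  7.64  8.27 0.140

glance(rfh_monte_carlo(stack, profile, n_iter = 50, seed = 11, mode = "rfh"))
#>   metric                       n_iter  mean   min   max    sd
#> 1 reachable_functional_habitat     50  8.59  8.30  9.02 0.158
```

Reading: the crisp baseline says 9.6% of the landscape is connected
habitat — an overstatement, because arg-max classification counts whole
cells as woodland wherever woodland merely wins. The fuzzy single-class
estimate is lower (mean 7.9%) and comes with honest spread. The
functional-habitat estimate sits between (mean 8.6%): grassland foraging
spillover adds habitat that the single-class view misses, urban edge
effects remove some, and its distribution is wider because neighbourhood
effects move cells across the α-cut in both directions.

Transition softness propagates into metric uncertainty:

```r
lo <- make_single_patch(scenario_spec("single_patch_low_contrast",  seed = 3))
hi <- make_single_patch(scenario_spec("single_patch_high_contrast", seed = 3))
glance(habitat_amount_mc(lo, n_iter = 1000, seed = 21))$sd  # 20.4 m^2
glance(habitat_amount_mc(hi, n_iter = 1000, seed = 21))$sd  #  8.2 m^2
```

The ecotone-rich patch yields a habitat-amount distribution two and a half
times wider than the hard-edged one — the uncertainty is in the landscape,
not the method.

Results objects are tibble-first: `tidy()` returns per-iteration values,
`glance()` the summary row, `autoplot()` a histogram; surfaces plot with
`plot_surface()` / `autoplot()`. I/O uses multi-band 32-bit float TIFF
with a JSON sidecar (`write_class_stack()` / `read_class_stack()`), and
`inst/scripts/fuzzyhab` provides a small CLI (`generate`, `run`) over the
same functions.

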