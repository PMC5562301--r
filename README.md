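# paleorange

Two-tier demo-genetic inference of post-glacial range expansions for
island endemics, in R.

Many relict species survived the last glacial period in restricted
refugia and re-expanded afterwards. Their present genetic structure
records that history twice over: genome-wide SNP frequencies carry the
deep demography (how many ancestral populations, when they diverged, how
population sizes changed), and fine-scale microsatellite variation
carries the geography (where the expansions started and how terrain
shaped the advance). `paleorange` implements both readings as one tested
pipeline, aimed at population geneticists studying range expansions on
heterogeneous landscapes:

* **Non-spatial tier** — a continuous-time structured coalescent
  simulator for declarative demographic scenarios; maximum composite
  likelihood on the folded joint 2D site frequency spectrum,
  `CL = Σ_ij o_ij log p_ij` over polymorphic cells; AIC evidence ratios
  `exp(ΔAIC/2)`; parametric bootstrap; predictive checks (Weir &
  Cockerham F_ST, singleton fractions, heterozygosity).
* **Spatial tier** — forward stepping-stone expansion over an elevation
  raster (discrete logistic growth `N(1 + r(1 − N/K))`, zoned carrying
  capacities, migrant weights `∝ s(e_j)·exp(β Δe/100)` with logistic
  suitability `s`), a backward coalescent conditioned on the recorded
  per-generation demography, generalized stepwise microsatellite
  mutation, and ABC with MAD-standardized rejection plus
  regression adjustment, origin density maps with 50%/95% envelopes,
  leave-one-out cross-validation (SRMSE, great-circle error) and
  posterior predictive checks over a 159-statistic summary vector.
* **Synthetic-data module** — procedural island landscapes (central
  ridge, transverse valleys that set the three carrying-capacity zones),
  sampling designs and pseudo-observed datasets with recorded ground
  truth, so everything runs with no download.

## Worked example

Simulate a range expansion on a synthetic island, generate a
pseudo-observed microsatellite dataset at a known truth, and localize the
two expansion origins by ABC:

```r
library(paleorange)

g <- make_synthetic_landscape(12, 24, seed = 5,
       georef = list(xllcorner = 165, yllcorner = -22, cellsize = 0.03))
g
#> landscape_grid: 12 x 24 cells (1.73 km^2 each), 152 habitable
#>   NORTH CENTRAL   SOUTH
#>      46      60      46

# seed the two expansion origins ~30% in from each island tip
hab <- which(g$habitable, arr.ind = TRUE)
latv <- g$lat[g$habitable]; lonv <- g$lon[g$habitable]
ax <- (latv - min(latv)) / diff(range(latv)) +
  (lonv - min(lonv)) / diff(range(lonv))
on <- hab[which.min(abs(ax - quantile(ax, 0.8))), ]
os <- hab[which.min(abs(ax - quantile(ax, 0.2))), ]
base <- spatial_params(origin_north = on, origin_south = os,
                       k_north = 400, k_central = 400, k_south = 80,
                       anc_north = 800, anc_south = 300,
                       r = 3, m = 0.15, mu = 5e-4, p_gsm = 0.3,
                       t_exp = 60, t_div = 200, grid = g)
des <- default_sampling_design(g, seed = 2)   # 11 sites, 222 diploids
prior <- prior_spec(params = list(
  m = list(dist = "logunif", lower = 0.05, upper = 0.5),
  k_south = list(dist = "logunif", lower = 40, upper = 800),
  mu = list(dist = "logunif", lower = 1e-4, upper = 2e-3)))

tab <- run_reference_table(g, prior, des, n_sims = 700, seed = 41,
                           base_params = base)
po <- make_pseudo_observed_microsat(g, base, des, seed = 4001)
post <- abc_posterior(assemble_stat_vector(po$dataset), tab, g,
                      tolerance = 0.08, adjust = "linear")
round(posterior_median(post)[c("m", "k_south", "mu")], 4)
#>        m  k_south       mu
#>   0.1325 559.2143   0.0005
```

The true emigration rate is 0.15 and the true mutation rate 5e-4; the
posterior-median origin estimates land 4.6 km (north) and 7.0 km (south)
from the seeded truth on this ~75-km island. `origin_density(post, g)`
adds the highest-density envelopes and the distance between the two
density maxima.

On the non-spatial side, the reference two-refugium model (`2M`) carries
the study's fitted point estimates and predicts its differentiation
statistics:

```r
spec <- build_scenario_catalogue()$`2M`
pc <- predictive_check(list(estimate = spec$defaults), spec, seed = 101,
                       n_sequences = 1e5)
round(c(fst = pc$wc_fst, pc$singleton_fraction), 3)
#>   fst
#> 0.463 0.300 0.312
```

F_ST is the Weir & Cockerham estimate over the ~120k simulated SNPs; the
two other numbers are the fractions of private single-copy variants among
sites segregating within the northern and southern group.

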