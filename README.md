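# landres

Landscape genetics in R: optimized resistance surfaces, MLPE mixed models
of pairwise genetic distance, circuit-theory connectivity, and gravity
models of gene flow.

## What problem this solves

Field studies of dispersal rarely observe dispersal. Instead they genotype
individuals across a region and ask the landscape which features — terrain
ruggedness, canopy height, land cover, fire, rivers — explain who exchanges
genes with whom. `landres` implements that inference chain for
individual-based microsatellite data:

- **Genetic distances**: maximum-likelihood pairwise relatedness over the
  Cotterman coefficients (`estimate_relatedness`, `filter_related`),
  Rousset's â (`rousset_ar`), proportion of shared alleles D<sub>PS</sub>
  (`dps`).
- **Terrain and event surfaces**: ruggedness index (TRI), topographic
  position index (TPI), truncated-quartic kernel point density
  (`tri`, `tpi`, `point_density`).
- **Resistance surfaces**: the eight Monomolecular / Ricker transformation
  families with shape and maximum parameters, categorical class
  assignments, and additive composites (`transform_spec`,
  `apply_transform`, `apply_categorical`, `combine_surfaces`).
- **Circuit theory**: commute distances
  C(i,j) = vol(G) · (L⁺<sub>ii</sub> + L⁺<sub>jj</sub> − 2 L⁺<sub>ij</sub>)
  on eight-neighbor conductance graphs, and cumulative current-flow maps
  (`conductance_graph`, `commute_distance`, `current_map`).
- **MLPE regression**: y<sub>ij</sub> = β₀ + Σ β<sub>m</sub> x<sub>m,ij</sub>
  + u<sub>i</sub> + u<sub>j</sub> + ε<sub>ij</sub>, the mixed model for
  dyadic data in which each pair loads on the random effects of its two
  members (`fit_mlpe`, `aicc`, `ibd_regression`).
- **Optimization**: a genetic algorithm over transformation parameters
  maximizing MLPE log-likelihood of commute distances against genetic
  distance, with independent repeats and per-family local refinement
  (`optimize_surface`, `optimize_composite`).
- **Model selection**: bootstrap subsampling of individuals with AICc
  ranking — average rank, Akaike weight ω̄, and top-model frequency π̂
  (`bootstrap_select`).
- **Gravity models**: singly-constrained log-log mixed models separating
  between-site resistance (c), distance (ω), and within-site attraction
  (υ) on the saturated dyad network (`build_gravity_network`,
  `fit_gravity`, `gravity_model_table`).
- **Synthetic studies**: autocorrelated landscapes, genotypes structured
  by a known true resistance surface, and gravity networks with planted
  effects (`make_landscape`, `simulate_genotypes`,
  `simulate_genetic_distances`, `simulate_gravity_network`), plus an
  end-to-end `run_pipeline()` driven by a YAML-able config.

## Worked example

A complete synthetic study: simulate genotypes structured by a known
Monomolecular resistance surface, recover the surface by GA, and rank it
against the distance-only null.

```r
library(landres)

land  <- make_landscape("smooth", 40, 40, seed = 11, range = 6)
locs  <- sample_locations(land, 60, seed = 12, min_separation = 200)
truth <- synthetic_truth(transform_spec("Monomolecular", 3, 100), seed = 13)
gen   <- simulate_genetic_distances(truth, land, locs)

opt <- optimize_surface(land, gen, locs, kind = "continuous",
                        cfg = ga_control(pop_size = 20, max_generations = 30,
                                         stall_generations = 8, n_runs = 2),
                        seed = 5)
opt
#> <optimization_result>
#>   best objective (ML logL): -1207.7911
#>   runs: -1207.7913, -1207.7911 (converged)
#> <transform_spec> Monomolecular, shape = 2.376, maximum = 5000

best <- apply_transform(rescale_surface(land), opt$best_spec)
cands <- list(optimized = commute_distance(conductance_graph(best), locs),
              Distance  = euclidean_distances(locs))
bootstrap_select(cands, gen, frac = 0.75, iters = 500, seed = 7)
#>   candidate k avg_rank    omega_bar pi_hat
#> 1 optimized 3        1 1.000000e+00    100
#> 2  Distance 3        2 1.468762e-25      0
```

The optimizer recovers the generating family (Monomolecular; shape 2.38
against a truth of 3 under sampling noise, with the maximum running to the
search bound because the likelihood is nearly flat in the maximum once the
surface's cost ordering has saturated), the two independent runs agree to
four decimals, and the optimized surface wins every bootstrap iteration
against isolation by distance. `fit_mlpe(gen, list(commute =
cands$optimized))` exposes the underlying coefficients, variance
components, log-likelihood, and AICc; `current_map()` renders where the
recovered surface concentrates gene flow.

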