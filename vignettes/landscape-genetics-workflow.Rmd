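---
title: "Inferring environmental drivers of dispersal with landres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring environmental drivers of dispersal with landres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dispersal leaves a genetic signature: individuals separated by landscapes
that are easy to cross exchange more genes than individuals separated by
hostile terrain. `landres` implements the individual-based inference chain
that turns that signature into estimates of which environmental features
drive dispersal:

1. **Genetic distances** between individuals from microsatellite
   genotypes — maximum-likelihood pairwise relatedness (for filtering
   close kin), Rousset's a-hat (a dissimilarity), and the proportion of
   shared alleles Dps (a similarity used as a gene-flow measure).
2. **Resistance surfaces**: environmental rasters mapped to
   cost-of-movement via parametric transformation curves.
3. **Commute distances**: circuit-theory resistance distances between
   sampling locations on the eight-neighbor conductance graph of a
   resistance raster.
4. **MLPE mixed models** linking genetic distance to commute distance
   while respecting the non-independence of dyads that share an
   individual.
5. A **genetic algorithm** searching transformation space for the
   resistance parameterization with the highest MLPE likelihood.
6. **Bootstrap model selection** across optimized surfaces (average AICc
   rank, Akaike weight, top-model frequency).
7. **Gravity models** separating between-site resistance from
   within-site attraction on the saturated dyad network.

Because the workflow is usually applied to unrepeatable field data, the
package ships a synthetic-data module that generates every input with the
statistical structure the analysis assumes, so each stage can be validated
against a known truth.

## Models and conventions

### Genetic distances

Relatedness is estimated per dyad by maximizing the multilocus likelihood
over the Cotterman coefficients $(k_0, k_1, k_2)$ — the probabilities of
sharing 0, 1 or 2 alleles identical by descent — with the no-inbreeding
constraint $k_1^2 \ge 4 k_0 k_2$ and $r = k_2 + k_1/2$. The log-likelihood
is concave on the simplex, so the unconstrained optimum is found from four
canonical starts (unrelated, half-sib, full-sib, parent-offspring); when
it violates the constraint, the constrained optimum lies on the boundary
curve $(a^2,\, 2a(1-a),\, (1-a)^2)$ and is located by a one-dimensional
search. Sample allele frequencies are used unless the caller supplies
reference frequencies. Kin filtering is greedy by descending number of
above-threshold partners (ties to the lexicographically smallest id),
which tends to keep the most individuals; dyads exactly at the threshold
are retained.

Rousset's a-hat for a dyad is $(\bar Q_w - Q_{ij}) / (1 - \bar Q_w)$ with
$Q_{ij}$ the mean identity of the four cross-individual allele draws and
$\bar Q_w$ the mean within-individual identity across the sample. Loci are
pooled as a ratio of sums (numerators and denominators summed over loci
before dividing), the convention of the estimator family; loci missing in
either member are dropped from that dyad only.

### Resistance transformations

Continuous surfaces are affinely rescaled to $[0, 10]$ and pushed through
one of eight curves built from two bases — Monomolecular
$g(x) = 1 - e^{-x/s}$ and Ricker $g(x) = x e^{-x/s}$ — with "Reverse"
evaluating at $10 - x$ and "Inverse" reflecting vertically. The result is
rescaled so resistance spans exactly $[1, \text{maximum}]$. A degenerate
"Distance" family (flat surface) represents the isolation-by-distance
null and lets a composite component become non-influential. Categorical
surfaces assign one resistance per class with a reference class fixed
at 1. Composites are cell-wise sums re-anchored to a minimum of 1
(resistances act as additive costs; the upper search bound doubles from
5,000 to 10,000 for composites, mirroring that additivity).

One numerical subtlety: the final min/max anchoring uses the *observed*
cell values, so for non-monotone (Ricker) curves the exact location of
resistance 1 depends on how densely the raster samples the curve's peak.
On the 40 x 40 and larger grids used here the difference from anchoring on
the theoretical curve is negligible.

### Commute distances and current maps

A resistance raster becomes an undirected graph whose nodes are
non-missing cells; an edge's conductance is the reciprocal of the mean
resistance of its two cells, with diagonal edges divided by $\sqrt 2$
(geometry correction, the convention of the commute-distance
implementation this mirrors). The commute distance is
$C(i,j) = \mathrm{vol}(G)\, (L^+_{ii} + L^+_{jj} - 2 L^+_{ij})$; it equals
the expected round-trip steps of the random walk, which the test suite
verifies by direct simulation. The pseudoinverse columns are obtained by
grounding one node and factoring the reduced Laplacian once (sparse
Cholesky), which is exact up to solver tolerance (~1e-10 in practice) and
scales to raster graphs. Query coordinates snap to the nearest non-missing
cell center, ties toward the lower row then column index. Current maps
solve the same linear system per node pair and accumulate per-cell current
magnitude (half the summed absolute incident edge currents, so a cell on a
single series path carries exactly the injected current).

### MLPE regression

The model is $y_{ij} = \beta_0 + \sum_m \beta_m x_{m,ij} + u_i + u_j +
\varepsilon_{ij}$ with iid normal node effects $u$. Writing $Z$ for the
dyad-by-individual incidence matrix (two ones per row), the covariance is
$\sigma^2_\varepsilon (I + \theta Z Z^\top)$ with
$\theta = \sigma^2_u / \sigma^2_\varepsilon$. $\beta$ and
$\sigma^2_\varepsilon$ are profiled out in closed form; the remaining
one-dimensional likelihood in $\log\theta$ is maximized to high precision,
with the Woodbury identity reducing every solve to the number of
individuals rather than the number of dyads. ML is used for model
comparison and optimization; REML is available. Predictors are z-scored.
The test suite verifies the fit against an independent route — `lme4` with
the random-effects design matrix replaced by the dyad incidence — to
6+ digits in both ML and REML.

Information criteria follow the conventions under which published
optimized-surface tables are reproducible from their log-likelihoods:
$\mathrm{AICc} = -2\ell + 2k + 2k(k{+}1)/(n{-}k{-}1)$ with $n$ the number
of genotyped individuals and $k$ the per-surface transformation parameter
count (4 for continuous surfaces, the class count for categorical ones,
2 for the distance null). Both choices are deliberate and verified by the
acceptance tests; the package also reports each fit's own parameter count
(slopes + intercept + two variance components) when no table convention is
imposed.

### Surface optimization

The genetic algorithm searches family (categorical gene), $\log s$ in
$[\log 0.01, \log 100]$ and $\log(\text{maximum} - 1)$ jointly, with
tournament selection, uniform crossover, Gaussian mutation, elitism, and
a stall rule (stop after 25 generations without 0.1 log-likelihood units
of improvement; smaller budgets are used in tests). Commute matrices are
cached by parameter signature. After the population search, the best
genome of each of the top three transformation families is refined by
Nelder-Mead with the family fixed; the refined optimum is returned. The
search runs at least twice independently and flags runs disagreeing by
more than 0.5 log-likelihood units instead of merging them.

A genuine identifiability limit is worth knowing: a Ricker curve whose
shape parameter exceeds the rescaled domain (peak beyond $x = 10$) is an
increasing, saturating curve nearly indistinguishable from a
Monomolecular one. On noisy draws the maximum-likelihood family can
therefore legitimately land on the neighboring family even when the
generating family was Monomolecular; the per-family refinement removes
search-driven misses, and the remainder are data-driven ties, not
optimizer failures.

### Bootstrap model selection

Each iteration subsamples 75% of individuals without replacement,
restricts every candidate distance matrix to the subsample's dyads, refits
the MLPE model per candidate (no re-optimization), and ranks candidates by
AICc. Reported per candidate: average rank, average Akaike weight
$\bar\omega$, and $\hat\pi$, the percentage of iterations ranked first
(the bootstrap analogue of $\omega$). Subsampling is by individuals —
applying the 75% convention to the genotyped sample. Exact AICc ties break
toward fewer parameters, then uniformly at random within the seeded RNG,
so two identical candidates split $\hat\pi \approx 50/50$ while the
summary stays bit-reproducible under a fixed seed.

### Gravity models

The singly-constrained gravity model regresses $\log D_{PS}$ on
$\log(\text{distance})$, log within-site attributes of the destination
site, and log between-site resistance distances, with a random intercept
per origin individual as the single constraint (a destination-side
constraint is available). Fits use REML via `lmer` with Satterthwaite
degrees of freedom; $\mathrm{AIC} = 2k_{\mathrm{eff}} - 2\ell$ with
$k_{\mathrm{eff}}$ = fixed effects + 2 variance components, the convention
that reproduces published gravity tables. REML likelihoods are comparable
only across models sharing a fixed-effects design; an ML refit option
exists for strict nested comparisons and the model table notes the fit
type used. Zero responses are raised by half the smallest positive value
(configurable) and non-positive covariates are shifted before logging;
both adjustments announce themselves.

## What the synthetic module emulates — and what it does not

`make_landscape()` produces Gaussian-filtered noise fields (autocorrelated
continuous surfaces), multiscale ridged DEMs, and quantile-thresholded
categorical maps. `simulate_genetic_distances()` draws directly from the
MLPE generative model on the true resistance surface. Defaults are
$\beta = (0, 1)$ on the standardized commute distance with
$\sigma^2_u = \sigma^2_\varepsilon = 0.2$ — a strong but noisy
isolation-by-resistance signal of the kind a significant landscape effect
leaves in microsatellite data. `simulate_genotypes()` generates site
allele frequencies from a logistic-normal field whose between-site
correlation decays exponentially with commute distance
($e^{-c_{ij}/\mathrm{decay}}$, commute standardized to unit dyad SD,
decay 0.5 by default), then draws diploid genotypes; planted clone and
parent-offspring dyads exercise the kin filter.
`simulate_gravity_network()` plants log-linear distance and attraction
effects with an origin random effect.

These generators validate the *inference machinery*, not population
genetics at large: there is no mutation model, no drift through time, no
linkage, and allele-frequency correlation stands in for coalescent
history. Passing recovery tests therefore shows the chain estimates what
it claims to estimate when its assumptions hold — it does not certify
performance on demographically complex real data. Forward-time or
coalescent simulation is an explicit non-goal; the frequency-correlation
design keeps the full test suite at desk scale (minutes, not hours).

## Problem sizes and numerical choices

Tests and the acceptance script run on 40 x 40 rasters with 50-60
sampling locations (mirroring a ~60-individual field study), 200
replicates for MLPE slope recovery, 500 bootstrap iterations, and GA
populations of ~20 over <= 30 generations — sizes at which each stage's
Monte-Carlo error is far below the effects being recovered. The MLPE
profile likelihood is optimized to 1e-9 on $\log\theta$ with the
$\theta = 0$ boundary checked explicitly; Laplacian solves use sparse
Cholesky with one grounded node; commute matrices are clamped at 0 to
absorb roundoff on near-coincident nodes. Degenerate inputs fail loudly:
constant surfaces cannot be rescaled, monomorphic genotype tables cannot
support relatedness, disconnected query nodes name their components.

## Known limitations

- Family identification near the Monomolecular/large-shape-Ricker
  boundary is data-limited (above).
- Whether composite resistances should be re-anchored to 1 after
  summation is a convention, not an identity; re-anchoring leaves commute
  *orderings* unchanged but shifts the volume term. The composite tests
  check ordering-level agreement for that reason.
- The bootstrap treats optimized surfaces as fixed, so $\hat\pi$ reflects
  selection uncertainty conditional on the optimized parameterizations,
  not joint optimization uncertainty.
- Gravity degrees of freedom come from Satterthwaite approximation on the
  saturated directed network; dyadic dependence beyond the origin
  constraint is not modeled.
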