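# taxabias

Quantifying taxonomic bias in research interest: species-level citation
indices and Bayesian phylogenetic Poisson mixed models, with multiple
imputation, multi-tree posterior pooling, and a synthetic-data generator
so the entire pipeline runs and is tested offline.

## What it does

Research attention is distributed extremely unevenly across species. This
package measures that bias and models its drivers:

* **Citation indices** per species from per-publication citation records:
  the h-index (largest *n* with *n* publications cited ≥ *n* times), the
  m-index (h per year since first publication), h5 (h over the last five
  calendar years) and i10 (publications with ≥ 10 citations), plus the
  log10(h+1) display transform.
* **Species-table harmonization**, offline: synonym resolution against an
  explicit mapping table, subspecies removal, deduplication with conflict
  reporting, Boolean `TITLE-ABS-KEY(...)` search-string construction, and
  condensation of the 30 mammalian orders into 5 major clades.
* **Multiple imputation** of missing traits (body mass, latitude, IUCN
  status) by chained equations with predictive mean matching.
* **The model**: for species *i*,

  ```
  h_i ~ Poisson(exp(x_i' beta + a_i + e_i))
  a   ~ MVN(0, sigma2_phylo * A)        # A from the tree, unit diagonal
  e_i ~ N(0, sigma2_overdisp)           # additive overdispersion
  ```

  fitted by an adaptive Metropolis-within-Gibbs sampler (C++ core), one
  run per (tree, imputation) pair, posteriors pooled across runs with
  provenance. Phylogenetic heritability

  ```
  H2 = sigma2_phylo / (sigma2_phylo + sigma2_overdisp + ln(1 + 1/mean(h)))
  ```

  (the count-model analogue of Pagel's lambda) is derived per draw, and
  variance-inflation factors diagnose predictor collinearity.
* **A synthetic-data module** (Yule trees, trait tables, latent
  phylogenetic Poisson counts, citation profiles with an exactly
  prescribed h-index, MCAR/MAR missingness) that defines the ground truth
  for every test.

Who it is for: researchers in macroecology / comparative biology who want
a tested, reproducible implementation of this analysis to run on their
own bibliometric extractions, and methodologists who want the sampler and
generator for simulation studies.

## Worked example

```r
library(taxabias)

tr  <- simulate_tree(200, seed = 1)                 # Yule tree, 200 tips
tt  <- simulate_traits(tr, seed = 2)                # complete trait table
truth <- simulation_truth(
  beta = c(-1, 0.1, 0.02, -3.5, 0.6, 0.3, -0.2, 0.5),
  sigma2_phylo = 1, sigma2_overdisp = 0.5, seed = 3)
tt$h <- simulate_latent_counts(tr, tt, truth)$h     # per-species h

mean(tt$h == 0)                                     # 0.46 — point mass at h = 0
dm  <- build_design(tt, variant = 1)
fit <- fit_phylo_poisson(tt$h, dm, tr, chain_config(), seed = 4)
tidy(fit)
#>    term                           type    estimate conf.low conf.high
#>  1 (Intercept)                    fixed    -1.40   -2.16      -0.718
#>  2 log10_body_mass                fixed     0.0867 -0.0830     0.259
#>  3 abs_latitude                   fixed     0.0181  0.0113     0.0258
#>  4 iucn_poly1                     fixed    -3.79   -5.56      -2.25
#>  5 iucn_poly2                     fixed     1.37    0.224      2.63
#>  6 human_use                      fixed     0.164  -0.275      0.588
#>  7 domestication                  fixed     1.00    0.321      1.66
#>  8 log10_search                   fixed     0.509   0.164      0.859
#>  9 Phylogeny                      random    0.145   0.00513    0.487
#> 10 Nonphylogeny                   random    0.973   0.534      1.49
#> 11 Phylogenetic heritability (H2) derived   0.0891  0.00321    0.278

phylo_heritability(fit)
#> Phylogenetic heritability H2: 0.089 (95% CI 0.003, 0.278)
```

Each fixed-effect row is the posterior mean and central 95% credible
interval of that coefficient on the log citation rate: here absolute
latitude, the U-shaped IUCN contrasts and the search-interest effect are
recovered cleanly, while rare covariates (domestication: six non-wild
species in this draw) and the variance split are weakly identified at
200 species — their intervals are wide, and the H2 point estimate is
correspondingly noisy. `autoplot(fit)`, `plot_trace(fit)` and
`plot_h_distribution()` visualize the results; `run_pipeline()` chains
the whole analysis (simulate → indices → impute → fit per tree ×
imputation → pool → report) and writes a manifest with seeds and file
digests.

A thin command-line wrapper over the same functions ships in
`inst/cli/taxabias.R` (subcommands `run-all`, `simulate`, `indices`,
`impute`).

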