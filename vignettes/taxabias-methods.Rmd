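---
title: "Methods: citation indices and the phylogenetic Poisson mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: citation indices and the phylogenetic Poisson mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxabias)
```

## The problem

Scientific attention is spread very unevenly across species: a handful of
mammals dominate the literature while a third or so of species have never
been the subject of a cited paper. `taxabias` provides the statistical
machinery to quantify that bias. Research interest in a species is
summarized by its *h*-index — the largest number *n* of publications about
the species cited at least *n* times each — and the h-index is then
modeled as a function of species traits while controlling for shared
evolutionary history.

All of the package's tooling runs on synthetic data generated by the
package itself, so the full pipeline (indices, harmonization, imputation,
model fitting, pooling) is testable offline, with known ground truth.

## Citation indices

For one species with publication citation counts $c_1, \dots, c_m$:

* $h = \max\{n : \#\{i: c_i \ge n\} \ge n\}$, 0 for an empty profile;
* $m\text{-index} = h / \max(1,\; y_{census} - y_{first})$ — the
  denominator is the integer calendar-year difference, clamped at 1 so a
  first publication in the census year is well defined (fractional years
  are not used; publication dates are only resolved to years here);
* $h5$ = the h-index restricted to the five calendar years
  $[y_{census}-4, y_{census}]$ inclusive — "the past 5 years" needs a
  boundary convention, and the inclusive five-year window is the one used
  by Google Scholar's h5;
* $i10$ = number of publications with $\ge 10$ citations.

Ties and duplicated citation counts need no special treatment under the
max-$n$ definition. The display transform is $\log_{10}(h+1)$; modeling
always uses the raw counts.

## The model

For species $i$ with h-index $h_i$:

$$h_i \sim \mathrm{Poisson}(\exp(\mathbf{x}_i^\top\boldsymbol\beta + a_i + e_i)),
\qquad \mathbf{a} \sim \mathrm{MVN}(\mathbf{0},\,\sigma^2_{phylo}\mathbf{A}),
\qquad e_i \sim \mathrm{N}(0,\,\sigma^2_{od}),$$

where $\mathbf{A}$ is the phylogenetic correlation matrix
($A_{ij}$ = shared root-to-MRCA path length, scaled to unit diagonal) and
$e_i$ is an observation-level ("additive overdispersion") effect
absorbing extra-Poisson variance. The fixed effects are: log10 body mass,
absolute median latitude (signed latitude is simulated and stored; the
model uses $|$latitude$|$), first- and second-degree orthogonal-polynomial
contrasts of the six-level IUCN Red List status (scored 1..6 from Least
Concern to Extinct in the Wild; "Extinct" and "Data Deficient" are outside
the modeled scale), documented human use (0/1), domestication
(wild = 0, partially domesticated = 1, domesticated = 2; model variant 1
only — the coding is configurable via `build_design()` because the sign
convention of an ordinal score is a modeling choice, not a fact), and
log10(search interest + 1). Model variant 2 drops the domestication
column and is fitted to wild species only.

The IUCN contrasts are Gram–Schmidt orthogonalizations of the score and
its square against the constant, normalized to unit length on the fitted
sample. A consequence worth knowing: coefficients on these columns scale
with $\sqrt{n}$, so they are numerically large in big samples and weakly
identified in small ones.

Phylogenetic heritability on the latent (log) scale is

$$H^2 = \frac{\sigma^2_{phylo}}
{\sigma^2_{phylo} + \sigma^2_{od} + \ln(1 + 1/\bar h)},$$

the count-model analogue of Pagel's $\lambda$; the $\ln(1+1/\bar h)$ term
is the distribution-specific observation-level variance of a log-link
Poisson. $\bar h$ is the arithmetic mean of the counts actually entering
the model (the fitted subset, not any larger corpus) — when rows are
filtered, the variance decomposition should refer to the data that
produced it.

## The sampler

`fit_phylo_poisson()` uses a Metropolis-within-Gibbs scheme written in
C++:

* **Fixed effects**: one multivariate random-walk block proposal whose
  covariance is adapted (Haario-style running covariance) and whose scale
  targets ~0.23 acceptance during burn-in.
* **Phylogenetic effects**: non-centered parameterization
  $\mathbf{a} = \sigma_{phylo} \mathbf{L}\mathbf{u}$ with
  $\mathbf{L}$ the lower Cholesky factor of $\mathbf{A}$ and
  $u_i \sim N(0,1)$; univariate adaptive random walks on each $u_i$
  targeting ~0.44 acceptance.
* **Overdispersion effects**: univariate adaptive random walks on each
  $e_i$, same target.
* **Variances**: conjugate inverse-gamma Gibbs draws.
  $\sigma^2_{od}\,|\,\mathbf{e}$ is standard. For $\sigma^2_{phylo}$ an
  interweaving step is used: conditioning on
  $\mathbf{a}$ (sufficient parameterization), draw
  $\sigma^2_{phylo} \sim \mathrm{IG}(a_0 + n/2,\; b_0 +
  \mathbf{a}^\top\mathbf{A}^{-1}\mathbf{a}/2)$ — with the whitened state
  the quadratic form is just $\sigma^2_{phylo,old}\,\mathbf{u}^\top\mathbf{u}$
  — then rescale $\mathbf{u}$ so $\mathbf{a}$ (and the likelihood) is
  unchanged. This mixes the variance without the slow random-walk
  behaviour of a purely non-centered scheme.

Priors: $\beta_j \sim N(0, 10^8)$ and
$\sigma^2 \sim \mathrm{IG}(0.001, 0.001)$ for both components — a
conventional reading of "noninformative", and configurable
(`chain_config()`). Adaptation runs only during burn-in, so the retained
chain is a fixed-kernel Markov chain. All randomness flows through R's
RNG: a seed makes a fit bit-reproducible.

Numerical choices: $\mathbf{A}$ gets up to three rounds of $10^{-8}$
diagonal jitter before a Cholesky failure becomes an error; non-finite
proposal log-ratios are rejected; a non-finite latent state aborts the
chain with its iteration index. Posterior summaries sort draws before
averaging so pooled summaries are bit-identical under permutation of the
runs.

Validation is by three independent oracles in the test suite: the
zero-variance limit against the IRLS Poisson GLM solution (`stats::glm`),
a prior-only chain against inverse-gamma prior quantiles, and parameter
recovery plus credible-interval coverage against simulation truth.

### Chain sizes

The survey-scale protocol (130,000 iterations, 30,000 burn-in, thinning
to 1,000 stored draws, last 100 retained per run, 10 imputations x 50
trees = 500 runs) is expressible through `chain_config()` and
`pipeline_config()`. The package defaults are desk scale: 20,000
iterations, and in recovery work half the chain is spent on burn-in and
adaptation — with a few hundred species the sampler settles within a few
thousand iterations, and a 200-tip fit takes seconds. The pipeline
default (a few thousand iterations per run over a handful of trees and
imputations) is sized for interactive use; both scales use the same code
path.

## Multiple imputation

`impute_traits()` implements chained equations with predictive mean
matching (PMM): each incomplete variable is regressed on all others, the
coefficients are drawn from their Bayesian sampling distribution, and
each missing cell receives the observed value of one of the $k = 5$
donors with the closest predicted mean. Ten sweeps (`n_cycles = 10`) and
$m = 10$ completed tables are the conventional defaults; desk-scale
pipelines use fewer. The ordinal IUCN status is imputed by PMM on its
1..6 score, so imputed values are always valid levels; continuous
variables always land in the observed support. The species name is an
identifier, never a predictor. Per-imputation seeds are split
deterministically from the master seed, so streams are independent but
reproducible, and observed cells are bit-identical across all $m$ tables.

Pooling happens on posterior draws, not on point estimates: one model per
(tree, imputation) pair, the last draws of each run concatenated with
provenance tags (`pool_runs()`). This propagates both imputation and
phylogenetic uncertainty into a single posterior and is why no
Rubin's-rules combination step exists in the package.

## The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions for every downstream test:

* **Trees**: constant-rate pure-birth (Yule) trees, ultrametric by
  construction, tips labelled with deterministic pseudo-Latin binomials.
  A single-rate Yule process is the simplest ultrametric generator;
  uncertainty across phylogenies is emulated by resimulating topologies
  per seed, mirroring the multi-tree design of real analyses.
* **Traits**: log10 body mass normal (default mean 2.4, SD 1.2 decades —
  a few-hundred-gram typical mammal with rodents-to-whales spread);
  signed latitude uniform within bounds; IUCN status categorical with a
  Least-Concern-dominated default; rare domestication (0.2% / 1.8% /
  98%); Bernoulli human use (19%); zero-inflated exponential search
  interest (80% zeros). These marginal shapes are desk-scale stand-ins
  chosen once to resemble published mammalian trait summaries.
* **Counts**: the exact model above, with truth retained for recovery
  tests. The default effect vector puts a U-shaped IUCN effect (negative
  linear, positive quadratic contrast) and positive body-mass, human-use
  and search effects on the log rate, at magnitudes that reproduce a
  right-skewed h distribution with a point mass at zero (checked by a
  property test: $\Pr(h=0) > \Pr(h=k)$ for all $k \ge 5$).
* **Citation profiles**: `synthesize_citation_profile()` is a
  constructive inverse of the h-index — `target_h` papers cited at least
  `target_h` times plus extras cited at most `target_h` times — so the
  profile's computed h equals the target exactly, for every target. The
  number of extra low-cited papers is discretized log-normal, giving the
  heavy right tail seen in real citation data. The record-level simulator
  is a testing device: no claim is made that real citation profiles arise
  from traits this way.
* **Missingness**: MCAR or MAR; the MAR mechanism conditions on the
  always-observed h and human-use columns (matching the predictor set a
  real imputation would lean on), with the logistic intercept calibrated
  so the realized missingness rate equals the target. Default synthetic
  scale is 200–500 species.

What passing tests therefore show: the indices, the design construction,
the imputation machinery and the sampler are correct on data generated by
this model. What they do not show: that real bibliometric corpora follow
a phylogenetic Poisson mixed model, that real missingness is MAR, or
that synonym lists are complete — those are substantive assumptions of
any real analysis, not properties of the software.

## Species-table harmonization

Offline only: synonym resolution uses an explicit synonym-to-accepted
mapping file rather than a live taxonomy service, which makes runs
reproducible; records under subspecies names (three or more tokens) are
dropped; duplicate records under one accepted name merge first-seen-wins
with every conflict reported. Boolean search strings
(`TITLE-ABS-KEY("..." OR "...")`, accepted name first, synonyms in
lexical order) are emitted for use against literature databases, and a
bundled lookup condenses the 30 mammalian orders into the 5 major clades
(Afrotheria, Xenarthra, Euarchontoglires, Laurasiatheria, Marsupials and
Monotremes); unknown orders error rather than guess.

## Known limitations

* The variance components are weakly identified at desk scale (a few
  hundred species): posteriors for $\sigma^2_{phylo}$ are wide and $H^2$
  point estimates are noisy. That is a property of the model at small
  $n$, not of the sampler; survey-scale data narrow them.
* Univariate latent-effect updates cost $O(n^2)$ per sweep; fits with
  thousands of tips are feasible but minutes-scale rather than
  seconds-scale.
* The search-interest index enters as a continuous
  $\log_{10}(x+1)$ covariate; treating such an index as binary
  (used/not used) is a defensible alternative that the design function
  does not currently offer.
* Imputation noise in covariates attenuates their coefficients and
  inflates the overdispersion component relative to a complete-data fit;
  with many missing cells the pooled fixed effects should be read
  accordingly.
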