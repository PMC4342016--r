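# phylorao

Taxonomic and phylogenetic diversity partitioning along forest
modification gradients.

## What it does, and for whom

Community ecologists comparing how *taxonomic* diversity (TD) and
*phylogenetic* diversity (PD) respond to habitat modification — locally
(α) and across a landscape (β), for several species groups such as
successive tree life stages and birds — face a pipeline that is easy to
get subtly wrong: Rao quadratic-entropy partitioning with its corrections,
tip-shuffle null models, environmental ordination, multimodel inference,
and spatially explicit β-diversity statistics. `phylorao` implements that
pipeline end to end, tidyverse-style (data frames in, tibbles out), with a
synthetic-landscape generator so every stage can be calibrated and
power-tested without field data.

The core quantities:

* **Rao quadratic entropy** `Q = Σᵢ Σⱼ d_ij p_i p_j` — expected
  dissimilarity of two random individuals; Gini–Simpson with unit
  distances (TD), phylogenetic diversity with patristic distances (PD);
  corrected to equivalent numbers `1/(1−Q)` after rescaling `d` to [0,1].
* **Multiplicative pairwise β** `(γ_pair − ᾱ)/γ_pair × 100`, with an
  optional two-community-maximum correction.
* **SES** `(OBS − mean(EXP))/sd(EXP)` against uniform tip shuffles of the
  regional phylogeny; overdispersion (limiting similarity) and
  underdispersion (environmental filtering) flagged at α = 0.025 per tail.
* **Forest disturbance / forest loss** axes: PC1/PC2 of a
  correlation-matrix PCA of 15 plot-level forest variables, with
  broken-stick retention.
* **AICc model averaging** of mixed-effects (plants) and OLS (birds)
  diversity regressions over all marginality-respecting predictor subsets
  with ΔAICc < 2.0.
* **Partial Mantel tests**, **PCNM** spatial eigenvectors with double-stop
  forward selection, and three-set **variation partitioning** (adjusted
  R², inclusion–exclusion Venn fractions, permutation tests).

## Worked example

Simulate a survey-scale landscape in which environmental filtering
strengthens with forest disturbance and acts more strongly on saplings and
seedlings than on adult trees, then run both pipelines:

```r
library(phylorao)
set.seed(1)

bundle <- simulate_dataset(scenario_config("filtering"))
alpha <- run_alpha(bundle, n_perm = 500)
print(as.data.frame(dplyr::filter(alpha$coefficients,
                                  response == "plants_pd")), digits = 3)
#>    response n_models n_perm               term estimate    se adjusted_se     z        p importance
#> 1 plants_pd        1    500        (Intercept)  -0.3499 0.226       0.230 1.524 1.27e-01          1
#> 2 plants_pd        1    500  life_stagesapling   0.0311 0.271       0.275 0.113 9.10e-01          1
#> 3 plants_pd        1    500 life_stageseedling  -0.6761 0.271       0.275 2.456 1.41e-02          1
#> 4 plants_pd        1    500        disturbance  -0.9658 0.166       0.168 5.735 9.77e-09          1
```

The averaged disturbance coefficient on plant α-PD is strongly negative
(−0.97, p ≈ 1e-8): phylogenetic diversity falls as disturbance rises. The
seedling term sits significantly below the adult reference — the generated
time-lag signal in the regenerating cohort. `alpha$dispersion` tabulates
the per-plot dispersion classes behind it and `alpha$ses` holds every SES.

The landscape-scale analysis relates pairwise β-diversity to the
environmental axes, conditioned on space:

```r
beta <- run_beta(bundle, mantel_n_perm = 499, ses_n_perm = 500)
print(as.data.frame(dplyr::filter(beta$mantel, facet == "td",
                                  predictor == "disturbance")), digits = 3)
#>      group facet   predictor     r      p n_perm alternative
#> 1    adult    td disturbance 0.348 0.0000    499     greater
#> 2  sapling    td disturbance 0.247 0.0000    499     greater
#> 3 seedling    td disturbance 0.338 0.0000    499     greater
#> 4    birds    td disturbance 0.131 0.0381    499     greater
```

Taxonomic turnover tracks the disturbance gradient strongly for every
sessile plant stage and far more weakly for the mobile birds.
`beta$varpart` decomposes each β matrix into unique and joint adjusted-R²
fractions of disturbance, loss and the forward-selected PCNM axes;
`autoplot()` methods plot SES distributions, scree/broken-stick curves,
averaged coefficients and variation-partitioning fractions.

Robustness to phylogenetic uncertainty:

```r
bundle <- simulate_dataset(scenario_config("filtering"),
                           n_posterior = 50, jitter_cv = 0.1)
sweep <- posterior_sweep(bundle, n_sweep = 50)
sweep$alpha_terms   # across-tree mean/sd of averaged coefficients
```

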