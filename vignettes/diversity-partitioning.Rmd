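---
title: "Partitioning taxonomic and phylogenetic diversity along forest modification gradients"
author: "phylorao"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning taxonomic and phylogenetic diversity along forest modification gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorao)
```

## The scientific problem

Human modification of subtropical forests — within-forest disturbance and
the loss of forest cover — reshapes plant and bird communities, but its
fingerprint differs between *taxonomic* diversity (TD: how many species,
how evenly) and *phylogenetic* diversity (PD: how much evolutionary history
those species span), and between the local (α) and landscape (β) scales.
Comparing successive plant life stages (adult trees, saplings, seedlings)
against mobile taxa such as birds can further reveal time-lags: losses that
are already visible in the regenerating cohorts before they reach the
canopy.

`phylorao` implements this analysis as a reusable pipeline:

1. **Diversity** — Rao quadratic-entropy partitioning of α-, and pairwise
   β-diversity for both facets, with equivalent-number corrections.
2. **Null models** — tip-shuffle randomizations of the regional phylogeny
   and standardized effect sizes (SES) of PD, with dispersion
   classification.
3. **Environment** — condensation of plot-level forest characteristics
   into "forest disturbance" and "forest loss" axes by correlation-matrix
   PCA with broken-stick retention.
4. **Models** — AICc dredging and multimodel averaging of (mixed-effects)
   regressions of α-diversity on the environmental axes.
5. **Spatial** — partial Mantel tests, PCNM spatial eigenvectors,
   double-stop forward selection and three-set variation partitioning of
   β-diversity.
6. **Synthetic data** — a generator producing complete landscapes with
   known assembly processes, so every stage is testable without field data.

## The diversity model

Rao's quadratic entropy for a community with relative abundances $p_i$ and
pairwise species dissimilarities $d_{ij}$ is

$$Q = \sum_i \sum_j d_{ij} \, p_i \, p_j,$$

the expected dissimilarity between two randomly drawn individuals. With
$d_{ij} = 1$ for all distinct pairs, $Q$ is the Gini–Simpson index (the
taxonomic facet); with patristic distances summed along the phylogeny it
measures PD. Because raw $Q$ saturates, we apply the standard correction:
dissimilarities are first rescaled to $[0,1]$ by the regional maximum, and
$Q$ is transformed to an *equivalent number* $1/(1-Q)$ — the count of
equally abundant, maximally distinct species with the same entropy.

Pairwise β-diversity partitions the diversity of a plot pair
multiplicatively:

$$\beta = \frac{\gamma_{pair} - \bar\alpha}{\gamma_{pair}} \times 100,$$

where $\gamma_{pair}$ is the Rao diversity of the pooled pair (summed
counts, renormalized — an effort-weighted pooling; an equal-weight option
averages the two relative-abundance vectors instead) and $\bar\alpha$ the
mean of the two plot diversities. In the corrected form the
equivalent-number transform is applied to $\gamma$ and both $\alpha$s
first, and the proportional β is divided by its two-community maximum
$1 - 1/2$, so both forms live on a 0–100 scale. Both corrections are
independent flags recorded in the output, because published analyses
combine them in more than one way and the choice should be visible.

As a robustness alternative, the abundance-weighted mean pairwise distance
$\mathrm{MPD} = \sum_{i \ne j} d_{ij} p_i p_j / \sum_{i \ne j} p_i p_j$
is available as the α-PD response (note that some implementations include
conspecific pairs, which turns MPD into plain $Q$; ours excludes them, and
the test suite pins down the exact relation).

## The null model

Observed PD mixes two signals: how many species co-occur, and *which*
species. To isolate the second, community tables are held fixed while
species labels are shuffled uniformly across the tips of the **regional**
phylogeny — the pooled tree of all life stages, including plots without
bird counts — and the α- or β-PD recomputed per shuffle (3000 by default;
999 for the MPD check). The standardized effect size is

$$\mathrm{SES} = \frac{\mathrm{OBS} - \overline{\mathrm{EXP}}}{\mathrm{sd}(\mathrm{EXP})},$$

with the sample (n−1) standard deviation. A plot is *overdispersed* when
the fraction of null values ≥ observed falls below α = 0.025 (limiting
similarity), *underdispersed* when the fraction ≤ observed falls below
0.025 (environmental filtering), otherwise *random*. Ties count toward
both tails and the observed value is not added to the null set. A
monospecific plot has an identical diversity under every shuffle — null
standard deviation zero — and its SES is reported as *undefined*, never
silently dropped or zero-filled. Because the accumulator computes the null
variance from running sums, a relative floor of $10^{-6}$ on the null
standard deviation separates genuine nulls from floating-point residue
(taxonomic diversity under tip shuffles is the canonical degenerate case:
unit distances are shuffle-invariant, which is exactly why SES is only
meaningful for PD).

One shuffle per iteration is shared across all species groups, so
cross-stage comparisons see a common null; an independent-shuffle flag is
provided and recorded in the output attributes.

## Environmental axes

Fifteen plot-level variables (fragment size, edge length, perimeter/area,
seven vertical biomass layers, canopy cover, relative light, the Shannon
heterogeneity of the biomass profile, and two binary dummies for forest
type and surrounding matrix) enter a PCA on the correlation matrix — the
dummies as 0/1 numeric columns, whose point-biserial correlations are
well-defined. Broken-stick retention is computed and reported, but the
first two components are always exposed because the downstream models
require exactly a disturbance and a loss axis. Signs are fixed so that
higher PC1 means lower canopy cover ("forest disturbance") and higher PC2
means smaller fragments ("forest loss"); within a component the sign is
otherwise arbitrary, so fixing it keeps coefficient signs interpretable
across runs.

## Diversity regressions and model averaging

For the multi-stage plant data the global model is

```
response ~ life_stage * disturbance + loss + easting + northing + (1 | plot)
```

fitted by maximum likelihood (lme4), with `life_stage` a factor whose
reference level is the adult stage; for birds an ordinary least-squares
model without the stage terms. All continuous predictors are Z-transformed.
Every admissible subset of fixed terms is fitted (interactions only
alongside both parents — 40 models for the plant global model), ranked by
AICc with $k$ = fixed effects + residual variance (+ the random-intercept
variance when present). Models within ΔAICc < 2.0 of the best are averaged
with Akaike weights $w_m \propto e^{-\Delta_m/2}$: term estimates are
conditional averages over the models containing the term (full-model
zero-substitution averaging is available as an option), the unconditional
SE follows Burnham–Anderson
$\sqrt{\sum w_m (se_m^2 + (\hat\theta_m - \bar\theta)^2)}$, and the
adjusted SE uses the revised form with a per-model $t$/normal quantile
factor at $df = n - k$. Per-term importance is the summed weight of
retained models containing the term. Non-converging members are dropped
with a warning, never silently retained.

## Landscape-scale statistics

β-diversity responses are relatable to gradients only through distance
matrices, so the pipeline uses partial Mantel tests: the Pearson
correlation of the vectorized lower triangles of the β matrix and the
|Δgradient| matrix, conditioned on the Euclidean plot-distance matrix via
the first-order partial-correlation formula, with significance from
permutations of the response matrix only (999 by default, one-tailed).
Conditioning a matrix on itself is returned as r = 0 by construction.

Spatial structure enters variation partitioning through PCNM eigenvectors:
the plot distance matrix truncated at the longest minimum-spanning-tree
edge (beyond-threshold entries replaced by 4× the threshold),
double-centered and eigen-decomposed; the positive-eigenvalue eigenvectors
form an orthonormal multi-scale spatial basis (vegan's `pcnm` stands
behind this step). Eigenvectors are screened by forward selection on a
redundancy analysis with a double stopping rule: selection only starts if
the full-candidate model is significant at α = 0.050; each step admits the
candidate with the largest added variance only if its residual-permutation
F-test is significant; and selection stops once the cumulative adjusted R²
reaches the full model's. We deliberately retain the candidate whose
admission crosses that ceiling: rejecting it (as some implementations do)
discards a single dominant true predictor whenever noise candidates drag
the full model's *adjusted* R² below that of the good subset, which
defeats the criterion's purpose. An empty selection is a valid outcome and
propagates as a zero space fraction.

Because β matrices are dissimilarities, redundancy analysis operates on
their principal coordinates (Lingoes correction for negative eigenvalues,
switchable). R² is the explained-inertia fraction and the adjusted R² uses
Ezekiel's formula $1-(1-R^2)(n-1)/(n-p-1)$. Three-set variation
partitioning fits the seven marginal models (disturbance, loss, space,
each pair, all three), converts to adjusted R², and solves the unique,
pairwise-joint and triple-joint Venn fractions by inclusion–exclusion;
adjusted fractions may be slightly negative, which is reported rather than
clipped. Unique fractions are tested by partial permutation F-tests that
permute the residuals of the conditioning model.

## What the generator emulates — and what it does not

`scenario_config()` fixes the survey geometry at a realistic scale: 30 plots
in 5 forest-modification classes, a 166-species plant pool observed as
adults (70 individuals/plot), saplings (23) and seedlings (27), an
85-species bird pool on 27 plots, and plot coordinates in two reserve
clusters (within-cluster scatter 3 km). Latent class-level disturbance and
a weaker, partly independent loss gradient drive the 15 observed
environmental variables with a realistic loading pattern
(disturbance: canopy cover and high-layer biomass down, low-layer biomass
and light up; loss: fragment size and edge length down, matrix dummy
flips).

Communities assemble on a birth–death phylogeny (birth 1, death 0.3)
carrying a Brownian trait. Per plot and stage the sampling weight of
species $s$ is

$$w_s \;\propto\; \mathrm{SAD}_s \cdot \exp\!\big(-\lambda \,
  (t_s - \mathrm{opt})^2\big), \qquad
  \lambda = \mathrm{fs}_{stage} + \mathrm{de} \cdot \mathrm{disturbance},$$

with the optimum tracking disturbance (one trait SD per gradient unit) and
a lognormal regional species-abundance distribution (σ = 0.5) shared
across plots — without it, random draws from a 166-species pool show
near-complete turnover everywhere and the corrected β saturates. Negative
λ switches to limiting similarity: species are chosen sequentially with a
penalty on their similarity to the already-chosen set (richness matched to
a uniform multinomial draw), with a mild central habitat preference that
fades as repulsion deepens. The default *filtering* scenario makes
environmental filtering strengthen with disturbance and act more strongly
on saplings and seedlings than on adults — the regenerating cohorts feel
the contemporary environment; the adults span the full regime from
limiting similarity in intact forest to filtering in disturbed forest.
The *neutral* scenario (all strengths zero) reduces every plot to a
uniform-SAD multinomial draw and is the calibration standard for the null
model; *repulsion* applies limiting similarity everywhere.

The generator deliberately omits features of real data: dispersal
limitation and spatially autocorrelated composition beyond the
environment, observation error in species identification, stage-linked
demography (saplings are not thinned adults), and any phylogenetic
uncertainty beyond branch-length jitter (the posterior generator multiplies
branch lengths by lognormal noise around a fixed topology). Passing the
calibration and power tests therefore shows the *statistical machinery* is
correct and the design detectable under its assumptions — not that real
forests behave this way.

A consequence worth knowing when interpreting the power analyses: with a
single Brownian trait, whether a narrow trait band maps onto a clade (and
so whether filtering yields *phylogenetic* clustering) varies across tree
realizations. Deep trait-tail optima cluster almost always; mid-range
bands are occasionally phylogenetically scattered. The default scenario's
strength settings were chosen so that the disturbance signal on α-PD and
the compositional turnover signal on β-TD are both detectable at the
survey scale in the large majority of simulated landscapes; single
replicates can still be flat, exactly as a single empirical landscape
could be.

## Numerical choices and degenerate inputs

* Branch lengths are mandatory on input trees; missing lengths are a
  parse-level error, never zero-filled, because every dissimilarity is a
  sum of branch lengths. Zero-length terminal branches are allowed
  (polytomy resolutions produce them).
* All distance matrices are emitted in lexicographic label order for
  reproducible file diffs.
* Equivalent numbers require $Q<1$; after the $[0,1]$ rescale this holds
  by construction and is clamped at $1-10^{-12}$ against rounding.
* An uncorrected pooled diversity of zero (two monospecific plots sharing
  the species) defines β = 0, with a console note.
* Species present in a community table but absent from the distance matrix
  are a hard error, not a silent drop; species in the matrix but absent
  from a plot contribute $p = 0$.
* Mixed-model members that fail to converge are dropped from the dredge
  with a warning; the intercept-only model is always present, so the
  averaged set is never empty.
* All permutation machinery consumes R's global RNG stream: a single
  `set.seed()` before a pipeline call reproduces every result bit for bit.
  `posterior_sweep()` additionally derives one common seed for all sweeps
  (common random numbers), so an identical-tree posterior shows zero
  across-sweep spread.

## Problem sizes used by the test and acceptance suites

The statistical checks run at the following sizes, chosen to estimate the
relevant rates with useful precision: null-model calibration on 200
neutral landscapes (30 plots × 100 species, 500 shuffles each; the flag
rate is compared with the nominal 2 × 0.025); power on 50 filtering
landscapes at the full survey scale (500 shuffles, 199 Mantel
permutations); Mantel type-I rates on 1000 random-matrix datasets at 199
permutations; oracle equivalence on 100 random instances per estimator.
The acceptance script re-runs a reduced calibration (60 landscapes, 400
type-I datasets) alongside one full study-scale analysis.

## Known limitations

* The exact combination of Rao corrections used in any given published
  table is rarely recoverable; both corrections are exposed as flags and
  the uncorrected values are always available.
* Conditional model averaging reports terms present in only part of the
  retained set; its estimates are not shrinkage estimates, and the
  "importance" weights inherit the usual caveats of summed Akaike weights.
* The db-RDA route (PCoA + RDA) is one standard way to regress a
  dissimilarity response; raw-β regressions on distance classes are not
  implemented.
* P-values from forward selection are selection-inflated at each step (the
  best candidate is tested); the global pre-test keeps the family-wise
  false-start rate near α, but individual admitted noise axes remain
  possible.
```
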