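---
title: "Methods: from multi-amplicon counts to similarity models and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-amplicon counts to similarity models and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casvpipe)
```

This vignette documents the statistical procedures implemented by
`casvpipe`, the reasoning behind their default parameters, and what the
bundled synthetic-data generator does and does not emulate. The package is
organised as a pipeline for multi-amplicon gut-microbiome surveys of wild
mammal populations, where one faecal sample is profiled with several
primer pairs at once and repeated samples exist for some individuals.

## 1. Synthetic data with known ground truth

Real survey data cannot tell you whether a merging algorithm merged the
right things, because the truth is unknown. The generator therefore builds
the truth first and the observation second:

* `simulate_hosts()` draws a cohort of individuals organised into clans,
  with sex, a standardised social rank in [-1, 1], and a mother link;
  a fraction of individuals (default `repeat_fraction = 0.25`) is sampled
  two or three times, 30–365 days apart. Ages are drawn log-uniformly
  between 5 and 5800 days so juveniles and adults are both represented.
* `simulate_immune()` adds faecal IgA and mucin as linear functions of
  log-age plus noise, clipped at zero — enough structure for the
  downstream models to have something to find, without pretending to be an
  assay model.
* `simulate_latent()` builds per-sample log-abundances for each latent
  taxon: an intercept, optional slopes on log-age, IgA and mucin, plus
  clan, season and individual random effects and residual noise, then
  exponentiates. Taxa are assigned to bacterial, fungal and parasite
  components with genus labels drawn from component-appropriate pools.
* `amplicon_design()` and `render_amplicons()` turn the latent community
  into per-amplicon ASV count tables: each amplicon detects each taxon
  with some probability, splits a taxon's signal across its ASVs with
  gamma-distributed efficiencies, and draws negative-binomial sequencing
  depths and multinomial reads per sample. The returned `truth` table maps
  every ASV back to its taxon.

What is deliberately **not** emulated: chimeras and sequencing error
(ASVs are taken as correctly denoised input), primer-site evolution,
copy-number variation within a genome, contamination, and batch effects on
counts (batch exists only as a label for the dyadic model). The generator
is a validation harness, not a sequencing simulator.

## 2. Preprocessing

`filter_asvs_and_samples()` removes ASVs present in fewer than
`min_sample_prevalence = 2` samples and samples with fewer than
`min_reads = 100` reads (a sample with exactly 100 reads is kept). The two
filters interact — dropping a shallow sample can push an ASV below the
prevalence cutoff and dropping an ASV can push a sample below the read
cutoff — so they are iterated to a fixed point. This makes the operation
idempotent: filtering a filtered table is an identity, which the tests
assert. Every removal is recorded in a `removal_log` attribute.

`tss_normalize()` converts counts to relative abundances per sample and
`collate()` block-concatenates the per-amplicon tables over the union of
samples, zero-filling samples missing from an amplicon and retaining
ASV-to-amplicon provenance.

## 3. Merging ASVs into cASVs

A multi-amplicon design profiles each organism at several loci, so one
taxon surfaces as several ASVs whose relative abundances co-vary across
samples. `merge_casvs()` therefore:

1. groups ASVs by annotated genus;
2. within each genus, computes all pairwise Pearson correlations of
   relative abundance, with two-sided p-values from the exact
   t-transform on n − 2 degrees of freedom (`pairwise_pearson()`,
   validated against `cor.test` to 1e-12);
3. keeps edges with r > 0 and Benjamini–Hochberg adjusted p < `alpha`
   (default 0.01; adjustment per genus by default, or one global family
   with `bh_scope = "global"`, which can only be more conservative);
4. finds communities in each genus network by fast-greedy modularity
   clustering and sums the member ASVs' abundances into one cASV.

Two implementation notes. First, `bh_adjust()` writes out the textbook
step-up (sort, scale the i-th order statistic by m/i, running minimum from
the top, cap at 1) rather than delegating, so the arithmetic follows the
canonical `p * m / i` association; `stats::p.adjust` agrees up to one ulp.
Second, modularity clustering ties on an isolated two-node component and
can leave the pair split, but a connected pair *is* a community by the
merge criterion (one significant positive edge), so size-2 components are
merged directly.

Merging is conservative by construction: per-sample totals are preserved
exactly (group sums), singletons pass through unchanged, and merging never
crosses genus boundaries. On synthetic fixtures the recovered partition is
compared to the taxon truth by adjusted Rand index.

## 4. Beta-diversity and repeatability

`beta_diversity()` computes Bray–Curtis and binary Jaccard with
`vegan::vegdist`, and the Aitchison distance as Euclidean distance between
CLR-transformed compositions. The CLR pseudocount defaults to `1e-6`,
appropriate for relative abundances; a pseudocount of 0 is allowed only
for strictly positive tables (where CLR is exactly scale-invariant). A
Bray–Curtis distance between two all-zero samples is defined as 0 with a
warning. `to_similarity()` maps bounded metrics as s = 1 − d and min-max
normalises unbounded ones first.

`dicc()` measures how repeatable an individual's community is: a one-way
ANOVA decomposition on squared distances (within-group sum
$\sum_g \frac{1}{n_g}\sum_{i<j\in g} d_{ij}^2$, total sum
$\frac{1}{N}\sum_{i<j} d_{ij}^2$) yields mean squares and the classical
ICC formula with the unbalanced-design group size $n_0$. On 1-D Euclidean
data this equals the classical ICC exactly (tested to 1e-10), which is the
justification for the construction. Uncertainty comes from bootstrapping
individuals (not samples) with replacement, `n_boot = 1000` by default;
the SE is the standard deviation of the bootstrap replicates.

## 5. The dyadic similarity model

`build_dyadic()` makes one row per unordered sample pair: the response is
community similarity; predictors are min-max scaled distances in age, IgA,
mucin, rank and sampling date, same/different indicators for mother, clan,
season and batch, and the age×IgA, age×mucin interactions. Because both
samples of a pair contribute, each observation belongs to two individuals
at once; the model adds a multi-membership random effect
$(u_{A} + u_{B})/2$.

`fit_dyadic()` samples the posterior by a blocked Gibbs scheme written for
this structure:

* flat priors on the regression coefficients; half-t(3, 0, 2.5·sd(y))
  priors on both scales via the inverse-gamma mixture representation;
* per iteration, $\log\sigma_u^2$ is updated by slice sampling with
  **both** the coefficients and the random effects integrated out of the
  likelihood (the marginal covariance $\sigma_e^2 I + \sigma_u^2 ZZ'$ is
  handled through the eigendecomposition of $Z'Z$, computed once);
  then the coefficients are drawn from their GLS posterior with the random
  effects still marginalised (Woodbury identity in the same eigenbasis),
  the random effects from their conjugate conditional, and
  $\sigma_e^2$ conjugately.

The marginalised updates are the load-bearing design choice: the additive
confounding of the intercept with the mean random effect, and the
small-variance funnel of $\sigma_u$, never enter the chain's dynamics, so
short chains mix well (split-R-hat < 1.01 across validation replicates).
Numerical safeguards — exact zeroing of null eigendirections of $Z'Z$, a
bounded slice domain, and a relative floor on $\sigma_e^2$ so a perfect
fit cannot collapse the variance ratio — are documented in the code.
Without the random effect the posterior mean reproduces OLS (tested).
A coefficient is reported significant when its central 95% credible
interval excludes zero; the fit is flagged unconverged if any split-R-hat
reaches 1.01. Default run length is 4 chains × 3000 iterations with 1000
warmup.

`fit_component_models()` refits the model per taxonomic component
(bacteria, fungi, parasites), entering the other components' similarities
as additional scaled predictors to ask whether components covary beyond
shared host structure.

## 6. Random-forest immune prediction

`build_feature_matrix()` assembles cASV abundances plus host covariates.
`stratified_split()` holds out 20% stratified by outcome quartile;
`tune_and_train()` selects `mtry` by repeated k-fold cross-validation
(folds shared across the grid so comparisons are paired) and refits with
`ranger` (variance split rule, `min.node.size = 10` against overfitting
small n). `evaluate_model()` reports held-out R² and Spearman's ρ;
`permutation_importance()` measures the mean MSE increase when one
feature is shuffled (averaged over permutations), and
`partial_dependence()` traces the marginal effect of one feature over a
grid. All forests run single-threaded with fixed seeds so results are
bit-reproducible.

## 7. Co-occurrence networks

`mb_network()` implements Meinshausen–Bühlmann neighbourhood selection on
CLR-transformed abundances: every taxon is lasso-regressed on all others
at a fixed penalty (a `glmnet` path is fit from each node's
$\lambda_{max}$ down to the target so warm starts behave), and an edge is
kept under the OR rule, signed by the mean coefficient. The edge set is
monotone non-increasing in the penalty (tested). The default annotation
`lambda = 0.055` marks the scale used for full-size gut communities; the
bundled 40-taxon analyses use `lambda = 0.15`, chosen a priori from the
$O(1/\sqrt{n})$ scaling of the selection threshold, and validated on a
three-variable Markov-chain generator (A→B→C) where the correct
conditional-independence graph {A–B, B–C} without A–C is recovered in
over 90% of seeds.

`centralities()` reports degree, closeness, unnormalised betweenness and
the Kleinberg hub score — computed as the principal eigenvector of the
adjacency matrix by a dense symmetric eigendecomposition, which is
deterministic where iterative solvers are not, and scaled to maximum 1.
`compare_centrality()` runs a one-way ANOVA per metric between an
immune-predictive node set and the rest; with two groups the F statistic
equals the squared pooled t statistic (tested to 1e-9).

## 8. Problem sizes and limitations

The bundled analyses (see `analysis/`) use 110 individuals, 150 samples,
40 latent taxa and 3 amplicons at depth 10⁴ — sizes chosen so the full
pipeline, including MCMC, runs in minutes on one CPU while leaving every
recovery target statistically identifiable. These are package defaults,
not claims about any particular study system.

Known limitations: the merge step trusts genus annotations and cannot
join unannotated ASVs across genera (an opt-in groups unannotated ASVs by
their lowest available rank); the dyadic model treats pair similarities as
conditionally independent given the individual effects, ignoring residual
dyadic dependence beyond the multi-membership structure; neighbourhood
selection at a single penalty does not quantify edge uncertainty; and the
dICC bootstrap resamples individuals, so it reflects cohort-level, not
within-individual, uncertainty.
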