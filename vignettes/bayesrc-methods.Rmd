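---
title: "Annotation-informed Bayesian mixture models for genomic prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-informed Bayesian mixture models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bayesrc` fits the linear mixed model

$$
\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{a} + \mathbf{W}\mathbf{v} + \mathbf{e},
\qquad \mathbf{e} \sim N(0, \mathbf{E}\,\sigma^2_e),\;
\mathbf{E} = \mathrm{diag}(1/w_j),
$$

where $\mathbf{y}$ are phenotypes, $\mathbf{X}\mathbf{b}$ fixed effects with
a flat prior, $\mathbf{a} \sim N(0, \mathbf{A}\sigma^2_a)$ optional polygenic
values with $\mathbf{A}$ the pedigree numerator relationship matrix,
$\mathbf{W}$ the centred, unit-variance-standardized genotype dosages and
$w_j$ per-record reliability weights (a progeny-tested bull's average is far
less noisy than a single cow lactation record; the weights let both coexist
in one analysis).

Each variant effect $v_i$ follows a four-component normal mixture

$$
v_i \sim P_{c(i),1}\,\delta_0 + \sum_{d=2}^{4} P_{c(i),d}\,
N\!\left(0, \gamma_d\,\sigma^2_g\right),
\qquad \gamma = (0,\, 10^{-4},\, 10^{-3},\, 10^{-2}),
$$

so most variants can drop out of the model while a few carry moderate or
large effects. The BayesR model uses a single set of proportions
$\mathbf{P}$; the BayesRC extension assigns every variant to one annotation
class $c$ (for instance: non-synonymous sites in candidate genes, other
variants overlapping those genes, everything else) and gives each class its
own proportions with the same symmetric prior,

$$
\mathbf{P}_c \sim \mathrm{Dirichlet}(\boldsymbol{\alpha}_c + \boldsymbol{\beta}_c),
\qquad \boldsymbol{\alpha}_c = (1,1,1,1),
$$

$\boldsymbol{\beta}_c$ being the current count of the class's variants in
each component. Because the prior is identical and uniform across classes,
annotation only changes the posterior if the data show a class to be
enriched for (or depleted of) effects — an uninformative class costs
essentially nothing, which is the property that makes the method safe to use
with speculative gene lists. With one class the BayesRC update *is* the
BayesR update; `bayesr_fit()` is literally `bayesrc_fit()` with a single
class, and the equivalence is asserted bit-for-bit in the test suite.

## Gibbs sampler

Per iteration the sampler draws, in order: the fixed effects from their
weighted-least-squares conditional; the polygenic vector and $\sigma^2_a$
(when a pedigree is supplied); each variant's component indicator and effect
in a fresh random permutation; each class's $\mathbf{P}_c$; and $\sigma^2_e$
from the weighted residual sum of squares. The component indicator uses the
standard single-site marginal likelihood: with $s_i = \mathbf{W}_i'D\mathbf{W}_i$,
$r_i = \mathbf{W}_i'D\tilde{\mathbf{e}}$ ($D = \mathrm{diag}(w_j)$,
$\tilde{\mathbf{e}}$ the residual with variant $i$ added back),

$$
\log L_d = \log P_{c,d}
 - \tfrac12 \log\!\frac{\tau_d s_i + \sigma^2_e}{\sigma^2_e}
 + \tfrac12 \frac{\tau_d\, r_i^2}{\sigma^2_e(\tau_d s_i + \sigma^2_e)},
\qquad \tau_d = \gamma_d \sigma^2_g,
$$

followed, for a non-null draw, by the conjugate normal for $v_i$. Posterior
summaries (per-variant inclusion probabilities, mean effects, per-class
component counts, variances) are post-burn-in means computed within each
chain and then averaged across chains; the between-chain spread is reported
as $\mathrm{SD}/\sqrt{n_\text{chains}}$, a relative-convergence figure
rather than a standard error.

### Priors and fixed quantities

* $\sigma^2_g$ is **fixed**, not sampled. By default it is `h2_prior` times
  the weighted phenotypic variance *after absorbing the fixed effects*
  (breed offsets or data-type means would otherwise inflate it by orders of
  magnitude). A switch (`update_sigma_g`) re-estimates it from the current
  effects but is off by default: fixing the scale keeps the mixture tiers
  interpretable as fractions of a stated genetic variance.
* $\sigma^2_e$ and $\sigma^2_a$ carry scaled inverse-chi-square priors with
  $\nu_0 = -2$ and scale 0 — improper and uninformative, so the posteriors
  are data-dominated. Proper hyperparameters can be supplied; the
  prior-recovery (successive-conditional) test uses them, since recovery of
  an improper prior is not defined.
* Initialization is deterministic: $\mathbf{b}$ at its weighted LS solution,
  $\mathbf{v} = 0$, all variants in the null component, $\mathbf{P}_c$
  uniform, $\sigma^2_e$ at half the adjusted phenotypic variance.

### Numerical design

The per-iteration cost is dominated by the scan computing $r_i$ for all $m$
variants, which is memory-bound. When the dosages are integers in
$\{0,1,2\}$ (always true before mean-imputation introduces fractions) the
standardized column is carried implicitly as one byte per genotype with its
centre and scale, and the dot product accumulates in single precision
against a float image of the weighted residual; fractional dosages fall back
to a dense single-precision matrix. The residual itself is always kept in
double precision, updated incrementally, and refreshed from scratch every
500 iterations; the largest discrepancy ever observed between the running
and recomputed residual is returned (`max_resid_err`) and asserted below
$10^{-6}$ in the tests — in practice it sits near $10^{-13}$. Component
log-weights use a log-sum-exp guard with proportions floored at $10^{-300}$.
Categorical weights are evaluated in single precision, which perturbs
component probabilities by about $10^{-7}$ — far below Monte Carlo noise.

The polygenic conditional is sampled through a one-off eigendecomposition:
with $\mathbf{A} = \mathbf{L}\mathbf{L}'$ and
$\mathbf{L}'D\mathbf{L} = \mathbf{Q}\Lambda\mathbf{Q}'$, the full
conditional of $\mathbf{u}$ (where $\mathbf{a} = \mathbf{L}\mathbf{u}$) is
diagonal in the $\mathbf{Q}$ basis for any $\sigma^2_e/\sigma^2_a$, so each
iteration costs $O(n^2)$ instead of a fresh Cholesky. If $\mathbf{A}$ is
numerically semi-definite a $10^{-8}$ diagonal jitter is added once, with a
message.

## Genotype handling

`read_genotypes()` accepts plain delimited matrices, diploid-GT VCF (via
`vcfR`) and variant-major PLINK `.bed/.bim/.fam` (the 2-bit codec is
implemented in the package and validated in the tests against byte streams
composed independently by hand). Missing genotypes are resolved by
column-mean imputation — the neutral default when no external imputation is
available. MAF filtering excludes strictly below the threshold (a variant
exactly at it is kept). LD pruning removes one member of every pair with
squared dosage correlation above 0.999 within sliding windows of 500
variants advanced by 50, first within each annotation category, then
removing any other-category variant in high LD with an `NSC` variant, then
any `CHIP` variant in high LD with a `REG` variant; within a category the
variant earlier in position order is retained (the tie-break is a package
convention — which member to drop is not dictated by the method). Windows
are counted in variants, not base pairs, and $r^2$ is computed on dosages
(genotypic correlation), not phased haplotypes.

Standardization uses the sample standard deviation of the observed dosages
rather than $\sqrt{2pq}$: it makes the unit-variance invariant exact on the
data at hand, and the training centre/scale are stored so validation
genotypes are transformed with the *training* statistics
(`apply_standardization()`).

## The simulator

`sim_trait()` emulates the structure of a multi-breed dairy reference
population without any external data:

* **Genomes.** Two or more populations share base allele frequencies drawn
  uniformly on (0.05, 0.95) with independent normal drift (sd 0.1),
  giving mean Hudson $F_{ST}$ around 0.05–0.1 — on the order of what
  separates related cattle breeds. Haplotypes come from a Gaussian copula:
  a latent AR(1) process (correlation 0.95) within blocks of 50 variants,
  thresholded at the population frequency; dosage is the sum of two
  independent haplotypes. The `within_block_corr` parameter is the *latent*
  correlation; thresholding attenuates the realized adjacent-dosage
  correlation to roughly 0.4–0.8 depending on frequency. The default layout
  is three populations: two form the training set (the first carrying a
  breed offset drawn once from $N(10, 1)$), the third — drifted
  independently — serves as the less-related validation set, mimicking
  validation in a breed absent from training.
* **Annotation.** One hundred candidate-gene loci of 8 variants with 4
  flanking variants on each side are placed without overlap; categories
  (`NSC`/`REG`/`CHIP` analogues) are drawn per variant with an elevated
  coding rate inside gene bodies. Class I is coding-analogue variants inside
  genes, class II the rest of each gene region, class III the remainder
  (~325 / ~1,275 / ~8,400 variants at the 10,000-variant default).
* **Trait.** 200 QTL at tier counts 174/25/1 — the full-scale design's
  3485/500/15 at 1/20 — with effects from
  $N(0, \gamma_t\,\sigma^2_{g,\text{sim}})$ applied to raw dosages; the
  genetic value is exactly $\sum_i x_{ij}\alpha_i$. The environmental
  variance is scaled from the *realized* genetic-value variance so the
  target $h^2 = 0.6$ holds per replicate (the expected-variance convention
  would let realized heritability wander at small $n$). QTL placement
  follows the enrichment scheme: confined to gene regions
  (`candidate_gene`), on coding/regulatory categories genome-wide
  (`category_only`), or uniform.
* **Reproducibility.** All stages derive deterministic sub-streams from one
  integer seed.

What the simulator does **not** reproduce: coalescent-realistic LD decay and
haplotype sharing, selection, rare-variant site-frequency spectra, imputation
error, and crossbred individuals. Passing tests on these data show the
sampler and its statistics behave correctly under a controlled architecture;
they do not certify accuracy levels on real livestock data.

### The variance scale of a scaled-down architecture

In the full-scale design the tier fractions weighted by QTL counts satisfy
$\sum_t n_t \gamma_t = 3485 \cdot 10^{-4} + 500 \cdot 10^{-3} + 15 \cdot
10^{-2} \approx 1$, so the mixture's reference variance $\sigma^2_g$
coincides with the trait's additive genetic variance. Scaling the counts to
174/25/1 while keeping the fractions breaks that identity
($\sum_t n_t\gamma_t \approx 0.052$): deriving $\sigma^2_g$ naively from the
genetic variance would make every tier ~19× too small relative to the
simulated effects and shift all component assignments upward.
`tier_consistent_sigma2_g()` therefore supplies
$\sigma^2_g = h^2\,\widehat{\mathrm{var}}_\text{adj}(y) / \sum_t n_t\gamma_t$
for the scaled studies, restoring the full-scale correspondence between
tiers and true effect sizes. For real data (where nothing is scaled down)
the default `h2_prior` route is appropriate.

## Evaluation machinery

* `predict()` returns $\hat{\mathbf{y}}_v = \mathbf{W}_\text{val}\hat{\mathbf{v}}$
  per chain, then averaged; the polygenic term is never included in
  predictions, so validation sets need no pedigree link to training.
* `accuracy_and_bias()`: accuracy is the correlation of prediction with the
  reference (phenotypes, or the true genetic value in simulations); bias is
  the regression of reference on prediction (1 = unbiased, < 1 = inflated
  predictions). Both are computed within chains first.
* `calibration_table()` bins variants by posterior inclusion probability —
  the fraction of post-burn-in iterations in a non-null component — and
  reports the observed fraction of true QTL per bin. Five equal-width bins
  over (0.01, 1] are the default; equal width is a package convention, and
  the edges are configurable.
* `discovery_counts()` counts true QTL above thresholds 0.01 / 0.1 / 0.25.
* `class_architecture()` tabulates per-class component occupancy and fold
  enrichment against the all-variant baseline.
* `random_gene_null()` rebuilds the matched-size random-gene-set null: per
  replicate it draws gene regions with replacement, allocates the informed
  analysis's class sizes from them, derives per-class prediction equations
  from a *baseline single-class fit's* effects (so the null shares the
  informed analysis's data and differs only in the gene set), and records
  one accuracy per replicate and chain — ten replicates over five chains
  gives the conventional fifty.

Comparators: `gwas_single_snp()` fits one variant at a time by weighted
least squares after absorbing covariates, optionally whitening with a
polygenic covariance (fixed $h^2$ or, for uniform weights, profiled REML);
`gblup_fit()` is SNP-BLUP solved in its $n \times n$ dual form, equivalent
to GBLUP with $\mathbf{G} = \mathbf{W}\mathbf{W}'/m$ — the single-normal
model whose contrast with the mixture is the point of the comparison.

## Problem sizes used in the automated checks

The acceptance checks run the candidate-gene study at $n = 2000$ training
individuals (1300 + 700), 300 validation individuals from the third
population, $m = 10{,}000$ variants, five simulation seeds, BayesRC with 3
chains of 5,000 iterations (2,500 burn-in). The BayesR comparator uses 2
chains at the same length, and the uniform-QTL study runs at $m = 5{,}000$
with 2 chains of 3,000 iterations for both models — coarser settings chosen
because those checks compare seed-averaged accuracies, which stabilize well
before the per-variant posterior summaries do. Full-scale analyses would
follow the 5-chain, 40,000-iteration convention.

## Known limitations

* The sampler is single-threaded; chains run sequentially. Full-scale
  problems (~1M variants, tens of thousands of individuals) are outside the
  intended envelope of this implementation.
* Only diploid, biallelic variants are handled; multi-allelic sites, sex
  chromosomes and bp-distance LD windows are out of scope.
* The polygenic eigendecomposition costs one $O(n^3)$ factorization and
  $O(n^2)$ per iteration, practical to a few thousand pedigree individuals.
* Classes with fewer than ~50 variants trigger a warning: with a symmetric
  Dirichlet prior the posterior proportions of a tiny class stay
  prior-dominated, and classes of more than about 1000 variants are
  recommended.
* With very few training records the smallest mixture tier is statistically
  indistinguishable from the null component ($\gamma_2 \sigma^2_g s_i
  \ll \sigma^2_e$), and the corresponding proportions mix slowly; this is a
  property of the model, not of the implementation.
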