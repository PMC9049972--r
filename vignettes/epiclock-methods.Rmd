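---
title: "Methylation clocks, entropy, and QTL mapping of age acceleration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation clocks, entropy, and QTL mapping of age acceleration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclock)
```

# Overview

`epiclock` implements an end-to-end analysis of epigenetic aging in a
recombinant inbred (RI) mouse panel: elastic-net DNA-methylation clocks
with a log-linear age transform, age-adjusted epigenetic age acceleration
(EAA), methylome-wide Shannon entropy, a multivariable epigenome-wide
association study (EWAS) with differentially methylated CpG (DMC)
classification, a kinship-corrected mixed-model QTL scan of EAA with
Fisher meta-analysis across traits, strain heritability, and annotation
enrichment. Because array cohorts of this kind are large downloads with
restricted processing chains, the package pairs every stage with a
synthetic-cohort generator that emulates the statistical structure such a
study presents, so the whole pipeline can be exercised and validated
against known ground truth.

# The clock model

## Age transform

Chronological age is not used directly as the regression response.
Development compresses a large amount of methylome change into a short
interval, so the response is a log-linear transform that is logarithmic
before an adult-age knot and linear after it:

$$
f(a) = \begin{cases}
\log(a + c) & a \le A \\
\dfrac{a - A}{A + c} + \log(A + c) & a > A
\end{cases}
$$

with adult age $A = 1.2$ years and offset $c = 0.06$ years for the mouse.
The transform is continuous and differentiable at the knot and strictly
increasing, so it has an exact inverse; `transform_age()` and
`inverse_transform_age()` round-trip to better than $10^{-10}$ years over
the whole usable age range.

## Elastic-net training and prediction

`train_clock()` regresses $f(\text{age})$ on CpG beta-values with an
elastic-net penalty at mixing parameter $\alpha = 0.5$ (equal ridge and
lasso weight), choosing the penalty strength by 10-fold cross-validation
over glmnet's log-spaced path. Two choices here were genuinely open and
are worth stating:

* **Penalty rule.** Cross-validation can pick the error-minimizing
  penalty or the sparser one-standard-error point. The default is the
  minimum-error penalty; `cv_rule = "1se"` selects the alternative.
* **Fold assignment.** Folds are stratified by age tertile and drawn from
  a caller-supplied seed. Stratification keeps every fold's age range
  representative at a few hundred samples, which stabilizes the selected
  penalty across seeds; the seed makes training reproducible.

Prediction inverts the transform of the linear predictor
$b_0 + \sum_i b_i \beta_i$. A published formulation of this family of
clocks divides the linear predictor by $b_0 + \sum_i b_i$ before
inverting. That normalization is degenerate whenever the coefficients sum
to approximately $-b_0$, and conventional penalized-regression clocks use
no such division, so the package treats it as an opt-in: the default
`normalization = "standard"` applies no division, and
`"as-printed"` applies it with an explicit error when the denominator
falls below $10^{-8}$ in magnitude. The two agree exactly when the
denominator equals one.

Three clock families differ only in the CpG universe offered to the
penalty: *general* clocks see all CpGs; *developmental* clocks see the
1000 most positively and 1000 most negatively age-correlated CpGs
computed in mice younger than 1.6 months (`select_developmental_cpgs()`,
ties broken lexicographically for determinism); *interventional* clocks
see CpGs that respond consistently — same sign, each table significant —
across independent anti-aging intervention experiments such as caloric
restriction and growth-hormone-receptor knockout
(`select_interventional_cpgs()`, ranked by Fisher-combined p, truncated
to 537 by default, the size of the consistently responsive set in the
liver intervention data this design follows). The exact consistency rule
behind that set is not fully specified in the source material; the rule
implemented (per-table threshold + sign agreement + Fisher ranking) is
the package's own and is stated here rather than inferred.

## Epigenetic age acceleration

EAA is the residual of DNAm age regressed on chronological age over the
pooled cohort (both diets together, so diet contrasts of EAA remain
meaningful). By construction EAA has mean zero and is exactly orthogonal
to age; `compute_eaa()` asserts both. Positive EAA reads as "epigenetically
older than expected".

# Methylome entropy

Per sample, beta-values are discretized into 20 equal-width bins and the
maximum-likelihood Shannon entropy $H = -\sum p \log p$ is computed in
nats. The 20-bin default follows the Freedman–Diaconis rule applied to
this data scale; `fd_bin_count()` exposes the rule as a diagnostic
(width $2\,\mathrm{IQR}\,n^{-1/3}$, count
$\lceil \text{range}/\text{width} \rceil$, with IQR under R's default
quantile convention). Two binning ranges are shipped because the choice
is not derivable from first principles: `fixed01` bins over $[0,1]$
(default, comparable across samples) and `data-range` bins over the
observed range (the convention of common entropy estimators). The unit
is nats because a methylome-wide entropy of $\approx 2.67$ under 20 bins
sits below $\ln 20 \approx 3.00$ but would exceed the $\log_2$ maximum
under no plausible reading; `unit = "bits"` is available. The last bin is
right-closed so a beta of exactly 1 is counted.

Useful exact properties, all property-tested: $0 \le H \le \log(\text{bins})$;
permutation invariance; refinement (100 bins never yield less entropy
than 20 on the same vector); and mixing any distribution toward uniform
increases $H$ — which is why the erosion of the bimodal methylome with
age raises entropy.

# EWAS

`fit_site_regressions()` fits, per CpG,

```
beta_i ~ age + median_lifespan + diet + bwf + PC1
```

by ordinary least squares with two-sided t-tests, vectorized across CpGs
through one QR decomposition of the shared design. Diet is coded
HFD = 1 so estimates read as the change on high-fat diet relative to
control. Strain median lifespan is joined by (strain, diet) from
female natural-death cohorts with at least five observed deaths, which is
also why the default drops male samples. PC1 of the beta matrix enters as
the sole unmeasured-confounder covariate: in data of this design the top
component tracks array batch, while later components carry age and other
biology and therefore must stay out of the model. `classify_dmcs()`
applies an inclusive Bonferroni cutoff $\alpha / n_\text{tests}$ per
predictor and splits age-DMCs by estimate sign into age-gain and
age-loss; the Bonferroni denominator is an explicit argument because the
appropriate test count can differ between the full array and a filtered
analysis set.

# Kinship-corrected QTL mapping

## The mixed model

RI strains are related, so marker tests must correct for genetic
background. `lmm_scan()` fits, per marker,

$$ y = W\alpha + x\beta + u + \varepsilon, \quad
   u \sim N(0, \sigma_g^2 K), \quad \varepsilon \sim N(0, \sigma_e^2 I) $$

with $K$ the centered realized-relatedness matrix
(`kinship_matrix()`: $K = X_c X_c^\top / m$, missing dosages mean-imputed
per marker). Replicate mice of one strain share that strain's kinship
rows. The solver uses the efficient mixed-model device: one
eigendecomposition of $K$ per scan rotates the problem so the covariance
is diagonal in $\delta = \sigma_e^2/\sigma_g^2$, and the profile
likelihood in $\log\delta \in [-10, 10]$ is maximized per marker by
one-dimensional search (`mode = "exact"`). `mode = "null-delta"`
estimates $\delta$ once under the no-marker model and reuses it — the
standard fast approximation, available because exact mode costs one
optimization per marker.

The reported test is a Wald t-test with an $(n - p)$ residual divisor.
This choice is deliberate: as kinship effects vanish the scan then
reduces *exactly* to per-marker OLS (verified to $10^{-6}$), and the
fixed-$\delta$ path agrees with an explicit generalized-least-squares
inversion to $10^{-8}$. The test statistic and kinship flavor (centered
vs standardized) are conventions, not derivations; centered kinship and
the Wald test were chosen and both alternatives noted rather than
silently assumed. Markers below the MAF threshold (default 0.05) are
skipped and flagged. Calibration is property-tested: traits drawn from
the model's own null (polygenic background, no marker effect) give
uniform p across independent markers.

## Meta-analysis, LOD, heritability, marker models

Fisher's combination $X = -2\sum\log p \sim \chi^2_{2k}$ aggregates
evidence across EAA traits (`fisher_combine()`, `meta_scan()`), with p
floored at $10^{-300}$ before logs. LOD scores come from the 1-df
chi-square quantile identity $\mathrm{LOD} = Q_{\chi^2_1}(1-p)/(2\ln 10)$
— the conversion that reproduces printed pairs like
$p = 3.5\times10^{-6} \rightarrow 4.7$ and
$p = 9\times10^{-7} \rightarrow 5.2$ where a naive $-\log_{10} p$ does
not. Strain heritability is the one-way ANOVA ratio
$h^2 = SS_\text{strain}/(SS_\text{strain}+SS_\text{residual})$.
Marker-specific follow-ups use `lm(trait ~ genotype + diet)` with
heterozygotes excluded, and longitudinal body weight uses the REML
random-intercept model `weight ~ age + diet + genotype + (1 | mouse)`
via lme4.

# Enrichment and expression correlates

`hypergeom_enrich()` computes both hypergeometric tails (enrichment and
depletion) of a foreground CpG set against the assayed background for
any user-supplied label map — genomic class, chromatin state, or gene
sets — with Benjamini–Hochberg adjustment per tail. External
gene-ontology services are out of scope; the statistic is not.
`chromatin_state_profile()` aggregates mean methylation and mean EWAS
coefficients per chromatin state and fits degree-1 and degree-2
polynomials of coefficient on methylation across states, the analysis
behind "inverse linear" age profiles and "U-shaped" diet profiles.
`rank_correlates()` ranks expression features by $|r|$ against an EAA
trait (top 2000 by default; constant features excluded);
`cluster_correlates()` groups shared correlates by average-linkage
hierarchical clustering on the $1 - r$ distance with $k = 3$ by default.
Linkage, distance, and $k$ are this package's choices — the source
design says only "unsupervised hierarchical clustering".

# The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_study()` draws
genotypes, covariates, lifespans, and the methylome from them. Defaults
describe a cohort of 45 RI strains × 10 mice aged uniformly 0.47–2.78
years (5.6–33.4 months), 38% on high-fat diet, ~5% male, three array
batches, 1900 markers on 19 autosomes of 80 cM, and 2000 CpGs of which
7.5% are age-gain and 2.5% age-loss (the ~3:1 split such cohorts show).
All randomness flows from one seed through fixed per-stage child seeds.

**Genotypes.** Each strain is an independent two-state B/D mosaic per
chromosome with transition probability $R = 4r/(1+6r)$ between adjacent
markers — the RI-by-sib-mating map expansion of the Haldane fraction
$r = (1 - e^{-2d/100})/2$. Inbred strains carry no heterozygotes. Note
$R \to 1/2$ as $d \to \infty$: distant markers decouple completely.

**Methylome.** Beta-values are inverse-logit transforms of a per-CpG
baseline plus effect terms, which keeps betas in $(0,1)$ without
truncation and makes planted slopes interpretable in logit units:

* Baselines are drawn from a two-component mixture (modes near logit
  $\pm 2.2$), giving the bimodal beta distribution of conserved CpGs with
  a hypermethylated excess. Age-gain CpGs start on the hypomethylated
  shoulder (logit $-1.5$), age-loss CpGs on the hypermethylated shoulder
  ($+1.5$): their drift toward mid-methylation erodes the bimodal peaks,
  which is exactly why entropy rises with age.
* Age slopes are $0.2 + |N(0, 0.3)|$ logit/yr, signed by class. The
  floor ensures a labeled age CpG is genuinely distinguishable from
  age-ns at cohort size; the cap implied by the scale keeps betas from
  sweeping the whole unit interval, which would make entropy
  non-monotone in age.
* High-fat diet multiplies age-gain slopes by $1 + 0.3$; final weight
  (±0.02 logit/g at 100 CpGs) and strain median lifespan (±0.002
  logit/day at 80 CpGs) act on random CpG subsets with random signs.
* The EAA locus acts as a genotype × age interaction through each age
  CpG's own slope: every sample has a biological age
  $b_i = a_i(1 + 0.2\,d_i) + \gamma_i$ with $\gamma_i \sim N(0, 0.1)$
  years, and age CpGs respond to $b_i$ rather than $a_i$. A constant
  additive interaction term applied to a CpG set would cancel between
  gain and loss CpGs inside any trained clock and could not move EAA;
  scaling by the slope is the formulation under which the planted locus
  actually shifts the trait being mapped. The per-sample offset
  $b_i - a_i$ is recorded as ground truth.
* Each batch carries its own independent per-CpG bias profile
  ($N(0, 0.7)$ logit). This magnitude was calibrated jointly so the
  generator reproduces the qualitative structure the analysis design
  assumes: the top principal component is batch-driven (so PC1 is the
  right EWAS covariate), while every batch perturbs the beta spread by
  the same expected amount (so entropy–age correlation survives).
  Weaker batch effects hand PC1 to the age axis — and then the PC1
  covariate would null the EWAS age signal; stronger ones dominate
  per-sample entropy.
* Residual noise is $N(0, 0.3)$ on the logit scale.

**Cohort.** Weights combine baseline, strain, diet, and noise terms with
high-fat mice gaining weight; strain median lifespan is 750 days plus
150 days per D allele at the lifespan locus plus $N(0, 60)$ strain
noise, with order statistics placed symmetrically around the median and
an 80-day high-fat deficit. Quantitative per-CpG effect sizes for diet,
weight, and lifespan are not stated in the source material; the defaults
above are the generator's own recorded choices, not estimates.

**What passing tests do and do not show.** The generator reproduces the
*statistical shape* of a real cohort — bimodality, class structure,
batch-dominated PC1, kinship, a mappable locus — but not array
measurement error, LD fine-structure, X-dosage, epistasis, or the true
effect-size spectrum. Recovery results on synthetic data therefore
validate the estimators and their contracts, not any biological claim
about real mice.

# Numerical choices and degenerate inputs

* Beta-values are validated into $[0,1]$ with the offending cell named;
  readers and writers are exact inverses, with floats written at the
  shortest decimal representation that parses back to the same double.
* BED annotation is 0-based half-open on disk, 1-based in memory.
* Correlation-based selections break ties lexicographically by CpG id.
* `fisher_combine()` rejects $p = 0$ rather than silently flooring;
  callers floor at $10^{-300}$ where mass-produced p-values may underflow.
* The profile-likelihood search space $\log\delta \in [-10,10]$ covers
  variance ratios from $5\times10^{-5}$ to $2\times10^{4}$; outside that
  range the model is numerically indistinguishable from pure-strain or
  pure-noise anyway.
* Degenerate inputs (constant traits, single genotype classes, IQR = 0,
  empty subsets, rank-deficient designs) raise errors that name the
  problem instead of returning NaN.

# Problem sizes

The shipped tests and the acceptance script run the full pipeline at
cohort scale (450 mice × 2000 CpGs × 1900 markers), the EWAS null
calibration at 200 × 5000, and the QTL recovery experiment over 20
seeds. These sizes were chosen so every recovery experiment has
comfortable statistical margin while a complete validation run stays in
the tens of seconds on one core.

# Known limitations

* The mixed-model scan refits $\delta$ per marker by ML (not REML); in
  small panels this makes per-marker variance estimates slightly
  optimistic, though the $(n-p)$ Wald divisor compensates in the tests
  shipped.
* Entropy is the plug-in estimator; no small-sample bias correction
  (Miller–Madow, shrinkage) is applied, matching the convention the
  pipeline follows.
* The interventional-CpG rule is a reconstruction (see above), so the
  specific 537-site set of the original liver data is not reproducible
  from this package alone.
* Strain-level traits are mapped at individual level by expanding
  kinship through strain identity; a two-level model with explicit
  strain means is a possible alternative not implemented here.
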