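# epiclock

Epigenetic clocks, methylome entropy, and QTL mapping of epigenetic age
acceleration for recombinant inbred (RI) mouse panels.

DNA methylation at conserved CpGs changes predictably with age, which
makes it possible to train *methylation clocks* — penalized regressions
that predict age from a beta-value profile — and to study the residual,
*epigenetic age acceleration* (EAA), as a quantitative trait. In an RI
panel like the BXD family, every genome is replicable, so EAA can be
mapped to causal loci with a kinship-corrected mixed model, correlated
with strain longevity, and dissected against diet and body-weight
covariates. `epiclock` implements that entire analysis for researchers
working with methylome × genotype panel data, together with a
synthetic-cohort generator so every stage is testable end to end against
known ground truth.

## What it computes

* **Clocks** — elastic-net regression (α = 0.5, 10-fold CV) of the
  log-linear transformed age
  `f(a) = log(a + 0.06)` for `a ≤ 1.2`, linear continuation above, on CpG
  beta-values; general, developmental (top ±1000 young-age correlates),
  and interventional (consistently intervention-responsive CpGs, ≤ 537)
  variants; DNAm age by the exact inverse transform; EAA as the
  age-orthogonal residual.
* **Entropy** — per-sample Shannon entropy of 20-bin discretized
  beta-values (maximum-likelihood estimator, nats), methylome-wide or per
  CpG class, with the Freedman–Diaconis rule as a bin-count diagnostic.
* **EWAS** — per-CpG OLS of `beta ~ age + median lifespan + diet + BWF + PC1`,
  Bonferroni classification into age-gain / age-loss / age-ns plus
  weight-, diet-, and lifespan-DMC flags, and Venn-region overlap counts.
* **QTL** — centered realized-relatedness kinship; per-marker
  efficient-mixed-model scan (ML over the variance ratio in the kinship
  eigenbasis, Wald t-test, MAF filter); Fisher p-value combination across
  EAA traits; `LOD = qchisq(1−p, 1) / (2 ln 10)`; one-way-ANOVA strain
  heritability `h² = SSq_strain/(SSq_strain + SSq_residual)`;
  marker-specific `lm(trait ~ genotype + diet)`; REML random-intercept
  weight model via lme4.
* **Enrichment** — two-tailed hypergeometric enrichment/depletion with BH
  adjustment over any label map; chromatin-state methylation/effect
  profiles with linear and quadratic fits; expression-correlate ranking
  (top 2000 by |r|) and average-linkage hierarchical clustering.
* **Simulation** — RI genotype mosaics (`R = 4r/(1+6r)` map expansion),
  bimodal methylomes with planted age/diet/weight/lifespan effects, a
  planted EAA locus (genotype × age interaction) and lifespan locus, and
  batch structure calibrated so the top principal component is
  batch-driven, as in real array cohorts.

## Worked example

```r
library(epiclock)

cfg <- sim_config(seed = 1)          # 45 strains x 10 mice, 2000 CpGs, 1900 markers
dat <- simulate_study(cfg)
dat$meth
#> methylome: 450 samples x 2000 CpGs (annotated)

## train a clock on 300 mice, evaluate on the rest
set.seed(2)
train <- sort(sample(450, 300))
model <- train_clock(methylome(dat$meth$beta[train, ]), dat$samples, seed = 2)
model
#> general clock (pan), 40 CpGs, alpha = 0.5, lambda = 0.0446, standard normalization

test <- setdiff(1:450, train)
pred <- predict_dnam_age(model, methylome(dat$meth$beta[test, ]))
cor(pred, dat$samples$age[test])
#> [1] 0.941

## EAA: age-orthogonal by construction, recovers the planted offsets
eaa <- compute_eaa(predict_dnam_age(model, dat$meth), dat$samples)
cor(eaa$eaa, eaa$age)                          #> 4.05e-18
cor(eaa$eaa, dat$truth$eaa_offset)             #> 0.776

## entropy rises with age as the bimodal peaks erode
ent <- methylome_entropy(dat$meth)
mean(ent$entropy)                              #> 2.680  (nats, 20 bins)
cor(ent$entropy, dat$samples$age)              #> 0.765

## EWAS with Bonferroni DMC classification
tab <- classify_dmcs(
  fit_site_regressions(dat$meth, dat$samples, dat$longevity, compute_pcs(dat$meth)),
  n_tests = 2000)
table(tab$class)
#> age-gain age-loss   age-ns
#>      149       50     1801

## kinship-corrected scan of EAA finds the planted locus
K <- kinship_matrix(dat$geno)
scan <- lmm_scan(setNames(eaa$eaa, eaa$sample_id),
                 cbind(diet = as.numeric(dat$samples$diet == "HFD"),
                       bwf  = dat$samples$bwf),
                 dat$geno, K, strain_ids = dat$samples$strain_id)
scan[which.min(scan$p), c("marker_id", "p", "lod")]
#>   marker_id        p  lod
#>    chr5_m50 3.92e-65 63.1   (marker 450 -- exactly the planted locus)

anova_heritability(eaa$eaa, dat$samples$strain_id)
#> [1] 0.45
```

The held-out correlation of 0.94 says the clock predicts age to a few
months at this cohort size; the EAA residual is numerically orthogonal to
age, and its correlation of 0.78 with the planted per-sample offsets
shows the clock is recovering biological age differences, not noise. The
scan's global minimum falls on the planted marker with LOD ≈ 63, and
about 45% of EAA variance is between strains — i.e. heritable in this
panel.

`run_pipeline(pipeline_config(out_dir, sim = sim_config(seed = 1)))`
executes all stages in order and writes every result table plus an MD5
manifest; rerunning with the same config and seed reproduces identical
checksums.

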