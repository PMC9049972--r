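#' Simulation configuration for a recombinant-inbred methylome cohort
#'
#' Defaults emulate the statistical structure of a BXD-like aging study:
#' ~45 RI strains with replicate mice aged roughly 5.6-33.4 months on two
#' diets, a bimodal conserved-CpG methylome with distinct age-gain and
#' age-loss classes (~3:1), diet augmentation of age-gain slopes, weight
#' and strain-lifespan effects on CpG subsets, dense biallelic genotypes,
#' and one planted locus each for epigenetic age acceleration and for
#' strain lifespan.
#'
#' @param n_strains Number of RI strains.
#' @param replicates_per_strain Mice per strain.
#' @param n_markers Total marker count (split evenly over chromosomes).
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_cM Genetic length of each chromosome.
#' @param n_cpgs Number of CpGs.
#' @param n_age_gain,n_age_loss Counts of CpGs gaining/losing methylation
#'   with age.
#' @param age_range Ages (years) are uniform over this range; default
#'   0.47-2.78 (5.6-33.4 months).
#' @param diet_fraction_hfd Fraction of mice on high-fat diet.
#' @param male_fraction Fraction of male mice (cohort is mostly female).
#' @param age_slope_sd Scale of per-CpG age slopes: class CpGs get
#'   0.2 + |N(0, age_slope_sd)| logit/yr, signed by class.
#' @param diet_aug Multiplier by which HFD augments age-gain slopes
#'   (slope x (1 + diet_aug) under HFD).
#' @param weight_effect Absolute per-gram logit effect at weight-responsive
#'   CpGs; `n_weight_cpgs` CpGs get it with random sign.
#' @param lifespan_effect Absolute per-day logit effect of strain median
#'   lifespan at `n_lifespan_cpgs` CpGs, random sign.
#' @param n_weight_cpgs,n_lifespan_cpgs Sizes of the affected CpG subsets.
#' @param eaa_qtl_marker_index Marker index of the planted EAA locus.
#' @param eaa_qtl_effect Fractional increase in epigenetic aging rate per
#'   D-allele dosage (genotype x age interaction on age-informative CpGs).
#' @param eaa_noise_sd SD (years) of the per-sample biological-age offset
#'   independent of genotype.
#' @param lifespan_qtl_marker_index Marker index of the planted lifespan locus.
#' @param lifespan_qtl_effect Days of median lifespan added per D-allele dosage.
#' @param noise_sd Residual SD on the logit scale per (sample, CpG).
#' @param n_batches Number of array batches.
#' @param batch_sd SD of the per-(batch, CpG) bias profile on the logit
#'   scale; sized so batch occupies the top principal component.
#' @param seed Global seed; each stage derives a fixed child seed from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_strains = 45, replicates_per_strain = 10,
                       n_markers = 1900, n_chromosomes = 19,
                       chromosome_length_cM = 80,
                       n_cpgs = 2000, n_age_gain = NULL, n_age_loss = NULL,
                       age_range = c(0.47, 2.78),
                       diet_fraction_hfd = 0.38, male_fraction = 0.05,
                       age_slope_sd = 0.3, diet_aug = 0.3,
                       weight_effect = 0.02, lifespan_effect = 0.002,
                       n_weight_cpgs = 100, n_lifespan_cpgs = 80,
                       eaa_qtl_marker_index = NULL, eaa_qtl_effect = 0.2,
                       eaa_noise_sd = 0.1,
                       lifespan_qtl_marker_index = NULL,
                       lifespan_qtl_effect = 150,
                       noise_sd = 0.3, n_batches = 3, batch_sd = 0.7,
                       seed = 1) {
  # proportional defaults: 7.5% age-gain / 2.5% age-loss CpGs (the ~3:1
  # gain:loss split), causal loci at fixed relative map positions
  if (is.null(n_age_gain)) n_age_gain <- round(0.075 * n_cpgs)
  if (is.null(n_age_loss)) n_age_loss <- round(0.025 * n_cpgs)
  if (is.null(eaa_qtl_marker_index)) {
    eaa_qtl_marker_index <- max(1, round(0.237 * n_markers))
  }
  if (is.null(lifespan_qtl_marker_index)) {
    lifespan_qtl_marker_index <- max(1, round(0.658 * n_markers))
  }
  cfg <- as.list(environment())
  stopifnot(
    n_strains > 0, replicates_per_strain > 0, n_markers > 0,
    n_chromosomes > 0, n_cpgs > 0, n_age_gain >= 0, n_age_loss >= 0,
    n_age_gain + n_age_loss <= n_cpgs,
    diet_fraction_hfd >= 0, diet_fraction_hfd <= 1,
    male_fraction >= 0, male_fraction <= 1,
    length(age_range) == 2, age_range[1] > 0, age_range[2] > age_range[1],
    eaa_qtl_marker_index >= 1, eaa_qtl_marker_index <= n_markers,
    lifespan_qtl_marker_index >= 1, lifespan_qtl_marker_index <= n_markers,
    noise_sd >= 0, n_batches >= 1
  )
  if (n_markers %% n_chromosomes != 0) {
    stop("n_markers must be divisible by n_chromosomes")
  }
  class(cfg) <- "sim_config"
  cfg
}

# fixed per-stage child seeds derived from the global seed
child_seed <- function(config, stage) {
  offsets <- c(genotypes = 101L, cohort = 202L, methylome = 303L,
               expression = 404L)
  (config$seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate recombinant-inbred genotypes
#'
#' Each strain is an independent two-state (B/D) mosaic per chromosome:
#' the initial marker state is Bernoulli(0.5) and the state switches
#' between adjacent markers with probability `R = 4r / (1 + 6r)`, the
#' RI-by-sib-mating map expansion of the Haldane recombination fraction
#' `r = (1 - exp(-2d/100)) / 2` for inter-marker distance `d` cM. Strains
#' are fully inbred, so dosages are 0 (B) or 1 (D) with no heterozygotes.
#'
#' @param config A [sim_config()].
#' @return A [genotypes()] object (markers named `chr<k>_m<j>`, positions
#'   at ~2 Mb per cM).
#' @export
simulate_ri_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_chr <- config$n_markers / config$n_chromosomes
  if (per_chr < 2) stop("need >= 2 markers per chromosome")
  set.seed(child_seed(config, "genotypes"))
  d_cM <- config$chromosome_length_cM / (per_chr - 1)
  r <- (1 - exp(-2 * d_cM / 100)) / 2
  R <- 4 * r / (1 + 6 * r)
  n_s <- config$n_strains
  dosage <- matrix(NA_real_, n_s, config$n_markers)
  for (chr in seq_len(config$n_chromosomes)) {
    cols <- (chr - 1) * per_chr + seq_len(per_chr)
    state <- stats::rbinom(n_s, 1, 0.5)
    dosage[, cols[1]] <- state
    for (j in 2:per_chr) {
      flip <- stats::rbinom(n_s, 1, R)
      state <- ifelse(flip == 1, 1 - state, state)
      dosage[, cols[j]] <- state
    }
  }
  chrom <- rep(seq_len(config$n_chromosomes), each = per_chr)
  pos_cM <- rep(seq(0, config$chromosome_length_cM, length.out = per_chr),
                config$n_chromosomes)
  rownames(dosage) <- sprintf("BXD%03d", seq_len(n_s))
  colnames(dosage) <- sprintf("chr%d_m%d", chrom, rep(seq_len(per_chr), config$n_chromosomes))
  genotypes(dosage, chrom = chrom, pos = round(pos_cM * 2e6) + 1)
}

#' Simulate the cohort: covariates, lifespans, and ground truth
#'
#' Ages are uniform over `age_range`; diet is Bernoulli and independent of
#' strain; body weights combine baseline, diet, strain, and noise terms
#' (high-fat mice gain weight: bw0 < mean(bwf) on HFD); strain median
#' lifespan is a base value plus the lifespan-QTL effect times dosage plus
#' strain noise, with order statistics derived consistently around the
#' median. The per-sample biological-age offset (the planted EAA) is
#' `age * eaa_qtl_effect * dosage + N(0, eaa_noise_sd)`.
#'
#' @param config A [sim_config()].
#' @param geno Genotypes from [simulate_ri_genotypes()].
#' @return List with `samples` ([sample_table()]), `longevity`
#'   ([longevity_table()]), and `truth` (list of class `ground_truth`).
#' @export
simulate_cohort <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotypes"))
  set.seed(child_seed(config, "cohort"))
  n_s <- config$n_strains
  n <- n_s * config$replicates_per_strain
  strain_id <- rep(geno$strain_ids, each = config$replicates_per_strain)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  diet <- ifelse(stats::rbinom(n, 1, config$diet_fraction_hfd) == 1, "HFD", "CD")
  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  batch <- sample(sprintf("batch%d", seq_len(config$n_batches)), n, replace = TRUE)

  strain_w <- stats::rnorm(n_s, 0, 3)
  names(strain_w) <- geno$strain_ids
  hfd <- as.numeric(diet == "HFD")
  bw0 <- 30 + strain_w[strain_id] + stats::rnorm(n, 0, 2)
  bw1 <- bw0 + 3 + 3 * hfd + stats::rnorm(n, 0, 1.5)
  bwf <- bw0 + 8 + 12 * hfd + stats::rnorm(n, 0, 3)

  # strain median lifespan (days): base + QTL effect x dosage + strain noise
  ls_dos <- geno$dosage[, config$lifespan_qtl_marker_index]
  ls_strain <- 750 + config$lifespan_qtl_effect * ls_dos + stats::rnorm(n_s, 0, 60)
  names(ls_strain) <- geno$strain_ids
  longevity <- do.call(rbind, lapply(geno$strain_ids, function(s) {
    med_cd <- ls_strain[s]
    data.frame(
      strain_id = s, diet = c("CD", "HFD"),
      n_deaths = sample(5:12, 2, replace = TRUE),
      median_ls = c(med_cd, med_cd - 80),
      stringsAsFactors = FALSE
    )
  }))
  longevity$min_ls <- longevity$median_ls - 280
  longevity$q25_ls <- longevity$median_ls - 120
  longevity$mean_ls <- longevity$median_ls
  longevity$q75_ls <- longevity$median_ls + 120
  longevity$max_ls <- longevity$median_ls + 280
  longevity <- longevity_table(longevity)

  eaa_dos <- geno$dosage[strain_id, config$eaa_qtl_marker_index]
  eaa_offset <- age * config$eaa_qtl_effect * eaa_dos +
    stats::rnorm(n, 0, config$eaa_noise_sd)

  samples <- sample_table(data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    strain_id = strain_id, sex = sex, diet = diet, age = age,
    bw0 = bw0, bw1 = bw1, bwf = bwf, batch = batch,
    stringsAsFactors = FALSE
  ))

  # per-CpG ground truth (classes, slopes, covariate effects)
  set.seed(child_seed(config, "cohort") + 1L)
  n_c <- config$n_cpgs
  cpg_ids <- sprintf("cg%05d", seq_len(n_c))
  class <- rep("age-ns", n_c)
  gain_idx <- seq_len(config$n_age_gain)
  loss_idx <- config$n_age_gain + seq_len(config$n_age_loss)
  class[gain_idx] <- "age-gain"
  class[loss_idx] <- "age-loss"
  # planted class slopes: half-normal magnitude with a floor of 0.2
  # logit/yr, so labeled age-gain/age-loss CpGs are genuinely
  # distinguishable from age-ns at cohort-scale n, while staying small
  # enough that betas do not sweep across the full unit interval
  slope <- numeric(n_c)
  slope[gain_idx] <- 0.2 + abs(stats::rnorm(config$n_age_gain, 0, config$age_slope_sd))
  slope[loss_idx] <- -(0.2 + abs(stats::rnorm(config$n_age_loss, 0, config$age_slope_sd)))
  diet_aug <- ifelse(class == "age-gain", config$diet_aug, 0)
  weight_eff <- numeric(n_c)
  w_idx <- sample(n_c, min(config$n_weight_cpgs, n_c))
  weight_eff[w_idx] <- config$weight_effect * sample(c(-1, 1), length(w_idx), replace = TRUE)
  ls_eff <- numeric(n_c)
  l_idx <- sample(n_c, min(config$n_lifespan_cpgs, n_c))
  ls_eff[l_idx] <- config$lifespan_effect * sample(c(-1, 1), length(l_idx), replace = TRUE)

  truth <- structure(
    list(
      cpg_ids = cpg_ids, class = class, slope = slope, diet_aug = diet_aug,
      weight_effect = weight_eff, lifespan_effect = ls_eff,
      eaa_qtl_marker_index = config$eaa_qtl_marker_index,
      lifespan_qtl_marker_index = config$lifespan_qtl_marker_index,
      strain_median_lifespan = ls_strain,
      eaa_offset = stats::setNames(eaa_offset, samples$sample_id)
    ),
    class = "ground_truth"
  )
  list(samples = samples, longevity = longevity, truth = truth)
}

#' Simulate the methylome from cohort ground truth
#'
#' Each CpG's beta-value is the inverse logit of a per-CpG baseline drawn
#' from a two-component mixture (hypo- vs hyper-methylated modes, giving
#' the bimodal beta distribution of conserved CpGs), plus its age slope
#' times the sample's *biological* age — chronological age plus the
#' planted EAA offset, so the EAA locus acts as a genotype x age
#' interaction through each age-CpG's own slope — with HFD augmentation of
#' age-gain slopes, plus centered final-weight and strain-lifespan effects
#' on their CpG subsets, a per-batch shift, and logit-scale noise.
#'
#' @param config A [sim_config()].
#' @param samples Sample table from [simulate_cohort()].
#' @param geno Genotypes (unused directly; the QTL enters via the planted
#'   offset in `truth`, kept in the signature for interface symmetry).
#' @param truth Ground truth from [simulate_cohort()].
#' @return A [methylome] with synthetic annotation (chromosome, position,
#'   genomic class, chromatin state) attached.
#' @export
simulate_methylome <- function(config, samples, geno, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (nrow(samples) != length(truth$eaa_offset)) stop("samples/truth dimension mismatch")
  set.seed(child_seed(config, "methylome"))
  n <- nrow(samples)
  n_c <- config$n_cpgs
  class <- truth$class

  # baseline mixture: age-gain CpGs start hypomethylated, age-loss
  # hypermethylated (nearer the shoulder than the extremes, so drifting
  # toward mid-methylation erodes the bimodal peaks); the unlabeled rest
  # split 55% hyper / 45% hypo at the modes
  base <- numeric(n_c)
  hyper <- stats::runif(n_c) < 0.55
  hyper[class == "age-gain"] <- FALSE
  hyper[class == "age-loss"] <- TRUE
  base[hyper] <- stats::rnorm(sum(hyper), 2.2, 0.5)
  base[!hyper] <- stats::rnorm(sum(!hyper), -2.2, 0.5)
  base[class == "age-gain"] <- stats::rnorm(config$n_age_gain, -1.5, 0.5)
  base[class == "age-loss"] <- stats::rnorm(config$n_age_loss, 1.5, 0.5)

  bioage <- samples$age + truth$eaa_offset
  hfd <- as.numeric(samples$diet == "HFD")
  med_ls <- truth$strain_median_lifespan[samples$strain_id]
  bwf_c <- samples$bwf - mean(samples$bwf)
  ls_c <- med_ls - mean(med_ls)
  # probe-specific batch effect: each batch carries its own random
  # per-CpG bias profile of common magnitude, so the batch structure is
  # low-rank and dominates the leading principal components (as array
  # batch effects do) while perturbing every batch's beta spread equally
  batch_profile <- matrix(stats::rnorm(config$n_batches * n_c, 0, config$batch_sd),
                          config$n_batches, n_c)
  rownames(batch_profile) <- sprintf("batch%d", seq_len(config$n_batches))

  # logit(beta)_ij = base_j + slope_j * bioage_i * (1 + aug_j * HFD_i)
  #                + w_j * bwf_i + ls_j * medLS_i + batch_ij + eps_ij
  slope_mat <- outer(bioage, truth$slope) *
    (1 + outer(hfd, truth$diet_aug))
  lin <- slope_mat +
    outer(bwf_c, truth$weight_effect) +
    outer(ls_c, truth$lifespan_effect) +
    matrix(base, n, n_c, byrow = TRUE) +
    batch_profile[samples$batch, , drop = FALSE] +
    matrix(stats::rnorm(n * n_c, 0, config$noise_sd), n, n_c)
  beta <- stats::plogis(lin)
  dimnames(beta) <- list(samples$sample_id, truth$cpg_ids)

  annotation <- synthetic_cpg_annotation(truth$cpg_ids)
  methylome(beta, annotation)
}

#' Synthetic CpG annotation table
#'
#' Assigns each CpG a chromosome/position and random genomic-class and
#' 15-state chromatin-state labels. Purely synthetic; for exercising the
#' enrichment machinery, not a model of real annotation structure.
#'
#' @param cpg_ids CpG identifiers.
#' @param n_chromosomes Number of chromosomes to spread CpGs over.
#' @return data.frame suitable as [methylome()] annotation.
#' @export
synthetic_cpg_annotation <- function(cpg_ids, n_chromosomes = 19) {
  n <- length(cpg_ids)
  classes <- c("promoter", "5'UTR", "exon", "intron", "3'UTR", "intergenic")
  states <- c(sprintf("E%d", 1:15), "NRS")
  data.frame(
    cpg_id = cpg_ids,
    chrom = sample(seq_len(n_chromosomes), n, replace = TRUE),
    pos = sample.int(150e6, n),
    genomic_class = sample(classes, n, replace = TRUE,
                           prob = c(0.15, 0.05, 0.1, 0.3, 0.05, 0.35)),
    chromatin_state = sample(states, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort in one call
#'
#' Runs [simulate_ri_genotypes()], [simulate_cohort()] and
#' [simulate_methylome()] with the per-stage child seeds derived from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `geno`, `samples`, `longevity`, `truth`, `meth`.
#' @export
simulate_study <- function(config = sim_config()) {
  geno <- simulate_ri_genotypes(config)
  cohort <- simulate_cohort(config, geno)
  meth <- simulate_methylome(config, cohort$samples, geno, cohort$truth)
  list(
    geno = geno, samples = cohort$samples, longevity = cohort$longevity,
    truth = cohort$truth, meth = meth
  )
}

#' Simulate an expression matrix correlated with a sample-level trait
#'
#' Generates `n_features` features of which `n_correlated` are linear in
#' the given trait plus noise (random sign), the rest pure noise. Used to
#' exercise the expression-correlate ranking and clustering stages.
#'
#' @param trait Named numeric vector (names = sample ids).
#' @param n_features Total features.
#' @param n_correlated Number of trait-linked features.
#' @param effect Coefficient of the trait in linked features.
#' @param noise_sd Residual SD.
#' @param seed Seed.
#' @return List with `expr` (samples x features matrix) and
#'   `linked_features` (character vector).
#' @export
simulate_expression <- function(trait, n_features = 500, n_correlated = 50,
                                effect = 1, noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- length(trait)
  ids <- sprintf("gene%04d", seq_len(n_features))
  expr <- matrix(stats::rnorm(n * n_features, 0, noise_sd), n, n_features,
                 dimnames = list(names(trait), ids))
  linked <- sample(n_features, n_correlated)
  signs <- sample(c(-1, 1), n_correlated, replace = TRUE)
  expr[, linked] <- expr[, linked] +
    outer(as.numeric(trait), effect * signs)
  list(expr = expr, linked_features = ids[linked])
}
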