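#' Pipeline configuration
#'
#' Exactly one of `input` (paths to on-disk data) or `sim` (a
#' [sim_config()]) must be supplied; with `sim` the cohort is generated in
#' memory with the config's seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim Optional [sim_config()] for simulation mode.
#' @param input Optional named list of paths: `beta`, `annotation`
#'   (optional BED), `samples`, `longevity`, `geno`, `map`.
#' @param train_fraction Fraction of samples used to train the clock.
#' @param clock_alpha Elastic-net mixing parameter.
#' @param clock_folds CV folds for the clock.
#' @param ewas_alpha Bonferroni family-wise level for DMC classification.
#' @param females_only EWAS female restriction.
#' @param maf_min QTL scan MAF threshold.
#' @param scan_mode "exact" or "null-delta" (see [lmm_scan()]).
#' @param entropy_bins Bin count for entropy.
#' @param seed Seed for stages not covered by `sim` (train/test split).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, input = NULL,
                            train_fraction = 2 / 3, clock_alpha = 0.5,
                            clock_folds = 10, ewas_alpha = 0.05,
                            females_only = TRUE, maf_min = 0.05,
                            scan_mode = "exact", entropy_bins = 20,
                            seed = 1) {
  if (is.null(sim) == is.null(input)) {
    stop("exactly one of `sim` or `input` must be given")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: data (simulated or read from disk) ->
#' clock training / DNAm-age prediction / EAA -> methylome entropy ->
#' multivariable EWAS with DMC classification and per-class entropy ->
#' kinship-corrected QTL scan of EAA with heritability -> annotation
#' enrichment and chromatin-state profile. Every output table is written
#' to `out_dir`; the returned manifest lists each file with its MD5
#' checksum, so identical config + seed reproduce identical manifests.
#' A stage failure aborts with the stage named; outputs written so far
#' are kept.
#'
#' @param cfg A [pipeline_config()].
#' @return data.frame manifest (`file`, `md5`), invisibly also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outputs <- character(0)
  note_output <- function(path) outputs <<- c(outputs, path)
  emit <- function(obj, file) {
    path <- file.path(cfg$out_dir, file)
    write_result_table(obj, path)
    note_output(path)
    path
  }

  dat <- stage("data", {
    if (!is.null(cfg$sim)) {
      simulate_study(cfg$sim)
    } else {
      list(
        meth = read_methylome(cfg$input$beta, cfg$input$annotation),
        samples = read_sample_table(cfg$input$samples),
        longevity = longevity_table(utils::read.delim(cfg$input$longevity,
                                                      stringsAsFactors = FALSE)),
        geno = read_genotypes(cfg$input$geno, cfg$input$map),
        truth = NULL
      )
    }
  })

  clockres <- stage("clocks", {
    set.seed(cfg$seed)
    n <- length(dat$meth$sample_ids)
    train_idx <- sort(sample(n, round(cfg$train_fraction * n)))
    train_meth <- methylome(dat$meth$beta[train_idx, , drop = FALSE],
                            dat$meth$annotation)
    model <- train_clock(train_meth, dat$samples,
                         alpha = cfg$clock_alpha, n_folds = cfg$clock_folds,
                         seed = cfg$seed)
    dnam <- predict_dnam_age(model, dat$meth)
    eaa <- compute_eaa(dnam, dat$samples)
    model_path <- file.path(cfg$out_dir, "clock_model.json")
    write_clock_model(model, model_path)
    note_output(model_path)
    emit(eaa, "eaa.tsv")
    list(model = model, eaa = eaa, train_idx = train_idx)
  })

  ent <- stage("entropy", {
    e <- methylome_entropy(dat$meth, n_bins = cfg$entropy_bins)
    emit(e, "entropy.tsv")
    e
  })

  ewasres <- stage("ewas", {
    pcs <- compute_pcs(dat$meth, n_components = min(10, length(dat$meth$sample_ids) - 1))
    tab <- fit_site_regressions(dat$meth, dat$samples, dat$longevity, pcs,
                                females_only = cfg$females_only)
    tab <- classify_dmcs(tab, alpha = cfg$ewas_alpha, n_tests = nrow(tab))
    emit(tab, "ewas.tsv")
    emit(overlap_dmcs(tab), "dmc_overlap.tsv")
    for (cl in c("age-gain", "age-loss")) {
      ids <- tab$cpg_id[tab$class == cl]
      if (length(ids) >= 2) {
        ecl <- methylome_entropy(dat$meth, ids, n_bins = cfg$entropy_bins,
                                 cpg_set_label = cl)
        emit(ecl, sprintf("entropy_%s.tsv", sub("age-", "", cl)))
      }
    }
    tab
  })

  scan <- stage("qtl", {
    K <- kinship_matrix(dat$geno)
    covar <- cbind(
      diet = as.numeric(dat$samples$diet == "HFD"),
      bwf = dat$samples$bwf
    )
    trait <- stats::setNames(clockres$eaa$eaa, clockres$eaa$sample_id)
    sc <- lmm_scan(trait, covar, dat$geno, K,
                   strain_ids = dat$samples$strain_id,
                   maf_min = cfg$maf_min, mode = cfg$scan_mode)
    emit(sc, "eaa_scan.tsv")
    h2 <- anova_heritability(clockres$eaa$eaa, dat$samples$strain_id)
    emit(data.frame(trait = "eaa", h2 = h2), "heritability.tsv")
    sc
  })

  stage("enrichment", {
    if (!is.null(dat$meth$annotation)) {
      fg <- ewasres$cpg_id[ewasres$class != "age-ns"]
      if (length(fg) >= 1) {
        cats <- stats::setNames(dat$meth$annotation$genomic_class,
                                dat$meth$annotation$cpg_id)
        enr <- hypergeom_enrich(fg, ewasres$cpg_id, cats)
        emit(enr, "enrichment_genomic_class.tsv")
      }
      prof <- chromatin_state_profile(dat$meth, ewasres)
      emit(prof$states, "chromatin_state_profile.tsv")
    }
    NULL
  })

  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  write_result_table(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  manifest
}
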