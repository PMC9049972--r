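#' Realized-relatedness kinship matrix
#'
#' Centered genomic relatedness: `K = Xc Xc' / m` over the `m` markers,
#' where `Xc` is the dosage matrix with each marker column centered at its
#' mean (missing dosages mean-imputed per marker first). Symmetric and
#' positive semidefinite by construction.
#'
#' @param geno A [genotypes()] object.
#' @return Matrix of class `kinship` (strains x strains, dimnames = strain
#'   ids).
#' @export
kinship_matrix <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  if (length(geno$strain_ids) < 2) stop("need >= 2 strains")
  X <- geno$dosage
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  poly <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!any(poly)) stop("no polymorphic markers; kinship undefined")
  Xc <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(geno$strain_ids, geno$strain_ids)
  class(K) <- c("kinship", class(K))
  K
}

# profile log-likelihood machinery for the single-random-effect LMM
# y = W a + x b + u + e,  u ~ N(0, sg2 K), e ~ N(0, se2 I), delta = se2/sg2.
# In the eigenbasis of K (K = U L U'), Var(U'y) = sg2 diag(lambda + delta):
# weighted least squares with weights 1/(lambda + delta) profiles out the
# fixed effects and sg2, leaving a 1-D likelihood in delta.
lmm_profile <- function(log_delta, yt, Wt, lambda) {
  delta <- exp(log_delta)
  v <- lambda + delta
  w <- 1 / v
  Ww <- Wt * w
  XtX <- crossprod(Wt, Ww)
  Xty <- crossprod(Ww, yt)
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  r <- yt - Wt %*% beta
  rss <- sum(r^2 * w)
  n <- length(yt)
  sg2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sg2) + sum(log(v)) + n)
  list(ll = ll, beta = beta, rss = rss, XtX = XtX, delta = delta)
}

#' Kinship-corrected mixed-model genome scan
#'
#' Per-marker association of a quantitative trait under the model
#' `y = W a + x b + u + e` with `u ~ N(0, sg2 K)` — the efficient
#' mixed-model (EMMA/GEMMA-style) formulation solved in the eigenbasis of
#' the kinship matrix, one decomposition per scan. The variance ratio
#' `delta = se2/sg2` is optimized per marker by maximum likelihood over
#' `log delta` in \[-10, 10\] (`mode = "exact"`), or fixed once at the
#' no-marker null fit (`mode = "null-delta"`, faster). The reported test
#' is a Wald t-test on the marker coefficient with an (n - p) residual
#' divisor, so with zero kinship it reduces exactly to OLS. Markers below
#' the MAF threshold are skipped and flagged.
#'
#' @param trait Named numeric vector (names = sample ids).
#' @param covariates Optional numeric matrix / data.frame of fixed
#'   covariates (rows = samples, same order as `trait`). An intercept is
#'   always added.
#' @param geno A [genotypes()] object (strain-level dosages).
#' @param kinship A [kinship_matrix()] over the same strains.
#' @param strain_ids Strain of each sample (maps samples to genotype and
#'   kinship rows; replicates of a strain share its genome).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param mode "exact" (per-marker delta) or "null-delta".
#' @return data.frame of class `scan_result`: per marker `marker_id`,
#'   `chrom`, `pos`, `maf`, `beta`, `se`, `p`, `neg_log10_p`, `lod`,
#'   `skipped`.
#' @export
lmm_scan <- function(trait, covariates = NULL, geno, kinship, strain_ids,
                     maf_min = 0.05, mode = c("exact", "null-delta")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geno, "genotypes"))
  n <- length(trait)
  if (any(!is.finite(trait))) stop("trait must be finite")
  if (stats::sd(trait) == 0) stop("trait is constant")
  if (length(strain_ids) != n) stop("strain_ids must match trait length")
  if (!all(strain_ids %in% rownames(kinship))) {
    stop("kinship does not cover all sample strains")
  }
  # expand strain-level kinship to samples (replicates share kinship rows)
  Ks <- kinship[strain_ids, strain_ids]
  eig <- eigen(Ks, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, trait)
  W <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    W <- cbind(W, as.matrix(covariates))
  }
  Wt <- crossprod(U, W)
  Xall <- geno$dosage[strain_ids, , drop = FALSE]
  Xt_all <- crossprod(U, Xall)

  null_delta <- NULL
  if (mode == "null-delta") {
    opt0 <- stats::optimize(function(ld) lmm_profile(ld, yt, Wt, lambda)$ll,
                            interval = c(-10, 10), maximum = TRUE, tol = 1e-6)
    null_delta <- exp(opt0$maximum)
  }

  m <- length(geno$marker_ids)
  beta_out <- se_out <- p_out <- rep(NA_real_, m)
  skipped <- geno$maf < maf_min | is.na(geno$maf)
  p_fixed <- ncol(Wt) + 1
  for (j in which(!skipped)) {
    Wj <- cbind(Wt, marker = Xt_all[, j])
    if (mode == "exact") {
      opt <- stats::optimize(function(ld) lmm_profile(ld, yt, Wj, lambda)$ll,
                             interval = c(-10, 10), maximum = TRUE, tol = 1e-6)
      fit <- lmm_profile(opt$maximum, yt, Wj, lambda)
    } else {
      fit <- lmm_profile(log(null_delta), yt, Wj, lambda)
    }
    if (!is.finite(fit$ll)) next
    sg2 <- fit$rss / (n - p_fixed)
    covb <- tryCatch(chol2inv(chol(fit$XtX)) * sg2, error = function(e) NULL)
    if (is.null(covb)) next
    b <- fit$beta[p_fixed]
    se <- sqrt(covb[p_fixed, p_fixed])
    tt <- b / se
    beta_out[j] <- b
    se_out[j] <- se
    p_out[j] <- 2 * stats::pt(abs(tt), n - p_fixed, lower.tail = FALSE)
  }
  lod_out <- rep(NA_real_, m)
  ok <- !is.na(p_out)
  lod_out[ok] <- p_to_lod(pmin(pmax(p_out[ok], 1e-300), 1 - 1e-16))
  out <- data.frame(
    marker_id = geno$marker_ids, chrom = geno$chrom, pos = geno$pos,
    maf = geno$maf, beta = beta_out, se = se_out, p = p_out,
    neg_log10_p = -log10(p_out),
    lod = lod_out,
    skipped = skipped,
    stringsAsFactors = FALSE
  )
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Fisher combination of per-trait p-values
#'
#' `X = -2 sum(log p)` referred to a chi-square with `2k` degrees of
#' freedom. Used to highlight markers with consistent linkage across
#' several EAA traits.
#'
#' @param p Vector of p-values in (0, 1\].
#' @return Meta p-value.
#' @export
fisher_combine <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]; floor zeros upstream (e.g. at 1e-300)")
  }
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Combine several genome scans into a meta scan
#'
#' Applies [fisher_combine()] marker-by-marker across scans of different
#' traits on the same marker set, flooring p at `p_floor` first.
#'
#' @param scans List of `scan_result` objects over identical markers.
#' @param p_floor Lower bound applied to each p before taking logs.
#' @return The first scan's marker frame with `meta_p` and `meta_lod`.
#' @export
meta_scan <- function(scans, p_floor = 1e-300) {
  stopifnot(length(scans) >= 2)
  ids <- scans[[1]]$marker_id
  for (s in scans) {
    if (!identical(s$marker_id, ids)) stop("scans must share one marker set")
  }
  pm <- sapply(scans, `[[`, "p")
  meta <- apply(pm, 1, function(p) {
    if (any(is.na(p))) return(NA_real_)
    fisher_combine(pmax(p, p_floor))
  })
  out <- scans[[1]][, c("marker_id", "chrom", "pos")]
  out$meta_p <- meta
  out$meta_lod <- ifelse(is.na(meta), NA_real_, p_to_lod(pmax(meta, 1e-300)))
  out
}

#' Convert a p-value to a LOD score
#'
#' Uses the 1-df chi-square quantile identity
#' `LOD = qchisq(1 - p, 1) / (2 ln 10)`; strictly decreasing in p. This is
#' the conversion that reproduces printed (p, LOD) pairs such as
#' 3.5e-6 -> 4.7 and 9e-7 -> 5.2, where a naive `-log10(p)` does not.
#'
#' @param p p-value(s) in (0, 1).
#' @return LOD score(s).
#' @export
p_to_lod <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly in (0, 1)")
  }
  stats::qchisq(p, df = 1, lower.tail = FALSE) / (2 * log(10))
}

#' Inverse of [p_to_lod()]
#' @param lod LOD score(s) >= 0.
#' @return p-value(s).
#' @export
lod_to_p <- function(lod) {
  if (any(!is.finite(lod)) || any(lod < 0)) stop("lod must be >= 0")
  stats::pchisq(lod * 2 * log(10), df = 1, lower.tail = FALSE)
}

#' Strain heritability from one-way ANOVA
#'
#' `h2 = SSq_strain / (SSq_strain + SSq_residual)` from `aov(trait ~ strain)`
#' — the fraction of trait variance explained by background genotype.
#'
#' @param trait Numeric trait per sample.
#' @param strain_ids Strain of each sample.
#' @return h2 in \[0, 1\].
#' @export
anova_heritability <- function(trait, strain_ids) {
  stopifnot(length(trait) == length(strain_ids))
  strain <- factor(strain_ids)
  if (nlevels(strain) < 2) stop("need >= 2 strains")
  if (!any(table(strain) >= 2)) stop("need at least one strain with >= 2 samples")
  if (stats::var(trait) == 0) stop("trait is constant; heritability undefined")
  fit <- stats::aov(trait ~ strain)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  ss[1] / sum(ss)
}

#' Marker-specific linkage model
#'
#' OLS of the trait on a genotype indicator (D homozygote = 1) with diet
#' as covariate: `lm(trait ~ genotype + diet)`. Heterozygotes (dosage 0.5)
#' are excluded before fitting.
#'
#' @param trait Numeric trait per sample.
#' @param genotype_at_marker Dosage per sample in {0, 0.5, 1, NA}.
#' @param diet Diet per sample ("CD"/"HFD" or any 2-level coding).
#' @return List with `estimate`, `se`, `t`, `p`, `n` for the genotype term.
#' @export
marker_linkage <- function(trait, genotype_at_marker, diet) {
  keep <- !is.na(genotype_at_marker) & genotype_at_marker %in% c(0, 1) &
    is.finite(trait)
  g <- genotype_at_marker[keep]
  if (length(unique(g)) < 2) stop("need both homozygote classes after excluding heterozygotes")
  d <- factor(diet[keep])
  df <- data.frame(y = trait[keep], g = g, d = d)
  fit <- stats::lm(y ~ g + d, data = df)
  cf <- summary(fit)$coefficients["g", ]
  list(
    estimate = unname(cf[1]), se = unname(cf[2]),
    t = unname(cf[3]), p = unname(cf[4]), n = sum(keep)
  )
}

#' Random-intercept model for longitudinal body weight
#'
#' REML linear mixed model `weight ~ age + diet + genotype + (1 | mouse)`
#' with a single random intercept per mouse, for testing genotype effects
#' on weight trajectories. Fit with lme4; Wald z-tests on fixed effects.
#'
#' @param weights Numeric weight observations (grams).
#' @param ages Age (months or years, any consistent unit) per observation.
#' @param diet Diet per observation.
#' @param genotype Genotype indicator per observation (e.g. dosage 0/1).
#' @param mouse_ids Mouse identifier per observation.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p` for the
#'   fixed effects, and attribute `fit` carrying the lme4 object.
#' @export
random_intercept_weight_model <- function(weights, ages, diet, genotype, mouse_ids) {
  df <- data.frame(
    weight = weights, age = ages, diet = factor(diet),
    genotype = genotype, mouse = factor(mouse_ids)
  )
  if (!any(table(df$mouse) >= 2)) stop("need >= 2 observations for at least one mouse")
  fit <- lme4::lmer(weight ~ age + diet + genotype + (1 | mouse),
                    data = df, REML = TRUE)
  cf <- as.data.frame(summary(fit)$coefficients)
  out <- data.frame(
    term = rownames(cf), estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
    z = cf[, "t value"], p = 2 * stats::pnorm(abs(cf[, "t value"]), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
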