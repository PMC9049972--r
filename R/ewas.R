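#' Principal components of the beta matrix
#'
#' Singular value decomposition of the column-centered samples x CpGs
#' matrix. Scores are sample coordinates; the sign of each component is
#' fixed so that its largest-magnitude CpG loading is positive. PC1 is
#' used as the unmeasured-confounder (batch) correction in the EWAS.
#'
#' @param meth A [methylome].
#' @param n_components Number of components to return (default 10, capped
#'   implicitly by the matrix rank).
#' @return List of class `pc_result`: `scores` (samples x k, rownames =
#'   sample ids), `variance_fraction` (length k), `n_components`.
#' @export
compute_pcs <- function(meth, n_components = 10) {
  stopifnot(inherits(meth, "methylome"))
  x <- meth$beta
  if (nrow(x) < 2) stop("need >= 2 samples")
  if (n_components > min(dim(x))) {
    stop(sprintf("n_components = %d exceeds min(dim) = %d", n_components, min(dim(x))))
  }
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, `*`)
  rownames(scores) <- meth$sample_ids
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  structure(
    list(
      scores = scores,
      variance_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
      n_components = n_components
    ),
    class = "pc_result"
  )
}

#' Site-by-site multivariable EWAS
#'
#' Fits, for every CpG, the ordinary-least-squares model
#' `beta_i ~ age + median_lifespan + diet + bwf + PC1` with two-sided
#' t-tests per coefficient. Diet is coded HFD = 1, CD = 0, so its estimate
#' is the change on high-fat diet relative to control. Strain median
#' lifespan is joined by (strain, diet); samples of strains without a
#' longevity row, or with any missing covariate, are dropped listwise with
#' a message. Because lifespan summaries come from female cohorts the
#' default drops male samples.
#'
#' @param meth A [methylome].
#' @param samples A [sample_table()].
#' @param longevity A [longevity_table()].
#' @param pcs Optional [compute_pcs()] result; if NULL, computed from
#'   `meth`. Only PC1 enters the model.
#' @param females_only Drop male samples first (default TRUE).
#' @return data.frame of class `ewas_table`, one row per CpG with
#'   `estimate_*`, `se_*`, `p_*` for predictors age, lifespan, diet, bwf,
#'   and attribute `n_used` (samples in the fit).
#' @export
fit_site_regressions <- function(meth, samples, longevity, pcs = NULL,
                                 females_only = TRUE) {
  stopifnot(inherits(meth, "methylome"))
  if (is.null(pcs)) pcs <- compute_pcs(meth, n_components = 1)
  idx <- match(meth$sample_ids, samples$sample_id)
  if (anyNA(idx)) stop("sample table does not cover all methylome samples")
  cov <- samples[idx, , drop = FALSE]
  key <- paste(cov$strain_id, cov$diet)
  ls_key <- paste(longevity$strain_id, longevity$diet)
  cov$median_ls <- longevity$median_ls[match(key, ls_key)]
  cov$pc1 <- pcs$scores[match(meth$sample_ids, rownames(pcs$scores)), 1]

  keep <- rep(TRUE, nrow(cov))
  if (females_only) keep <- keep & cov$sex == "F"
  need <- c("age", "median_ls", "bwf", "pc1")
  complete <- stats::complete.cases(cov[, need])
  n_drop <- sum(keep & !complete)
  if (n_drop > 0) {
    message(sprintf("EWAS: dropping %d sample(s) with missing covariates", n_drop))
  }
  keep <- keep & complete
  if (sum(keep) < 7) stop("too few samples after filtering for a 6-parameter model")

  X <- cbind(
    intercept = 1,
    age = cov$age[keep],
    lifespan = cov$median_ls[keep],
    diet = as.numeric(cov$diet[keep] == "HFD"),
    bwf = cov$bwf[keep],
    pc1 = cov$pc1[keep]
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient EWAS design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  Y <- meth$beta[keep, , drop = FALSE]
  coefs <- qr.coef(qrX, Y)                       # p x m
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(xtx_inv), sigma2))       # p x m
  dimnames(se) <- dimnames(coefs)
  tstat <- coefs / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  preds <- c("age", "lifespan", "diet", "bwf")
  out <- data.frame(cpg_id = meth$cpg_ids, stringsAsFactors = FALSE)
  for (pr in preds) {
    out[[paste0("estimate_", pr)]] <- coefs[pr, ]
    out[[paste0("se_", pr)]] <- se[pr, ]
    out[[paste0("p_", pr)]] <- pval[pr, ]
  }
  attr(out, "n_used") <- nrow(X)
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Classify differentially methylated CpGs (DMCs)
#'
#' Applies a Bonferroni threshold `alpha / n_tests` (inclusive) per
#' predictor. CpGs passing for age are split by the sign of the age
#' estimate into age-gain / age-loss; the rest are age-ns. Flags mark
#' weight-, diet-, and lifespan-DMCs.
#'
#' @param table An `ewas_table`.
#' @param alpha Family-wise error target (default 0.05).
#' @param n_tests Bonferroni denominator; must be at least the number of
#'   CpGs tested.
#' @return The table with columns `class`, `weight_dmc`, `diet_dmc`,
#'   `ls_dmc` filled, and attribute `threshold`.
#' @export
classify_dmcs <- function(table, alpha = 0.05, n_tests = nrow(table)) {
  stopifnot(inherits(table, "ewas_table"))
  if (n_tests < nrow(table)) stop("n_tests must be >= number of CpGs tested")
  thr <- alpha / n_tests
  age_dmc <- table$p_age <= thr
  table$class <- ifelse(age_dmc & table$estimate_age > 0, "age-gain",
    ifelse(age_dmc & table$estimate_age < 0, "age-loss", "age-ns")
  )
  table$weight_dmc <- table$p_bwf <= thr
  table$diet_dmc <- table$p_diet <= thr
  table$ls_dmc <- table$p_lifespan <= thr
  attr(table, "threshold") <- thr
  table
}

#' Intersection counts among DMC sets
#'
#' Counts CpGs in every non-empty intersection region of the four DMC
#' sets (age, weight, diet, lifespan), i.e. the 15 cells of the Venn
#' partition. Region sums are consistent with the marginal counts.
#'
#' @param table A classified `ewas_table` (see [classify_dmcs()]).
#' @return data.frame with logical membership columns `age`, `weight`,
#'   `diet`, `ls` and a `count` per region.
#' @export
overlap_dmcs <- function(table) {
  if (is.null(table$class)) stop("run classify_dmcs() first")
  mem <- cbind(
    age = table$class != "age-ns",
    weight = table$weight_dmc,
    diet = table$diet_dmc,
    ls = table$ls_dmc
  )
  grid <- expand.grid(
    age = c(FALSE, TRUE), weight = c(FALSE, TRUE),
    diet = c(FALSE, TRUE), ls = c(FALSE, TRUE)
  )
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  grid$count <- apply(grid, 1, function(g) {
    sum(apply(mem == matrix(as.logical(g[1:4]), nrow(mem), 4, byrow = TRUE), 1, all))
  })
  rownames(grid) <- NULL
  grid
}
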