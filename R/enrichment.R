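#' Hypergeometric enrichment and depletion of a CpG set
#'
#' For each annotation category with `K` members among the `N` background
#' ids, of which `k` fall in the `n`-id foreground, computes the
#' over-representation tail `P(X >= k)` and depletion tail `P(X <= k)` of
#' `X ~ Hypergeometric(N, K, n)`, the observed/expected fold, and
#' Benjamini-Hochberg adjusted p-values (adjusted separately for the two
#' tails across categories).
#'
#' @param foreground Character vector of ids (must be a subset of the
#'   background).
#' @param background Character vector of all ids assayed.
#' @param categories Named character vector or data.frame
#'   (`id`, `label`) mapping every background id to a category label.
#' @return data.frame with `category`, `background_count`,
#'   `foreground_count`, `expected`, `fold`, `p_over`, `p_under`,
#'   `p_over_adj`, `p_under_adj`.
#' @export
hypergeom_enrich <- function(foreground, background, categories) {
  if (is.data.frame(categories)) {
    categories <- stats::setNames(as.character(categories[[2]]), categories[[1]])
  }
  offenders <- setdiff(foreground, background)
  if (length(offenders)) {
    stop("foreground ids not in background: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  }
  unlabeled <- setdiff(background, names(categories))
  if (length(unlabeled)) {
    stop("background ids without a category label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(foreground)
  lab_bg <- categories[background]
  lab_fg <- categories[foreground]
  cats <- sort(unique(lab_bg))
  K <- as.vector(table(factor(lab_bg, levels = cats)))
  k <- as.vector(table(factor(lab_fg, levels = cats)))
  expected <- n * K / N
  p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  data.frame(
    category = cats, background_count = K, foreground_count = k,
    expected = expected, fold = ifelse(expected > 0, k / expected, NA_real_),
    p_over = p_over, p_under = p_under,
    p_over_adj = bh_adjust(p_over), p_under_adj = bh_adjust(p_under),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' adjusted values never fall below the raw p.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Chromatin-state methylation and effect profile
#'
#' Aggregates mean beta-value and mean EWAS coefficient per chromatin
#' state, then regresses the per-state mean coefficient on the per-state
#' mean methylation with degree-1 and degree-2 polynomials — the analysis
#' behind "inverse linear" (age) and "U-shaped" (diet) profiles across
#' states.
#'
#' @param meth An annotated [methylome] (chromatin_state column present).
#' @param ewas An `ewas_table` over the same CpGs.
#' @param predictors Coefficient columns to profile (default age,
#'   lifespan, diet, bwf).
#' @return List with `states` (per-state means) and `fits` (per predictor:
#'   linear r/p and quadratic coefficient/p, R-squared of both fits), or
#'   fits NULL (with a warning) when fewer than 3 states carry data.
#' @export
chromatin_state_profile <- function(meth, ewas,
                                    predictors = c("age", "lifespan", "diet", "bwf")) {
  stopifnot(inherits(meth, "methylome"))
  if (is.null(meth$annotation) || is.null(meth$annotation$chromatin_state)) {
    stop("methylome has no chromatin-state annotation")
  }
  state <- meth$annotation$chromatin_state[match(ewas$cpg_id, meth$annotation$cpg_id)]
  mean_beta_cpg <- colMeans(meth$beta)[ewas$cpg_id]
  states <- sort(unique(state))
  agg <- data.frame(state = states, stringsAsFactors = FALSE)
  agg$mean_beta <- vapply(states, function(s) mean(mean_beta_cpg[state == s]), numeric(1))
  for (pr in predictors) {
    est <- ewas[[paste0("estimate_", pr)]]
    agg[[paste0("mean_estimate_", pr)]] <-
      vapply(states, function(s) mean(est[state == s]), numeric(1))
  }
  fits <- NULL
  if (nrow(agg) < 3) {
    warning("fewer than 3 chromatin states with data; skipping fits")
  } else {
    fits <- lapply(predictors, function(pr) {
      y <- agg[[paste0("mean_estimate_", pr)]]
      x <- agg$mean_beta
      lin <- stats::lm(y ~ x)
      r <- stats::cor(x, y)
      lin_p <- summary(lin)$coefficients[2, 4]
      quad_fit <- if (nrow(agg) >= 4) stats::lm(y ~ x + I(x^2)) else NULL
      list(
        predictor = pr, linear_r = r, linear_p = lin_p,
        linear_r2 = summary(lin)$r.squared,
        quadratic_coef = if (!is.null(quad_fit)) stats::coef(quad_fit)[["I(x^2)"]] else NA_real_,
        quadratic_p = if (!is.null(quad_fit)) summary(quad_fit)$coefficients["I(x^2)", 4] else NA_real_,
        quadratic_r2 = if (!is.null(quad_fit)) summary(quad_fit)$r.squared else NA_real_
      )
    })
    names(fits) <- predictors
  }
  list(states = agg, fits = fits)
}

#' Rank expression features by correlation with an EAA trait
#'
#' Pearson correlation of every feature with the trait over shared
#' samples; features are ranked by |r| descending (ties broken by feature
#' id) and truncated to `top_n`. Constant features are excluded with a
#' message since their correlation is undefined.
#'
#' @param eaa An `eaa_result` (or any data.frame with `sample_id` and a
#'   trait column named by `trait_col`).
#' @param expr Numeric matrix, samples x features, rownames = sample ids.
#' @param top_n Maximum features returned (default 2000).
#' @param trait_col Column of `eaa` to correlate (default "eaa").
#' @return data.frame of class `correlate_table`: `feature_id`, `r`, `p`,
#'   `rank`; attributes `n_positive`, `n_negative`, `n_shared_samples`.
#' @export
rank_correlates <- function(eaa, expr, top_n = 2000, trait_col = "eaa") {
  shared <- intersect(eaa$sample_id, rownames(expr))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  y <- eaa[[trait_col]][match(shared, eaa$sample_id)]
  x <- expr[shared, , drop = FALSE]
  sdv <- apply(x, 2, stats::sd)
  n_const <- sum(sdv == 0)
  if (n_const > 0) {
    message(sprintf("excluding %d constant feature(s)", n_const))
    x <- x[, sdv > 0, drop = FALSE]
  }
  r <- as.vector(stats::cor(y, x))
  nshared <- length(shared)
  tstat <- r * sqrt((nshared - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), nshared - 2, lower.tail = FALSE)
  ord <- order(-abs(r), colnames(x))
  keep <- utils::head(ord, top_n)
  out <- data.frame(
    feature_id = colnames(x)[keep], r = r[keep], p = p[keep],
    rank = seq_along(keep), stringsAsFactors = FALSE
  )
  attr(out, "n_positive") <- sum(out$r > 0)
  attr(out, "n_negative") <- sum(out$r < 0)
  attr(out, "n_shared_samples") <- nshared
  class(out) <- c("correlate_table", "data.frame")
  out
}

#' Cluster correlated features by hierarchical clustering
#'
#' Agglomerative clustering of features with distance `1 - Pearson r`
#' between feature profiles, average linkage, cut into `k` groups.
#' Deterministic.
#'
#' @param expr Numeric matrix, samples x features (the shared-correlate
#'   submatrix).
#' @param k Number of clusters (default 3).
#' @return Named integer vector of cluster labels per feature.
#' @export
cluster_correlates <- function(expr, k = 3) {
  if (ncol(expr) < 2) stop("need >= 2 features")
  if (k > ncol(expr)) stop("k exceeds the number of features")
  d <- stats::as.dist(1 - stats::cor(expr))
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = k)
}
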