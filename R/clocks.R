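#' Log-linear age transform parameters
#'
#' The clock response is not chronological age itself but a log-linear
#' transform of it that is logarithmic through development and linear in
#' adulthood, continuous and differentiable at the adult-age knot. For the
#' mouse the knot sits at 1.2 years with an offset of 0.06 years.
#'
#' @param adult_age Age (years) at which the transform switches from
#'   logarithmic to linear. Default 1.2.
#' @param offset Positive offset (years) inside the logarithm. Default 0.06.
#' @return List of class `transform_params`.
#' @export
transform_params <- function(adult_age = 1.2, offset = 0.06) {
  stopifnot(adult_age > 0, offset > 0)
  structure(list(adult_age = adult_age, offset = offset), class = "transform_params")
}

#' Transform chronological age to the clock response scale
#'
#' `f(a) = log(a + offset)` for `a <= adult_age`, and
#' `f(a) = (a - adult_age) / (adult_age + offset) + log(adult_age + offset)`
#' above it. Strictly increasing and C1 at the knot.
#'
#' @param age Ages in years (vectorized). Must exceed `-offset`.
#' @param params A [transform_params()].
#' @return Transformed ages (dimensionless).
#' @export
transform_age <- function(age, params = transform_params()) {
  if (any(!is.finite(age)) || any(age <= -params$offset)) {
    stop("age must be finite and > -offset")
  }
  k <- params$adult_age + params$offset
  ifelse(age <= params$adult_age,
    log(age + params$offset),
    (age - params$adult_age) / k + log(k)
  )
}

#' Invert the log-linear age transform
#'
#' @param y Transformed ages (finite).
#' @param params A [transform_params()].
#' @return Ages in years; exact inverse of [transform_age()].
#' @export
inverse_transform_age <- function(y, params = transform_params()) {
  if (any(!is.finite(y))) stop("transformed age must be finite")
  k <- params$adult_age + params$offset
  ifelse(y <= log(k),
    exp(y) - params$offset,
    k * (y - log(k)) + params$adult_age
  )
}

#' Select developmental CpGs by correlation with age in young mice
#'
#' Restricts to samples younger than `age_cutoff`, computes the Pearson
#' correlation of each CpG's beta-values with age on that subset, and
#' returns the `n_per_sign` most positive plus `n_per_sign` most negative
#' correlates. Ties are broken lexicographically by CpG id so the
#' selection is deterministic.
#'
#' @param meth A [methylome].
#' @param samples A [sample_table()] covering the methylome samples.
#' @param age_cutoff Upper age bound in years for the "young" subset
#'   (default 1.6/12, i.e. 1.6 months).
#' @param n_per_sign Number of CpGs to keep per correlation sign.
#' @return Character vector of 2 * n_per_sign CpG ids.
#' @export
select_developmental_cpgs <- function(meth, samples, age_cutoff = 1.6 / 12,
                                      n_per_sign = 1000) {
  idx <- match(meth$sample_ids, samples$sample_id)
  if (anyNA(idx)) stop("sample table does not cover all methylome samples")
  age <- samples$age[idx]
  young <- which(age < age_cutoff)
  if (length(young) < 3) {
    stop(sprintf("need >= 3 samples younger than %.3g years, have %d", age_cutoff, length(young)))
  }
  b <- meth$beta[young, , drop = FALSE]
  sdv <- apply(b, 2, stats::sd)
  if (all(sdv == 0)) stop("all CpGs constant in the young subset; correlation undefined")
  r <- rep(NA_real_, ncol(b))
  r[sdv > 0] <- as.vector(stats::cor(age[young], b[, sdv > 0, drop = FALSE]))
  ids <- meth$cpg_ids
  pos <- ids[!is.na(r) & r > 0]
  neg <- ids[!is.na(r) & r < 0]
  if (length(pos) < n_per_sign || length(neg) < n_per_sign) {
    stop(sprintf(
      "need %d CpGs per sign, have %d positive and %d negative correlates",
      n_per_sign, length(pos), length(neg)
    ))
  }
  ord_pos <- pos[order(-r[match(pos, ids)], pos)][seq_len(n_per_sign)]
  ord_neg <- neg[order(r[match(neg, ids)], neg)][seq_len(n_per_sign)]
  sort(c(ord_pos, ord_neg))
}

#' Select intervention-responsive CpGs consistent across studies
#'
#' Given two or more per-CpG association tables from anti-aging
#' intervention experiments (e.g. caloric restriction, growth-hormone
#' receptor knockout), keeps the CpGs that are significant in every table
#' with the same effect sign throughout, ranks them by Fisher-combined
#' p-value, and truncates to `max_k`.
#'
#' @param assoc_tables List (length >= 2) of data.frames with columns
#'   `cpg_id`, `estimate`, `p`, all sharing one CpG universe.
#' @param p_threshold Per-table significance threshold.
#' @param max_k Maximum number of CpGs returned (default 537, the size of
#'   the consistently intervention-responsive set used for the
#'   interventional clock).
#' @return Character vector of CpG ids, ranked by combined evidence.
#' @export
select_interventional_cpgs <- function(assoc_tables, p_threshold = 0.05, max_k = 537) {
  if (!is.list(assoc_tables) || length(assoc_tables) < 2) {
    stop("need >= 2 association tables; consistency is undefined for one")
  }
  ids <- sort(assoc_tables[[1]]$cpg_id)
  for (tab in assoc_tables) {
    if (!setequal(tab$cpg_id, ids)) stop("association tables must share one CpG universe")
  }
  est <- sapply(assoc_tables, function(t) t$estimate[match(ids, t$cpg_id)])
  p <- sapply(assoc_tables, function(t) t$p[match(ids, t$cpg_id)])
  sig <- rowSums(p < p_threshold) == ncol(p)
  consistent <- apply(sign(est), 1, function(s) all(s == s[1]) && all(s != 0))
  keep <- which(sig & consistent)
  if (!length(keep)) return(character(0))
  meta <- apply(p[keep, , drop = FALSE], 1, fisher_combine)
  sel <- keep[order(meta, ids[keep])]
  ids[utils::head(sel, max_k)]
}

#' Train an elastic-net methylation clock
#'
#' Regresses the transformed chronological age on CpG beta-values with an
#' elastic-net penalty (mixing parameter `alpha`, default 0.5). The penalty
#' strength is chosen by k-fold cross-validation over a log-spaced path;
#' fold assignment is seeded and stratified by age tertile so training is
#' reproducible. Only CpGs with nonzero coefficients are stored.
#'
#' @param meth Training [methylome].
#' @param samples [sample_table()] with ages for the training samples.
#' @param cpg_subset Optional CpG id subset to train on (developmental or
#'   interventional pre-selection); default all CpGs.
#' @param clock_type Label: "general", "developmental" or "interventional".
#' @param training_subset Tissue tag, "pan" or "liver".
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (0.5 = equal ridge
#'   and lasso weight).
#' @param n_folds Cross-validation folds (default 10).
#' @param cv_rule "min" picks the penalty minimizing CV error;
#'   "1se" the sparsest model within one standard error of it.
#' @param params [transform_params()] for the age transform.
#' @param seed Integer seed for fold assignment.
#' @return Object of class `clock_model` with fields `clock_type`,
#'   `training_subset`, `transform`, `intercept`, `coefficients` (named by
#'   CpG id, all nonzero), `alpha`, `lambda`, `normalization`.
#' @export
train_clock <- function(meth, samples, cpg_subset = NULL,
                        clock_type = "general", training_subset = "pan",
                        alpha = 0.5, n_folds = 10, cv_rule = c("min", "1se"),
                        params = transform_params(), seed = 1) {
  cv_rule <- match.arg(cv_rule)
  idx <- match(meth$sample_ids, samples$sample_id)
  if (anyNA(idx)) stop("sample table does not cover all methylome samples")
  age <- samples$age[idx]
  if (length(age) < 2 * n_folds) stop("need >= 2 samples per fold")
  if (stats::sd(age) == 0) stop("chronological age is constant; nothing to train on")
  x <- meth$beta
  if (!is.null(cpg_subset)) {
    missing_cpg <- setdiff(cpg_subset, meth$cpg_ids)
    if (length(missing_cpg)) {
      stop("cpg_subset not in methylome: ", paste(utils::head(missing_cpg, 5), collapse = ", "))
    }
    x <- x[, cpg_subset, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need >= 2 CpGs to train")
  y <- transform_age(age, params)

  # age-tertile-stratified fold ids, deterministic given seed
  set.seed(seed)
  tert <- cut(rank(age, ties.method = "first"), breaks = 3, labels = FALSE)
  foldid <- integer(length(age))
  for (g in unique(tert)) {
    members <- which(tert == g)
    foldid[members] <- sample(rep_len(seq_len(n_folds), length(members)))
  }
  cv <- glmnet::cv.glmnet(x, y,
    alpha = alpha, foldid = foldid,
    family = "gaussian", standardize = TRUE
  )
  lambda <- if (cv_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = lambda))
  b0 <- cf[1, 1]
  b <- cf[-1, 1]
  b <- b[b != 0]
  if (!length(b)) stop("all coefficients shrunk to zero; lower the penalty floor or add signal")
  structure(
    list(
      clock_type = clock_type, training_subset = training_subset,
      transform = params, intercept = b0, coefficients = b,
      alpha = alpha, lambda = lambda, normalization = "standard"
    ),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "%s clock (%s), %d CpGs, alpha = %g, lambda = %.4g, %s normalization\n",
    x$clock_type, x$training_subset, length(x$coefficients), x$alpha,
    x$lambda, x$normalization
  ))
  invisible(x)
}

#' Predict DNAm age from a trained clock
#'
#' Computes the linear predictor `b0 + sum_i b_i * beta_i` over the clock
#' CpGs and maps it back to years with the inverse age transform. In
#' `"as-printed"` normalization the linear predictor is first divided by
#' `b0 + sum_i b_i` (the published formula's denominator); in the default
#' `"standard"` mode no division is applied, as in conventional
#' Horvath-style clocks. The two agree whenever the denominator equals 1.
#'
#' @param model A `clock_model`.
#' @param meth A [methylome] containing every clock CpG.
#' @param normalization "standard" or "as-printed" (overrides the model's
#'   stored mode if given).
#' @return Named numeric vector of DNAm ages (years) per sample.
#' @export
predict_dnam_age <- function(model, meth, normalization = NULL) {
  stopifnot(inherits(model, "clock_model"))
  mode <- if (is.null(normalization)) model$normalization else normalization
  mode <- match.arg(mode, c("standard", "as-printed"))
  cpgs <- names(model$coefficients)
  missing_cpg <- setdiff(cpgs, meth$cpg_ids)
  if (length(missing_cpg)) {
    stop("methylome lacks clock CpGs: ", paste(utils::head(missing_cpg, 5), collapse = ", "))
  }
  lin <- model$intercept +
    as.vector(meth$beta[, cpgs, drop = FALSE] %*% model$coefficients)
  if (mode == "as-printed") {
    denom <- model$intercept + sum(model$coefficients)
    if (abs(denom) < 1e-8) {
      stop("as-printed normalization denominator |b0 + sum(b)| < 1e-8; use standard mode")
    }
    lin <- lin / denom
  }
  out <- inverse_transform_age(lin, model$transform)
  names(out) <- meth$sample_ids
  out
}

#' Epigenetic age acceleration (EAA)
#'
#' EAA is the residual of DNAm age regressed on chronological age over the
#' whole cohort, so it is mean-zero and exactly uncorrelated with age:
#' positive values mean epigenetically older than expected for the
#' chronological age.
#'
#' @param dnam_age Named vector of DNAm ages (years), names = sample ids.
#' @param samples [sample_table()] with chronological ages.
#' @return Object of class `eaa_result`: data.frame with `sample_id`,
#'   `age`, `dnam_age`, `eaa`, plus attributes `slope` and `intercept` of
#'   the calibration line.
#' @export
compute_eaa <- function(dnam_age, samples) {
  idx <- match(names(dnam_age), samples$sample_id)
  if (anyNA(idx)) stop("sample table does not cover all predicted samples")
  age <- samples$age[idx]
  if (length(age) < 3) stop("need >= 3 samples")
  if (stats::sd(age) == 0) stop("chronological age is constant; EAA undefined")
  fit <- stats::lm.fit(cbind(1, age), dnam_age)
  out <- data.frame(
    sample_id = names(dnam_age), age = age,
    dnam_age = as.numeric(dnam_age), eaa = as.numeric(fit$residuals),
    stringsAsFactors = FALSE
  )
  attr(out, "intercept") <- unname(fit$coefficients[1])
  attr(out, "slope") <- unname(fit$coefficients[2])
  class(out) <- c("eaa_result", "data.frame")
  out
}

#' Serialize a clock model to JSON
#' @param model A `clock_model`.
#' @param path Output JSON path.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  obj <- list(
    format_version = "1.0",
    clock_type = model$clock_type,
    training_subset = model$training_subset,
    transform = list(
      adult_age = model$transform$adult_age,
      offset = model$transform$offset
    ),
    intercept = model$intercept,
    cpg_ids = names(model$coefficients),
    coefficients = unname(model$coefficients),
    alpha = model$alpha,
    lambda = model$lambda,
    normalization = model$normalization
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a clock model from JSON written by [write_clock_model()]
#' @param path JSON path.
#' @return A `clock_model`.
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- obj$coefficients
  names(cf) <- obj$cpg_ids
  structure(
    list(
      clock_type = obj$clock_type, training_subset = obj$training_subset,
      transform = transform_params(obj$transform$adult_age, obj$transform$offset),
      intercept = obj$intercept, coefficients = cf,
      alpha = obj$alpha, lambda = obj$lambda, normalization = obj$normalization
    ),
    class = "clock_model"
  )
}
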