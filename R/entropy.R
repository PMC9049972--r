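#' Freedman-Diaconis bin count
#'
#' Histogram bin count from the Freedman-Diaconis rule: bin width
#' `2 * IQR * n^(-1/3)`, count `ceil((max - min) / width)`. Exposed as a
#' diagnostic for choosing the discretization used by the entropy
#' estimator; the pipeline default stays at 20 bins.
#'
#' @param values Numeric vector, `n >= 2`, with positive interquartile range.
#' @return Integer bin count.
#' @export
fd_bin_count <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need >= 2 finite values")
  iqr <- stats::IQR(values)
  if (iqr <= 0) stop("IQR is zero; the Freedman-Diaconis rule is undefined")
  width <- 2 * iqr * n^(-1 / 3)
  as.integer(ceiling((max(values) - min(values)) / width))
}

#' Shannon entropy of a discretized beta-value vector
#'
#' Bins the values into `n_bins` equal-width bins — over \[0, 1\] in
#' `"fixed01"` mode, or over \[min, max\] in `"data-range"` mode — and
#' returns the maximum-likelihood (plug-in) Shannon entropy
#' `H = -sum p log p` of the bin frequencies, in nats by default. The last
#' bin is right-closed so a beta of exactly 1 is counted.
#'
#' @param values Numeric vector of beta-values.
#' @param n_bins Number of bins (default 20).
#' @param range_mode "fixed01" (default; values must lie in \[0,1\]) or
#'   "data-range".
#' @param unit "nats" (natural log, default) or "bits" (log2).
#' @return Entropy; lies in \[0, log(n_bins)\].
#' @export
shannon_entropy <- function(values, n_bins = 20,
                            range_mode = c("fixed01", "data-range"),
                            unit = c("nats", "bits")) {
  range_mode <- match.arg(range_mode)
  unit <- match.arg(unit)
  stopifnot(n_bins >= 2, length(values) >= 1)
  if (any(!is.finite(values))) stop("values must be finite")
  if (range_mode == "fixed01") {
    if (any(values < 0 | values > 1)) stop("values outside [0,1] in fixed01 mode")
    lo <- 0; hi <- 1
  } else {
    lo <- min(values); hi <- max(values)
    if (hi == lo) return(0)
  }
  # bin index in 1..n_bins; right edge closed so hi falls in the last bin
  idx <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(values)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (unit == "bits") h / log(2) else h
}

#' Per-sample methylome entropy
#'
#' Shannon entropy of each sample's beta-value distribution over a CpG set
#' (all CpGs, or a class subset such as age-gain/age-loss CpGs). Higher
#' entropy means a flatter, more hemi-methylated profile; the erosion of
#' the bimodal methylome with age raises it.
#'
#' @param meth A [methylome].
#' @param cpg_ids Optional CpG subset (default: all CpGs).
#' @param n_bins Bin count for discretization (default 20).
#' @param range_mode Passed to [shannon_entropy()].
#' @param unit Passed to [shannon_entropy()].
#' @param cpg_set_label Label recorded in the output (e.g. "all",
#'   "age-gain", "age-loss", "age-ns").
#' @return data.frame of class `entropy_result` with `sample_id`,
#'   `entropy`, plus attributes `n_bins`, `range_mode`, `unit`, `cpg_set`.
#' @export
methylome_entropy <- function(meth, cpg_ids = NULL, n_bins = 20,
                              range_mode = "fixed01", unit = "nats",
                              cpg_set_label = "all") {
  stopifnot(inherits(meth, "methylome"))
  if (is.null(cpg_ids)) {
    b <- meth$beta
  } else {
    unknown <- setdiff(cpg_ids, meth$cpg_ids)
    if (length(unknown)) {
      stop("unknown CpG ids: ", paste(utils::head(unknown, 5), collapse = ", "))
    }
    if (!length(cpg_ids)) stop("cpg_ids subset is empty")
    b <- meth$beta[, cpg_ids, drop = FALSE]
  }
  h <- apply(b, 1, shannon_entropy, n_bins = n_bins,
             range_mode = range_mode, unit = unit)
  out <- data.frame(
    sample_id = meth$sample_ids, entropy = as.numeric(h),
    stringsAsFactors = FALSE
  )
  attr(out, "n_bins") <- n_bins
  attr(out, "range_mode") <- range_mode
  attr(out, "unit") <- unit
  attr(out, "cpg_set") <- cpg_set_label
  class(out) <- c("entropy_result", "data.frame")
  out
}
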