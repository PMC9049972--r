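#' Construct a methylome matrix
#'
#' A methylome is a samples x CpGs matrix of beta-values (methylated fraction
#' of signal, in \[0, 1\]) with optional per-CpG genomic annotation.
#'
#' @param beta Numeric matrix, rows = samples, columns = CpGs. Must have
#'   unique, non-empty rownames (sample ids) and colnames (CpG ids).
#' @param annotation Optional data.frame with one row per CpG and columns
#'   `cpg_id`, `chrom`, `pos` (1-based bp), `genomic_class` (one of
#'   promoter, 5'UTR, exon, intron, 3'UTR, intergenic) and `chromatin_state`
#'   (15-state ChromHMM label or "NRS"). Must cover every CpG in `beta`.
#' @return An object of class `methylome`: a list with elements `beta`,
#'   `sample_ids`, `cpg_ids`, `annotation`.
#' @export
methylome <- function(beta, annotation = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix (samples x CpGs)")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("`beta` must have sample ids as rownames and CpG ids as colnames")
  }
  if (anyDuplicated(rownames(beta))) stop("duplicate sample ids in beta matrix")
  if (anyDuplicated(colnames(beta))) stop("duplicate CpG ids in beta matrix")
  bad <- which(!is.finite(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta-value out of [0,1] at sample '%s', CpG '%s' (value %s)",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      format(beta[bad[1, , drop = FALSE]])
    ))
  }
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    req <- c("cpg_id", "chrom", "pos")
    miss <- setdiff(req, names(annotation))
    if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
    missing_cpg <- setdiff(colnames(beta), annotation$cpg_id)
    if (length(missing_cpg)) {
      stop(
        "annotation missing CpGs: ",
        paste(utils::head(missing_cpg, 5), collapse = ", "),
        if (length(missing_cpg) > 5) sprintf(" (and %d more)", length(missing_cpg) - 5) else ""
      )
    }
    annotation <- annotation[match(colnames(beta), annotation$cpg_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }
  structure(
    list(
      beta = beta,
      sample_ids = rownames(beta),
      cpg_ids = colnames(beta),
      annotation = annotation
    ),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf(
    "methylome: %d samples x %d CpGs%s\n",
    length(x$sample_ids), length(x$cpg_ids),
    if (is.null(x$annotation)) "" else " (annotated)"
  ))
  invisible(x)
}

#' @export
dim.methylome <- function(x) dim(x$beta)

#' Read a beta-value matrix (and optional CpG annotation) from disk
#'
#' The beta TSV has a header row of CpG ids and the sample id in the first
#' column. The optional annotation is BED-like: chrom, start, end, cpg_id,
#' genomic_class, chromatin_state, tab-separated, no header. BED intervals
#' are 0-based half-open; the stored `pos` is 1-based (`start + 1`).
#'
#' @param beta_path Path to the beta-value TSV.
#' @param annotation_path Optional path to the BED annotation.
#' @return A [methylome] object.
#' @export
read_methylome <- function(beta_path, annotation_path = NULL) {
  tab <- utils::read.delim(beta_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("beta TSV needs a sample-id column plus >= 1 CpG column")
  sample_ids <- as.character(tab[[1]])
  beta <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- sample_ids
  annotation <- if (!is.null(annotation_path)) read_cpg_bed(annotation_path) else NULL
  methylome(beta, annotation)
}

#' Read a BED file of CpG annotations
#'
#' Columns: chrom, start, end, cpg_id, genomic_class, chromatin_state
#' (0-based half-open intervals; position reported 1-based).
#'
#' @param path BED file path.
#' @return data.frame with cpg_id, chrom, pos, genomic_class, chromatin_state.
#' @export
read_cpg_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("CpG BED needs >= 4 columns (chrom, start, end, cpg_id)")
  out <- data.frame(
    cpg_id = as.character(bed[[4]]),
    chrom = as.character(bed[[1]]),
    pos = as.integer(bed[[2]]) + 1L,
    stringsAsFactors = FALSE
  )
  out$genomic_class <- if (ncol(bed) >= 5) as.character(bed[[5]]) else NA_character_
  out$chromatin_state <- if (ncol(bed) >= 6) as.character(bed[[6]]) else NA_character_
  if (anyDuplicated(out$cpg_id)) stop("duplicate cpg_id in annotation BED")
  out
}

#' Write a methylome beta matrix to TSV
#'
#' Inverse of [read_methylome()]: first column `sample_id`, then one column
#' per CpG, full double precision.
#'
#' @param x A [methylome].
#' @param path Output TSV path.
#' @export
write_methylome <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  tab <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(x$beta, check.names = FALSE))
  write_result_table(tab, path)
}

#' Construct a sample covariate table
#'
#' Per-mouse covariates: strain, sex, diet arm, age at tissue collection,
#' longitudinal body weights, and array batch.
#'
#' @param df data.frame with columns `sample_id`, `strain_id`, `sex`
#'   ("F"/"M"), `diet` ("CD"/"HFD"), `age` (years at collection), and
#'   optionally `bw0`, `bw1`, `bwf` (grams; bw1 is the ~6-month weight,
#'   bwf the final weight) and `batch`.
#' @return The validated data.frame, classed `sample_table`.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df)
  req <- c("sample_id", "strain_id", "sex", "diet", "age")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(df$diet %in% c("CD", "HFD"))) stop("diet must be 'CD' or 'HFD'")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be positive and finite")
  for (w in intersect(c("bw0", "bw1", "bwf"), names(df))) {
    if (any(df[[w]] <= 0, na.rm = TRUE)) stop("weight column ", w, " has non-positive values")
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path TSV path with the columns documented in [sample_table()].
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Construct a strain-by-diet longevity summary table
#'
#' Lifespan order statistics per (strain, diet) from natural-death cohorts.
#' Rows with fewer than `min_deaths` observed deaths are dropped, mirroring
#' the restriction of lifespan correlations to well-observed strains.
#'
#' @param df data.frame with `strain_id`, `diet`, `n_deaths`, and lifespan
#'   columns in days: `min_ls`, `q25_ls`, `mean_ls`, `median_ls`, `q75_ls`,
#'   `max_ls`.
#' @param min_deaths Minimum death count for a row to be retained (default 5).
#' @return Validated data.frame classed `longevity_table`.
#' @export
longevity_table <- function(df, min_deaths = 5) {
  df <- as.data.frame(df)
  req <- c("strain_id", "diet", "n_deaths", "median_ls")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("longevity table lacks columns: ", paste(miss, collapse = ", "))
  df <- df[df$n_deaths >= min_deaths, , drop = FALSE]
  ord_cols <- intersect(c("min_ls", "q25_ls", "median_ls", "q75_ls", "max_ls"), names(df))
  if (length(ord_cols) > 1) {
    om <- as.matrix(df[, ord_cols, drop = FALSE])
    if (any(apply(om, 1, function(r) any(diff(r[!is.na(r)]) < 0)))) {
      stop("lifespan order statistics must be monotone (min <= q25 <= median <= q75 <= max)")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("longevity_table", "data.frame")
  df
}

#' Read genotypes in mean-genotype format plus a marker map
#'
#' The genotype TSV has one row per marker: `marker_id`, `allele1`,
#' `allele0`, then one numeric dosage per strain (header row carries the
#' strain ids). Dosages are 0 (B homozygote), 0.5 (heterozygote), 1
#' (D homozygote), NA for missing. The map TSV has columns `marker_id`,
#' `pos` (bp), `chrom`. Markers are returned sorted by (chrom, pos).
#'
#' @param geno_path Genotype TSV path.
#' @param map_path Marker map TSV path.
#' @return An object of class `genotypes`: list with `strain_ids`,
#'   `marker_ids`, `chrom`, `pos`, `dosage` (strains x markers), `maf`.
#' @export
read_genotypes <- function(geno_path, map_path) {
  geno <- utils::read.delim(geno_path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (ncol(geno) < 4) stop("genotype TSV needs marker_id, allele1, allele0 + >= 1 strain")
  if (!all(c("marker_id", "pos", "chrom") %in% names(map))) {
    stop("map TSV needs columns marker_id, pos, chrom")
  }
  marker_ids <- as.character(geno[[1]])
  strain_ids <- colnames(geno)[-(1:3)]
  dos <- as.matrix(geno[, -(1:3), drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "double")
  if (any(is.na(dos) & !is.na(as.matrix(geno[, -(1:3), drop = FALSE])))) {
    stop("non-numeric dosage value in genotype TSV")
  }
  ok <- is.na(dos) | dos %in% c(0, 0.5, 1)
  if (!all(ok)) stop("dosages must be 0, 0.5, 1 or NA")
  absent <- setdiff(marker_ids, map$marker_id)
  if (length(absent)) {
    stop("markers absent from map: ", paste(utils::head(absent, 5), collapse = ", "))
  }
  map <- map[match(marker_ids, map$marker_id), ]
  ord <- order(map$chrom, map$pos)
  dosage <- t(dos)[, ord, drop = FALSE]
  dimnames(dosage) <- list(strain_ids, marker_ids[ord])
  genotypes(dosage, chrom = map$chrom[ord], pos = map$pos[ord])
}

#' Construct a genotype matrix object
#'
#' @param dosage Numeric matrix, strains x markers, values in {0, 0.5, 1, NA}
#'   with strain ids as rownames and marker ids as colnames.
#' @param chrom Chromosome label per marker.
#' @param pos 1-based bp position per marker.
#' @return `genotypes` object; `maf` is computed ignoring missing values.
#' @export
genotypes <- function(dosage, chrom, pos) {
  stopifnot(is.matrix(dosage), length(chrom) == ncol(dosage), length(pos) == ncol(dosage))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage needs strain ids (rownames) and marker ids (colnames)")
  }
  freq <- colMeans(dosage, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  structure(
    list(
      strain_ids = rownames(dosage), marker_ids = colnames(dosage),
      chrom = chrom, pos = pos, dosage = dosage, maf = maf
    ),
    class = "genotypes"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf(
    "genotypes: %d strains x %d markers on %d chromosome(s)\n",
    length(x$strain_ids), length(x$marker_ids), length(unique(x$chrom))
  ))
  invisible(x)
}

#' Write genotypes to mean-genotype + map TSVs
#' @param x A `genotypes` object.
#' @param geno_path,map_path Output paths.
#' @export
write_genotypes <- function(x, geno_path, map_path) {
  stopifnot(inherits(x, "genotypes"))
  tab <- data.frame(
    marker_id = x$marker_ids, allele1 = "D", allele0 = "B",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  tab <- cbind(tab, as.data.frame(t(x$dosage), check.names = FALSE))
  write_result_table(tab, geno_path)
  write_result_table(
    data.frame(marker_id = x$marker_ids, pos = x$pos, chrom = x$chrom),
    map_path
  )
}

#' Write a result table as TSV
#'
#' Header row, tab-separated, no quoting beyond what R needs, `NA` for
#' missing, and floats at full double precision (round-trip faithful).
#'
#' @param rows data.frame with named columns.
#' @param path Output path.
#' @export
write_result_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- out[[j]]
      # shortest decimal representation that parses back to the same double
      v <- formatC(x, digits = 15, format = "g")
      for (d in 16:17) {
        bad <- !is.na(x) & suppressWarnings(as.numeric(v)) != x
        if (!any(bad)) break
        v[bad] <- formatC(x[bad], digits = d, format = "g")
      }
      v[is.na(x)] <- NA
      out[[j]] <- v
    }
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = "NA"
  )
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
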