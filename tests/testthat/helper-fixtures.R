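# shared builders for small in-code fixtures

tiny_methylome <- function(beta = NULL, n = 4, m = 3) {
  if (is.null(beta)) {
    beta <- matrix(seq(0.1, 0.9, length.out = n * m), n, m)
  }
  dimnames(beta) <- list(sprintf("s%d", seq_len(nrow(beta))),
                         sprintf("cg%03d", seq_len(ncol(beta))))
  methylome(beta)
}

tiny_samples <- function(n, age = NULL, diet = NULL, strain = NULL) {
  sample_table(data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    strain_id = if (is.null(strain)) sprintf("st%d", rep(1:2, length.out = n)) else strain,
    sex = "F",
    diet = if (is.null(diet)) rep("CD", n) else diet,
    age = if (is.null(age)) seq(0.5, 2.5, length.out = n) else age,
    bw0 = rep(30, n), bw1 = rep(33, n), bwf = rep(40, n),
    batch = "batch1",
    stringsAsFactors = FALSE
  ))
}

# genotypes object from an explicit strains x markers dosage matrix
tiny_genotypes <- function(dosage, chrom = NULL, pos = NULL) {
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("st%d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("m%d", seq_len(ncol(dosage)))
  genotypes(dosage,
            chrom = if (is.null(chrom)) rep(1L, ncol(dosage)) else chrom,
            pos = if (is.null(pos)) seq_len(ncol(dosage)) else pos)
}
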