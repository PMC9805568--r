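# Small in-code fixtures shared across test files.

# Random panel built directly (no VCF round-trip).
tiny_panel <- function(H, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hap <- matrix(rbinom(H * M, 1L, 0.5), H, M)
  # avoid monomorphic sites so genotype classes are distinguishable
  for (j in seq_len(M)) {
    if (all(hap[, j] == hap[1L, j])) hap[1L, j] <- 1L - hap[1L, j]
  }
  reference_panel("1", seq_len(M) * 100L, rep("A", M), rep("C", M), hap)
}

# Random strictly positive likelihood rows.
rand_lik <- function(M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  likelihood_matrix(matrix(runif(M * 3, 0.05, 1), M, 3))
}

rand_params <- function(panel, seed = NULL, eps = 0.02) {
  if (!is.null(seed)) set.seed(seed)
  p <- hmm_parameters(panel, epsilon = eps)
  p$theta <- c(NA_real_, runif(panel$M - 1L, 0.01, 0.4))
  p
}

# A small multi-sample phased panel VCF written as text.
write_fixture_panel_vcf <- function(path, gts, chrom = "20",
                                    pos = NULL, ref = NULL, alt = NULL) {
  M <- nrow(gts); S <- ncol(gts)
  if (is.null(pos)) pos <- seq_len(M) * 10L
  if (is.null(ref)) ref <- rep("A", M)
  if (is.null(alt)) alt <- rep("G", M)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("S", seq_len(S))),
                 collapse = "\t"))
  rec <- vapply(seq_len(M), function(j) {
    paste(c(chrom, pos[j], ".", ref[j], alt[j], ".", "PASS", ".", "GT",
            gts[j, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, rec), path)
  path
}

# Single-sample target VCF with a FORMAT likelihood field (PL or GL).
write_fixture_target_vcf <- function(path, field, values, chrom = "20",
                                     pos = NULL, ref = NULL, alt = NULL,
                                     sample = "S1") {
  M <- length(values)
  if (is.null(pos)) pos <- seq_len(M) * 10L
  if (is.null(ref)) ref <- rep("A", M)
  if (is.null(alt)) alt <- rep("G", M)
  type <- if (field == "PL") "Integer" else "Float"
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           paste0('##FORMAT=<ID=', field, ',Number=G,Type=', type,
                  ',Description="Likelihoods">'),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  rec <- vapply(seq_len(M), function(j) {
    paste(c(chrom, pos[j], ".", ref[j], alt[j], ".", "PASS", ".", field,
            values[j]), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, rec), path)
  path
}
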