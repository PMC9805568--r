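#' Reference haplotype panel
#'
#' Container for a phased reference panel: `H` haplotypes at `M` biallelic
#' SNP sites on one chromosome.  Usually built by [read_reference_panel()] or
#' [make_synthetic_panel()].
#'
#' @param chrom chromosome name (single string).
#' @param positions 1-based physical positions, strictly increasing.
#' @param ref,alt single-nucleotide reference / alternative alleles per site.
#' @param haplotypes `H x M` integer matrix of allele codes in `{0, 1}`;
#'   rows are haplotypes, consecutive row pairs belong to one sample.
#' @param sample_names optional character vector of panel sample names.
#' @param n_skipped count of VCF records skipped during ingestion.
#' @return an object of class `"reference_panel"`.
#' @export
reference_panel <- function(chrom, positions, ref, alt, haplotypes,
                            sample_names = NULL, n_skipped = 0L) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  M <- length(positions)
  H <- nrow(haplotypes)
  if (ncol(haplotypes) != M) stop("haplotypes must have one column per site")
  if (M < 1L) stop("panel must contain at least one site")
  if (H < 2L) stop("panel must contain at least two haplotypes")
  if (M > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
    stop("panel haplotypes must be fully called 0/1 alleles")
  }
  structure(
    list(chrom = as.character(chrom)[1L], positions = as.integer(positions),
         ref = as.character(ref), alt = as.character(alt),
         haplotypes = haplotypes, H = H, M = M,
         sample_names = sample_names, n_skipped = as.integer(n_skipped)),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel:", x$H, "haplotypes x", x$M, "biallelic SNPs on",
      x$chrom, "\n")
  cat("  positions", min(x$positions), "-", max(x$positions),
      "; records skipped on import:", x$n_skipped, "\n")
  invisible(x)
}

# Read a VCF with VariantAnnotation, optionally restricted to "chr" or
# "chr:start-end" (subset after parsing; fixtures are small).
.read_vcf <- function(vcf_path, region = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcf_path))
  if (!is.null(region)) {
    part <- strsplit(region, ":", fixed = TRUE)[[1L]]
    keep <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(vcf))) == part[1L]
    if (length(part) > 1L) {
      se <- as.numeric(strsplit(part[2L], "-", fixed = TRUE)[[1L]])
      pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
      keep <- keep & pos >= se[1L] & pos <= se[2L]
    }
    vcf <- vcf[keep, ]
  }
  vcf
}

.vcf_sites <- function(vcf) {
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(VariantAnnotation::alt(vcf), function(a) {
    if (length(a) == 1L) as.character(a) else NA_character_
  }, character(1L))
  list(chrom = as.character(GenomicRanges::seqnames(rr)),
       pos = GenomicRanges::start(rr),
       ref = as.character(VariantAnnotation::ref(vcf)),
       alt = alt)
}

.is_biallelic_snp <- function(sites) {
  !is.na(sites$alt) &
    nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T")
}

#' Read a phased reference panel from VCF
#'
#' Ingests phased GT records, keeping biallelic SNPs only.  Multiallelic and
#' indel records are skipped and counted; an unphased genotype ("/") is a
#' hard error because the copying model requires known haplotypes.
#'
#' @param vcf_path path to a VCF file with phased GT for all samples.
#' @param region optional region string, `"chr"` or `"chr:start-end"`.
#' @return a [reference_panel] with `H = 2 *` number of samples.
#' @export
read_reference_panel <- function(vcf_path, region = NULL) {
  vcf <- .read_vcf(vcf_path, region)
  if (nrow(vcf) == 0L) stop("no records in region")
  sites <- .vcf_sites(vcf)
  keep <- .is_biallelic_snp(sites)
  n_skipped <- sum(!keep)
  vcf <- vcf[keep, ]
  if (nrow(vcf) == 0L) stop("no usable biallelic SNPs in region")
  sites <- lapply(sites, `[`, keep)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("panel VCF has no GT field")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotype in reference panel (\"/\" separator); ",
         "the panel must be fully phased")
  }
  if (any(grepl(".", gt, fixed = TRUE))) {
    stop("missing allele in reference panel genotypes")
  }
  a1 <- suppressWarnings(as.integer(sub("\\|.*", "", gt)))
  a2 <- suppressWarnings(as.integer(sub(".*\\|", "", gt)))
  if (anyNA(a1) || anyNA(a2)) stop("malformed GT in reference panel")
  # gt is sites x samples; haplotypes are rows 2s-1, 2s for sample s
  M <- nrow(gt); S <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * S, ncol = M)
  hap[seq(1L, 2L * S, by = 2L), ] <- t(matrix(a1, M, S))
  hap[seq(2L, 2L * S, by = 2L), ] <- t(matrix(a2, M, S))
  if (length(unique(sites$chrom)) > 1L) {
    stop("panel spans multiple chromosomes; restrict with `region`")
  }
  reference_panel(sites$chrom[1L], sites$pos, sites$ref, sites$alt, hap,
                  sample_names = colnames(gt), n_skipped = n_skipped)
}

#' Genotype-likelihood matrix for one target sample
#'
#' `M x 3` matrix of genotype likelihoods `L(0), L(1), L(2)` aligned 1:1 with
#' a reference panel, each row rescaled so its maximum is 1 (the model is
#' invariant to per-row scale).  Sites without data carry the uniform triplet
#' and `observed = FALSE`.
#'
#' @param lik `M x 3` numeric matrix.
#' @param observed logical vector of length `M`.
#' @param n_dropped count of target records that did not match the panel.
#' @return an object of class `"likelihood_matrix"`.
#' @export
likelihood_matrix <- function(lik, observed = NULL, n_dropped = 0L) {
  lik <- as.matrix(lik)
  if (ncol(lik) != 3L) stop("likelihoods must have three columns")
  if (anyNA(lik) || any(lik < 0)) stop("likelihoods must be non-negative")
  mx <- apply(lik, 1L, max)
  if (any(mx == 0)) stop("every likelihood row needs a positive entry")
  lik <- lik / mx
  if (is.null(observed)) observed <- rep(TRUE, nrow(lik))
  structure(
    list(lik = lik, observed = observed, M = nrow(lik),
         n_dropped = as.integer(n_dropped)),
    class = "likelihood_matrix"
  )
}

#' @export
print.likelihood_matrix <- function(x, ...) {
  cat("Genotype likelihoods:", x$M, "sites,", sum(x$observed), "observed;",
      x$n_dropped, "unmatched target records dropped\n")
  invisible(x)
}

.uniform_row <- function() c(1, 1, 1) / 3

#' Read target genotype likelihoods from VCF
#'
#' Extracts the GL (log10-scaled) or PL (phred-scaled) triplet of one sample
#' and aligns it to a reference panel.  Matching is exact on
#' (chromosome, position, ref, alt); allele-swapped or strand-flipped records
#' are dropped and counted, never reconciled.  Panel sites without a target
#' record — and matched records whose GL/PL value is missing — get the
#' uniform triplet with `observed = FALSE`.
#'
#' @param vcf_path path to the target VCF.
#' @param sample_id sample name in the VCF.
#' @param panel the [reference_panel] to align against.
#' @return a [likelihood_matrix] with exactly `panel$M` rows.
#' @export
read_target_likelihoods <- function(vcf_path, sample_id, panel) {
  vcf <- .read_vcf(vcf_path)
  smp <- colnames(vcf)
  if (!sample_id %in% smp) {
    stop("sample '", sample_id, "' not present in ", vcf_path)
  }
  vcf <- vcf[, sample_id]
  gl <- VariantAnnotation::geno(vcf)$GL
  pl <- VariantAnnotation::geno(vcf)$PL
  if (is.null(gl) && is.null(pl)) {
    stop("target VCF carries neither GL nor PL for sample ", sample_id)
  }
  sites <- .vcf_sites(vcf)
  key_t <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  key_p <- paste(panel$chrom, panel$positions, panel$ref, panel$alt, sep = ":")
  idx <- match(key_t, key_p)       # target record -> panel row
  n_dropped <- sum(is.na(idx))

  lik <- matrix(rep(.uniform_row(), panel$M), ncol = 3L, byrow = TRUE)
  observed <- rep(FALSE, panel$M)
  triplet_at <- function(field, i) {
    v <- if (is.list(field)) field[[i, 1L]] else field[i, 1L, ]
    as.numeric(v)
  }
  for (i in which(!is.na(idx))) {
    row <- NULL
    if (!is.null(gl)) {
      v <- triplet_at(gl, i)
      if (length(v) == 3L && !anyNA(v)) row <- 10^v
    }
    if (is.null(row) && !is.null(pl)) {
      v <- triplet_at(pl, i)
      if (length(v) == 3L && !anyNA(v)) row <- 10^(-v / 10)
    }
    if (is.null(row)) next  # declared field, missing value -> unobserved
    lik[idx[i], ] <- row / max(row)
    observed[idx[i]] <- TRUE
  }
  likelihood_matrix(lik, observed, n_dropped)
}

#' Genetic map
#'
#' Monotone mapping from physical position to cumulative genetic distance in
#' centiMorgans.
#'
#' @param positions physical positions, strictly increasing; at least 2.
#' @param cumulative_cM non-decreasing cumulative distances in cM.
#' @return an object of class `"genetic_map"`.
#' @export
genetic_map <- function(positions, cumulative_cM) {
  if (length(positions) < 2L) stop("genetic map needs at least 2 entries")
  if (any(diff(positions) <= 0)) stop("map positions must increase")
  if (any(diff(cumulative_cM) < 0)) stop("cumulative cM must be non-decreasing")
  structure(list(positions = as.numeric(positions),
                 cumulative_cM = as.numeric(cumulative_cM)),
            class = "genetic_map")
}

#' Read a genetic map from whitespace-delimited text
#'
#' Accepts the 3-column HapMap dialect (position, rate cM/Mb, cumulative cM)
#' and the 4-column PLINK dialect (chrom, id, cumulative cM, position),
#' autodetected by column count; a header line is detected and skipped.
#'
#' @param path map file path.
#' @return a [genetic_map].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  tok <- strsplit(trimws(first), "\\s+")[[1L]]
  # data rows always end in a number (cM or position); header lines don't
  header <- is.na(suppressWarnings(as.numeric(tok[length(tok)])))
  tab <- utils::read.table(path, header = FALSE, skip = as.integer(header))
  if (ncol(tab) == 3L) {
    genetic_map(tab[[1L]], tab[[3L]])
  } else if (ncol(tab) == 4L) {
    genetic_map(tab[[4L]], tab[[3L]])
  } else {
    stop("unrecognised genetic map dialect (", ncol(tab), " columns)")
  }
}

#' Interpolate cumulative genetic distance at physical positions
#'
#' Linear interpolation inside the map; outside the map's range the nearest
#' flanking interval's recombination rate is extrapolated (a degenerate
#' flat interval extrapolates at rate 0).
#'
#' @param map a [genetic_map].
#' @param positions physical positions to evaluate.
#' @return numeric vector of cumulative cM, non-decreasing for non-decreasing
#'   input positions.
#' @export
interpolate_genetic_distance <- function(map, positions) {
  x <- map$positions; y <- map$cumulative_cM
  n <- length(x)
  out <- stats::approx(x, y, xout = positions, rule = 2L, ties = "ordered")$y
  rate_lo <- max((y[2L] - y[1L]) / (x[2L] - x[1L]), 0)
  rate_hi <- max((y[n] - y[n - 1L]) / (x[n] - x[n - 1L]), 0)
  lo <- positions < x[1L]
  hi <- positions > x[n]
  out[lo] <- y[1L] - (x[1L] - positions[lo]) * rate_lo
  out[hi] <- y[n] + (positions[hi] - x[n]) * rate_hi
  out
}

.fmt_vcf_header <- function(chrom, sample_id, format_lines) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    format_lines,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
}

#' Write an imputed sample to VCF
#'
#' Emits one record per panel site with FORMAT `GT:GP:DS`: the phased
#' genotype from the maximum-posterior hidden state, the three genotype
#' posteriors rounded to 3 decimals (largest entry adjusted so the rounded
#' triplet still sums to 1), and the dosage `GP(1) + 2 GP(2)`.
#'
#' @param result an [ls_impute] fit covering all panel sites.
#' @param panel the [reference_panel] used for the fit.
#' @param sample_id sample name to write.
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
write_imputed_vcf <- function(result, panel, sample_id, out_path) {
  stopifnot(inherits(result, "ls_impute"), result$M == panel$M)
  gp <- round(result$gp, 3L)
  # re-impose sum 1 after rounding: the residual (a multiple of 0.001) goes
  # to the entry it distorts least, keeping the round-trip near 5e-4
  fix <- 1 - rowSums(gp)
  err <- gp - result$gp
  pick <- max.col(-sign(fix) * err, ties.method = "first")
  gp[cbind(seq_len(nrow(gp)), pick)] <- gp[cbind(seq_len(nrow(gp)), pick)] + fix
  gt <- paste0(result$haplotypes[1L, ], "|", result$haplotypes[2L, ])
  rec <- paste(
    panel$chrom, panel$positions, ".", panel$ref, panel$alt, ".", "PASS", ".",
    "GT:GP:DS",
    paste0(gt, ":",
           sprintf("%.3f,%.3f,%.3f", gp[, 1L], gp[, 2L], gp[, 3L]), ":",
           sprintf("%.3f", result$dosage)),
    sep = "\t")
  hdr <- .fmt_vcf_header(panel$chrom, sample_id, c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype from the maximum-posterior state">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Posterior genotype probabilities">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of the alternative allele">'))
  writeLines(c(hdr, rec), out_path)
  invisible(out_path)
}

#' Read an imputed VCF back
#'
#' Round-trip reader for files written by [write_imputed_vcf()].
#'
#' @param vcf_path path to the imputed VCF.
#' @param sample_id sample to read (defaults to the first).
#' @return list with `gt` (character "a|b"), `gp` (`M x 3`), `ds`, `positions`.
#' @export
read_imputed_vcf <- function(vcf_path, sample_id = NULL) {
  vcf <- .read_vcf(vcf_path)
  if (is.null(sample_id)) sample_id <- colnames(vcf)[1L]
  vcf <- vcf[, sample_id]
  gp_field <- VariantAnnotation::geno(vcf)$GP
  gp <- t(vapply(seq_len(nrow(vcf)), function(i) {
    as.numeric(if (is.list(gp_field)) gp_field[[i, 1L]] else gp_field[i, 1L, ])
  }, numeric(3L)))
  list(gt = as.character(VariantAnnotation::geno(vcf)$GT[, 1L]),
       gp = gp,
       ds = as.numeric(VariantAnnotation::geno(vcf)$DS[, 1L]),
       positions = GenomicRanges::start(SummarizedExperiment::rowRanges(vcf)))
}

#' Read truth genotypes (alt-allele counts) for one sample
#'
#' @param vcf_path VCF with a GT field; phased or unphased.
#' @param sample_id sample name.
#' @param panel optional [reference_panel]; when given, genotypes are aligned
#'   to the panel sites (unmatched panel sites become `NA`).
#' @return integer vector of genotypes in `{0, 1, 2}`, `NA` where missing.
#' @export
read_truth_genotypes <- function(vcf_path, sample_id, panel = NULL) {
  vcf <- .read_vcf(vcf_path)
  if (!sample_id %in% colnames(vcf)) {
    stop("sample '", sample_id, "' not present in ", vcf_path)
  }
  gt <- VariantAnnotation::geno(vcf[, sample_id])$GT[, 1L]
  g <- vapply(strsplit(gt, "[|/]"), function(a) {
    v <- suppressWarnings(as.integer(a))
    if (length(v) != 2L || anyNA(v)) NA_integer_ else sum(v)
  }, integer(1L))
  if (is.null(panel)) return(unname(g))
  sites <- .vcf_sites(vcf)
  key_t <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  key_p <- paste(panel$chrom, panel$positions, panel$ref, panel$alt, sep = ":")
  unname(g[match(key_p, key_t)])
}

#' Write a genotype-likelihood VCF
#'
#' Emits one record per panel site with FORMAT `GL`.  Observed sites are
#' written as log10 likelihoods (rows rescaled to max 1, so the top entry is
#' 0); unobserved sites are written as the literal `0.3333,0.3333,0.3333`
#' triplet, which reads back as exactly uniform because likelihood rows are
#' scale-free.
#'
#' @param lik a [likelihood_matrix] aligned to `panel`.
#' @param panel the [reference_panel].
#' @param sample_id sample name to write.
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
write_gl_vcf <- function(lik, panel, sample_id, out_path) {
  stopifnot(inherits(lik, "likelihood_matrix"), lik$M == panel$M)
  gl <- vapply(seq_len(lik$M), function(j) {
    if (!lik$observed[j]) return("0.3333,0.3333,0.3333")
    v <- pmax(log10(lik$lik[j, ] / max(lik$lik[j, ])), -99)  # cap -Inf
    paste(sprintf("%.6g", v), collapse = ",")
  }, character(1L))
  rec <- paste(panel$chrom, panel$positions, ".", panel$ref, panel$alt,
               ".", "PASS", ".", "GL", gl, sep = "\t")
  hdr <- .fmt_vcf_header(panel$chrom, sample_id, c(
    '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10-scaled genotype likelihoods">'))
  writeLines(c(hdr, rec), out_path)
  invisible(out_path)
}
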