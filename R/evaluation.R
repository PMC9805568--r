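# Concordance evaluation protocol: GP post-imputation filtering, genotype
# concordance (optionally restricted to truth heterozygotes, which are the
# hard cases and immune to chance agreement with the panel majority allele),
# and stratification over reference-panel minor-allele-frequency bins.

.gp_matrix <- function(imputed) {
  if (inherits(imputed, "ls_impute")) imputed$gp else as.matrix(imputed)
}

#' Post-imputation GP filter
#'
#' Keeps a site when the GP of its most probable genotype reaches the
#' threshold.
#'
#' @param imputed an [ls_impute] fit or an `M x 3` GP matrix.
#' @param threshold GP threshold in `[0, 1]`; 0 keeps everything.
#' @return logical keep-mask of length `M`.
#' @export
gp_filter <- function(imputed, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  gp <- .gp_matrix(imputed)
  apply(gp, 1L, max) >= threshold
}

#' Genotype concordance against a gold standard
#'
#' Concordance is the fraction of evaluated sites where the imputed genotype
#' (argmax GP, ties towards the lower genotype code) equals the gold-standard
#' genotype.  Comparable sites are those with a non-missing gold standard
#' (restricted to heterozygotes if `het_only`); evaluated sites are the
#' comparable sites that also pass the keep-mask.
#'
#' @param imputed an [ls_impute] fit or `M x 3` GP matrix.
#' @param truth integer genotypes in `{0, 1, 2}`, `NA` where missing.
#' @param mask optional logical keep-mask (from [gp_filter()]); default all.
#' @param het_only restrict to truth-heterozygous sites.
#' @param threshold recorded in the report (metadata only).
#' @return an object of class `"concordance_report"`: `concordance`
#'   (`NA` with `undefined = TRUE` when no site is evaluated), `n_evaluated`,
#'   `n_comparable`, `evaluated_fraction`, plus the inputs needed for
#'   [maf_bin_summary()].
#' @export
concordance <- function(imputed, truth, mask = NULL, het_only = FALSE,
                        threshold = NA_real_) {
  gp <- .gp_matrix(imputed)
  M <- nrow(gp)
  if (length(truth) != M) stop("truth and imputed output must be aligned")
  if (is.null(mask)) mask <- rep(TRUE, M)
  call_gt <- max.col(gp, ties.method = "first") - 1L
  comparable <- !is.na(truth)
  if (het_only) comparable <- comparable & truth == 1L
  evaluated <- comparable & mask
  n_eval <- sum(evaluated)
  conc <- if (n_eval > 0L) mean(call_gt[evaluated] == truth[evaluated])
          else NA_real_
  structure(list(
    threshold = threshold, het_only = het_only,
    n_comparable = sum(comparable), n_evaluated = n_eval,
    evaluated_fraction = if (sum(comparable) > 0L) n_eval / sum(comparable)
                         else NA_real_,
    concordance = conc, undefined = n_eval == 0L,
    match = call_gt == truth, evaluated = evaluated
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Genotype concordance report",
      if (x$het_only) "(heterozygous truth only)", "\n")
  if (!is.na(x$threshold)) cat("  GP threshold:", x$threshold, "\n")
  cat("  comparable sites:", x$n_comparable,
      "  evaluated:", x$n_evaluated,
      sprintf("(%.1f%%)\n", 100 * x$evaluated_fraction))
  if (x$undefined) {
    cat("  concordance: undefined (no evaluated sites)\n")
  } else {
    cat(sprintf("  concordance: %.4f\n", x$concordance))
  }
  if (!is.null(x$maf_bins)) {
    cat("\nPer-MAF-bin concordance:\n")
    print(x$maf_bins[x$maf_bins$n_evaluated > 0L, ], row.names = FALSE)
  }
  invisible(x)
}

#' Reference-panel minor allele frequencies
#'
#' @param panel a [reference_panel].
#' @return per-site MAF, `min(f, 1 - f)` with `f` the panel alt-allele
#'   frequency.
#' @export
panel_maf <- function(panel) {
  f <- colMeans(panel$haplotypes)
  pmin(f, 1 - f)
}

#' Concordance stratified by reference-panel MAF
#'
#' Splits `[0, 0.5]` into `n_bins` equal-width, right-closed bins (MAF 0
#' falls in bin 1, MAF 0.5 in the top bin) and reports per-bin concordance
#' and evaluated counts.
#'
#' @param report a [concordance()] report.
#' @param panel the [reference_panel] (source of the allele frequencies).
#' @param n_bins number of bins; default 25.
#' @return the report with a `maf_bins` data frame attached (columns
#'   `bin`, `maf_lo`, `maf_hi`, `n_evaluated`, `concordance`).
#' @export
maf_bin_summary <- function(report, panel, n_bins = 25) {
  stopifnot(inherits(report, "concordance_report"))
  maf <- panel_maf(panel)
  if (length(maf) != length(report$evaluated)) {
    stop("panel and report cover different site sets")
  }
  width <- 0.5 / n_bins
  bin <- pmax(ceiling(maf / width), 1L)         # right-closed; MAF 0 -> bin 1
  bin <- pmin(bin, n_bins)                      # MAF 0.5 -> top bin
  tab <- data.frame(bin = seq_len(n_bins),
                    maf_lo = (seq_len(n_bins) - 1L) * width,
                    maf_hi = seq_len(n_bins) * width)
  tab$n_evaluated <- vapply(seq_len(n_bins), function(b) {
    sum(report$evaluated & bin == b)
  }, integer(1L))
  tab$concordance <- vapply(seq_len(n_bins), function(b) {
    sel <- report$evaluated & bin == b
    if (!any(sel)) NA_real_ else mean(report$match[sel])
  }, numeric(1L))
  report$maf_bins <- tab
  report$n_bins <- n_bins
  report
}

#' Write a concordance report as tab-separated text
#'
#' Emits a header of key-value summary lines (prefixed `#`) followed by the
#' per-MAF-bin table when present.
#'
#' @param report a [concordance()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_concordance_report <- function(report, path) {
  hdr <- c(
    paste0("#threshold\t", report$threshold),
    paste0("#het_only\t", report$het_only),
    paste0("#n_comparable\t", report$n_comparable),
    paste0("#n_evaluated\t", report$n_evaluated),
    paste0("#evaluated_fraction\t", format(report$evaluated_fraction)),
    paste0("#concordance\t", format(report$concordance)),
    paste0("#undefined\t", report$undefined))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  if (!is.null(report$maf_bins)) {
    utils::write.table(report$maf_bins, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
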