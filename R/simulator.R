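# Low-coverage read-thinning simulator and synthetic fixture generator.
#
# Coverage c in [0, 1] is emulated per site: a Bernoulli(p = c) decision on
# whether a single read is sampled.  A sampled read is drawn from the truth
# genotype with per-base error delta; its genotype likelihoods follow the
# GATK single-read formula.  Unsampled sites carry the uniform triplet.

#' Sample a single read from a truth genotype
#'
#' The probability that the read carries the alternative allele is
#' `1 - delta` for genotype 2 (alt hom), `0.5` for a heterozygote and
#' `delta` for genotype 0 (ref hom).
#'
#' @param truth_genotype genotype code(s) in `{0, 1, 2}` (alt-allele count).
#' @param delta per-base sequencing error rate in `[0, 0.5)`.
#' @return integer vector: 1 where the sampled read is the alternative
#'   allele, 0 where it is the reference allele.
#' @export
sample_read <- function(truth_genotype, delta) {
  if (!all(truth_genotype %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  if (delta < 0 || delta >= 0.5) stop("delta must lie in [0, 0.5)")
  p_alt <- c(delta, 0.5, 1 - delta)[truth_genotype + 1L]
  as.integer(stats::runif(length(truth_genotype)) < p_alt)
}

#' Genotype likelihoods of a single sampled read
#'
#' GATK-style single-read likelihoods: with `X` the sampled allele and `Y`
#' the other, `L(XX) = 1 - delta`, `L(YX) = 0.5 delta/3 + 0.5 (1 - delta)`,
#' `L(YY) = delta/3`.  With no read, all three genotypes get 1/3.
#'
#' @param sampled_allele 1 if the read carries the alternative allele, 0 if
#'   the reference allele, `NA` if no read was sampled.
#' @param delta per-base error rate in `[0, 0.5)`.
#' @return likelihood triplet on genotype codes `(0, 1, 2)`.
#' @export
read_likelihoods <- function(sampled_allele, delta) {
  if (delta < 0 || delta >= 0.5) stop("delta must lie in [0, 0.5)")
  if (is.na(sampled_allele)) return(.uniform_row())
  l_xx <- 1 - delta
  l_yx <- 0.5 * (delta / 3) + 0.5 * (1 - delta)
  l_yy <- delta / 3
  if (sampled_allele == 1L) c(l_yy, l_yx, l_xx) else c(l_xx, l_yx, l_yy)
}

#' Thin truth genotypes to low-coverage genotype likelihoods
#'
#' Per site: sample a read with probability `coverage`; if sampled, draw the
#' read from the truth genotype and convert to likelihoods; otherwise emit
#' the uniform triplet.  Missing truth genotypes are emitted as unobserved
#' and counted.
#'
#' @param truth integer vector of truth genotypes in `{0, 1, 2}` (`NA`
#'   allowed).
#' @param coverage target coverage `c` in `[0, 1]`; the per-site sampling
#'   probability `p` equals `c` (one read per sampled site).
#' @param delta per-base error rate; default 0.001 (Illumina-like).
#' @param seed optional integer seed for exact reproducibility.
#' @return a [likelihood_matrix]; the count of missing truth genotypes is in
#'   attribute `"n_missing_truth"`.
#' @export
thin_genotypes <- function(truth, coverage, delta = 0.001, seed = NULL) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  M <- length(truth)
  miss <- is.na(truth)
  sampled <- stats::runif(M) < coverage
  sampled[miss] <- FALSE
  lik <- matrix(rep(.uniform_row(), M), ncol = 3L, byrow = TRUE)
  if (any(sampled)) {
    reads <- sample_read(truth[sampled], delta)
    lik[sampled, ] <- t(vapply(reads, read_likelihoods, numeric(3L),
                               delta = delta))
  }
  out <- likelihood_matrix(lik, observed = sampled)
  attr(out, "n_missing_truth") <- sum(miss)
  out
}

# Piecewise-constant template choice: switch templates between consecutive
# sites with probability `rate`, drawing the new template uniformly.
.mosaic_haplotype <- function(source_haps, rate) {
  n <- nrow(source_haps); M <- ncol(source_haps)
  tmpl <- integer(M)
  tmpl[1L] <- sample.int(n, 1L)
  if (M > 1L) {
    sw <- stats::runif(M - 1L) < rate
    for (j in 2:M) tmpl[j] <- if (sw[j - 1L]) sample.int(n, 1L) else tmpl[j - 1L]
  }
  source_haps[cbind(tmpl, seq_len(M))]
}

#' Generate a synthetic reference panel with held-out targets
#'
#' Builds founder haplotypes with per-site allele frequencies kept above
#' `maf_floor`, derives the panel as recombinant mosaics of the founders, and
#' derives held-out diploid targets as fresh mosaics of the *panel*
#' haplotypes — so the targets are imputable from the panel but none of
#' their haplotypes is a panel member (unless `mosaic_switch_rate = 0`, in
#' which case a target is exactly one panel haplotype pair).  Sites sit
#' every 1 kb on chromosome "1".
#'
#' @param H number of panel haplotypes (>= 4, even).
#' @param M number of sites (>= 10).
#' @param n_targets number of held-out diploid targets.
#' @param mosaic_switch_rate per-interval template switch probability for
#'   the panel mosaics; default 0.01.
#' @param target_switch_rate switch probability for the target mosaics;
#'   defaults to `mosaic_switch_rate`.  At 0 each target copies one panel
#'   haplotype pair exactly.
#' @param maf_floor minimum panel minor-allele frequency; default 0.05.
#' @param n_founders number of founder haplotypes; default 8.
#' @param seed optional integer seed; a fixed seed regenerates the fixture
#'   byte-identically.
#' @return list with `panel` (a [reference_panel]), `target_haplotypes`
#'   (list of `2 x M` matrices), `truth` (`n_targets x M` genotype matrix),
#'   and `map` (a constant-rate [genetic_map], 1 cM/Mb).
#' @export
make_synthetic_panel <- function(H = 20, M = 500, n_targets = 1,
                                 mosaic_switch_rate = 0.01, maf_floor = 0.05,
                                 n_founders = 8, seed = NULL,
                                 target_switch_rate = mosaic_switch_rate) {
  if (H < 4L || M < 10L) stop("need H >= 4 and M >= 10")
  if (H %% 2L != 0L) stop("H must be even (whole diploid panel samples)")
  if (maf_floor < 0 || maf_floor > 0.5) stop("maf_floor must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)

  # founders: balanced per-site allele counts, frequencies in [0.2, 0.8]
  founders <- matrix(0L, n_founders, M)
  for (j in seq_len(M)) {
    rng <- seq.int(max(1L, round(0.2 * n_founders)),
                   min(n_founders - 1L, round(0.8 * n_founders)))
    n_alt <- rng[sample.int(length(rng), 1L)]
    founders[sample.int(n_founders, n_alt), j] <- 1L
  }

  hap <- t(vapply(seq_len(H), function(i) {
    .mosaic_haplotype(founders, mosaic_switch_rate)
  }, integer(M)))

  # enforce the MAF floor site-wise by flipping majority-allele carriers
  need <- ceiling(maf_floor * H)
  for (j in seq_len(M)) {
    cnt <- sum(hap[, j])
    minority <- if (cnt <= H / 2) 1L else 0L
    n_min <- min(cnt, H - cnt)
    if (n_min < need) {
      carriers <- which(hap[, j] != minority)
      flip <- carriers[sample.int(length(carriers), need - n_min)]
      hap[flip, j] <- minority
    }
  }

  positions <- seq_len(M) * 1000L
  panel <- reference_panel("1", positions,
                           ref = rep("A", M), alt = rep("G", M),
                           haplotypes = hap,
                           sample_names = paste0("P", seq_len(H / 2L)))
  targets <- lapply(seq_len(n_targets), function(i) {
    rbind(.mosaic_haplotype(hap, target_switch_rate),
          .mosaic_haplotype(hap, target_switch_rate))
  })
  truth <- do.call(rbind, lapply(targets, colSums))
  storage.mode(truth) <- "integer"
  map <- genetic_map(c(1, max(positions)),
                     c(0, (max(positions) - 1) / 1e6))  # 1 cM/Mb
  list(panel = panel, target_haplotypes = targets, truth = truth, map = map)
}
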