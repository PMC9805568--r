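# S3 methods for the "ls_impute" fit object.

#' @export
print.ls_impute <- function(x, ...) {
  cat("Diploid Li-Stephens imputation fit\n")
  cat("  panel: H =", x$H, "haplotypes,", x$M, "sites on", x$chrom, "\n")
  cat("  observed target sites:", sum(x$observed), "of", x$M, "\n")
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  cat("  checkpointing:", x$plan$mode,
      sprintf("(k1 = %d, k2 = %d, forward updates = %d)\n",
              x$plan$k1, x$plan$k2, x$n_forward_updates))
  cat(sprintf("  mean max GP: %.4f   mean dosage: %.4f\n",
              mean(apply(x$gp, 1L, max)), mean(x$dosage)))
  invisible(x)
}

#' Summarise an imputation fit
#'
#' @param object an [ls_impute] fit.
#' @param ... unused.
#' @return an object of class `"summary.ls_impute"` with per-genotype call
#'   counts, quantiles of the maximum GP, and the share of sites exceeding
#'   common GP-filter thresholds.
#' @export
summary.ls_impute <- function(object, ...) {
  max_gp <- apply(object$gp, 1L, max)
  calls <- max.col(object$gp, ties.method = "first") - 1L
  thresholds <- c(0.5, 0.8, 0.9, 0.99)
  structure(list(
    H = object$H, M = object$M, loglik = object$loglik,
    plan = object$plan, gp_mode = object$gp_mode,
    genotype_calls = table(factor(calls, levels = 0:2)),
    max_gp_quantiles = stats::quantile(max_gp, c(0, .25, .5, .75, 1)),
    pass_fraction = vapply(thresholds,
                           function(t) mean(max_gp >= t), numeric(1L)),
    thresholds = thresholds
  ), class = "summary.ls_impute")
}

#' @export
print.summary.ls_impute <- function(x, ...) {
  cat("Diploid Li-Stephens imputation fit:", x$H, "haplotypes x", x$M,
      "sites\n")
  cat(sprintf("log-likelihood %.4f; GP mode '%s'; checkpointing '%s'\n",
              x$loglik, x$gp_mode, x$plan$mode))
  cat("\nImputed genotype calls (argmax GP):\n")
  print(x$genotype_calls)
  cat("\nMax-GP quantiles:\n")
  print(round(x$max_gp_quantiles, 4L))
  cat("\nFraction of sites passing GP threshold:\n")
  print(stats::setNames(round(x$pass_fraction, 4L),
                        paste0(">=", x$thresholds)))
  invisible(x)
}

#' @export
coef.ls_impute <- function(object, ...) {
  stats::setNames(object$dosage, object$positions)
}

#' @export
fitted.ls_impute <- function(object, ...) coef(object)

#' Extract predictions from an imputation fit
#'
#' @param object an [ls_impute] fit.
#' @param type `"gp"` for the `M x 3` genotype-posterior matrix, `"dosage"`
#'   for expected alt-allele counts, `"genotype"` for the argmax-GP hard call
#'   (ties towards the lower code), `"haplotypes"` for the phased `2 x M`
#'   allele matrix.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.ls_impute <- function(object, type = c("gp", "dosage", "genotype",
                                               "haplotypes"), ...) {
  type <- match.arg(type)
  switch(type,
    gp = object$gp,
    dosage = object$dosage,
    genotype = max.col(object$gp, ties.method = "first") - 1L,
    haplotypes = object$haplotypes)
}

#' @export
logLik.ls_impute <- function(object, ...) {
  structure(object$loglik, df = NA_integer_, nobs = sum(object$observed),
            class = "logLik")
}

#' Plot an imputation fit
#'
#' Draws dosage along the chromosome, shaded by imputation confidence
#' (maximum GP), with unobserved target sites marked in grey below.
#'
#' @param x an [ls_impute] fit.
#' @param ... passed on to [graphics::plot()].
#' @export
plot.ls_impute <- function(x, ...) {
  max_gp <- apply(x$gp, 1L, max)
  shade <- grDevices::gray(1 - pmin(pmax((max_gp - 1 / 3) / (2 / 3), 0), 1))
  graphics::plot(x$positions, x$dosage, col = shade, pch = 16, cex = 0.6,
                 xlab = paste0("position (", x$chrom, ")"),
                 ylab = "imputed dosage", ylim = c(-0.15, 2), ...)
  unobs <- !x$observed
  if (any(unobs)) {
    graphics::points(x$positions[unobs], rep(-0.1, sum(unobs)),
                     pch = "|", col = "grey70", cex = 0.5)
  }
  invisible(x)
}

#' Simulate genotypes from the posterior
#'
#' Draws hard genotypes site-by-site from the fitted GP rows (independently
#' across sites; linkage between sites is not resampled).
#'
#' @param object an [ls_impute] fit.
#' @param nsim number of replicate draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return `M x nsim` integer matrix of genotypes in `{0, 1, 2}`.
#' @export
simulate.ls_impute <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(nsim), function(k) {
    vapply(seq_len(object$M), function(j) {
      sample(0:2, 1L, prob = object$gp[j, ])
    }, integer(1L))
  }, integer(object$M))
  matrix(out, nrow = object$M, ncol = nsim)
}
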