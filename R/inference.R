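# Forward-backward engine over the H^2 diploid copying states.
#
# A state (x1, x2) is stored at linear index (x2 - 1) * H + x1, i.e. a state
# vector of length H^2 is the column-major layout of an H x H matrix whose
# rows index the first chromosome's template and columns the second's.

#' Collapsed transition propagation
#'
#' Multiplies a state vector by the dense `H^2 x H^2` diploid transition
#' matrix in `O(H^2)` time.  Because the transition factorises per chromosome
#' slot into `(1-theta) I + (theta/H) 1 1'`, applying
#' `v' = (1-theta) v + (theta/H) (slot marginal)` once per slot reproduces
#' the dense product exactly; total mass is preserved.
#'
#' @param v non-negative state vector of length `H^2`.
#' @param theta per-interval switch probability in `[0, 1)`.
#' @param H number of reference haplotypes.
#' @return the propagated vector, same length and total mass.
#' @export
collapsed_propagate <- function(v, theta, H) {
  V <- matrix(v, H, H)
  # slot 1 (rows): mix towards the column sums
  V <- (1 - theta) * V + (theta / H) * rep(colSums(V), each = H)
  dim(V) <- c(H, H)
  # slot 2 (columns): mix towards the row sums
  V <- (1 - theta) * V + (theta / H) * rowSums(V)
  as.vector(V)
}

#' Checkpointing plan for the forward-backward sweep
#'
#' `full` keeps every forward vector (memory `O(M)`); `one_level` keeps every
#' `k1`-th and recomputes inside blocks during the backward sweep (memory
#' `O(M/k1 + k1)`, about twice the forward work); `two_level` additionally
#' checkpoints every `k2`-th vector inside the active block (memory
#' `O(M/k1 + k1/k2 + k2)`, about three times the forward work).
#'
#' @param mode `"full"`, `"one_level"` or `"two_level"`.
#' @param M number of sites.
#' @param k1 level-1 block size; defaults to `ceiling(sqrt(M))` for
#'   `one_level` and `ceiling(M^(2/3))` for `two_level`.
#' @param k2 level-2 block size (two-level only); default `ceiling(M^(1/3))`.
#' @return an object of class `"checkpoint_plan"`.
#' @export
checkpoint_plan <- function(mode = c("full", "one_level", "two_level"),
                            M, k1 = NULL, k2 = NULL) {
  mode <- match.arg(mode)
  M <- as.integer(M)
  if (mode == "one_level" && is.null(k1)) k1 <- ceiling(sqrt(M))
  if (mode == "two_level") {
    if (is.null(k1)) k1 <- ceiling(M^(2 / 3))
    if (is.null(k2)) k2 <- ceiling(M^(1 / 3))
  }
  if (mode == "full") { k1 <- M; k2 <- M }
  if (mode == "one_level" && is.null(k2)) k2 <- k1
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k2 < 1L || k2 > k1 || k1 > M) stop("need 1 <= k2 <= k1 <= M")
  peak <- switch(mode,
    full = M,
    one_level = ceiling(M / k1) + k1,
    two_level = ceiling(M / k1) + ceiling(k1 / k2) + k2)
  structure(list(mode = mode, k1 = k1, k2 = k2, M = M,
                 peak_stored_vectors = as.integer(peak)),
            class = "checkpoint_plan")
}

# Per-site machinery shared by the passes.  `u[, j]` holds
# u_k = sum_g P(g | k) L_j(g) for implied genotype k; the emission vector
# over states is u_k evaluated at each state's implied genotype.
.site_context <- function(panel, lik, params) {
  M <- panel$M
  u <- vapply(seq_len(M), function(j) {
    as.vector(crossprod(observation_matrix(params$epsilon[j]), lik$lik[j, ]))
  }, numeric(3L))
  list(
    M = M, H = panel$H, S = panel$H^2L, theta = params$theta,
    epsilon = params$epsilon,
    u = u, hap = panel$haplotypes,
    gidx = function(j) {
      h <- panel$haplotypes[, j]
      as.vector(outer(h, h, "+")) + 1L   # implied genotype + 1, length H^2
    },
    emission = function(j, gi) u[gi, j]
  )
}

.rescale <- function(v, j) {
  s <- sum(v)
  if (s <= 0) {
    stop("all states have zero emission weight at site ", j,
         " (contradictory one-hot likelihoods with epsilon = 0)")
  }
  list(v = v / s, logc = log(s))
}

#' Forward pass
#'
#' Runs the scaled forward recursion and returns every forward vector (no
#' checkpointing).  `alpha[, j]` is the forward distribution at site `j`
#' rescaled to sum 1; the per-site log scale factors sum to the data
#' log-likelihood.
#'
#' @param panel a [reference_panel].
#' @param lik a [likelihood_matrix] aligned to the panel.
#' @param params an [hmm_parameters] object.
#' @return list with `alpha` (`H^2 x M`), `log_scale` (length `M`), `loglik`.
#' @export
forward_pass <- function(panel, lik, params) {
  ctx <- .site_context(panel, lik, params)
  alpha <- matrix(0, ctx$S, ctx$M)
  logc <- numeric(ctx$M)
  r <- .rescale(ctx$emission(1L, ctx$gidx(1L)) / ctx$S, 1L)
  alpha[, 1L] <- r$v; logc[1L] <- r$logc
  for (j in seq_len(ctx$M)[-1L]) {
    r <- .rescale(
      collapsed_propagate(alpha[, j - 1L], ctx$theta[j], ctx$H) *
        ctx$emission(j, ctx$gidx(j)), j)
    alpha[, j] <- r$v; logc[j] <- r$logc
  }
  list(alpha = alpha, log_scale = logc, loglik = sum(logc))
}

#' Backward pass
#'
#' Scaled backward recursion; `beta[, j]` is rescaled to sum 1 at every site,
#' which leaves posteriors unchanged.  The diploid transition matrix is
#' symmetric, so the same collapsed propagation serves both directions.
#'
#' @inheritParams forward_pass
#' @return list with `beta` (`H^2 x M`) and `log_scale` (length `M`;
#'   `log_scale[j]` is the log of the factor divided out when producing
#'   `beta[, j]`, with `log_scale[M] = log(H^2)` from the all-ones start).
#' @export
backward_pass <- function(panel, lik, params) {
  ctx <- .site_context(panel, lik, params)
  beta <- matrix(0, ctx$S, ctx$M)
  logc <- numeric(ctx$M)
  beta[, ctx$M] <- 1 / ctx$S
  logc[ctx$M] <- log(ctx$S)
  for (j in rev(seq_len(ctx$M)[-1L])) {
    v <- collapsed_propagate(
      ctx$emission(j, ctx$gidx(j)) * beta[, j], ctx$theta[j], ctx$H)
    r <- .rescale(v, j - 1L)
    beta[, j - 1L] <- r$v
    logc[j - 1L] <- r$logc
  }
  list(beta = beta, log_scale = logc)
}

#' Genotype posteriors at one site
#'
#' Combines the forward and backward state vectors at a site into the
#' posterior genotype distribution.  The default (`"posterior"`) is the true
#' posterior of the latent genotype, which keeps the local likelihood term:
#' `GP(g) = sum_X P(X | Y) P(g | X) L(g) / sum_g' P(g' | X) L(g')`.  The
#' `"predictive"` alternative integrates the copying model only:
#' `GP(g) = sum_X P(X | Y) P(g | X)`.
#'
#' @param alpha_j,beta_j forward/backward state vectors at site `j`.
#' @param likelihood_row the site's likelihood triplet.
#' @param epsilon the site's error parameter.
#' @param panel a [reference_panel].
#' @param j site index.
#' @param gp_mode `"posterior"` (default) or `"predictive"`.
#' @return genotype posterior triplet summing to 1.
#' @export
genotype_posteriors <- function(alpha_j, beta_j, likelihood_row, epsilon,
                                panel, j,
                                gp_mode = c("posterior", "predictive")) {
  gp_mode <- match.arg(gp_mode)
  gamma <- alpha_j * beta_j
  gamma <- gamma / sum(gamma)
  h <- panel$haplotypes[, j]
  gi <- as.vector(outer(h, h, "+")) + 1L
  m <- vapply(1:3, function(k) sum(gamma[gi == k]), numeric(1L))
  Tm <- observation_matrix(epsilon)
  .gp_from_masses(m, Tm, likelihood_row, gp_mode)
}

.gp_from_masses <- function(m, Tm, L, gp_mode) {
  if (gp_mode == "predictive") {
    gp <- as.vector(Tm %*% m)
  } else {
    u <- as.vector(crossprod(Tm, L))
    ratio <- ifelse(m > 0, m / u, 0)
    gp <- L * as.vector(Tm %*% ratio)
  }
  gp / sum(gp)
}

#' Run the (optionally checkpointed) forward-backward algorithm
#'
#' Computes per-site state posteriors, genotype posteriors, dosage, phased
#' haplotypes and the total data log-likelihood.  All checkpoint modes give
#' identical results; they differ only in how many forward vectors are kept
#' versus recomputed during the backward sweep.  The number of forward
#' updates actually executed is returned (`n_forward_updates`) — close to
#' `M`, `2M` and `3M` for the three modes.
#'
#' @inheritParams forward_pass
#' @param plan a [checkpoint_plan]; default full storage.
#' @param gp_mode see [genotype_posteriors()].
#' @return list with `gp`, `dosage`, `haplotypes`, `state_index`,
#'   `state_prob`, `loglik`, `n_forward_updates`, `plan`, `gp_mode`.
#' @export
run_forward_backward <- function(panel, lik, params,
                                 plan = checkpoint_plan("full", panel$M),
                                 gp_mode = c("posterior", "predictive")) {
  gp_mode <- match.arg(gp_mode)
  stopifnot(inherits(plan, "checkpoint_plan"), plan$M == panel$M)
  ctx <- .site_context(panel, lik, params)
  M <- ctx$M; S <- ctx$S; H <- ctx$H; k1 <- plan$k1; k2 <- plan$k2
  n_fwd <- 0L

  fwd_step <- function(a_prev, j) {
    n_fwd <<- n_fwd + 1L
    .rescale(collapsed_propagate(a_prev, ctx$theta[j], H) *
               ctx$emission(j, ctx$gidx(j)), j)
  }

  # ---- forward sweep, storing what the plan allows -------------------------
  logc <- numeric(M)
  full_store <- if (plan$mode == "full") matrix(0, S, M)
  cp_idx <- seq.int(1L, M, by = k1)
  cp <- if (plan$mode != "full") matrix(0, S, length(cp_idx))
  r <- .rescale(ctx$emission(1L, ctx$gidx(1L)) / S, 1L)
  a <- r$v; logc[1L] <- r$logc
  if (plan$mode == "full") full_store[, 1L] <- a else cp[, 1L] <- a
  if (M > 1L) for (j in 2:M) {
    r <- fwd_step(a, j)
    a <- r$v; logc[j] <- r$logc
    if (plan$mode == "full") {
      full_store[, j] <- a
    } else if ((j - 1L) %% k1 == 0L) {
      cp[, (j - 1L) %/% k1 + 1L] <- a
    }
  }

  # ---- backward sweep with per-plan alpha retrieval ------------------------
  blk_buf <- NULL; blk_id <- -1L          # one-level block buffer
  l2 <- NULL; l2_blk <- -1L               # two-level: in-block checkpoints
  sub_buf <- NULL; sub_id <- -1L

  get_alpha <- function(j) {
    if (plan$mode == "full") return(full_store[, j])
    blk <- (j - 1L) %/% k1
    start <- blk * k1 + 1L
    end <- min(start + k1 - 1L, M)
    if (plan$mode == "one_level") {
      if (blk != blk_id) {
        buf <- matrix(0, S, end - start + 1L)
        buf[, 1L] <- cp[, blk + 1L]
        if (end > start) for (t in (start + 1L):end) {
          buf[, t - start + 1L] <- fwd_step(buf[, t - start], t)$v
        }
        blk_buf <<- buf; blk_id <<- blk
      }
      return(blk_buf[, j - start + 1L])
    }
    # two-level
    if (blk != l2_blk) {
      n2 <- (end - start) %/% k2 + 1L
      l2m <- matrix(0, S, n2)
      v <- cp[, blk + 1L]; l2m[, 1L] <- v
      if (end > start) for (t in (start + 1L):end) {
        v <- fwd_step(v, t)$v
        if ((t - start) %% k2 == 0L) l2m[, (t - start) %/% k2 + 1L] <- v
      }
      l2 <<- l2m; l2_blk <<- blk; sub_id <<- -1L
    }
    sub <- (j - start) %/% k2
    sstart <- start + sub * k2
    send <- min(sstart + k2 - 1L, end)
    if (sub != sub_id) {
      buf <- matrix(0, S, send - sstart + 1L)
      buf[, 1L] <- l2[, sub + 1L]
      if (send > sstart) for (t in (sstart + 1L):send) {
        buf[, t - sstart + 1L] <- fwd_step(buf[, t - sstart], t)$v
      }
      sub_buf <<- buf; sub_id <<- sub
    }
    sub_buf[, j - sstart + 1L]
  }

  gp <- matrix(0, M, 3L)
  state_index <- integer(M); state_prob <- numeric(M)
  hap_out <- matrix(0L, 2L, M)
  b <- rep(1 / S, S)
  for (j in M:1L) {
    gi <- ctx$gidx(j)
    gamma <- get_alpha(j) * b
    gamma <- gamma / sum(gamma)
    m <- vapply(1:3, function(k) sum(gamma[gi == k]), numeric(1L))
    gp[j, ] <- .gp_from_masses(m, observation_matrix(ctx$epsilon[j]),
                               lik$lik[j, ], gp_mode)
    smax <- which.max(gamma)              # ties -> smallest linear index
    state_index[j] <- smax
    state_prob[j] <- gamma[smax]
    x1 <- (smax - 1L) %% H + 1L
    x2 <- (smax - 1L) %/% H + 1L
    hap_out[, j] <- c(ctx$hap[x1, j], ctx$hap[x2, j])
    if (j > 1L) {
      v <- collapsed_propagate(ctx$emission(j, gi) * b, ctx$theta[j], H)
      b <- v / sum(v)
    }
  }

  list(gp = gp, dosage = gp[, 2L] + 2 * gp[, 3L], haplotypes = hap_out,
       state_index = state_index, state_prob = state_prob,
       loglik = sum(logc), log_scale = logc,
       n_forward_updates = n_fwd, plan = plan, gp_mode = gp_mode)
}

#' Fit the diploid Li-Stephens imputation model to one sample
#'
#' The main entry point: given a phased reference panel and a target sample's
#' genotype likelihoods, runs the collapsed forward-backward algorithm over
#' all `H^2` ordered haplotype-pair states and returns per-site genotype
#' posteriors (GP), alternative-allele dosage, a phased haplotype pair taken
#' from the per-site maximum-posterior state, and the total log-likelihood.
#'
#' @param panel a [reference_panel].
#' @param target a [likelihood_matrix] (from [read_target_likelihoods()] or
#'   [thin_genotypes()]), or a bare `M x 3` matrix of likelihoods.
#' @param map optional [genetic_map]; see [hmm_parameters()].
#' @param Ne effective-size constant (default 11418).
#' @param epsilon error parameter (default 0.01), scalar or per-site.
#' @param rate_cM_per_Mb constant map rate used when `map` is `NULL`.
#' @param checkpoint checkpoint mode: `"full"`, `"one_level"`, `"two_level"`.
#' @param k1,k2 optional block sizes, see [checkpoint_plan()].
#' @param gp_mode `"posterior"` (default) or `"predictive"`, see
#'   [genotype_posteriors()].
#' @param params optional pre-built [hmm_parameters]; overrides `map`, `Ne`,
#'   `epsilon` and `rate_cM_per_Mb`.
#' @return an object of class `"ls_impute"`; see [run_forward_backward()] for
#'   the computed fields.  Methods: [print()], [summary()], [coef()]
#'   (dosage), [fitted()], [predict()], [logLik()], [plot()], [simulate()].
#' @examples
#' fx <- make_synthetic_panel(H = 8, M = 60, n_targets = 1, seed = 1)
#' tl <- thin_genotypes(fx$truth[1, ], coverage = 0.8, delta = 0.01, seed = 2)
#' fit <- ls_impute(fx$panel, tl)
#' fit
#' head(predict(fit, type = "gp"))
#' @export
ls_impute <- function(panel, target, map = NULL, Ne = 11418, epsilon = 0.01,
                      rate_cM_per_Mb = 1,
                      checkpoint = c("full", "one_level", "two_level"),
                      k1 = NULL, k2 = NULL,
                      gp_mode = c("posterior", "predictive"),
                      params = NULL) {
  checkpoint <- match.arg(checkpoint)
  gp_mode <- match.arg(gp_mode)
  if (!inherits(target, "likelihood_matrix")) {
    target <- likelihood_matrix(target)
  }
  if (target$M != panel$M) stop("target likelihoods must cover all panel sites")
  if (is.null(params)) {
    params <- hmm_parameters(panel, map = map, Ne = Ne, epsilon = epsilon,
                             rate_cM_per_Mb = rate_cM_per_Mb)
  }
  plan <- checkpoint_plan(checkpoint, panel$M, k1 = k1, k2 = k2)
  res <- run_forward_backward(panel, target, params, plan, gp_mode)
  res$M <- panel$M; res$H <- panel$H
  res$chrom <- panel$chrom; res$positions <- panel$positions
  res$params <- params
  res$observed <- target$observed
  res$call <- match.call()
  class(res) <- "ls_impute"
  res
}
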