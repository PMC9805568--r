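test_that("collapsed propagation equals the dense transition product", {
  set.seed(42)
  for (H in 2:6) {
    for (theta in c(0, 0.05, 0.3, 0.8)) {
      A <- dense_transition_matrix(theta, H)
      for (r in 1:5) {
        v <- runif(H^2)
        expect_lt(max(abs(collapsed_propagate(v, theta, H) -
                            as.vector(A %*% v))), 1e-12)
      }
    }
  }
})

test_that("collapsed propagation limits: identity at theta 0, uniform at 1", {
  set.seed(1)
  v <- runif(25)
  expect_equal(collapsed_propagate(v, 0, 5), v)
  out <- collapsed_propagate(v, 1, 5)
  expect_equal(out, rep(sum(v) / 25, 25), tolerance = 1e-12)
  # mass preservation at intermediate theta
  expect_equal(sum(collapsed_propagate(v, 0.37, 5)), sum(v),
               tolerance = 1e-12)
})

test_that("single-site forward pass normalises as expected", {
  panel <- tiny_panel(3, 1, seed = 2)
  # raw 1/3 triplet, bypassing the constructor's max-1 rescaling: the
  # emission is then exactly 1/3 per state and the data log-likelihood
  # log(1/3); rescaled input shifts it by log(3), posteriors unchanged
  lik <- structure(list(lik = matrix(1 / 3, 1, 3), observed = TRUE,
                        M = 1L, n_dropped = 0L), class = "likelihood_matrix")
  params <- hmm_parameters(panel, epsilon = 0.05)
  fwd <- forward_pass(panel, lik, params)
  expect_equal(fwd$alpha[, 1], rep(1 / 9, 9))
  expect_equal(fwd$loglik, log(1 / 3), tolerance = 1e-12)
  lik_scaled <- likelihood_matrix(matrix(1 / 3, 1, 3))
  expect_equal(forward_pass(panel, lik_scaled, params)$loglik, 0,
               tolerance = 1e-12)
})

test_that("forward-backward matches exhaustive path enumeration", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    oracle <- oracle_forward_backward(inst$panel, inst$lik, inst$params)
    fwd <- forward_pass(inst$panel, inst$lik, inst$params)
    bwd <- backward_pass(inst$panel, inst$lik, inst$params)
    expect_equal(fwd$loglik, oracle$loglik, tolerance = 1e-9)
    gamma <- fwd$alpha * bwd$beta
    gamma <- sweep(gamma, 2, colSums(gamma), "/")
    expect_lt(max(abs(gamma - oracle$state_posteriors)), 1e-9)
    res <- run_forward_backward(inst$panel, inst$lik, inst$params)
    expect_lt(max(abs(res$gp - oracle$gp)), 1e-9)
    res_pred <- run_forward_backward(inst$panel, inst$lik, inst$params,
                                     gp_mode = "predictive")
    expect_lt(max(abs(res_pred$gp - oracle$gp_predictive)), 1e-9)
  }
})

test_that("backward pass invariants hold", {
  inst <- random_instance(99)
  fwd <- forward_pass(inst$panel, inst$lik, inst$params)
  bwd <- backward_pass(inst$panel, inst$lik, inst$params)
  M <- inst$panel$M
  # beta_M is constant over states
  expect_equal(bwd$beta[, M], rep(1 / inst$H^2, inst$H^2))
  # the unscaled normaliser sum_X alpha_j beta_j is the same at every site
  logn <- vapply(seq_len(M), function(j) {
    log(sum(fwd$alpha[, j] * bwd$beta[, j])) +
      sum(fwd$log_scale[seq_len(j)]) + sum(bwd$log_scale[j:M])
  }, numeric(1))
  expect_lt(max(logn) - min(logn), 1e-10)
})

test_that("posteriors are invariant to likelihood-row scale", {
  inst <- random_instance(7)
  res <- run_forward_backward(inst$panel, inst$lik, inst$params)
  # bypass the constructor's max-1 rescaling to scale one row by 5
  lik2 <- inst$lik
  lik2$lik[2, ] <- lik2$lik[2, ] * 5
  res2 <- run_forward_backward(inst$panel, lik2, inst$params)
  expect_equal(res2$loglik - res$loglik, log(5), tolerance = 1e-10)
  expect_lt(max(abs(res2$gp - res$gp)), 1e-12)
  expect_identical(res2$state_index, res$state_index)
})

test_that("posteriors are equivariant under panel haplotype relabelling", {
  inst <- random_instance(13)
  panel <- inst$panel
  perm <- sample(panel$H)
  panel2 <- reference_panel(panel$chrom, panel$positions, panel$ref,
                            panel$alt, panel$haplotypes[perm, , drop = FALSE])
  res <- run_forward_backward(panel, inst$lik, inst$params)
  res2 <- run_forward_backward(panel2, inst$lik, inst$params)
  expect_equal(res2$loglik, res$loglik, tolerance = 1e-10)
  expect_lt(max(abs(res2$gp - res$gp)), 1e-10)
})

test_that("checkpointing modes agree exactly, including ragged blocks", {
  for (M in c(10L, 101L)) {
    panel <- tiny_panel(4, M, seed = M)
    lik <- rand_lik(M, seed = M + 1)
    params <- rand_params(panel, seed = M + 2)
    full <- run_forward_backward(panel, lik, params,
                                 checkpoint_plan("full", M))
    # block sizes chosen not to divide M, to hit ragged final blocks
    one <- run_forward_backward(panel, lik, params,
                                checkpoint_plan("one_level", M,
                                                k1 = if (M == 10L) 4L else 7L))
    two <- run_forward_backward(panel, lik, params,
                                checkpoint_plan("two_level", M,
                                                k1 = if (M == 10L) 4L else 16L,
                                                k2 = if (M == 10L) 3L else 5L))
    for (alt in list(one, two)) {
      expect_lt(max(abs(alt$gp - full$gp)), 1e-10)
      expect_equal(alt$loglik, full$loglik, tolerance = 1e-10)
      expect_identical(alt$state_index, full$state_index)
      expect_identical(alt$haplotypes, full$haplotypes)
    }
    # forward-update accounting: ~M, ~2M, ~3M
    expect_identical(full$n_forward_updates, M - 1L)
    expect_lt(one$n_forward_updates, 2L * M)
    expect_lt(two$n_forward_updates, 3L * M)
    expect_gt(two$n_forward_updates, one$n_forward_updates)
  }
})

test_that("checkpoint plans enforce sizes and report peak storage", {
  p <- checkpoint_plan("two_level", 1000L)
  expect_identical(p$k1, 100L)   # ceil(1000^(2/3))
  expect_identical(p$k2, 10L)
  expect_identical(p$peak_stored_vectors, 10L + 10L + 10L)
  p1 <- checkpoint_plan("one_level", 100L)
  expect_identical(p1$k1, 10L)
  expect_identical(p1$peak_stored_vectors, 20L)
  expect_error(checkpoint_plan("two_level", 10L, k1 = 2L, k2 = 5L),
               "k2 <= k1")
  expect_identical(checkpoint_plan("full", 50L)$peak_stored_vectors, 50L)
})

test_that("GP rows and state posteriors are normalised on random fits", {
  fx <- make_synthetic_panel(H = 10, M = 80, n_targets = 1, seed = 21)
  lik <- thin_genotypes(fx$truth[1, ], coverage = 0.4, delta = 0.01,
                        seed = 22)
  fit <- ls_impute(fx$panel, lik, checkpoint = "two_level")
  expect_equal(rowSums(fit$gp), rep(1, 80), tolerance = 1e-9)
  expect_equal(fit$dosage, fit$gp[, 2] + 2 * fit$gp[, 3], tolerance = 1e-12)
  expect_true(all(fit$state_prob > 0 & fit$state_prob <= 1))
  # phased alleles match the stored max-posterior state at every site
  x1 <- (fit$state_index - 1L) %% fit$H + 1L
  x2 <- (fit$state_index - 1L) %/% fit$H + 1L
  expect_identical(fit$haplotypes[1, ],
                   fx$panel$haplotypes[cbind(x1, seq_len(80))])
  expect_identical(fit$haplotypes[2, ],
                   fx$panel$haplotypes[cbind(x2, seq_len(80))])
})

test_that("an exact panel-pair target is rephased correctly", {
  fx <- make_synthetic_panel(H = 12, M = 150, n_targets = 1,
                             target_switch_rate = 0, seed = 31)
  truth_h <- fx$target_haplotypes[[1]]
  # full-information likelihoods: one-hot at the true genotype
  lik <- likelihood_matrix(diag(3)[fx$truth[1, ] + 1L, ])
  fit <- ls_impute(fx$panel, lik, epsilon = 0.001)
  # recovered allele pair equals the truth pair up to slot swap per site
  got <- apply(fit$haplotypes, 2, sort)
  want <- apply(truth_h, 2, sort)
  expect_identical(got, want)
  expect_equal(colSums(fit$haplotypes), fx$truth[1, ],
               ignore_attr = TRUE)
})

test_that("exact posterior ties resolve to the smallest state index", {
  # identical haplotypes make every state equivalent -> uniform posterior
  hap <- matrix(0L, 4, 5)
  panel <- reference_panel("1", seq_len(5) * 10L, rep("A", 5), rep("G", 5),
                           hap)
  lik <- likelihood_matrix(matrix(1, 5, 3))
  res <- run_forward_backward(panel, lik, hmm_parameters(panel))
  expect_identical(res$state_index, rep(1L, 5))
})

test_that("contradictory one-hot data at epsilon 0 raises a site error", {
  hap <- matrix(0L, 4, 3)  # implied genotype 0 everywhere
  panel <- reference_panel("1", c(10L, 20L, 30L), rep("A", 3), rep("G", 3),
                           hap)
  lik <- likelihood_matrix(rbind(c(1, 0, 0), c(0, 0, 1), c(1, 0, 0)))
  expect_error(
    run_forward_backward(panel, lik, hmm_parameters(panel, epsilon = 0)),
    "site 2")
})

test_that("genotype_posteriors combines alpha and beta at a single site", {
  inst <- random_instance(55)
  fwd <- forward_pass(inst$panel, inst$lik, inst$params)
  bwd <- backward_pass(inst$panel, inst$lik, inst$params)
  res <- run_forward_backward(inst$panel, inst$lik, inst$params)
  for (j in seq_len(inst$panel$M)) {
    gp <- genotype_posteriors(fwd$alpha[, j], bwd$beta[, j],
                              inst$lik$lik[j, ], inst$params$epsilon[j],
                              inst$panel, j)
    expect_equal(gp, res$gp[j, ], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(gp), 1, tolerance = 1e-12)
  }
})

test_that("fit object methods are coherent", {
  fx <- make_synthetic_panel(H = 8, M = 50, n_targets = 1, seed = 41)
  lik <- thin_genotypes(fx$truth[1, ], coverage = 0.6, delta = 0.01,
                        seed = 42)
  fit <- ls_impute(fx$panel, lik)
  expect_s3_class(fit, "ls_impute")
  expect_output(print(fit), "Li-Stephens")
  s <- summary(fit)
  expect_s3_class(s, "summary.ls_impute")
  expect_output(print(s), "Max-GP quantiles")
  expect_equal(unname(coef(fit)), fit$dosage)
  expect_identical(predict(fit, "gp"), fit$gp)
  expect_identical(predict(fit, "genotype"),
                   max.col(fit$gp, ties.method = "first") - 1L)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(50L, 3L))
  expect_true(all(sims %in% 0:2))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
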