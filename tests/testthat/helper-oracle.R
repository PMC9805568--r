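# Independent oracles: dense transition matrix assembled state by state from
# the three switch-count probabilities, and exhaustive enumeration of all
# (H^2)^M hidden-state paths.  Feasible for H <= 3, M <= 5 (and H <= 6 for
# single propagation steps); used to pin down the collapsed recursion.

dense_transition_matrix <- function(theta, H) {
  S <- H^2
  x1 <- (seq_len(S) - 1L) %% H + 1L
  x2 <- (seq_len(S) - 1L) %/% H + 1L
  A <- matrix(0, S, S)
  for (a in seq_len(S)) {
    for (b in seq_len(S)) {
      n_sw <- (x1[a] != x1[b]) + (x2[a] != x2[b])
      A[a, b] <- state_transition_prob(theta, H, n_sw)
    }
  }
  A
}

# Per-state emission weights for every site (S x M), by direct summation.
oracle_emissions <- function(panel, lik, params) {
  S <- panel$H^2
  x1 <- (seq_len(S) - 1L) %% panel$H + 1L
  x2 <- (seq_len(S) - 1L) %/% panel$H + 1L
  vapply(seq_len(panel$M), function(j) {
    Tm <- observation_matrix(params$epsilon[j])
    vapply(seq_len(S), function(s) {
      g <- panel$haplotypes[x1[s], j] + panel$haplotypes[x2[s], j]
      sum(Tm[, g + 1L] * lik$lik[j, ])
    }, numeric(1L))
  }, numeric(S))
}

# Full path enumeration.  Returns per-site state posteriors (S x M), genotype
# posteriors (M x 3, both conventions), and the data log-likelihood.
oracle_forward_backward <- function(panel, lik, params) {
  H <- panel$H; S <- H^2; M <- panel$M
  emis <- oracle_emissions(panel, lik, params)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
  w <- rep(1 / S, nrow(paths)) * emis[cbind(paths[, 1L], 1L)]
  if (M > 1L) for (j in 2:M) {
    A <- dense_transition_matrix(params$theta[j], H)
    w <- w * A[cbind(paths[, j - 1L], paths[, j])] *
      emis[cbind(paths[, j], j)]
  }
  py <- sum(w)
  post <- vapply(seq_len(M), function(j) {
    vapply(seq_len(S), function(s) sum(w[paths[, j] == s]), numeric(1L)) / py
  }, numeric(S))

  x1 <- (seq_len(S) - 1L) %% H + 1L
  x2 <- (seq_len(S) - 1L) %/% H + 1L
  gp_both <- lapply(c("posterior", "predictive"), function(mode) {
    t(vapply(seq_len(M), function(j) {
      gi <- panel$haplotypes[x1, j] + panel$haplotypes[x2, j]  # implied g
      Tm <- observation_matrix(params$epsilon[j])
      L <- lik$lik[j, ]
      u <- as.vector(crossprod(Tm, L))
      k <- gi[paths[, j]] + 1L
      gp <- vapply(0:2, function(g) {
        if (mode == "posterior") {
          sum(w * Tm[g + 1L, k] * L[g + 1L] / u[k])
        } else {
          sum(w * Tm[g + 1L, k])
        }
      }, numeric(1L))
      gp / sum(gp)
    }, numeric(3L)))
  })
  list(state_posteriors = post, gp = gp_both[[1L]],
       gp_predictive = gp_both[[2L]], loglik = log(py))
}

# Random tiny instance for the oracle battery.
random_instance <- function(seed) {
  set.seed(seed)
  H <- sample(2:3, 1L)
  M <- sample(2:5, 1L)
  panel <- tiny_panel(H, M)
  lik <- rand_lik(M)
  params <- rand_params(panel, eps = runif(1L, 0.005, 0.1))
  list(panel = panel, lik = lik, params = params, H = H, M = M)
}
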