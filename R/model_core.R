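#' Per-interval recombination fraction
#'
#' Converts a genetic-map distance between two consecutive panel sites into
#' the haplotype-copying switch probability \eqn{\theta} of the Li-Stephens
#' model, \eqn{\theta = 1 - \exp(-4 N_e d / H)} with \eqn{d} the distance in
#' Morgans.  The effective-size constant `Ne` is a model parameter, not a
#' quantity estimated from the data; the default used throughout the package
#' is the HapMap-era value 11418.
#'
#' @param delta_cM non-negative genetic distance(s) in centiMorgans.
#' @param Ne effective population size constant (dimensionless).
#' @param H number of reference haplotypes.
#' @return numeric vector of switch probabilities in `[0, 1)`.
#' @examples
#' recombination_fraction(0.01, Ne = 100, H = 4)  # ~0.00995
#' @export
recombination_fraction <- function(delta_cM, Ne, H) {
  if (any(delta_cM < 0)) stop("genetic distances must be non-negative")
  d <- delta_cM / 100  # Morgans
  1 - exp(-4 * Ne * d / H)
}

#' Diploid state transition probability
#'
#' Probability of moving from one ordered haplotype pair to another, as a
#' function of how many of the two template haplotypes switch.  The three
#' cases are
#' \deqn{\theta^2/H^2,\quad (1-\theta)\theta/H + \theta^2/H^2,\quad
#'       (1-\theta)^2 + 2(\theta-\theta^2)/H + \theta^2/H^2}
#' for 2, 1 and 0 switches respectively.
#'
#' @param theta per-interval switch probability in `[0, 1)`.
#' @param H number of reference haplotypes.
#' @param n_switch number of template switches: 0, 1 or 2.
#' @return transition probability.
#' @export
state_transition_prob <- function(theta, H, n_switch) {
  if (!n_switch %in% 0:2) stop("n_switch must be 0, 1 or 2")
  if (any(theta < 0 | theta >= 1)) stop("theta must lie in [0, 1)")
  if (H < 2) stop("H must be at least 2")
  switch(as.character(n_switch),
    "2" = theta^2 / H^2,
    "1" = (1 - theta) * theta / H + theta^2 / H^2,
    "0" = (1 - theta)^2 + 2 * (theta - theta^2) / H + theta^2 / H^2
  )
}

#' Per-haplotype transition factor
#'
#' The single-chromosome copying factor whose product over the two diploid
#' slots reproduces [state_transition_prob()] exactly: `(1 - theta) + theta/H`
#' when the template haplotype is retained, `theta/H` when it switches to any
#' particular other haplotype.  This factorisation is what makes the collapsed
#' forward update linear in the number of states.
#'
#' @inheritParams state_transition_prob
#' @param same logical; `TRUE` if the template haplotype is unchanged.
#' @return transition factor.
#' @export
haplotype_transition_prob <- function(theta, H, same) {
  if (any(theta < 0 | theta >= 1)) stop("theta must lie in [0, 1)")
  ifelse(same, (1 - theta) + theta / H, theta / H)
}

#' Genotype observation matrix
#'
#' The 3x3 column-stochastic matrix `P(observed genotype | implied genotype)`
#' of the copying-error model.  Rows index the observed genotype (0, 1, 2 alt
#' alleles), columns the genotype implied by the hidden state.  Each allele is
#' read correctly with probability `1 - epsilon` independently, hence e.g.
#' `P(1 | 1) = (1-eps)^2 + eps^2`.
#'
#' @param epsilon per-site error parameter in `[0, 0.5)`.
#' @return 3x3 numeric matrix with columns summing to 1.
#' @export
observation_matrix <- function(epsilon) {
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)")
  e <- epsilon
  matrix(c(
    (1 - e)^2,     (1 - e) * e,       e^2,
    2 * e * (1 - e), (1 - e)^2 + e^2, 2 * e * (1 - e),
    e^2,           (1 - e) * e,       (1 - e)^2
  ), nrow = 3, ncol = 3, byrow = TRUE)
}

#' Single observation probability
#'
#' @param g_obs observed genotype code (0, 1 or 2).
#' @param g_implied genotype implied by the hidden state (0, 1 or 2).
#' @param epsilon error parameter in `[0, 0.5)`.
#' @return `P(g_obs | g_implied)`.
#' @export
observation_prob <- function(g_obs, g_implied, epsilon) {
  if (!g_obs %in% 0:2 || !g_implied %in% 0:2) {
    stop("genotype codes must be 0, 1 or 2")
  }
  observation_matrix(epsilon)[g_obs + 1L, g_implied + 1L]
}

#' Genotype implied by a hidden state
#'
#' The hidden state is an ordered pair of reference-haplotype indices; the
#' genotype it implies at site `j` is the sum of the two template alleles.
#'
#' @param state integer pair `c(x1, x2)` of haplotype indices in `1..H`.
#' @param panel a [reference_panel] object.
#' @param j site index.
#' @return implied genotype in `{0, 1, 2}`.
#' @export
implied_genotype <- function(state, panel, j) {
  stopifnot(length(state) == 2L, all(state >= 1L), all(state <= panel$H))
  panel$haplotypes[state[1L], j] + panel$haplotypes[state[2L], j]
}

#' Likelihood-integrated emission weight
#'
#' The contribution of one site to the joint probability of hidden and
#' observed states when the observation is a genotype-likelihood triplet:
#' \eqn{\sum_{g=0}^{2} P(g \mid X_j)\, L_j(g)}.  With a uniform likelihood
#' row this is 1/3 for every state because the observation matrix is
#' column-stochastic, so unobserved sites carry no information.
#'
#' @param state integer pair `c(x1, x2)`.
#' @param likelihood_row numeric triplet `L(0), L(1), L(2)`.
#' @param epsilon error parameter.
#' @param panel a [reference_panel].
#' @param j site index.
#' @return non-negative emission weight.
#' @export
emission_weight <- function(state, likelihood_row, epsilon, panel, j) {
  g <- implied_genotype(state, panel, j)
  sum(observation_matrix(epsilon)[, g + 1L] * likelihood_row)
}

#' HMM parameters for a reference panel
#'
#' Assembles the per-interval switch probabilities `theta` and per-site error
#' parameters `epsilon` for a panel.  Genetic distances come from a genetic
#' map when one is supplied (linearly interpolated at the panel positions);
#' otherwise a constant recombination rate in cM/Mb is applied to the physical
#' positions.
#'
#' @param panel a [reference_panel].
#' @param map optional [genetic_map] object.
#' @param Ne effective-size constant used in [recombination_fraction()];
#'   default 11418.
#' @param epsilon error parameter, a scalar (recycled) or a length-`M` vector;
#'   default 0.01.  A per-site vector is the hook for damage-aware error
#'   models; none is shipped.
#' @param rate_cM_per_Mb constant recombination rate used when `map` is
#'   `NULL`; default 1.
#' @return an object of class `"hmm_parameters"`: list with `H`, `theta`
#'   (length `M`, entry `j` is the switch probability between sites `j-1` and
#'   `j`; entry 1 is `NA`), `epsilon` (length `M`), `Ne`, `cumulative_cM`.
#' @export
hmm_parameters <- function(panel, map = NULL, Ne = 11418, epsilon = 0.01,
                           rate_cM_per_Mb = 1) {
  M <- panel$M
  if (is.null(map)) {
    cM <- panel$positions * rate_cM_per_Mb / 1e6
  } else {
    cM <- interpolate_genetic_distance(map, panel$positions)
  }
  theta <- c(NA_real_,
             if (M > 1) recombination_fraction(diff(cM), Ne, panel$H))
  if (length(epsilon) == 1L) epsilon <- rep(epsilon, M)
  if (length(epsilon) != M) stop("epsilon must be scalar or length M")
  if (any(epsilon < 0 | epsilon >= 0.5)) stop("epsilon must lie in [0, 0.5)")
  structure(
    list(H = panel$H, theta = theta, epsilon = epsilon, Ne = Ne,
         cumulative_cM = cM),
    class = "hmm_parameters"
  )
}
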