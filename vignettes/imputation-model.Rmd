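---
title: "The diploid Li-Stephens imputation model in lshmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diploid Li-Stephens imputation model in lshmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lshmm)
```

## The model and its assumptions

`lshmm` treats a diploid sample as an imperfect mosaic of a phased reference
panel. With `H` reference haplotypes over `M` biallelic SNPs, the hidden
state at site `j` is the ordered pair `X_j = (x1, x2)` of template
haplotypes copied by the sample's two chromosomes. The chain assumes:

* **Markov copying.** Template choice changes only through recombination
  between adjacent sites. Each chromosome slot independently keeps its
  template with probability `(1 - θ_j) + θ_j/H` and switches to any given
  other one with probability `θ_j/H`. The product of the two per-slot
  factors reproduces the three diploid transition cases (0, 1 or 2
  switches) exactly — this factorisation is what the collapsed `O(H²)`
  update exploits, and the test suite checks the equivalence against the
  dense `H² × H²` matrix product to 1e-12.
* **Site-independent emission given the state.** The observation at a site
  is a genotype-likelihood triplet `Y_j = [L(0), L(1), L(2)]`, produced
  upstream by a caller from the raw reads. The latent true genotype `g` is
  tied to the state through a symmetric error model with parameter `ε_j`
  (each allele read correctly with probability `1 - ε_j`), and the
  emission weight integrates it out: `Σ_g P(g | X_j) L_j(g)`. Because the
  error matrix is column-stochastic, a uniform triplet contributes the same
  weight to every state — unobserved sites carry no information, they are
  smoothed over by linkage.
* **Uniform start.** `P(X_1) = 1/H²`. Nothing in the data argues for a
  non-uniform prior over templates at the left edge.
* **Exact alignment.** Target sites are matched to the panel on
  (chromosome, position, ref, alt). Allele-swapped or strand-flipped
  records are dropped and counted, never reconciled; reconciliation is
  error-prone and out of scope.

The sample's phase is never an input: the state space itself carries it, so
imputation integrates over the unknown phase. Posterior genotype
probabilities (GP), dosage `DS = GP(1) + 2 GP(2)` and a phased haplotype
pair (the per-site maximum-posterior state's alleles) are read off the
forward-backward state posteriors.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `Ne` | 11418 | — | effective-size constant in `θ_j = 1 - exp(-4 Ne d_j / H)`; the HapMap-era value used by a long line of copying-model software. Exposed, never hard-coded. |
| `epsilon` | 0.01 | — | per-site copying/genotyping error. Constant by default; a per-site vector is accepted as the hook for damage-aware models (none shipped). `ε = 0` is permitted for tests but degenerate: contradictory one-hot likelihoods then zero out whole sites, which the engine reports as a hard error naming the site. |
| `rate_cM_per_Mb` | 1 | cM/Mb | fallback constant recombination rate when no genetic map is supplied. |
| `checkpoint`, `k1`, `k2` | `full`; `⌈√M⌉`; `⌈M^(2/3)⌉, ⌈M^(1/3)⌉` | sites | memory/compute trade (see below). |
| `gp_mode` | `"posterior"` | — | whether GP keeps the local likelihood term (see below). |
| `coverage`, `delta` | —, 0.001 | ×, per-base | simulator: per-site read probability and sequencing error. 0.001 is Illumina-like; the value is a free parameter of the simulated world, not an estimate. |

Genetic distances come from a genetic map (3-column HapMap or 4-column
PLINK dialect, autodetected) linearly interpolated at the panel positions;
positions beyond the map ends extrapolate at the nearest flanking
interval's rate. The exact interpolation scheme is a package choice — maps
are dense relative to panels, so the choice is numerically immaterial, but
it is stated here because it is a choice.

## Two GP conventions

"Integrating the hidden states out of the posterior" admits two readings,
and both are implemented:

* `gp_mode = "posterior"` (default): the true posterior of the latent
  genotype, `GP(g) ∝ Σ_X P(X | Y) · P(g | X) L(g) / Σ_g' P(g' | X) L(g')`.
  This is the quantity a downstream caller wants: it conditions on all the
  data, including the site's own reads.
* `gp_mode = "predictive"`: the panel-only predictive
  `Σ_X P(X | Y) P(g | X)`, which ignores the local likelihood term at the
  reported site. Useful for diagnosing how much the panel alone supports a
  call.

The default is the full posterior because discarding observed local reads
from the reported genotype probability is hard to defend; the alternative
is kept behind the flag for comparison.

## Numerical choices

* **Scaling, not log-space.** The collapsed transition update is a linear
  operation; running it in log-space would destroy the rank-one structure.
  The classic per-site remedy is used instead: every forward (and backward)
  vector is rescaled to sum 1 and the log scale factors are accumulated;
  their sum is the data log-likelihood. Likelihood rows are additionally
  stored rescaled to maximum 1 — the model is invariant to per-row scale,
  so this is pure hygiene (it shifts the log-likelihood by the log of the
  scale and nothing else, which the tests verify).
* **Checkpointing.** `full` stores all `M` forward vectors. `one_level`
  stores every `k1`-th and recomputes each block once during the backward
  sweep (~2× forward work, `O(M/k1 + k1)` vectors). `two_level` stores
  level-1 checkpoints, regenerates level-2 checkpoints inside the active
  block, then regenerates each sub-block (~3× forward work,
  `O(M/k1 + k1/k2 + k2)` vectors). Because recomputation repeats the exact
  same floating-point operations, all three modes agree bit-for-bit in
  practice; the tests require 1e-10 including block sizes that do not
  divide `M`. The two-level defaults `k1 = ⌈M^(2/3)⌉, k2 = ⌈M^(1/3)⌉` are
  the two-level memory optimum; `one_level` defaults to its own optimum
  `k1 = ⌈√M⌉`.
* **Tie-breaking.** Argmax over states (phasing) takes the smallest linear
  state index; argmax over genotypes (hard calls, concordance) takes the
  lower genotype code. Both are arbitrary but deterministic and tested.
* **VCF rounding.** Written GP values are rounded to 3 decimals and the
  rounding residual (a single 0.001 unit at most) is added to the entry it
  distorts least so the written triplet sums to exactly 1. A written
  triplet can therefore sit up to ~1e-3 from the in-memory GP — rounding
  alone bounds each entry at 5e-4, and the sum constraint can stack one
  more unit on one entry.
* **Uniform GL emission.** Unobserved sites are written to GL-field VCFs as
  the literal `0.3333,0.3333,0.3333` (the convention of the low-coverage
  simulation literature) even though GL is log10-scaled. This is
  self-consistent here: the reader rescales each row to maximum 1, so any
  constant triplet reads back as exactly uniform.

## What the synthetic world does and does not emulate

`make_synthetic_panel()` builds founder haplotypes with allele frequencies
kept above `maf_floor` (default 0.05), derives the panel as recombinant
mosaics of the founders (per-interval switch probability 0.01, sites every
1 kb, ~20 switches over 2000 sites — segments of realistic LD scale), and
derives held-out diploid targets as fresh mosaics of the panel haplotypes.
Targets are therefore imputable but never panel members, mirroring a
leave-out evaluation design. The read simulator implements exactly the
stated thinning model: Bernoulli(`c`) per-site sampling, one read per
sampled site, per-base error `delta`, GATK-style single-read likelihoods,
uniform triplets elsewhere.

What this world does **not** contain: population structure or panel-sample
divergence (targets are mosaics of the panel itself, the best case for the
copying model); multi-read pileups or coverage above 1×; indels,
multi-allelic sites, or genotyping artefacts; post-mortem deamination
damage or any position-dependent error. A green recovery test therefore
establishes that the inference machinery is correct and that accuracy
responds to coverage as it must — it does not certify accuracy on real
(ancient) data, where panel mismatch and damage dominate.

## Known limitations

* Per-site maximum-posterior phasing can produce switch-inconsistent
  haplotype pairs across sites; this is the behaviour of per-site argmax
  decoding, reproduced as defined rather than patched with a joint
  (Viterbi-style) path.
* One sample, one region per run; looping over samples and windowed
  chromosome chunking live in user scripts.
* `residuals()` is deliberately not provided on the fit object: the input
  is a likelihood triplet per site, so there is no observed response on a
  residual scale. `simulate()` draws genotypes from the per-site GP rows
  independently and does not resample linkage.
* The error model is symmetric and site-constant by default; a damage-aware
  asymmetric `ε_j` vector is accepted but no damage estimator ships.
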