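#' Two-locus haplotype state
#'
#' Frequencies of the four enhancer/gene haplotypes `E2A`, `E2a`, `E1A`,
#' `E1a` in an infinite population.  `E2` is the focal enhancer allele whose
#' frequency `p` is tracked; `a` is the deleterious gene allele.  The linkage
#' disequilibrium `D_EA = x_E2A * x_E1a - x_E2a * x_E1A` is positive when the
#' focal enhancer is over-represented on wild-type backgrounds.
#'
#' @param x_E2A,x_E2a,x_E1A,x_E1a Haplotype frequencies (non-negative,
#'   summing to 1 within `1e-12`; renormalized).
#' @return An object of class `"two_locus_state"`: a named numeric vector of
#'   length 4.
#' @seealso [state_from_freqs()], [state_freqs()]
#' @export
two_locus_state <- function(x_E2A, x_E2a, x_E1A, x_E1a) {
  x <- c(E2A = x_E2A, E2a = x_E2a, E1A = x_E1A, E1a = x_E1a)
  if (any(!is.finite(x)) || any(x < -1e-12))
    stop("haplotype frequencies must be finite and non-negative",
         call. = FALSE)
  x[x < 0] <- 0
  tot <- sum(x)
  if (abs(tot - 1) > 1e-6)
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  x <- x / tot
  class(x) <- "two_locus_state"
  x
}

#' Build a two-locus state from allele frequencies and disequilibrium
#'
#' @param p Frequency of the focal enhancer allele `E2`.
#' @param p_a Frequency of the deleterious gene allele.
#' @param D_EA Linkage disequilibrium (positive when `E2A`/`E1a` are
#'   over-represented); default 0 (linkage equilibrium).
#' @return A [two_locus_state()].
#' @export
state_from_freqs <- function(p, p_a, D_EA = 0) {
  q <- 1 - p
  pA <- 1 - p_a
  two_locus_state(p * pA + D_EA, p * p_a - D_EA,
                  q * pA - D_EA, q * p_a + D_EA)
}

#' Derived frequencies of a two-locus state
#'
#' @param state A [two_locus_state()].
#' @return List with `p` (focal enhancer frequency), `q = 1 - p`, `p_a`
#'   (deleterious allele frequency) and `D_EA`.
#' @export
state_freqs <- function(state) {
  x <- unclass(state)
  p <- x[["E2A"]] + x[["E2a"]]
  list(p = p, q = 1 - p,
       p_a = x[["E2a"]] + x[["E1a"]],
       D_EA = x[["E2A"]] * x[["E1a"]] - x[["E2a"]] * x[["E1A"]])
}

#' @export
print.two_locus_state <- function(x, ...) {
  f <- state_freqs(x)
  cat("two-locus state: ")
  cat(paste(sprintf("%s = %.6g", names(unclass(x)), unclass(x)),
            collapse = ", "), "\n")
  cat(sprintf("  p = %.6g, p_a = %.6g, D_EA = %.3e\n", f$p, f$p_a, f$D_EA))
  invisible(x)
}

# internal: 4x4 diploid fitness matrix for haplotypes (E2A, E2a, E1A, E1a)
hap_fitness_matrix <- function(e1, e2, h, s) {
  wg <- c(1, 1 - s, 1, 1 - s)        # gene allele fitness per haplotype
  eh <- c(e2, e2, e1, e1)            # enhancer strength per haplotype
  outer(1:4, 1:4, function(i, j)
    genotype_fitness(wg[i], wg[j], eh[i], eh[j], h))
}

# recombinant haplotype index: enhancer from row haplotype, gene from column
.rec_index <- outer(c(0, 0, 2, 2), c(1, 2, 1, 2), `+`)
.rec_masks <- lapply(1:4, function(k) .rec_index == k)

# internal one-generation kernel on a bare frequency 4-vector; W is the
# cached fitness matrix from hap_fitness_matrix()
step_core <- function(x, W, r, u) {
  G <- outer(x, x) * W
  wbar <- sum(G)
  if (wbar <= 0)
    stop("degenerate state: zero population mean fitness", call. = FALSE)
  G <- G / wbar
  g <- (1 - r) * rowSums(G) +
    r * vapply(.rec_masks, function(m) sum(G[m]), numeric(1))
  gm <- c(g[1] * (1 - u), g[2] + g[1] * u, g[3] * (1 - u), g[4] + g[3] * u)
  gm <- pmax(gm, 0)
  gm / sum(gm)
}

#' One exact generation of the deterministic two-locus recursion
#'
#' Applies one generation of the life cycle - diploid selection, meiosis with
#' recombination at rate `r`, one-way gene mutation A -> a at rate `u_gene`
#' per allele copy, and syngamy (random union of gametes) - to a haplotype
#' frequency vector in an infinite population.  Diploid fitnesses come from
#' [genotype_fitness()] with enhancer strengths `e1` (resident `E1`) and `e2`
#' (focal `E2`).
#'
#' @param state A [two_locus_state()].
#' @param e1,e2 Strengths of enhancer alleles `E1` and `E2`.
#' @param params A [model_params()]; uses `s_mean`, `h`, `u_gene`, `r`.
#' @return The next-generation [two_locus_state()].
#' @export
step_exact <- function(state, e1, e2, params) {
  x <- as.numeric(unclass(state))
  W <- hap_fitness_matrix(e1, e2, params$h, params$s_mean)
  gm <- step_core(x, W, params$r, params$u_gene)
  two_locus_state(gm[1], gm[2], gm[3], gm[4])
}

#' Iterate the exact recursion, optionally recording the trajectory
#'
#' @inheritParams step_exact
#' @param n_gen Number of generations to iterate.
#' @param record If `TRUE`, return a data frame with one row per generation
#'   (columns `generation`, `p`, `p_a`, `D_EA`, `mean_fitness`); otherwise
#'   return the final state.
#' @return A [two_locus_state()] or a data frame.
#' @export
iterate_exact <- function(state, e1, e2, params, n_gen, record = FALSE) {
  x <- as.numeric(unclass(state))
  W <- hap_fitness_matrix(e1, e2, params$h, params$s_mean)
  r <- params$r
  u <- params$u_gene
  if (record) {
    out <- matrix(NA_real_, nrow = n_gen + 1, ncol = 5,
                  dimnames = list(NULL, c("generation", "p", "p_a", "D_EA",
                                          "mean_fitness")))
    for (t in 0:n_gen) {
      out[t + 1, ] <- c(t, x[1] + x[2], x[2] + x[4],
                        x[1] * x[4] - x[2] * x[3], sum(outer(x, x) * W))
      if (t < n_gen) x <- step_core(x, W, r, u)
    }
    return(as.data.frame(out))
  }
  for (t in seq_len(n_gen)) x <- step_core(x, W, r, u)
  two_locus_state(x[1], x[2], x[3], x[4])
}

#' Population mean fitness of a two-locus state
#'
#' Mean fitness of the diploid population formed by random union of the
#' state's haplotypes.  With no variation at the enhancer locus and the gene
#' locus at mutation-selection balance this is `1 - 2u` to leading order;
#' while both enhancer alleles segregate (and before the deleterious
#' frequency re-equilibrates to the elevated mean dominance) it is lower.
#'
#' @inheritParams step_exact
#' @return Mean fitness, a scalar in (0, 1].
#' @export
state_mean_fitness <- function(state, e1, e2, params) {
  x <- as.numeric(unclass(state))
  W <- hap_fitness_matrix(e1, e2, params$h, params$s_mean)
  sum(outer(x, x) * W)
}

#' Linearized per-generation change in focal-enhancer frequency
#'
#' Leading-order decomposition of the change `Delta p` in the frequency of
#' the focal enhancer allele into a frequency-dependent "masking" term,
#' \deqn{-2\,\Delta h\, p_a\, p q (1-2p)\, s,}
#' which penalizes the rarer enhancer allele (rare alleles are over-exposed
#' in double heterozygotes, whose mean dominance is elevated), and a linkage
#' "purging" term,
#' \deqn{D_{EA}\,[\,4 h p q + (1-2p)(h_2 q - h_1 p)\,]\, s,}
#' which has the sign of `D_EA`: chromosomes carrying stronger enhancers are
#' more exposed to selection and hence purged of deleterious mutations,
#' building positive `D_EA` for the stronger allele.  The bracket is positive
#' for all `p` in [0, 1].
#'
#' @param state A [two_locus_state()] supplying `p`, `p_a` and `D_EA`.
#' @param e1,e2 Enhancer strengths of `E1` and the focal allele `E2`.
#' @param params A [model_params()]; uses `h` and `s_mean`.
#' @return List with `masking`, `purging` and `total` (their sum).
#' @export
delta_p_linearized <- function(state, e1, e2, params) {
  f <- state_freqs(state)
  dom <- dominance_focal(e1, e2, params$h)
  s <- params$s_mean
  masking <- -2 * dom$Delta_h * f$p_a * f$p * f$q * (1 - 2 * f$p) * s
  bracket <- 4 * params$h * f$p * f$q +
    (1 - 2 * f$p) * (dom$h2 * f$q - dom$h1 * f$p)
  purging <- f$D_EA * bracket * s
  list(masking = masking, purging = purging, total = masking + purging)
}

# internal: effective dominances labelled by focal allele E2 (strength e2),
# regardless of which allele is stronger: h2 = dominance of the deleterious
# gene allele when cis to E2, h1 when cis to E1.  delta_h = h2 - h1 is then
# negative for a weaker focal allele, while Delta_h >= 0 always.
dominance_focal <- function(e1, e2, h) {
  beta <- -log2(h)
  h1 <- (e1 / (e1 + e2))^beta
  h2 <- (e2 / (e1 + e2))^beta
  list(h1 = h1, h2 = h2, Delta_h = (h1 + h2) / 2 - h, delta_h = h2 - h1)
}

#' Quasi-linkage-equilibrium value of the enhancer-gene disequilibrium
#'
#' Under quasi-linkage equilibrium (disequilibrium equilibrates fast compared
#' with allele-frequency change, with selection and recombination terms both
#' retained so the expression stays finite as `r -> 0`):
#' \deqn{D_{EA}^{QLE} = \frac{p q p_a\,[\,2\Delta h (1-2p) + \delta h\,]\,s}
#'       {2\,(r + [\,h_1 p^2 + 2 p q h + h_2 q^2\,]\,s)}.}
#' The denominator is the per-generation relaxation rate of the
#' disequilibrium (recombination plus the effective selective decay), the
#' numerator the per-generation association built by selection on double
#' heterozygotes; both were re-derived from a symbolic leading-order
#' expansion of the exact recursion and verified against it numerically.
#' For a stronger focal enhancer (`e2 > e1`) this is positive whenever
#' `p_a > 0` and `0 < p < 1`.
#'
#' @inheritParams delta_p_linearized
#' @return The QLE disequilibrium `D_EA`.
#' @export
d_EA_qle <- function(state, e1, e2, params) {
  f <- state_freqs(state)
  dom <- dominance_focal(e1, e2, params$h)
  s <- params$s_mean
  denom <- 2 * (params$r +
    (dom$h1 * f$p^2 + 2 * f$p * f$q * params$h + dom$h2 * f$q^2) * s)
  if (denom == 0)
    stop("invalid parameter: r and s cannot both be zero", call. = FALSE)
  f$p * f$q * f$p_a * (2 * dom$Delta_h * (1 - 2 * f$p) + dom$delta_h) * s /
    denom
}

#' Mutation-selection equilibrium frequency of the deleterious allele
#'
#' With enhancer polymorphism the population mean dominance is
#' `hbar = h + 2 Delta_h p q`, so the equilibrium deleterious frequency
#' \deqn{p_a^{Eq} = u / (\bar h s)} is depressed below the monomorphic value
#' `u/(h s)` while the enhancer locus segregates.
#'
#' @param params A [model_params()]; uses `u_gene`, `h`, `s_mean`.
#' @param p Focal enhancer allele frequency.
#' @param e1,e2 Enhancer strengths.
#' @return Equilibrium frequency `p_a`.
#' @export
p_a_equilibrium <- function(params, p, e1, e2) {
  dom <- dominance_focal(e1, e2, params$h)
  hbar <- params$h + 2 * dom$Delta_h * p * (1 - p)
  if (hbar * params$s_mean == 0)
    stop("invalid parameter: hbar * s must be non-zero", call. = FALSE)
  params$u_gene / (hbar * params$s_mean)
}

#' Gradient of population mean fitness in enhancer frequency
#'
#' \deqn{\partial \bar W / \partial p = -4 \Delta h (D_{EA} + (1-2p) p_a) s.}
#' Negative for `p < 1/2` and positive for `p > 1/2` (when `D_EA` is small
#' relative to `(1-2p) p_a`): the spread of a new enhancer allele transiently
#' unmasks deleterious mutations and depresses mean fitness, which returns to
#' its boundary value once the enhancer locus is again monomorphic.
#'
#' @inheritParams delta_p_linearized
#' @return The derivative of mean fitness with respect to `p`.
#' @export
mean_fitness_gradient <- function(state, e1, e2, params) {
  f <- state_freqs(state)
  dom <- dominance_focal(e1, e2, params$h)
  -4 * dom$Delta_h * (f$D_EA + (1 - 2 * f$p) * f$p_a) * params$s_mean
}
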