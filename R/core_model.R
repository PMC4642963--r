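#' Fitness as a function of the fraction of defective proteins
#'
#' In a diploid whose gene locus carries one wild-type and one deleterious
#' allele, the share of defective protein depends on the relative strengths of
#' the two cis enhancers.  Fitness is a concave, monotonically decreasing
#' power function of that share,
#' \deqn{W = 1 - s \, f_a^{-\log(h)/\log(2)},}
#' chosen so that equal expression of both alleles (`f_a = 0.5`) recovers the
#' classical heterozygote fitness `1 - h s`, and so that the map is concave
#' whenever deleterious mutations are partially recessive (`h < 1/2`).
#'
#' @param f_a Fraction of defective proteins, in [0, 1].  Vectorized.
#' @param h Baseline dominance in (0, 1).
#' @param s Selection coefficient in [0, 1].
#' @return Fitness value(s) in `[1 - s, 1]`.
#' @examples
#' fitness_from_fraction(c(0, 0.5, 1), h = 0.25, s = 0.1)
#' @export
fitness_from_fraction <- function(f_a, h, s) {
  if (any(!is.finite(f_a)) || any(f_a < 0) || any(f_a > 1))
    stop("invalid parameter 'f_a': must lie in [0, 1]", call. = FALSE)
  if (length(h) != 1L || !is.finite(h) || h <= 0 || h >= 1)
    stop("invalid parameter 'h': must lie in (0, 1)", call. = FALSE)
  if (length(s) != 1L || !is.finite(s) || s < 0 || s > 1)
    stop("invalid parameter 's': must lie in [0, 1]", call. = FALSE)
  1 - s * f_a^(-log2(h))
}

#' Effective dominance under allele-specific expression
#'
#' With enhancer strengths `e1 <= e2` on the two homologs, the gene allele in
#' cis with the weaker (stronger) enhancer contributes a share
#' `e1/(e1+e2)` (`e2/(e1+e2)`) of the protein pool, so the effective dominance
#' of a deleterious allele depends on which enhancer it sits next to:
#' \deqn{h_1 = \left(\frac{e_1}{e_1+e_2}\right)^{-\log(h)/\log(2)}, \qquad
#'       h_2 = \left(\frac{e_2}{e_1+e_2}\right)^{-\log(h)/\log(2)}.}
#' By Jensen's inequality on the concave fitness map, enhancer polymorphism
#' raises mean dominance: `Delta_h = (h1 + h2)/2 - h >= 0`, with equality only
#' for `e1 = e2` or `h = 1/2` (the additive case).
#'
#' @param e1,e2 Enhancer strengths (> 0).  If `e1 > e2` they are swapped
#'   internally and `swapped = TRUE` is reported.
#' @param h Baseline dominance in (0, 1).
#' @return A list with `h1` (weaker-cis dominance), `h2` (stronger-cis
#'   dominance), `Delta_h = (h1+h2)/2 - h`, `delta_h = h2 - h1`, and
#'   `swapped`.
#' @examples
#' effective_dominances(1, 3, h = 0.25)
#' @export
effective_dominances <- function(e1, e2, h) {
  if (!is.finite(e1) || !is.finite(e2) || e1 <= 0 || e2 <= 0)
    stop("invalid parameter: enhancer strengths must be > 0", call. = FALSE)
  if (!is.finite(h) || h <= 0 || h >= 1)
    stop("invalid parameter 'h': must lie in (0, 1)", call. = FALSE)
  swapped <- e1 > e2
  if (swapped) { tmp <- e1; e1 <- e2; e2 <- tmp }
  beta <- -log2(h)
  h1 <- (e1 / (e1 + e2))^beta
  h2 <- (e2 / (e1 + e2))^beta
  list(h1 = h1, h2 = h2, Delta_h = (h1 + h2) / 2 - h, delta_h = h2 - h1,
       swapped = swapped)
}

#' Fitness of a diploid genotype at the gene locus
#'
#' Given the marginal fitness values `w_a`, `w_b` of the two gene alleles and
#' the strengths `e_a`, `e_b` of their cis enhancers, the genotype's fitness
#' is `w1 - h_i (w1 - w2)` with `w1 >= w2` the fitter/less fit allele and
#' `h_i = f_a^{-log(h)/log(2)}`, `f_a` being the expression share of the less
#' fit allele.  When the two alleles are equally fit the enhancers are
#' irrelevant and the result is `w1` (no dominance term is evaluated).
#'
#' All arguments are vectorized and recycled.
#'
#' @param w_a,w_b Allele fitness values in (0, 1].
#' @param e_a,e_b Strengths of the enhancers in cis with `w_a`, `w_b`.
#' @param h Baseline dominance in (0, 1).
#' @return Genotype fitness value(s).
#' @examples
#' # deleterious allele (w = 0.9) cis to a 3x-stronger enhancer:
#' genotype_fitness(1, 0.9, e_a = 1, e_b = 3, h = 0.25)
#' @export
genotype_fitness <- function(w_a, w_b, e_a, e_b, h) {
  if (any(w_a <= 0) || any(w_a > 1) || any(w_b <= 0) || any(w_b > 1))
    stop("invalid parameter: allele fitness must lie in (0, 1]", call. = FALSE)
  if (any(e_a <= 0) || any(e_b <= 0))
    stop("invalid parameter: enhancer strengths must be > 0", call. = FALSE)
  n <- max(length(w_a), length(w_b), length(e_a), length(e_b))
  w_a <- rep_len(w_a, n); w_b <- rep_len(w_b, n)
  e_a <- rep_len(e_a, n); e_b <- rep_len(e_b, n)
  w1 <- pmax(w_a, w_b)
  out <- w1
  het <- w_a != w_b
  if (any(het)) {
    w2 <- pmin(w_a, w_b)[het]
    e_del <- ifelse(w_a[het] < w_b[het], e_a[het], e_b[het])
    f_a <- e_del / (e_a[het] + e_b[het])
    out[het] <- w1[het] - f_a^(-log2(h)) * (w1[het] - w2)
  }
  out
}

#' Intensity of stabilizing selection on expression, scaled to the gene locus
#'
#' Models 2 and 3 scale the strength of stabilizing selection on (log) total
#' expression to the per-generation fitness loss caused by deleterious
#' mutations at the gene locus, `u h s`.  With scaling factor `gamma`, the
#' intensity `I` solves `1 - gamma u h s = exp(-4 I sigma_E^2)`:
#' \deqn{I = \frac{-\log(1 - \gamma u h s)}{4 \sigma_E^2}.}
#' One round of random regulatory mutation then costs about `gamma` times one
#' round of gene mutation.  `gamma = 0` gives `I = 0` (no stabilizing
#' selection).
#'
#' @param gamma Scaling factor (>= 0); requires `gamma * u_gene * h * s_mean < 1`.
#' @param u_gene Gene mutation rate per allele copy per generation.
#' @param h Baseline dominance.
#' @param s_mean Mean selection coefficient at the gene locus.
#' @param sigma_E Mutational SD on log regulator strength (> 0).
#' @return The intensity `I` (>= 0).
#' @examples
#' stabilizing_intensity(gamma = 1, u_gene = 1e-3, h = 0.25,
#'                       s_mean = 0.1, sigma_E = 0.1)
#' @export
stabilizing_intensity <- function(gamma, u_gene, h, s_mean, sigma_E) {
  if (!is.finite(gamma) || gamma < 0)
    stop("invalid parameter 'gamma': must be >= 0", call. = FALSE)
  if (!is.finite(sigma_E) || sigma_E <= 0)
    stop("invalid parameter 'sigma_E': must be > 0", call. = FALSE)
  arg <- 1 - gamma * u_gene * h * s_mean
  if (arg <= 0)
    stop("invalid parameter: gamma * u_gene * h * s_mean must be < 1",
         call. = FALSE)
  -log(arg) / (4 * sigma_E^2)
}

#' Gaussian stabilizing-selection fitness component on summed log strengths
#'
#' `Z1` and `Z2` are the sums of the two allelic log strengths at two
#' regulator loci.  In `"dosage"` mode (model 2) selection penalizes
#' imbalance between two enhancer loci, `W_E = exp(-I (Z1 - Z2)^2)`; in
#' `"absolute"` mode (model 3) the TF log strength `Z2` must oppose the
#' enhancer log strength `Z1` to keep total expression at its optimum,
#' `W_E = exp(-I (Z1 + Z2)^2)`.
#'
#' @param Z1,Z2 Summed log strengths (vectorized).
#' @param I Stabilizing-selection intensity (>= 0).
#' @param mode `"dosage"` or `"absolute"`.
#' @return Fitness component(s) in (0, 1].
#' @export
stabilizing_fitness <- function(Z1, Z2, I, mode = c("dosage", "absolute")) {
  mode <- match.arg(mode)
  if (!is.finite(I) || I < 0)
    stop("invalid parameter 'I': must be >= 0", call. = FALSE)
  d <- if (mode == "dosage") Z1 - Z2 else Z1 + Z2
  exp(-I * d^2)
}
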