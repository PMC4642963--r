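#' Run fixation trials for a mutant enhancer allele
#'
#' Individual-based Wright-Fisher protocol (model 1, two-allele): each trial
#' starts from a population monomorphic for the wild-type gene allele and the
#' resident enhancer, runs a 2000-generation burn-in of the life cycle
#' (diploid selection by rejection sampling, meiosis with recombination at
#' rate `r`, Poisson(`2 N u`) gene mutation, syngamy) during which the
#' enhancer locus does not mutate, so the gene locus settles near its
#' mutation-selection balance `u/(h s)`.  One chromosome is then chosen at
#' random and given a new enhancer allele of strength `strength_ratio` times
#' the resident's (keeping its gene allele), and the life cycle is iterated
#' until the mutant enhancer is fixed or lost.
#'
#' Trial `k` uses its own deterministic RNG stream derived from
#' `params$seed`, so results are reproducible and independent of how trials
#' are batched.
#'
#' @param params A [model_params()]; uses `N_pop`, `s_mean`, `h`, `u_gene`,
#'   `r`, `p_self`, `seed`.
#' @param strength_ratio Mutant strength / resident strength (> 0).
#' @param n_trials Number of independent trials.
#' @param burnin Burn-in generations before the mutant is introduced
#'   (default 2000).
#' @param max_gen Hard cap on post-introduction generations per trial
#'   (liveness guard; unreachable at moderate population sizes).
#' @return Data frame with one row per trial: `trial`, `outcome`
#'   (`"fixed"`/`"lost"`) and `generations` elapsed after introduction; the
#'   parameters and strength ratio are echoed as attributes.
#' @export
run_fixation_trials <- function(params, strength_ratio, n_trials,
                                burnin = 2000, max_gen = 1e6) {
  validate_params(params)
  if (strength_ratio <= 0)
    stop("invalid parameter 'strength_ratio': must be > 0", call. = FALSE)
  if (n_trials < 1)
    stop("invalid parameter 'n_trials': must be >= 1", call. = FALSE)
  res <- cpp_fixation_trials(as.integer(n_trials), params$N_pop,
                             params$s_mean, params$h, params$u_gene,
                             params$r, strength_ratio, params$p_self,
                             as.integer(burnin), max_gen,
                             as.double(params$seed))
  out <- data.frame(trial = seq_len(n_trials),
                    outcome = ifelse(res$outcome == 1, "fixed", "lost"),
                    generations = res$generations)
  attr(out, "params") <- params
  attr(out, "strength_ratio") <- strength_ratio
  out
}

#' Estimate a fixation probability and its ratio to neutral
#'
#' Runs [run_fixation_trials()] and summarizes: the fixation probability
#' `p_fix` with a Wilson 95\% confidence interval, and the fold change
#' relative to the neutral fixation probability `1/(2 N_pop)` of a mutant of
#' unchanged strength, i.e. `ratio_to_neutral = 2 N_pop p_fix`.
#'
#' @inheritParams run_fixation_trials
#' @param n_trials Number of trials (>= 100).
#' @return List with `p_fix`, `ci` (Wilson 95\% CI on `p_fix`),
#'   `ratio_to_neutral`, `ratio_ci`, `n_fixed` and `n_trials`.
#' @export
estimate_fixation_probability <- function(params, strength_ratio, n_trials,
                                          burnin = 2000) {
  if (n_trials < 100)
    stop("invalid parameter 'n_trials': need at least 100 trials",
         call. = FALSE)
  trials <- run_fixation_trials(params, strength_ratio, n_trials, burnin)
  k <- sum(trials$outcome == "fixed")
  ci <- wilson_ci(k, n_trials)
  twoN <- 2 * params$N_pop
  list(p_fix = k / n_trials, ci = ci,
       ratio_to_neutral = twoN * k / n_trials, ratio_ci = twoN * ci,
       n_fixed = k, n_trials = n_trials)
}

# internal: Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Long-term escalation run (infinite-allele models 1-4)
#'
#' Individual-based simulation of open-ended enhancer-strength evolution.
#' All regulator alleles start at log strength `z = 0` (strength 1; in model
#' 3 the TF locus also starts at 0, so total log expression starts at its
#' optimum).  Each generation applies the life cycle with infinite-allele
#' mutation kernels: gene-allele fitness is multiplied by `1 - s_i` with
#' `s_i ~ Exponential(mean = s_mean)` truncated below 1 (or replaced by
#' `1 - s_i` with `mutation_kernel = "replace"`), and enhancer/TF log
#' strengths receive Normal(0, `sigma_E^2`) increments.  Fitness is composed
#' per model: gene fitness only (models 1 and 4, the latter with selfing
#' probability `p_self`); the product of two enhancer/gene pairs and a
#' Gaussian dosage-balance component `exp(-I (Z1 - Z2)^2)` (model 2); or gene
#' fitness times an absolute-expression component `exp(-I (Z1 + Z2)^2)` with
#' a coevolving TF locus (model 3).  The stabilizing intensity `I` is derived
#' from `params$gamma` via [stabilizing_intensity()].
#'
#' Replicate `j` uses the deterministic seed stream `params$seed + j`.
#'
#' @param params A [model_params()].
#' @param model Model id: 1 (constant total expression), 2 (gene-dosage
#'   stabilizing selection), 3 (enhancer-TF coevolution), 4 (partial
#'   selfing).
#' @param record_every Sampling interval in generations (default 100).
#' @param mutation_kernel How gene mutations act on allele fitness:
#'   `"multiplicative"` (default) or `"replace"`.
#' @return Data frame in long format: `iteration`, `generation`, `mean_z`
#'   (population mean log strength at the focal enhancer locus) and
#'   `mean_z2` (second enhancer locus in model 2, TF locus in model 3; `NA`
#'   otherwise).
#' @examples
#' \donttest{
#' pars <- model_params(N_pop = 200, n_gen = 2000, n_iter = 2)
#' traj <- run_escalation(pars, model = 1)
#' }
#' @export
run_escalation <- function(params, model = 1, record_every = 100,
                           mutation_kernel = c("multiplicative", "replace")) {
  validate_params(params)
  mutation_kernel <- match.arg(mutation_kernel)
  if (!model %in% 1:4)
    stop("invalid parameter 'model': must be 1, 2, 3 or 4", call. = FALSE)
  I <- stabilizing_intensity(params$gamma, params$u_gene, params$h,
                             params$s_mean, params$sigma_E)
  p_self <- if (model == 4) params$p_self else 0
  out <- vector("list", params$n_iter)
  for (j in seq_len(params$n_iter)) {
    m <- cpp_escalation(as.integer(model), params$N_pop, params$s_mean,
                        params$h, params$u_gene, params$u_enh, params$u_tf,
                        params$r, params$sigma_E, I, p_self,
                        params$n_gen, as.integer(record_every),
                        as.double(params$seed + j),
                        mutation_kernel == "replace")
    out[[j]] <- data.frame(iteration = j, generation = m[, "generation"],
                           mean_z = m[, "mean_z"], mean_z2 = m[, "mean_z2"])
  }
  do.call(rbind, out)
}

#' Low-level two-allele trajectory (testing and diagnostics)
#'
#' Runs the bi-allelic two-locus engine for a fixed number of generations
#' from a configurable initial population and records allele frequencies and
#' mean fitness.  Useful for checking neutral drift properties, selfing
#' genotype ratios and the mutation-selection balance of the gene locus.
#'
#' @param params A [model_params()].
#' @param e1,e2 Enhancer strengths of the resident and focal alleles.
#' @param n_gen Generations to run.
#' @param record_every Sampling interval.
#' @param init `"monomorphic"` (all wild type, resident enhancer),
#'   `"random"` (haplotypes drawn independently with the given frequencies)
#'   or `"het_gene"` (every individual heterozygous Aa at the gene locus).
#' @param init_p_enh,init_p_a Initial allele frequencies for `init = "random"`.
#' @return List with `trajectory` (data frame: `generation`, `p_enh`, `p_a`,
#'   `mean_fitness`) and `genotype_counts` (final AA/Aa/aa counts).
#' @export
simulate_two_locus <- function(params, e1 = 1, e2 = 1, n_gen = 1000,
                               record_every = 10,
                               init = c("monomorphic", "random", "het_gene"),
                               init_p_enh = 0, init_p_a = 0) {
  validate_params(params)
  init <- match.arg(init)
  res <- cpp_two_allele_run(params$N_pop, params$s_mean, params$h,
                            params$u_gene, params$r, e1, e2, params$p_self,
                            as.integer(n_gen), as.integer(record_every),
                            as.double(params$seed), init_p_enh, init_p_a,
                            init)
  list(trajectory = as.data.frame(res$trajectory),
       genotype_counts = res$genotype_counts)
}
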