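#' Model parameters for enhancer-runaway models
#'
#' Bundles every rate, size and intensity parameter used by the deterministic
#' recursions, the diffusion approximation and the individual-based simulators
#' (models 1-4).  Defaults are the reference conditions used throughout:
#' partially recessive deleterious mutations (`h = 0.25`, the typical value for
#' mildly deleterious mutations), selection `s = 0.1`, per-copy mutation rates
#' `1e-3` at gene and enhancer loci, tight enhancer-gene linkage (`r = 1e-6`).
#'
#' @param s_mean Selection coefficient against deleterious gene alleles
#'   (dimensionless).  In the infinite-allele simulators this is the mean of
#'   the exponential distribution of mutational fitness effects.
#' @param h Baseline dominance of deleterious gene alleles, in (0, 1).
#' @param u_gene Gene mutation rate per allele copy per generation.
#' @param u_enh Enhancer mutation rate per allele copy per generation.
#' @param u_tf Transcription-factor mutation rate per allele copy per
#'   generation (model 3 only).
#' @param r Recombination rate between an enhancer and its cis gene, per
#'   meiosis, in [0, 0.5].
#' @param r_TE Recombination rate between the TF locus (or second
#'   enhancer-gene pair) and the focal pair.  Fixed at 0.5: independent
#'   chromosomes.
#' @param N_pop Diploid population size.
#' @param sigma_E Standard deviation of mutational increments on log enhancer
#'   (and TF) strength.
#' @param gamma Scaling factor for the intensity of stabilizing selection on
#'   expression, relative to the per-generation mutational fitness loss at the
#'   gene locus (models 2 and 3).
#' @param p_self Selfing probability: chance that an individual's second
#'   gamete is drawn from the same parent as the first (model 4).
#' @param n_gen Generations per simulation run.
#' @param n_iter Independent replicate runs.
#' @param seed Integer master seed; replicate `j` uses the derived stream
#'   `seed + j`.
#'
#' @return An object of class `"model_params"` (a validated named list).
#' @examples
#' p <- model_params(s_mean = 0.01, N_pop = 1e4)
#' p$s_mean
#' @export
model_params <- function(s_mean = 0.1, h = 0.25, u_gene = 1e-3, u_enh = 1e-3,
                         u_tf = 1e-3, r = 1e-6, r_TE = 0.5, N_pop = 1000,
                         sigma_E = 0.1, gamma = 0, p_self = 0,
                         n_gen = 10000, n_iter = 10, seed = 1L) {
  p <- list(s_mean = s_mean, h = h, u_gene = u_gene, u_enh = u_enh,
            u_tf = u_tf, r = r, r_TE = r_TE, N_pop = as.integer(N_pop),
            sigma_E = sigma_E, gamma = gamma, p_self = p_self,
            n_gen = as.integer(n_gen), n_iter = as.integer(n_iter),
            seed = as.integer(seed))
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a model_params object
#'
#' Checks the parameter invariants: `0 < h < 1`, `0 < s_mean <= 1`, all
#' mutation rates non-negative, `0 <= r <= 0.5`, `0 <= p_self <= 1`,
#' `sigma_E > 0`, `N_pop >= 2`, `gamma >= 0` and
#' `gamma * u_gene * h * s_mean < 1` (so the stabilizing intensity is
#' defined).  Errors name the offending parameter.
#'
#' @param p A `model_params` object (or plain list with the same fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  chk <- function(ok, key, msg) {
    if (!isTRUE(ok)) stop("invalid parameter '", key, "': ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (key in c("s_mean", "h", "u_gene", "u_enh", "u_tf", "r", "r_TE",
                "sigma_E", "gamma", "p_self")) {
    chk(num1(p[[key]]), key, "must be a single finite numeric value")
  }
  chk(p$h > 0 && p$h < 1, "h", "dominance must lie strictly in (0, 1)")
  chk(p$s_mean > 0 && p$s_mean <= 1, "s_mean", "must lie in (0, 1]")
  chk(p$u_gene >= 0, "u_gene", "mutation rate must be >= 0")
  chk(p$u_enh >= 0, "u_enh", "mutation rate must be >= 0")
  chk(p$u_tf >= 0, "u_tf", "mutation rate must be >= 0")
  chk(p$r >= 0 && p$r <= 0.5, "r", "recombination rate must lie in [0, 0.5]")
  chk(p$r_TE >= 0 && p$r_TE <= 0.5, "r_TE", "must lie in [0, 0.5]")
  chk(p$p_self >= 0 && p$p_self <= 1, "p_self", "must lie in [0, 1]")
  chk(p$sigma_E > 0, "sigma_E", "mutational SD must be > 0")
  chk(is.numeric(p$N_pop) && p$N_pop >= 2, "N_pop", "need at least 2 diploids")
  chk(p$gamma >= 0, "gamma", "must be >= 0")
  chk(p$gamma * p$u_gene * p$h * p$s_mean < 1, "gamma",
      "gamma * u_gene * h * s_mean must be < 1")
  chk(is.numeric(p$n_gen) && p$n_gen >= 1, "n_gen", "must be >= 1")
  chk(is.numeric(p$n_iter) && p$n_iter >= 1, "n_iter", "must be >= 1")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Enhancer-runaway model parameters\n")
  cat(sprintf("  gene locus:     s_mean = %g, h = %g, u_gene = %g\n",
              x$s_mean, x$h, x$u_gene))
  cat(sprintf("  regulators:     u_enh = %g, u_tf = %g, sigma_E = %g\n",
              x$u_enh, x$u_tf, x$sigma_E))
  cat(sprintf("  linkage:        r = %g, r_TE = %g\n", x$r, x$r_TE))
  cat(sprintf("  population:     N_pop = %d, p_self = %g\n",
              x$N_pop, x$p_self))
  cat(sprintf("  stabilizing:    gamma = %g\n", x$gamma))
  cat(sprintf("  run:            n_gen = %d, n_iter = %d, seed = %d\n",
              x$n_gen, x$n_iter, x$seed))
  invisible(x)
}

# internal: coerce a list of overrides into a model_params object
params_from_list <- function(lst) {
  known <- names(formals(model_params))
  unknown <- setdiff(names(lst), known)
  if (length(unknown) > 0)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_params, lst)
}
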