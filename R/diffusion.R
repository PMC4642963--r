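#' Deterministic drift on a mutant enhancer at quasi-stationarity
#'
#' Per-generation expected frequency change of a mutant enhancer allele with
#' strength `strength_ratio` times the resident's, with the deleterious-allele
#' frequency slaved to its mutation-selection equilibrium
#' ([p_a_equilibrium()]) and the linkage disequilibrium to its
#' quasi-linkage-equilibrium value ([d_EA_qle()]) at each `p`.  This is the
#' drift coefficient used by [fixation_probability()].
#'
#' @param p Mutant enhancer frequency (vectorized, in (0, 1); the analytic
#'   limit is used at 0 and 1).
#' @param params A [model_params()].
#' @param strength_ratio Mutant strength / resident strength (> 0).
#' @return Expected `Delta p` per generation at each `p`.
#' @export
drift_coefficient <- function(p, params, strength_ratio) {
  p * (1 - p) * drift_over_pq(p, params, strength_ratio)
}

# internal: Delta_p / (p q), which has finite limits at p = 0 and 1 because
# both the masking and purging terms carry a p q factor.  Vectorized in p.
drift_over_pq <- function(p, params, strength_ratio) {
  if (strength_ratio <= 0)
    stop("invalid parameter 'strength_ratio': must be > 0", call. = FALSE)
  e1 <- 1
  e2 <- strength_ratio
  dom <- dominance_focal(e1, e2, params$h)
  s <- params$s_mean
  q <- 1 - p
  hbar <- params$h + 2 * dom$Delta_h * p * q
  p_a <- params$u_gene / (hbar * s)
  masking_pq <- -2 * dom$Delta_h * p_a * (1 - 2 * p) * s
  denom <- 2 * (params$r +
    (dom$h1 * p^2 + 2 * p * q * params$h + dom$h2 * q^2) * s)
  d_pq <- p_a * (2 * dom$Delta_h * (1 - 2 * p) + dom$delta_h) * s / denom
  bracket <- 4 * params$h * p * q + (1 - 2 * p) * (dom$h2 * q - dom$h1 * p)
  masking_pq + d_pq * bracket * s
}

#' Fixation probability of a mutant enhancer (diffusion approximation)
#'
#' Sojourn-integral solution of the diffusion with frequency-dependent drift
#' [drift_coefficient()] and Wright-Fisher variance `p q / (2 N)`:
#' \deqn{U(p_0) = \frac{\int_0^{p_0} \psi(p)\,dp}{\int_0^1 \psi(p)\,dp},
#'       \qquad \psi(p) = \exp\left(-\int_0^p
#'       \frac{4 N_{pop}\, \Delta p}{p q}\, dp\right).}
#' The inner integral is accumulated on a uniform grid by the trapezoid rule
#' and exponentiated in log space (shifted by its minimum) to avoid overflow;
#' its integrand has removable singularities at the boundaries, evaluated by
#' their analytic limits.  The lower reference point of the inner integral is
#' 0; any other choice cancels in the ratio.  The numerator for a small
#' initial frequency `p0` (typically `1/(2N)`) is computed on a dedicated
#' fine sub-grid of `[0, p0]`.
#'
#' For a neutral mutant (`strength_ratio = 1`) the drift vanishes and
#' `U(p0) = p0`.
#'
#' @param p0 Initial mutant frequency in (0, 1).
#' @param params A [model_params()].
#' @param strength_ratio Mutant strength / resident strength.
#' @param n_grid Number of grid intervals on [0, 1] (>= 1000).
#' @return The fixation probability `U(p0)`.
#' @examples
#' pars <- model_params(s_mean = 0.01, N_pop = 1e3, r = 1e-6)
#' 2 * pars$N_pop * fixation_probability(1 / (2 * pars$N_pop), pars, 3)
#' @export
fixation_probability <- function(p0, params, strength_ratio, n_grid = 1e4) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("invalid parameter 'p0': must lie in (0, 1)", call. = FALSE)
  if (n_grid < 1000)
    stop("invalid parameter 'n_grid': need at least 1000 intervals",
         call. = FALSE)
  fourN <- 4 * params$N_pop
  grid <- seq(0, 1, length.out = n_grid + 1)
  g <- fourN * drift_over_pq(grid, params, strength_ratio)
  M <- cumtrapz(grid, g)                       # inner integral from 0
  # fine sub-grid for the numerator on [0, p0]
  sub <- seq(0, p0, length.out = 257)
  gsub <- fourN * drift_over_pq(sub, params, strength_ratio)
  Msub <- cumtrapz(sub, gsub)
  shift <- min(M, Msub)
  psi <- exp(-(M - shift))
  psi_sub <- exp(-(Msub - shift))
  if (any(!is.finite(psi)) || any(!is.finite(psi_sub)))
    stop("numeric-range error: exp overflow in the sojourn density even ",
         "after log-space shifting; reduce N_pop or the drift magnitude",
         call. = FALSE)
  num <- trapz(sub, psi_sub)
  den <- trapz(grid, psi)
  num / den
}

#' Fixation-probability ratio curve against recombination rate
#'
#' For each recombination rate, the fixation probability of a new mutant
#' enhancer starting from one copy (`p0 = 1/(2 N_pop)`) is divided by the
#' neutral value `1/(2 N_pop)`, giving the fold change relative to a neutral
#' mutation.  For stronger mutants the curve decreases with `r` and crosses 1
#' at a critical recombination distance beyond which the masking cost
#' outweighs the purging benefit.
#'
#' @param params A [model_params()] (its `r` field is ignored here).
#' @param strength_ratio Mutant strength / resident strength.
#' @param r_values Recombination rates in [0, 0.5].
#' @param n_grid Grid intervals passed to [fixation_probability()].
#' @return Data frame with columns `r` and `ratio_to_neutral`.
#' @export
fixation_ratio_curve <- function(params, strength_ratio, r_values,
                                 n_grid = 1e4) {
  if (any(r_values < 0) || any(r_values > 0.5))
    stop("invalid parameter 'r_values': must lie in [0, 0.5]", call. = FALSE)
  p0 <- 1 / (2 * params$N_pop)
  ratios <- vapply(r_values, function(rv) {
    pr <- params
    pr$r <- rv
    2 * params$N_pop * fixation_probability(p0, pr, strength_ratio, n_grid)
  }, numeric(1))
  data.frame(r = r_values, ratio_to_neutral = ratios)
}

# internal trapezoid helpers (uniform or non-uniform grids)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}
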