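#' Mean log enhancer strength across replicates
#'
#' Averages the population mean log strength over replicate runs at each
#' sampled generation:
#' \deqn{\bar z(t) = \frac{1}{N_{it}} \sum_j \frac{1}{N_{pop}} \sum_i
#'       \frac{z_1(i,j,t) + z_2(i,j,t)}{2}.}
#' The per-replicate population averages are those recorded by
#' [run_escalation()] (`mean_z` is already the mean of `(z1 + z2)/2` over
#' individuals).
#'
#' @param traj Long-format trajectory data frame with columns `iteration`,
#'   `generation`, `mean_z` (as returned by [run_escalation()]).  All
#'   replicates must share the same sampled generations.
#' @return Data frame with columns `generation` and `z_bar`.
#' @export
mean_log_strength <- function(traj) {
  need <- c("iteration", "generation", "mean_z")
  if (!all(need %in% names(traj)))
    stop("trajectory must have columns iteration, generation, mean_z",
         call. = FALSE)
  counts <- table(traj$iteration)
  if (length(unique(counts)) != 1L)
    stop("shape error: replicate series have unequal lengths", call. = FALSE)
  gens <- sort(unique(traj$generation))
  per_rep <- split(traj, traj$iteration)
  for (rep in per_rep) {
    if (!identical(sort(rep$generation), gens))
      stop("shape error: replicates sample different generations",
           call. = FALSE)
  }
  z_bar <- tapply(traj$mean_z, traj$generation, mean)
  data.frame(generation = as.numeric(names(z_bar)), z_bar = as.numeric(z_bar),
             row.names = NULL)
}

#' Doubling time of mean enhancer strength
#'
#' Fits an ordinary least-squares regression of mean log strength on
#' generation over all sampled points and converts the slope `a` into the
#' doubling time \deqn{T_{\times 2} = \log(2)/a,} the expected number of
#' generations for mean enhancer strength to double on the geometric scale
#' (log strength starts at 0, so a gain of log 2 doubles the strength).
#' When the slope is not positive the doubling time is undefined and
#' reported as `NA`.
#'
#' @param series Data frame with columns `generation` and `z_bar` (as from
#'   [mean_log_strength()]), or a numeric vector of `z_bar` values with
#'   `generation` supplied separately.
#' @param generation Sampled generations, if `series` is a bare numeric
#'   vector.
#' @return An object of class `"trajectory_summary"`: list with `slope`,
#'   `doubling_time`, `r_squared`, `n_points`.
#' @examples
#' doubling_time(data.frame(generation = 0:10 * 100,
#'                          z_bar = 1e-5 * 0:10 * 100))
#' @export
doubling_time <- function(series, generation = NULL) {
  if (is.data.frame(series)) {
    if (!all(c("generation", "z_bar") %in% names(series)))
      stop("series must have columns generation and z_bar", call. = FALSE)
    t <- series$generation
    z <- series$z_bar
  } else {
    z <- as.numeric(series)
    t <- generation
    if (is.null(t)) stop("generation must be supplied", call. = FALSE)
  }
  if (length(z) < 3)
    stop("invalid input: need at least 3 time points", call. = FALSE)
  if (stats::var(t) == 0)
    stop("invalid input: zero variance in generation", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, t), z)
  a <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((z - mean(z))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out <- list(slope = a,
              doubling_time = if (a > 0) log(2) / a else NA_real_,
              r_squared = r2, n_points = length(z))
  class(out) <- "trajectory_summary"
  out
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("Escalation trajectory summary\n")
  cat(sprintf("  slope:         %.4g per generation\n", x$slope))
  if (is.na(x$doubling_time)) {
    cat("  doubling time: undefined (slope <= 0)\n")
  } else {
    cat(sprintf("  doubling time: %.4g generations\n", x$doubling_time))
  }
  cat(sprintf("  R^2:           %.4f  (n = %d points)\n",
              x$r_squared, x$n_points))
  invisible(x)
}

#' Per-replicate escalation slopes
#'
#' OLS slope of the population mean log strength on generation, one per
#' replicate.  Used for resampling tests of escalation-rate orderings, where
#' comparing slopes avoids the undefined doubling times of replicates whose
#' slope happens to be non-positive.
#'
#' @param traj Long-format trajectory (see [mean_log_strength()]).
#' @return Named numeric vector of slopes, one per iteration.
#' @export
replicate_slopes <- function(traj) {
  vapply(split(traj, traj$iteration), function(d) {
    unname(stats::lm.fit(cbind(1, d$generation), d$mean_z)$coefficients[2])
  }, numeric(1))
}

#' One-sided permutation test for a trend across groups
#'
#' Tests whether `y` decreases (or increases) with the group variable `x`
#' using the OLS slope of `y` on `x` as the statistic and permuting group
#' labels.  With two groups this reduces to a permutation test on the
#' difference of means.
#'
#' @param y Response values (e.g. per-replicate escalation slopes).
#' @param x Numeric group variable (e.g. `gamma`, `p_self`, `sigma_E`).
#' @param alternative `"decreasing"` (slope of `y` on `x` < 0) or
#'   `"increasing"`.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return List with `statistic` (observed slope) and `p_value`.
#' @export
resample_trend_test <- function(y, x, alternative = c("decreasing",
                                                      "increasing"),
                                n_perm = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  if (length(y) != length(x))
    stop("y and x must have the same length", call. = FALSE)
  slope_of <- function(yy) {
    xc <- x - mean(x)
    sum(xc * yy) / sum(xc^2)
  }
  obs <- slope_of(y)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) slope_of(sample(y)), numeric(1))
  p <- if (alternative == "decreasing") {
    (1 + sum(perm <= obs)) / (n_perm + 1)
  } else {
    (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  list(statistic = obs, p_value = p)
}

# internal: save/restore the global RNG state so test helpers do not disturb
# user-level reproducibility
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
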