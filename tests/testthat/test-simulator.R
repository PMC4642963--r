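test_that("seeded runs are bit-reproducible", {
  pars <- ref_params(N_pop = 200, seed = 9L)
  a <- run_fixation_trials(pars, 3, n_trials = 50, burnin = 100)
  b <- run_fixation_trials(pars, 3, n_trials = 50, burnin = 100)
  expect_identical(a, b)
  pe <- ref_params(N_pop = 100, n_gen = 500, n_iter = 2, seed = 4L)
  expect_identical(run_escalation(pe, model = 2), run_escalation(pe, model = 2))
  # a different seed gives a different realization
  pars2 <- ref_params(N_pop = 200, seed = 10L)
  c <- run_fixation_trials(pars2, 3, n_trials = 50, burnin = 100)
  expect_false(identical(a$generations, c$generations))
})

test_that("engine RNG kernels have the documented distributions", {
  z <- enhancerun:::cpp_rng_draws("normal", 20000, 0.1, 123)
  expect_lt(abs(mean(z)), 5 * 0.1 / sqrt(20000))
  expect_equal(stats::sd(z), 0.1, tolerance = 0.01)
  expect_gt(stats::ks.test(z, stats::pnorm, sd = 0.1)$p.value, 1e-4)
  k <- enhancerun:::cpp_rng_draws("poisson", 20000, 2, 52)
  expect_equal(mean(k), 2, tolerance = 3 * sqrt(2 / 20000))
  s <- enhancerun:::cpp_rng_draws("exponential", 20000, 0.1, 7)
  expect_equal(mean(s), 0.1, tolerance = 5 / sqrt(20000))
  expect_gt(stats::ks.test(s, stats::pexp, rate = 10)$p.value, 1e-4)
  st <- enhancerun:::cpp_rng_draws("exp_trunc1", 20000, 0.1, 7)
  expect_true(all(st < 1))
  u <- enhancerun:::cpp_rng_draws("unif", 20000, 0, 99)
  expect_true(all(u >= 0 & u < 1))
  expect_equal(mean(u), 0.5, tolerance = 0.01)
})

test_that("neutral drift loses heterozygosity at rate 1/(2N)", {
  # all-Aa start, no selection, no mutation: E[2 p q] decays by
  # (1 - 1/(2N)) per generation
  N <- 50
  t_end <- 30
  set.seed(1)
  het <- replicate(200, {
    pars <- model_params(s_mean = 1e-9, u_gene = 0, N_pop = N,
                         seed = sample.int(1e6, 1))
    tr <- simulate_two_locus(pars, n_gen = t_end, record_every = t_end,
                             init = "het_gene")$trajectory
    p <- tr$p_a[2]
    2 * p * (1 - p)
  })
  expected <- 0.5 * (1 - 1 / (2 * N))^t_end
  se <- stats::sd(het) / sqrt(length(het))
  expect_equal(mean(het), expected, tolerance = 3.5 * se / expected)
})

test_that("full selfing of heterozygotes yields 1:2:1 offspring genotypes", {
  pars <- model_params(s_mean = 1e-9, u_gene = 0, N_pop = 4000, p_self = 1,
                       seed = 31L)
  res <- simulate_two_locus(pars, n_gen = 1, record_every = 1,
                            init = "het_gene")
  counts <- res$genotype_counts
  expect_equal(sum(counts), 4000)
  p <- c(0.25, 0.5, 0.25)
  se <- sqrt(p * (1 - p) * 4000)
  for (i in 1:3) {
    expect_equal(counts[[i]], 4000 * p[i], tolerance = 4 * se[i] / (4000 * p[i]))
  }
  # chi-square against the Mendelian ratio does not reject
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 1e-4)
})

test_that("gene locus settles near mutation-selection balance u/(hs)", {
  pa <- vapply(1:6, function(j) {
    pars <- ref_params(seed = 100L + j)
    tr <- simulate_two_locus(pars, n_gen = 2000, record_every = 100)$trajectory
    mean(tr$p_a[tr$generation >= 1000])
  }, numeric(1))
  expect_equal(mean(pa), 0.04, tolerance = 0.2)
})

test_that("neutral fixation probability equals the initial frequency", {
  pars <- model_params(s_mean = 1e-9, u_gene = 0, N_pop = 100, seed = 77L)
  est <- estimate_fixation_probability(pars, 1, n_trials = 4000, burnin = 20)
  # one copy among 2N = 200: P(fix) = 1/200
  expect_true(est$ci[1] <= 1 / 200 && 1 / 200 <= est$ci[2])
  # Wilson interval is proper
  expect_true(est$ci[1] >= 0 && est$ci[2] <= 1 && est$ci[1] < est$ci[2])
})

test_that("escalation is inert without enhancer mutation", {
  pars <- ref_params(u_enh = 0, N_pop = 100, n_gen = 300, n_iter = 2)
  traj <- run_escalation(pars, model = 1)
  expect_equal(max(abs(traj$mean_z)), 0)
  expect_true(all(is.na(traj$mean_z2)))
})

# second-locus (enhancer 2 or TF) replicate-averaged mean log strength
second_locus_zbar <- function(traj) {
  agg <- tapply(traj$mean_z2, traj$generation, mean)
  as.numeric(agg)[order(as.numeric(names(agg)))]
}

test_that("mean log strength escalates under the runaway conditions", {
  # a mutation-rich regime makes the runaway resolvable above drift noise
  # within a short run: N u_E = 10, tight linkage, recessive deleterious load
  pars <- ref_params(N_pop = 2000, u_enh = 5e-3, n_gen = 20000, n_iter = 3,
                     seed = 8L)
  traj <- run_escalation(pars, model = 1)
  sl <- replicate_slopes(traj)
  expect_true(all(sl > 0))
  s <- doubling_time(mean_log_strength(traj))
  expect_gt(s$slope, 2e-5)
  expect_gt(tail(mean_log_strength(traj)$z_bar, 1), 0.5)
  expect_false(is.na(s$doubling_time))
})

test_that("model 2 holds dosage balance while both enhancer loci escalate", {
  run <- function(gam) {
    pars <- ref_params(N_pop = 1000, u_enh = 5e-3, n_gen = 15000, n_iter = 2,
                       gamma = gam, seed = 14L)
    traj <- run_escalation(pars, model = 2)
    list(z1 = mean_log_strength(traj)$z_bar, z2 = second_locus_zbar(traj))
  }
  off <- run(0)
  on <- run(10)
  gap <- function(x) stats::sd(2 * (x$z1 - x$z2))   # Z1 - Z2 spread
  # stabilizing selection pins the dosage gap well below its free wander
  expect_lt(gap(on), 0.5 * gap(off))
  # ... while both loci still escalate in parallel
  expect_gt(tail(on$z1, 1), 0.3)
  expect_gt(tail(on$z2, 1), 0.3)
})

test_that("model 3 TF strength compensates total expression", {
  run <- function(gam) {
    pars <- ref_params(N_pop = 1000, u_enh = 5e-3, u_tf = 5e-3,
                       n_gen = 15000, n_iter = 2, gamma = gam, seed = 14L)
    traj <- run_escalation(pars, model = 3)
    list(z1 = mean_log_strength(traj)$z_bar, zt = second_locus_zbar(traj))
  }
  off <- run(0)
  on <- run(10)
  tot <- function(x) 2 * (x$z1 + x$zt)   # Z1 + Z2, optimum at 0
  # enhancer-TF coevolution keeps total log expression near its optimum,
  # far more tightly than the gamma = 0 free walk
  expect_lt(stats::sd(tot(on)), 0.5 * stats::sd(tot(off)))
  expect_lt(max(abs(tot(on))), 0.5)
})

test_that("invalid simulator inputs are rejected", {
  pars <- ref_params()
  expect_error(run_fixation_trials(pars, -1, 10), "strength_ratio")
  expect_error(run_fixation_trials(pars, 3, 0), "n_trials")
  expect_error(estimate_fixation_probability(pars, 3, 50), "n_trials")
  expect_error(run_escalation(pars, model = 5), "model")
})
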