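test_that("two-locus state bookkeeping round-trips frequencies", {
  st <- state_from_freqs(0.3, 0.05, 0.002)
  f <- state_freqs(st)
  expect_equal(f$p, 0.3)
  expect_equal(f$p_a, 0.05)
  expect_equal(f$D_EA, 0.002)
  expect_error(two_locus_state(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(two_locus_state(-0.1, 0.6, 0.3, 0.2), "non-negative")
})

test_that("monomorphic wild type without mutation is a fixed point", {
  pars <- ref_params(u_gene = 0)
  st <- two_locus_state(0, 0, 1, 0)
  st1 <- step_exact(st, 1, 3, pars)
  expect_equal(as.numeric(unclass(st1)), c(0, 0, 1, 0))
})

test_that("the enhancer locus is neutral when strengths are equal", {
  pars <- ref_params()
  st <- state_from_freqs(0.37, 0.04, 0)
  tr <- iterate_exact(st, 1, 1, pars, 500, record = TRUE)
  expect_equal(max(abs(tr$p - 0.37)), 0, tolerance = 1e-12)
})

test_that("gene locus converges to mutation-selection balance", {
  pars <- ref_params()  # s = 0.1, h = 0.25, u = 1e-3 -> u/(hs) = 0.04
  st <- two_locus_state(0, 0, 1, 0)  # enhancer fixed for E1
  st <- iterate_exact(st, 1, 3, pars, 5000)
  pa_hat <- state_freqs(st)$p_a
  # independent one-locus oracle: Hardy-Weinberg genotypes, viability
  # selection 1 : 1-hs : 1-s, per-copy one-way mutation
  pa <- 0.5
  for (i in 1:5000) {
    q <- 1 - pa
    geno <- c(q^2, 2 * q * pa, pa^2) * c(1, 1 - 0.025, 1 - 0.1)
    pa_s <- (geno[2] / 2 + geno[3]) / sum(geno)
    pa <- pa_s + (1 - pa_s) * 1e-3
  }
  expect_equal(pa_hat, pa, tolerance = 1e-9)
  # u/(hs) is the leading-order value; the exact equilibrium sits a few
  # percent below it at these parameters
  expect_equal(pa_hat, 0.04, tolerance = 0.08)
  # same at the other enhancer boundary
  st2 <- iterate_exact(two_locus_state(1, 0, 0, 0), 1, 3, pars, 5000)
  expect_equal(state_freqs(st2)$p_a, pa_hat, tolerance = 1e-9)
})

test_that("linearized frequency change matches its closed form", {
  pars <- ref_params()
  # p = 0.5 kills the masking term
  st <- state_from_freqs(0.5, 0.04, 0)
  expect_equal(delta_p_linearized(st, 1, 3, pars)$masking, 0)
  # direct evaluation at p = 0.25, D = 0 (3x ratio: Delta_h = 0.0625)
  st <- state_from_freqs(0.25, 0.04, 0)
  lin <- delta_p_linearized(st, 1, 3, pars)
  expect_equal(lin$masking, -2 * 0.0625 * 0.04 * 0.25 * 0.75 * 0.5 * 0.1)
  expect_equal(lin$purging, 0)
  # a rare stronger enhancer with no disequilibrium is disfavored
  st <- state_from_freqs(1e-4, 0.04, 0)
  expect_lt(delta_p_linearized(st, 1, 3, pars)$total, 0)
})

test_that("masking term flips sign at p = 1/2; purging follows D_EA", {
  pars <- ref_params()
  for (p in c(0.05, 0.2, 0.45)) {
    st <- state_from_freqs(p, 0.04, 0)
    expect_lt(delta_p_linearized(st, 1, 3, pars)$masking, 0)
    st <- state_from_freqs(1 - p, 0.04, 0)
    expect_gt(delta_p_linearized(st, 1, 3, pars)$masking, 0)
  }
  for (D in c(-1e-3, 1e-3)) {
    st <- state_from_freqs(0.3, 0.04, D)
    expect_equal(sign(delta_p_linearized(st, 1, 3, pars)$purging), sign(D))
  }
})

test_that("the purging bracket is positive across the frequency range", {
  # positivity holds over the study's parameter domain (partial recessivity
  # h in [0.15, 0.5), strength contrasts up to 3x); far outside it (very
  # small h with large contrasts) the bracket can change sign
  pars <- ref_params()
  set.seed(11)
  for (i in 1:200) {
    p <- stats::runif(1)
    h <- stats::runif(1, 0.15, 0.49)
    e2 <- stats::runif(1, 1.01, 3)
    prs <- ref_params(h = h)
    dom <- effective_dominances(1, e2, h)
    bracket <- 4 * h * p * (1 - p) +
      (1 - 2 * p) * (dom$h2 * (1 - p) - dom$h1 * p)
    expect_gt(bracket, 0)
    # equivalently, purging has exactly the sign of D_EA
    st <- state_from_freqs(p, 0.02, 1e-4 * min(p, 1 - p))
    expect_gte(delta_p_linearized(st, 1, e2, prs)$purging, 0)
  }
})

test_that("QLE disequilibrium: zeros, closed form and positivity", {
  pars <- ref_params()
  # no deleterious variation, or no enhancer contrast -> D = 0
  expect_equal(d_EA_qle(state_from_freqs(0.5, 0, 0), 1, 3, pars), 0)
  expect_equal(d_EA_qle(state_from_freqs(0.5, 0.04, 0), 1, 1, pars), 0)
  # direct evaluation at p = q = 1/2, 3x ratio, r = 0: the numerator is
  # pq pa delta_h s = 5e-4 and the relaxation rate 2(r + 0.28125 s)
  pars0 <- ref_params(r = 0)
  D <- d_EA_qle(state_from_freqs(0.5, 0.04, 0), 1, 3, pars0)
  expect_equal(D, 5e-4 / (2 * 0.028125))
  # positivity for stronger focal enhancers over a randomized grid
  set.seed(5)
  for (i in 1:200) {
    st <- state_from_freqs(stats::runif(1, 0.01, 0.99),
                           stats::runif(1, 1e-4, 0.1), 0)
    prs <- ref_params(h = stats::runif(1, 0.05, 0.49),
                      r = stats::runif(1, 0, 0.5))
    expect_gt(d_EA_qle(st, 1, exp(stats::runif(1, 0.05, 2)), prs), 0)
  }
  expect_error(d_EA_qle(state_from_freqs(0.5, 0.04, 0), 1, 3,
                        ref_params(r = 0, s_mean = 1e-300)), NA)
})

test_that("QLE disequilibrium tracks the exact recursion", {
  # the closed form should match the relaxed disequilibrium of the full
  # recursion in its asymptotic regime, and stay close at reference values
  pars <- ref_params(s_mean = 0.01, u_gene = 1e-6, r = 1e-3)
  st <- relax_state(0.5, 1, 3, pars, n = 3000)
  f <- state_freqs(st)
  expect_equal(d_EA_qle(st, 1, 3, pars), f$D_EA, tolerance = 0.15)
  pars2 <- ref_params()  # s = 0.1, u = 1e-3, r = 1e-6
  st2 <- relax_state(0.5, 1, 3, pars2, n = 400)
  expect_equal(d_EA_qle(st2, 1, 3, pars2), state_freqs(st2)$D_EA,
               tolerance = 0.15)
})

test_that("equilibrium deleterious frequency uses mean dominance", {
  pars <- ref_params()
  expect_equal(p_a_equilibrium(pars, 0, 1, 3), 0.04)     # u/(hs)
  expect_equal(p_a_equilibrium(pars, 0.7, 1, 1), 0.04)   # Delta_h = 0
  # 3x ratio at p = 1/2: hbar = 0.25 + 2 * 0.0625 * 0.25 = 0.28125
  expect_equal(p_a_equilibrium(pars, 0.5, 1, 3), 1e-3 / 0.028125)
  # decreasing in Delta_h * p * q
  pa <- vapply(c(0, 0.1, 0.3, 0.5), function(p)
    p_a_equilibrium(pars, p, 1, 3), numeric(1))
  expect_true(all(diff(pa) < 0))
})

test_that("mean-fitness gradient matches Delta_h-weighted form", {
  pars <- ref_params()
  expect_equal(mean_fitness_gradient(state_from_freqs(0.5, 0.04, 0),
                                     1, 3, pars), 0)
  expect_equal(mean_fitness_gradient(state_from_freqs(0.3, 0.04, 0),
                                     1, 1, pars), 0)
  expect_equal(mean_fitness_gradient(state_from_freqs(0.25, 0.04, 0),
                                     1, 3, pars),
               -4 * 0.0625 * 0.5 * 0.04 * 0.1)
})

test_that("linearized drift agrees with the exact recursion oracle", {
  # small-parameter regime: weak selection, rare mutation, loose-ish linkage,
  # small strength contrast; disequilibrium relaxed to quasi-stationarity
  for (ratio in c(1.1, 1 / 1.1)) {
    pars <- ref_params(s_mean = 0.01, u_gene = 1e-5, r = 1e-3)
    st <- relax_state(0.5, 1, ratio, pars, n = 2500)
    f <- state_freqs(st)
    dp_exact <- state_freqs(step_exact(st, 1, ratio, pars))$p - f$p
    st_qle <- state_from_freqs(f$p, f$p_a, d_EA_qle(st, 1, ratio, pars))
    dp_lin <- delta_p_linearized(st_qle, 1, ratio, pars)$total
    expect_equal(dp_lin, dp_exact, tolerance = 0.15)
    expect_equal(sign(dp_lin), sign(dp_exact))
  }
})

test_that("enhancer polymorphism depresses mean fitness below 1 - 2u", {
  # an enhancer that has just risen in frequency unmasks deleterious
  # mutations before their frequency can fall to the new, lower equilibrium:
  # at fixed p_a = u/(hs), mean fitness dips below its boundary value 1 - 2u
  # at intermediate p and is back at ~1 - 2u once either allele is fixed
  pars <- ref_params()
  boundary <- 1 - 2 * pars$u_gene
  pa0 <- pars$u_gene / (pars$h * pars$s_mean)
  wbar <- vapply(seq(0, 1, by = 0.05), function(p)
    state_mean_fitness(state_from_freqs(p, pa0, 0), 1, 3, pars), numeric(1))
  expect_equal(wbar[1], boundary, tolerance = 3e-4)
  expect_equal(wbar[length(wbar)], boundary, tolerance = 3e-4)
  expect_lt(min(wbar), boundary - 1e-4)
  expect_equal(which.min(wbar), 11L)  # deepest at p = 1/2
  # the gradient form agrees in sign with finite differences of the profile
  grad <- vapply(seq(0.05, 0.95, by = 0.05), function(p)
    mean_fitness_gradient(state_from_freqs(p, pa0, 0), 1, 3, pars),
    numeric(1))
  expect_true(all(sign(grad[1:9]) == -1) && all(sign(grad[11:19]) == 1))
})

test_that("a stronger tightly linked enhancer sweeps to fixation", {
  pars <- ref_params()
  st <- state_from_freqs(0.01, 0.04, 0)
  tr <- iterate_exact(st, 1, 3, pars, 40000, record = TRUE)
  expect_gt(tail(tr$p, 1), 0.999)
  # monotone increase through the interior of the sweep
  expect_gt(min(diff(tr$p[tr$p > 0.05 & tr$p < 0.95])), 0)
})
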