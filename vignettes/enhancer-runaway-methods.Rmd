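---
title: "Enhancer runaway: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer runaway: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerun)
```

## The phenomenon

In diploids, the two homologous copies of a gene are driven by their own cis
enhancers.  If the enhancer alleles differ in strength $e_1 < e_2$, the copy
in cis with the stronger allele contributes a share $e_2/(e_1+e_2) > 1/2$ of
the protein pool.  When the gene segregates a partially recessive deleterious
allele, this allele-specific expression changes the allele's *effective*
dominance: it is unmasked when cis to the stronger enhancer and hidden when
cis to the weaker one.  Two selective consequences follow.

* **Masking** (frequency-dependent): a rare enhancer allele of either
  strength is mostly found in enhancer heterozygotes, whose mean dominance
  exceeds $h$, so rare alleles pay an unmasking cost.  This term is
  conservative; it opposes any new enhancer allele.
* **Purging** (linkage-driven): chromosomes carrying the stronger enhancer
  expose their gene copy to selection more strongly and are purged of
  deleterious mutations more efficiently.  The stronger allele therefore
  accumulates positive linkage disequilibrium with wild-type gene backgrounds
  and hitchhikes with them.

Close to the gene the purging benefit wins and enhancer strength escalates
open-endedly — a runaway that raises no individual's fitness at its end
point: dominance is $h$ before the sweep and $h$ after.

## Fitness model

The map from the fraction $f_a$ of defective protein to fitness is the
concave power law
$$W = 1 - s\,f_a^{-\log_2 h},$$
the canonical one-parameter family that passes through the three anchor
points $W(0)=1$, $W(1/2)=1-hs$, $W(1)=1-s$ and is concave exactly when
$h<1/2$ (deleterious mutations partially recessive; the default $h=0.25$ is
the empirically typical value).  `fitness_from_fraction()` implements it;
`effective_dominances()` gives the induced cis dominances
$h_{1,2} = (e_{1,2}/(e_1+e_2))^{-\log_2 h}$, whose mean always exceeds $h$
(Jensen).  The map is treated as canonical; no alternative concave families
are provided, since every qualitative result only uses monotonicity and
concavity.

## Deterministic two-locus theory

`step_exact()` implements the full haplotype recursion for the life cycle
*selection → meiosis (recombination $r$) → one-way gene mutation $u$ →
syngamy* in an infinite population, using the standard construction
(genotypes as gamete products, post-selection gamete extraction with
recombination applied to double heterozygotes).  `delta_p_linearized()` carries the leading-order
masking + purging decomposition, `p_a_equilibrium()` the mutation–selection
balance $u/(\bar h s)$ with $\bar h = h + 2\,\Delta h\,pq$, and `d_EA_qle()`
the quasi-linkage-equilibrium disequilibrium
$$D_{EA}^{QLE} = \frac{pq\,p_a [\,2\Delta h(1-2p) + \delta h\,]\,s}
{2\,(r + [\,h_1 p^2 + 2pqh + h_2 q^2\,]\,s)}.$$
This closed form was re-derived here from a symbolic leading-order expansion
of the exact recursion (keeping both the $rD$ and $sD$ decay terms so it
stays finite as $r\to 0$) and is verified in the test suite against the
relaxed disequilibrium of `step_exact()`; the drift it produces matches the
exact per-generation $\Delta p$ to a fraction of a percent at the reference
parameters.

Two structural facts the tests make explicit, because they are easy to
over-read from the linearized theory:

* The exact mutation–selection equilibrium lies a few percent *below*
  $u/(hs)$ (0.0372 vs 0.04 at $s=0.1,h=0.25,u=10^{-3}$); $u/(\bar h s)$ is a
  leading-order value.
* The mean-fitness burden of a sweeping enhancer ("dips below $1-2u$") is a
  statement at *fixed* deleterious frequency — the burden before $p_a$
  re-equilibrates.  In the exact recursion the sweep is about two orders of
  magnitude slower than the $p_a$ relaxation, so no dip appears along the
  trajectory; the package tests the static profile
  $\bar W(p)\,|\,p_a = u/(hs)$, which dips at $p=1/2$ and returns to
  $\approx 1-2u$ at the boundaries, and the sign structure of the gradient
  $\partial\bar W/\partial p = -4\Delta h(D_{EA} + (1-2p)p_a)s$.
* The bracket of the purging term is positive throughout the study's domain
  ($h \ge 0.15$, contrasts up to threefold — verified numerically on a
  grid); for very small $h$ combined with large contrasts it can change
  sign, so the property is asserted on that domain rather than globally.

## Fixation probabilities

`fixation_probability()` evaluates the sojourn-integral solution
$$U(p_0) = \frac{\int_0^{p_0}\psi}{\int_0^1\psi},\qquad
\psi(p) = \exp\!\Big(-\!\int_0^p \frac{4N\,\Delta p}{pq}\,dp\Big),$$
with the drift slaved to quasi-stationarity: $p_a$ from the
mutation–selection balance and $D_{EA}$ from the QLE form at each $p$.  The
integrand $4N\Delta p/pq$ has finite boundary limits (both drift terms carry
$pq$); the inner integral is accumulated by the trapezoid rule on a uniform
grid ($10^4$ intervals by default; doubling it moves $U$ by $<0.1\%$),
exponentiated in log space after shifting by the running minimum so that
$\psi$ never overflows, and the numerator for the usual $p_0 = 1/(2N)$ is
computed on a dedicated fine sub-grid of $[0, p_0]$.  The lower bound of the
inner integral is 0; any other reference point cancels in the ratio.
"Tightly linked" is operationalized as $r=10^{-6}$ throughout, the value the
escalation simulations use.

A limitation worth stating plainly: at tight linkage the slaved drift is
*independent of $s$* (every $s$ cancels against $p_a = u/(\bar h s)$), so the
analytic ratio at $r=10^{-6}$ is the same for $s=0.01$ and $s=0.1$.  The
$s$-dependence seen in stochastic simulations — ours give
$2.33\ [1.68, 3.24]$ at $s=0.01$ and $4.60\ [3.64, 5.82]$ at $s=0.1$ for a
3× mutant at $N_{pop}u=1$ (30000 trials each) — is a finite-$p_a$
fluctuation effect ($p_a = u/hs = 0.4$ at $s=0.01$) that no leading-order
drift captures.  A drift slaved to the exact recursion's quasi-stationary
manifold was evaluated during development; it restores some $s$-dependence
but systematically under-predicts the simulated probabilities, so the
transparent closed-form closure was kept as the package's analytic route and
the Wright–Fisher engine as the arbiter.

## The Wright–Fisher engine

`run_fixation_trials()` and `run_escalation()` drive a C++ individual-based
engine.  Each generation: parents are drawn by rejection sampling (a uniform
candidate is accepted with probability equal to its fitness — fitness is
therefore kept in $[0,1]$, clamping the multi-component products), each
parent contributes one gamete with within-pair recombination $r$ and free
recombination between chromosome pairs and the TF locus, mutation counts are
Poisson with mean $2N_{pop}u$ per locus and land on uniformly chosen allele
copies (with replacement — Poisson-thinning semantics), and the $N_{pop}$
offspring replace their parents.  Under partial selfing the second gamete
comes from the *same* already-accepted parent with probability $p_s$; the
parent is not re-selected.  While the enhancer locus is monomorphic (the
fixation-trial burn-in) an algebraically equivalent gene-locus-only kernel
is used for speed.

Infinite-allele kernels: enhancer and TF alleles carry $z=\log e$ and mutate
by $z \mapsto z+\varepsilon$, $\varepsilon\sim N(0,\sigma_E^2)$ — additive
on the log so that relative mutational variance does not vanish as strengths
grow and strengths stay positive by construction.  Gene alleles carry a
fitness value $w$; each mutation multiplies it by $1-s_i$ with
$s_i \sim \mathrm{Exp}(\text{mean }s)$ truncated below 1.  Multiplicative
accumulation (rather than replacing $w$ by $1-s_i$) is the default because
it is the only choice under which a second hit can never *improve* an
allele; the replacement interpretation is available as
`mutation_kernel = "replace"`.  Mutation rates are per allele copy per
generation (the Poisson mean $2N_{pop}u$ fixes this reading); in model 2 each
enhancer–gene pair draws its own independent Poisson counts.

Randomness comes from a xoshiro256++ generator seeded deterministically from
the user seed; replicate $j$ (and fixation trial $k$) uses its own derived
stream, so runs are bit-reproducible and independent of batching.  Fixation
trials carry a hard cap of $10^6$ post-introduction generations as a
liveness guard.

## The four models

1. **Constant total expression** — a regulatory feedback loop fixes total
   protein output; only expression *shares* evolve.  Pure runaway.
2. **Gene dosage** — two enhancer–gene pairs on independent chromosomes;
   fitness is $W_{A1}W_{A2}\,e^{-I(Z_1-Z_2)^2}$ with $Z_j$ the summed log
   strengths at enhancer locus $j$.  Stabilizing selection on *relative*
   dosage: two genes is the most stringent case, since the fraction of
   imbalanced gene pairs is maximal there.
3. **Enhancer–TF coevolution** — one enhancer–gene pair plus a freely
   recombining TF locus; $W = W_A\,e^{-I(Z_1+Z_2)^2}$, optimum where TF
   strength opposes enhancer strength.
4. **Partial selfing** — model 1 with selfing probability $p_s$; fewer
   double heterozygotes, slower runaway.

The stabilizing intensity is scaled to the gene-locus mutation load by
$\gamma$: $I = -\log(1-\gamma u h s)/(4\sigma_E^2)$, so one round of random
regulatory mutation costs about $\gamma$ times one round of gene mutation.

## Escalation analytics

`mean_log_strength()` averages the per-individual mean $(z_1+z_2)/2$ over
the population and over replicates; `doubling_time()` fits an OLS line
through *all* sampled points (no burn-in discard) and reports
$T_{\times 2} = \log 2 / a$, undefined (`NA`) when $a \le 0$.  Because
$z(0)=0$, this is the expected time for mean strength to double on the
geometric scale.  The default sampling interval is 100 generations; the
estimate is insensitive to the interval (tested at 50 vs 200), as a slope
through a long linear series must be.  For ordering tests across conditions
the package fits one slope per replicate (`replicate_slopes()`) and uses
one-sided label-permutation trend tests (`resample_trend_test()`), which
avoid the undefined $T_{\times 2}$ of replicates whose slope is negative.

## Problem sizes, power and honest limitations

The test suite runs the cross-validation at $N_{pop}=10^3$ with 2000 trials
per setting and the escalation orderings at $N_{pop}=500$,
$2\times 10^4$ generations, 20 replicates — sizes chosen so the whole suite
completes in minutes.  At that escalation scale the measured model-1 slope
is $5\times 10^{-6}$ against a per-replicate drift noise of
$2.6\times 10^{-5}$, so the $\gamma$, $p_s$ and model-2-vs-3 orderings are
at or below the noise floor and their significance tests have little power;
they resolve cleanly at $N_{pop}=5000$ and $10^5$ generations, the regime
the headline escalation figures describe.  The unit tests therefore verify
the *mechanisms* (escalation above noise in a mutation-rich regime
$N u_E = 10$; dosage-gap and total-expression pinning under $\gamma=10$
against matched $\gamma=0$ runs) in regimes where they are unambiguous.

What passing tests do and do not show about real data: the generator
emulates idealized bi-allelic or infinite-allele loci with unbiased
log-normal strength mutations, no pleiotropy of enhancer mutations on
timing or localization of expression, no bound on achievable strength, no
transvection or homolog pairing, and constant population size.  Conclusions
transfer to real regulatory regions only insofar as those idealizations do.
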