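# enhancerun

Population genetics of **enhancer runaway**: in diploids, the two homologous
copies of a gene are driven by their own cis enhancers, and the copy in cis
with the stronger enhancer allele contributes the larger share
`e2/(e1+e2)` of the protein pool. When the gene segregates partially
recessive deleterious mutations, this allele-specific expression modifies
their effective dominance (`h1 < h < h2`), and enhancer alleles start to
behave as self-promoting genetic elements: stronger alleles hitchhike with
the better-purged chromosomes they create and can spread without any
individual-level benefit, escalating enhancer strength open-endedly near
genes.

The package is for population geneticists and evolutionary biologists who
want to compute with this theory: the closed-form fitness/dominance
calculus, exact and linearized deterministic two-locus dynamics with the
masking/purging decomposition of selection on an enhancer allele,

```
Δp = −2Δh p_a p q (1−2p) s            (masking, frequency-dependent)
    + D_EA [4hpq + (1−2p)(h2 q − h1 p)] s   (purging, linkage-driven)
```

diffusion-approximation fixation probabilities
`U(p0) = ∫0^p0 ψ / ∫0^1 ψ`, `ψ = exp(−∫ 4N Δp/(pq) dp)`, and fast
individual-based Wright–Fisher simulators (C++ core) for four model
variants: constant total expression, gene-dosage stabilizing selection,
enhancer–transcription-factor coevolution, and partial selfing, plus
doubling-time analytics `T×2 = log(2)/a` for escalation runs.

## Worked example

How strongly is a new enhancer allele three times stronger than the resident
favored, relative to a neutral mutation, as a function of its linkage to the
gene it drives? (`s = 0.1`, `h = 0.25`, `u = 1e-3`, `N = 1000`):

```r
library(enhancerun)
pars <- model_params(s_mean = 0.1, h = 0.25, u_gene = 1e-3,
                     N_pop = 1000, r = 1e-6)
fixation_ratio_curve(pars, strength_ratio = 3,
                     r_values = c(1e-6, 1e-3, 0.01, 0.1, 0.5))
#>       r ratio_to_neutral
#> 1 1e-06            3.188
#> 2 1e-03            3.105
#> 3 1e-02            2.529
#> 4 1e-01            1.198
#> 5 5e-01            0.828
```

Tightly linked stronger enhancers fix ~3× more often than neutral alleles;
beyond a critical recombination distance (here between r = 0.1 and 0.5) they
are selected *against* — the runaway is a property of the gene's immediate
regulatory neighbourhood. The same quantity can be estimated stochastically
(`estimate_fixation_probability()`, with a Wilson 95% CI) from the
individual-based engine.

Long-term escalation and its doubling time, in a mutation-rich regime where
the runaway is well resolved above drift noise:

```r
esc <- model_params(s_mean = 0.1, h = 0.25, u_gene = 1e-3, u_enh = 5e-3,
                    N_pop = 2000, r = 1e-6, n_gen = 20000, n_iter = 3,
                    seed = 8)
traj <- run_escalation(esc, model = 1)
doubling_time(mean_log_strength(traj))
#> Escalation trajectory summary
#>   slope:         0.0001125 per generation
#>   doubling time: 6159 generations
#>   R^2:           0.9776  (n = 201 points)
```

Mean log enhancer strength climbs linearly — strength itself grows
geometrically, doubling every ~6200 generations here — with no ceiling in
the model. `run_escalation(..., model = 2)` (dosage constraint),
`model = 3` (coevolving TF) and `model = 4` (selfing) slow the process but,
for models 2–3, do not stop it: the coupled regulators escalate in concert
while dosage balance `Z1 − Z2` (or total expression `Z1 + Z2`) stays pinned
near its optimum.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/enhancerun fixprob-theory --s 0.1 --ratio 3 \
    --r-grid 1e-6,1e-3,0.5 --Npop 1000 --out curve.tsv
Rscript inst/cli/enhancerun escalate --model 2 --gamma 5 --out traj.tsv
Rscript inst/cli/enhancerun doubling-time --in traj.tsv
```

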