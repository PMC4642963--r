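# reference parameter sets used across tests: partially recessive deleterious
# mutations (h = 0.25), per-copy mutation rate 1e-3, tight linkage
ref_params <- function(...) {
  args <- utils::modifyList(
    list(s_mean = 0.1, h = 0.25, u_gene = 1e-3, u_enh = 1e-3, r = 1e-6,
         N_pop = 1000, sigma_E = 0.1, seed = 42L),
    list(...))
  do.call(model_params, args)
}

# relax a two-locus state to its quasi-stationary (p_a, D_EA) by iterating
# the exact recursion, then return it with the derived frequencies
relax_state <- function(p0, e1, e2, params, n = 400) {
  st <- state_from_freqs(p0, p_a_equilibrium(params, p0, e1, e2), 0)
  for (i in seq_len(n)) st <- step_exact(st, e1, e2, params)
  st
}
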