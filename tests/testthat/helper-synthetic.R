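# Shared fixtures built in code.

# One synthetic strain world: phenotypes at two timepoints per stress plus an
# expression matrix planted against the shared heat robustness.
make_world <- function(seed, n_genes = 1000, n_planted = 20, noise_sd = 0.5,
                       pheno_noise = 0.3) {
  sim <- generate_phenotypes(seed = seed, noise_sd = pheno_noise)
  ge <- generate_expression(sim$true_robustness$heat, n_genes,
                            n_planted = n_planted, noise_sd = noise_sd,
                            seed = seed + 10000L)
  heat <- sim$table[sim$table$stress == "heat", ]
  list(sim = sim, expr = ge$expr, truth = ge$truth,
       rob_t1 = heat$robustness[heat$timepoint_min == 10],
       rob_t2 = heat$robustness[heat$timepoint_min == 30])
}

heat_signature <- function(w, ...) {
  strain_signature(fit_all_genes(w$expr, w$rob_t1),
                   fit_all_genes(w$expr, w$rob_t2), ...)
}
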