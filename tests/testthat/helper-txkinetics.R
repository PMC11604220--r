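# Shared small fixtures: reduced architectures and quick configurations
# keep the stochastic tests fast while leaving room for 3-SE assertions.

reduced_arch <- function(has_uas = FALSE) {
  gene_architecture(n_transcript_bins = 2, has_uas = has_uas)
}

quick_cfg <- function(n_genes = 2000, seed = 1) {
  sim_config(n_genes = n_genes, seed = seed)
}

# z-statistics of simulated means against exact oracle values
oracle_z <- function(profile, oracle) {
  (profile$mean - as.numeric(oracle)) / pmax(profile$se, 1e-12)
}

make_profile <- function(mean, n_genes = 1000) {
  txkinetics:::new_occupancy_profile(names(mean), as.numeric(mean),
                                     rep(0, length(mean)), n_genes,
                                     c(940, 1000), list())
}
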