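# Small cohort configurations reused across test files.

lattice_topology <- function(groups, k = 4) {
  stats::setNames(rep(list(list(family = "lattice", k = k)), length(groups)),
                  groups)
}

small_cohort <- function(sizes = c(A = 10, B = 10), n_regions = 20, seed = 1,
                         ...) {
  generate_cohort(scn_sim_config(
    group_sizes = sizes, n_regions = n_regions,
    topology = lattice_topology(names(sizes)), seed = seed, ...))
}
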