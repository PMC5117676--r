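# One shared small simulated dataset, built once per test run.  Scaled to a
# 400 kb genome / 60 clones so the unit suites stay fast; the full-scale
# study conditions are exercised in the acceptance suite.

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 101, genome_size = 4e5, n_clones = 60,
                      insert_meanlog = log(4e4), insert_sdlog = 0.3,
                      insert_min = 15e3, insert_max = 3e5,
                      contamination = 0.03)
    .sim_cache$sim <- simulate_bes(simulate_genome(cfg))
  }
  .sim_cache$sim
}
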