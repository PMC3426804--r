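# Scaled-down factorial grids shared by the trend tests. Each grid is run at
# most once per session (memoised), always with G = 2000 genes, all blocks
# active, the tent theta scenario unless theta itself is the factor, 20
# replicates per configuration, and fixed base seeds.

.trend_cache <- new.env(parent = emptyenv())

trend_config <- function() {
  simulation_config(n_genes = 2000, active_fraction = 1)
}

trend_grid <- function(name) {
  if (!is.null(.trend_cache[[name]])) {
    return(.trend_cache[[name]])
  }
  rec <- switch(
    name,
    # block-size effect at N = 25, psi = 10%
    xi = run_grid(
      grid_spec(
        sample_sizes = 25, block_sizes = c(1, 100, 1000),
        theta_scenarios = list("tent"), psi_levels = 0.1,
        n_reps = 20, base_seed = 11, config = trend_config()
      ),
      n_pairs = 20000
    ),
    # sample-size effect at xi = 10, psi = 10%
    n = run_grid(
      grid_spec(
        sample_sizes = c(10, 100), block_sizes = 10,
        theta_scenarios = list("tent"), psi_levels = 0.1,
        n_reps = 20, base_seed = 12, config = trend_config()
      ),
      n_pairs = 20000
    ),
    # DE-level effect at N = 25
    psi = run_grid(
      grid_spec(
        sample_sizes = 25, block_sizes = c(1, 100),
        theta_scenarios = list("tent"),
        psi_levels = c(0, 0.05, 0.1, 0.2, 0.4),
        n_reps = 20, base_seed = 13, config = trend_config()
      ),
      n_pairs = 20000
    ),
    # theta scenarios at otherwise matched settings
    theta = run_grid(
      grid_spec(
        sample_sizes = 25, block_sizes = 10,
        theta_scenarios = list(0, 0.1, 0.25, "tent"), psi_levels = 0.1,
        n_reps = 20, base_seed = 14, config = trend_config()
      ),
      n_pairs = 20000
    ),
    # dispersion-vs-FDP sign structure at N = 10, where power is limited
    # enough for the dispersion variate to respond visibly to psi
    afdp = run_grid(
      grid_spec(
        sample_sizes = 10, block_sizes = c(1, 10, 100),
        theta_scenarios = list("tent"),
        psi_levels = c(0.05, 0.1, 0.2, 0.4),
        n_reps = 20, base_seed = 15, config = trend_config()
      ),
      n_pairs = 20000
    ),
    stop("unknown trend grid: ", name)
  )
  .trend_cache[[name]] <- rec
  rec
}
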