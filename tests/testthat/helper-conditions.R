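# Shared reference condition: the 1 m x 4.76 mm pipe at 8.4 m/s that the
# collision-number studies use, with air at room temperature.
ref_gas <- function() gas_properties()
ref_geometry <- function(length = 1) pipe_geometry(length, 4.76e-3)
ref_flow <- function(u = 8.4, length = 1, ...) {
  build_profile(ref_geometry(length), ref_gas(), u, ...)
}

# Mean collision number averaged over seeds at the reference condition.
mean_collisions <- function(diameter, seeds = 1:3, density = 1440,
                            flow = ref_flow(), n_particles = 100, ...) {
  mean(vapply(seeds, function(s) {
    simulate_particles(particle_spec(diameter, density), flow,
                       config = tracking_config(n_particles = n_particles,
                                                rng_seed = s, ...)
    )$mean_collision_number
  }, numeric(1)))
}

# The 197-point simulator database is expensive enough to share across
# tests; built lazily once per test run.
.test_cache <- new.env(parent = emptyenv())
get_test_database <- function() {
  if (is.null(.test_cache$db)) {
    plan <- sampling_plan(197, seed = 42)
    .test_cache$db <- suppressWarnings(build_database(plan, seed = 42))
  }
  .test_cache$db
}
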