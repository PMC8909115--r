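test_that("Schiller-Naumann drag matches its closed form on both branches", {
  expect_equal(drag_coefficient(1), 27.6)
  expect_equal(drag_coefficient(10000), 0.44)
  expect_equal(drag_coefficient(5),
               24 / 5 * (1 + 0.15 * 5^0.687))
  # the branches nearly meet at the switch point
  expect_lt(abs(drag_coefficient(1000) - 0.44), 0.01)
  expect_error(drag_coefficient(0), "positive")
  expect_error(drag_coefficient(-2), "positive")
})

test_that("particle response time is the Stokes time with its scalings", {
  gas <- gas_properties(dynamic_viscosity = 1.8e-5)
  tau <- particle_response_time(particle_spec(100e-6, 1440), gas)
  expect_equal(tau, 1440 * (100e-6)^2 / (18 * 1.8e-5))
  expect_equal(tau, 0.0444, tolerance = 1e-2)
  # tau ~ d^2 and linear in density
  expect_equal(particle_response_time(particle_spec(400e-6, 1440), gas),
               16 * tau)
  expect_equal(particle_response_time(particle_spec(100e-6, 2880), gas),
               2 * tau)
})

test_that("Stokes number classifies dispersion regimes with tie at 1", {
  gas <- ref_gas()
  fl <- ref_flow(8.4)
  s10 <- stokes_number(particle_spec(10e-6, 1440), gas, fl)
  s300 <- stokes_number(particle_spec(300e-6, 1440), gas, fl)
  expect_identical(s10$regime, "low")
  expect_identical(s300$regime, "high")
  expect_equal(s10$stokes,
               particle_response_time(particle_spec(10e-6, 1440), gas) /
                 fl$integral_timescale)
  # the Stk = 1 boundary belongs to the moderate class
  d_eq <- sqrt(fl$integral_timescale * 18 * gas$dynamic_viscosity / 1440)
  expect_equal(stokes_number(particle_spec(d_eq, 1440), gas, fl)$stokes, 1,
               tolerance = 1e-9)
  expect_identical(
    stokes_number(particle_spec(d_eq * 1.001, 1440), gas, fl)$regime,
    "moderate")
  expect_identical(
    stokes_number(particle_spec(d_eq * 0.999, 1440), gas, fl)$regime,
    "low")
  expect_error(stokes_number(particle_spec(10e-6, 1440), gas,
                             ref_flow(6.5, regime = "laminar")),
               "without turbulence timescale")
})

test_that("axisymmetric laminar release without gravity never collides", {
  fl <- ref_flow(6.5, regime = "laminar")
  sm <- simulate_particles(
    particle_spec(100e-6, 1440), fl,
    config = tracking_config(n_particles = 5, gravity = 0,
                             release_radius = 0, rng_seed = 3))
  expect_identical(sum(sm$per_particle_counts), 0L)
  expect_identical(sm$n_exited, 5L)
})

test_that("runs are bitwise reproducible under a fixed seed", {
  fl <- ref_flow(8.4)
  cfg <- tracking_config(n_particles = 30, rng_seed = 11)
  a <- simulate_particles(particle_spec(61.7e-6, 1440), fl, config = cfg)
  b <- simulate_particles(particle_spec(61.7e-6, 1440), fl, config = cfg)
  expect_identical(a$per_particle_counts, b$per_particle_counts)
  expect_identical(a$mean_normal_impact_speed, b$mean_normal_impact_speed)
  d <- simulate_particles(particle_spec(61.7e-6, 1440), fl,
                          config = tracking_config(n_particles = 30,
                                                   rng_seed = 12))
  expect_false(identical(a$per_particle_counts, d$per_particle_counts))
})

test_that("exit accounting closes for every run", {
  fl <- ref_flow(8.4)
  for (d in c(25e-6, 100e-6, 300e-6)) {
    sm <- simulate_particles(particle_spec(d, 1440), fl,
                             config = tracking_config(n_particles = 40,
                                                      rng_seed = 5))
    expect_identical(sm$n_exited + sm$n_timed_out, sm$n_released)
    expect_equal(sm$mean_collision_number,
                 sum(sm$per_particle_counts) / sm$n_released)
    expect_true(all(sm$per_particle_counts >= 0))
  }
})

test_that("a settling particle reaches the Schiller-Naumann terminal velocity", {
  # independent oracle: fixed-point solve of g = f(Re(v)) * v / tau_p
  gas <- ref_gas()
  spec <- particle_spec(100e-6, 1440)
  tau_p <- particle_response_time(spec, gas)
  f_corr <- function(v) {
    rep_p <- gas$density * v * spec$diameter / gas$dynamic_viscosity
    if (rep_p <= 1000) 1 + 0.15 * rep_p^0.687 else 0.44 * rep_p / 24
  }
  v <- 9.81 * tau_p
  for (i in 1:100) v <- 9.81 * tau_p / f_corr(v)

  # a wide, nearly still laminar pipe (negligible axial shear, so the slip
  # is purely vertical): the particle falls 0.2 m from the axis and its
  # first wall impact is at terminal speed. It never exits axially, so
  # read the event off the timeout diagnostics.
  geo <- suppressWarnings(pipe_geometry(0.5, 0.4))
  fl <- build_profile(geo, gas_properties(), 1e-3, regime = "laminar")
  cond <- tryCatch(
    simulate_particles(spec, fl, geo, gas,
                       tracking_config(n_particles = 1, rng_seed = 1,
                                       release_radius = 0,
                                       max_residence_factor = 1,
                                       record_events = TRUE)),
    tribochar_all_timed_out = function(c) c)
  expect_s3_class(cond, "tribochar_all_timed_out")
  expect_equal(cond$events$normal_impact_speed[1], v, tolerance = 0.01)
})

test_that("tracer-limit particles collide no more than the 25-micron size", {
  n10 <- mean_collisions(10e-6, seeds = 1:3)
  n25 <- mean_collisions(25e-6, seeds = 1:3)
  expect_lte(n10, n25)
})

test_that("an unresolved user time step is shrunk with a warning", {
  fl <- ref_flow(8.4)
  spec <- particle_spec(25e-6, 1440)
  expect_warning(
    sm <- simulate_particles(spec, fl,
                             config = tracking_config(n_particles = 5,
                                                      time_step = 0.01)),
    "shrunk")
  tau_p <- particle_response_time(spec, ref_gas())
  expect_lte(sm$time_step, tau_p / 5)
})

test_that("oversized particles are rejected", {
  fl <- ref_flow(8.4)
  expect_error(simulate_particles(particle_spec(5e-3, 1440), fl,
                                  config = tracking_config(n_particles = 2)),
               "exceeds the pipe diameter")
})

test_that("a singleton sweep reproduces a direct simulation", {
  fl <- ref_flow(8.4)
  spec <- particle_spec(61.7e-6, 1440)
  cfg <- tracking_config(n_particles = 30, rng_seed = 9)
  tab <- sweep_collisions(data.frame(diameter = 61.7e-6), spec,
                          ref_geometry(), ref_gas(), 8.4, config = cfg)
  cfg1 <- cfg
  cfg1$rng_seed <- tab$seed[1]
  direct <- simulate_particles(spec, fl, config = cfg1)
  expect_equal(tab$mean_collision_number, direct$mean_collision_number)
  expect_equal(tab$mean_normal_impact_speed,
               direct$mean_normal_impact_speed)
})

test_that("sweeps flag failing points and keep going", {
  spec <- particle_spec(100e-6, 1440)
  grid <- data.frame(diameter = c(100e-6, 5e-3, 25e-6))
  expect_warning(
    tab <- sweep_collisions(grid, spec, ref_geometry(), ref_gas(), 8.4,
                            config = tracking_config(n_particles = 20)),
    "outside the studied range")
  expect_true(is.na(tab$mean_collision_number[2]))
  expect_match(tab$error[2], "exceeds")
  expect_false(anyNA(tab$mean_collision_number[c(1, 3)]))
})
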