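#' Particle specification
#'
#' Physical identity of a powder particle: size, density and the elastic
#' constants entering the Hertzian contact-area estimate. Defaults for the
#' elastic constants are representative of a protein-rich flour particle.
#'
#' @param diameter Particle diameter, m.
#' @param density Particle density, kg/m^3.
#' @param youngs_modulus Young's modulus of the particle, Pa.
#' @param poisson_ratio Poisson's ratio of the particle (in `[0, 0.5)`).
#' @return An object of class `particle_spec`.
#' @export
#' @examples
#' particle_spec(61.7e-6, 1440)
particle_spec <- function(diameter, density, youngs_modulus = 2e9,
                          poisson_ratio = 0.3) {
  check_positive(diameter, "diameter")
  check_positive(density, "density")
  check_positive(youngs_modulus, "youngs_modulus")
  check_poisson_ratio(poisson_ratio, "poisson_ratio")
  structure(list(diameter = diameter, density = density,
                 youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "particle_spec")
}

#' Tracking configuration
#'
#' Options for one Lagrangian release. The default release count of 100
#' particles is the base condition of the collision-number studies; the time
#' step defaults to an automatic choice (see [simulate_particles()]).
#'
#' @param n_particles Number of particles released, >= 1.
#' @param time_step Integration step, s, or `NULL` for automatic
#'   (`min(tau_p/5, tau_e/2, transit/2000)`). A user step larger than
#'   `tau_p/5` is shrunk with a warning.
#' @param rng_seed Integer seed; identical seed and configuration reproduce
#'   the run bitwise.
#' @param restitution Normal restitution coefficient in `(0, 1]`; default 1
#'   (elastic spheres).
#' @param max_residence_factor Particles still inside after this multiple of
#'   the nominal transit time `length/mean_velocity` are counted as timed
#'   out; default 50.
#' @param initial_vertical_speed Injection wall-normal (downward) speed,
#'   m/s; default 0.
#' @param gravity Gravitational acceleration along -z (wall-normal for the
#'   horizontal pipe), m/s^2. Set 0 to disable.
#' @param van_driest_aplus A+ constant of the van Driest damping applied to
#'   the wall-normal velocity fluctuation; default 26.
#' @param rebound_clearance_plus Re-arming clearance for collision counting,
#'   in viscous wall units (`y+`): after a wall impact, a new collision is
#'   counted only once the particle has separated from the wall by more
#'   than this distance, so sustained sliding contact is one collision, not
#'   a train of micro-impacts. Default 5 (the viscous sublayer edge).
#' @param release_radius Radial release position, m; `NULL` (default) draws
#'   uniformly over the inlet cross-section.
#' @param record_events If `TRUE`, individual collision events (axial
#'   position, normal impact speed, time, particle id) are returned.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(n_particles = 100, time_step = NULL,
                            rng_seed = 1L, restitution = 1.0,
                            max_residence_factor = 50,
                            initial_vertical_speed = 0,
                            gravity = 9.81, van_driest_aplus = 26,
                            rebound_clearance_plus = 5,
                            release_radius = NULL, record_events = FALSE) {
  if (n_particles < 1) stop_invalid("n_particles must be >= 1")
  if (!is.null(time_step)) check_positive(time_step, "time_step")
  if (restitution <= 0 || restitution > 1)
    stop_invalid("restitution must lie in (0, 1]")
  if (max_residence_factor < 1)
    stop_invalid("max_residence_factor must be >= 1")
  check_nonnegative(initial_vertical_speed, "initial_vertical_speed")
  check_nonnegative(gravity, "gravity")
  structure(list(n_particles = as.integer(n_particles), time_step = time_step,
                 rng_seed = as.integer(rng_seed), restitution = restitution,
                 max_residence_factor = max_residence_factor,
                 initial_vertical_speed = initial_vertical_speed,
                 gravity = gravity, van_driest_aplus = van_driest_aplus,
                 rebound_clearance_plus = rebound_clearance_plus,
                 release_radius = release_radius,
                 record_events = isTRUE(record_events)),
            class = "tracking_config")
}

#' Schiller-Naumann drag coefficient
#'
#' `Cd = 24/Rep (1 + 0.15 Rep^0.687)` for `Rep <= 1000` and `Cd = 0.44`
#' above, the standard closure for rigid spheres in dilute flows.
#'
#' @param reynolds_p Particle (slip) Reynolds number, > 0. Vectorised.
#' @return Drag coefficient(s).
#' @export
#' @examples
#' drag_coefficient(1)      # 27.6
#' drag_coefficient(10000)  # 0.44
drag_coefficient <- function(reynolds_p) {
  if (!is.numeric(reynolds_p) || any(!is.finite(reynolds_p)) ||
      any(reynolds_p <= 0))
    stop_invalid("reynolds_p must be positive and finite")
  ifelse(reynolds_p <= 1000,
         24 / reynolds_p * (1 + 0.15 * reynolds_p^0.687),
         0.44)
}

#' Particle response (relaxation) time
#'
#' Stokes response time `tau_p = rho_p d_p^2 / (18 mu)`: the time a particle
#' needs to adjust to changes in the surrounding gas velocity. Grows with
#' particle size and density and shrinks with gas viscosity.
#'
#' @param spec A [particle_spec()].
#' @param gas A [gas_properties()].
#' @return Response time, s.
#' @export
particle_response_time <- function(spec, gas) {
  stopifnot(inherits(spec, "particle_spec"), inherits(gas, "gas_properties"))
  spec$density * spec$diameter^2 / (18 * gas$dynamic_viscosity)
}

#' Stokes number and dispersion regime
#'
#' `Stk = tau_p / tau_L`, the ratio of the particle response time to the
#' integral timescale of the turbulence. Regimes: low (`Stk < 1`, tracer-like
#' particles that follow eddies and barely reach the wall), moderate
#' (`1 <= Stk <= 10`, particles trapped near the wall), high (`Stk > 10`,
#' ballistic particles that cross eddies). The boundary `Stk = 1` is
#' classified as moderate.
#'
#' @param spec A [particle_spec()].
#' @param gas A [gas_properties()].
#' @param flow A turbulent [build_profile()] result (laminar flow has no
#'   turbulence timescale and errors).
#' @return A list with `stokes` and `regime`.
#' @export
stokes_number <- function(spec, gas, flow) {
  stopifnot(inherits(flow, "flow_profile"))
  if (!is.finite(flow$integral_timescale))
    stop("Stokes regime undefined without turbulence timescale ",
         "(laminar flow)", call. = FALSE)
  stk <- particle_response_time(spec, gas) / flow$integral_timescale
  regime <- if (stk < 1) "low" else if (stk <= 10) "moderate" else "high"
  list(stokes = stk, regime = regime)
}

#' Simulate particle-wall collisions for one release
#'
#' Lagrangian integration of `n_particles` non-interacting particles through
#' the pipe under Schiller-Naumann drag, gravity transverse to the axis
#' (horizontal pipe) and, in turbulent flow, discrete-random-walk eddy
#' fluctuations. Particles are released at seeded uniformly random positions
#' on the inlet cross-section with the local gas velocity as the initial
#' axial velocity and `-initial_vertical_speed` as the initial wall-normal
#' velocity. Wall contact at centre radius `R - D_p/2` reflects the normal
#' velocity times the restitution coefficient, preserves the tangential
#' velocity and logs the pre-impact normal speed `v_i`. A particle
#' terminates on axial exit or after `max_residence_factor` transit times;
#' timed-out particles stay in the denominator of the mean collision number.
#'
#' @param spec A [particle_spec()].
#' @param flow A [build_profile()] result.
#' @param geometry A [pipe_geometry()] (defaults to the one inside `flow`).
#' @param gas A [gas_properties()] (defaults to the one inside `flow`).
#' @param config A [tracking_config()].
#' @return An object of class `collision_summary` with
#'   `mean_collision_number` (n, collisions per released particle),
#'   `mean_normal_impact_speed` (m/s, `NA` if no collisions),
#'   `per_particle_counts`, `n_released`, `n_exited`, `n_timed_out`,
#'   `time_step`, `events` (data frame if recorded) and the condition.
#' @export
#' @examples
#' geo <- pipe_geometry(1, 4.76e-3)
#' fl <- build_profile(geo, gas_properties(), 8.4)
#' simulate_particles(particle_spec(25e-6, 1440), fl,
#'                    config = tracking_config(n_particles = 10, rng_seed = 7))
simulate_particles <- function(spec, flow, geometry = flow$geometry,
                               gas = flow$gas,
                               config = tracking_config()) {
  stopifnot(inherits(spec, "particle_spec"), inherits(flow, "flow_profile"),
            inherits(geometry, "pipe_geometry"),
            inherits(gas, "gas_properties"),
            inherits(config, "tracking_config"))
  R <- geometry$radius
  contact_radius <- R - spec$diameter / 2
  if (contact_radius <= 0)
    stop_invalid("particle diameter exceeds the pipe diameter")

  tau_p <- particle_response_time(spec, gas)
  turbulent <- flow$regime == "turbulent"
  sigma <- if (turbulent) sqrt(2 * flow$turb_kinetic_energy / 3) else 0
  tau_e <- if (turbulent) flow$integral_timescale else Inf
  eddy_len <- if (turbulent) tau_e * sigma else 0
  transit <- geometry$length / flow$mean_velocity
  max_time <- config$max_residence_factor * transit

  dt_stab <- tau_p / 5
  dt <- config$time_step
  if (is.null(dt)) {
    dt <- min(dt_stab, tau_e / 2, transit / 2000)
  } else if (dt > dt_stab) {
    warning(sprintf(
      "time_step %.3g s does not resolve the particle response time; shrunk to %.3g s",
      dt, dt_stab), call. = FALSE)
    dt <- dt_stab
  }

  release_radius <- if (is.null(config$release_radius)) -1 else config$release_radius

  ## collision re-arming clearance in physical units, capped so it can
  ## always be cleared inside the pipe
  nu <- gas$dynamic_viscosity / gas$density
  clearance <- config$rebound_clearance_plus * nu / flow$friction_velocity
  clearance <- min(clearance, 0.25 * contact_radius)

  set.seed(config$rng_seed)
  res <- track_particles_cpp(
    n_particles = config$n_particles, dt = dt, pipe_radius = R,
    pipe_length = geometry$length, contact_radius = contact_radius,
    u_mean = flow$mean_velocity, u_center = flow$centerline,
    profile_kind = switch(flow$profile, parabolic = 0L, power_law = 1L,
                          wall_resolved = 2L),
    sigma = sigma, tau_eddy = tau_e, eddy_len = eddy_len,
    tau_p = tau_p, particle_diameter = spec$diameter,
    gas_density = gas$density, gas_viscosity = gas$dynamic_viscosity,
    gravity = config$gravity, restitution = config$restitution,
    w0 = config$initial_vertical_speed, max_time = max_time,
    aplus = config$van_driest_aplus, u_tau = flow$friction_velocity,
    clearance = clearance, prof_scale = flow$profile_scale,
    release_radius = release_radius,
    record_events = config$record_events)

  n_exited <- sum(res$exited)
  n_timed_out <- config$n_particles - n_exited
  events <- NULL
  if (config$record_events)
    events <- data.frame(particle = res$event_particle,
                         axial_position = res$event_axial_position,
                         normal_impact_speed = res$event_normal_impact_speed,
                         time = res$event_time)
  if (n_exited == 0L) {
    ## error condition carries the run diagnostics for post-mortem use
    cond <- structure(
      class = c("tribochar_all_timed_out", "error", "condition"),
      list(message = paste0(
             "all ", config$n_particles, " particles timed out after ",
             format(max_time, digits = 3),
             " s; check the flow condition and max_residence_factor"),
           call = sys.call(-1),
           per_particle_counts = res$per_particle_counts,
           mean_normal_impact_speed = res$mean_normal_impact_speed,
           events = events, max_time = max_time, time_step = dt))
    stop(cond)
  }

  structure(list(
    mean_collision_number = mean(res$per_particle_counts),
    mean_normal_impact_speed = res$mean_normal_impact_speed,
    per_particle_counts = res$per_particle_counts,
    n_released = config$n_particles,
    n_exited = n_exited, n_timed_out = n_timed_out,
    time_step = dt, events = events,
    condition = list(diameter = spec$diameter, density = spec$density,
                     pipe_length = geometry$length,
                     pipe_diameter = geometry$inner_diameter,
                     mean_velocity = flow$mean_velocity,
                     regime = flow$regime, seed = config$rng_seed)),
    class = "collision_summary")
}

#' @export
print.collision_summary <- function(x, ...) {
  cat(sprintf(
    "<collision_summary> n = %.3g collisions/particle, v_i = %.3g m/s\n",
    x$mean_collision_number, x$mean_normal_impact_speed))
  cat(sprintf("  released %d, exited %d, timed out %d (dt = %.3g s)\n",
              x$n_released, x$n_exited, x$n_timed_out, x$time_step))
  invisible(x)
}

## Table 1 envelope of the surrogate database; sweeps outside it warn.
PARAM_RANGES <- list(diameter = c(10e-6, 600e-6),
                     density = c(1410, 7850),
                     pipe_diameter = c(0.002, 0.006),
                     pipe_length = c(0.25, 1.5),
                     mean_velocity = c(6.5, 36),
                     initial_vertical_speed = c(0, 1.2))

warn_outside_ranges <- function(grid) {
  for (nm in intersect(names(grid), names(PARAM_RANGES))) {
    rng <- PARAM_RANGES[[nm]]
    bad <- grid[[nm]] < rng[1] | grid[[nm]] > rng[2]
    if (any(bad))
      warning(sprintf("%d grid value(s) of '%s' outside the studied range [%g, %g]",
                      sum(bad), nm, rng[1], rng[2]), call. = FALSE)
  }
}

#' Parameter sweep of collision simulations
#'
#' Runs [simulate_particles()] over a grid of conditions. The grid may vary
#' any of `diameter` (m), `density` (kg/m^3), `pipe_length` (m),
#' `pipe_diameter` (m), `mean_velocity` (m/s), `initial_vertical_speed`
#' (m/s) and `regime`; unspecified columns fall back to the base condition.
#' Each grid point gets its own seed derived deterministically from the base
#' seed and the row index, so single points can be reproduced in isolation.
#' A failing point is flagged in the `error` column and the sweep continues.
#'
#' @param grid A data frame of conditions (one row per point).
#' @param spec Base [particle_spec()].
#' @param geometry Base [pipe_geometry()].
#' @param gas A [gas_properties()].
#' @param mean_velocity Base mean velocity, m/s.
#' @param regime Base regime passed to [build_profile()].
#' @param config Base [tracking_config()]; its seed is the master seed.
#' @return A data frame: the realised condition columns plus
#'   `mean_collision_number`, `mean_normal_impact_speed`, `sd_counts`,
#'   `sem` (Monte-Carlo standard error of the mean collision number),
#'   `n_exited`, `n_timed_out`, `seed`, `error`.
#' @export
sweep_collisions <- function(grid, spec, geometry, gas = gas_properties(),
                             mean_velocity, regime = "auto",
                             config = tracking_config()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  warn_outside_ranges(grid)
  base <- list(diameter = spec$diameter, density = spec$density,
               pipe_length = geometry$length,
               pipe_diameter = geometry$inner_diameter,
               mean_velocity = mean_velocity,
               initial_vertical_speed = config$initial_vertical_speed,
               regime = regime)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cond <- base
    for (nm in names(grid)) cond[[nm]] <- grid[[nm]][i]
    seed_i <- derive_seed(config$rng_seed, i)
    row <- data.frame(diameter = cond$diameter, density = cond$density,
                      pipe_length = cond$pipe_length,
                      pipe_diameter = cond$pipe_diameter,
                      mean_velocity = cond$mean_velocity,
                      initial_vertical_speed = cond$initial_vertical_speed,
                      mean_collision_number = NA_real_,
                      mean_normal_impact_speed = NA_real_,
                      sd_counts = NA_real_, sem = NA_real_,
                      n_exited = NA_integer_, n_timed_out = NA_integer_,
                      seed = seed_i, error = NA_character_)
    sm <- tryCatch({
      geo_i <- pipe_geometry(cond$pipe_length, cond$pipe_diameter)
      fl_i <- build_profile(geo_i, gas, cond$mean_velocity,
                            regime = cond$regime)
      spec_i <- particle_spec(cond$diameter, cond$density,
                              spec$youngs_modulus, spec$poisson_ratio)
      cfg_i <- config
      cfg_i$rng_seed <- seed_i
      cfg_i$initial_vertical_speed <- cond$initial_vertical_speed
      simulate_particles(spec_i, fl_i, geo_i, gas, cfg_i)
    }, error = function(e) e)
    if (inherits(sm, "error")) {
      row$error <- conditionMessage(sm)
    } else {
      row$mean_collision_number <- sm$mean_collision_number
      row$mean_normal_impact_speed <- sm$mean_normal_impact_speed
      row$sd_counts <- sd(sm$per_particle_counts)
      row$sem <- row$sd_counts / sqrt(sm$n_released)
      row$n_exited <- sm$n_exited
      row$n_timed_out <- sm$n_timed_out
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
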