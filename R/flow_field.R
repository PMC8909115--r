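## Reichardt's law of the wall u+(y+); same closed form as the tracker uses.
reichardt_uplus <- function(yplus) {
  kappa <- 0.41
  log(1 + kappa * yplus) / kappa +
    7.8 * (1 - exp(-yplus / 11) - (yplus / 11) * exp(-yplus / 3))
}

#' Pipe geometry
#'
#' Describes the straight circular tribocharging pipe. The flow model assumes
#' fully developed flow, which is conventionally taken to require a length of
#' at least ten diameters; shorter pipes are accepted with a warning.
#'
#' @param length Axial extent of the pipe, m.
#' @param inner_diameter Inner diameter, m.
#' @return An object of class `pipe_geometry` with fields `length`,
#'   `inner_diameter` and `radius`.
#' @export
#' @examples
#' pipe_geometry(1, 4.76e-3)
pipe_geometry <- function(length, inner_diameter) {
  check_positive(length, "length")
  check_positive(inner_diameter, "inner_diameter")
  if (length / inner_diameter < 10)
    warning("pipe length is below 10 diameters; the fully developed ",
            "profile assumption is questionable", call. = FALSE)
  structure(list(length = length, inner_diameter = inner_diameter,
                 radius = inner_diameter / 2),
            class = "pipe_geometry")
}

#' Gas properties
#'
#' Carrier-gas constants. Defaults are dry air at room temperature. The
#' vacuum permittivity is fixed at 8.854e-12 F/m and is not a free parameter.
#'
#' @param density Gas density, kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity, Pa s.
#' @return An object of class `gas_properties`.
#' @export
gas_properties <- function(density = 1.2, dynamic_viscosity = 1.81e-5) {
  check_positive(density, "density")
  check_positive(dynamic_viscosity, "dynamic_viscosity")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity,
                 permittivity_vacuum = EPSILON_0),
            class = "gas_properties")
}

#' Pipe Reynolds number
#'
#' `Re = rho * u * D / mu` on the mean velocity and inner diameter.
#'
#' @param geometry A [pipe_geometry()].
#' @param gas A [gas_properties()].
#' @param mean_velocity Area-averaged axial gas speed, m/s (may be zero).
#' @return Dimensionless Reynolds number.
#' @export
#' @examples
#' reynolds_number(pipe_geometry(1, 4.76e-3), gas_properties(), 8.4)
reynolds_number <- function(geometry, gas, mean_velocity) {
  stopifnot(inherits(geometry, "pipe_geometry"), inherits(gas, "gas_properties"))
  check_nonnegative(mean_velocity, "mean_velocity")
  gas$density * mean_velocity * geometry$inner_diameter / gas$dynamic_viscosity
}

#' Turbulence quantities for fully developed pipe flow
#'
#' Standard engineering correlations in place of a transport-equation solve:
#' turbulence intensity `I = 0.16 Re^(-1/8)`, kinetic energy
#' `k = 1.5 (u I)^2`, mixing length `l = 0.07 D`, dissipation
#' `eps = Cmu^(3/4) k^(3/2) / l`, and integral (eddy-lifetime) timescale
#' `tau_L = C_T k / eps`.
#'
#' @param reynolds Pipe Reynolds number (> 0).
#' @param mean_velocity Mean axial speed, m/s.
#' @param geometry A [pipe_geometry()].
#' @param c_mu k-epsilon model constant, default 0.09.
#' @param eddy_lifetime_const `C_T`, the eddy-lifetime scaling of `k/eps`;
#'   default 0.30 (the classic discrete-random-walk value).
#' @return A list with `k` (m^2/s^2), `eps` (m^2/s^3), `tau_L` (s),
#'   `intensity` and `mixing_length` (m).
#' @export
turbulence_quantities <- function(reynolds, mean_velocity, geometry,
                                  c_mu = 0.09, eddy_lifetime_const = 0.30) {
  check_positive(reynolds, "reynolds")
  check_positive(mean_velocity, "mean_velocity")
  stopifnot(inherits(geometry, "pipe_geometry"))
  intensity <- 0.16 * reynolds^(-1 / 8)
  k <- 1.5 * (mean_velocity * intensity)^2
  l <- 0.07 * geometry$inner_diameter
  eps <- c_mu^0.75 * k^1.5 / l
  list(k = k, eps = eps, tau_L = eddy_lifetime_const * k / eps,
       intensity = intensity, mixing_length = l)
}

#' Build a fully developed pipe flow profile
#'
#' Constructs the Eulerian gas-phase description sampled by the Lagrangian
#' tracker. Laminar flow uses the Hagen-Poiseuille parabola
#' `u(r) = 2 u_mean (1 - (r/R)^2)`. Turbulent flow offers two shapes:
#'
#' * `"power_law"` (default): the classic 1/7th-power outer approximation
#'   `u = u_c (1 - r/R)^(1/7)`.
#' * `"wall_resolved"`: Reichardt's law of the wall,
#'   `u+ = ln(1 + 0.41 y+)/0.41 + 7.8 (1 - exp(-y+/11) - (y+/11) exp(-y+/3))`,
#'   which resolves the viscous sublayer and buffer layer. The low-velocity
#'   zone next to the wall is what axially traps near-wall particles, so
#'   this shape matters for collision statistics at low pipe Reynolds
#'   numbers where the sublayer occupies a sizable fraction of the radius,
#'   at the price of letting wall-deposited fine particles crawl almost
#'   indefinitely.
#'
#' Either way the profile is scaled so its area average equals
#' `mean_velocity` (the power law via `u_c = u_mean (n+1)(2n+1)/(2 n^2)`,
#' the Reichardt profile by numerical quadrature at build time).
#' Turbulence quantities come from [turbulence_quantities()]; in laminar
#' flow they are zero and the integral timescale is `Inf` (no eddies).
#'
#' @param geometry A [pipe_geometry()].
#' @param gas A [gas_properties()].
#' @param mean_velocity Area-averaged axial speed, m/s (> 0).
#' @param regime `"auto"` (threshold Re = 2300), `"laminar"` or
#'   `"turbulent"`. An explicit `"turbulent"` below Re = 2300 warns but
#'   proceeds, so transitional conditions can be forced either way.
#' @param profile Turbulent mean-profile shape, `"power_law"` or
#'   `"wall_resolved"`.
#' @param eddy_lifetime_const Passed to [turbulence_quantities()].
#' @return An object of class `flow_profile` with fields `mean_velocity`,
#'   `regime`, `reynolds`, `centerline`, `axial_velocity_at(r)`,
#'   `turb_kinetic_energy`, `turb_dissipation`, `integral_timescale`,
#'   `friction_velocity`, plus the geometry and gas used.
#' @export
#' @examples
#' fl <- build_profile(pipe_geometry(1, 4.76e-3), gas_properties(), 8.4)
#' fl$regime
#' fl$axial_velocity_at(0)
build_profile <- function(geometry, gas, mean_velocity,
                          regime = c("auto", "laminar", "turbulent"),
                          profile = c("power_law", "wall_resolved"),
                          eddy_lifetime_const = 0.30) {
  stopifnot(inherits(geometry, "pipe_geometry"), inherits(gas, "gas_properties"))
  check_positive(mean_velocity, "mean_velocity")
  regime <- match.arg(regime)
  profile <- match.arg(profile)
  re <- reynolds_number(geometry, gas, mean_velocity)
  if (regime == "auto") regime <- if (re >= 2300) "turbulent" else "laminar"
  if (regime == "turbulent" && re < 2300)
    warning(sprintf("regime forced turbulent at Re = %.0f (< 2300)", re),
            call. = FALSE)
  R <- geometry$radius

  if (regime == "laminar") {
    u_at <- function(r) ifelse(r >= R, 0, 2 * mean_velocity * (1 - (r / R)^2))
    k <- 0; eps <- 0; tau_L <- Inf
    centerline <- 2 * mean_velocity
    ## exact laminar wall shear: tau_w = 4 mu u_mean / R
    u_tau <- sqrt(4 * (gas$dynamic_viscosity / gas$density) * mean_velocity / R)
    profile <- "parabolic"
    prof_scale <- 1
  } else {
    tq <- turbulence_quantities(re, mean_velocity, geometry,
                                eddy_lifetime_const = eddy_lifetime_const)
    k <- tq$k; eps <- tq$eps; tau_L <- tq$tau_L
    ## Blasius friction factor -> friction velocity (also used for the van
    ## Driest wall damping of the wall-normal fluctuation in the tracker)
    f_darcy <- 0.316 * re^(-0.25)
    u_tau <- mean_velocity * sqrt(f_darcy / 8)
    nu <- gas$dynamic_viscosity / gas$density
    if (profile == "power_law") {
      n_exp <- 7
      centerline <- mean_velocity * (n_exp + 1) * (2 * n_exp + 1) / (2 * n_exp^2)
      u_at <- function(r) ifelse(r >= R, 0,
                                 centerline * (1 - r / R)^(1 / n_exp))
      prof_scale <- 1
    } else {
      u_raw <- function(r) u_tau * reichardt_uplus((R - r) * u_tau / nu)
      area_avg <- integrate(function(r) u_raw(r) * 2 * r / R^2, 0, R,
                            rel.tol = 1e-9)$value
      prof_scale <- mean_velocity / area_avg
      u_at <- function(r) ifelse(r >= R, 0, prof_scale * u_raw(r))
      centerline <- u_at(0)
    }
  }

  structure(list(mean_velocity = mean_velocity, regime = regime,
                 reynolds = re, centerline = centerline,
                 axial_velocity_at = u_at,
                 turb_kinetic_energy = k, turb_dissipation = eps,
                 integral_timescale = tau_L, friction_velocity = u_tau,
                 profile = profile, profile_scale = prof_scale,
                 geometry = geometry, gas = gas),
            class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("<flow_profile> %s, u_mean = %.3g m/s, Re = %.0f\n",
              x$regime, x$mean_velocity, x$reynolds))
  if (x$regime == "turbulent")
    cat(sprintf("  k = %.3g m2/s2, eps = %.3g m2/s3, tau_L = %.3g s\n",
                x$turb_kinetic_energy, x$turb_dissipation,
                x$integral_timescale))
  invisible(x)
}
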