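#' Convert a volumetric airflow rate to mean pipe velocity
#'
#' `u = Q / (pi d^2 / 4)` with `Q` converted from L/min to m^3/s.
#'
#' @param flow_rate_lpm Airflow rate, L/min.
#' @param inner_diameter Pipe inner diameter, m.
#' @return Mean axial velocity, m/s.
#' @export
#' @examples
#' airflow_to_velocity(7, 4.76e-3)  # ~6.56 m/s
airflow_to_velocity <- function(flow_rate_lpm, inner_diameter) {
  check_nonnegative(flow_rate_lpm, "flow_rate_lpm")
  check_positive(inner_diameter, "inner_diameter")
  (flow_rate_lpm / 1000 / 60) / (pi * inner_diameter^2 / 4)
}

#' Tribocharging rig configuration
#'
#' Geometry and operating point of the charge-measurement rig: a PTFE tube
#' fed with dry air and a dilute powder stream, discharging into a Faraday
#' cup. Defaults match the reference rig (150 cm x 4.76 mm, 7 L/min air,
#' 1 g/min solids). The mean velocity is derived from the airflow rate
#' unless overridden; the override is useful for matching simulation
#' studies run at a different nominal velocity (e.g. 8.4 m/s).
#'
#' @param tube_length m, default 1.5.
#' @param tube_inner_diameter m, default 4.76e-3.
#' @param airflow_rate_lpm L/min, default 7.
#' @param solid_mass_rate_g_min Solids feed, g/min, default 1.
#' @param mean_velocity_override m/s, or `NULL` to use the airflow rate.
#' @param regime Flow regime passed to [build_profile()]; default
#'   `"turbulent"` (the rig operates near the transition; forcing the
#'   turbulent closure keeps dispersion on).
#' @return An object of class `rig_config` (with derived `mean_velocity`).
#' @export
rig_config <- function(tube_length = 1.5, tube_inner_diameter = 4.76e-3,
                       airflow_rate_lpm = 7, solid_mass_rate_g_min = 1,
                       mean_velocity_override = NULL,
                       regime = "turbulent") {
  check_positive(tube_length, "tube_length")
  check_positive(tube_inner_diameter, "tube_inner_diameter")
  check_positive(airflow_rate_lpm, "airflow_rate_lpm")
  check_positive(solid_mass_rate_g_min, "solid_mass_rate_g_min")
  u <- if (is.null(mean_velocity_override))
    airflow_to_velocity(airflow_rate_lpm, tube_inner_diameter)
  else check_positive(mean_velocity_override, "mean_velocity_override")
  structure(list(tube_length = tube_length,
                 tube_inner_diameter = tube_inner_diameter,
                 airflow_rate_lpm = airflow_rate_lpm,
                 solid_mass_rate_g_min = solid_mass_rate_g_min,
                 mean_velocity = u, regime = regime),
            class = "rig_config")
}

#' Solids volume fraction of the rig feed
#'
#' The one-way-coupling (dilute) assumption requires a solids volume
#' fraction below about 1e-6; above that a warning is emitted since
#' particle-particle effects start to matter.
#'
#' @param rig A [rig_config()].
#' @param particle_density kg/m^3.
#' @return The solids volume fraction (volumetric solids rate over
#'   volumetric air rate).
#' @export
solids_volume_fraction <- function(rig, particle_density) {
  stopifnot(inherits(rig, "rig_config"))
  check_positive(particle_density, "particle_density")
  q_air <- rig$airflow_rate_lpm / 1000 / 60
  q_solid <- rig$solid_mass_rate_g_min / 1000 / 60 / particle_density
  phi <- q_solid / q_air
  if (phi >= 1e-6)
    warning(sprintf(
      "solids volume fraction %.2g >= 1e-6: one-way coupling is an approximation here",
      phi), call. = FALSE)
  else
    message(sprintf("solids volume fraction %.2g < 1e-6: one-way coupling holds",
                    phi))
  phi
}

#' Correlation and linear fit of two vectors
#'
#' Pearson product-moment and Spearman rank correlations plus the ordinary
#' least-squares line `y = slope * x + intercept`.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, finite.
#' @return A list: `pearson_r`, `spearman_rho`, `slope`, `intercept`, `n`.
#' @export
#' @examples
#' correlate(1:5, 2 * (1:5) + 1)
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("x and y must have equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("x and y must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  fit <- lm(y ~ x)
  list(pearson_r = cor(x, y),
       spearman_rho = cor(x, y, method = "spearman"),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' Characterize sieved powder fractions from charge measurements
#'
#' The headline pipeline: for each sieved fraction (represented as a
#' monodisperse particle at its volume mean diameter D4,3), predict the
#' particle-wall mean collision number and mean normal impact speed at the
#' rig condition (Lagrangian simulator or trained surrogate), compute the
#' Hertzian contact area, invert the condenser model for the contact
#' potential difference `V_c`, and correlate `V_c` with protein content and
#' the measured charge-to-mass ratio with the collision number.
#'
#' Fractions with no predicted collisions cannot be inverted and are
#' listed as uncharacterizable. With `collision_model = "surrogate"` the
#' collision number comes from the ensemble while the impact speed (which
#' the surrogate does not model) still comes from a reduced simulator run.
#'
#' @param fractions Data frame with columns `mesh_label`, `d43_um`,
#'   `protein_wt_pct`, `qm_nC_per_g` (as from `load_fixture("table2")`).
#' @param rig A [rig_config()].
#' @param pair A [contact_pair()] (its `V_c` is ignored; `k`, `z0` and the
#'   wall elastic constants are used).
#' @param collision_model `"simulator"` or `"surrogate"`.
#' @param surrogate A trained [train_ensemble()] ensemble (required for the
#'   surrogate model).
#' @param gas A [gas_properties()].
#' @param particle_density Density used for all fractions, kg/m^3; default
#'   1440 (flour).
#' @param particle_youngs_modulus,particle_poisson_ratio Particle elastic
#'   constants for the contact area.
#' @param config A [tracking_config()]; its seed is the master seed, and
#'   each fraction gets a derived seed.
#' @return An object of class `characterization_result`: `table` (one row
#'   per fraction: inputs, `collision_number`, `impact_speed`,
#'   `contact_area`, `cpd_volt`), `correlations` (`cpd_vs_protein`,
#'   `qm_vs_collisions`), `uncharacterizable` (mesh labels), `rig`.
#' @export
characterize <- function(fractions, rig = rig_config(),
                         pair = contact_pair(),
                         collision_model = c("simulator", "surrogate"),
                         surrogate = NULL, gas = gas_properties(),
                         particle_density = 1440,
                         particle_youngs_modulus = 2e9,
                         particle_poisson_ratio = 0.3,
                         config = tracking_config()) {
  collision_model <- match.arg(collision_model)
  needed <- c("mesh_label", "d43_um", "protein_wt_pct", "qm_nC_per_g")
  stopifnot(is.data.frame(fractions), nrow(fractions) >= 1,
            all(needed %in% names(fractions)))
  if (collision_model == "surrogate" &&
      !inherits(surrogate, "surrogate_ensemble"))
    stop_invalid("a trained surrogate ensemble is required for collision_model = 'surrogate'")

  geo <- pipe_geometry(rig$tube_length, rig$tube_inner_diameter)
  fl <- suppressWarnings(
    build_profile(geo, gas, rig$mean_velocity, regime = rig$regime))
  ke <- elasticity_parameter(particle_youngs_modulus, particle_poisson_ratio,
                             pair$wall_youngs_modulus,
                             pair$wall_poisson_ratio)

  n_fr <- nrow(fractions)
  coll_n <- vi <- S <- vc <- rep(NA_real_, n_fr)
  for (i in seq_len(n_fr)) {
    dp <- fractions$d43_um[i] * 1e-6
    spec <- particle_spec(dp, particle_density, particle_youngs_modulus,
                          particle_poisson_ratio)
    cfg <- config
    ## seed from the fraction's size, not its row position, so the result
    ## is invariant to the input ordering
    cfg$rng_seed <- derive_seed(config$rng_seed,
                                round(fractions$d43_um[i] * 1000))
    if (collision_model == "surrogate") {
      feat <- data.frame(particle_size = fractions$d43_um[i],
                         particle_density = particle_density,
                         pipe_diameter = rig$tube_inner_diameter,
                         pipe_length = rig$tube_length,
                         air_velocity = rig$mean_velocity,
                         particle_vertical_velocity =
                           config$initial_vertical_speed)
      coll_n[i] <- suppressWarnings(predict(surrogate, feat))
      cfg$n_particles <- max(25L, cfg$n_particles %/% 4L)
      sm <- suppressWarnings(simulate_particles(spec, fl, geo, gas, cfg))
      vi[i] <- sm$mean_normal_impact_speed
    } else {
      sm <- suppressWarnings(simulate_particles(spec, fl, geo, gas, cfg))
      coll_n[i] <- sm$mean_collision_number
      vi[i] <- sm$mean_normal_impact_speed
    }
    if (is.finite(coll_n[i]) && coll_n[i] > 0 && is.finite(vi[i])) {
      S[i] <- contact_area(ke, particle_density, dp, vi[i])
      vc[i] <- invert_cpd(nC_per_g_to_C_per_kg(fractions$qm_nC_per_g[i]),
                          S[i], coll_n[i], dp, particle_density, pair)
    }
  }

  tab <- cbind(fractions[, needed, drop = FALSE],
               data.frame(collision_number = coll_n, impact_speed = vi,
                          contact_area = S, cpd_volt = vc))
  rownames(tab) <- NULL
  ok <- is.finite(tab$cpd_volt)
  correlations <- list(cpd_vs_protein = NULL, qm_vs_collisions = NULL)
  if (sum(ok) >= 3) {
    correlations$cpd_vs_protein <-
      correlate(tab$protein_wt_pct[ok], tab$cpd_volt[ok])
    correlations$qm_vs_collisions <-
      correlate(tab$collision_number[ok], tab$qm_nC_per_g[ok])
  }
  structure(list(table = tab, correlations = correlations,
                 uncharacterizable = tab$mesh_label[!ok], rig = rig,
                 collision_model = collision_model,
                 elasticity_parameter = ke),
            class = "characterization_result")
}

#' @export
print.characterization_result <- function(x, ...) {
  cat(sprintf("<characterization_result> %d fractions (%s model)\n",
              nrow(x$table), x$collision_model))
  print(x$table, digits = 4)
  if (!is.null(x$correlations$cpd_vs_protein))
    cat(sprintf("  CPD vs protein: Pearson r = %.3f, Spearman rho = %.3f\n",
                x$correlations$cpd_vs_protein$pearson_r,
                x$correlations$cpd_vs_protein$spearman_rho))
  if (length(x$uncharacterizable) > 0)
    cat("  uncharacterizable:", paste(x$uncharacterizable, collapse = ", "),
        "\n")
  invisible(x)
}
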