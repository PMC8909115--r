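#' Electro-mechanical contact pair
#'
#' Parameters of the particle-wall contact entering the condenser model:
#' the contact potential difference `V_c` (V), the dimensionless charging
#' efficiency `k`, the critical gap `z0` (m) below which charge transfer
#' occurs, and the wall elastic constants. The reference rig's wall is a
#' PTFE tube, whose elastic constants are the defaults.
#'
#' `k` and `z0` are not measurable here, so the absolute scale of any
#' inferred `V_c` is only defined up to the factor `k/z0`; every correlation
#' between `V_c` and composition is invariant to that scale.
#'
#' @param contact_potential_difference `V_c`, V; may be `NA` when the pair
#'   is used for inversion.
#' @param charging_efficiency Dimensionless `k` > 0, default 1.
#' @param critical_gap `z0`, m, default 2.5e-7.
#' @param wall_youngs_modulus Pa, default 0.5e9 (PTFE).
#' @param wall_poisson_ratio Default 0.46 (PTFE).
#' @return An object of class `contact_pair`.
#' @export
contact_pair <- function(contact_potential_difference = NA_real_,
                         charging_efficiency = 1,
                         critical_gap = 2.5e-7,
                         wall_youngs_modulus = 0.5e9,
                         wall_poisson_ratio = 0.46) {
  check_positive(charging_efficiency, "charging_efficiency")
  check_positive(critical_gap, "critical_gap")
  check_positive(wall_youngs_modulus, "wall_youngs_modulus")
  check_poisson_ratio(wall_poisson_ratio, "wall_poisson_ratio")
  structure(list(contact_potential_difference = contact_potential_difference,
                 charging_efficiency = charging_efficiency,
                 critical_gap = critical_gap,
                 wall_youngs_modulus = wall_youngs_modulus,
                 wall_poisson_ratio = wall_poisson_ratio),
            class = "contact_pair")
}

#' Charge relaxation parameters
#'
#' Exponential-saturation description of repeated-impact charging: initial
#' and saturation charge-to-mass ratios plus the dimensionless
#' characteristic collision number `n0` governing how fast saturation is
#' approached.
#'
#' @param qm0 Initial charge per mass, C/kg.
#' @param qm_inf Saturation charge per mass, C/kg (finite).
#' @param n0 Characteristic collision number, > 0.
#' @return An object of class `charge_relaxation`.
#' @export
charge_relaxation <- function(qm0 = 0, qm_inf, n0) {
  if (!is.finite(qm_inf)) stop_invalid("qm_inf must be finite")
  check_positive(n0, "n0")
  structure(list(qm0 = qm0, qm_inf = qm_inf, n0 = n0),
            class = "charge_relaxation")
}

#' Elasticity parameter of two contacting bodies
#'
#' `k_e = (1 - v1^2)/E1 + (1 - v2^2)/E2`, symmetric in the two bodies.
#'
#' @param E1,E2 Young's moduli, Pa.
#' @param v1,v2 Poisson ratios in `[0, 0.5)`.
#' @return `k_e`, 1/Pa.
#' @export
#' @examples
#' elasticity_parameter(1e9, 0.3, 1e9, 0.3)  # 1.82e-9
elasticity_parameter <- function(E1, v1, E2, v2) {
  check_positive(E1, "E1"); check_positive(E2, "E2")
  check_poisson_ratio(v1, "v1"); check_poisson_ratio(v2, "v2")
  (1 - v1^2) / E1 + (1 - v2^2) / E2
}

#' Maximum contact area of an elastic sphere-wall impact
#'
#' `S = 1.36 k_e^(2/5) rho_p^(2/5) D_p^2 v_i^(4/5)` for a smooth elastic
#' sphere striking a wall at normal speed `v_i`.
#'
#' @param ke Elasticity parameter, 1/Pa.
#' @param rho_p Particle density, kg/m^3.
#' @param Dp Particle diameter, m.
#' @param vi Normal impact speed, m/s (>= 0).
#' @return Contact area, m^2 (0 iff `vi` = 0).
#' @export
contact_area <- function(ke, rho_p, Dp, vi) {
  check_positive(ke, "ke"); check_positive(rho_p, "rho_p")
  check_positive(Dp, "Dp"); check_nonnegative(vi, "vi")
  1.36 * ke^0.4 * rho_p^0.4 * Dp^2 * vi^0.8
}

#' Charge gained over a pipe segment with exponential saturation
#'
#' For a particle that has already experienced `n_before` collisions and
#' undergoes `n_segment` more in the segment, the charge-to-mass gain is
#' `(qm_inf - qm0) exp(-n_before/n0) (1 - exp(-n_segment/n0))`. The gain is
#' additive over consecutive segments and saturates at `qm_inf - qm0`.
#'
#' @param relax A [charge_relaxation()].
#' @param n_before Collisions before the segment, >= 0.
#' @param n_segment Collisions within the segment, >= 0.
#' @return Charge-to-mass gain, C/kg.
#' @export
charge_saturation <- function(relax, n_before, n_segment) {
  stopifnot(inherits(relax, "charge_relaxation"))
  check_nonnegative(n_before, "n_before")
  check_nonnegative(n_segment, "n_segment")
  (relax$qm_inf - relax$qm0) * exp(-n_before / relax$n0) *
    (1 - exp(-n_segment / relax$n0))
}

#' Condenser-model charge-to-mass ratio
#'
#' The low-charge (negligible initial charge) limit of repeated-impact
#' condenser charging:
#' `dq/m = 6 eps0 V_c n k S / (pi D_p^3 rho_p z0)`,
#' linear in the contact potential difference, collision number, charging
#' efficiency and contact area.
#'
#' @param pair A [contact_pair()] with a finite
#'   `contact_potential_difference`.
#' @param S Contact area, m^2.
#' @param n Mean collision number over the pipe, dimensionless.
#' @param Dp Particle diameter, m.
#' @param rho_p Particle density, kg/m^3.
#' @return Charge-to-mass ratio, C/kg (use [C_per_kg_to_nC_per_g()] for
#'   display units).
#' @export
charge_to_mass <- function(pair, S, n, Dp, rho_p) {
  stopifnot(inherits(pair, "contact_pair"))
  if (!is.finite(pair$contact_potential_difference))
    stop_invalid("contact_potential_difference must be set for the forward model")
  check_nonnegative(S, "S"); check_nonnegative(n, "n")
  check_positive(Dp, "Dp"); check_positive(rho_p, "rho_p")
  6 * EPSILON_0 * pair$contact_potential_difference * n *
    pair$charging_efficiency * S /
    (pi * Dp^3 * rho_p * pair$critical_gap)
}

#' Invert the condenser model for the contact potential difference
#'
#' Solves the charge-to-mass relation for `V_c` given a measured
#' charge-to-mass ratio and the simulated collision statistics:
#' `V_c = qm pi D_p^3 rho_p z0 / (6 eps0 n k S)`. Exact algebraic inverse of
#' [charge_to_mass()]. The absolute scale of `V_c` carries the unknown
#' factor `z0/k`; see [contact_pair()].
#'
#' @param measured_qm Measured charge-to-mass ratio, C/kg (signed).
#' @param S Contact area, m^2 (> 0).
#' @param n Mean collision number (> 0).
#' @param Dp Particle diameter, m.
#' @param rho_p Particle density, kg/m^3.
#' @param pair A [contact_pair()] supplying `k`, `z0` (its `V_c` is ignored).
#' @return Contact potential difference, V.
#' @export
invert_cpd <- function(measured_qm, S, n, Dp, rho_p, pair = contact_pair()) {
  stopifnot(inherits(pair, "contact_pair"))
  if (!is.numeric(n) || !is.finite(n) || n <= 0 ||
      !is.numeric(S) || !is.finite(S) || S <= 0)
    stop("uncharacterizable: no collisions/contact (n and S must be > 0)",
         call. = FALSE)
  check_positive(Dp, "Dp"); check_positive(rho_p, "rho_p")
  measured_qm * pi * Dp^3 * rho_p * pair$critical_gap /
    (6 * EPSILON_0 * n * pair$charging_efficiency * S)
}

#' Convert nC/g to C/kg
#'
#' 1 nC/g = 1e-9 C / 1e-3 kg = 1e-6 C/kg.
#'
#' @param x Charge-to-mass ratio in nC/g.
#' @return The same quantity in C/kg.
#' @export
nC_per_g_to_C_per_kg <- function(x) x * 1e-6

#' Convert C/kg to nC/g
#'
#' @param x Charge-to-mass ratio in C/kg.
#' @return The same quantity in nC/g.
#' @export
C_per_kg_to_nC_per_g <- function(x) x * 1e6
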