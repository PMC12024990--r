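#' Nanoparticle properties
#'
#' Physical properties of a spherical nanoparticle.  The drag coefficient is
#' `drag_prefactor * pi * mu * diameter`; the printed transport model uses
#' prefactor 6, the classical Stokes law corresponds to 3.  The momentum
#' relaxation time is `mass / drag` and therefore depends on the configured
#' drag law (see [np_relaxation_time()]).
#'
#' @param diameter Particle diameter (m).
#' @param density Particle material density (kg/m^3).
#' @param msat Saturation magnetization per unit volume (A/m); 4.8e5 is
#'   typical of magnetite.
#' @param zeta Surface zeta potential (V).
#' @param drag_prefactor Drag-law prefactor multiplying `pi * mu * d_p`.
#' @return An object of class `np_props` with derived `volume` and `mass`.
#' @export
np_props <- function(diameter = 50e-9, density = 5e3, msat = 4.8e5,
                     zeta = 0, drag_prefactor = 6) {
  assert_scalar_num(diameter, "diameter", 0, strict_lower = TRUE)
  assert_scalar_num(density, "density", 0, strict_lower = TRUE)
  assert_scalar_num(msat, "msat", 0)
  assert_scalar_num(drag_prefactor, "drag_prefactor", 0, strict_lower = TRUE)
  vol <- pi / 6 * diameter^3
  structure(
    list(diameter = diameter, density = density, msat = msat, zeta = zeta,
         drag_prefactor = drag_prefactor, volume = vol, mass = density * vol),
    class = "np_props")
}

#' Momentum relaxation time of a particle in a fluid
#'
#' `tau_p = m_p / (drag_prefactor * pi * mu * d_p)`.  With the Stokes
#' prefactor 3 this equals the familiar `rho_p d_p^2 / (18 mu)`.
#' @param props An [np_props()].
#' @param mu Dynamic viscosity of the suspending fluid (Pa s).
#' @return Relaxation time (s).
#' @export
np_relaxation_time <- function(props, mu) {
  assert_scalar_num(mu, "mu", 0, strict_lower = TRUE)
  props$mass / (props$drag_prefactor * pi * mu * props$diameter)
}

#' Surface interaction chemistry
#'
#' All constants governing near-wall particle-surface forces.  Separations
#' `d` are particle-surface to wall-surface distances.  Sign convention for
#' all wall-force functions: positive = repulsive (directed along the outward
#' wall normal), negative = attractive.
#'
#' The acid-base (hydrophilic/hydrophobic) term can be specified either via
#' the interaction energy per area `delta_g_ab` (J/m^2, positive =
#' hydrophilic repulsion) or directly via its contact force `fab_contact`
#' (N at separation `d0`, positive = repulsive), e.g. when contact forces
#' from molecular-dynamics calculations are available.
#'
#' @param hamaker Hamaker constant A (J).
#' @param psi_particle,psi_wall Surface potentials (V).
#' @param eps_r Relative permittivity of the medium.
#' @param debye_length Electrostatic screening length 1/kappa (m).
#' @param d0 Minimum-contact (equilibrium) separation (m).
#' @param lambda Decay length of the acid-base interaction (m).
#' @param delta_g_ab Acid-base interaction energy per area at contact (J/m^2).
#' @param fab_contact Acid-base force at contact (N); overrides `delta_g_ab`
#'   when not `NULL`. For a particle of diameter `dp`,
#'   `fab_contact = pi * dp * delta_g_ab`.
#' @param cutoff Wall-interaction cutoff separation (m).
#' @param d_park Standoff separation at which an adhered particle rests (m);
#'   represents the ligand/protein-corona contact layer that keeps particles
#'   out of the deep primary minimum (typical PEG/ligand brush thickness).
#' @param stick_prob Attachment efficiency: the probability that a
#'   barrier-free wall collision leads to attachment (the collision
#'   efficiency of colloidal deposition kinetics).
#' @param tau_bond_ref Reference adhesion bond lifetime (s): the mean
#'   residence time of a bond whose strength equals the Brownian force
#'   magnitude `2 k_B T / d_p`.  Lifetimes scale linearly with the bond
#'   force; deterministic outward pull shortens them by the Bell factor
#'   `exp(F_out d_park / k_B T)`.
#' @return An object of class `surface_chemistry`.
#' @export
surface_chemistry <- function(hamaker = 1e-20, psi_particle = 0, psi_wall = 0,
                              eps_r = 78.5, debye_length = 10e-9,
                              d0 = 0.157e-9, lambda = 1e-9,
                              delta_g_ab = 0, fab_contact = NULL,
                              cutoff = 100e-9, d_park = 7.5e-9,
                              stick_prob = 0.05, tau_bond_ref = 0.05) {
  assert_scalar_num(hamaker, "hamaker", 0)
  assert_scalar_num(debye_length, "debye_length", 0, strict_lower = TRUE)
  assert_scalar_num(d0, "d0", 0, strict_lower = TRUE)
  assert_scalar_num(lambda, "lambda", 0, strict_lower = TRUE)
  assert_scalar_num(cutoff, "cutoff", 0, strict_lower = TRUE)
  assert_scalar_num(d_park, "d_park", 0, strict_lower = TRUE)
  assert_scalar_num(tau_bond_ref, "tau_bond_ref", 0, strict_lower = TRUE)
  assert_scalar_num(stick_prob, "stick_prob", 0, 1)
  structure(
    list(hamaker = hamaker, psi_particle = psi_particle, psi_wall = psi_wall,
         eps_r = eps_r, kappa = 1 / debye_length, debye_length = debye_length,
         d0 = d0, lambda = lambda, delta_g_ab = delta_g_ab,
         fab_contact = fab_contact, cutoff = cutoff, d_park = d_park,
         stick_prob = stick_prob, tau_bond_ref = tau_bond_ref),
    class = "surface_chemistry")
}

#' Lewis acid-base interaction energy from surface-tension components
#'
#' Combines electron-acceptor (`plus`) and electron-donor (`minus`)
#' surface-tension components (J/m^2) of the two interacting surfaces and the
#' intervening water:
#' \deqn{\Delta G^{AB} = 2[\sqrt{\gamma_w^+}(\sqrt{\gamma_1^-}+\sqrt{\gamma_2^-}
#'   -\sqrt{\gamma_w^-}) + \sqrt{\gamma_w^-}(\sqrt{\gamma_1^+}+\sqrt{\gamma_2^+}
#'   -\sqrt{\gamma_w^+}) - \sqrt{\gamma_1^+\gamma_2^-} -
#'   \sqrt{\gamma_1^-\gamma_2^+}]}
#' Positive values correspond to net hydrophilic repulsion between the
#' surfaces across water.
#'
#' @param gamma_w,gamma_1,gamma_2 Named vectors `c(plus = , minus = )` with
#'   the acceptor/donor components of water and the two surfaces (J/m^2).
#' @return Interaction energy per unit area (J/m^2).
#' @export
delta_g_ab <- function(gamma_w, gamma_1, gamma_2) {
  g <- function(v, comp) {
    if (!comp %in% names(v)) abort("gamma components need names 'plus'/'minus'.")
    sqrt(v[[comp]])
  }
  2 * (g(gamma_w, "plus") * (g(gamma_1, "minus") + g(gamma_2, "minus") -
                               g(gamma_w, "minus")) +
       g(gamma_w, "minus") * (g(gamma_1, "plus") + g(gamma_2, "plus") -
                                g(gamma_w, "plus")) -
       g(gamma_1, "plus") * g(gamma_2, "minus") -
       g(gamma_1, "minus") * g(gamma_2, "plus"))
}

ab_contact_force <- function(chem, diameter) {
  if (!is.null(chem$fab_contact)) chem$fab_contact
  else pi * diameter * chem$delta_g_ab
}

#' Fluid drag force on a particle
#'
#' `F = drag_prefactor * pi * mu * d_p * (u - u_p)`; points from the particle
#' velocity toward the local fluid velocity.
#' @param u_local,u_p Fluid and particle velocity vectors (m/s).
#' @param mu Dynamic viscosity (Pa s).
#' @param diameter Particle diameter (m).
#' @param prefactor Drag prefactor (6 = printed law, 3 = Stokes).
#' @return Force vector (N).
#' @export
drag_force <- function(u_local, u_p, mu, diameter, prefactor = 6) {
  assert_scalar_num(mu, "mu", 0, strict_lower = TRUE)
  prefactor * pi * mu * diameter * (vec3(u_local, "u_local") - vec3(u_p, "u_p"))
}

#' Brownian force
#'
#' The model's thermal kick has fixed magnitude `2 k_B T / d_p` and an
#' independent uniformly random direction at each evaluation.
#' @param temperature Absolute temperature (K).
#' @param diameter Particle diameter (m).
#' @param n Number of independent draws.
#' @return An `n x 3` matrix of force vectors (N).
#' @export
brownian_force <- function(temperature, diameter, n = 1) {
  assert_scalar_num(temperature, "temperature", 0)
  mag <- 2 * .kB * temperature / diameter
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  mag * v
}

#' Magnetic gradient force
#'
#' `F = V_p M_sat (dB/dx, dB/dy, dB/dz)` for a saturated magnetic particle.
#' @param props An [np_props()].
#' @param grad_b Field-magnitude gradient vector (T/m).
#' @return Force vector (N).
#' @export
magnetic_force <- function(props, grad_b) {
  props$volume * props$msat * vec3(grad_b, "grad_b")
}

#' Van der Waals sphere-plate force
#'
#' `F = -A d_p / (12 d^2)`, attractive for positive Hamaker constants;
#' regularized below the minimum-contact distance `d0`.
#' @param chem A [surface_chemistry()].
#' @param diameter Particle diameter (m).
#' @param separation Surface-to-surface separation d (m).
#' @return Signed scalar force along the outward wall normal (N);
#'   negative = attraction toward the wall.
#' @export
vdw_force <- function(chem, diameter, separation) {
  d <- pmax(separation, chem$d0)
  -chem$hamaker * diameter / (12 * d^2)
}

#' Electrostatic double-layer sphere-plate force
#'
#' Constant-potential sphere-plate expression,
#' \deqn{F_{EL} = \pi d_p \kappa \varepsilon \varepsilon_0
#'   \frac{2\Psi_1\Psi_2 - (\Psi_1^2+\Psi_2^2) e^{-\kappa d}}
#'        {e^{\kappa d} - e^{-\kappa d}}}
#' Repulsive (positive) for like-signed potentials except at very small
#' separations with unequal potentials; decays as `exp(-kappa d)`.
#' @inheritParams vdw_force
#' @return Signed scalar force along the outward wall normal (N).
#' @export
electrostatic_force <- function(chem, diameter, separation) {
  kd <- pmin(pmax(chem$kappa * separation, 1e-9), 500)
  em <- exp(-kd)
  ep <- exp(kd)
  pi * diameter * chem$kappa * chem$eps_r * .eps0 *
    (2 * chem$psi_particle * chem$psi_wall -
       (chem$psi_particle^2 + chem$psi_wall^2) * em) / (ep - em)
}

#' Lewis acid-base (hydration / hydrophobic) force
#'
#' `F_AB = F_contact * exp((d0 - d) / lambda)` with
#' `F_contact = pi d_p DeltaG^AB`; positive interaction energies (hydrophilic
#' surfaces) give short-range repulsion, negative (hydrophobic) attraction.
#' @inheritParams vdw_force
#' @return Signed scalar force along the outward wall normal (N).
#' @export
acid_base_force <- function(chem, diameter, separation) {
  ab_contact_force(chem, diameter) * exp((chem$d0 - separation) / chem$lambda)
}

#' Net wall-normal force profile
#'
#' Sum of the van der Waals, electrostatic and acid-base terms at the given
#' separations.
#' @inheritParams vdw_force
#' @return Signed scalar (N); positive = net repulsion.
#' @export
wall_force <- function(chem, diameter, separation) {
  vdw_force(chem, diameter, separation) +
    electrostatic_force(chem, diameter, separation) +
    acid_base_force(chem, diameter, separation)
}

#' Total non-drag acceleration on a particle
#'
#' Sums Brownian, magnetic and (inside the cutoff) wall-chemistry
#' accelerations.  Drag is handled exactly by the exponential velocity
#' integrator and is therefore not part of this sum.
#'
#' @param props An [np_props()].
#' @param chem A [surface_chemistry()] or `NULL` when no wall is nearby.
#' @param temperature Fluid temperature (K); set 0 to disable the thermal kick.
#' @param grad_b Magnetic gradient (T/m), length 3.
#' @param separation Wall separation (m), or `Inf`/`NA` when far from walls.
#' @param normal Outward unit wall normal, length 3 (required within cutoff).
#' @param brownian_dir Optional fixed unit direction for the Brownian kick
#'   (for reproducible composition tests); random when `NULL`.
#' @return List with the acceleration vector `sigma_a` (m/s^2) and the force
#'   components (`f_brown`, `f_mag`, `f_wall`).
#' @export
total_acceleration <- function(props, chem = NULL, temperature = 0,
                               grad_b = c(0, 0, 0), separation = Inf,
                               normal = c(1, 0, 0), brownian_dir = NULL) {
  f_brown <- c(0, 0, 0)
  if (temperature > 0) {
    dir <- if (is.null(brownian_dir)) {
      v <- rnorm(3); v / sqrt(sum(v^2))
    } else vec3(brownian_dir, "brownian_dir")
    f_brown <- 2 * .kB * temperature / props$diameter * dir
  }
  f_mag <- magnetic_force(props, grad_b)
  f_wall <- c(0, 0, 0)
  if (is.finite(separation)) {
    if (is.null(chem))
      abort("particle is within the wall cutoff but no `chem` was supplied.")
    if (separation <= chem$cutoff) {
      nrm <- vec3(normal, "normal")
      f_wall <- wall_force(chem, props$diameter,
                           max(separation, chem$d_park)) * nrm
    }
  }
  list(sigma_a = (f_brown + f_mag + f_wall) / props$mass,
       f_brown = f_brown, f_mag = f_mag, f_wall = f_wall)
}
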