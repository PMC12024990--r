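# Pre-configured studies: geometry -> (fields) -> particle ensembles ->
# diffusion analysis.  Default problem sizes are desk-scale reproductions
# (60 particles, 10 replicates); counts and lattice sizes are plain arguments
# so paper-scale runs (120 particles, 50 replicates) are config-reachable.

# wall-side chemistry presets; particle-side potential comes from np_props()
wall_chem <- function(wall = c("collagen", "hyaluronic", "cell", "none"), ...) {
  wall <- match.arg(wall)
  psi <- switch(wall, collagen = 0.010, hyaluronic = -0.020,
                cell = -0.015, none = 0)
  surface_chemistry(psi_wall = psi, ...)
}

new_experiment <- function(name, results, estimates, config, seed) {
  structure(list(name = name, results = results, estimates = estimates,
                 config = config, seed = seed, config_hash = rlang::hash(config)),
            class = "np_experiment")
}

#' @export
print.np_experiment <- function(x, ...) {
  cat(sprintf("<np_experiment> %s (seed %d, config %s)\n", x$name, x$seed,
              substr(x$config_hash, 1, 8)))
  print(x$results)
  invisible(x)
}

#' @export
tidy.np_experiment <- function(x, ...) x$results

run_one_condition <- function(lattice, props, control, chem, mu, n_steps,
                              record_every, n_particles, replicates, seed,
                              window, grad_b = c(0, 0, 0), u_field = NULL,
                              temperature = 310) {
  sim <- simulate_particles(
    lattice, props, control, chem, mu = mu, temperature = temperature,
    grad_b = grad_b, u_field = u_field, n_steps = n_steps,
    n_particles = n_particles, replicates = replicates,
    record_every = record_every, init = "entrance", seed = seed)
  est <- ensemble_diffusion(sim, window = window)
  list(est = est, events = sim$events,
       glance = glance(sim))
}

cond_row <- function(est, gl) {
  ax <- est$summary
  tibble(mean_D = est$mean_D, sd_D = est$sd_D,
         D_x = ax$mean_D[ax$axis == "x"], D_y = ax$mean_D[ax$axis == "y"],
         D_z = ax$mean_D[ax$axis == "z"],
         representative = est$representative,
         n_adhere = gl$n_adhere, n_release = gl$n_release,
         frac_adhered_final = gl$frac_adhered_final)
}

#' ECM porosity sweep
#'
#' Nanoparticle ensembles in ECM fiber networks of increasing porosity;
#' reproduces the strong porosity dependence of the ensemble diffusion
#' coefficient.
#'
#' @param porosities Target ECM porosities.
#' @param n_nodes Lattice nodes per axis (50 nm spacing).
#' @param dt Particle time step (s).
#' @param n_steps Steps per replicate.
#' @param record_every Recording stride.
#' @param n_particles,replicates Ensemble size.
#' @param zeta Particle zeta potential (V).
#' @param wall Wall material preset for [wall_chem()].
#' @param window MSD fit window (fractions of the largest lag).
#' @param seed Root seed.
#' @return A `np_experiment`; `results` has one row per porosity.
#' @export
experiment_porosity_sweep <- function(porosities = c(0.90, 0.92, 0.94, 0.96, 0.98),
                                      n_nodes = 100L, dt = 1e-4,
                                      n_steps = 30000L, record_every = 100L,
                                      n_particles = 60L, replicates = 10L,
                                      zeta = 0, wall = "collagen",
                                      window = c(0.1, 0.5), seed = 1L) {
  cfg <- as.list(environment())
  props <- np_props(zeta = zeta)
  control <- transport_control(dt)
  chem <- wall_chem(wall)
  out <- vector("list", length(porosities))
  ests <- vector("list", length(porosities))
  for (i in seq_along(porosities)) {
    lat <- generate_ecm(geometry_spec("ecm", target_porosity = porosities[i],
                                      n_nodes = n_nodes,
                                      domain_size = n_nodes * 50e-9,
                                      seed = derive_seed(seed, 100 + i)))
    r <- run_one_condition(lat, props, control, chem, mu = 0.7e-3, n_steps,
                           record_every, n_particles, replicates,
                           derive_seed(seed, i), window)
    out[[i]] <- cbind(tibble(porosity = porosity(lat),
                             target_porosity = porosities[i],
                             connectivity = measure_connectivity(lat)),
                      cond_row(r$est, r$glance))
    ests[[i]] <- r$est
  }
  new_experiment("porosity-sweep", list_rbind(out), ests, cfg, seed)
}

#' Tumor cell volume fraction study
#'
#' Particle transport among tumor/stromal cells embedded in an
#' equivalent-viscosity interstitium, at increasing cell packing fraction.
#'
#' @param fractions Cell volume fractions.
#' @param d_sub_reference ECM subdiffusion coefficient (m^2/s) used to derive
#'   the interstitial equivalent viscosity.
#' @inheritParams experiment_porosity_sweep
#' @export
experiment_cell_fraction <- function(fractions = c(0.21, 0.54),
                                     n_nodes = 100L, dt = 1e-2,
                                     n_steps = 2000L, record_every = 5L,
                                     n_particles = 60L, replicates = 10L,
                                     zeta = 0, d_sub_reference = 3.82e-13,
                                     window = c(0.1, 0.5), seed = 1L) {
  cfg <- as.list(environment())
  props <- np_props(zeta = zeta)
  control <- transport_control(dt)
  chem <- wall_chem("cell")
  mu_e <- equivalent_viscosity(d_sub_reference, props$diameter / 2)$mu_e
  out <- list(); ests <- list()
  for (i in seq_along(fractions)) {
    lat <- generate_tumor(geometry_spec("tumor",
                                        cell_volume_fraction = fractions[i],
                                        n_nodes = n_nodes,
                                        domain_size = n_nodes * 1e-6,
                                        seed = derive_seed(seed, 200 + i)))
    r <- run_one_condition(lat, props, control, chem, mu = mu_e, n_steps,
                           record_every, n_particles, replicates,
                           derive_seed(seed, i), window)
    out[[i]] <- cbind(tibble(cell_fraction = 1 - porosity(lat),
                             target_fraction = fractions[i], mu_e = mu_e),
                      cond_row(r$est, r$glance))
    ests[[i]] <- r$est
  }
  new_experiment("cell-fraction", list_rbind(out), ests, cfg, seed)
}

#' ECM degradation study
#'
#' A single ECM realization is degraded at an increasing number of fiber
#' loci (nested choices, so larger counts strictly extend smaller ones) and
#' the particle ensembles re-run.
#'
#' @param n_points Numbers of degradation points.
#' @param porosity Base ECM porosity.
#' @param segment_length Degraded fiber length per point (m).
#' @inheritParams experiment_porosity_sweep
#' @export
experiment_degradation <- function(n_points = c(0, 200, 600, 1000),
                                   porosity = 0.94, segment_length = 200e-9,
                                   n_nodes = 100L, dt = 1e-4,
                                   n_steps = 30000L, record_every = 100L,
                                   n_particles = 60L, replicates = 10L,
                                   zeta = 0, window = c(0.1, 0.5), seed = 1L) {
  cfg <- as.list(environment())
  props <- np_props(zeta = zeta)
  control <- transport_control(dt)
  chem <- wall_chem("collagen")
  base <- generate_ecm(geometry_spec("ecm", target_porosity = porosity,
                                     n_nodes = n_nodes,
                                     domain_size = n_nodes * 50e-9,
                                     seed = derive_seed(seed, 300)))
  out <- list(); ests <- list()
  for (i in seq_along(n_points)) {
    lat <- apply_degradation(base, n_points[i], segment_length,
                             seed = derive_seed(seed, 301))
    r <- run_one_condition(lat, props, control, chem, mu = 0.7e-3, n_steps,
                           record_every, n_particles, replicates,
                           derive_seed(seed, i), window)
    out[[i]] <- cbind(tibble(n_degradation_points = n_points[i],
                             porosity = porosity(lat),
                             connectivity = measure_connectivity(lat)),
                      cond_row(r$est, r$glance))
    ests[[i]] <- r$est
  }
  new_experiment("degradation", list_rbind(out), ests, cfg, seed)
}

#' Zeta-potential sweep
#'
#' Particle surface potential is varied against a charged wall (tumor cell
#' membranes or ECM fiber types); the same geometry realization is reused
#' across potentials so only the surface chemistry changes.
#'
#' @param zetas Particle zeta potentials (V).
#' @param medium `"tumor"`, `"ecm_hyaluronic"` or `"ecm_collagen"`.
#' @param cell_fraction Tumor cell volume fraction (tumor medium).
#' @param porosity ECM porosity (ECM media).
#' @inheritParams experiment_cell_fraction
#' @export
experiment_zeta_sweep <- function(zetas = c(0, -5e-3, -10e-3, -15e-3),
                                  medium = c("tumor", "ecm_hyaluronic",
                                             "ecm_collagen"),
                                  cell_fraction = 0.21, porosity = 0.94,
                                  n_nodes = 100L, dt = NULL, n_steps = NULL,
                                  record_every = NULL,
                                  n_particles = 60L, replicates = 10L,
                                  d_sub_reference = 3.82e-13,
                                  window = c(0.1, 0.5), seed = 1L) {
  medium <- match.arg(medium)
  cfg <- as.list(environment())
  tumor <- medium == "tumor"
  dt <- dt %||% if (tumor) 1e-2 else 1e-4
  n_steps <- n_steps %||% if (tumor) 2000L else 30000L
  record_every <- record_every %||% if (tumor) 5L else 100L
  control <- transport_control(dt)
  if (tumor) {
    lat <- generate_tumor(geometry_spec("tumor",
                                        cell_volume_fraction = cell_fraction,
                                        n_nodes = n_nodes,
                                        domain_size = n_nodes * 1e-6,
                                        seed = derive_seed(seed, 400)))
    chem <- wall_chem("cell")
    mu <- equivalent_viscosity(d_sub_reference, 25e-9)$mu_e
  } else {
    lat <- generate_ecm(geometry_spec("ecm", target_porosity = porosity,
                                      n_nodes = n_nodes,
                                      domain_size = n_nodes * 50e-9,
                                      seed = derive_seed(seed, 400)))
    chem <- wall_chem(if (medium == "ecm_hyaluronic") "hyaluronic" else "collagen")
    mu <- 0.7e-3
  }
  out <- list(); ests <- list()
  for (i in seq_along(zetas)) {
    props <- np_props(zeta = zetas[i])
    r <- run_one_condition(lat, props, control, chem, mu = mu, n_steps,
                           record_every, n_particles, replicates,
                           derive_seed(seed, i), window)
    out[[i]] <- cbind(tibble(zeta = zetas[i], medium = medium,
                             psi_wall = chem$psi_wall),
                      cond_row(r$est, r$glance))
    ests[[i]] <- r$est
  }
  new_experiment("zeta-sweep", list_rbind(out), ests, cfg, seed)
}

#' Surface hydrophilicity study
#'
#' The short-range acid-base interaction is configured from contact forces
#' between each particle material and the matrix polymer (negative =
#' hydrophobic attraction); all other chemistry parameters are identical.
#' Default contact forces are molecular-dynamics values for polystyrene,
#' silica and PEG-6000 against hyaluronic acid (ECM medium) or dextran
#' (tumor cell membranes).
#'
#' @param contact_forces Named vector of acid-base contact forces (N).
#' @inheritParams experiment_zeta_sweep
#' @export
experiment_hydrophilicity <- function(contact_forces = NULL,
                                      medium = c("ecm_hyaluronic", "tumor"),
                                      cell_fraction = 0.21, porosity = 0.94,
                                      n_nodes = 100L, dt = NULL,
                                      n_steps = NULL, record_every = NULL,
                                      n_particles = 60L, replicates = 10L,
                                      d_sub_reference = 3.82e-13,
                                      window = c(0.1, 0.5), seed = 1L) {
  medium <- match.arg(medium)
  if (is.null(contact_forces))
    contact_forces <- if (medium == "ecm_hyaluronic")
      c(polystyrene = -6.46e-10, silica = 1.12e-10, peg6000 = 1.12e-9)
    else
      c(polystyrene = -4.96e-10, silica = 6.40e-10, peg6000 = 1.08e-9)
  cfg <- as.list(environment())
  tumor <- medium == "tumor"
  dt <- dt %||% if (tumor) 1e-2 else 1e-4
  n_steps <- n_steps %||% if (tumor) 2000L else 30000L
  record_every <- record_every %||% if (tumor) 5L else 100L
  control <- transport_control(dt)
  if (tumor) {
    lat <- generate_tumor(geometry_spec("tumor",
                                        cell_volume_fraction = cell_fraction,
                                        n_nodes = n_nodes,
                                        domain_size = n_nodes * 1e-6,
                                        seed = derive_seed(seed, 500)))
    mu <- equivalent_viscosity(d_sub_reference, 25e-9)$mu_e
  } else {
    lat <- generate_ecm(geometry_spec("ecm", target_porosity = porosity,
                                      n_nodes = n_nodes,
                                      domain_size = n_nodes * 50e-9,
                                      seed = derive_seed(seed, 500)))
    mu <- 0.7e-3
  }
  props <- np_props(zeta = 0)
  out <- list(); ests <- list()
  for (i in seq_along(contact_forces)) {
    chem <- surface_chemistry(psi_wall = 0,
                              fab_contact = unname(contact_forces[i]))
    r <- run_one_condition(lat, props, control, chem, mu = mu, n_steps,
                           record_every, n_particles, replicates,
                           derive_seed(seed, i), window)
    out[[i]] <- cbind(tibble(material = names(contact_forces)[i],
                             fab_contact = unname(contact_forces[i]),
                             medium = medium),
                      cond_row(r$est, r$glance))
    ests[[i]] <- r$est
  }
  new_experiment("hydrophilicity", list_rbind(out), ests, cfg, seed)
}

#' Nanoparticle heating study
#'
#' Heated particles act as fixed-temperature sources for the coupled
#' thermal-flow solver; the resulting natural-convection velocity field is
#' frozen and the particle ensembles are advected through it.  Reports the
#' peak interstitial fluid speed and the diffusion estimate per particle
#' temperature.
#'
#' @param temperatures Particle temperatures (K).
#' @param T0 Reference tissue temperature (K).
#' @param lbm_steps Coupled solver cycles before freezing the field.
#' @param tau_f Flow relaxation time (sets the physical LBM time step).
#' @inheritParams experiment_porosity_sweep
#' @export
experiment_heating <- function(temperatures = c(312, 314, 316), T0 = 310,
                               porosity = 0.94, n_nodes = 32L,
                               lbm_steps = 2000L, tau_f = 1.1,
                               dt = 1e-4, n_steps = 3000L, record_every = 10L,
                               n_particles = 60L, replicates = 10L,
                               window = c(0.1, 0.5), seed = 1L) {
  cfg <- as.list(environment())
  lat <- generate_ecm(geometry_spec("ecm", target_porosity = porosity,
                                    n_nodes = n_nodes,
                                    domain_size = n_nodes * 50e-9,
                                    seed = derive_seed(seed, 600)))
  props <- np_props(zeta = 0)
  control <- transport_control(dt)
  chem <- wall_chem("collagen")
  units <- lbm_units(lat$spacing, 0.7e-3 / 1e3, tau_f)
  # gravity and expansion coefficient of water at body temperature,
  # converted to lattice units
  g_lat <- 9.81 * units$dt^2 / units$dx
  hot0 <- init_positions(lat, n_particles, "entrance", derive_seed(seed, 601))
  out <- list(); ests <- list()
  for (i in seq_along(temperatures)) {
    tf <- run_thermal_flow(lat, hot0, temperatures[i], T0 = T0,
                           tau_f = tau_f, tau_g = tau_f, beta = 3e-4,
                           gravity = c(0, 0, -g_lat), steps = lbm_steps)
    scale <- units$dx / units$dt
    uf <- list(ux = tf$ux * scale, uy = tf$uy * scale, uz = tf$uz * scale)
    peak <- max(sqrt(uf$ux^2 + uf$uy^2 + uf$uz^2))
    r <- run_one_condition(lat, props, control, chem, mu = 0.7e-3, n_steps,
                           record_every, n_particles, replicates,
                           derive_seed(seed, i), window, u_field = uf)
    out[[i]] <- cbind(tibble(T_p = temperatures[i], T0 = T0,
                             peak_fluid_speed = peak),
                      cond_row(r$est, r$glance))
    ests[[i]] <- r$est
  }
  new_experiment("heating", list_rbind(out), ests, cfg, seed)
}

#' Magnetic gradient sweep
#'
#' Magnetite particles in tumor tissue under a static field-magnitude
#' gradient along z.  Reports per-axis diffusion coefficients, the mean
#' z-penetration depth, and adhesion/detachment counts.
#'
#' @param gradients Field gradients dB/dz (T/m).
#' @inheritParams experiment_cell_fraction
#' @export
experiment_magnetic_sweep <- function(gradients = c(0, 2000, 4000, 6000),
                                      cell_fraction = 0.21, n_nodes = 100L,
                                      dt = 1e-2, n_steps = 2000L,
                                      record_every = 5L, n_particles = 60L,
                                      replicates = 10L,
                                      d_sub_reference = 3.82e-13,
                                      window = c(0.1, 0.5), seed = 1L) {
  cfg <- as.list(environment())
  lat <- generate_tumor(geometry_spec("tumor",
                                      cell_volume_fraction = cell_fraction,
                                      n_nodes = n_nodes,
                                      domain_size = n_nodes * 1e-6,
                                      seed = derive_seed(seed, 700)))
  props <- np_props(zeta = 0)  # magnetite defaults: msat = 4.8e5 A/m
  control <- transport_control(dt)
  chem <- wall_chem("cell")
  mu <- equivalent_viscosity(d_sub_reference, 25e-9)$mu_e
  out <- list(); ests <- list()
  for (i in seq_along(gradients)) {
    sim <- simulate_particles(lat, props, control, chem, mu = mu,
                              grad_b = c(0, 0, gradients[i]),
                              n_steps = n_steps, n_particles = n_particles,
                              replicates = replicates,
                              record_every = record_every, init = "entrance",
                              seed = derive_seed(seed, i))
    est <- ensemble_diffusion(sim, window = window)
    zdisp <- mean(map_dbl(sim$trajectories, function(tr) {
      nr <- dim(tr)[1]
      mean(tr[nr, , 3] - tr[1, , 3])
    }))
    gl <- glance(sim)
    out[[i]] <- cbind(tibble(grad_b = gradients[i],
                             mean_z_penetration = zdisp),
                      cond_row(est, gl))
    ests[[i]] <- est
  }
  new_experiment("magnetic-sweep", list_rbind(out), ests, cfg, seed)
}

#' Sphere-array diffusion validation
#'
#' Brownian ensembles (fluctuation-dissipation mode, continuous moves, no
#' wall chemistry) in simple-cubic sphere arrays of several diameters; the
#' simulated relative diffusivity `D_eff/D_0` is compared against the
#' analytic Maxwell reference at the voxelized porosity.  `D_0` is measured
#' in an obstacle-free domain with identical numerics so discretization
#' effects cancel.
#'
#' @param d_over_pitch Sphere diameter / pitch ratios.
#' @param pitch Unit-cell edge (m).
#' @param n_nodes Nodes per unit-cell axis.
#' @inheritParams experiment_porosity_sweep
#' @export
validate_spheres <- function(d_over_pitch = c(0.2, 0.3, 0.4), pitch = 1e-6,
                             n_nodes = 40L, dt = 4e-6, n_steps = 800000L,
                             record_every = 1000L, n_particles = 15L,
                             replicates = 16L, window = c(0.08, 0.3),
                             seed = 1L) {
  cfg <- as.list(environment())
  props <- np_props(zeta = 0)
  control <- transport_control(dt, brownian = "fluctuation_dissipation",
                               moves = "continuous")
  free <- free_fluid_domain(pitch / n_nodes, n_nodes)
  out <- list(); ests <- list()
  for (i in seq_along(d_over_pitch)) {
    lat <- generate_sphere_array(d_over_pitch[i] * pitch, pitch, n_nodes)
    # the obstacle-free reference run is paired with the obstacle run by a
    # common seed: both ensembles see identical Brownian histories except at
    # collisions, so the common-mode sampling noise cancels in the ratio
    sim <- simulate_particles(lat, props, control, chem = NULL, mu = 0.7e-3,
                              n_steps = n_steps, n_particles = n_particles,
                              replicates = replicates,
                              record_every = record_every, init = "uniform",
                              seed = derive_seed(seed, i))
    sim0 <- simulate_particles(free, props, control, chem = NULL, mu = 0.7e-3,
                               n_steps = n_steps, n_particles = n_particles,
                               replicates = replicates,
                               record_every = record_every, init = "uniform",
                               seed = derive_seed(seed, i))
    est <- ensemble_diffusion(sim, window = window)
    d0 <- ensemble_diffusion(sim0, window = window)$mean_D
    eps <- porosity(lat)
    ref <- sphere_array_reference_D(eps)
    out[[i]] <- tibble(d_over_pitch = d_over_pitch[i], porosity = eps,
                       D = est$mean_D, D0 = d0, ratio = est$mean_D / d0,
                       reference = ref,
                       rel_error_pct = 100 * abs(est$mean_D / d0 - ref) / ref)
    ests[[i]] <- est
  }
  new_experiment("validate-spheres", list_rbind(out), ests, cfg, seed)
}

#' Equivalent-viscosity consistency validation
#'
#' For each ECM porosity: measure the subdiffusion coefficient in the
#' explicit fiber geometry, map it to an equivalent viscosity
#' `mu_e = k_B T/(6 pi R0 D_sub)`, re-run the particles in a homogeneous
#' fluid of that viscosity (no obstacles, Stokes drag on the particle
#' radius), and compare the recovered free diffusion coefficient with
#' `D_sub`.  Both legs use the fluctuation-dissipation Brownian mode and
#' continuous moves, the regime in which the Stokes-Einstein map is exact.
#'
#' @param porosities ECM porosities.
#' @inheritParams validate_spheres
#' @export
validate_equivalent_viscosity <- function(porosities = c(0.92, 0.95, 0.98),
                                          n_nodes = 64L, dt = 6e-6,
                                          n_steps = 20000L,
                                          record_every = 40L,
                                          n_particles = 30L, replicates = 20L,
                                          window = c(0.1, 0.5), seed = 1L) {
  cfg <- as.list(environment())
  control <- transport_control(dt, brownian = "fluctuation_dissipation",
                               moves = "continuous")
  out <- list(); ests <- list()
  for (i in seq_along(porosities)) {
    lat <- generate_ecm(geometry_spec("ecm", target_porosity = porosities[i],
                                      n_nodes = n_nodes,
                                      domain_size = n_nodes * 50e-9,
                                      seed = derive_seed(seed, 800 + i)))
    props <- np_props(zeta = 0)
    sim <- simulate_particles(lat, props, control, chem = NULL, mu = 0.7e-3,
                              n_steps = n_steps, n_particles = n_particles,
                              replicates = replicates,
                              record_every = record_every, init = "uniform",
                              seed = derive_seed(seed, i))
    d_sub <- ensemble_diffusion(sim, window = window)$mean_D
    ev <- equivalent_viscosity(d_sub, props$diameter / 2)
    props_s <- np_props(zeta = 0, drag_prefactor = 3)  # Stokes law on R0
    free <- free_fluid_domain(lat$spacing, 16L)
    sim_f <- simulate_particles(free, props_s, control, chem = NULL,
                                mu = ev$mu_e, n_steps = n_steps,
                                n_particles = n_particles,
                                replicates = replicates,
                                record_every = record_every,
                                init = "uniform",
                                seed = derive_seed(seed, 50 + i))
    d_free <- ensemble_diffusion(sim_f, window = window)$mean_D
    out[[i]] <- tibble(porosity = porosity(lat), D_sub = d_sub,
                       mu_e = ev$mu_e, D_free = d_free,
                       rel_error_pct = 100 * abs(d_free - d_sub) / d_sub)
    ests[[i]] <- NULL
  }
  new_experiment("validate-equivalent-viscosity", list_rbind(out), ests, cfg,
                 seed)
}

#' Run a named experiment
#'
#' Dispatcher over the pre-configured studies; `config` entries override the
#' corresponding experiment arguments.
#'
#' @param name One of `"porosity-sweep"`, `"cell-fraction"`, `"degradation"`,
#'   `"zeta-sweep"`, `"hydrophilicity"`, `"heating"`, `"magnetic-sweep"`,
#'   `"validate-spheres"`, `"validate-equivalent-viscosity"`.
#' @param config Named list of argument overrides.
#' @param seed Root seed.
#' @return A `np_experiment`.
#' @export
run_experiment <- function(name, config = list(), seed = 1L) {
  fns <- list(
    "porosity-sweep" = experiment_porosity_sweep,
    "cell-fraction" = experiment_cell_fraction,
    "degradation" = experiment_degradation,
    "zeta-sweep" = experiment_zeta_sweep,
    "hydrophilicity" = experiment_hydrophilicity,
    "heating" = experiment_heating,
    "magnetic-sweep" = experiment_magnetic_sweep,
    "validate-spheres" = validate_spheres,
    "validate-equivalent-viscosity" = validate_equivalent_viscosity)
  if (!name %in% names(fns))
    abort(sprintf("unknown experiment '%s'; choose one of: %s", name,
                  paste(names(fns), collapse = ", ")))
  fn <- fns[[name]]
  bad <- setdiff(names(config), names(formals(fn)))
  if (length(bad))
    abort(sprintf("unknown config keys for %s: %s", name,
                  paste(bad, collapse = ", ")))
  do.call(fn, c(config, list(seed = as.integer(seed))))
}
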