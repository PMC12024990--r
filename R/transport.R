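#' Exact exponential velocity update
#'
#' Integrates `du_p/dt = (u - u_p)/tau_p + Sigma_a` exactly over one step:
#' `u_p* = u + tau_p Sigma_a + (u_p - u - tau_p Sigma_a) exp(-dt/tau_p)`.
#' For `dt >> tau_p` this relaxes to the terminal velocity
#' `u + tau_p Sigma_a`.
#'
#' @param u_p Particle velocity (m/s), length 3.
#' @param u_local Local fluid velocity (m/s).
#' @param sigma_a Sum of non-drag accelerations (m/s^2).
#' @param dt Time step (s).
#' @param tau_p Momentum relaxation time (s), > 0.
#' @return Updated velocity vector.
#' @export
update_velocity <- function(u_p, u_local, sigma_a, dt, tau_p) {
  assert_scalar_num(tau_p, "tau_p", 0, strict_lower = TRUE)
  term <- vec3(u_local, "u_local") + tau_p * vec3(sigma_a, "sigma_a")
  term + (vec3(u_p, "u_p") - term) * exp(-dt / tau_p)
}

#' Exact displacement over one step
#'
#' Time integral of the exponential velocity solution:
#' `dx = (u + tau_p Sigma_a) dt + (u_p - u - tau_p Sigma_a) tau_p
#'  (1 - exp(-dt/tau_p))`.
#' @inheritParams update_velocity
#' @return Displacement vector (m).
#' @export
update_displacement <- function(u_p, u_local, sigma_a, dt, tau_p) {
  assert_scalar_num(tau_p, "tau_p", 0, strict_lower = TRUE)
  term <- vec3(u_local, "u_local") + tau_p * vec3(sigma_a, "sigma_a")
  term * dt + (vec3(u_p, "u_p") - term) * tau_p * (-expm1(-dt / tau_p))
}

#' Lattice migration probabilities
#'
#' For the six face directions, `P_i = max(0, dx_p . e_i / dx)`: the
#' probability of hopping one node along each axis is proportional to the
#' continuum displacement component, and directions opposing the displacement
#' have probability zero.
#'
#' @param dxp Continuum displacement over the step (m), length 3.
#' @param dx Node spacing (m).
#' @return Named length-6 vector `(+x, -x, +y, -y, +z, -z)`, each in `[0, 1]`.
#'   Components exceeding one indicate a violated step guard and are an error
#'   (the simulator sub-steps instead).
#' @export
migration_probabilities <- function(dxp, dx) {
  dxp <- vec3(dxp, "dxp")
  assert_scalar_num(dx, "dx", 0, strict_lower = TRUE)
  if (any(abs(dxp) > dx))
    abort("`|dxp|` exceeds one lattice spacing; sub-step the displacement.")
  p <- c(pmax(0, dxp / dx), pmax(0, -dxp / dx))[c(1, 4, 2, 5, 3, 6)]
  setNames(p, c("+x", "-x", "+y", "-y", "+z", "-z"))
}

#' Transport model configuration
#'
#' @param dt Particle time step (s).
#' @param brownian `"printed"` uses the fixed-magnitude thermal kick
#'   `2 k_B T / d_p` with a fresh random direction each step;
#'   `"fluctuation_dissipation"` uses Gaussian components with variance
#'   `2 zeta k_B T / dt`, which recovers the Einstein diffusivity
#'   `k_B T / zeta` exactly.
#' @param moves `"lattice"` uses the stochastic node-migration rule;
#'   `"continuous"` displaces particles in continuous space (used for
#'   quantitative diffusion validation).
#' @param interpolation `"trilinear"` or `"nearest"` sampling of the fluid
#'   velocity field at the particle position.
#' @export
transport_control <- function(dt, brownian = c("printed", "fluctuation_dissipation"),
                              moves = c("lattice", "continuous"),
                              interpolation = c("trilinear", "nearest")) {
  assert_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  structure(list(dt = dt, brownian = match.arg(brownian),
                 moves = match.arg(moves),
                 interpolation = match.arg(interpolation)),
            class = "transport_control")
}

init_positions <- function(lattice, n, mode, rng_seed) {
  set.seed(rng_seed)
  nn <- dim(lattice$occupancy)
  dx <- lattice$spacing
  if (mode == "entrance") {
    face <- which(lattice$occupancy[, , 1] == 0L, arr.ind = TRUE)
    if (nrow(face) == 0L) abort("no fluid nodes on the entrance surface.")
    pick <- face[sample.int(nrow(face), n, replace = TRUE), , drop = FALSE]
    cbind((pick[, 1] - 0.5) * dx, (pick[, 2] - 0.5) * dx, rep(0.5 * dx, n))
  } else {
    fl <- which(lattice$occupancy == 0L)
    pick <- fl[sample.int(length(fl), n, replace = TRUE)] - 1L
    i <- pick %% nn[1]
    j <- (pick %/% nn[1]) %% nn[2]
    k <- pick %/% (nn[1] * nn[2])
    cbind((i + 0.5) * dx, (j + 0.5) * dx, (k + 0.5) * dx)
  }
}

#' Simulate a nanoparticle ensemble
#'
#' Runs `replicates` independent stochastic replicates of `n_particles`
#' particles through the coupled force/transport model on the given lattice.
#' Each replicate and each particle has its own deterministically derived
#' random stream, so identical seeds give identical trajectories.
#'
#' @param lattice A `porous_lattice` (use [free_fluid_domain()] for
#'   obstacle-free runs).
#' @param props An [np_props()].
#' @param control A [transport_control()].
#' @param chem A [surface_chemistry()], or `NULL` to disable wall chemistry
#'   (walls then reflect; nothing adheres).
#' @param mu Dynamic viscosity of the suspending fluid (Pa s).
#' @param temperature Fluid temperature (K).
#' @param grad_b Magnetic field gradient (T/m), length 3.
#' @param u_field Optional frozen fluid velocity: list of arrays
#'   `ux`, `uy`, `uz` in SI units (m/s) on the lattice nodes.
#' @param n_steps Number of particle steps.
#' @param n_particles Particles per replicate.
#' @param replicates Number of independent replicates.
#' @param record_every Record positions every this many steps.
#' @param init `"entrance"` seeds particles on fluid nodes of the z = 0 face;
#'   `"uniform"` anywhere in the pore space.
#' @param seed Root integer seed.
#' @return A `np_ensemble` object: list of per-replicate trajectory arrays
#'   (time x particle x axis, unwrapped positions in m), adhesion records,
#'   and run metadata.  Use [tidy()] for a long tibble and [compute_msd()] /
#'   [ensemble_diffusion()] for analysis.
#' @export
simulate_particles <- function(lattice, props, control, chem = NULL,
                               mu = 0.7e-3, temperature = 310,
                               grad_b = c(0, 0, 0), u_field = NULL,
                               n_steps = 2000, n_particles = 120,
                               replicates = 50, record_every = 10,
                               init = c("entrance", "uniform"), seed = 1L) {
  stopifnot(inherits(lattice, "porous_lattice"), inherits(props, "np_props"),
            inherits(control, "transport_control"))
  init <- match.arg(init)
  nn <- dim(lattice$occupancy)
  chem_on <- !is.null(chem)
  if (chem_on) stopifnot(inherits(chem, "surface_chemistry"))

  scan <- max(2L, as.integer(ceiling(
    ((if (chem_on) chem$cutoff else 0) + props$diameter) / lattice$spacing)) + 1L)
  nw <- cpp_near_wall(lattice$occupancy, nn, scan)

  uf <- NULL
  if (!is.null(u_field))
    uf <- list(ux = as.numeric(u_field$ux), uy = as.numeric(u_field$uy),
               uz = as.numeric(u_field$uz))

  params <- list(
    dt = control$dt, dp = props$diameter, rho_p = props$density, mu = mu,
    temperature = temperature, msat = props$msat,
    drag_pref = props$drag_prefactor,
    brownian_mode = if (control$brownian == "printed") 0L else 1L,
    move_mode = if (control$moves == "lattice") 0L else 1L,
    interp_mode = if (control$interpolation == "trilinear") 0L else 1L,
    gradB = vec3(grad_b, "grad_b"),
    chem_on = chem_on,
    hamaker = if (chem_on) chem$hamaker else 0,
    psi_particle = if (chem_on) props$zeta else 0,  # particle side from np_props
    psi_wall = if (chem_on) chem$psi_wall else 0,
    eps_r = if (chem_on) chem$eps_r else 78.5,
    kappa = if (chem_on) chem$kappa else 1e9,
    d0 = if (chem_on) chem$d0 else 0.157e-9,
    lambda = if (chem_on) chem$lambda else 1e-9,
    fab_contact = if (chem_on) ab_contact_force(chem, props$diameter) else 0,
    cutoff = if (chem_on) chem$cutoff else 0,
    d_park = if (chem_on) chem$d_park else 1e-9,
    stick_prob = if (chem_on) chem$stick_prob else 0,
    tau_bond_ref = if (chem_on) chem$tau_bond_ref else 1)

  traj <- vector("list", replicates)
  adh <- vector("list", replicates)
  events <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sr <- derive_seed(seed, r)
    pos0 <- init_positions(lattice, n_particles, init, sr)
    res <- cpp_simulate(lattice$occupancy, nn, lattice$spacing, nw, pos0,
                        params, uf, as.integer(n_steps),
                        as.integer(record_every), sr)
    if (isTRUE(res$substep_overflow))
      warn(sprintf("replicate %d: displacement sub-stepping hit its cap; %s",
                   r, "results near walls may be under-resolved."))
    traj[[r]] <- res$traj
    adh[[r]] <- res$adhered
    events[[r]] <- tibble(replicate = r,
                          particle = seq_len(n_particles),
                          n_adhere = res$n_adhere,
                          n_release = res$n_release)
  }
  structure(
    list(trajectories = traj, adhesion = adh,
         events = list_rbind(events),
         time = seq(0, n_steps, by = record_every) * control$dt,
         meta = list(dt = control$dt, n_steps = as.integer(n_steps),
                     record_every = as.integer(record_every),
                     n_particles = as.integer(n_particles),
                     replicates = as.integer(replicates), seed = seed, mu = mu,
                     temperature = temperature, grad_b = vec3(grad_b, "g"),
                     control = control, props = props, chem = chem,
                     spacing = lattice$spacing, kind = lattice$kind,
                     porosity = lattice$porosity,
                     tau_p = np_relaxation_time(props, mu))),
    class = "np_ensemble")
}

#' @export
print.np_ensemble <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<np_ensemble> %d replicates x %d particles, %d steps of %.3g s (%s moves)\n",
    m$replicates, m$n_particles, m$n_steps, m$dt, m$control$moves))
  cat(sprintf("  lattice: %s, porosity %.3f; adhesion events: %d\n",
              m$kind, m$porosity, sum(x$events$n_adhere)))
  invisible(x)
}

#' Tidy trajectories of an ensemble
#'
#' @param x A `np_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `replicate`, `particle`, `t`, `x`, `y`, `z`
#'   (unwrapped positions, m) and `adhered`.
#' @export
tidy.np_ensemble <- function(x, ...) {
  out <- imap(x$trajectories, function(tr, r) {
    d <- dim(tr)
    adh <- as.vector(x$adhesion[[r]])
    tibble(
      replicate = as.integer(r),
      particle = rep(seq_len(d[2]), each = d[1]),
      t = rep(x$time, d[2]),
      x = as.vector(tr[, , 1]),
      y = as.vector(tr[, , 2]),
      z = as.vector(tr[, , 3]),
      adhered = adh)
  })
  list_rbind(out)
}

#' Summary of an ensemble run
#' @param x A `np_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: replicate/particle counts, duration, adhesion
#'   totals and the fraction of particles adhered at the final time.
#' @export
glance.np_ensemble <- function(x, ...) {
  m <- x$meta
  final_adh <- mean(map_dbl(x$adhesion, function(a) mean(a[nrow(a), ])))
  tibble(replicates = m$replicates, n_particles = m$n_particles,
         n_steps = m$n_steps, dt = m$dt, duration = m$n_steps * m$dt,
         porosity = m$porosity, n_adhere = sum(x$events$n_adhere),
         n_release = sum(x$events$n_release), frac_adhered_final = final_adh)
}
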