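#' Discrete velocity models
#'
#' `d3q19` (flow) and `d3q7` (temperature) lattice stencils in lattice units
#' (`dx = dt = 1`).  Weights satisfy the usual moment identities: they sum to
#' one, have zero first moment, and second moment `cs2 * I`.
#'
#' @param type `"d3q19"` or `"d3q7"`.
#' @return List with velocity matrix `e` (q x 3), weights `w`, and squared
#'   lattice sound speed `cs2`.
#' @export
lattice_model <- function(type = c("d3q19", "d3q7")) {
  type <- match.arg(type)
  if (type == "d3q19") {
    e <- cbind(
      c(0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0),
      c(0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0, 1, -1, 1, -1),
      c(0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, 1, -1, -1, 1))
    w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
    cs2 <- 1 / 3
  } else {
    e <- cbind(c(0, 1, -1, 0, 0, 0, 0),
               c(0, 0, 0, 1, -1, 0, 0),
               c(0, 0, 0, 0, 0, 1, -1))
    w <- c(1 / 4, rep(1 / 8, 6))
    cs2 <- 1 / 4
  }
  structure(list(type = type, e = e, w = w, cs2 = cs2), class = "lattice_model")
}

#' Equilibrium distribution
#'
#' Second-order (flow) or first-order (temperature) equilibrium for one node.
#' Moments reproduce the density/temperature and momentum exactly.
#'
#' @param rho Density (flow) or temperature (d3q7 advection-diffusion).
#' @param u Velocity vector, lattice units.
#' @param model A [lattice_model()].
#' @param mach_limit Maximum allowed `|u|` (lattice units).
#' @param on_mach `"warn"` clamps `u` to the limit with a warning; `"error"`
#'   aborts.
#' @return Vector of q equilibrium populations.
#' @export
equilibrium_f <- function(rho, u = c(0, 0, 0), model = lattice_model("d3q19"),
                          mach_limit = 0.1, on_mach = c("warn", "error")) {
  on_mach <- match.arg(on_mach)
  u <- vec3(u, "u")
  speed <- sqrt(sum(u^2))
  if (speed > mach_limit) {
    if (on_mach == "error")
      abort(sprintf("|u| = %.3g exceeds the lattice Mach limit %.3g.",
                    speed, mach_limit))
    warn(sprintf("|u| = %.3g exceeds the Mach limit %.3g; clamping.",
                 speed, mach_limit))
    u <- u * mach_limit / speed
  }
  eu <- drop(model$e %*% u)
  if (model$type == "d3q19")
    model$w * rho * (1 + 3 * eu + 4.5 * eu^2 - 1.5 * sum(u^2))
  else
    model$w * rho * (1 + eu / model$cs2)
}

#' Discrete forcing terms
#'
#' Guo forcing for one node: the discrete contributions whose zeroth moment
#' vanishes and whose first moment equals `(1 - 1/(2 tau)) * F`.
#' @param f_node Body-force vector (lattice units).
#' @param u Node velocity (lattice units, including the half-force shift).
#' @param tau Relaxation time.
#' @param model A [lattice_model()] (flow stencil).
#' @return Vector of q forcing terms.
#' @export
forcing_terms <- function(f_node, u, tau, model = lattice_model("d3q19")) {
  u <- vec3(u, "u")
  f_node <- vec3(f_node, "f_node")
  eu <- drop(model$e %*% u)
  ef <- drop(model$e %*% f_node)
  uf <- sum(u * f_node)
  (1 - 1 / (2 * tau)) * model$w * (3 * (ef - uf) + 9 * eu * ef)
}

#' Map SI transport properties onto lattice units
#'
#' Chooses the physical time step so the flow relaxation time falls at
#' `tau_f`; kinematic viscosity in lattice units is `cs2 (tau_f - 1/2)`.
#' @param spacing Node spacing dx (m).
#' @param viscosity Kinematic viscosity (m^2/s).
#' @param tau_f Target relaxation time (> 0.5; 0.6-1.2 is a good range).
#' @return List with `dx`, `dt`, `tau_f`, and converter functions
#'   `to_lattice_velocity` / `from_lattice_velocity` (exact inverses).
#' @export
lbm_units <- function(spacing, viscosity, tau_f = 0.9) {
  assert_scalar_num(tau_f, "tau_f", 0.5, strict_lower = TRUE)
  dt <- (tau_f - 0.5) / 3 * spacing^2 / viscosity
  scale <- spacing / dt
  list(dx = spacing, dt = dt, tau_f = tau_f,
       to_lattice_velocity = function(u) u / scale,
       from_lattice_velocity = function(u) u * scale)
}

#' Boundary configuration for the flow solver
#'
#' Solid voxels always impose halfway bounce-back (the no-slip wall sits
#' midway between the fluid and solid nodes).  The outer domain is either
#' fully periodic or has fixed-density (pressure) z-faces with periodic x/y;
#' solid nodes on a pressure face simply keep their bounce-back behaviour.
#' @param kind `"periodic"` or `"pressure"`.
#' @param rho_in,rho_out Imposed densities at the z = 0 / z = max faces.
#' @export
flow_boundary <- function(kind = c("periodic", "pressure"),
                          rho_in = 1, rho_out = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rho_in = rho_in, rho_out = rho_out),
            class = "flow_boundary")
}

#' Initialize a flow state
#'
#' Populations start at the uniform equilibrium.
#' @param lattice A `porous_lattice` providing geometry.
#' @param tau_f Relaxation time (> 0.5).
#' @param rho0 Initial density (lattice units).
#' @param u0 Initial velocity (lattice units).
#' @return A `flow_state`.
#' @export
flow_state <- function(lattice, tau_f = 0.9, rho0 = 1, u0 = c(0, 0, 0)) {
  stopifnot(inherits(lattice, "porous_lattice"))
  assert_scalar_num(tau_f, "tau_f", 0.5, strict_lower = TRUE)
  nn <- dim(lattice$occupancy)
  n <- prod(nn)
  feq <- equilibrium_f(rho0, u0)
  f <- rep(feq, each = n)
  f[rep(lattice$occupancy != 0L, 19)] <- 0
  structure(list(f = f, tau = tau_f, dim = nn), class = "flow_state")
}

#' Advance the flow field
#'
#' One (or more) BGK collide-stream cycles with Guo forcing.  Detects
#' instability (non-finite density or velocity beyond `max_u`) and aborts
#' naming the failing step and the maximum velocity.
#'
#' @param state A [flow_state()].
#' @param lattice The `porous_lattice` the state lives on.
#' @param force Body force in lattice units: length-3 vector (uniform) or a
#'   `3 * n` vector/array (per-node field).
#' @param steps Number of cycles.
#' @param boundary A [flow_boundary()].
#' @param max_u Stability guard on the lattice velocity.
#' @return The updated `flow_state`.
#' @export
step_flow <- function(state, lattice, force = c(0, 0, 0), steps = 1,
                      boundary = flow_boundary("periodic"), max_u = 0.1) {
  stopifnot(inherits(state, "flow_state"))
  res <- cpp_flow_run(state$f, lattice$occupancy, state$dim, state$tau,
                      as.numeric(force), as.integer(steps),
                      if (boundary$kind == "pressure") 1L else 0L,
                      boundary$rho_in, boundary$rho_out, max_u)
  if (!isTRUE(res$ok))
    abort(sprintf("flow solver unstable at step %d (max |u| = %.3g).",
                  res$failed_step, res$max_u))
  state$f <- res$f
  state$mass <- res$mass
  state
}

#' Macroscopic flow fields
#'
#' Density and velocity moments; when the body force is supplied the velocity
#' includes the half-force correction consistent with the forcing scheme.
#' @param state A `flow_state`.
#' @param lattice The lattice.
#' @param force Optional body force (as in [step_flow()]).
#' @return List of 3-d arrays `rho`, `ux`, `uy`, `uz` (lattice units).
#' @export
flow_moments <- function(state, lattice, force = NULL) {
  m <- cpp_flow_moments(state$f, lattice$occupancy, state$dim,
                        if (is.null(force)) NULL else as.numeric(force))
  lapply(m, array, dim = state$dim)
}

#' Initialize a temperature state
#'
#' @param lattice A `porous_lattice`.
#' @param tau_g Thermal relaxation time (> 0.5); lattice diffusivity is
#'   `(tau_g - 1/2) / 4`.
#' @param T0 Initial (reference) temperature.
#' @return A `thermal_state` with an empty source set.
#' @export
thermal_state <- function(lattice, tau_g = 0.9, T0 = 0) {
  stopifnot(inherits(lattice, "porous_lattice"))
  assert_scalar_num(tau_g, "tau_g", 0.5, strict_lower = TRUE)
  nn <- dim(lattice$occupancy)
  n <- prod(nn)
  model <- lattice_model("d3q7")
  g <- rep(model$w * T0, each = n)
  g[rep(lattice$occupancy != 0L, 7)] <- 0
  structure(list(g = g, tau = tau_g, dim = nn, T0 = T0,
                 sources = list(nodes = integer(0), T = numeric(0))),
            class = "thermal_state")
}

#' Pin heated-particle nodes to a fixed temperature
#'
#' Marks the lattice nodes hosting the given particle positions as Dirichlet
#' sources held at `T_p` before every streaming step (heated nanoparticles).
#' With no particles the state is returned unchanged.
#'
#' @param tstate A [thermal_state()].
#' @param positions `n x 3` matrix of particle positions (m), or `NULL`.
#' @param T_p Imposed particle temperature.
#' @param lattice The lattice (for the node spacing).
#' @return The updated `thermal_state`.
#' @export
impose_np_heat <- function(tstate, positions, T_p, lattice) {
  if (is.null(positions) || NROW(positions) == 0L) return(tstate)
  positions <- matrix(positions, ncol = 3)
  nn <- tstate$dim
  ijk <- floor(positions / lattice$spacing)
  ijk <- sweep(ijk, 2, nn, function(i, n) ((i %% n) + n) %% n)
  nodes <- as.integer(ijk[, 1] + nn[1] * (ijk[, 2] + nn[2] * ijk[, 3]))
  keep <- lattice$occupancy[nodes + 1L] == 0L
  tstate$sources <- list(nodes = unique(nodes[keep]),
                         T = rep(T_p, length(unique(nodes[keep]))))
  tstate
}

#' Advance the temperature field
#'
#' Advection-diffusion cycles of the temperature distribution in a frozen
#' velocity field (or quiescent fluid), with bounce-back (adiabatic) solid
#' surfaces and any Dirichlet sources applied each step.
#' @param tstate A [thermal_state()].
#' @param lattice The lattice.
#' @param velocity Optional moments list from [flow_moments()] (lattice
#'   units); `NULL` for a quiescent fluid.
#' @param steps Number of cycles.
#' @return The updated `thermal_state`.
#' @export
step_temperature <- function(tstate, lattice, velocity = NULL, steps = 1) {
  stopifnot(inherits(tstate, "thermal_state"))
  uf <- if (is.null(velocity)) NULL else
    list(ux = as.numeric(velocity$ux), uy = as.numeric(velocity$uy),
         uz = as.numeric(velocity$uz))
  res <- cpp_temp_run(tstate$g, lattice$occupancy, tstate$dim, tstate$tau,
                      uf, as.integer(steps), tstate$sources$nodes,
                      tstate$sources$T)
  tstate$g <- res$g
  tstate$heat <- res$heat
  tstate
}

#' Temperature field
#' @param tstate A `thermal_state`.
#' @return 3-d array of node temperatures.
#' @export
temperature_field <- function(tstate) {
  array(cpp_temp_moments(tstate$g, tstate$dim), dim = tstate$dim)
}

#' Boussinesq buoyancy force field
#'
#' `F = beta (T0 - T) rho g` per node, in lattice units, ready to pass to
#' [step_flow()]; the discrete forcing terms assembled from it carry the
#' `(1 - 1/(2 tau_f))` prefactor (see [forcing_terms()]).
#' @param tstate A `thermal_state`.
#' @param rho0 Reference density (lattice units).
#' @param gravity Gravity vector (lattice units).
#' @param beta Thermal expansion coefficient (1/K).
#' @param T0 Reference temperature; defaults to the state's.
#' @return A `3 * n` force field vector.
#' @export
boussinesq_force <- function(tstate, rho0 = 1, gravity = c(0, 0, -1),
                             beta = 1e-3, T0 = NULL) {
  T0 <- T0 %||% tstate$T0
  temp <- cpp_temp_moments(tstate$g, tstate$dim)
  amp <- beta * (T0 - temp) * rho0
  gravity <- vec3(gravity, "gravity")
  c(amp * gravity[1], amp * gravity[2], amp * gravity[3])
}

#' Coupled thermal-flow run
#'
#' Alternates flow and temperature steps with the Boussinesq force assembled
#' from the instantaneous temperature field; heated-particle nodes are held
#' at `T_p`.  Used to compute the natural-convection velocity field driven by
#' nanoparticle heating, which can then be frozen for particle transport.
#'
#' @param lattice A `porous_lattice`.
#' @param hot_positions `n x 3` matrix of heated-particle positions (m).
#' @param T_p Particle temperature (K).
#' @param T0 Reference tissue temperature (K).
#' @param tau_f,tau_g Relaxation times.
#' @param beta Thermal expansion coefficient (1/K).
#' @param gravity Gravity vector (lattice units).
#' @param steps Number of coupled cycles.
#' @param max_u Stability guard.
#' @return List with `flow` (a `flow_state`), `thermal` (a `thermal_state`)
#'   and the velocity arrays `ux`, `uy`, `uz` (lattice units).
#' @export
run_thermal_flow <- function(lattice, hot_positions, T_p, T0 = 310,
                             tau_f = 0.9, tau_g = 0.9, beta = 3e-4,
                             gravity = c(0, 0, -1e-5), steps = 2000,
                             max_u = 0.3) {
  fs <- flow_state(lattice, tau_f)
  ts <- thermal_state(lattice, tau_g, T0)
  ts <- impose_np_heat(ts, hot_positions, T_p, lattice)
  res <- cpp_coupled_run(fs$f, ts$g, lattice$occupancy, fs$dim, tau_f, tau_g,
                         beta, T0, vec3(gravity, "gravity"),
                         ts$sources$nodes, ts$sources$T,
                         as.integer(steps), max_u)
  if (!isTRUE(res$ok))
    abort(sprintf("coupled thermal flow unstable at step %d.", res$failed_step))
  fs$f <- res$f
  ts$g <- res$g
  list(flow = fs, thermal = ts,
       ux = array(res$ux, fs$dim), uy = array(res$uy, fs$dim),
       uz = array(res$uz, fs$dim))
}
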