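test_that("the exponential integrator matches a fine-step ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:5) {
    tau_p <- 10^runif(1, -7, -5)
    dt <- 10^runif(1, -6, -4)
    u <- runif(3, -1e-4, 1e-4)
    up <- runif(3, -1e-4, 1e-4)
    sa <- runif(3, -1e3, 1e3)
    v_exact <- update_velocity(up, u, sa, dt, tau_p)
    x_exact <- update_displacement(up, u, sa, dt, tau_p)
    rhs <- function(t, y, p) {
      v <- y[4:6]
      list(c(v, (u - v) / tau_p + sa))
    }
    sol <- deSolve::ode(c(rep(0, 3), up), c(0, dt), rhs, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-22)
    y <- sol[2, -1]
    expect_equal(v_exact, unname(y[4:6]), tolerance = 1e-6)
    expect_equal(x_exact, unname(y[1:3]), tolerance = 1e-6)
  }
})

test_that("integrator limits: fixed point, terminal velocity, pure advection", {
  u <- c(1e-6, -2e-6, 0)
  expect_equal(update_velocity(u, u, c(0, 0, 0), 1e-4, 1e-9), u)
  # dt >> tau_p relaxes to the terminal velocity u + tau_p * Sigma_a
  sa <- c(100, 0, -50)
  expect_equal(update_velocity(c(0, 0, 0), u, sa, 1, 1e-9), u + 1e-9 * sa)
  expect_equal(update_displacement(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                   1e-3, 1e-9), c(0, 0, 0))
  expect_equal(update_displacement(u, u, c(0, 0, 0), 1e-3, 1e-9),
               u * 1e-3, tolerance = 1e-6)
})

test_that("migration probabilities implement the directional max(0, .) rule", {
  expect_equal(unname(migration_probabilities(c(0, 0, 0), 50e-9)), rep(0, 6))
  p <- migration_probabilities(c(50e-9, 0, 0), 50e-9)
  expect_equal(unname(p), c(1, 0, 0, 0, 0, 0))
  p2 <- migration_probabilities(c(20e-9, -10e-9, 5e-9), 50e-9)
  expect_equal(unname(p2), c(0.4, 0, 0, 0.2, 0.1, 0))
  # opposing directions always have zero probability
  expect_true(all(p2[c("-x", "+y", "-z")] == 0))
  expect_error(migration_probabilities(c(60e-9, 0, 0), 50e-9), "sub-step")
})

test_that("realized lattice moves are unbiased estimates of the displacement", {
  dxp <- c(18e-9, -31e-9, 7e-9)
  dx <- 50e-9
  mv <- nanolga:::cpp_sample_moves(dxp, dx, 2e5, seed = 9L)
  se <- dx * sqrt(abs(dxp) / dx) / sqrt(2e5)
  for (a in 1:3)
    expect_lt(abs(mean(mv[, a]) - dxp[a]), 4 * se[a] + 1e-15)
})

test_that("ensembles are deterministic under a fixed seed", {
  lat <- small_ecm(0.95, n = 24L)
  props <- np_props()
  ctrl <- quick_control()
  args <- list(lat, props, ctrl, surface_chemistry(psi_wall = 0.01),
               n_steps = 300, n_particles = 10, replicates = 2,
               record_every = 10, seed = 42L)
  s1 <- do.call(simulate_particles, args)
  s2 <- do.call(simulate_particles, args)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$events, s2$events)
})

test_that("zero forces and zero flow leave particles stationary", {
  lat <- free_fluid_domain(50e-9, 16L)
  props <- np_props()
  sim <- simulate_particles(lat, props, quick_control(), chem = NULL,
                            temperature = 0, n_steps = 200, n_particles = 8,
                            replicates = 1, record_every = 20, seed = 1L)
  expect_equal(max(abs(sim$trajectories[[1]])), 0)
})

test_that("particles never enter solid nodes", {
  lat <- lone_pore()
  props <- np_props()
  sim <- simulate_particles(lat, props, quick_control(), chem = NULL,
                            n_steps = 500, n_particles = 5, replicates = 1,
                            record_every = 10, init = "uniform", seed = 3L)
  # the only fluid voxel is walled in on all sides: no displacement possible
  expect_equal(max(abs(sim$trajectories[[1]])), 0)
})

test_that("fluctuation-dissipation mode recovers the Einstein diffusivity", {
  mu <- 0.7e-3
  for (pref in c(6, 3)) {
    props <- np_props(drag_prefactor = pref)
    D_se <- kB * 310 / (pref * pi * mu * props$diameter)
    ctrl <- transport_control(2e-6, brownian = "fluctuation_dissipation",
                              moves = "continuous")
    sim <- simulate_particles(free_fluid_domain(25e-9, 16L), props, ctrl,
                              chem = NULL, mu = mu, n_steps = 8000,
                              n_particles = 40, replicates = 12,
                              record_every = 20, init = "uniform", seed = 5L)
    est <- ensemble_diffusion(sim)
    expect_lt(abs(est$mean_D - D_se) / D_se, 0.05)
  }
})

test_that("free diffusion is independent of the time step in FD mode", {
  props <- np_props()
  ds <- vapply(c(2e-6, 8e-6), function(dt) {
    ctrl <- transport_control(dt, brownian = "fluctuation_dissipation",
                              moves = "continuous")
    sim <- simulate_particles(free_fluid_domain(25e-9, 16L), props, ctrl,
                              chem = NULL, n_steps = round(0.016 / dt),
                              n_particles = 40, replicates = 10,
                              record_every = round(4e-5 / dt),
                              init = "uniform", seed = 8L)
    ensemble_diffusion(sim)$mean_D
  }, numeric(1))
  expect_lt(abs(ds[2] - ds[1]) / ds[1], 0.08)
})

test_that("strongly repulsive walls prevent adhesion; attractive walls bind", {
  lat <- small_ecm(0.92, n = 32L, seed = 13L)
  ctrl <- quick_control()
  # like-charged particle and wall: electrostatic barrier blocks attachment
  rep_chem <- surface_chemistry(psi_wall = -20e-3)
  sim_rep <- simulate_particles(lat, np_props(zeta = -20e-3), ctrl, rep_chem,
                                n_steps = 1500, n_particles = 20,
                                replicates = 2, record_every = 50, seed = 6L)
  expect_identical(sum(sim_rep$events$n_adhere), 0L)
  # neutral particle, attractive van der Waals wall: adhesion occurs
  sim_att <- simulate_particles(lat, np_props(zeta = 0), ctrl,
                                surface_chemistry(psi_wall = 0),
                                n_steps = 1500, n_particles = 20,
                                replicates = 2, record_every = 50, seed = 6L)
  expect_gt(sum(sim_att$events$n_adhere), 0L)
})

test_that("adhesion decision follows the barrier force balance", {
  # zero external field, attractive wall, particle at contact: the barrier is
  # zero, the drive finite, so the contact must lead to adhesion
  ch <- surface_chemistry(psi_wall = 0)
  prof <- nanolga:::cpp_wall_profile(
    c(1e-9, 5e-9, 20e-9, 80e-9),
    c(ch[c("hamaker", "eps_r", "kappa", "d0", "lambda", "cutoff", "d_park")],
      list(psi_particle = 0, psi_wall = 0, fab_contact = 0, dp = 50e-9)))
  expect_equal(prof$barrier, 0)
  # a hydrophilic silica-like coating produces a finite barrier
  prof2 <- nanolga:::cpp_wall_profile(
    c(1e-9, 5e-9, 20e-9, 80e-9),
    c(ch[c("hamaker", "eps_r", "kappa", "d0", "lambda", "cutoff", "d_park")],
      list(psi_particle = 0, psi_wall = 0, fab_contact = 1.12e-10,
           dp = 50e-9)))
  expect_gt(prof2$barrier, 2 * kB * 310 / 50e-9)
})

test_that("magnetic gradient increases detachment and biases transport to +z", {
  lat <- generate_tumor(geometry_spec("tumor", cell_volume_fraction = 0.35,
                                      n_nodes = 40L, domain_size = 40e-6,
                                      seed = 4L))
  props <- np_props(zeta = 0)
  ctrl <- transport_control(1e-2)
  chem <- surface_chemistry(psi_wall = -15e-3)
  runs <- lapply(c(0, 6000), function(g)
    simulate_particles(lat, props, ctrl, chem, mu = 0.02,
                       grad_b = c(0, 0, g), n_steps = 800, n_particles = 40,
                       replicates = 4, record_every = 10, seed = 12L))
  rel <- vapply(runs, function(s) sum(s$events$n_release), integer(1))
  expect_gt(rel[2], rel[1])
  # mean z-displacement under the +z gradient exceeds the x displacement
  tr <- runs[[2]]$trajectories[[1]]
  nr <- dim(tr)[1]
  expect_gt(mean(tr[nr, , 3] - tr[1, , 3]), abs(mean(tr[nr, , 1] - tr[1, , 1])))
})
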