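test_that("velocity sets satisfy the moment identities", {
  for (type in c("d3q19", "d3q7")) {
    m <- lattice_model(type)
    expect_equal(sum(m$w), 1)
    expect_equal(drop(t(m$w) %*% m$e), c(0, 0, 0))
    second <- t(m$e) %*% diag(m$w) %*% m$e
    expect_equal(second, m$cs2 * diag(3), tolerance = 1e-12)
  }
})

test_that("equilibrium reproduces its moments and parity", {
  model <- lattice_model("d3q19")
  expect_equal(equilibrium_f(1.3, c(0, 0, 0)), 1.3 * model$w)
  set.seed(1)
  for (i in 1:5) {
    rho <- runif(1, 0.5, 2)
    u <- runif(3, -0.02, 0.02)
    fe <- equilibrium_f(rho, u)
    expect_equal(sum(fe), rho)
    expect_equal(drop(t(fe) %*% model$e), rho * u)
    # parity: reversing u permutes populations by direction reversal
    fe_rev <- equilibrium_f(rho, -u)
    opp <- vapply(seq_len(19), function(i)
      which(colSums(abs(t(model$e) + model$e[i, ])) == 0), integer(1))
    expect_equal(fe_rev, fe[opp])
  }
  expect_warning(equilibrium_f(1, c(0.5, 0, 0)), "clamp")
  expect_error(equilibrium_f(1, c(0.5, 0, 0), on_mach = "error"), "Mach")
})

test_that("discrete forcing terms carry the correct moments", {
  model <- lattice_model("d3q19")
  set.seed(2)
  for (i in 1:5) {
    Fn <- runif(3, -1e-4, 1e-4)
    u <- runif(3, -0.05, 0.05)
    tau <- runif(1, 0.6, 1.2)
    Fa <- forcing_terms(Fn, u, tau, model)
    expect_equal(sum(Fa), 0, tolerance = 1e-18)  # no mass injection
    expect_equal(drop(t(Fa) %*% model$e), (1 - 1 / (2 * tau)) * Fn)
  }
})

test_that("a uniform rest state is a fixed point and mass is conserved", {
  lat <- free_fluid_domain(1e-6, 8L)
  st <- flow_state(lat, tau_f = 0.8)
  st2 <- step_flow(st, lat, steps = 5)
  expect_equal(st2$f, st$f, tolerance = 1e-14)
  # perturbed state: mass exactly conserved under periodic force-free steps
  sw <- shear_wave_state(lat, 0.8)
  mass0 <- sum(sw$f)
  sw2 <- step_flow(sw, lat, steps = 20)
  expect_equal(sum(sw2$f), mass0, tolerance = 1e-12)
})

test_that("body-force channel flow converges to the parabolic profile", {
  n <- c(4L, 4L, 16L)
  occ <- array(0L, n)
  occ[, , 1] <- 1L
  occ[, , n[3]] <- 1L   # two solid walls normal to z
  lat <- nanolga:::new_porous_lattice(occ, 1e-6, "ecm")
  tau <- 0.9
  g <- 1e-6
  st <- flow_state(lat, tau)
  st <- step_flow(st, lat, force = c(g, 0, 0), steps = 6000)
  mom <- flow_moments(st, lat, force = c(g, 0, 0))
  ux <- mom$ux[1, 1, ]
  nu <- (tau - 0.5) / 3
  H <- n[3] - 2             # fluid layers; walls sit half-way outside them
  z <- seq_len(n[3]) - 1.5  # distance from the lower wall plane
  u_ref <- g / (2 * nu) * z * (H - z)
  inner <- 2:(n[3] - 1)
  expect_lt(abs(ux[n[3] / 2] - u_ref[n[3] / 2]) / u_ref[n[3] / 2], 0.01)
  expect_lt(max(abs(ux[inner] - u_ref[inner])) / max(u_ref), 0.02)
})

test_that("shear-wave decay recovers the viscosity-relaxation relation", {
  lat <- free_fluid_domain(1e-6, 8L)
  lat$occupancy <- array(0L, c(4L, 4L, 32L))
  lat <- nanolga:::new_porous_lattice(lat$occupancy, 1e-6, "free")
  tau <- 0.8
  sw <- shear_wave_state(lat, tau, amp = 0.005)
  k <- 2 * pi / 32
  amp_at <- function(st) {
    mom <- flow_moments(st, lat)
    ux <- mom$ux[1, 1, ]
    2 * mean(ux * sin(k * (seq_len(32) - 0.5)))
  }
  a0 <- amp_at(sw)
  nsteps <- 200
  sw <- step_flow(sw, lat, steps = nsteps)
  a1 <- amp_at(sw)
  nu_meas <- log(a0 / a1) / (k^2 * nsteps)
  nu_theory <- (tau - 0.5) / 3
  expect_lt(abs(nu_meas - nu_theory) / nu_theory, 0.02)
})

test_that("steady conduction between fixed-temperature planes is linear", {
  n <- c(4L, 4L, 20L)
  lat <- nanolga:::new_porous_lattice(array(0L, n), 1e-6, "free")
  ts <- thermal_state(lat, tau_g = 0.9, T0 = 0)
  # Dirichlet planes: z = 0 at T = 1, z = max at T = 0
  nodes0 <- seq_len(n[1] * n[2]) - 1L
  nodesN <- nodes0 + n[1] * n[2] * (n[3] - 1L)
  ts$sources <- list(nodes = c(nodes0, nodesN),
                     T = c(rep(1, length(nodes0)), rep(0, length(nodesN))))
  ts <- step_temperature(ts, lat, steps = 6000)
  Tz <- temperature_field(ts)[1, 1, ]
  lin <- seq(1, 0, length.out = n[3])
  expect_lt(max(abs(Tz - lin)), 0.005)
})

test_that("thermal wave decay recovers the diffusivity-relaxation relation", {
  n <- c(4L, 4L, 32L)
  lat <- nanolga:::new_porous_lattice(array(0L, n), 1e-6, "free")
  tau_g <- 0.8
  ts <- thermal_state(lat, tau_g, T0 = 1)
  k <- 2 * pi / 32
  prof <- 1 + 0.1 * sin(k * (seq_len(32) - 0.5))
  model <- lattice_model("d3q7")
  nvox <- prod(n)
  g <- numeric(7 * nvox)
  for (kk in seq_len(n[3])) {
    sel <- (kk - 1) * n[1] * n[2] + seq_len(n[1] * n[2])
    for (q in 1:7) g[sel + nvox * (q - 1)] <- model$w[q] * prof[kk]
  }
  ts$g <- g
  amp_at <- function(ts) {
    Tz <- temperature_field(ts)[1, 1, ]
    2 * mean((Tz - mean(Tz)) * sin(k * (seq_len(32) - 0.5)))
  }
  a0 <- amp_at(ts)
  ts <- step_temperature(ts, lat, steps = 150)
  a1 <- amp_at(ts)
  alpha_meas <- log(a0 / a1) / (k^2 * 150)
  alpha_theory <- (tau_g - 0.5) / 4
  expect_lt(abs(alpha_meas - alpha_theory) / alpha_theory, 0.02)
})

test_that("a temperature pulse advects at the flow speed and diffuses", {
  n <- c(4L, 4L, 64L)
  lat <- nanolga:::new_porous_lattice(array(0L, n), 1e-6, "free")
  tau_g <- 0.7
  uadv <- 0.04
  ts <- thermal_state(lat, tau_g, T0 = 0)
  model <- lattice_model("d3q7")
  nvox <- prod(n)
  z <- seq_len(n[3]) - 0.5
  sig0 <- 3
  prof <- exp(-(z - 20)^2 / (2 * sig0^2))
  g <- numeric(7 * nvox)
  for (kk in seq_len(n[3])) {
    sel <- (kk - 1) * n[1] * n[2] + seq_len(n[1] * n[2])
    feq <- model$w * prof[kk] * (1 + 4 * model$e[, 3] * uadv)
    for (q in 1:7) g[sel + nvox * (q - 1)] <- feq[q]
  }
  ts$g <- g
  vel <- list(ux = array(0, n), uy = array(0, n), uz = array(uadv, n))
  nsteps <- 300
  ts <- step_temperature(ts, lat, velocity = vel, steps = nsteps)
  Tz <- temperature_field(ts)[1, 1, ]
  # moments of the advected-diffused Gaussian
  m0 <- sum(Tz); mu1 <- sum(Tz * z) / m0
  sig2 <- sum(Tz * (z - mu1)^2) / m0
  alpha <- (tau_g - 0.5) / 4
  expect_lt(abs(mu1 - (20 + uadv * nsteps)), 0.5)
  expect_lt(abs(sig2 - (sig0^2 + 2 * alpha * nsteps)) / sig2, 0.05)
})

test_that("a fixed hot node in quiescent fluid gives a 1/r steady field", {
  n <- 24L
  lat <- nanolga:::new_porous_lattice(array(0L, rep(n, 3)), 1e-6, "free")
  ts <- thermal_state(lat, tau_g = 0.9, T0 = 0)
  lin <- function(i, j, k) (i - 1) + n * ((j - 1) + n * (k - 1))
  # cold faces + one hot node at the center
  faces <- integer(0)
  for (i in 1:n) for (j in 1:n)
    faces <- c(faces, lin(i, j, 1), lin(i, j, n), lin(i, 1, j), lin(i, n, j),
               lin(1, i, j), lin(n, i, j))
  c0 <- n / 2
  ts$sources <- list(nodes = c(unique(faces), lin(c0, c0, c0)),
                     T = c(rep(0, length(unique(faces))), 1))
  ts <- step_temperature(ts, lat, steps = 4000)
  Tf <- temperature_field(ts)
  rr <- 3:7
  vals <- vapply(rr, function(r) Tf[c0 + r, c0, c0], numeric(1))
  # away from source and boundaries the field follows the point-source form
  # A/r + B (B absorbs the cold-boundary image contribution)
  fit <- lm(vals ~ I(1 / rr))
  expect_lt(max(abs(residuals(fit))) / diff(range(vals)), 0.05)
})

test_that("Boussinesq forcing vanishes at T0 and points against gravity", {
  lat <- free_fluid_domain(1e-6, 6L)
  ts <- thermal_state(lat, 0.9, T0 = 310)
  f0 <- boussinesq_force(ts, gravity = c(0, 0, -1), beta = 1e-3, T0 = 310)
  expect_equal(max(abs(f0)), 0)
  # heat part of the domain: buoyancy must push hot fluid upward
  n <- prod(dim(lat$occupancy))
  hot <- rep(320, n)
  model <- lattice_model("d3q7")
  ts$g <- as.numeric(outer(hot, model$w))
  fh <- boussinesq_force(ts, gravity = c(0, 0, -1), beta = 1e-3, T0 = 310)
  fz <- fh[(2 * n + 1):(3 * n)]
  expect_true(all(fz > 0))
})

test_that("hotter particles drive faster steady natural convection", {
  lat <- small_ecm(0.95, n = 16L, seed = 21L)
  pos <- matrix(c(8, 8, 8) * lat$spacing, 1)
  peak <- vapply(c(312, 316), function(Tp) {
    tf <- run_thermal_flow(lat, pos, Tp, T0 = 310, tau_f = 0.9, tau_g = 0.9,
                           beta = 1e-3, gravity = c(0, 0, -1e-4), steps = 600)
    max(sqrt(tf$ux^2 + tf$uy^2 + tf$uz^2))
  }, numeric(1))
  expect_gt(peak[2], peak[1])
  # no particles: the temperature state is unchanged by the source setter
  ts <- thermal_state(lat, 0.9, 310)
  expect_identical(impose_np_heat(ts, NULL, 316, lat), ts)
})

test_that("zero pressure difference drives no net flow", {
  n <- c(6L, 6L, 12L)
  occ <- array(0L, n)
  occ[1, , ] <- 1L; occ[n[1], , ] <- 1L   # duct walls
  lat <- nanolga:::new_porous_lattice(occ, 1e-6, "ecm")
  st <- flow_state(lat, 0.9)
  st <- step_flow(st, lat, steps = 500,
                  boundary = flow_boundary("pressure", rho_in = 1, rho_out = 1))
  mom <- flow_moments(st, lat)
  expect_lt(max(abs(mom$uz)), 1e-10)
  # a finite density difference does drive flow through the duct
  st2 <- flow_state(lat, 0.9)
  st2 <- step_flow(st2, lat, steps = 2000,
                   boundary = flow_boundary("pressure", rho_in = 1.001,
                                            rho_out = 0.999))
  mom2 <- flow_moments(st2, lat)
  expect_gt(mean(mom2$uz[occ == 0L]), 1e-6)
})

test_that("the instability guard reports the failing step", {
  lat <- free_fluid_domain(1e-6, 6L)
  st <- flow_state(lat, 0.51)
  expect_error(step_flow(st, lat, force = c(0.5, 0, 0), steps = 500),
               "unstable at step")
})

test_that("unit mapping round-trips velocities exactly", {
  u <- lbm_units(50e-9, 7e-7, tau_f = 0.9)
  expect_equal(u$from_lattice_velocity(u$to_lattice_velocity(0.123)), 0.123)
  # viscosity implied by the mapping matches the relaxation relation
  expect_equal((u$tau_f - 0.5) / 3 * u$dx^2 / u$dt, 7e-7)
})

test_that("mirrored geometry and forcing give mirrored flow fields", {
  set.seed(33)
  n <- c(6L, 6L, 10L)
  occ <- array(ifelse(runif(prod(n)) < 0.15, 1L, 0L), n)
  occ_m <- occ[, , n[3]:1]   # mirror through the z mid-plane
  lat <- nanolga:::new_porous_lattice(occ, 1e-6, "ecm")
  lat_m <- nanolga:::new_porous_lattice(occ_m, 1e-6, "ecm")
  g <- 5e-7
  st <- step_flow(flow_state(lat, 0.8), lat, force = c(0, 0, g), steps = 300)
  st_m <- step_flow(flow_state(lat_m, 0.8), lat_m, force = c(0, 0, -g),
                    steps = 300)
  uz <- flow_moments(st, lat, force = c(0, 0, g))$uz
  uz_m <- flow_moments(st_m, lat_m, force = c(0, 0, -g))$uz
  expect_lt(max(abs(uz_m[, , n[3]:1] + uz)), 1e-9 * max(abs(uz)))
})
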