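test_that("drag force follows the printed law", {
  expect_equal(drag_force(c(1, 2, 3) * 1e-6, c(1, 2, 3) * 1e-6, 0.7e-3, 50e-9),
               c(0, 0, 0))
  f <- drag_force(c(1e-6, 0, 0), c(0, 0, 0), 0.7e-3, 50e-9)
  expect_gt(f[1], 0)  # points from particle velocity toward fluid velocity
  # direct arithmetic: 6 pi mu d_p |u - u_p|
  expect_equal(f[1], 6 * pi * 0.7e-3 * 50e-9 * 1e-6)
  f3 <- drag_force(c(1e-6, 0, 0), c(0, 0, 0), 0.7e-3, 50e-9, prefactor = 3)
  expect_equal(f3[1], f[1] / 2)
})

test_that("Brownian kicks have the printed magnitude and isotropic direction", {
  expect_equal(brownian_force(0, 50e-9), matrix(0, 1, 3))
  set.seed(3)
  f <- brownian_force(310, 50e-9, n = 1e5)
  mag <- sqrt(rowSums(f^2))
  expect_equal(mean(mag), 2 * kB * 310 / 50e-9, tolerance = 1e-12)
  expect_lt(diff(range(mag)), 1e-18)  # fixed magnitude
  # empirical mean direction vanishes for an isotropic distribution
  expect_lt(sqrt(sum(colMeans(f / mag)^2)), 0.02)
})

test_that("magnetic force is V_p M_sat grad B along the gradient", {
  props <- np_props()
  expect_equal(magnetic_force(props, c(0, 0, 0)), c(0, 0, 0))
  f <- magnetic_force(props, c(0, 0, 6000))
  expect_equal(f[1:2], c(0, 0))
  expect_equal(f[3], pi / 6 * (50e-9)^3 * 4.8e5 * 6000)
})

test_that("van der Waals attraction follows the inverse-square law", {
  ch <- surface_chemistry()
  expect_lt(abs(vdw_force(ch, 50e-9, 1)), 1e-27)   # vanishes far away
  f10 <- vdw_force(ch, 50e-9, 10e-9)
  f5 <- vdw_force(ch, 50e-9, 5e-9)
  expect_equal(f5 / f10, 4)        # halving d quadruples the magnitude
  expect_equal(f10, -1e-20 * 50e-9 / (12 * (10e-9)^2))
  expect_lt(f10, 0)                # attractive for positive Hamaker constant
})

test_that("double-layer force has the right sign, limits and decay", {
  ch0 <- surface_chemistry(psi_particle = 0, psi_wall = 0)
  expect_equal(electrostatic_force(ch0, 50e-9, 5e-9), 0)
  ch <- surface_chemistry(psi_particle = -10e-3, psi_wall = -10e-3)
  # like-signed potentials repel at small separations
  expect_gt(electrostatic_force(ch, 50e-9, 1e-9), 0)
  # asymptotic exp(-kappa d) decay: one Debye length reduces F by 1/e
  d <- 80e-9
  r <- electrostatic_force(ch, 50e-9, d + ch$debye_length) /
       electrostatic_force(ch, 50e-9, d)
  expect_equal(r, exp(-1), tolerance = 0.01)
})

test_that("acid-base force and the surface-tension combination rule agree", {
  ch0 <- surface_chemistry(delta_g_ab = 0)
  expect_equal(acid_base_force(ch0, 50e-9, 1e-9), 0)
  ch <- surface_chemistry(delta_g_ab = 2e-3)
  expect_equal(acid_base_force(ch, 50e-9, ch$d0), pi * 50e-9 * 2e-3)
  # worked combination: water against two identical monopolar surfaces
  gw <- c(plus = 25.5e-3, minus = 25.5e-3)
  g1 <- c(plus = 0, minus = 30e-3)
  g2 <- c(plus = 0, minus = 30e-3)
  want <- 2 * (sqrt(25.5e-3) * (sqrt(30e-3) + sqrt(30e-3) - sqrt(25.5e-3)) +
                 sqrt(25.5e-3) * (0 + 0 - sqrt(25.5e-3)) - 0 - 0)
  expect_equal(delta_g_ab(gw, g1, g2), want)
  expect_gt(want, 0)  # electron-donor surfaces across water repel (hydrophilic)
})

test_that("R force profile matches the engine's wall-force kernel", {
  props <- np_props(zeta = -10e-3)
  ch <- surface_chemistry(psi_particle = -10e-3, psi_wall = -15e-3,
                          fab_contact = 2e-10)
  d <- c(0.2e-9, 1e-9, 5e-9, 20e-9, 80e-9)
  prof <- nanolga:::cpp_wall_profile(d, c(ch[c("hamaker", "eps_r", "kappa",
                                                "d0", "lambda", "cutoff",
                                                "d_park")],
                                          list(psi_particle = -10e-3,
                                               psi_wall = ch$psi_wall,
                                               fab_contact = 2e-10,
                                               dp = props$diameter)))
  expect_equal(prof$vdw, vdw_force(ch, props$diameter, d))
  expect_equal(prof$el, electrostatic_force(ch, props$diameter, d))
  expect_equal(prof$ab, acid_base_force(ch, props$diameter, d))
  expect_equal(prof$net, wall_force(ch, props$diameter, d))
})

test_that("total acceleration is additive over its force terms", {
  props <- np_props(zeta = -5e-3)
  ch <- surface_chemistry(psi_particle = -5e-3, psi_wall = -15e-3)
  # far from walls, no field, no thermal kick: nothing accelerates
  a0 <- total_acceleration(props, ch, temperature = 0)
  expect_equal(a0$sigma_a, c(0, 0, 0))
  # each term contributes exactly its own force / mass
  dirn <- c(0, 0, 1)
  full <- total_acceleration(props, ch, temperature = 310,
                             grad_b = c(0, 0, 2000), separation = 20e-9,
                             normal = dirn, brownian_dir = c(1, 0, 0))
  no_mag <- total_acceleration(props, ch, temperature = 310,
                               grad_b = c(0, 0, 0), separation = 20e-9,
                               normal = dirn, brownian_dir = c(1, 0, 0))
  expect_equal(full$sigma_a - no_mag$sigma_a,
               magnetic_force(props, c(0, 0, 2000)) / props$mass)
  expect_equal(full$f_wall,
               wall_force(ch, props$diameter, 20e-9) * dirn)
  expect_error(total_acceleration(props, NULL, separation = 20e-9),
               "chem")
})

test_that("forces scale correctly with particle diameter", {
  ch <- surface_chemistry()
  d1 <- 50e-9; d2 <- 100e-9
  expect_equal(drag_force(c(1e-6, 0, 0), c(0, 0, 0), 1e-3, d2)[1] /
                 drag_force(c(1e-6, 0, 0), c(0, 0, 0), 1e-3, d1)[1], 2)
  expect_equal(vdw_force(ch, d2, 10e-9) / vdw_force(ch, d1, 10e-9), 2)
  expect_equal(magnetic_force(np_props(diameter = d2), c(0, 0, 1))[3] /
                 magnetic_force(np_props(diameter = d1), c(0, 0, 1))[3], 8)
})

test_that("every wall term vanishes when its governing parameter is zero", {
  d <- 5e-9
  expect_equal(vdw_force(surface_chemistry(hamaker = 0), 50e-9, d), 0)
  expect_equal(electrostatic_force(
    surface_chemistry(psi_particle = 0, psi_wall = 0), 50e-9, d), 0)
  expect_equal(acid_base_force(surface_chemistry(delta_g_ab = 0), 50e-9, d), 0)
  expect_equal(magnetic_force(np_props(msat = 0), c(0, 0, 6000)), c(0, 0, 0))
})
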