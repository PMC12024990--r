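make_traj_tibble <- function(pos_fun, n_t = 50, n_p = 3, dt = 0.1) {
  tg <- (0:(n_t - 1)) * dt
  out <- list()
  for (p in seq_len(n_p)) {
    xyz <- pos_fun(tg, p)
    out[[p]] <- tibble::tibble(replicate = 1L, particle = p, t = tg,
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  dplyr::bind_rows(out)
}

test_that("MSD of stationary and ballistic trajectories is exact", {
  still <- make_traj_tibble(function(tg, p) matrix(0, length(tg), 3))
  m <- compute_msd(still)
  expect_true(all(m$ensemble[, c("msd_x", "msd_y", "msd_z", "msd_total")] == 0))
  v <- 2.5
  ball <- make_traj_tibble(function(tg, p) cbind(v * tg, 0, 0))
  mb <- compute_msd(ball)
  expect_equal(mb$ensemble$msd_x, v^2 * mb$ensemble$t^2)
  expect_equal(mb$ensemble$msd_total, v^2 * mb$ensemble$t^2)
})

test_that("MSD is invariant under rigid translation of all trajectories", {
  set.seed(10)
  steps <- matrix(rnorm(3 * 60), ncol = 3)
  walk <- apply(steps, 2, cumsum)
  base <- make_traj_tibble(function(tg, p) walk, n_t = 60, n_p = 1)
  shifted <- dplyr::mutate(base, x = .data$x + 100, y = .data$y - 7,
                           z = .data$z + 3)
  expect_equal(compute_msd(base)$ensemble, compute_msd(shifted)$ensemble)
})

test_that("non-uniform sampling is rejected", {
  bad <- tibble::tibble(replicate = 1L, particle = 1L,
                        t = c(0, 0.1, 0.3), x = 0, y = 0, z = 0)
  expect_error(compute_msd(bad), "uniform")
})

test_that("a Gaussian random walk recovers its diffusion coefficient", {
  set.seed(4)
  D <- 2e-13
  dt <- 1e-3
  n_t <- 10000L; n_p <- 100L
  arr <- array(0, c(n_t, n_p, 3))
  for (a in 1:3)
    arr[, , a] <- apply(matrix(rnorm(n_t * n_p, sd = sqrt(2 * D * dt)),
                               n_t, n_p), 2, cumsum)
  fake <- structure(list(trajectories = list(`1` = arr),
                         time = (0:(n_t - 1)) * dt), class = "np_ensemble")
  msd <- compute_msd(fake, n_lags = 60)
  fit <- fit_diffusion(msd)
  expect_lt(abs(fit$D[fit$axis == "total"] - D) / D, 0.03)
  # per-axis consistency: the total equals the mean of the axes
  expect_equal(fit$D[fit$axis == "total"],
               mean(fit$D[fit$axis != "total"]), tolerance = 1e-12)
})

test_that("anisotropic walks give the right axis ratio", {
  set.seed(5)
  Dx <- 1e-13; Dz <- 2e-13
  dt <- 1e-3; n_t <- 8000L; n_p <- 250L
  arr <- array(0, c(n_t, n_p, 3))
  for (a in 1:3) {
    D <- if (a == 3) Dz else Dx
    arr[, , a] <- apply(matrix(rnorm(n_t * n_p, sd = sqrt(2 * D * dt)),
                               n_t, n_p), 2, cumsum)
  }
  fake <- structure(list(trajectories = list(`1` = arr),
                         time = (0:(n_t - 1)) * dt), class = "np_ensemble")
  # early lags: time-origin averaging is most efficient well below the
  # trajectory length, so restrict the lag range before fitting
  fit <- fit_diffusion(compute_msd(fake, max_lag_frac = 0.2, n_lags = 60))
  ratio <- fit$D[fit$axis == "z"] / fit$D[fit$axis == "x"]
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("an exact line MSD = 2 D N t returns D and warns on negatives", {
  tg <- seq(0, 1, by = 0.02)
  D <- 3e-12
  msd <- structure(list(
    curves = tibble::tibble(replicate = 1L, lag = seq_along(tg), t = tg,
                            msd_x = 2 * D * tg, msd_y = 2 * D * tg,
                            msd_z = 2 * D * tg, msd_total = 6 * D * tg),
    ensemble = tibble::tibble(lag = seq_along(tg), t = tg,
                              msd_x = 2 * D * tg, msd_y = 2 * D * tg,
                              msd_z = 2 * D * tg, msd_total = 6 * D * tg),
    dt_record = 0.02, n_replicates = 1L), class = "msd_result")
  fit <- fit_diffusion(msd)
  expect_equal(fit$D, rep(D, 4), tolerance = 1e-12)
  neg <- msd
  neg$ensemble$msd_x <- -neg$ensemble$msd_x
  expect_warning(fit_diffusion(neg), "negative")
})

test_that("ensemble summary takes the mean and the closest replicate", {
  s <- ensemble_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_identical(s$representative, 2L)
  tie <- ensemble_summary(c(5, 5, 5))
  expect_equal(tie$mean, 5)
  expect_identical(tie$representative, 1L)  # ties take the lowest index
  set.seed(6)
  v <- runif(20)
  expect_equal(ensemble_summary(v)$mean, sum(v) / length(v))
  expect_error(ensemble_summary(1), "two")
})

test_that("representative selection is permutation-invariant up to ties", {
  set.seed(8)
  v <- runif(15)
  perm <- sample.int(15)
  s1 <- ensemble_summary(v)
  s2 <- ensemble_summary(v[perm])
  expect_equal(v[s1$representative], v[perm][s2$representative])
})

test_that("equivalent viscosity follows the inverse Stokes-Einstein map", {
  ev <- equivalent_viscosity(3e-13, 25e-9, 310)
  expect_equal(ev$mu_e, kB * 310 / (6 * pi * 25e-9 * 3e-13))
  # monotone: faster subdiffusion means thinner equivalent fluid
  expect_gt(ev$mu_e, equivalent_viscosity(6e-13, 25e-9, 310)$mu_e)
  expect_error(equivalent_viscosity(-1, 25e-9), "d_sub")
})

test_that("the sphere-array reference relation behaves", {
  expect_equal(sphere_array_reference_D(1), 1)
  expect_equal(sphere_array_reference_D(0.5), 0.4)
  eps <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(sphere_array_reference_D(eps)) > 0))
  expect_error(sphere_array_reference_D(0), "0, 1")
})
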