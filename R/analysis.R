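#' Mean squared displacement of an ensemble
#'
#' Time-origin-averaged MSD per axis, computed from unwrapped coordinates and
#' averaged over all particles of each replicate; the ensemble curve is the
#' mean across replicates.  Total MSD is the sum of the three axis curves.
#'
#' @param ensemble A `np_ensemble` from [simulate_particles()], or a tidy
#'   trajectory tibble with columns `replicate`, `particle`, `t`, `x`, `y`,
#'   `z` on a uniform time grid.
#' @param max_lag_frac Largest lag as a fraction of the record length.
#' @param n_lags Number of (approximately evenly spaced) lags to evaluate.
#' @return A `msd_result`: tibble of per-replicate curves, the ensemble
#'   curve, and metadata.  `tidy()` returns the curves.
#' @export
compute_msd <- function(ensemble, max_lag_frac = 0.5, n_lags = 80) {
  if (inherits(ensemble, "np_ensemble")) {
    trajs <- ensemble$trajectories
    tgrid <- ensemble$time
  } else {
    df <- ensemble
    need <- c("replicate", "particle", "t", "x", "y", "z")
    if (!all(need %in% names(df)))
      abort("trajectory data needs columns replicate, particle, t, x, y, z.")
    tgrid <- sort(unique(df$t))
    dts <- diff(tgrid)
    if (length(dts) > 1 && diff(range(dts)) > 1e-9 * max(dts))
      abort("trajectory sampling is not uniform in time.")
    trajs <- lapply(split(df, df$replicate), function(dr) {
      parts <- sort(unique(dr$particle))
      arr <- array(NA_real_, c(length(tgrid), length(parts), 3))
      for (pi in seq_along(parts)) {
        dp <- dr[dr$particle == parts[pi], ]
        dp <- dp[order(dp$t), ]
        if (nrow(dp) != length(tgrid))
          abort("each particle must be sampled on the common time grid.")
        arr[, pi, ] <- cbind(dp$x, dp$y, dp$z)
      }
      arr
    })
  }
  nrec <- dim(trajs[[1]])[1]
  max_lag <- max(1L, floor(max_lag_frac * (nrec - 1)))
  lags <- unique(round(seq(1, max_lag, length.out = min(n_lags, max_lag))))
  curves <- imap(trajs, function(tr, r) {
    m <- cpp_msd(tr, as.integer(lags))
    tibble(replicate = as.integer(r), lag = lags, t = tgrid[lags + 1] - tgrid[1],
           msd_x = m[, 1], msd_y = m[, 2], msd_z = m[, 3],
           msd_total = rowSums(m))
  })
  curves <- list_rbind(curves)
  ens <- curves |>
    group_by(.data$lag, .data$t) |>
    summarise(across(c("msd_x", "msd_y", "msd_z", "msd_total"), mean),
              .groups = "drop")
  structure(list(curves = curves, ensemble = ens,
                 dt_record = tgrid[2] - tgrid[1], n_replicates = length(trajs)),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> %d replicates, %d lags, record interval %.3g s\n",
              x$n_replicates, nrow(x$ensemble), x$dt_record))
  invisible(x)
}

#' @export
tidy.msd_result <- function(x, ...) x$curves

#' Fit diffusion coefficients from MSD curves
#'
#' Least-squares fit of `<MSD> = 2 D N t` over a lag window, per axis
#' (dimension coefficient N = 1) and for the total MSD (N = 3).  The default
#' window, lags between 10% and 50% of the maximum recorded lag, skips the
#' short-time transient and the long-lag noise.  Negative slopes are reported
#' with a warning, never clamped.
#'
#' @param msd A [compute_msd()] result.
#' @param window Fit window as fractions of the largest evaluated lag time.
#' @param replicate `NULL` fits the ensemble curve; otherwise the given
#'   replicate's curve.
#' @return Tibble with one row per axis (`x`, `y`, `z`, `total`): diffusion
#'   coefficient `D` (m^2/s), its standard error, the dimension coefficient
#'   `N`, and the window.
#' @export
fit_diffusion <- function(msd, window = c(0.1, 0.5), replicate = NULL) {
  stopifnot(inherits(msd, "msd_result"))
  cur <- if (is.null(replicate)) msd$ensemble
         else msd$curves[msd$curves$replicate == replicate, ]
  tmax <- max(cur$t)
  sel <- cur$t >= window[1] * tmax & cur$t <= window[2] * tmax
  if (sum(sel) < 2) abort("fit window contains fewer than two lags.")
  cw <- cur[sel, ]
  fit_one <- function(y, N) {
    # plain least squares; the slope standard error is computed directly so
    # that degenerate (perfectly linear) inputs do not warn
    tt <- cw$t - mean(cw$t)
    sxx <- sum(tt^2)
    sl <- sum(tt * (y - mean(y))) / sxx
    r <- y - mean(y) - sl * tt
    se <- sqrt(sum(r^2) / (length(y) - 2) / sxx)
    if (sl < 0) warn("negative MSD slope; reporting the negative D as is.")
    c(D = unname(sl) / (2 * N), se = unname(se) / (2 * N))
  }
  res <- rbind(x = c(fit_one(cw$msd_x, 1), N = 1),
               y = c(fit_one(cw$msd_y, 1), N = 1),
               z = c(fit_one(cw$msd_z, 1), N = 1),
               total = c(fit_one(cw$msd_total, 3), N = 3))
  tibble(axis = rownames(res), D = unname(res[, "D"]),
         se = unname(res[, "se"]), N = unname(res[, "N"]),
         window_lo = window[1] * tmax, window_hi = window[2] * tmax)
}

#' Ensemble statistics of per-replicate diffusion coefficients
#'
#' @param d Numeric vector of per-replicate diffusion coefficients (>= 2).
#' @return List with the arithmetic `mean`, `sd`, and `representative`, the
#'   index of the replicate closest to the mean (ties take the lowest index).
#' @export
ensemble_summary <- function(d) {
  if (length(d) < 2) abort("need at least two replicates.")
  m <- mean(d)
  list(mean = m, sd = sd(d), representative = which.min(abs(d - m)))
}

#' Per-replicate and ensemble diffusion estimate
#'
#' Computes per-replicate MSD curves, fits D for each replicate and axis,
#' and summarises the ensemble: mean, SD, and the representative replicate
#' whose total D is closest to the ensemble mean.
#'
#' @param ensemble A `np_ensemble`.
#' @inheritParams fit_diffusion
#' @inheritParams compute_msd
#' @return A `diffusion_estimate`: `per_replicate` tibble, `summary` tibble
#'   (one row per axis) and the underlying `msd_result`.
#' @export
ensemble_diffusion <- function(ensemble, window = c(0.1, 0.5),
                               max_lag_frac = 0.5, n_lags = 80) {
  msd <- compute_msd(ensemble, max_lag_frac = max_lag_frac, n_lags = n_lags)
  reps <- unique(msd$curves$replicate)
  per <- list_rbind(map(reps, function(r) {
    fit_diffusion(msd, window, replicate = r) |>
      mutate(replicate = r)
  }))
  summ <- per |>
    group_by(.data$axis) |>
    summarise(mean_D = mean(.data$D), sd_D = sd(.data$D), .groups = "drop")
  dtot <- per$D[per$axis == "total"]
  es <- if (length(dtot) >= 2) ensemble_summary(dtot)
        else list(mean = mean(dtot), sd = NA_real_, representative = 1L)
  structure(list(per_replicate = per, summary = summ, msd = msd,
                 representative = es$representative,
                 mean_D = es$mean, sd_D = es$sd),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> ensemble D = %.4g +/- %.2g m^2/s (total)\n",
              x$mean_D, x$sd_D))
  cat(sprintf("  representative replicate: %d\n", x$representative))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) x$per_replicate

#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble(mean_D = x$mean_D, sd_D = x$sd_D,
         representative = x$representative,
         n_replicates = length(unique(x$per_replicate$replicate)))
}

#' Equivalent viscosity of a hindered medium
#'
#' Inverse Stokes-Einstein map from a measured (sub)diffusion coefficient to
#' the viscosity of a fictitious homogeneous fluid reproducing it:
#' `mu_e = k_B T / (6 pi R0 D_sub)`.  Free diffusion of the same particle in
#' a fluid of viscosity `mu_e` (with the Stokes drag law, prefactor 3 on the
#' diameter) recovers `D_sub` exactly.
#'
#' @param d_sub Measured subdiffusion coefficient (m^2/s), > 0.
#' @param radius Particle radius R0 (m).
#' @param temperature Temperature (K).
#' @return An `equivalent_viscosity` object with element `mu_e` (Pa s).
#' @export
equivalent_viscosity <- function(d_sub, radius, temperature = 310) {
  assert_scalar_num(d_sub, "d_sub", 0, strict_lower = TRUE)
  assert_scalar_num(radius, "radius", 0, strict_lower = TRUE)
  assert_scalar_num(temperature, "temperature", 0, strict_lower = TRUE)
  structure(list(mu_e = .kB * temperature / (6 * pi * radius * d_sub),
                 d_sub = d_sub, radius = radius, temperature = temperature),
            class = "equivalent_viscosity")
}

#' @export
print.equivalent_viscosity <- function(x, ...) {
  cat(sprintf("<equivalent_viscosity> mu_e = %.4g Pa s (D_sub = %.3g m^2/s)\n",
              x$mu_e, x$d_sub))
  invisible(x)
}

#' Analytic relative diffusivity of a dilute sphere array
#'
#' Maxwell's effective-medium relation for diffusion around impermeable
#' spheres, `D_eff / D_0 = 2 eps / (3 - eps)` with porosity `eps`; accurate
#' for dilute and moderately dense simple-cubic arrays and used as the
#' analytic reference for the sphere-array validation.
#'
#' @param porosity Fluid volume fraction, in `(0, 1]`.
#' @return Relative diffusivity `D_eff / D_0`.
#' @export
sphere_array_reference_D <- function(porosity) {
  if (any(porosity <= 0 | porosity > 1))
    abort("`porosity` must lie in (0, 1].")
  2 * porosity / (3 - porosity)
}
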