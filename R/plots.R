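# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_errorbar labs scale_fill_manual theme_minimal facet_wrap
#'   coord_equal annotate
NULL

#' Plot MSD curves
#'
#' Ensemble per-axis and total mean-squared-displacement curves; per-replicate
#' total curves are drawn faintly behind the ensemble mean.
#' @param object A `msd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_result <- function(object, ...) {
  ens <- object$ensemble |>
    pivot_longer(c("msd_x", "msd_y", "msd_z", "msd_total"),
                 names_to = "component", values_to = "msd") |>
    mutate(component = sub("msd_", "", .data$component))
  ggplot(ens, aes(x = .data$t, y = .data$msd, colour = .data$component)) +
    geom_line(data = object$curves,
              mapping = aes(x = .data$t, y = .data$msd_total,
                            group = .data$replicate),
              colour = "grey80", linewidth = 0.3, inherit.aes = FALSE) +
    geom_line(linewidth = 0.8) +
    labs(x = "lag time (s)", y = expression(MSD ~ (m^2)), colour = NULL) +
    theme_minimal()
}

#' Plot an experiment's diffusion coefficients
#'
#' Ensemble mean D (with +/- one SD error bars) against the first condition
#' column of the experiment's result table.
#' @param object A `np_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.np_experiment <- function(object, ...) {
  res <- object$results
  xcol <- names(res)[1]
  xv <- res[[xcol]]
  if (!is.numeric(xv)) xv <- factor(xv, levels = unique(xv))
  ggplot(res, aes(x = xv, y = .data$mean_D)) +
    geom_errorbar(aes(ymin = .data$mean_D - .data$sd_D,
                      ymax = .data$mean_D + .data$sd_D), width = 0.02) +
    geom_point(size = 2) +
    geom_line(group = 1) +
    labs(x = xcol, y = expression(D ~ (m^2 / s)), title = object$name) +
    theme_minimal()
}

#' Plot a slice through a lattice
#'
#' Occupancy of one z-plane as a raster image.
#' @param lattice A `porous_lattice`.
#' @param k z-index of the slice (1-based); defaults to the mid-plane.
#' @return A ggplot.
#' @export
plot_lattice_slice <- function(lattice, k = NULL) {
  stopifnot(inherits(lattice, "porous_lattice"))
  nn <- dim(lattice$occupancy)
  k <- k %||% ceiling(nn[3] / 2)
  sl <- lattice$occupancy[, , k]
  df <- tibble(
    x = rep(seq_len(nn[1]), nn[2]) * lattice$spacing * 1e6,
    y = rep(seq_len(nn[2]), each = nn[1]) * lattice$spacing * 1e6,
    label = factor(names(.labels)[match(as.vector(sl), .labels)],
                   levels = names(.labels)))
  cols <- c(fluid = "white", fiber = "#8d6e63", tumor_cell = "#c2185b",
            stromal_cell = "#1976d2", sphere = "#455a64")
  ggplot(df, aes(.data$x, .data$y, fill = .data$label)) +
    geom_raster() +
    scale_fill_manual(values = cols, drop = TRUE) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", fill = NULL,
         title = sprintf("%s slice k = %d", lattice$kind, k)) +
    theme_minimal()
}
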