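# Plain-text I/O: legacy-VTK structured grids for lattices and fields,
# CSV tables for trajectories and analysis results.

#' Write a lattice as a legacy VTK structured-points file
#'
#' ASCII format readable by standard structured-grid viewers; the title line
#' carries the lattice kind and spacing so [read_lattice_vtk()] can restore
#' the object exactly.
#' @param lattice A `porous_lattice`.
#' @param path Output path (conventionally `.vtk`).
#' @export
write_lattice_vtk <- function(lattice, path) {
  stopifnot(inherits(lattice, "porous_lattice"))
  nn <- dim(lattice$occupancy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("nanolga porous_lattice kind=%s spacing=%.17g", lattice$kind,
            lattice$spacing),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", nn[1], nn[2], nn[3]),
    "ORIGIN 0 0 0",
    sprintf("SPACING %.17g %.17g %.17g", lattice$spacing, lattice$spacing,
            lattice$spacing),
    sprintf("POINT_DATA %d", prod(nn)),
    "SCALARS occupancy int 1",
    "LOOKUP_TABLE default"), con)
  writeLines(paste(lattice$occupancy), con)
  invisible(path)
}

#' Read a lattice written by [write_lattice_vtk()]
#' @param path Path to the VTK file.
#' @return A `porous_lattice`.
#' @export
read_lattice_vtk <- function(path) {
  lines <- readLines(path)
  title <- lines[2]
  kind <- sub(".*kind=([a-z_]+).*", "\\1", title)
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "", lines[grep("^DIMENSIONS", lines)]),
                              " ")[[1]])
  spacing <- as.numeric(strsplit(sub("SPACING ", "", lines[grep("^SPACING", lines)]),
                                 " ")[[1]][1])
  start <- grep("^LOOKUP_TABLE", lines)[1] + 1L
  vals <- as.integer(lines[start:(start + prod(dims) - 1L)])
  new_porous_lattice(array(vals, dims), spacing, kind)
}

#' Write scalar/vector fields as a legacy VTK structured-points file
#'
#' @param fields Named list of 3-d arrays (scalars) and/or a list
#'   `velocity = list(ux, uy, uz)` written as a VECTORS block.
#' @param spacing Node spacing (m).
#' @param path Output path.
#' @export
write_field_vtk <- function(fields, spacing, path) {
  scalars <- fields[!names(fields) %in% "velocity"]
  nn <- dim(if (length(scalars)) scalars[[1]] else fields$velocity$ux)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "nanolga fields",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", nn[1], nn[2], nn[3]),
    "ORIGIN 0 0 0",
    sprintf("SPACING %.17g %.17g %.17g", spacing, spacing, spacing),
    sprintf("POINT_DATA %d", prod(nn))), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(as.numeric(scalars[[nm]]), digits = 10), con)
  }
  if (!is.null(fields$velocity)) {
    v <- fields$velocity
    writeLines("VECTORS velocity double", con)
    writeLines(paste(format(as.numeric(v$ux), digits = 10),
                     format(as.numeric(v$uy), digits = 10),
                     format(as.numeric(v$uz), digits = 10)), con)
  }
  invisible(path)
}

#' Write all artifacts of a configured run
#'
#' Trajectories, MSD curves, per-replicate and ensemble diffusion tables as
#' CSV; the lattice as VTK; the configuration (with hash and seeds) as YAML.
#' Re-running with the same configuration and seed reproduces every file
#' byte for byte.
#' @param ensemble A `np_ensemble`.
#' @param estimate A `diffusion_estimate`.
#' @param lattice The `porous_lattice` used.
#' @param config The `run_config`.
#' @param dir Output directory (created if needed).
#' @export
write_run_outputs <- function(ensemble, estimate, lattice, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(ensemble), file.path(dir, "trajectories.csv"))
  readr::write_csv(estimate$msd$curves, file.path(dir, "msd_curves.csv"))
  readr::write_csv(estimate$per_replicate, file.path(dir, "per_replicate_D.csv"))
  readr::write_csv(estimate$summary, file.path(dir, "ensemble_D.csv"))
  write_lattice_vtk(lattice, file.path(dir, "lattice.vtk"))
  meta <- c(unclass(config),
            list(provenance = list(config_hash = rlang::hash(unclass(config)),
                                   package = "nanolga",
                                   version = as.character(utils::packageVersion("nanolga")))))
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write experiment tables
#'
#' Condition-level results and per-replicate diffusion coefficients of a
#' [run_experiment()] result, plus the configuration with hash and seed.
#' @param experiment A `np_experiment`.
#' @param dir Output directory.
#' @export
write_experiment_outputs <- function(experiment, dir) {
  stopifnot(inherits(experiment, "np_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(experiment$results, file.path(dir, "results.csv"))
  per <- imap(experiment$estimates, function(e, i) {
    if (is.null(e)) return(NULL)
    mutate(e$per_replicate, condition = i)
  })
  per <- list_rbind(per[!vapply(per, is.null, logical(1))])
  if (NROW(per)) readr::write_csv(per, file.path(dir, "per_replicate_D.csv"))
  yaml::write_yaml(list(name = experiment$name, seed = experiment$seed,
                        config_hash = experiment$config_hash,
                        config = experiment$config),
                   file.path(dir, "experiment.yaml"))
  invisible(dir)
}
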