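#' Default run configuration
#'
#' Full configuration of a single simulation run: geometry, particle and
#' fluid properties, surface chemistry, external field, and run controls.
#' Defaults are the reference conditions: 120 particles of 50 nm diameter
#' seeded on the entrance surface, 50 replicates.  All values can be
#' overridden from a YAML file via [load_config()]; unknown keys are
#' rejected and out-of-range values named explicitly.
#'
#' @param ... Named overrides of top-level sections (each a named list).
#' @return A validated `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    geometry = list(kind = "ecm", target_porosity = 0.94,
                    cell_volume_fraction = 0.21, n_nodes = 100L,
                    domain_size = NULL, seed = 1L, file = NULL,
                    n_degradation_points = 0L,
                    degradation_segment_length = 200e-9),
    particles = list(n = 120L, diameter = 50e-9, density = 5e3,
                     msat = 4.8e5, zeta = 0, drag_prefactor = 6),
    fluid = list(mu = 0.7e-3, temperature = 310),
    chemistry = list(enabled = TRUE, wall = "collagen", hamaker = 1e-20,
                     debye_length = 10e-9, lambda = 1e-9, d0 = 0.157e-9,
                     fab_contact = NULL, delta_g_ab = 0, cutoff = 100e-9,
                     d_park = 7.5e-9, stick_prob = 0.05, tau_bond_ref = 0.05),
    field = list(grad_b = c(0, 0, 0)),
    run = list(dt = 1e-4, n_steps = 3000L, record_every = 10L,
               replicates = 50L, seed = 1L, brownian = "printed",
               moves = "lattice", init = "entrance",
               window = c(0.1, 0.5)),
    output = list(dir = NULL))
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

merge_config <- function(defaults, overrides, path) {
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    abort(sprintf("unknown configuration key%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste0(path, bad, collapse = ", ")))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(overrides[[nm]]))
      defaults[nm] <- list(merge_config(defaults[[nm]], overrides[[nm]],
                                        paste0(path, nm, ".")))
    else
      defaults[nm] <- list(overrides[[nm]])  # keeps explicit NULLs
  }
  defaults
}

validate_config <- function(cfg) {
  pos <- function(x, key) {
    if (!is.null(x) && (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)))
      abort(sprintf("configuration key `%s` must be positive (got %s).",
                    key, paste(format(x), collapse = ", ")))
  }
  pos(cfg$particles$diameter, "particles.diameter")
  pos(cfg$particles$density, "particles.density")
  pos(cfg$fluid$mu, "fluid.mu")
  pos(cfg$fluid$temperature, "fluid.temperature")
  pos(cfg$run$dt, "run.dt")
  pos(cfg$run$n_steps, "run.n_steps")
  pos(cfg$run$replicates, "run.replicates")
  pos(cfg$chemistry$debye_length, "chemistry.debye_length")
  pos(cfg$chemistry$lambda, "chemistry.lambda")
  if (!cfg$geometry$kind %in% c("ecm", "tumor", "sphere_array", "free"))
    abort("configuration key `geometry.kind` must be one of ecm, tumor, sphere_array, free.")
  tp <- cfg$geometry$target_porosity
  if (!is.null(tp) && (tp <= 0 || tp > 1))
    abort("configuration key `geometry.target_porosity` must lie in (0, 1].")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Missing keys take documented defaults; unknown keys and out-of-range
#' values are rejected with a message naming the key.  A written
#' configuration ([write_config()]) parses back to an identical object.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Execute a single configured run
#'
#' Builds the geometry, runs the particle ensemble and the diffusion
#' analysis described by a [run_config()].  When an output directory is
#' configured it is checked to be writable before any computation starts,
#' and all artifacts (tables, MSD curves, configuration with its hash and
#' seeds) are written there.
#'
#' @param config A `run_config`.
#' @return List with the `np_ensemble`, the `diffusion_estimate`, the
#'   lattice, and the configuration.
#' @export
run_from_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output$dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    probe <- file.path(out_dir, ".write_probe")
    ok <- tryCatch(suppressWarnings({
      writeLines("x", probe)
      file.remove(probe)
      TRUE
    }), error = function(e) FALSE)
    if (!ok) abort(sprintf("output directory '%s' is not writable.", out_dir))
  }
  g <- config$geometry
  lattice <- if (!is.null(g$file)) {
    read_lattice_vtk(g$file)
  } else {
    spec <- geometry_spec(g$kind, target_porosity = g$target_porosity,
                          cell_volume_fraction = g$cell_volume_fraction,
                          domain_size = g$domain_size, n_nodes = g$n_nodes,
                          seed = g$seed)
    lat <- switch(g$kind,
                  ecm = generate_ecm(spec),
                  tumor = generate_tumor(spec),
                  free = free_fluid_domain(5e-6 / g$n_nodes, g$n_nodes),
                  abort("sphere_array geometries are built with generate_sphere_array()."))
    if (g$kind == "ecm" && g$n_degradation_points > 0)
      lat <- apply_degradation(lat, g$n_degradation_points,
                               g$degradation_segment_length, seed = g$seed)
    lat
  }
  p <- config$particles
  props <- np_props(diameter = p$diameter, density = p$density, msat = p$msat,
                    zeta = p$zeta, drag_prefactor = p$drag_prefactor)
  ch <- config$chemistry
  chem <- if (isTRUE(ch$enabled))
    surface_chemistry(hamaker = ch$hamaker,
                      psi_wall = wall_chem(ch$wall)$psi_wall,
                      debye_length = ch$debye_length, lambda = ch$lambda,
                      d0 = ch$d0, fab_contact = ch$fab_contact,
                      delta_g_ab = ch$delta_g_ab, cutoff = ch$cutoff,
                      d_park = ch$d_park, stick_prob = ch$stick_prob,
                      tau_bond_ref = ch$tau_bond_ref)
  else NULL
  r <- config$run
  control <- transport_control(r$dt, brownian = r$brownian, moves = r$moves)
  sim <- simulate_particles(lattice, props, control, chem,
                            mu = config$fluid$mu,
                            temperature = config$fluid$temperature,
                            grad_b = config$field$grad_b,
                            n_steps = r$n_steps, n_particles = p$n,
                            replicates = r$replicates,
                            record_every = r$record_every,
                            init = r$init, seed = r$seed)
  est <- ensemble_diffusion(sim, window = r$window)
  if (!is.null(out_dir)) write_run_outputs(sim, est, lattice, config, out_dir)
  list(ensemble = sim, estimate = est, lattice = lattice, config = config)
}
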