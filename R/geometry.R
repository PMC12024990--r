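#' Specify a stochastic tissue geometry
#'
#' A `geometry_spec` collects all parameters needed to generate a voxelized
#' porous structure: an extracellular-matrix (ECM) fiber network, a packing of
#' tumor and stromal cells, or a regular sphere array used for validation.
#'
#' Defaults mirror the reference tissue models: collagen fibers of 100 nm
#' diameter and 70 um length in a 5 um cube resolved on a 100^3 grid;
#' 10 um spherical stromal cells and ellipsoidal tumor cells (default
#' semi-axes 7.5 x 5 x 5 um) at a 4:1 tumor:stromal count ratio in a
#' 100 um cube on a 100^3 grid.
#'
#' @param kind One of `"ecm"`, `"tumor"`, `"sphere_array"`.
#' @param target_porosity Fluid volume fraction to reach (ECM); in `(0, 1]`.
#' @param cell_volume_fraction Cell (solid) volume fraction to reach (tumor).
#' @param domain_size Edge length of the cubic domain (m).
#' @param n_nodes Number of lattice nodes per axis.
#' @param fiber_diameter,fiber_length Fiber rod dimensions (m).
#' @param stromal_diameter Diameter of spherical stromal cells (m).
#' @param tumor_semiaxes Semi-axes of ellipsoidal tumor cells (m), length 3.
#'   The long axis is oriented along a random coordinate axis per cell.
#' @param tumor_stromal_ratio Target tumor:stromal cell count ratio.
#' @param porosity_tol Acceptable deviation from the target fraction.
#' @param seed Integer seed; identical specs give bit-identical lattices.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(kind = c("ecm", "tumor", "sphere_array"),
                          target_porosity = 0.94,
                          cell_volume_fraction = 0.21,
                          domain_size = NULL,
                          n_nodes = 100L,
                          fiber_diameter = 100e-9,
                          fiber_length = 70e-6,
                          stromal_diameter = 10e-6,
                          tumor_semiaxes = c(7.5e-6, 5e-6, 5e-6),
                          tumor_stromal_ratio = 4,
                          porosity_tol = 0.005,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(domain_size))
    domain_size <- if (kind == "ecm") 5e-6 else 100e-6
  assert_fraction(target_porosity, "target_porosity")
  assert_scalar_num(cell_volume_fraction, "cell_volume_fraction", 0, 1)
  assert_scalar_num(domain_size, "domain_size", 0, strict_lower = TRUE)
  assert_scalar_num(fiber_diameter, "fiber_diameter", 0, strict_lower = TRUE)
  assert_scalar_num(fiber_length, "fiber_length", 0, strict_lower = TRUE)
  assert_scalar_num(stromal_diameter, "stromal_diameter", 0, strict_lower = TRUE)
  assert_scalar_num(tumor_stromal_ratio, "tumor_stromal_ratio", 0,
                    strict_lower = TRUE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) abort("`n_nodes` must be >= 2.")
  if (length(tumor_semiaxes) != 3L || any(tumor_semiaxes <= 0))
    abort("`tumor_semiaxes` must be three positive lengths (m).")
  structure(
    list(kind = kind, target_porosity = target_porosity,
         cell_volume_fraction = cell_volume_fraction,
         domain_size = domain_size, n_nodes = n_nodes,
         fiber_diameter = fiber_diameter, fiber_length = fiber_length,
         stromal_diameter = stromal_diameter,
         tumor_semiaxes = as.numeric(tumor_semiaxes),
         tumor_stromal_ratio = tumor_stromal_ratio,
         porosity_tol = porosity_tol, seed = as.integer(seed)),
    class = "geometry_spec")
}

new_porous_lattice <- function(occupancy, spacing, kind, spec = NULL) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3L)
  storage.mode(occupancy) <- "integer"
  structure(
    list(occupancy = occupancy, spacing = spacing, kind = kind,
         porosity = mean(occupancy == .labels[["fluid"]]), spec = spec),
    class = "porous_lattice")
}

#' @export
print.porous_lattice <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<porous_lattice> %s, %d x %d x %d nodes, spacing %.3g m\n",
              x$kind, d[1], d[2], d[3], x$spacing))
  cat(sprintf("  porosity %.4f; labels:", x$porosity))
  tab <- table(factor(x$occupancy, levels = .labels,
                      labels = names(.labels)))
  for (nm in names(tab)) if (tab[[nm]] > 0) cat(sprintf(" %s=%d", nm, tab[[nm]]))
  cat("\n")
  invisible(x)
}

#' Fluid volume fraction of a lattice
#'
#' Recomputed directly from the occupancy grid, never cached elsewhere.
#' @param lattice A `porous_lattice`.
#' @return Fraction of nodes labelled fluid, in `[0, 1]`.
#' @export
porosity <- function(lattice) {
  stopifnot(inherits(lattice, "porous_lattice"))
  mean(lattice$occupancy == .labels[["fluid"]])
}

#' Generate an ECM fiber network
#'
#' Straight cylindrical fibers with random positions and orientations are
#' added (wrapping periodically at the domain faces) until the fluid fraction
#' falls inside `target_porosity +/- porosity_tol`.  The final fiber is
#' shortened by bisection so the target is met exactly within tolerance;
#' fibers may interpenetrate, as physical collagen networks do.
#'
#' @param spec A [geometry_spec()] with `kind = "ecm"`.
#' @return A `porous_lattice`.
#' @export
generate_ecm <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$kind != "ecm") abort("`spec` must have kind = 'ecm'.")
  dx <- spec$domain_size / spec$n_nodes
  if (spec$fiber_diameter < dx)
    abort(sprintf(
      "fiber diameter (%.3g m) must be at least the node spacing (%.3g m).",
      spec$fiber_diameter, dx))
  nn <- rep(spec$n_nodes, 3)
  occ <- array(0L, nn)
  radius_vox <- spec$fiber_diameter / 2 / dx
  len_vox <- spec$fiber_length / dx
  target <- spec$target_porosity
  tol <- spec$porosity_tol
  if (target >= 1 - tol)  # porosity 1: empty domain
    return(new_porous_lattice(occ, dx, "ecm", spec))

  set.seed(spec$seed)
  max_fibers <- 100000L
  for (i in seq_len(max_fibers)) {
    p0 <- runif(3) * spec$n_nodes
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    trial <- occ + 0L   # force a real copy: the C++ filler writes in place
    cpp_fill_fibers(trial, nn, matrix(p0, 1), matrix(u, 1), len_vox,
                    radius_vox, .labels[["fiber"]])
    por <- mean(trial == 0L)
    if (por >= target - tol) {
      occ <- trial
      if (por <= target + tol) {
        return(new_porous_lattice(array(occ, nn), dx, "ecm", spec))
      }
    } else {
      # overshoot: bisect this fiber's length to land inside the band
      lo <- 0; hi <- len_vox
      for (b in 1:40) {
        mid <- (lo + hi) / 2
        trial <- occ + 0L
        cpp_fill_fibers(trial, nn, matrix(p0, 1), matrix(u, 1), mid,
                        radius_vox, .labels[["fiber"]])
        por <- mean(trial == 0L)
        if (por < target) hi <- mid else lo <- mid
        if (por >= target - tol && por <= target + tol) {
          return(new_porous_lattice(array(trial, nn), dx, "ecm", spec))
        }
      }
      abort(sprintf(
        "could not reach porosity %.4f within tolerance; achieved %.4f",
        target, mean(occ == 0L)))
    }
  }
  abort(sprintf(
    "target porosity %.4f unreachable with these fiber dimensions; achieved %.4f",
    target, mean(occ == 0L)))
}

#' Generate a tumor-tissue cell packing
#'
#' Ellipsoidal tumor cells and spherical stromal cells grow from randomly
#' placed seed points; every voxel is claimed by the seed with the smallest
#' scaled distance, so cells never overlap and, at high packing fractions,
#' truncate one another at their mutual boundary as cells in dense tissue do.
#' The growth factor is bisected until the solid fraction matches
#' `cell_volume_fraction` within tolerance.  The tumor:stromal count split is
#' the nearest integer split to the requested ratio.
#'
#' @param spec A [geometry_spec()] with `kind = "tumor"`.
#' @return A `porous_lattice`.
#' @export
generate_tumor <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$kind != "tumor") abort("`spec` must have kind = 'tumor'.")
  dx <- spec$domain_size / spec$n_nodes
  nn <- rep(spec$n_nodes, 3)
  occ <- array(0L, nn)
  target <- spec$cell_volume_fraction
  tol <- spec$porosity_tol
  vox_vol <- dx^3
  if (target * prod(nn) < 1)  # fewer than one solid voxel: empty domain
    return(new_porous_lattice(occ, dx, "tumor", spec))

  set.seed(spec$seed)
  ax_t <- spec$tumor_semiaxes / dx
  r_s <- spec$stromal_diameter / 2 / dx
  v_t <- 4 / 3 * pi * prod(spec$tumor_semiaxes)
  v_s <- 4 / 3 * pi * (spec$stromal_diameter / 2)^3
  rr <- spec$tumor_stromal_ratio
  frac_t <- rr / (rr + 1)
  v_mean <- frac_t * v_t + (1 - frac_t) * v_s
  n_seeds <- max(2L, ceiling(1.6 * target * spec$domain_size^3 / v_mean))

  for (attempt in 1:6) {
    n_t <- round(n_seeds * frac_t)
    n_s <- n_seeds - n_t
    seeds <- matrix(runif(3 * n_seeds) * spec$n_nodes, ncol = 3)
    semi <- matrix(0, n_seeds, 3)
    labels <- integer(n_seeds)
    for (i in seq_len(n_seeds)) {
      if (i <= n_t) {
        semi[i, ] <- ax_t[sample.int(3)]   # random long-axis orientation
        labels[i] <- .labels[["tumor_cell"]]
      } else {
        semi[i, ] <- rep(r_s, 3)
        labels[i] <- .labels[["stromal_cell"]]
      }
    }
    f_full <- cpp_grow_cells(occ, nn, seeds, semi, labels, 1.0)
    if (f_full < target - tol) {
      n_seeds <- ceiling(n_seeds * 1.3)  # truncation losses: add seeds
      next
    }
    lo <- 0; hi <- 1
    for (b in 1:50) {
      mid <- (lo + hi) / 2
      f <- cpp_grow_cells(occ, nn, seeds, semi, labels, mid)
      if (abs(f - target) <= tol) {
        lat <- new_porous_lattice(array(occ, nn), dx, "tumor", spec)
        attr(lat, "n_tumor") <- n_t
        attr(lat, "n_stromal") <- n_s
        return(lat)
      }
      if (f > target) hi <- mid else lo <- mid
    }
    break
  }
  abort(sprintf(
    "cell packing failed: target fraction %.3f, achieved %.3f", target,
    mean(occ != 0L)))
}

#' Generate a simple-cubic sphere array
#'
#' One sphere centered in a cubic periodic unit cell; under the periodic
#' boundaries this represents an infinite regular array.  Used as the
#' validation geometry for hindered-diffusion runs.
#'
#' @param sphere_diameter Sphere diameter (m); must be smaller than `pitch`.
#' @param pitch Center-to-center spacing of the array (m); also the unit-cell
#'   edge length.
#' @param n_nodes Lattice nodes per axis of the unit cell.
#' @return A `porous_lattice`.
#' @export
generate_sphere_array <- function(sphere_diameter, pitch, n_nodes = 40L) {
  assert_scalar_num(sphere_diameter, "sphere_diameter", 0)
  assert_scalar_num(pitch, "pitch", 0, strict_lower = TRUE)
  if (sphere_diameter >= pitch) abort("`sphere_diameter` must be < `pitch`.")
  n_nodes <- as.integer(n_nodes)
  dx <- pitch / n_nodes
  nn <- rep(n_nodes, 3)
  occ <- array(0L, nn)
  if (sphere_diameter > 0) {
    r <- sphere_diameter / 2 / dx
    cpp_fill_ellipsoids(occ, nn, matrix(rep(n_nodes / 2, 3), 1),
                        matrix(rep(r, 3), 1), .labels[["sphere"]])
  }
  lat <- new_porous_lattice(array(occ, nn), dx, "sphere_array")
  attr(lat, "pitch") <- pitch
  attr(lat, "sphere_diameter") <- sphere_diameter
  lat
}

#' Degrade fiber segments
#'
#' Converts `n_points` randomly chosen fiber loci to fluid: all fiber voxels
#' within a ball of diameter `segment_length` around each locus are removed,
#' which on a thin fiber excises a segment of about that length along the
#' fiber axis.  With a common seed, the loci of a smaller `n_points` are a
#' prefix of those of a larger one, so removal is nested and porosity is
#' monotone in `n_points`.
#'
#' @param lattice A `porous_lattice` containing fiber nodes.
#' @param n_points Number of degradation points (>= 0).
#' @param segment_length Length of fiber converted to fluid per point (m).
#' @param seed Integer seed for locus selection.
#' @return A new `porous_lattice`; porosity never decreases.
#' @export
apply_degradation <- function(lattice, n_points, segment_length = 200e-9,
                              seed = 1L) {
  stopifnot(inherits(lattice, "porous_lattice"))
  n_points <- as.integer(n_points)
  if (n_points < 0) abort("`n_points` must be >= 0.")
  if (n_points == 0L) return(lattice)
  assert_scalar_num(segment_length, "segment_length", 0, strict_lower = TRUE)
  fib <- which(lattice$occupancy == .labels[["fiber"]])
  if (length(fib) == 0L) abort("lattice contains no fiber nodes.")
  if (n_points > length(fib))
    abort(sprintf("n_points (%d) exceeds available fiber loci (%d).",
                  n_points, length(fib)))
  set.seed(seed)
  loci <- sample(fib, n_points) - 1L  # 0-based for C++
  occ <- lattice$occupancy + 0L       # real copy; cpp_degrade edits in place
  nn <- dim(occ)
  rad <- segment_length / 2 / lattice$spacing
  cpp_degrade(occ, nn, loci, rad, .labels[["fiber"]])
  out <- new_porous_lattice(array(occ, nn), lattice$spacing, lattice$kind,
                            lattice$spec)
  attr(out, "n_degradation_points") <- n_points
  out
}

#' Pore connectivity
#'
#' Fraction of fluid nodes belonging to the largest face-connected
#' (6-neighbour, periodic) fluid component.  1 means all pore space is one
#' component.
#'
#' @param lattice A `porous_lattice` with at least one fluid node.
#' @return A fraction in `[0, 1]`.
#' @export
measure_connectivity <- function(lattice) {
  stopifnot(inherits(lattice, "porous_lattice"))
  if (!any(lattice$occupancy == .labels[["fluid"]]))
    abort("lattice has no fluid nodes; connectivity undefined.")
  cpp_largest_component(lattice$occupancy, dim(lattice$occupancy))
}

#' An all-fluid domain
#'
#' Convenience constructor for free-diffusion runs (no obstacles).
#' @param spacing Node spacing (m).
#' @param n_nodes Nodes per axis.
#' @return A `porous_lattice` of porosity 1.
#' @export
free_fluid_domain <- function(spacing, n_nodes = 16L) {
  new_porous_lattice(array(0L, rep(as.integer(n_nodes), 3)), spacing, "free")
}
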