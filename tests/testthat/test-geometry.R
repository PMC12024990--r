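test_that("ECM generation hits the target porosity and is seed-deterministic", {
  spec <- geometry_spec("ecm", target_porosity = 0.94, n_nodes = 48L,
                        domain_size = 48 * 50e-9, seed = 5L)
  lat <- generate_ecm(spec)
  expect_s3_class(lat, "porous_lattice")
  expect_lt(abs(porosity(lat) - 0.94), 0.005 + 1e-12)
  # porosity bookkeeping: independent voxel count equals the stored value
  expect_identical(porosity(lat), mean(lat$occupancy == 0L))
  expect_identical(lat$porosity, porosity(lat))
  # only fluid and fiber labels appear
  expect_true(all(lat$occupancy %in% c(0L, 1L)))
  # bit-identical regeneration under the same spec
  lat2 <- generate_ecm(spec)
  expect_identical(lat$occupancy, lat2$occupancy)
  # different seed gives a different realization
  lat3 <- generate_ecm(geometry_spec("ecm", target_porosity = 0.94,
                                     n_nodes = 48L, domain_size = 48 * 50e-9,
                                     seed = 6L))
  expect_false(identical(lat$occupancy, lat3$occupancy))
})

test_that("degenerate ECM targets and invalid specs are handled", {
  empty <- generate_ecm(geometry_spec("ecm", target_porosity = 1,
                                      n_nodes = 16L, domain_size = 16 * 50e-9))
  expect_identical(porosity(empty), 1)
  # fiber thinner than a voxel cannot be resolved
  expect_error(
    generate_ecm(geometry_spec("ecm", fiber_diameter = 10e-9, n_nodes = 16L,
                               domain_size = 16 * 50e-9)),
    "node spacing")
  expect_error(geometry_spec("ecm", target_porosity = 1.2), "0, 1")
  expect_error(geometry_spec("ecm", fiber_diameter = -1), "fiber_diameter")
})

test_that("tumor packing reaches high cell fractions without cell overlap", {
  spec <- geometry_spec("tumor", cell_volume_fraction = 0.54, n_nodes = 50L,
                        domain_size = 50e-6, seed = 2L)
  lat <- generate_tumor(spec)
  expect_lt(abs((1 - porosity(lat)) - 0.54), 0.005 + 1e-12)
  # voxel claims are exclusive by construction: labels are well formed
  expect_true(all(lat$occupancy %in% c(0L, 2L, 3L)))
  # nearest-integer split to the 4:1 tumor:stromal ratio
  nt <- attr(lat, "n_tumor"); ns <- attr(lat, "n_stromal")
  expect_identical(nt, round((nt + ns) * 4 / 5))
  expect_identical(generate_tumor(spec)$occupancy, lat$occupancy)
})

test_that("vanishing cell fraction leaves an all-fluid domain", {
  lat <- generate_tumor(geometry_spec("tumor", cell_volume_fraction = 1e-9,
                                      n_nodes = 16L, domain_size = 16e-6))
  expect_identical(porosity(lat), 1)
})

test_that("nearest-integer split matches a 4:1 ratio for 20 cells", {
  # the seed-count arithmetic used by the generator
  n <- 20
  nt <- round(n * 4 / 5)
  expect_identical(c(nt, n - nt), c(16, 4))
})

test_that("degradation is a porosity-monotone nested edit of fiber voxels", {
  lat <- small_ecm(0.92, n = 48L, seed = 9L)
  expect_identical(apply_degradation(lat, 0), lat)
  d600 <- apply_degradation(lat, 600, seed = 4L)
  d1000 <- apply_degradation(lat, 1000, seed = 4L)
  expect_gte(porosity(d600), porosity(lat))
  expect_gte(porosity(d1000), porosity(d600))
  # degraded voxels only ever go fiber -> fluid
  expect_true(all(d1000$occupancy[lat$occupancy == 0L] == 0L))
  n_fib <- sum(lat$occupancy == 1L)
  expect_error(apply_degradation(lat, n_fib + 1L), "exceeds")
})

test_that("a degradation point removes about 200 nm of fiber axis", {
  # one straight fiber along x through a small domain
  n <- 40L
  occ <- array(0L, rep(n, 3))
  nanolga:::cpp_fill_fibers(occ, rep(n, 3), matrix(c(0, 20, 20), 1),
                            matrix(c(1, 0, 0), 1), n, 1, 1L)
  lat <- nanolga:::new_porous_lattice(occ, 50e-9, "ecm")
  set.seed(1)
  deg <- apply_degradation(lat, 1, segment_length = 200e-9, seed = 3L)
  removed <- which(lat$occupancy == 1L & deg$occupancy == 0L, arr.ind = TRUE)
  extent <- diff(range(removed[, 1])) + 1L   # voxels along the fiber axis
  expect_gte(extent, 3L)  # 200 nm = 4 voxels; ball clipping allows one less
  expect_lte(extent, 5L)
})

test_that("sphere arrays match the closed-form porosity and converge", {
  expect_identical(porosity(generate_sphere_array(0, 1e-6, 24L)), 1)
  closed <- 1 - pi / 48  # d/pitch = 1/2
  p24 <- porosity(generate_sphere_array(0.5e-6, 1e-6, 24L))
  p48 <- porosity(generate_sphere_array(0.5e-6, 1e-6, 48L))
  expect_lt(abs(p24 - closed), 0.01)
  # voxelization error shrinks as resolution doubles
  expect_lt(abs(p48 - closed), abs(p24 - closed))
  expect_error(generate_sphere_array(2e-6, 1e-6), "pitch")
})

test_that("connectivity is exact on constructed cases", {
  allf <- free_fluid_domain(1e-6, 4L)
  expect_identical(measure_connectivity(allf), 1)
  # two isolated fluid voxels in a solid block: largest component holds half
  occ <- array(1L, c(4, 4, 4))
  occ[1, 1, 1] <- 0L
  occ[3, 3, 3] <- 0L
  lat <- nanolga:::new_porous_lattice(occ, 1e-6, "ecm")
  expect_identical(measure_connectivity(lat), 0.5)
  solid <- nanolga:::new_porous_lattice(array(1L, c(3, 3, 3)), 1e-6, "ecm")
  expect_error(measure_connectivity(solid), "no fluid")
})

test_that("connectivity agrees with an independent igraph flood fill", {
  skip_if_not_installed("igraph")
  set.seed(42)
  n <- 12L
  for (rep in 1:3) {
    occ <- array(ifelse(runif(n^3) < 0.35, 1L, 0L), rep(n, 3))
    if (!any(occ == 0L)) next
    lat <- nanolga:::new_porous_lattice(occ, 1e-6, "ecm")
    got <- measure_connectivity(lat)
    # oracle: components of the periodic 6-neighbour fluid graph
    idx <- which(occ == 0L)
    coord <- arrayInd(idx, rep(n, 3)) - 1L
    id <- setNames(seq_along(idx), idx)
    edges <- integer(0)
    for (ax in 1:3) {
      nb <- coord
      nb[, ax] <- (nb[, ax] + 1L) %% n
      nbl <- nb[, 1] + n * (nb[, 2] + n * nb[, 3]) + 1L
      ok <- occ[nbl] == 0L
      edges <- c(edges, rbind(id[as.character(idx[ok])],
                              id[as.character(nbl[ok])]))
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    want <- max(igraph::components(g)$csize) / length(idx)
    expect_equal(got, want)
  }
})
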