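# shared fixture builders; everything is generated in code at test time

kB <- 1.380649e-23

# a small ECM lattice reused by several transport tests
small_ecm <- function(porosity = 0.94, n = 32L, seed = 11L) {
  generate_ecm(geometry_spec("ecm", target_porosity = porosity, n_nodes = n,
                             domain_size = n * 50e-9, seed = seed))
}

# a lattice that is solid except for a single fluid voxel
lone_pore <- function(n = 3L) {
  occ <- array(1L, rep(n, 3))
  occ[2, 2, 2] <- 0L
  nanolga:::new_porous_lattice(occ, 50e-9, "ecm")
}

quick_control <- function(dt = 1e-4, ...) transport_control(dt, ...)

# uniform-density flow state with a tiny sinusoidal shear perturbation
shear_wave_state <- function(lattice, tau, amp = 0.01) {
  nn <- dim(lattice$occupancy)
  st <- flow_state(lattice, tau)
  n <- prod(nn)
  kz <- 2 * pi / nn[3]
  uz <- rep(amp * sin(kz * (seq_len(nn[3]) - 0.5)), each = nn[1] * nn[2])
  model <- lattice_model("d3q19")
  f <- numeric(19 * n)
  for (p in seq_len(n)) {
    fe <- equilibrium_f(1, c(uz[p], 0, 0), model)
    f[p + n * (0:18)] <- fe
  }
  st$f <- f
  st
}
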