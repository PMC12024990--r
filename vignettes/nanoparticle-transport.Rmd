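---
title: "Modeling nanoparticle transport in tumor tissue with nanolga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nanoparticle transport in tumor tissue with nanolga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nanolga)
```

Nanoparticle (NP) drug carriers must cross two porous obstacles on their way
into a tumor: the extracellular matrix (ECM), a network of ~100 nm collagen
or hyaluronic-acid fibers with micron-scale pores, and the packed tumor and
stromal cells themselves, with interstitial gaps of a few microns.
`nanolga` simulates this transport at the mesoscale with three coupled
pieces:

1. **Stochastic voxel geometries** — fiber networks, cell packings and
   regular sphere arrays on a periodic cubic lattice;
2. **A lattice Boltzmann (LB) solver** for the interstitial fluid — D3Q19
   BGK flow coupled to a D3Q7 temperature distribution through a Boussinesq
   buoyancy force, with halfway bounce-back at every solid voxel;
3. **A lattice-gas particle tracker** — each NP carries a continuous
   velocity updated by an exact exponential drag integrator and moves
   between lattice nodes with probabilities proportional to its continuum
   displacement, interacting with walls through van der Waals,
   electrostatic double-layer and Lewis acid-base forces.

The analysis layer estimates diffusion coefficients from time-origin-averaged
mean squared displacements (MSD), `<MSD>_i = 2 D_i N t`, and implements the
*equivalent viscosity* reduction `mu_e = k_B T / (6 pi R0 D_sub)` that
replaces the explicit ECM by a homogeneous fluid for tissue-scale runs.

# Geometry generation

ECM networks place straight cylindrical fibers (default: 100 nm diameter,
70 um length, wrapping periodically) with random positions and orientations
until the fluid fraction reaches the target porosity; the last fiber's
length is bisected so the achieved porosity lands within ±0.005 of the
target. Fibers may interpenetrate, as physical fiber networks do.

Tumor tissue is built by *seeded growth*: tumor (ellipsoidal, default
semi-axes 7.5 × 5 × 5 um, long axis along a random coordinate axis) and
stromal (spherical, 10 um) cells grow from random seeds at a 4:1 count
ratio, each voxel claimed exclusively by the seed with the smallest scaled
distance. Grown cells never overlap; at high packing fractions they
truncate one another at the mutual boundary, which is how packings beyond
the ~38% jamming limit of rigid-body random sequential placement — up to the
54% fraction studied here — are reached. The growth factor is bisected to
hit the target fraction.

```{r}
lat <- generate_ecm(geometry_spec("ecm", target_porosity = 0.94, seed = 1))
porosity(lat)
measure_connectivity(lat)
plot_lattice_slice(lat)
```

A *degradation point* converts all fiber voxels inside a ball of diameter
200 nm (configurable) around a random fiber locus to fluid; on a thin fiber
this removes a segment of about that length along the axis. Loci are drawn
without replacement with a shared seed, so a 600-point edit is a strict
subset of a 1000-point edit and porosity is monotone in the point count.

# Fluid and temperature fields

The flow solver is a standard single-relaxation-time BGK scheme with Guo
forcing: velocity includes the half-force correction and the discrete force
terms carry the `(1 - 1/(2 tau_f))` prefactor, so the kinematic viscosity is
exactly `cs^2 (tau_f - 1/2)` in lattice units (verified to 2% by a decaying
shear wave in the test suite; the analogous thermal relation holds for the
D3Q7 stencil with diffusivity `(tau_g - 1/2)/4`). Solid voxels impose
halfway bounce-back, placing the no-slip wall midway between fluid and solid
nodes; domain faces are periodic, or fixed-density (pressure) on the z faces
via non-equilibrium extrapolation from the adjacent interior node, falling
back to bounce-back wherever the face is solid. A stability guard aborts
with the failing step and maximum velocity whenever `|u|` exceeds a
configurable lattice Mach limit (default 0.1).

Heated nanoparticles enter the temperature equation as Dirichlet nodes held
at the particle temperature before each streaming step. The coupled driver
(`run_thermal_flow()`) assembles the Boussinesq force
`F = beta (T0 - T) rho g` from the instantaneous temperature field each
cycle; the resulting steady velocity field is then frozen and handed to the
particle tracker (sub-cycling the ~0.5 ns LB step inside the ~0.1 ms
particle step would be pointless).

A magnitude note documented up front: with water properties at body
temperature, buoyant velocities at the 5 um ECM scale are of order
`g beta dT L^2 / nu ≈ 1e-7 m/s`, three orders below the Brownian terminal
speed of a 50 nm particle. The solver reproduces the *ordering* (hotter
particles, stronger convection — asserted in the tests); claims of
order-unity diffusion enhancement by micro-scale natural convection are not
reproducible from this physics and the package does not assert them.

# Particle transport

Per step `dt`, each particle accumulates the non-drag acceleration
`Sigma_a` (Brownian + magnetic + wall) and is advanced with the exact
solution of `du/dt = (u_f - u)/tau_p + Sigma_a`:

- velocity: `u* = u_f + tau_p Sigma_a + (u - u_f - tau_p Sigma_a) e^{-dt/tau_p}`
- displacement: the exact time integral of that solution.

`tau_p = m_p / (pref * pi * mu * d_p)` with the printed drag prefactor 6 by
default (the classical Stokes value 3 is a flag). The Brownian kick has the
fixed magnitude `2 k_B T / d_p` with a fresh uniformly random direction each
step (`"printed"` mode); a `"fluctuation_dissipation"` mode draws Gaussian
components with variance `2 zeta k_B T / dt` instead, which recovers the
Einstein diffusivity `k_B T / zeta` exactly and is used wherever results are
compared against Einstein-based references.

The displacement is then realized on the lattice: for each of the six face
directions `P_i = max(0, dx_p . e_i / dx)`, an independent Bernoulli trial
per axis, opposing directions zero. Components exceeding one lattice
spacing trigger automatic sub-stepping (never silent clipping), and the
realized moves are unbiased estimators of the continuum displacement
(property-tested). A `"continuous"` move mode bypasses the lattice
quantization for quantitative diffusion validation. MSDs always use
unwrapped coordinates.

Lattice quantization has a documented side effect in `"printed"` mode: when
the per-step displacement is much smaller than the spacing, rare whole-node
hops inflate the free diffusivity to roughly `v dx / 4` per axis. Absolute
coefficients in printed mode therefore depend on the resolution (they are
reported as-is); all headline comparisons in this package are *ratios*
between conditions sharing one resolution.

# Wall chemistry and adhesion

Within a 100 nm cutoff of a solid surface the particle feels, along the
outward wall normal (positive = repulsive):

- van der Waals: `F = -A d_p / (12 d^2)`, regularized below the 0.157 nm
  minimum-contact distance;
- electrostatic double layer (constant-potential sphere-plate):
  `F = pi d_p kappa eps eps0 [2 Psi1 Psi2 - (Psi1^2 + Psi2^2) e^{-kappa d}] /
  (e^{kappa d} - e^{-kappa d})`;
- Lewis acid-base: `F = pi d_p dG_AB e^{(d0 - d)/lambda}`, positive
  interaction energies (hydrophilic surfaces) repelling. The contact force
  can be set directly, e.g. from molecular-dynamics values for specific
  particle/polymer pairs.

Default constants (all configurable, all logged with every run): Hamaker
`1e-20` J, relative permittivity 78.5, screening length 10 nm, acid-base
decay length 1 nm, interaction cutoff 100 nm. The 10 nm screening length is
deliberate: at physiological-saline screening (~1 nm) the double-layer term
is dominated by van der Waals attraction at every separation for surface
potentials below ±20 mV, and surface charge could not modulate transport at
all — incompatible with the strong zeta-potential effects this model is
meant to express. The default instead describes the low-ionic-strength
regime in which charge stabilization operates.

**Adhesion** is event-based. A rejected move into a solid voxel is a
contact: if the net force profile between contact and cutoff has a repulsive
barrier exceeding the driving mobile forces (Brownian magnitude + inward
magnetic and drag components), the particle bounces. Otherwise it attaches
with probability `alpha = 0.05` (the attachment efficiency of colloidal
deposition kinetics) and parks at a 7.5 nm standoff — the ligand/PEG corona
thickness that keeps engineered particles out of the deep primary minimum.
The bond force is the net attraction at the standoff.

**Detachment** is a stochastic escape with mean lifetime proportional to the
bond force, `tau_b = tau_ref * F_bond / (2 k_B T / d_p)` with
`tau_ref = 50 ms`, accelerated by deterministic outward pull (magnetic force,
drag) through the Bell factor `exp(F_out d_park / k_B T)`. Desorbed
particles step one node outward so they genuinely leave the interaction
layer. The two kinetic constants (`alpha`, `tau_ref`) are the model's free
parameters; both sit in their conventional literature ranges (collision
efficiencies 0.01–0.1; sub-second residence of nonspecifically bound NPs)
and were fixed once so that bound and mobile populations exchange on the
timescale of a run — the regime in which MSD curves keep growing with
graded, surface-chemistry-dependent slopes. Stronger bonds (hydrophobic
attraction) lengthen residence; barriers (like charges, hydrophilic
coatings) block attachment entirely; magnetic gradients detach particles at
a rate that rises smoothly with the gradient.

# Equivalent viscosity and the validation studies

Tissue-scale runs replace the unresolved ECM + interstitial fluid by a
homogeneous fluid of viscosity `mu_e = k_B T / (6 pi R0 D_sub)`. The
package's default `D_sub` reference (3.82e-13 m^2/s, the mean of the
per-axis subdiffusion coefficients reported for the reference ECM
simulations) is a configuration input and can be replaced by a value
measured with `validate_equivalent_viscosity()`.

Two validation studies ship as experiments (both use the
fluctuation-dissipation mode with continuous moves, since their references —
the Maxwell relation and the Stokes–Einstein map — presuppose
fluctuation-dissipation-consistent transport):

- `validate-spheres`: Brownian ensembles in simple-cubic sphere arrays
  (one sphere per periodic 40^3 unit cell; diameters 0.2–0.4 of the
  pitch), compared to the Maxwell effective-medium relation
  `D_eff/D0 = 2 eps / (3 - eps)` at the voxelized porosity. `D0` is
  measured in an empty domain with identical numerics — and with the *same
  random streams* as the paired obstacle run, so the two ensembles see
  identical Brownian histories except at collisions and the common-mode
  sampling noise cancels in the ratio (common-random-number variance
  reduction). The diameters stay dilute because the Maxwell relation is a
  dilute-limit formula; an independent lattice-walk cross-check shows the
  voxelized domain's true hindrance departs from it by several percent once
  the sphere fills half the cell. Runs last 3.2 s with the fit window over
  lags of 0.13–0.48 s: long enough for each particle to sample several unit
  cells (the effective-medium regime) while keeping the lag-to-duration
  ratio small, where the time-origin-averaged estimator is efficient.
- `validate-equivalent-viscosity`: `D_sub` measured in explicit ECM
  geometries at three porosities, mapped to `mu_e`, re-run obstacle-free
  with the Stokes drag law on the particle radius, and compared back. The
  round trip is exact in expectation; the residual is sampling error.

# Study conditions (desk scale)

All experiments default to desk-scale versions of the reference conditions;
counts are plain arguments, so the full-scale setup (120 particles, 50
replicates) is one argument away.

| study | lattice | dt | steps | particles × replicates |
|---|---|---|---|---|
| ECM sweeps (porosity, degradation, zeta-ECM, hydrophilicity-ECM) | 100³ @ 50 nm | 1e-4 s | 30 000 (3 s) | 60 × 10 |
| tumor sweeps (cell fraction, zeta, magnetic) | 100³ @ 1 um | 1e-2 s | 2 000 (20 s) | 60 × 10 |
| sphere validation | 40³ @ 25 nm | 4e-6 s | 800 000 | 15 × 16 |
| equivalent-viscosity validation | 64³ @ 50 nm | 6e-6 s | 20 000 | 30 × 20 |

The ECM duration (3 s) is chosen so that several adhesion–release cycles
(bond lifetimes ~0.3 s) fall inside the MSD fit window — the quasi-steady
transport regime; shorter runs probe the initial-capture transient, whose
apparent D depends strongly on the window. Tumor runs (20 s) let free
particles cover roughly a cell diameter. The MSD fit window spans lags
between 10% and 50% of the maximum evaluated lag, skipping the ballistic
transient and the noisy long-lag tail; windows are logged with every fit.

```{r}
px <- run_experiment("porosity-sweep", seed = 1)
tidy(px)
autoplot(px)
```

# What the generator does and does not emulate

The synthetic geometries reproduce the *statistics* the tissue models
specify — porosity, fiber dimensions, cell shapes and ratio, degradation
editing — with straight rigid fibers and quasi-ellipsoidal cells. They do
not include fiber curvature or bundling, vasculature, lymphatics, cell
deformability or motion, particle–particle interactions, or receptor–ligand
binding. Passing tests therefore demonstrate correctness of the transport
machinery and fidelity of the implemented trends under these idealized
microstructures, not quantitative prediction for real tissue.

# Numerical choices and degenerate inputs

- Porosity targets are met within ±0.005 by construction or the generator
  fails loudly, naming the achieved value; porosity 1 returns an empty
  domain; a vanishing cell fraction returns all fluid.
- Node-centered voxels, 0-based indices, `x = (index + 0.5) dx`; all
  boundaries periodic unless a pressure face is requested.
- Near-wall normals are averaged over all equidistant nearest solid voxels,
  so symmetric gaps exert no net pull (a single-nearest tie-break would
  introduce a systematic drift — caught by a directional-bias check during
  development).
- The migration guard sub-steps displacements beyond one spacing; a hard
  cap (64 sub-steps) flags pathological force configurations with a warning.
- Ensemble statistics: arithmetic mean and SD across replicates; the
  representative replicate minimizes `|D_r - mean|`, ties to the lowest
  index. Negative fitted slopes are reported with a warning, never clamped.
- RNG: one root seed; replicate seeds derived by a fixed affine map;
  per-particle `mt19937_64` streams seeded from (replicate seed, particle
  index). All pipelines are bit-reproducible.

# Known limitations

- In printed-Brownian lattice mode, absolute D values are
  resolution-dependent (quantization inflation); ratios between conditions
  are the meaningful outputs, and the fluctuation-dissipation mode exists
  for absolute work.
- At 1 um tumor voxels, interstitial channels narrower than a voxel are not
  resolved, so dense-packing hindrance is underestimated relative to a
  continuum treatment at the same cell fraction.
- The adhesion kinetics are a declared model (barrier test + attachment
  efficiency + force-scaled lifetimes), not derived from first principles;
  its two constants are calibrated once, as documented above.
- Micro-scale natural convection is faithfully weak; see the magnitude note
  in the fluid section.
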