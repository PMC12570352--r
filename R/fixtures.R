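# Synthetic benchmark systems: ready-made simulations used for validation.
# Each builder is a pure function of its arguments plus the seed it stores on
# the simulation, so runs are reproducible.

#' Hard-sphere-like fluid (harmonic repulsion)
#'
#' A monodisperse fluid of 1 nm diameter particles at packing fraction `eta`
#' interacting by stiff harmonic repulsion.  With the default stiffness the
#' Barker-Henderson effective hard-sphere diameter is within ~2% of the
#' nominal diameter, so structural and thermodynamic observables can be
#' compared against hard-sphere theory at the nominal packing fraction.  The
#' default time step keeps the per-step force relaxation `D k dt / kT` below
#' ~0.3 for stability.
#'
#' @param eta packing fraction.
#' @param box box edge (nm).
#' @param diameter particle diameter (nm).
#' @param k repulsion stiffness (kJ/(mol nm^2)).
#' @param D translational diffusion coefficient (nm^2/ns).
#' @param dt time step (ns).
#' @param seed RNG seed.
#' @param barostat optional [berendsen_barostat()]; switches the run to NPT
#'   (the NPT benchmark uses the soft stiffness `k = 100` and `dt = 0.1` ns).
#' @return a configured [new_simulation()].
#' @export
fixture_hard_sphere_fluid <- function(eta = 0.3, box = 10, diameter = 1,
                                      k = 1e4, D = 0.0859, dt = 8e-4,
                                      seed = 1L, barostat = NULL) {
  sim <- new_simulation(box = box, dt = dt, boundary = "periodic", seed = seed)
  ty <- define_molecule_type("HS", c(0, 0, 0), diameter / 2,
                             params = sim$params, D = D)
  sim_register_type(sim, ty)
  sim_set_potential(sim, "HS", "HS", harmonic_repulsion(k, diameter))
  if (!is.null(barostat)) sim_set_barostat(sim, barostat)
  v_sphere <- pi / 6 * diameter^3
  n <- round(eta * prod(sim$box) / v_sphere)
  set.seed(seed)
  pk <- mc_pack_dense(sim$box, rep(diameter / 2, n), tol = 5e-3,
                      inflate = 1.12)
  sim_place_molecules(sim, "HS", positions = pk$positions)
  sim
}

#' NPT hard-sphere fluid benchmark
#'
#' The hard-sphere-like fluid with the Berendsen barostat switched on at
#' 0.5 ns, target pressure 10 kJ/(mol nm^3), diffusion coefficient
#' 0.0859 nm^2/ns and time step 0.1 ns.  The soft stiffness (k = 100) keeps
#' the integration stable at this time step.
#'
#' @param seed RNG seed.
#' @param box box edge (nm).
#' @param P0 target pressure (kJ/(mol nm^3)).
#' @param tau_P barostat coupling time (ns).
#' @export
fixture_npt_hard_sphere <- function(seed = 1L, box = 10, P0 = 10,
                                    tau_P = 5) {
  fixture_hard_sphere_fluid(eta = 0.3, box = box, k = 100, D = 0.0859,
                            dt = 0.1, seed = seed,
                            barostat = berendsen_barostat(P0, tau_P,
                                                          start_time = 0.5))
}

#' Reversible bimolecular benchmark A + B <-> C
#'
#' Three point-like species (radii 1.5, 2.25 and 1.56 nm, Stokes-Einstein
#' diffusion) with a fusion reaction of microscopic rate `k1` within
#' `R_react` and a fission back-reaction of rate `km1` at the same
#' dissociation radius.  With the default reaction-limited rates the species
#' kinetics match the mass-action ODE system using the macroscopic rate from
#' the rate-conversion formula.
#'
#' @param n0 initial copy number of A and of B.
#' @param box box edge (nm).
#' @param k1 fusion microscopic rate (1/ns).
#' @param km1 fission rate (1/ns).
#' @param R_react reaction radius (nm).
#' @param dt time step (ns).
#' @param seed RNG seed.
#' @param with_repulsion add harmonic excluded-volume repulsion between all
#'   species (radii-summed contact distances).
#' @return list with the simulation and the ODE rate constants
#'   (`kmacro_f` nm^3/ns, `km1` 1/ns).
#' @export
fixture_bimolecular_ab <- function(n0 = 400, box = 75, k1 = 1e-3,
                                   km1 = 5e-5, R_react = 4.5, dt = 1,
                                   seed = 1L, with_repulsion = FALSE) {
  sim <- new_simulation(box = box, dt = dt, boundary = "periodic",
                        seed = seed)
  radii <- c(A = 1.5, B = 2.25, C = 1.56)
  for (nm in names(radii)) {
    ty <- define_molecule_type(nm, c(0, 0, 0), radii[[nm]],
                               params = sim$params)
    sim_register_type(sim, ty)
  }
  if (with_repulsion) {
    for (a in names(radii)) for (b in names(radii))
      sim_set_potential(sim, a, b,
                        harmonic_repulsion(20, radii[[a]] + radii[[b]]))
  }
  sim_add_bimolecular(sim, c("A", "B"), "fusion", k1, R_react,
                      products = "C")
  sim_add_unimolecular(sim, "C", "fission", km1, products = c("A", "B"),
                       radius = R_react)
  set.seed(seed)
  sim_place_molecules(sim, "A", n = n0)
  sim_place_molecules(sim, "B", n = n0)
  D_A <- sim$types$A$D_scalar
  D_B <- sim$types$B$D_scalar
  lambda_AB(D_A, D_B, dt, R_react)
  list(sim = sim, kmacro_f = k_macro(k1, D_A, D_B, R_react), km1 = km1,
       D_A = D_A, D_B = D_B)
}

#' Multi-path bimolecular benchmark with two-bead educts
#'
#' Molecules A and B each carry two beads (`a1`, `a2` and `b1`, `b2`); four
#' fusion paths are defined on the particle pairs: (a1, b1) -> C and -> D,
#' (a1, b2) -> C, (a2, b2) -> C, plus the fission back-reaction C -> A + B.
#' The companion mass-action ODE system uses per-pair macroscopic rates from
#' the rate-conversion formula (paths sharing a particle pair share one
#' encounter volume; their converted total is split proportionally to the
#' microscopic rates).
#'
#' @param n0 initial copies of A and of B.
#' @param box box edge (nm).
#' @param rate_scale multiplies all forward microscopic rates.
#' @param R_react reaction radius of all paths (nm).
#' @param dt time step (ns).
#' @param seed RNG seed.
#' @param with_repulsion excluded-volume harmonic repulsion between all
#'   beads (stiffness 50 kJ/(mol nm^2), contact 2 nm).
#' @return list with the simulation and the ODE rates per path
#'   (`kmacro`, nm^3/ns) and `km1`.
#' @export
fixture_multipath_ab <- function(n0 = 300, box = 75, rate_scale = 1,
                                 R_react = 3, dt = 1, seed = 1L,
                                 with_repulsion = FALSE) {
  sim <- new_simulation(box = box, dt = dt, boundary = "periodic",
                        seed = seed)
  tyA <- define_molecule_type("A", rbind(c(-0.75, 0, 0), c(0.75, 0, 0)),
                              1, bead_types = c("a1", "a2"),
                              params = sim$params)
  tyB <- define_molecule_type("B", rbind(c(-0.75, 0, 0), c(0.75, 0, 0)),
                              1, bead_types = c("b1", "b2"),
                              params = sim$params)
  tyC <- define_molecule_type("C", c(0, 0, 0), 1.56, params = sim$params)
  tyD <- define_molecule_type("D", c(0, 0, 0), 1.5, params = sim$params)
  for (ty in list(tyA, tyB, tyC, tyD)) sim_register_type(sim, ty)
  k1 <- 2e-3 * rate_scale; k2 <- 1e-3 * rate_scale
  k3 <- 2e-3 * rate_scale; k4 <- 2e-3 * rate_scale
  km1 <- 5e-5
  sim_add_bimolecular(sim, c("a1", "b1"), "fusion", k1, R_react,
                      products = "C")
  sim_add_bimolecular(sim, c("a1", "b1"), "fusion", k2, R_react,
                      products = "D")
  sim_add_bimolecular(sim, c("a1", "b2"), "fusion", k3, R_react,
                      products = "C")
  sim_add_bimolecular(sim, c("a2", "b2"), "fusion", k4, R_react,
                      products = "C")
  sim_add_unimolecular(sim, "C", "fission", km1, products = c("A", "B"),
                       radius = R_react)
  if (with_repulsion) {
    for (a in c("a1", "a2")) for (b in c("b1", "b2"))
      sim_set_potential(sim, a, b, harmonic_repulsion(50, 2))
  }
  set.seed(seed)
  sim_place_molecules(sim, "A", n = n0)
  sim_place_molecules(sim, "B", n = n0)
  D_A <- tyA$D_scalar; D_B <- tyB$D_scalar
  # macroscopic rates: shared-pair paths convert their summed rate, split
  # proportionally
  km12 <- k_macro(k1 + k2, D_A, D_B, R_react)
  kmacro <- c(km12 * k1 / (k1 + k2), km12 * k2 / (k1 + k2),
              k_macro(k3, D_A, D_B, R_react),
              k_macro(k4, D_A, D_B, R_react))
  list(sim = sim, kmacro = kmacro, km1 = km1, rates = c(k1, k2, k3, k4))
}

#' Surface-diffusion benchmark on an icosphere
#'
#' Non-interacting surface walkers ray-marched on an icosphere with a
#' prescribed lateral diffusion coefficient (43 nm^2/us by default); the
#' short-lag MSD slope divided by 4 recovers the input coefficient.
#'
#' @param n walkers.
#' @param radius sphere radius (nm).
#' @param subdiv icosphere subdivisions.
#' @param D lateral diffusion coefficient (nm^2/ns); 0.043 nm^2/ns =
#'   43 nm^2/us.
#' @param dt time step (ns).
#' @param seed RNG seed.
#' @export
fixture_surface_diffusion <- function(n = 1000, radius = 50, subdiv = 3,
                                      D = 0.043, dt = 20, seed = 1L) {
  sim <- new_simulation(box = 4 * radius, dt = dt, boundary = "periodic",
                        seed = seed)
  mesh <- icosphere(radius, subdiv)
  sim_add_compartment(sim, mesh, "sphere")
  ty <- define_molecule_type("R", c(0, 0, 0), 1, params = sim$params,
                             surface = TRUE, D = D)
  sim_register_type(sim, ty)
  set.seed(seed)
  sim_place_surface(sim, "R", n, "sphere")
  sim
}

#' Two-component dense packing benchmark
#'
#' Spheres of radius 10 nm and 2.5 nm in a cubic periodic box packed
#' overlap-free to a target volume fraction above 52%.
#'
#' @param box box edge (nm).
#' @param target_fraction requested volume fraction.
#' @param frac_large fraction of the sphere volume carried by the large
#'   component.
#' @param seed RNG seed.
#' @return the [mc_pack_dense()] result plus the per-sphere radii.
#' @export
fixture_binary_packing <- function(box = 75, target_fraction = 0.53,
                                   frac_large = 0.55, seed = 1L) {
  V <- box^3
  v_l <- 4 / 3 * pi * 10^3
  v_s <- 4 / 3 * pi * 2.5^3
  n_l <- floor(target_fraction * frac_large * V / v_l)
  n_s <- ceiling((target_fraction * V - n_l * v_l) / v_s)
  radii <- c(rep(10, n_l), rep(2.5, n_s))
  set.seed(seed)
  res <- mc_pack_dense(rep(box, 3), radii, inflate = 1.3, shrink = 0.0015)
  res$radii <- radii
  res
}
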