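# Reactions: rate conversion, exact lifetime sampling, the encounter-based
# firing rule, execution semantics per reaction kind, and kinetics against
# mass-action ODE integration.

test_that("lambda_AB is the RMS inter-molecular displacement per step", {
  expect_equal(lambda_AB(0, 0, 1), 0)
  expect_equal(lambda_AB(0.5, 0.5, 0.25), 1)   # sqrt(4 * 1 * 0.25)
  expect_warning(lambda_AB(1, 1, 10, R_react = 2), "pass reaction partners")
  expect_silent(lambda_AB(0.01, 0.01, 0.1, R_react = 2))
})

test_that("k_macro has the Smoluchowski and reaction-limited limits", {
  # k -> Inf: diffusion limit 4 pi (D_A + D_B) R = 56.549 nm^3/ns
  expect_equal(k_macro(1e9, 0.5, 0.5, 4.5), 4 * pi * 4.5, tolerance = 1e-4)
  expect_equal(4 * pi * 1 * 4.5, 56.549, tolerance = 1e-4)
  # k -> 0: k_macro -> (4/3) pi R^3 k
  for (R in c(1, 4.5)) {
    k <- 1e-9
    expect_equal(k_macro(k, 0.5, 0.5, R), 4 / 3 * pi * R^3 * k,
                 tolerance = 1e-6)
  }
  # monotone in k, bounded by the Smoluchowski value
  ks <- 10^seq(-4, 3, by = 0.5)
  km <- vapply(ks, k_macro, numeric(1), D_A = 0.3, D_B = 0.7, R = 2)
  expect_true(all(diff(km) > 0))
  expect_true(all(km < 4 * pi * 1 * 2))
})

test_that("microscopic rate inversion round-trips over a log grid", {
  for (k in 10^seq(-6, 4, by = 1)) {
    km <- k_macro(k, 0.2, 0.3, 3)
    expect_equal(solve_k_micro(km, 0.2, 0.3, 3), k, tolerance = 1e-9)
  }
  expect_error(solve_k_micro(4 * pi * 0.5 * 3 * 1.01, 0.2, 0.3, 3),
               "Smoluchowski")
})

test_that("reaction waiting times are exactly exponential", {
  set.seed(20)
  tau <- sample_next_reaction_time(2, n = 1e5)
  expect_lt(abs(mean(tau) - 0.5), 3 * 0.5 / sqrt(1e5))
  ks <- suppressWarnings(stats::ks.test(tau, stats::pexp, rate = 2))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sample_next_reaction_time(0, 3), rep(Inf, 3))
  # plug-in value: U = exp(-2), k_t = 2  =>  tau = 1
  expect_equal(log(1 / exp(-2)) / 2, 1)
})

test_that("encounter firing probability follows 1 - exp(-sum k dt)", {
  expect_equal(doi_probability(0, 0.1), 0)
  expect_equal(doi_probability(log(2), 1), 0.5)
  expect_equal(doi_probability(c(1, 2), 0.5), 1 - exp(-c(0.5, 1)))
})

test_that("held pairs fire with the stated per-step probability", {
  # immobile A-B pairs inside the reaction radius; one step; the fusion
  # count is Binomial(n, 1 - exp(-k dt))
  n <- 800
  kdt <- log(2)      # p = 1/2 at dt = 1
  sim <- new_simulation(400, 1, seed = 77)
  for (nm in c("A", "B", "C")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 1, params = sim$params, D = 0)
    sim_register_type(sim, ty)
  }
  sim_add_bimolecular(sim, c("A", "B"), "fusion", kdt, 2, products = "C")
  # pair lattice: A at grid points, B displaced by 1 nm (inside R = 2),
  # pairs 12 nm apart so they never interact across pairs
  g <- as.matrix(expand.grid(x = seq(-90, 90, by = 20),
                             y = seq(-90, 90, by = 20),
                             z = seq(-90, 90, by = 20)))[seq_len(n), ]
  sim_place_molecules(sim, "A", positions = g)
  sim_place_molecules(sim, "B", positions = sweep(g, 2, c(1, 0, 0), "+"))
  traj <- run_simulation(sim, 1)
  fused <- traj$traces$counts[2, "C"]
  expect_lt(abs(fused - n / 2), 4 * sqrt(n * 0.25))
  # low-rate check on the survivors over the next step
  n2 <- sim$count[1]
  simulation_step(sim)
  fused2 <- n2 - sim$count[1]
  expect_lt(abs(fused2 - n2 / 2), 4.5 * sqrt(n2 * 0.25))
})

test_that("engine lifetimes of a decaying species are exponential", {
  rate <- 0.02
  sim <- new_simulation(50, 0.25, seed = 31)
  ty <- define_molecule_type("A", c(0, 0, 0), 0.5, params = sim$params, D = 1)
  sim_register_type(sim, ty)
  sim_add_unimolecular(sim, "A", "decay", rate)
  set.seed(31)
  sim_place_molecules(sim, "A", n = 1500)
  run_simulation(sim, 1500)   # 375 ns ~ 7.5 mean lifetimes
  ev <- event_log(sim)
  tdec <- ev$time[ev$kind == "decay"]
  expect_gt(length(tdec), 1400)
  ks <- suppressWarnings(stats::ks.test(tdec, stats::pexp, rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("two equal-rate paths are chosen 50/50", {
  sim <- new_simulation(50, 0.5, seed = 13)
  for (nm in c("A", "B", "C")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 0.5, params = sim$params,
                               D = 0.5)
    sim_register_type(sim, ty)
  }
  sim_add_unimolecular(sim, "A", "conversion", 0.05, products = "B")
  sim_add_unimolecular(sim, "A", "conversion", 0.05, products = "C")
  set.seed(13)
  n <- 1200
  sim_place_molecules(sim, "A", n = n)
  traj <- run_simulation(sim, 250)  # ~ 12 mean lifetimes
  nb <- sim$count[2]; nc <- sim$count[3]
  expect_gt(nb + nc, n - 10)
  expect_lt(abs(nb - (nb + nc) / 2), 4 * sqrt((nb + nc) * 0.25))
})

test_that("execution semantics: stoichiometry and state changes per kind", {
  # fusion: (N_A, N_B, N_C) changes by (-1, -1, +1); product at the midpoint
  sim <- new_simulation(50, 0.01, seed = 2)
  for (nm in c("A", "B", "C")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 1, params = sim$params, D = 0)
    sim_register_type(sim, ty)
  }
  sim_add_bimolecular(sim, c("A", "B"), "fusion", 1e9, 2, products = "C")
  sim_place_molecules(sim, "A", positions = matrix(c(1, 0, 0), 1, 3))
  sim_place_molecules(sim, "B", positions = matrix(c(2, 0, 0), 1, 3))
  run_simulation(sim, 1)
  expect_equal(unname(sim$count), c(1, 0, 0) * 0 + c(0, 0, 1))
  expect_equal(sim$pos[1, ], c(1.5, 0, 0), tolerance = 1e-12)

  # fission: educt replaced by two products at the dissociation radius
  sim2 <- new_simulation(50, 0.01, seed = 3)
  for (nm in c("X", "P", "Q")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 1, params = sim2$params, D = 0)
    sim_register_type(sim2, ty)
  }
  sim_add_unimolecular(sim2, "X", "fission", 1e9, products = c("P", "Q"),
                       radius = 4.5)
  sim_place_molecules(sim2, "X", positions = matrix(0, 1, 3))
  run_simulation(sim2, 1)
  expect_equal(unname(sim2$count), c(0, 1, 1))
  d <- sim2$pos[1, ] - sim2$pos[2, ]
  expect_equal(sqrt(sum(d^2)), 4.5, tolerance = 1e-9)

  # enzymatic: substrate converted in place, enzyme kept
  sim3 <- new_simulation(50, 0.01, seed = 4)
  for (nm in c("S", "E", "P")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 1, params = sim3$params, D = 0)
    sim_register_type(sim3, ty)
  }
  sim_add_bimolecular(sim3, c("S", "E"), "enzymatic", 1e9, 3, products = "P")
  sim_place_molecules(sim3, "S", positions = matrix(c(0, 0, 0), 1, 3))
  sim_place_molecules(sim3, "E", positions = matrix(c(1, 0, 0), 1, 3))
  run_simulation(sim3, 1)
  expect_equal(unname(sim3$count), c(0, 1, 1))

  # production: educt kept, n products on the dissociation shell
  sim4 <- new_simulation(50, 0.01, seed = 5)
  for (nm in c("G", "M")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 1, params = sim4$params, D = 0)
    sim_register_type(sim4, ty)
  }
  sim_add_unimolecular(sim4, "G", "production", 1e9, products = "M",
                       radius = 2, n_products = 3L)
  sim_place_molecules(sim4, "G", positions = matrix(0, 1, 3))
  simulation_step(sim4)
  expect_equal(sim4$count[1], 1L)
  expect_gte(sim4$count[2], 3L)
  mrows <- which(sim4$tid[seq_len(sim4$n)] == 2L)[1:3]
  expect_equal(unname(sqrt(rowSums(sim4$pos[mrows, ]^2))), rep(2, 3),
               tolerance = 1e-9)
})

test_that("particle-scope reactions retype only the affected particle", {
  sim <- new_simulation(50, 0.1, seed = 6)
  ty <- define_molecule_type("M", rbind(c(-1, 0, 0), c(1, 0, 0)), 0.5,
                             bead_types = c("site", "core"),
                             params = sim$params)
  sim_register_type(sim, ty)
  sim_add_unimolecular(sim, "site", "decay", 1e9, on_particle = TRUE)
  set.seed(6)
  sim_place_molecules(sim, "M", n = 5)
  simulation_step(sim)
  # molecules alive, the "site" bead retyped to the inert type
  expect_equal(sim$count[1], 5L)
  for (r in 1:5) {
    pts <- sim$ptype_names[ridsim:::mol_ptypes(sim, r)]
    expect_equal(pts, c("void", "core"))
  }
  ev <- event_log(sim)
  expect_equal(sum(ev$kind == "particle_decay"), 5L)
})

test_that("binding creates a persistent bond with rest length at contact", {
  sim <- new_simulation(50, 0.001, seed = 8)
  for (nm in c("A", "B")) {
    ty <- define_molecule_type(nm, c(0, 0, 0), 1, params = sim$params, D = 0)
    sim_register_type(sim, ty)
  }
  sim_add_bimolecular(sim, c("A", "B"), "binding", 1e9, 3, bond_k = 40)
  sim_place_molecules(sim, "A", positions = matrix(c(0, 0, 0), 1, 3))
  sim_place_molecules(sim, "B", positions = matrix(c(2, 0, 0), 1, 3))
  run_simulation(sim, 2)
  expect_equal(length(sim$bonds), 1L)
  expect_equal(sim$bonds[[1]]$r0, 2, tolerance = 1e-9)
  expect_equal(sim$bonds[[1]]$k, 40)
  # both molecules survive, and the bond force appears in the next sweep
  expect_equal(unname(sim$count), c(1L, 1L))
  sim$pos[2, ] <- c(2.5, 0, 0)   # stretch by 0.5
  ridsim:::sim_sweep(sim)
  expect_equal(sim$Fm[1, 1], 40 * 0.5, tolerance = 1e-9)
  expect_equal(sim$Fm[2, 1], -40 * 0.5, tolerance = 1e-9)
})

test_that("reaction-limited A+B<->C kinetics match the mass-action ODE", {
  fx <- fixture_bimolecular_ab(n0 = 400, box = 75, dt = 1, seed = 2)
  steps <- 3000
  traj <- run_simulation(fx$sim, steps, record_every = 100)
  V <- 75^3
  idx <- seq(1, steps + 1, by = 100)
  times <- traj$traces$time[idx]
  ode <- ode_ab_c(times, 400, 400, 0, fx$kmacro_f, fx$km1, V)
  ssa <- traj$traces$counts[idx, ]
  reacted <- pmax(400 - ode[, "A"], 1)
  # MC error of a birth-death count ~ sqrt(#reactions)
  expect_true(all(abs(ssa[, "A"] - ode[, "A"]) < 4 * sqrt(reacted) + 4))
  expect_true(all(abs(ssa[, "C"] - ode[, "C"]) < 4 * sqrt(reacted) + 4))
})

test_that("multi-path fusion network matches its ODE system", {
  fx <- fixture_multipath_ab(n0 = 300, box = 75, rate_scale = 1, dt = 1,
                             seed = 7)
  steps <- 2500
  traj <- run_simulation(fx$sim, steps, record_every = 125)
  V <- 75^3
  idx <- seq(1, steps + 1, by = 125)
  times <- traj$traces$time[idx]
  ode <- ode_multipath(times, 300, 300, fx$kmacro, fx$km1, V)
  ssa <- traj$traces$counts[idx, ]
  reacted <- pmax(300 - ode[, "A"], 1)
  expect_true(all(abs(ssa[, "A"] - ode[, "A"]) < 4 * sqrt(reacted) + 4))
  expect_true(all(abs(ssa[, "C"] - ode[, "C"]) < 4 * sqrt(reacted) + 4))
  expect_true(all(abs(ssa[, "D"] - ode[, "D"]) < 4 * sqrt(0.2 * reacted) + 4))
  # branching: D production stays a ~1/7 fraction of all fusions
  expect_gt(ssa[length(idx), "D"], 0)
})

test_that("excluded-volume repulsion slows association relative to the ODE", {
  fx <- fixture_multipath_ab(n0 = 300, box = 75, rate_scale = 5, dt = 0.2,
                             seed = 4, with_repulsion = TRUE)
  steps <- 2500
  traj <- run_simulation(fx$sim, steps, record_every = 250)
  V <- 75^3
  idx <- seq(1, steps + 1, by = 250)
  times <- traj$traces$time[idx]
  ode <- ode_multipath(times, 300, 300, fx$kmacro, fx$km1, V)
  ssa <- traj$traces$counts[idx, ]
  dev <- ssa[, "A"] - ode[, "A"]
  # systematically positive deviation: educts react slower than mass action
  expect_true(all(dev[-(1:3)] > 0))
  expect_gt(dev[length(dev)], 25)
})

test_that("reaction network exports as a consistent node/edge list", {
  fx <- fixture_multipath_ab(n0 = 0, seed = 1)
  g <- export_reaction_graph(fx$sim)
  kinds <- vapply(g$edges, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "fusion"), 4L)    # the four educt-pair paths
  expect_equal(sum(kinds == "fission"), 1L)
  node_ids <- vapply(g$nodes, `[[`, character(1), "id")
  for (e in g$edges) {
    expect_true(all(e$educts %in% node_ids))
    expect_true(all(e$products %in% node_ids))
  }
  # empty reaction table -> empty graph
  sim0 <- new_simulation(10, 0.1)
  g0 <- export_reaction_graph(sim0)
  expect_equal(length(g0$edges), 0L)
})
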