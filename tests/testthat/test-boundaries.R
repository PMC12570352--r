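# Boundary conditions: minimum image arithmetic, the fixed-concentration
# influx law (hand values, depth distribution, Poisson dispersion,
# stationarity), and wall reflection.

test_that("minimum image wraps into [-L/2, L/2) with the half-open tie", {
  expect_equal(minimum_image(c(8, 0, 0), 10), c(-2, 0, 0))
  expect_equal(minimum_image(c(5, 5, 5), 10), c(-5, -5, -5))  # tie break
  expect_equal(minimum_image(c(1 - 9, 0, 0), 10), c(2, 0, 0)) # sep of 1 and 9
  m <- minimum_image(rbind(c(7, -13, 0.2), c(5, 5, -5)), c(10, 12, 8))
  expect_equal(m, rbind(c(-3, -1, 0.2), c(-5, 5, 3)))
  # idempotent
  expect_equal(minimum_image(m, c(10, 12, 8)), m)
})

test_that("pair distances are invariant under global translation", {
  set.seed(6)
  box <- c(10, 10, 10)
  pos <- matrix(runif(90, -5, 5), 30, 3)
  g <- build_hgrid(pos, rep(2, 30), box)
  p1 <- collect_pairs(g, pos, rep(2, 30))
  shifted <- minimum_image(sweep(pos, 2, c(3.3, -7.1, 0.4), "+"), box)
  g2 <- build_hgrid(shifted, rep(2, 30), box)
  p2 <- collect_pairs(g2, shifted, rep(2, 30))
  expect_identical(pair_key(p1$i, p1$j), pair_key(p2$i, p2$j))
  expect_equal(sort(p1$r), sort(p2$r), tolerance = 1e-9)
})

test_that("influx rate matches the hand-evaluated one-sided flux law", {
  ir <- influx_rate(A = 100, C = 0.01, D = 1, dt = 0.1)
  expect_equal(ir$l_n, 0.356825, tolerance = 1e-5)
  expect_equal(ir$N_hit, 0.178412, tolerance = 1e-5)
  # no insertions at zero concentration
  spec <- boundary_spec("fixed_concentration", c(10, 10, 10))
  ins <- fixed_conc_influx(spec, C = 0, D = 1, dt = 0.1)
  expect_equal(nrow(ins$positions), 0L)
})

test_that("influx depth law is a valid CDF with non-negative density", {
  x <- seq(0, 5, by = 0.01)
  P <- influx_depth_cdf(x)
  expect_equal(P[1], 0)
  expect_equal(influx_depth_cdf(8), 1, tolerance = 1e-12)
  expect_true(all(diff(P) >= 0))
  # density = sqrt(pi) erfc(x): check against the numeric derivative
  dens <- sqrt(pi) * 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  expect_equal(diff(P) / 0.01, (dens[-1] + dens[-length(dens)]) / 2,
               tolerance = 1e-4)
})

test_that("sampled influx depths match the stated distribution (KS)", {
  set.seed(15)
  xs <- influx_depth_sample(1e5)
  ks <- suppressWarnings(stats::ks.test(xs, influx_depth_cdf))
  expect_gt(ks$p.value, 0.01)
  # mean depth of the physical displacement: sqrt(pi) l_n E[x]
  # E[x] = int x sqrt(pi) erfc(x) dx = sqrt(pi)/6 * 2/sqrt(pi) ... check by
  # quadrature instead of closed form
  f <- function(x) x * sqrt(pi) * 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  expect_equal(mean(xs), stats::integrate(f, 0, Inf)$value, tolerance = 0.01)
})

test_that("insertion counts are Poisson-dispersed and faces uniform", {
  spec <- boundary_spec("fixed_concentration", c(12, 12, 12))
  set.seed(30)
  counts <- vapply(1:2500, function(i)
    nrow(fixed_conc_influx(spec, C = 0.004, D = 1, dt = 0.2)$positions),
    numeric(1))
  disp <- var(counts) / mean(counts)
  expect_lt(abs(disp - 1), 0.12)
  # inserted positions stay inside the box and hug the faces
  ins <- fixed_conc_influx(spec, C = 0.4, D = 1, dt = 0.2)
  expect_true(all(abs(ins$positions) <= 6))
  depth_to_face <- 6 - apply(abs(ins$positions), 1, max)
  expect_lt(mean(depth_to_face), 1)
})

test_that("ideal diffusers relax to the outside concentration", {
  C <- 0.005
  sim <- new_simulation(20, 0.1, boundary = "fixed_concentration", seed = 44)
  ty <- define_molecule_type("A", c(0, 0, 0), 1, params = sim$params, D = 1)
  sim_register_type(sim, ty)
  sim_set_concentrations(sim, c(A = C))
  traj <- run_simulation(sim, 3000)     # starts empty, fills by influx
  nbar <- mean(traj$traces$counts[1001:3001, "A"])
  expected <- C * 20^3                  # 40 molecules
  # ~50 effective samples given the ~20-step population turnover
  se <- sqrt(expected) / sqrt(50)
  expect_lt(abs(nbar - expected), 3 * se)
  # Poisson-like dispersion of the stationary copy number
  expect_lt(abs(var(traj$traces$counts[1001:3001, "A"]) / nbar - 1), 0.35)
})

test_that("repulsive boxes keep every position inside", {
  sim <- new_simulation(10, 0.05, boundary = "repulsive", seed = 3)
  ty <- define_molecule_type("A", c(0, 0, 0), 0.5, params = sim$params, D = 2)
  sim_register_type(sim, ty)
  set.seed(3)
  sim_place_molecules(sim, "A", n = 60)
  for (s in 1:2000) {
    simulation_step(sim)
    if (s %% 200 == 0)
      expect_true(all(abs(sim$pos[seq_len(sim$n), ]) <= 5))
  }
  expect_true(all(abs(sim$pos[seq_len(sim$n), ]) <= 5))
})

test_that("periodic runs keep unwrapped displacements consistent", {
  sim <- new_simulation(5, 0.1, seed = 9)
  ty <- define_molecule_type("A", c(0, 0, 0), 0.5, params = sim$params, D = 1)
  sim_register_type(sim, ty)
  set.seed(9)
  sim_place_molecules(sim, "A", n = 20)
  traj <- run_simulation(sim, 400, record_every = 20)
  # recorded positions are unwrapped: by 40 ns (MSD ~ 240 nm^2 >> box^2)
  # most walkers have left the primary box image
  last <- traj$frames[[length(traj$frames)]]
  expect_gt(mean(apply(abs(last$pos) > 2.5, 1, any)), 0.5)
  m <- msd(traj, "A")
  expect_gt(max(m$msd), 5^2)   # diffusion carried past the box edge
  slope <- coef(lm(msd ~ 0 + lag, m))[[1]]
  expect_lt(abs(slope - 6) / 6, 0.2)
})
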