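# Pair potentials: hand-computed values, energy/force consistency by central
# finite differences, continuity at the cutoff, and agreement between the R
# evaluator and the compiled sweep kernel.

fd_check <- function(pot, rs, h = 1e-6, tol = 1e-6) {
  ev <- evaluate_pair(pot, rs)
  up <- evaluate_pair(pot, rs + h)$U
  dn <- evaluate_pair(pot, rs - h)$U
  num <- (up - dn) / (2 * h)
  expect_equal(ev$dUdr, num, tolerance = tol)
}

test_that("harmonic repulsion matches hand evaluation", {
  pot <- harmonic_repulsion(k = 10, sigma = 3)
  at_contact <- evaluate_pair(pot, 3)
  expect_equal(at_contact$U, 0)
  expect_equal(at_contact$dUdr, 0)
  ev <- evaluate_pair(pot, 2)
  expect_equal(ev$U, 5)            # k/2 (r-sigma)^2 = 5 kJ/mol
  expect_equal(abs(ev$dUdr), 10)   # |F| = 10 kJ/(mol nm)
  expect_equal(evaluate_pair(pot, 4)$U, 0)
  expect_error(evaluate_pair(pot, -0.1), "non-negative")
})

test_that("all potential kinds are energy-force consistent and C1 at cutoff", {
  pots <- list(
    harmonic_repulsion(10, 3),
    weak_piecewise_harmonic(k = 60, sigma = 1.5, depth = 2, cutoff = 3),
    csw(eps = 3, rw = 2, delta = 0.3),
    phs(eps = 2.437, sigma = 2),
    custom_potential(U = function(r) exp(-r) * (r - 4)^2,
                     dUdr = function(r) exp(-r) * (2 * (r - 4) - (r - 4)^2),
                     cutoff = 4))
  for (pot in pots) {
    rs <- seq(0.7 * pot$cutoff, 0.999 * pot$cutoff, length.out = 23)
    fd_check(pot, rs, tol = 1e-5)
    # continuity at the cutoff
    eps <- 1e-8
    expect_lt(abs(evaluate_pair(pot, pot$cutoff - eps)$U -
                  evaluate_pair(pot, pot$cutoff + eps)$U), 1e-5)
  }
  # piecewise harmonic: well depth at contact, C1 at the two joints
  wph <- weak_piecewise_harmonic(60, 1.5, 2, 3)
  expect_equal(evaluate_pair(wph, 1.5)$U, -2)
  fd_check(wph, c(1.5 - 1e-4, 1.5 + 1e-4, 2.25 - 1e-4, 2.25 + 1e-4), tol = 1e-4)
})

test_that("compiled sweep kernel agrees with the R potential evaluator", {
  set.seed(21)
  box <- c(12, 12, 12)
  n <- 40
  pos <- cbind(runif(n, -6, 6), runif(n, -6, 6), runif(n, -6, 6))
  pots <- list(harmonic_repulsion(25, 2.5),
               weak_piecewise_harmonic(40, 1.2, 1.5, 2.8),
               csw(2, 1.5, 0.25),
               phs(2.437, 2))
  for (pot in pots) {
    sim <- new_simulation(box, 0.01, seed = 1)
    ty <- define_molecule_type("A", c(0, 0, 0), 0.6, params = sim$params)
    sim_register_type(sim, ty)
    sim_set_potential(sim, "A", "A", pot)
    sim_place_molecules(sim, "A", positions = pos)
    pr <- ridsim:::sim_sweep(sim)
    # brute-force reference from evaluate_pair
    Fref <- matrix(0, n, 3); virial <- 0; energy <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- minimum_image(pos[i, ] - pos[j, ], box)
      r <- sqrt(sum(d^2))
      if (r >= pot$cutoff) next
      ev <- evaluate_pair(pot, r)
      f <- -ev$dUdr * d / r
      Fref[i, ] <- Fref[i, ] + f
      Fref[j, ] <- Fref[j, ] - f
      virial <- virial + sum(f * d)
      energy <- energy + ev$U
    }
    expect_equal(sim$Fm[1:n, ], Fref, tolerance = 1e-9)
    expect_equal(sim$virial, virial, tolerance = 1e-9)
    expect_equal(sim$energy, energy, tolerance = 1e-9)
    # momentum conservation (relative: PHS magnitudes explode at random
    # overlaps, leaving only cancellation error)
    expect_lt(max(abs(colSums(sim$Fm[1:n, ]))),
              1e-12 * max(1, max(abs(sim$Fm[1:n, ]))))
  }
})

test_that("virial pressure has the ideal and single-pair limits", {
  expect_equal(virial_pressure(100, 2.437, 0, 1000), 100 * 2.437 / 1000)
  # one pair at fixed separation with known force: W = F . r = 10 * 2 = 20
  expect_equal(virial_pressure(2, 2.437, 20, 500), (2 * 2.437 + 20 / 3) / 500)
  expect_error(virial_pressure(1, 2.437, 0, 0), "positive")
})

test_that("bead-bead forces map to molecule force, torque and molecular virial", {
  # two rigid dumbbells arranged so only one bead pair interacts
  sim <- new_simulation(c(30, 30, 30), 0.01, seed = 1)
  ty <- define_molecule_type("M", rbind(c(-1, 0, 0), c(1, 0, 0)), 0.5,
                             params = sim$params)
  sim_register_type(sim, ty)
  sim_set_potential(sim, "M", "M", harmonic_repulsion(10, 1.5))
  q0 <- quat_identity(1)
  sim_place_molecules(sim, "M", positions = rbind(c(0, 0, 0), c(3, 0, 0)),
                      quats = rbind(q0, q0))
  ridsim:::sim_sweep(sim)
  # interacting beads: x=1 (mol 1) and x=2 (mol 2), r = 1, overlap 0.5
  f <- 10 * 0.5
  expect_equal(sim$Fm[1, ], c(-f, 0, 0), tolerance = 1e-12)
  expect_equal(sim$Fm[2, ], c(f, 0, 0), tolerance = 1e-12)
  # force along the lever arm: zero torque
  expect_equal(sim$Tq[1, ], c(0, 0, 0), tolerance = 1e-12)
  # molecular virial referenced to the centers: F . (R1 - R2) = (-5) * (-3)
  expect_equal(sim$virial, 15, tolerance = 1e-12)
  expect_equal(sim$energy, 0.5 * 10 * 0.5^2, tolerance = 1e-12)
})

test_that("total force vanishes on random 50-particle configurations", {
  set.seed(33)
  sim <- new_simulation(c(10, 10, 10), 0.01, seed = 1)
  ty <- define_molecule_type("A", c(0, 0, 0), 0.5, params = sim$params)
  sim_register_type(sim, ty)
  sim_set_potential(sim, "A", "A", harmonic_repulsion(100, 1.6))
  sim_place_molecules(sim, "A", n = 50)
  ridsim:::sim_sweep(sim)
  expect_lt(max(abs(colSums(sim$Fm[1:50, ]))), 1e-9)
})
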