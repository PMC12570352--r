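# Rigid-bead diffusion tensors: Stokes-Einstein closures, frame covariance,
# positive definiteness, center of diffusion, and agreement with the
# hand-derived two-bead closed forms.

par_default <- hydro_params()

test_that("single sphere reproduces Stokes-Einstein to 6+ digits", {
  a <- 1.0
  ten <- compute_diffusion_tensor(matrix(c(0, 0, 0), 1, 3), a, par_default)
  Dt <- par_default$kT / (6 * pi * par_default$viscosity * a)
  Dr <- par_default$kT / (8 * pi * par_default$viscosity * a^3)
  expect_equal(ten$D_tt, diag(Dt, 3), tolerance = 1e-9)
  expect_equal(ten$D_rr, diag(Dr, 3), tolerance = 1e-9)
  expect_equal(ten$D_scalar, Dt, tolerance = 1e-9)
  # center of diffusion at the bead center
  expect_equal(ten$center_of_diffusion, c(0, 0, 0), tolerance = 1e-9)
  # off-center input: center of diffusion found at the bead
  ten2 <- compute_diffusion_tensor(matrix(c(3, -2, 1), 1, 3), a, par_default)
  expect_equal(ten2$center_of_diffusion, c(3, -2, 1), tolerance = 1e-7)
})

test_that("tensors rotate covariantly under rigid rotation of the beads", {
  set.seed(5)
  beads <- matrix(rnorm(9, sd = 2), 3, 3)
  radii <- c(0.8, 1.2, 0.5)
  t0 <- compute_diffusion_tensor(beads, radii, par_default)
  th <- 0.7
  R <- quat_to_matrix(quat_from_rotvec(th * c(0, 0, 1)))
  t1 <- compute_diffusion_tensor(beads %*% t(R), radii, par_default)
  expect_equal(t1$D_tt, R %*% t0$D_tt %*% t(R), tolerance = 1e-8)
  expect_equal(t1$D_rr, R %*% t0$D_rr %*% t(R), tolerance = 1e-8)
  expect_equal(sort(eigen(t1$D_tt)$values), sort(eigen(t0$D_tt)$values),
               tolerance = 1e-9)
  expect_equal(as.numeric(R %*% t0$center_of_diffusion),
               t1$center_of_diffusion, tolerance = 1e-8)
})

test_that("D_tt and D_rr are symmetric positive definite for random models", {
  set.seed(8)
  for (trial in 1:8) {
    nb <- sample(2:5, 1)
    beads <- matrix(rnorm(3 * nb, sd = 1.5), nb, 3)
    radii <- runif(nb, 0.3, 1.2)
    ten <- compute_diffusion_tensor(beads, radii, par_default)
    expect_equal(ten$D_tt, t(ten$D_tt), tolerance = 1e-10)
    expect_true(all(eigen(ten$D_tt, symmetric = TRUE)$values > 0))
    expect_true(all(eigen(ten$D_rr, symmetric = TRUE)$values > 0))
    # coupling is symmetric at the center of diffusion (defining property)
    expect_lt(max(abs(ten$D_tr - t(ten$D_tr))), 1e-9 * max(abs(ten$D_tt)))
  }
})

test_that("two touching beads match the closed-form dumbbell tensors", {
  a <- 1; L <- 2
  orc <- dumbbell_oracle(a, L, par_default$viscosity, par_default$kT)
  beads <- rbind(c(0, 0, -L / 2), c(0, 0, L / 2))
  ten <- compute_diffusion_tensor(beads, c(a, a), par_default)
  expect_equal(ten$D_tt[3, 3], orc$D_par, tolerance = 1e-9)
  expect_equal(ten$D_tt[1, 1], orc$D_perp, tolerance = 1e-9)
  expect_equal(ten$D_tt[2, 2], orc$D_perp, tolerance = 1e-9)
  expect_equal(ten$D_rr[1, 1], orc$D_tumble, tolerance = 1e-9)
  expect_equal(ten$D_rr[3, 3], orc$D_spin, tolerance = 1e-9)
  # symmetric body: center of diffusion at the geometric center
  expect_equal(ten$center_of_diffusion, c(0, 0, 0), tolerance = 1e-9)
  # separated beads too (pure non-overlap RPY branch)
  L2 <- 3.5
  orc2 <- dumbbell_oracle(a, L2, par_default$viscosity, par_default$kT)
  ten2 <- compute_diffusion_tensor(rbind(c(0, 0, -L2 / 2), c(0, 0, L2 / 2)),
                                   c(a, a), par_default)
  expect_equal(ten2$D_tt[3, 3], orc2$D_par, tolerance = 1e-9)
  expect_equal(ten2$D_tt[1, 1], orc2$D_perp, tolerance = 1e-9)
  expect_equal(ten2$D_rr[1, 1], orc2$D_tumble, tolerance = 1e-9)
})

test_that("linear three-bead rod diffuses faster along its axis", {
  beads <- rbind(c(0, 0, -2), c(0, 0, 0), c(0, 0, 2))
  ten <- compute_diffusion_tensor(beads, rep(1, 3), par_default)
  expect_gt(ten$D_tt[3, 3], ten$D_tt[1, 1])
  expect_equal(ten$D_tt[1, 1], ten$D_tt[2, 2], tolerance = 1e-9)
})

test_that("degenerate geometries are rejected", {
  expect_error(compute_diffusion_tensor(rbind(c(0, 0, 0), c(0, 0, 0)),
                                        c(1, 1), par_default),
               "degenerate|singular")
  expect_error(define_molecule_type("X", matrix(0, 0, 3), numeric(0)),
               "at least one bead")
  expect_error(define_molecule_type("X", c(0, 0, 0), -1), "positive")
})

test_that("molecule types are recentred on the center of diffusion", {
  # asymmetric dumbbell: CoD lies on the axis, closer to the large bead
  beads <- rbind(c(0, 0, 0), c(0, 0, 3))
  ty <- define_molecule_type("Y", beads, c(2, 0.7), params = par_default)
  expect_lt(max(abs(ty$D_tr - t(ty$D_tr))), 1e-10)
  cod <- ty$center_of_diffusion
  expect_true(cod[3] > 0 && cod[3] < 1.5)      # toward the big bead
  expect_equal(ty$beads[1, ], -cod, tolerance = 1e-9)
  expect_equal(ty$D_scalar, sum(diag(ty$D_tt)) / 3, tolerance = 1e-12)
})

test_that("bead models round-trip through the CSV dialect", {
  df <- data.frame(x = c(0, 1.5), y = 0, z = 0, radius = c(1, 0.5),
                   type = c("core", "site"))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  ty <- read_bead_model(f, "M", params = par_default)
  expect_equal(ty$nbeads, 2L)
  expect_equal(ty$ptypes, c("core", "site"))
  expect_equal(ty$radii, c(1, 0.5))
})
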