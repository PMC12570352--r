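# Rigid-bead hydrodynamics: diffusion tensors and the center of diffusion.
#
# Unit system used throughout the package: lengths in nm, times in ns,
# energies in kJ/mol.  The Boltzmann constant is then
# kB = 0.008314462 kJ/(mol K), and a dynamic viscosity of 1 mPa s (water near
# 20 C) corresponds to 1e-3 J s/m^3 * N_A = 0.6022 kJ ns/(mol nm^3).

#' Boltzmann constant in kJ/(mol K)
#' @export
KB <- 0.008314462

#' Hydrodynamic parameters
#'
#' @param temperature solvent temperature in K.
#' @param viscosity dynamic viscosity in kJ ns/(mol nm^3).  The default,
#'   0.6022, is water at 20 C (1.0 mPa s times Avogadro's number, converted
#'   to the nm/ns/kJ/mol unit system).
#' @return a list with class `hydro_params`.
#' @export
hydro_params <- function(temperature = 293.15, viscosity = 0.6022) {
  stopifnot(temperature > 0, viscosity > 0)
  structure(list(temperature = temperature, viscosity = viscosity,
                 kB = KB, kT = KB * temperature),
            class = "hydro_params")
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)  # column-major: skew3(v) %*% x == v x x
}

# Rotne-Prager-Yamakawa mobility block for two beads of radii ai, aj at
# separation vector rij (world/body frame), including the overlap correction
# for unequal radii.
rpy_block <- function(rij, ai, aj, eta) {
  r <- sqrt(sum(rij^2))
  if (r < 1e-12) stop("degenerate geometry: coincident beads")
  rh <- rij / r
  P <- outer(rh, rh)
  if (r > ai + aj) {
    c1 <- (1 + (ai^2 + aj^2) / (3 * r^2))
    c2 <- (1 - (ai^2 + aj^2) / r^2)
    (c1 * diag(3) + c2 * P) / (8 * pi * eta * r)
  } else if (r > abs(ai - aj)) {
    c1 <- (16 * r^3 * (ai + aj) - ((ai - aj)^2 + 3 * r^2)^2) / (32 * r^3)
    c2 <- (3 * ((ai - aj)^2 - r^2)^2) / (32 * r^3)
    (c1 * diag(3) + c2 * P) / (6 * pi * eta * ai * aj)
  } else {
    diag(3) / (6 * pi * eta * max(ai, aj))
  }
}

#' Diffusion tensor of a rigid bead assembly
#'
#' Computes the 6x6 rigid-body diffusion tensor of a set of beads moving as
#' one rigid body, by the bead-model supermatrix method: the 3N x 3N
#' Rotne-Prager-Yamakawa pair mobility matrix (with overlap corrections for
#' unequal radii) is inverted to a friction supermatrix, contracted to the
#' 6x6 rigid-body friction tensor, the rotational block is given the standard
#' volume correction (6 eta V per bead volume), and the resulting diffusion
#' tensor is shifted to the center of diffusion -- the unique point at which
#' the translation-rotation coupling block is symmetric.
#'
#' @param beads numeric n x 3 matrix of bead centers (nm, any body frame).
#' @param radii numeric vector of n bead radii (nm).
#' @param params a [hydro_params()] object.
#' @return a list with elements `D_tt`, `D_rr`, `D_tr` (3x3 blocks of the
#'   diffusion tensor at the center of diffusion; nm^2/ns, 1/ns, nm/ns),
#'   `center_of_diffusion` (3-vector in the input frame) and `D_scalar`
#'   (`Tr(D_tt)/3`).
#' @export
compute_diffusion_tensor <- function(beads, radii, params = hydro_params()) {
  beads <- matrix(as.numeric(beads), ncol = 3)
  n <- nrow(beads)
  stopifnot(n >= 1, length(radii) == n, all(radii > 0))
  eta <- params$viscosity
  kT <- params$kT

  # grand mobility matrix
  M <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    M[ii, ii] <- diag(3) / (6 * pi * eta * radii[i])
    if (i < n) for (j in (i + 1):n) {
      jj <- (3 * j - 2):(3 * j)
      B <- rpy_block(beads[i, ] - beads[j, ], radii[i], radii[j], eta)
      M[ii, jj] <- B
      M[jj, ii] <- t(B)
    }
  }
  xi <- tryCatch(solve(M), error = function(e)
    stop("degenerate geometry: singular bead mobility supermatrix"))

  # contract to the 6x6 rigid-body friction tensor at the input origin
  A <- lapply(seq_len(n), function(i) skew3(beads[i, ]))
  Xtt <- matrix(0, 3, 3); Xtr <- matrix(0, 3, 3); Xrr <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in seq_len(n)) {
      jj <- (3 * j - 2):(3 * j)
      xij <- xi[ii, jj]
      Xtt <- Xtt + xij
      Xtr <- Xtr - xij %*% A[[j]]
      Xrr <- Xrr - A[[i]] %*% xij %*% A[[j]]
    }
  }
  # volume correction restores the rotational friction a point-force bead
  # model misses (exact for a single sphere)
  Xrr <- Xrr + 6 * eta * sum(4 / 3 * pi * radii^3) * diag(3)
  Xi6 <- rbind(cbind(Xtt, Xtr), cbind(t(Xtr), Xrr))
  Xi6 <- (Xi6 + t(Xi6)) / 2
  D0 <- kT * solve(Xi6)

  Dtt <- D0[1:3, 1:3]; Dtr <- D0[1:3, 4:6]
  Drt <- D0[4:6, 1:3]; Drr <- D0[4:6, 4:6]

  # center of diffusion: solve  skew(d) Drr + Drr skew(d) = Dtr - Drt
  # (the shift d = P - O that makes the coupling block symmetric)
  avec <- function(W) c(W[3, 2], W[1, 3], W[2, 1])
  Mmap <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- 1
    avec(skew3(e) %*% Drr + Drr %*% skew3(e))
  }, numeric(3))
  d <- solve(Mmap, avec(Dtr - Drt))

  # congruence transform of the diffusion tensor to the new origin P = O + d
  Ad <- skew3(d)
  Tinv <- rbind(cbind(diag(3), -Ad), cbind(matrix(0, 3, 3), diag(3)))
  DP <- Tinv %*% D0 %*% t(Tinv)
  DP <- (DP + t(DP)) / 2
  Dtr_P <- DP[1:3, 4:6]
  if (max(abs(Dtr_P - t(Dtr_P))) > 1e-9 * max(abs(DP)))
    warning("coupling tensor not symmetric at the computed center of diffusion")

  list(D_tt = DP[1:3, 1:3],
       D_rr = DP[4:6, 4:6],
       D_tr = (Dtr_P + t(Dtr_P)) / 2,
       center_of_diffusion = d,
       D_scalar = sum(diag(DP[1:3, 1:3])) / 3)
}

#' Define a rigid bead molecule type
#'
#' A molecule type fixes an immutable rigid topology (bead positions and
#' radii, plus optional patch particles acting as interaction/reaction
#' sites), and the hydrodynamic diffusion tensors computed from the bead
#' geometry with [compute_diffusion_tensor()].  All coordinates are recentred
#' on the center of diffusion, which is the reference point propagated by
#' the Brownian integrator and used for the molecular virial.
#'
#' @param name molecule type name.
#' @param beads n x 3 matrix of bead centers in the body frame (nm); a plain
#'   vector of length 3 is taken as a single bead.
#' @param radii bead radii (nm), recycled to the number of beads.
#' @param bead_types particle type name of each bead (defaults to `name`);
#'   particle types key pair potentials and bimolecular reactions.
#' @param patches optional m x 3 matrix of additional interaction/reaction
#'   site positions (body frame, nm).
#' @param patch_types particle type names of the patches.
#' @param params a [hydro_params()] object.
#' @param surface logical; `TRUE` for membrane species diffusing on a mesh
#'   surface.
#' @param D,D_rot optional scalar isotropic translational (nm^2/ns) and
#'   rotational (1/ns) diffusion coefficients that override the computed
#'   tensors (handy for benchmark species with prescribed D).
#' @return an object of class `molecule_type`.
#' @export
define_molecule_type <- function(name, beads, radii, bead_types = NULL,
                                 patches = NULL, patch_types = NULL,
                                 params = hydro_params(), surface = FALSE,
                                 D = NULL, D_rot = NULL) {
  if (is.null(dim(beads))) beads <- matrix(beads, ncol = 3, byrow = TRUE)
  beads <- matrix(as.numeric(beads), ncol = 3)
  n <- nrow(beads)
  if (n < 1) stop("molecule type needs at least one bead")
  radii <- rep_len(as.numeric(radii), n)
  if (any(radii <= 0)) stop("bead radii must be positive")
  if (is.null(bead_types)) bead_types <- rep(name, n)
  bead_types <- rep_len(as.character(bead_types), n)

  ten <- compute_diffusion_tensor(beads, radii, params)
  cod <- ten$center_of_diffusion
  local <- sweep(beads, 2, cod)
  ptypes <- bead_types
  pradii <- radii
  if (!is.null(patches)) {
    if (is.null(dim(patches))) patches <- matrix(patches, ncol = 3, byrow = TRUE)
    patches <- sweep(matrix(as.numeric(patches), ncol = 3), 2, cod)
    if (is.null(patch_types)) stop("patch_types required when patches are given")
    patch_types <- rep_len(as.character(patch_types), nrow(patches))
    local <- rbind(local, patches)
    ptypes <- c(ptypes, patch_types)
    pradii <- c(pradii, rep(0, nrow(patches)))
  }
  if (!is.null(D)) ten$D_tt <- diag(3) * D
  if (!is.null(D_rot)) ten$D_rr <- diag(3) * D_rot

  structure(list(
    name = name,
    beads = local[seq_len(n), , drop = FALSE],
    radii = radii,
    local = local,              # all particles: beads then patches
    ptypes = ptypes,
    pradii = pradii,
    nbeads = n,
    D_tt = ten$D_tt,
    D_rr = ten$D_rr,
    D_tr = ten$D_tr,
    center_of_diffusion = cod,  # in the input frame
    D_scalar = sum(diag(ten$D_tt)) / 3,
    surface = isTRUE(surface),
    point_like = n == 1L && is.null(patches)
  ), class = "molecule_type")
}

#' @export
print.molecule_type <- function(x, ...) {
  cat(sprintf("<molecule_type> %s: %d bead(s), %d particle(s)%s\n", x$name,
              x$nbeads, nrow(x$local), if (x$surface) ", surface-bound" else ""))
  cat(sprintf("  D = %.6g nm^2/ns (Tr(D_tt)/3)\n", x$D_scalar))
  invisible(x)
}

#' Read a bead model from CSV
#'
#' Expects columns `x`, `y`, `z`, `radius` and optionally `type`.
#'
#' @param file path to a CSV file.
#' @param name molecule type name.
#' @param ... passed on to [define_molecule_type()].
#' @export
read_bead_model <- function(file, name, ...) {
  df <- utils::read.csv(file)
  stopifnot(all(c("x", "y", "z", "radius") %in% names(df)))
  define_molecule_type(name, as.matrix(df[, c("x", "y", "z")]), df$radius,
                       bead_types = if ("type" %in% names(df)) df$type else NULL,
                       ...)
}
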