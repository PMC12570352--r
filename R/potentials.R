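# Short-ranged pair potentials.  Energies kJ/mol, distances nm, forces
# kJ/(mol nm).  All built-in kinds are C1 at their cutoff.

#' Pair potentials
#'
#' Constructors for the built-in short-ranged pair potentials:
#'
#' * `harmonic_repulsion(k, sigma)`: \eqn{U = k/2 (r - \sigma)^2} for
#'   \eqn{r \le \sigma}, 0 beyond; the workhorse excluded-volume potential
#'   (a stiff `k` approximates a hard sphere of diameter `sigma`).
#' * `weak_piecewise_harmonic(k, sigma, depth, cutoff)`: harmonic repulsion
#'   below the contact distance `sigma` joined to a piecewise-harmonic
#'   attractive well of the given `depth` that closes at `cutoff` (C1
#'   everywhere).
#' * `csw(eps, rw, delta)`: continuous square well,
#'   \eqn{U = -\epsilon/2 [1 - \tanh((r - r_w)/\delta)]}; cutoff at
#'   `rw + 6 delta` where the well has decayed to ~1e-5 of `eps`.
#' * `phs(eps, sigma)`: pseudo hard sphere, the cut-shifted 50-49 Mie
#'   potential with cutoff `(50/49) sigma`.
#' * `custom_potential(U, dUdr, cutoff)`: user-supplied vectorized energy and
#'   derivative functions.
#'
#' @param k force constant, kJ/(mol nm^2).
#' @param sigma contact distance, nm.
#' @param depth well depth, kJ/mol.
#' @param cutoff interaction cutoff, nm.
#' @param eps well depth / energy scale, kJ/mol.
#' @param rw well radius, nm.
#' @param delta well edge width, nm.
#' @param U,dUdr vectorized functions of distance r.
#' @return an object of class `pair_potential`.
#' @name pair_potentials
NULL

new_pair_potential <- function(kind_id, kind, cutoff, params) {
  stopifnot(cutoff > 0)
  structure(c(list(kind_id = kind_id, kind = kind, cutoff = cutoff), params),
            class = "pair_potential")
}

#' @rdname pair_potentials
#' @export
harmonic_repulsion <- function(k, sigma) {
  new_pair_potential(1L, "harmonic_repulsion", sigma,
                     list(k = k, sigma = sigma, p3 = 0))
}

#' @rdname pair_potentials
#' @export
weak_piecewise_harmonic <- function(k, sigma, depth, cutoff) {
  stopifnot(cutoff > sigma)
  new_pair_potential(2L, "weak_piecewise_harmonic", cutoff,
                     list(k = k, sigma = sigma, p3 = depth))
}

#' @rdname pair_potentials
#' @export
csw <- function(eps, rw, delta) {
  new_pair_potential(3L, "csw", rw + 6 * delta,
                     list(k = eps, sigma = rw, p3 = delta))
}

#' @rdname pair_potentials
#' @export
phs <- function(eps, sigma) {
  new_pair_potential(4L, "phs", 50 / 49 * sigma,
                     list(k = eps, sigma = sigma, p3 = 0))
}

#' @rdname pair_potentials
#' @export
custom_potential <- function(U, dUdr, cutoff) {
  stopifnot(is.function(U), is.function(dUdr))
  new_pair_potential(0L, "custom", cutoff, list(U = U, dUdr = dUdr))
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf("<pair_potential> %s, cutoff %.4g nm\n", x$kind, x$cutoff))
  invisible(x)
}

#' Evaluate a pair potential
#'
#' @param pot a [pair_potentials] object.
#' @param r distances (nm), vectorized.
#' @return list with `U` (kJ/mol) and `dUdr` (kJ/(mol nm)); the force on the
#'   first particle along the separation unit vector is `-dUdr`.
#' @export
evaluate_pair <- function(pot, r) {
  if (any(r < 0)) stop("distance r must be non-negative")
  switch(pot$kind,
    harmonic_repulsion = {
      d <- pmin(r - pot$sigma, 0)
      list(U = 0.5 * pot$k * d^2, dUdr = pot$k * d)
    },
    weak_piecewise_harmonic = {
      w <- pot$cutoff - pot$sigma
      U <- numeric(length(r)); dU <- numeric(length(r))
      a <- r < pot$sigma
      U[a] <- 0.5 * pot$k * (r[a] - pot$sigma)^2 - pot$p3
      dU[a] <- pot$k * (r[a] - pot$sigma)
      b <- r >= pot$sigma & r < pot$sigma + w / 2
      U[b] <- -pot$p3 + 2 * pot$p3 * (r[b] - pot$sigma)^2 / w^2
      dU[b] <- 4 * pot$p3 * (r[b] - pot$sigma) / w^2
      cc <- r >= pot$sigma + w / 2 & r < pot$cutoff
      U[cc] <- -2 * pot$p3 * (r[cc] - pot$cutoff)^2 / w^2
      dU[cc] <- -4 * pot$p3 * (r[cc] - pot$cutoff) / w^2
      list(U = U, dUdr = dU)
    },
    csw = {
      x <- (r - pot$sigma) / pot$p3
      list(U = -0.5 * pot$k * (1 - tanh(x)),
           dUdr = 0.5 * pot$k * (1 - tanh(x)^2) / pot$p3)
    },
    phs = {
      pref <- 50 * (50 / 49)^49 * pot$k
      inside <- r < pot$cutoff
      s50 <- ifelse(inside, (pot$sigma / r)^50, 0)
      s49 <- ifelse(inside, (pot$sigma / r)^49, 0)
      list(U = ifelse(inside, pref * (s50 - s49) + pot$k, 0),
           dUdr = ifelse(inside, pref * (-50 * s50 + 49 * s49) / r, 0))
    },
    custom = {
      inside <- r < pot$cutoff
      list(U = ifelse(inside, pot$U(r), 0),
           dUdr = ifelse(inside, pot$dUdr(r), 0))
    },
    stop("unknown potential kind ", pot$kind)
  )
}

#' Virial pressure
#'
#' \eqn{P = (N k_B T + W/3) / V} with the scalar molecular virial
#' \eqn{W = \sum_{pairs} \vec F_{ij} \cdot \vec r_{ij}} referenced to the
#' molecule centers of diffusion (the correct reference point for rigid-body
#' Brownian dynamics).
#'
#' @param n_molecules number of molecules.
#' @param kT thermal energy, kJ/mol.
#' @param virial scalar molecular virial, kJ/mol.
#' @param volume box volume, nm^3.
#' @return pressure in kJ/(mol nm^3).
#' @export
virial_pressure <- function(n_molecules, kT, virial, volume) {
  if (volume <= 0) stop("volume must be positive")
  (n_molecules * kT + virial / 3) / volume
}
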