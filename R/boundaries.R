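# Boundary conditions: periodic (minimum image), repulsive (specular box
# walls), and fixed concentration (absorbing walls coupled to an outside
# molecule pool by Poisson influx).

#' Minimum image convention
#'
#' Wraps separation vectors (or coordinates) into the half-open interval
#' `[-L/2, L/2)` per dimension.
#'
#' @param d numeric vector or n x 3 matrix of separations (nm).
#' @param box box edge lengths, recycled to 3.
#' @return wrapped values, same shape as `d`.
#' @export
minimum_image <- function(d, box) {
  if (is.null(dim(d))) {
    box <- rep_len(box, length(d))
    d - box * floor(d / box + 0.5)
  } else {
    box <- rep_len(box, ncol(d))
    d - rep(box, each = nrow(d)) * floor(sweep(d, 2, box, "/") + 0.5)
  }
}

#' Boundary specification
#'
#' @param kind one of `"periodic"`, `"repulsive"`, `"fixed_concentration"`.
#' @param box box edge lengths (3-vector, nm); the box is centered on the
#'   origin.
#' @param concentrations named vector of outside concentrations per molecule
#'   type (nm^-3), used by `"fixed_concentration"`.
#' @return a list of class `boundary_spec`.
#' @export
boundary_spec <- function(kind = c("periodic", "repulsive",
                                   "fixed_concentration"),
                          box, concentrations = numeric(0)) {
  kind <- match.arg(kind)
  box <- rep_len(as.numeric(box), 3)
  stopifnot(all(box > 0), all(concentrations >= 0))
  structure(list(kind = kind, box = box, concentrations = concentrations),
            class = "boundary_spec")
}

# inverse CDF of the influx depth distribution, precomputed once:
# P(x) = 1 - exp(-x^2) + sqrt(pi) x erfc(x)
influx_depth_icdf <- local({
  icdf <- NULL
  function() {
    if (is.null(icdf)) {
      x <- seq(0, 6, length.out = 4096)
      erfc <- 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
      P <- 1 - exp(-x^2) + sqrt(pi) * x * erfc
      P[length(P)] <- 1
      icdf <<- stats::approxfun(P, x, rule = 2, ties = "ordered")
    }
    icdf
  }
})

#' Influx depth distribution
#'
#' CDF of the normalized distance x from the boundary at which an entering
#' molecule materializes:
#' \eqn{P(\tilde x) = 1 - e^{-\tilde x^2} + \sqrt{\pi}\,\tilde x\,
#' \mathrm{erfc}(\tilde x)}; the physical depth is
#' \eqn{\sqrt{\pi}\, l_n \tilde x} along the inward normal with
#' \eqn{l_n = \sqrt{4 D \Delta t / \pi}} the mean one-sided normal
#' displacement per step.
#'
#' @param x normalized depth(s).
#' @param n number of random draws for `influx_depth_sample`.
#' @export
influx_depth_cdf <- function(x) {
  erfc <- 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
  1 - exp(-x^2) + sqrt(pi) * x * erfc
}

#' @rdname influx_depth_cdf
#' @export
influx_depth_sample <- function(n) {
  influx_depth_icdf()(stats::runif(n))
}

#' Expected boundary hits per step
#'
#' \eqn{N_{hit} = A (l_n/2) C} with boundary measure `A` (area in nm^2 for
#' volume species; replace by the boundary edge length in nm for surface
#' species with `C` per nm^2), outside concentration `C` and
#' \eqn{l_n = \sqrt{4 D \Delta t/\pi}}.
#'
#' @param A boundary surface area (nm^2) or edge length (nm).
#' @param C outside concentration (nm^-3 or nm^-2).
#' @param D scalar translational diffusion coefficient (nm^2/ns).
#' @param dt time step (ns).
#' @return list with `N_hit` and `l_n`.
#' @export
influx_rate <- function(A, C, D, dt) {
  l_n <- sqrt(4 * D * dt / pi)
  list(N_hit = A * (l_n / 2) * C, l_n = l_n)
}

#' Draw fixed-concentration boundary insertions for one species
#'
#' For each of the six box faces, the number of entering molecules is
#' Poisson with mean \eqn{A (l_n/2) C}; each insertion point is uniform on
#' the face, displaced inward by \eqn{\sqrt\pi\, l_n \tilde x} with
#' \eqn{\tilde x} drawn from [influx_depth_cdf()], with a uniformly random
#' orientation.
#'
#' @param spec a [boundary_spec()] of kind `"fixed_concentration"`.
#' @param C outside concentration of the species (nm^-3).
#' @param D scalar diffusion coefficient (nm^2/ns).
#' @param dt time step (ns).
#' @return list with `positions` (n x 3) and `quats` (n x 4).
#' @export
fixed_conc_influx <- function(spec, C, D, dt) {
  box <- spec$box
  if (C <= 0 || D <= 0)
    return(list(positions = matrix(0, 0, 3), quats = matrix(0, 0, 4)))
  l_n <- sqrt(4 * D * dt / pi)
  pos <- matrix(0, 0, 3)
  for (axis in 1:3) {
    oth <- setdiff(1:3, axis)
    A <- box[oth[1]] * box[oth[2]]
    Nhit <- A * (l_n / 2) * C
    for (side in c(-1, 1)) {
      n <- stats::rpois(1, Nhit)
      if (n == 0) next
      p <- matrix(0, n, 3)
      p[, oth[1]] <- stats::runif(n, -box[oth[1]] / 2, box[oth[1]] / 2)
      p[, oth[2]] <- stats::runif(n, -box[oth[2]] / 2, box[oth[2]] / 2)
      depth <- sqrt(pi) * l_n * influx_depth_sample(n)
      p[, axis] <- side * box[axis] / 2 - side * depth
      pos <- rbind(pos, p)
    }
  }
  list(positions = pos, quats = quat_random(nrow(pos)))
}

# Specular reflection of positions at the box walls (repulsive boundaries for
# point-like species; displacement magnitudes below box/2 assumed).
reflect_box <- function(pos, box) {
  for (d in 1:3) {
    h <- box[d] / 2
    over <- pos[, d] > h
    pos[over, d] <- 2 * h - pos[over, d]
    under <- pos[, d] < -h
    pos[under, d] <- -2 * h - pos[under, d]
  }
  pos
}
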