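# Reaction-rate machinery: microscopic <-> macroscopic rate conversion for
# the encounter-probability (Doi) scheme, exact lifetime sampling for
# unimolecular channels, and the per-step bimolecular firing rule.

#' Mean inter-molecular displacement per step
#'
#' \eqn{\lambda_{AB} = \sqrt{4 (D_A + D_B) \Delta t}}: the scale of the
#' change in distance between two diffusing molecules within one step.  The
#' reaction radius should not be smaller, otherwise partners can pass through
#' each other between bimolecular evaluations; a warning is emitted when
#' `R_react` is supplied and violated.
#'
#' @param D_A,D_B translational diffusion coefficients, nm^2/ns.
#' @param dt time step, ns.
#' @param R_react optional reaction radius to check against, nm.
#' @return `lambda_AB` in nm.
#' @export
lambda_AB <- function(D_A, D_B, dt, R_react = NULL) {
  stopifnot(D_A >= 0, D_B >= 0, dt > 0)
  lam <- sqrt(4 * (D_A + D_B) * dt)
  if (!is.null(R_react) && lam > R_react)
    warning(sprintf(paste("lambda_AB = %.4g nm exceeds the reaction radius",
                          "%.4g nm: molecules can pass reaction partners",
                          "between steps; reduce dt or increase R_react"),
                    lam, R_react))
  lam
}

#' Macroscopic rate constant of a Doi-scheme bimolecular reaction
#'
#' For two species with diffusion constants `D_A`, `D_B` reacting with
#' microscopic rate `k` whenever closer than `R`:
#' \deqn{k_{macro} = 4\pi (D_A+D_B) [R - \sqrt{(D_A+D_B)/k}
#'       \tanh(R \sqrt{k/(D_A+D_B)})].}
#' The Smoluchowski diffusion limit \eqn{4\pi(D_A+D_B)R} is approached as
#' `k` grows; for small `k` the reaction-limited form
#' \eqn{(4/3)\pi R^3 k} is recovered.
#'
#' @param k microscopic rate, 1/ns.
#' @param D_A,D_B diffusion coefficients, nm^2/ns.
#' @param R reaction radius, nm.
#' @return `k_macro` in nm^3/ns.
#' @export
k_macro <- function(k, D_A, D_B, R) {
  D <- D_A + D_B
  if (k <= 0) return(0)
  if (D <= 0) return(4 / 3 * pi * R^3 * k * 0 + NaN)
  x <- R * sqrt(k / D)
  if (x < 1e-4) {
    # series: kmacro = 4 pi D (R - tanh(x) R / x) ~ (4/3) pi R^3 k (1 - ...)
    4 * pi * D * R * (x^2 / 3 - 2 * x^4 / 15)
  } else {
    4 * pi * D * (R - sqrt(D / k) * tanh(x))
  }
}

#' Microscopic rate from a macroscopic rate constant
#'
#' Numerically inverts [k_macro()] by bracketed root finding (relative
#' tolerance 1e-12).  `k_macro` must lie below the Smoluchowski bound
#' \eqn{4\pi(D_A+D_B)R}.
#'
#' @param kmac macroscopic rate constant, nm^3/ns.
#' @param D_A,D_B diffusion coefficients, nm^2/ns.
#' @param R reaction radius, nm.
#' @return microscopic rate `k` in 1/ns.
#' @export
solve_k_micro <- function(kmac, D_A, D_B, R) {
  D <- D_A + D_B
  if (kmac <= 0) return(0)
  bound <- 4 * pi * D * R
  if (kmac >= bound)
    stop("no solution: k_macro = ", signif(kmac, 6),
         " exceeds the Smoluchowski bound 4 pi (D_A+D_B) R = ",
         signif(bound, 6), " nm^3/ns")
  f <- function(logk) k_macro(exp(logk), D_A, D_B, R) - kmac
  lo <- log(kmac / (4 / 3 * pi * R^3)) - 2
  while (f(lo) > 0) lo <- lo - 5
  hi <- lo + 5
  while (f(hi) < 0) hi <- hi + 5
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-14)$root)
}

#' Sample the next unimolecular reaction time
#'
#' Exact lifetime sampling: with total channel rate
#' \eqn{k_t = \sum_i k_i}, the waiting time is
#' \eqn{\tau = \ln(1/U)/k_t} with U uniform on (0,1), i.e. exponential with
#' mean \eqn{1/k_t}.  The timer is drawn once per molecule and only redrawn
#' when the molecule's channel set changes, which keeps the scheme exact
#' without per-step Bernoulli trials.
#'
#' @param k_t total reaction rate, 1/ns.
#' @param n number of samples.
#' @return waiting times in ns (`Inf` when `k_t <= 0`).
#' @export
sample_next_reaction_time <- function(k_t, n = 1L) {
  if (k_t <= 0) return(rep(Inf, n))
  log(1 / stats::runif(n)) / k_t
}

#' Doi firing probability
#'
#' Probability that a pair within the reaction radius undergoes at least one
#' reaction during a step: \eqn{p = 1 - \exp(-\sum_i k_i \Delta t)}.
#'
#' @param k_total summed path rates, 1/ns.
#' @param dt time step, ns.
#' @export
doi_probability <- function(k_total, dt) {
  -expm1(-k_total * dt)
}

# ---------------------------------------------------------------------------
# Channel constructors (attached to a simulation via sim_add_* in
# simulation.R).  Unimolecular kinds: decay, conversion, fission, production
# (molecule scope), decay, conversion, release (particle scope).  Bimolecular
# kinds: fusion, enzymatic (molecule scope, linked to a particle-type pair
# for the distance test), enzymatic_particle, binding (particle scope).

#' Reaction path descriptors
#'
#' Low-level constructors for reaction paths; normally created through
#' [sim_add_unimolecular()] / [sim_add_bimolecular()].
#'
#' @param kind reaction kind (see Details in the simulation help).
#' @param rate path rate, 1/ns.
#' @param products character vector of product molecule (or particle) types.
#' @param radius dissociation/reaction radius, nm.
#' @param n_products number of products for `production` paths.
#' @param bond_k,bond_unbind_rate harmonic bond stiffness (kJ/(mol nm^2)) and
#'   optional unbinding rate for `binding` paths.
#' @export
reaction_path <- function(kind, rate, products = character(0), radius = NA,
                          n_products = 1L, bond_k = NA,
                          bond_unbind_rate = 0) {
  stopifnot(rate >= 0)
  list(kind = kind, rate = rate, products = products, radius = radius,
       n_products = as.integer(n_products), bond_k = bond_k,
       bond_unbind_rate = bond_unbind_rate)
}
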