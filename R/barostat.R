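# Berendsen barostat for NPT runs.

#' Berendsen barostat parameters
#'
#' @param P0 target pressure, kJ/(mol nm^3).
#' @param tau_P pressure coupling time constant, ns (must exceed the time
#'   step).
#' @param start_time simulation time at which the barostat switches on, ns.
#' @return a list of class `barostat_params`.
#' @export
berendsen_barostat <- function(P0, tau_P, start_time = 0) {
  stopifnot(tau_P > 0)
  structure(list(P0 = P0, tau_P = tau_P, start_time = start_time,
                 mode = "isotropic"), class = "barostat_params")
}

#' One isotropic Berendsen pressure-coupling step
#'
#' Box lengths and molecule center positions are scaled by
#' \eqn{\mu = (1 - (\Delta t/\tau_P)(P_0 - P))^{1/3}}; when the instantaneous
#' pressure P is below target, \eqn{\mu < 1} compresses the system and drives
#' the pressure up.  Molecule-internal bead geometry is rigid and never
#' scaled.
#'
#' @param centers n x 3 molecule centers (nm).
#' @param box 3-vector of box edges (nm).
#' @param P instantaneous virial pressure, kJ/(mol nm^3).
#' @param params a [berendsen_barostat()] object.
#' @param dt time step, ns.
#' @return list with scaled `centers`, `box` and the factor `mu`.
#' @export
berendsen_step <- function(centers, box, P, params, dt) {
  arg <- 1 - (dt / params$tau_P) * (params$P0 - P)
  if (arg <= 0)
    stop("barostat instability: scaling factor mu^3 = ", signif(arg, 4),
         " <= 0; reduce dt/tau_P or the pressure deviation")
  mu <- arg^(1 / 3)
  list(centers = centers * mu, box = box * mu, mu = mu)
}
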