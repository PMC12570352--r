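# Overdamped rigid-body Brownian propagator.
#
# First-order Euler-Maruyama scheme in the body frame: with body-frame force
# F_b and torque T_b,
#   dx_b = (D_tt F_b / kT) dt + xi,          xi  ~ N(0, 2 D_tt dt)
#   dw_b = (D_rr T_b / kT) dt + xi_r,        xi_r ~ N(0, 2 D_rr dt)
# dx_b is rotated to the world frame and added to the center-of-diffusion
# position; dw_b is applied as a body-frame rotation quaternion by right
# multiplication, followed by renormalization.  Translation-rotation coupling
# is not used by the propagator (the coupling tensor is computed and stored
# with the molecule type, but is identically zero for the symmetric bodies
# the validation suite uses and small for typical bead models).

chol_2D <- function(D, dt) {
  S <- 2 * D * dt
  S <- (S + t(S)) / 2
  t(chol(S))  # lower factor L with L L' = 2 D dt
}

#' Propagate rigid bead molecules one Brownian step
#'
#' Vectorized over all molecules of one type.  Positions advance by the
#' deterministic drift `D_tt F dt / kT` plus Gaussian noise of covariance
#' `2 D_tt dt` (both in the body frame, rotated to world); orientations by a
#' body-frame random rotation vector with covariance `2 D_rr dt` plus torque
#' drift, applied by quaternion multiplication and renormalized.
#'
#' @param pos n x 3 positions (center of diffusion, world frame, nm).
#' @param quat n x 4 orientation quaternions.
#' @param force n x 3 world-frame forces (kJ/(mol nm)).
#' @param torque n x 3 world-frame torques (kJ/mol).
#' @param mtype a [define_molecule_type()] object.
#' @param dt time step (ns).
#' @param kT thermal energy (kJ/mol).
#' @param rotate update orientations (skipped for point-like isotropic
#'   species, whose orientation is dynamically irrelevant).
#' @return list with updated `pos` and `quat`.
#' @export
propagate_step <- function(pos, quat, force, torque, mtype, dt, kT,
                           rotate = TRUE) {
  n <- nrow(pos)
  if (n == 0L) return(list(pos = pos, quat = quat))
  if (any(!is.finite(force)) || any(!is.finite(torque)))
    stop("numerical error: non-finite force/torque for molecule(s) ",
         paste(utils::head(which(rowSums(!is.finite(cbind(force, torque))) > 0)),
               collapse = ", "))
  Dtt <- mtype$D_tt
  iso_t <- max(abs(Dtt - diag(Dtt[1, 1], 3))) < 1e-14
  if (iso_t) {
    s <- sqrt(2 * Dtt[1, 1] * dt)
    dx <- force * (Dtt[1, 1] * dt / kT) +
      matrix(stats::rnorm(3 * n, sd = s), n, 3)
  } else {
    Fb <- quat_rotate(quat_conjugate(quat), force)
    L <- chol_2D(Dtt, dt)
    xi <- matrix(stats::rnorm(3 * n), n, 3) %*% t(L)
    dxb <- Fb %*% t(Dtt) * (dt / kT) + xi
    dx <- quat_rotate(quat, dxb)
  }
  pos <- pos + dx
  if (rotate) {
    Drr <- mtype$D_rr
    iso_r <- max(abs(Drr - diag(Drr[1, 1], 3))) < 1e-14
    Tb <- quat_rotate(quat_conjugate(quat), torque)
    if (iso_r) {
      w <- Tb * (Drr[1, 1] * dt / kT) +
        matrix(stats::rnorm(3 * n, sd = sqrt(2 * Drr[1, 1] * dt)), n, 3)
    } else {
      Lr <- chol_2D(Drr, dt)
      w <- Tb %*% t(Drr) * (dt / kT) +
        matrix(stats::rnorm(3 * n), n, 3) %*% t(Lr)
    }
    quat <- quat_normalize(quat_multiply(quat, quat_from_rotvec(w)))
  }
  list(pos = pos, quat = quat)
}
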