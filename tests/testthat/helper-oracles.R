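# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force O(N^2) pair enumeration, closed-form
# two-bead hydrodynamics, direct ray/triangle scans, hard-sphere equations of
# state, and mass-action ODE integration.

# all unordered pairs with r_ij < (cut_i + cut_j)/2, by direct enumeration
brute_force_pairs <- function(pos, cutoffs, box, periodic) {
  n <- nrow(pos)
  out <- character(0)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    if (periodic) d <- d - box * floor(d / box + 0.5)
    if (sqrt(sum(d^2)) < (cutoffs[i] + cutoffs[j]) / 2)
      out <- c(out, paste(i, j))
  }
  sort(out)
}

pair_key <- function(i, j) sort(paste(pmin(i, j), pmax(i, j)))

# Rotne-Prager-Yamakawa scalar couplings of two equal beads (radius a) at
# center distance L >= 2a, and the closed-form rigid-dumbbell diffusion
# tensor derived by hand from the 2x2 block inversion:
#   D_par  = kT (m_s + m_l) / 2         (translation along the axis)
#   D_perp = kT (m_s + m_t) / 2         (translation transverse)
#   D_tumble = kT (m_s - m_t) / (2 h^2) friction-corrected by bead volume
#   D_spin   = kT / (16 pi eta a^3)     (volume term only)
# where m_s = 1/(6 pi eta a), m_l/m_t are the longitudinal/transverse RPY
# couplings and h = L/2.
dumbbell_oracle <- function(a, L, eta, kT) {
  m_s <- 1 / (6 * pi * eta * a)
  m_l <- (2 - (4 * a^2) / (3 * L^2)) / (8 * pi * eta * L)
  m_t <- (1 + (2 * a^2) / (3 * L^2) + (1 - (2 * a^2) / L^2) * 0) /
    (8 * pi * eta * L)
  h <- L / 2
  Vcorr <- 6 * eta * 2 * (4 / 3 * pi * a^3)
  xi_tumble <- 2 * h^2 / (m_s - m_t) + Vcorr
  list(D_par = kT * (m_s + m_l) / 2,
       D_perp = kT * (m_s + m_t) / 2,
       D_tumble = kT / xi_tumble,
       D_spin = kT / (16 * pi * eta * a^3))
}

# hard-sphere equations of state / structure
carnahan_starling_Z <- function(eta) (1 + eta + eta^2 - eta^3) / (1 - eta)^3
py_contact <- function(eta) (1 + eta / 2) / (1 - eta)^2

# first ray-triangle hit by exhaustive scan over all triangles, using the
# plane-intersection + projected barycentric formulation (independent of the
# package's Moller-Trumbore kernel)
oracle_first_hit <- function(V, F, origin, disp, tmin = 1e-12) {
  best <- NULL
  for (t in seq_len(nrow(F))) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; cc <- V[F[t, 3], ]
    n <- pracma_cross(b - a, cc - a)
    denom <- sum(n * disp)
    if (abs(denom) < 1e-14) next
    tt <- sum(n * (a - origin)) / denom
    if (tt <= tmin || tt > 1) next
    p <- origin + tt * disp
    # barycentric via normal equations
    e1 <- b - a; e2 <- cc - a; vp <- p - a
    d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
    det <- d11 * d22 - d12^2
    v <- (d22 * sum(vp * e1) - d12 * sum(vp * e2)) / det
    w <- (d11 * sum(vp * e2) - d12 * sum(vp * e1)) / det
    if (v >= -1e-10 && w >= -1e-10 && v + w <= 1 + 1e-10) {
      if (is.null(best) || tt < best$t) best <- list(t = tt, tri = t, point = p)
    }
  }
  best
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# mass-action ODE for A + B <-> C with rate constants kf (nm^3/ns) and
# kb (1/ns), copy numbers in a box of volume V
ode_ab_c <- function(times, A0, B0, C0, kf, kb, V) {
  deSolve::ode(y = c(A = A0, B = B0, C = C0), times = times,
               func = function(t, y, p) {
                 f <- kf * y["A"] * y["B"] / V - kb * y["C"]
                 list(c(-f, -f, f))
               }, parms = NULL)
}

# multi-path system: four fusion paths (three to C, one to D) plus fission
ode_multipath <- function(times, A0, B0, kmacro, km1, V) {
  kC <- sum(kmacro[c(1, 3, 4)]); kD <- kmacro[2]
  deSolve::ode(y = c(A = A0, B = B0, C = 0, D = 0), times = times,
               func = function(t, y, p) {
                 ab <- y["A"] * y["B"] / V
                 list(c(-(kC + kD) * ab + km1 * y["C"],
                        -(kC + kD) * ab + km1 * y["C"],
                        kC * ab - km1 * y["C"],
                        kD * ab))
               }, parms = NULL)
}
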