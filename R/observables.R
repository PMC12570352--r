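# Validation observables computed from recorded trajectories: mean squared
# displacement, rotational correlation, radial distribution function, and
# scalar traces.

traj_type_id <- function(traj, species) {
  id <- match(species, traj$type_names)
  if (is.na(id)) stop("unknown species '", species, "'")
  id
}

# align one species across frames into an id x frame x 3 array (ids present
# in every requested frame)
traj_array <- function(traj, species, what = "pos") {
  tid <- traj_type_id(traj, species)
  idsets <- lapply(traj$frames, function(f) f$ids[f$type == tid])
  common <- Reduce(intersect, idsets)
  nt <- length(traj$frames)
  k <- if (what == "pos") 3L else 4L
  arr <- array(NA_real_, c(length(common), nt, k))
  for (f in seq_len(nt)) {
    fr <- traj$frames[[f]]
    sel <- fr$type == tid
    m <- match(common, fr$ids[sel])
    arr[, f, ] <- (if (what == "pos") fr$pos else fr$quat)[sel, , drop = FALSE][m, , drop = FALSE]
  }
  arr
}

#' Mean squared displacement
#'
#' Time- and ensemble-averaged MSD
#' \eqn{\mathrm{MSD}(\tau) = \langle |x(t+\tau) - x(t)|^2 \rangle} from
#' unwrapped positions, per lag and (optionally) per axis.
#'
#' @param traj a trajectory from [run_simulation()].
#' @param species molecule type name.
#' @param lags integer frame lags (default: up to a quarter of the frames).
#' @param per_axis also return the per-axis displacement second moments.
#' @return data frame with `lag` (ns), `msd` (nm^2), standard error `se`,
#'   and per-axis columns when requested.
#' @export
msd <- function(traj, species, lags = NULL, per_axis = FALSE) {
  arr <- traj_array(traj, species)
  nt <- dim(arr)[2]
  if (nt < 2) stop("need at least 2 frames")
  if (is.null(lags)) lags <- seq_len(max(1L, nt %/% 4L))
  dtf <- traj$times[2] - traj$times[1]
  out <- lapply(lags, function(L) {
    d <- arr[, (1 + L):nt, , drop = FALSE] - arr[, 1:(nt - L), , drop = FALSE]
    sq <- d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2
    c(lag = L * dtf, msd = mean(sq),
      se = stats::sd(sq) / sqrt(length(sq)),
      if (per_axis) c(msd_x = mean(d[, , 1]^2), msd_y = mean(d[, , 2]^2),
                      msd_z = mean(d[, , 3]^2)))
  })
  as.data.frame(do.call(rbind, out))
}

#' Rotational time correlation
#'
#' \eqn{P(\tau) = \frac{3}{2}\langle (n(t+\tau)\cdot n(t))^2 \rangle -
#' \frac{1}{2}} for a body axis `n` rotated to the world frame; for an
#' isotropic rotor with rotational diffusion constant `D_r` it decays as
#' \eqn{\exp(-6 D_r \tau)}.
#'
#' @param traj a trajectory from [run_simulation()].
#' @param species molecule type name.
#' @param axis body-frame axis (default z).
#' @param lags integer frame lags.
#' @return data frame with `lag` (ns) and `P`.
#' @export
rotational_correlation <- function(traj, species, axis = c(0, 0, 1),
                                   lags = NULL) {
  qa <- traj_array(traj, species, "quat")
  nt <- dim(qa)[2]
  if (is.null(lags)) lags <- seq_len(max(1L, nt %/% 4L))
  dtf <- traj$times[2] - traj$times[1]
  # world-frame axis per molecule and frame
  nmol <- dim(qa)[1]
  nvec <- array(0, c(nmol, nt, 3))
  for (f in seq_len(nt))
    nvec[, f, ] <- quat_rotate(qa[, f, , drop = TRUE], axis)
  out <- lapply(lags, function(L) {
    dotp <- nvec[, (1 + L):nt, 1] * nvec[, 1:(nt - L), 1] +
            nvec[, (1 + L):nt, 2] * nvec[, 1:(nt - L), 2] +
            nvec[, (1 + L):nt, 3] * nvec[, 1:(nt - L), 3]
    c(lag = L * dtf, P = 1.5 * mean(dotp^2) - 0.5)
  })
  as.data.frame(do.call(rbind, out))
}

#' Radial distribution function
#'
#' Shell-normalized pair histogram over trajectory frames of a periodic
#' system; `g(r)` tends to 1 at large distances.
#'
#' @param traj a trajectory from [run_simulation()].
#' @param species molecule type name (pair of identical species).
#' @param r_max histogram range (must be at most half the box edge).
#' @param bin bin width (nm).
#' @param frames frame indices to average over (default: all but the first).
#' @return data frame with bin centers `r` and `g`.
#' @export
rdf <- function(traj, species, r_max, bin = 0.02, frames = NULL) {
  tid <- traj_type_id(traj, species)
  if (is.null(frames)) frames <- seq_len(length(traj$frames))[-1]
  box <- traj$frames[[frames[1]]]$box
  if (r_max > min(box) / 2) stop("r_max exceeds half the box edge")
  breaks <- seq(0, r_max, by = bin)
  counts <- numeric(length(breaks) - 1L)
  npairs_norm <- 0
  for (f in frames) {
    fr <- traj$frames[[f]]
    sel <- fr$type == tid
    # wrapped coordinates for pair distances
    p <- minimum_image(fr$pos[sel, , drop = FALSE], fr$box)
    n <- nrow(p)
    if (n < 2) next
    # per-particle cutoff r_max gives the pair gate (r_max + r_max)/2 = r_max
    hg <- build_hgrid(p, rep(r_max, n), fr$box, periodic = TRUE)
    pr <- collect_pairs(hg, p, rep(r_max, n))
    keep <- pr$r < r_max
    counts <- counts + graphics::hist(pr$r[keep], breaks = breaks,
                                      plot = FALSE)$counts
    rho <- n / prod(fr$box)
    npairs_norm <- npairs_norm + n * rho / 2
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  data.frame(r = centers, g = counts / (npairs_norm * shell))
}

#' Scalar traces of a run
#'
#' @param traj a trajectory from [run_simulation()].
#' @return data frame with per-step `time`, `pressure`, `energy`, `volume`
#'   and molecule counts per type.
#' @export
traces <- function(traj) {
  data.frame(time = traj$traces$time, pressure = traj$traces$pressure,
             energy = traj$traces$energy, volume = traj$traces$volume,
             traj$traces$counts, check.names = FALSE)
}

#' Write observables to CSV
#'
#' @param df a data frame (as returned by [msd()], [rdf()], [traces()], ...).
#' @param file output path.
#' @export
write_observable_csv <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
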