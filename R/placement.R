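# Initial distribution of molecules: polydisperse Poisson-disc sampling in
# volumes, Monte-Carlo insertion with overlap relaxation for dense packings,
# and blue-noise sampling on mesh surfaces.

#' Poisson-disc sampling of polydisperse spheres
#'
#' Bridson-style active-list sampling extended to polydisperse radii: the
#' pairwise minimum center distance is `r_i + r_j`; candidates are drawn
#' uniformly from the spherical annulus `[r_a + r_new, 2 (r_a + r_new)]`
#' around an active point (k candidate trials before an active point
#' retires).  Sampling stops when all target counts are reached or the
#' active list is exhausted (saturation); the monodisperse saturation volume
#' fraction is close to the method's ~30% density limit.
#'
#' @param box box edge lengths (3-vector, nm), centered on the origin.
#' @param radii per-species sphere radii (nm).
#' @param counts per-species target counts (`Inf` = fill to saturation).
#' @param k candidate trials per active point.
#' @param periodic wrap distances across the box faces.
#' @param mesh optional [build_mesh()] compartment; points outside are
#'   discarded.
#' @return list with `positions` (n x 3, origin-centered), `species`
#'   (integer index into `radii`) and `volume_fraction`.
#' @export
poisson_disc_volume <- function(box, radii, counts = Inf, k = 30L,
                                periodic = TRUE, mesh = NULL) {
  box <- rep_len(as.numeric(box), 3)
  stopifnot(all(radii > 0))
  counts <- rep_len(as.numeric(counts), length(radii))
  res <- cpp_poisson_disc(box, as.numeric(radii), counts, as.integer(k),
                          periodic)
  pos <- sweep(res$positions, 2, box / 2)  # to origin-centered coordinates
  spc <- res$species
  if (!is.null(mesh)) {
    keep <- mesh_contains(mesh, pos)
    pos <- pos[keep, , drop = FALSE]
    spc <- spc[keep]
  }
  if (any(is.finite(counts)) && any(tabulate(spc, length(radii)) < counts &
                                    is.finite(counts)))
    warning("poisson_disc_volume: target counts not reached (achieved: ",
            paste(tabulate(spc, length(radii)), collapse = ", "), ")")
  list(positions = pos, species = spc,
       volume_fraction = sum(4 / 3 * pi * radii[spc]^3) / prod(box))
}

#' Dense sphere packing by Monte-Carlo insertion and overlap relaxation
#'
#' Spheres are inserted uniformly at random (overlaps allowed) and relaxed
#' by iterated pairwise projection -- steepest descent on the harmonic
#' overlap energy with the per-pair optimal step -- until the largest
#' relative overlap is below `tol`.  For dense targets the system starts in
#' a slightly inflated box that is annealed down to the requested size.
#'
#' @param box box edge lengths (3-vector, nm).
#' @param radii per-sphere radii (nm), one entry per sphere to place (use
#'   `rep()` for species counts).
#' @param periodic wrap across box faces.
#' @param tol relative overlap tolerance (pair distances end up
#'   `>= (1 - tol)(r_i + r_j)`).
#' @param max_sweeps relaxation sweep limit.
#' @param inflate initial box inflation factor.
#' @param shrink fractional box shrink per relaxed sweep during annealing.
#' @return list with `positions` (origin-centered), `converged`,
#'   `max_overlap`, `sweeps` and `volume_fraction`.
#' @export
mc_pack_dense <- function(box, radii, periodic = TRUE, tol = 1e-3,
                          max_sweeps = 20000L, inflate = 1.25,
                          shrink = 0.002) {
  box <- rep_len(as.numeric(box), 3)
  n <- length(radii)
  pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  res <- cpp_pack_relax(pos, as.numeric(radii), box, periodic, tol,
                        as.integer(max_sweeps), inflate, shrink)
  if (!res$converged)
    warning("mc_pack_dense: residual relative overlap ",
            signif(res$max_overlap, 3), " after ", res$sweeps, " sweeps")
  list(positions = sweep(res$positions, 2, box / 2),
       converged = res$converged, max_overlap = res$max_overlap,
       sweeps = res$sweeps,
       volume_fraction = sum(4 / 3 * pi * radii^3) / prod(box))
}

#' Blue-noise sampling on a mesh surface
#'
#' Uniform area-weighted triangle sampling (square-root barycentric
#' transform), optionally thinned to a pairwise minimum Euclidean distance
#' by dart throwing, and optionally restricted to a face group.
#'
#' @param mesh a [build_mesh()] object.
#' @param n target number of samples.
#' @param min_dist pairwise minimum distance (nm); 0 = plain area-weighted
#'   sampling.
#' @param group optional face-group name.
#' @param max_trials dart-throwing budget.
#' @return list with `positions` (n x 3) and `tri` (triangle ids).
#' @export
sample_surface <- function(mesh, n, min_dist = 0, group = NULL,
                           max_trials = 100L * n) {
  tris <- if (is.null(group)) seq_len(nrow(mesh$F)) else {
    g <- mesh$face_groups[[group]]
    if (is.null(g)) stop("unknown face group '", group, "'")
    g
  }
  wts <- mesh$areas[tris]
  draw <- function(m) {
    tr <- tris[sample.int(length(tris), m, replace = TRUE, prob = wts)]
    r1 <- sqrt(stats::runif(m)); r2 <- stats::runif(m)
    a <- mesh$V[mesh$F[tr, 1], , drop = FALSE]
    b <- mesh$V[mesh$F[tr, 2], , drop = FALSE]
    cc <- mesh$V[mesh$F[tr, 3], , drop = FALSE]
    list(p = (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc, tri = tr)
  }
  if (min_dist <= 0) {
    d <- draw(n)
    return(list(positions = d$p, tri = d$tri))
  }
  pos <- matrix(0, 0, 3); tri <- integer(0)
  trials <- 0L
  while (nrow(pos) < n && trials < max_trials) {
    d <- draw(1L)
    trials <- trials + 1L
    if (nrow(pos) == 0 ||
        min(sqrt(rowSums(sweep(pos, 2, d$p[1, ])^2))) >= min_dist) {
      pos <- rbind(pos, d$p)
      tri <- c(tri, d$tri)
    }
  }
  if (nrow(pos) < n)
    warning("sample_surface: placed ", nrow(pos), " of ", n,
            " samples before the trial budget was exhausted")
  list(positions = pos, tri = tri)
}
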