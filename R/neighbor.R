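# Hierarchical cell grid for polydisperse neighbor search.
#
# Each particle carries a cutoff (the diameter of its interaction/reaction
# reach); a pair (i, j) is a neighbor when r_ij < (cutoff_i + cutoff_j)/2.
# Particles are binned into one cell level per distinct cutoff scale, so a
# few large particles do not force one giant cell size on everybody: the
# same-level sweep visits nearest-neighbor cells, and a cross-level sweep
# scans only levels with smaller cells (exploiting Newton's third law).

MAX_HGRID_LEVELS <- 8L

#' Build a hierarchical cell grid
#'
#' @param positions n x 3 matrix of particle positions (nm).
#' @param cutoffs per-particle cutoff diameters (nm); the pair cutoff is
#'   `(cutoff_i + cutoff_j)/2`.
#' @param box simulation box edge lengths (3-vector, nm); the box is centered
#'   on the origin.
#' @param periodic logical; minimum-image convention when `TRUE`.
#' @param n_levels optional cap on the number of levels (default: one level
#'   per distinct cutoff, at most 8; beyond that, geometric binning).
#' @return an object of class `hgrid` describing the level assignment.
#' @export
build_hgrid <- function(positions, cutoffs, box, periodic = TRUE,
                        n_levels = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  box <- rep_len(as.numeric(box), 3)
  stopifnot(all(box > 0))
  cutoffs <- rep_len(as.numeric(cutoffs), max(n, 1L))
  if (n > 0 && any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (n > 0 && any(cutoffs > min(box) / 2))
    stop("configuration error: a cutoff exceeds half the box edge (",
         min(box) / 2, " nm)")
  if (n == 0) {
    return(structure(list(levels = numeric(0), level_maxcut = numeric(0),
                          assignment = integer(0), box = box,
                          periodic = periodic, n = 0L), class = "hgrid"))
  }
  uc <- sort(unique(cutoffs), decreasing = TRUE)
  cap <- if (is.null(n_levels)) MAX_HGRID_LEVELS else as.integer(n_levels)
  if (length(uc) <= cap) {
    assignment <- match(cutoffs, uc)
    cell <- uc
  } else {
    # geometric binning between the largest and smallest cutoff
    edges <- exp(seq(log(max(uc)), log(min(uc)), length.out = cap + 1L))
    assignment <- pmax(1L, pmin(cap, findInterval(-cutoffs, -edges,
                                                  rightmost.closed = TRUE)))
    cell <- vapply(seq_len(cap), function(l)
      if (any(assignment == l)) max(cutoffs[assignment == l]) else edges[l],
      numeric(1))
  }
  maxcut <- vapply(seq_along(cell), function(l)
    if (any(assignment == l)) max(cutoffs[assignment == l]) else cell[l],
    numeric(1))
  structure(list(levels = cell, level_maxcut = maxcut,
                 assignment = assignment, box = box, periodic = periodic,
                 n = n), class = "hgrid")
}

#' @export
print.hgrid <- function(x, ...) {
  cat(sprintf("<hgrid> %d particle(s), %d level(s): cell sizes %s nm\n",
              x$n, length(x$levels),
              paste(signif(x$levels, 4), collapse = ", ")))
  invisible(x)
}

#' Collect neighbor pairs
#'
#' Returns exactly the unordered pairs with `r_ij < (cutoff_i + cutoff_j)/2`,
#' each once.
#'
#' @param hgrid a grid from [build_hgrid()].
#' @param positions,cutoffs the particle data (must match the grid's
#'   assignment).
#' @return a list with integer vectors `i`, `j` and numeric `r` (minimum
#'   image distance, nm).
#' @export
collect_pairs <- function(hgrid, positions, cutoffs) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (n != hgrid$n) stop("grid was built for a different particle count")
  if (n == 0) return(list(i = integer(0), j = integer(0), r = numeric(0)))
  cutoffs <- rep_len(as.numeric(cutoffs), n)
  res <- cpp_pair_sweep(positions, cutoffs, hgrid$assignment,
                        length(hgrid$levels), hgrid$levels, hgrid$level_maxcut,
                        hgrid$box, hgrid$periodic,
                        integer(n), seq_len(n), positions,
                        matrix(0L, 0, 0), matrix(0, 0, 0), matrix(0, 0, 0),
                        matrix(0, 0, 0), matrix(0, 0, 0),
                        TRUE, FALSE)
  list(i = res$i, j = res$j, r = res$r)
}
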