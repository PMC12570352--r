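# Triangulated-mesh compartments: shared-vertex data structure with
# per-triangle edge and neighbor tables, voxel grid for ray queries, volume
# collision response by reflective ray tracing, and surface ray marching for
# membrane-bound molecules.

#' Build a compartment mesh
#'
#' Validates that the triangle soup is a closed orientable manifold (every
#' edge shared by exactly two triangles, with consistent counterclockwise
#' winding seen from outside), and precomputes the per-triangle edge lists,
#' neighbor table, outward normals, areas, and a voxel grid of triangle ids
#' for fast ray queries.
#'
#' @param vertices nv x 3 matrix of vertex positions (nm, world frame).
#' @param triangles nt x 3 integer matrix of vertex indices (1-based,
#'   counterclockwise seen from outside).
#' @param face_groups optional named list of triangle-id vectors.
#' @param voxel_size voxel edge length for the ray-query grid (nm); default
#'   is twice the mean triangle edge length.
#' @return an object of class `compartment_mesh`.
#' @export
build_mesh <- function(vertices, triangles, face_groups = list(),
                       voxel_size = NULL) {
  V <- matrix(as.numeric(vertices), ncol = 3)
  Fc <- matrix(as.integer(triangles), ncol = 3)
  nt <- nrow(Fc)
  nv <- nrow(V)
  if (any(Fc < 1L | Fc > nv)) stop("triangle indices out of range")

  # directed edges (a,b) per triangle: (v1,v2), (v2,v3), (v3,v1)
  ea <- c(Fc[, 1], Fc[, 2], Fc[, 3])
  eb <- c(Fc[, 2], Fc[, 3], Fc[, 1])
  tri_of <- rep(seq_len(nt), 3L)
  dir_key <- paste(ea, eb)
  if (anyDuplicated(dir_key))
    stop("validation error: inconsistent winding (duplicated directed edge)")
  und_key <- paste(pmin(ea, eb), pmax(ea, eb))
  cnt <- table(und_key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad))
    stop("validation error: mesh is not a closed manifold; offending edges: ",
         paste(utils::head(bad, 10L), collapse = "; "))
  # neighbor across each directed edge = owner of the reversed edge
  owner <- structure(tri_of, names = dir_key)
  rev_key <- paste(eb, ea)
  neighbors <- matrix(owner[rev_key], nt, 3L)
  if (any(is.na(neighbors)))
    stop("validation error: open mesh (edge without twin)")

  e1 <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  e2 <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n2 <- sqrt(rowSums(nrm^2))
  if (any(n2 < 1e-14)) stop("degenerate geometry: zero-area triangle")
  areas <- n2 / 2
  nrm <- nrm / n2

  m <- list(V = V, F = Fc, neighbors = neighbors, normals = nrm,
            areas = areas, face_groups = face_groups,
            # cached barycentric solve: Gram inverse of (e1, e2)
            e1 = e1, e2 = e2,
            d11 = rowSums(e1 * e1), d12 = rowSums(e1 * e2),
            d22 = rowSums(e2 * e2))
  m$inv_det <- 1 / (m$d11 * m$d22 - m$d12^2)

  mean_edge <- mean(sqrt(rowSums((V[ea, , drop = FALSE] -
                                  V[eb, , drop = FALSE])^2)))
  if (is.null(voxel_size)) voxel_size <- 2 * mean_edge
  lo <- apply(V, 2, min) - 1e-6
  hi <- apply(V, 2, max) + 1e-6
  nc <- pmax(1L, as.integer(floor((hi - lo) / voxel_size)))
  cs <- (hi - lo) / nc
  cells <- vector("list", prod(nc))
  for (t in seq_len(nt)) {
    tv <- V[Fc[t, ], , drop = FALSE]
    clo <- pmax(1L, pmin(nc, as.integer(floor((apply(tv, 2, min) - lo) / cs)) + 1L))
    chi <- pmax(1L, pmin(nc, as.integer(floor((apply(tv, 2, max) - lo) / cs)) + 1L))
    for (cx in clo[1]:chi[1]) for (cy in clo[2]:chi[2]) for (cz in clo[3]:chi[3]) {
      id <- ((cz - 1L) * nc[2] + (cy - 1L)) * nc[1] + cx
      cells[[id]] <- c(cells[[id]], t)
    }
  }
  m$voxel <- list(lo = lo, hi = hi, nc = nc, cs = cs, cells = cells)
  m$transparent <- integer(0)
  class(m) <- "compartment_mesh"
  m
}

#' @export
print.compartment_mesh <- function(x, ...) {
  cat(sprintf("<compartment_mesh> %d vertices, %d triangles, area %.4g nm^2, volume %.4g nm^3\n",
              nrow(x$V), nrow(x$F), sum(x$areas), mesh_volume(x)))
  invisible(x)
}

#' Mesh summaries
#'
#' `mesh_volume` is the signed volume from the divergence theorem (positive
#' for outward-oriented closed meshes); `mesh_validate` returns a report of
#' the closure/orientation checks suitable for JSON export.
#'
#' @param mesh a [build_mesh()] object (or raw vertices/triangles for
#'   `mesh_validate`).
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$V[mesh$F[, 1], , drop = FALSE]
  b <- mesh$V[mesh$F[, 2], , drop = FALSE]
  cc <- mesh$V[mesh$F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @rdname mesh_volume
#' @param vertices,triangles raw mesh arrays.
#' @export
mesh_validate <- function(vertices, triangles) {
  res <- tryCatch({
    m <- build_mesh(vertices, triangles)
    list(valid = TRUE, closed = TRUE,
         n_vertices = nrow(m$V), n_triangles = nrow(m$F),
         n_edges = nrow(m$F) * 3L / 2L,
         euler_characteristic = nrow(m$V) - nrow(m$F) * 3L / 2L + nrow(m$F),
         area = sum(m$areas), volume = mesh_volume(m), errors = character(0))
  }, error = function(e) {
    list(valid = FALSE, closed = FALSE, errors = conditionMessage(e))
  })
  res
}

# barycentric coordinates of points P (n x 3) w.r.t. triangle t, after
# projecting into the triangle plane
mesh_bary <- function(mesh, t, P) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  a <- mesh$V[mesh$F[t, 1], ]
  vp <- sweep(P, 2, a)
  d1 <- vp %*% mesh$e1[t, ]
  d2 <- vp %*% mesh$e2[t, ]
  v <- (mesh$d22[t] * d1 - mesh$d12[t] * d2) * mesh$inv_det[t]
  w <- (mesh$d11[t] * d2 - mesh$d12[t] * d1) * mesh$inv_det[t]
  cbind(1 - v - w, v, w)  # weights of (v1, v2, v3)
}

#' Point-in-triangle test by barycentric coordinates
#'
#' @param p point (3-vector, assumed in or near the triangle plane).
#' @param tri 3 x 3 matrix of triangle vertices (rows), or a list
#'   `(mesh, t)`.
#' @param tol boundary tolerance; a point is inside when all barycentric
#'   weights are `>= -tol` (closed convention).
#' @return list with `inside` flag and the barycentric weights `(u, v, w)`
#'   of the three vertices.
#' @export
point_in_triangle <- function(p, tri, tol = 1e-9) {
  tri <- matrix(as.numeric(tri), ncol = 3)
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  det <- d11 * d22 - d12^2
  if (det < 1e-20 * max(d11, d22, 1)) stop("degenerate geometry: triangle has no area")
  vp <- p - tri[1, ]
  d1 <- sum(vp * e1); d2 <- sum(vp * e2)
  v <- (d22 * d1 - d12 * d2) / det
  w <- (d11 * d2 - d12 * d1) / det
  u <- 1 - v - w
  list(inside = u >= -tol && v >= -tol && w >= -tol, bary = c(u, v, w))
}

#' Distance from a point to a closed triangle
#'
#' Region-based closest-point computation (interior, edge, or vertex region)
#' on the parametrized triangle `B + s E0 + t E1`.
#'
#' @param p point (3-vector).
#' @param tri 3 x 3 matrix of triangle vertices (rows).
#' @return list with `distance` (nm) and `closest` point (3-vector).
#' @export
point_triangle_distance <- function(p, tri) {
  tri <- matrix(as.numeric(tri), ncol = 3)
  B <- tri[1, ]; E0 <- tri[2, ] - tri[1, ]; E1 <- tri[3, ] - tri[1, ]
  a <- sum(E0 * E0); b <- sum(E0 * E1); cc <- sum(E1 * E1)
  det <- a * cc - b * b
  if (det < 1e-20 * max(a, cc, 1)) stop("degenerate geometry: triangle has no area")
  D <- B - p
  d <- sum(E0 * D); e <- sum(E1 * D)
  s <- b * e - cc * d
  t <- b * d - a * e
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { # region 4
        if (d < 0) { t <- 0; s <- min(max(-d / a, 0), 1) }
        else { s <- 0; t <- min(max(-e / cc, 0), 1) }
      } else { # region 3
        s <- 0; t <- min(max(-e / cc, 0), 1)
      }
    } else if (t < 0) { # region 5
      t <- 0; s <- min(max(-d / a, 0), 1)
    } else { # region 0 (interior)
      s <- s / det; t <- t / det
    }
  } else {
    if (s < 0) { # region 2
      tmp0 <- b + d; tmp1 <- cc + e
      if (tmp1 > tmp0) {
        num <- tmp1 - tmp0
        s <- min(max(num / (a - 2 * b + cc), 0), 1); t <- 1 - s
      } else { s <- 0; t <- min(max(-e / cc, 0), 1) }
    } else if (t < 0) { # region 6
      tmp0 <- b + e; tmp1 <- a + d
      if (tmp1 > tmp0) {
        num <- tmp1 - tmp0
        t <- min(max(num / (a - 2 * b + cc), 0), 1); s <- 1 - t
      } else { t <- 0; s <- min(max(-d / a, 0), 1) }
    } else { # region 1
      num <- (cc + e) - (b + d)
      s <- min(max(num / (a - 2 * b + cc), 0), 1); t <- 1 - s
    }
  }
  q <- B + s * E0 + t * E1
  list(distance = sqrt(sum((p - q)^2)), closest = q)
}

# Moller-Trumbore ray/triangle intersection of one ray against all triangles
# of a mesh, vectorized.  Returns hit parameter t (Inf for misses).
ray_tri_all <- function(mesh, origin, dir, eps = 1e-12) {
  pvec <- cbind(dir[2] * mesh$e2[, 3] - dir[3] * mesh$e2[, 2],
                dir[3] * mesh$e2[, 1] - dir[1] * mesh$e2[, 3],
                dir[1] * mesh$e2[, 2] - dir[2] * mesh$e2[, 1])
  det <- rowSums(mesh$e1 * pvec)
  tvec <- sweep(-mesh$V[mesh$F[, 1], , drop = FALSE], 2, origin, "+")
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(tvec[, 2] * mesh$e1[, 3] - tvec[, 3] * mesh$e1[, 2],
                tvec[, 3] * mesh$e1[, 1] - tvec[, 1] * mesh$e1[, 3],
                tvec[, 1] * mesh$e1[, 2] - tvec[, 2] * mesh$e1[, 1])
  v <- (qvec %*% dir)[, 1] / det
  tt <- rowSums(mesh$e2 * qvec) / det
  ok <- abs(det) > eps & u >= -1e-12 & v >= -1e-12 & (u + v) <= 1 + 1e-12
  ifelse(ok, tt, Inf)
}

# Amanatides-Woo voxel walk: visits the voxels pierced by the segment
# origin + t*disp, t in (tmin, 1], testing only the triangles registered in
# each voxel.  Returns NULL or list(t, tri, point).
first_hit <- function(mesh, origin, disp, tmin = 1e-12, exclude = 0L) {
  vx <- mesh$voxel
  if (sum(disp^2) == 0) return(NULL)
  # clip the segment to the voxel grid's bounding box
  t0 <- 0; t1 <- 1
  for (d in 1:3) {
    if (disp[d] == 0) {
      if (origin[d] < vx$lo[d] || origin[d] > vx$hi[d]) return(NULL)
    } else {
      ta <- (vx$lo[d] - origin[d]) / disp[d]
      tb <- (vx$hi[d] - origin[d]) / disp[d]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 > t1) return(NULL)
  p0 <- origin + (t0 + 1e-12) * disp
  cell <- pmax(1L, pmin(vx$nc, as.integer(floor((p0 - vx$lo) / vx$cs)) + 1L))
  step <- ifelse(disp > 0, 1L, ifelse(disp < 0, -1L, 0L))
  tdelta <- ifelse(disp != 0, abs(vx$cs / disp), Inf)
  nextb <- vx$lo + (cell - 1L + (step > 0)) * vx$cs
  tmax <- ifelse(disp != 0, (nextb - origin) / disp, Inf)
  tested <- logical(nrow(mesh$F))
  best_t <- Inf; best <- 0L
  repeat {
    id <- ((cell[3] - 1L) * vx$nc[2] + (cell[2] - 1L)) * vx$nc[1] + cell[1]
    for (tr in vx$cells[[id]]) {
      if (tr == exclude || tested[tr]) next
      tested[tr] <- TRUE
      tt <- ray_tri_one(mesh, tr, origin, disp)
      if (!is.na(tt) && tt > tmin && tt <= 1 && tt < best_t) {
        best_t <- tt; best <- tr
      }
    }
    texit <- min(tmax)
    if (best > 0L && best_t <= texit + 1e-12)
      return(list(t = best_t, tri = best, point = origin + best_t * disp))
    if (texit >= min(t1, 1)) break
    d <- which.min(tmax)
    cell[d] <- cell[d] + step[d]
    if (cell[d] < 1L || cell[d] > vx$nc[d]) break
    tmax[d] <- tmax[d] + tdelta[d]
  }
  if (best > 0L)
    return(list(t = best_t, tri = best, point = origin + best_t * disp))
  NULL
}

ray_tri_one <- function(mesh, tr, origin, dir, eps = 1e-12) {
  e1 <- mesh$e1[tr, ]; e2 <- mesh$e2[tr, ]
  pvec <- c(dir[2] * e2[3] - dir[3] * e2[2],
            dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
  det <- sum(e1 * pvec)
  if (abs(det) < eps) return(NA_real_)
  tvec <- origin - mesh$V[mesh$F[tr, 1], ]
  u <- sum(tvec * pvec) / det
  if (u < -1e-12 || u > 1 + 1e-12) return(NA_real_)
  qvec <- c(tvec[2] * e1[3] - tvec[3] * e1[2],
            tvec[3] * e1[1] - tvec[1] * e1[3],
            tvec[1] * e1[2] - tvec[2] * e1[1])
  v <- sum(qvec * dir) / det
  if (v < -1e-12 || u + v > 1 + 1e-12) return(NA_real_)
  sum(e2 * qvec) / det
}

#' Trace a displacement with mirror reflection at mesh triangles
#'
#' The displacement is traced through the mesh voxel grid; at each triangle
#' hit the remaining displacement is reflected about the triangle plane, so
#' the total path length equals the input displacement length regardless of
#' the integration time step.
#'
#' @param origin starting point (3-vector, nm).
#' @param displacement displacement vector (nm).
#' @param mesh a [build_mesh()] object.
#' @param max_reflections abort limit for stuck geometry.
#' @return list with `position` and `hits` (triangle ids in hit order).
#' @export
ray_trace_reflect <- function(origin, displacement, mesh,
                              max_reflections = 50L) {
  pos <- as.numeric(origin)
  disp <- as.numeric(displacement)
  hits <- integer(0)
  last <- 0L
  for (k in seq_len(max_reflections)) {
    h <- first_hit(mesh, pos, disp, exclude = last)
    if (is.null(h)) return(list(position = pos + disp, hits = hits))
    n <- mesh$normals[h$tri, ]
    rem <- (1 - h$t) * disp
    rem <- rem - 2 * sum(rem * n) * n
    pos <- h$point
    disp <- rem
    hits <- c(hits, h$tri)
    last <- h$tri
  }
  stop("stuck geometry: more than ", max_reflections, " reflections")
}

#' Inside test for closed meshes
#'
#' Ray-parity classification: a point is inside when a ray cast from it
#' crosses the surface an odd number of times.  Degenerate hits are resolved
#' by jittering the ray direction.
#'
#' @param mesh a [build_mesh()] object.
#' @param points n x 3 matrix.
#' @return logical vector.
#' @export
mesh_contains <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  apply(points, 1, function(p) {
    dir <- c(0.57735027, 0.57735027, 0.57735027)
    for (try in 1:5) {
      tts <- ray_tri_all(mesh, p, dir)
      ok <- is.finite(tts) & tts > 1e-9
      # reject hits suspiciously close to edges by re-testing with jitter
      if (!anyNA(tts[ok])) {
        degenerate <- FALSE
        if (any(ok)) {
          b <- vapply(which(ok), function(tr) {
            min(mesh_bary(mesh, tr, p + tts[tr] * dir))
          }, numeric(1))
          degenerate <- any(b < 1e-7)
        }
        if (!degenerate) return(sum(ok) %% 2 == 1)
      }
      dir <- dir + stats::runif(3, -0.05, 0.05)
      dir <- dir / sqrt(sum(dir^2))
    }
    sum(ok) %% 2 == 1
  })
}

#' Surface ray marching
#'
#' Propagates a surface-bound molecule by a tangent-plane displacement:
#' whenever the path crosses a triangle edge it is advanced to the edge and
#' the residual displacement (and the molecule orientation) is rotated about
#' the shared edge into the neighboring triangle's plane.  The traveled arc
#' length equals the input displacement length, so walkers follow geodesics
#' on the mesh.
#'
#' @param mesh a [build_mesh()] object.
#' @param tri current triangle id.
#' @param pos current position on that triangle (3-vector).
#' @param disp displacement vector in the triangle plane (3-vector).
#' @param quat optional molecule orientation quaternion to co-rotate.
#' @param max_crossings abort limit.
#' @return list with `position`, `tri`, `quat`.
#' @export
surface_ray_march <- function(mesh, tri, pos, disp, quat = c(1, 0, 0, 0),
                              max_crossings = 500L) {
  pos <- as.numeric(pos); disp <- as.numeric(disp)
  for (k in seq_len(max_crossings)) {
    b0 <- mesh_bary(mesh, tri, pos)[1, ]
    b1 <- mesh_bary(mesh, tri, pos + disp)[1, ]
    if (all(b1 >= -1e-12)) {
      return(list(position = pos + disp, tri = tri, quat = quat))
    }
    # first crossed edge: smallest t where a barycentric weight reaches 0
    tmin <- Inf; kmin <- 0L
    for (kk in 1:3) {
      if (b1[kk] < 0 && b0[kk] > b1[kk]) {
        t <- b0[kk] / (b0[kk] - b1[kk])
        if (t < tmin) { tmin <- t; kmin <- kk }
      }
    }
    if (kmin == 0L) { # numerically on an edge; nudge inward and retry
      ctr <- (mesh$V[mesh$F[tri, 1], ] + mesh$V[mesh$F[tri, 2], ] +
              mesh$V[mesh$F[tri, 3], ]) / 3
      pos <- pos + 1e-9 * (ctr - pos)
      next
    }
    tmin <- max(tmin, 0)
    edge <- (kmin %% 3L) + 1L   # edge opposite vertex kmin
    pos <- pos + tmin * disp
    disp <- (1 - tmin) * disp
    nb <- mesh$neighbors[tri, edge]
    a <- mesh$V[mesh$F[tri, edge], ]
    b <- mesh$V[mesh$F[tri, (edge %% 3L) + 1L], ]
    axis <- b - a
    axis <- axis / sqrt(sum(axis^2))
    n1 <- mesh$normals[tri, ]; n2 <- mesh$normals[nb, ]
    cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
            n1[3] * n2[1] - n1[1] * n2[3],
            n1[1] * n2[2] - n1[2] * n2[1])
    ang <- atan2(sum(cr * axis), sum(n1 * n2))
    if (abs(ang) > 1e-15) {
      rq <- quat_from_rotvec(ang * axis)
      disp <- quat_rotate(rq, disp)[1, ]
      quat <- quat_normalize(quat_multiply(rq, quat))[1, ]
    }
    # keep the advanced point exactly in the new triangle's plane
    va <- mesh$V[mesh$F[nb, 1], ]
    pos <- pos - sum((pos - va) * n2) * n2
    tri <- nb
  }
  stop("stuck geometry: more than ", max_crossings, " edge crossings")
}

#' Orthonormal tangent basis of a triangle
#'
#' @param mesh a [build_mesh()] object.
#' @param tri triangle ids (vectorized).
#' @return list of matrices `u`, `v` (rows are unit vectors spanning each
#'   triangle plane).
#' @export
triangle_basis <- function(mesh, tri) {
  u <- mesh$e1[tri, , drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  n <- mesh$normals[tri, , drop = FALSE]
  v <- cbind(n[, 2] * u[, 3] - n[, 3] * u[, 2],
             n[, 3] * u[, 1] - n[, 1] * u[, 3],
             n[, 1] * u[, 2] - n[, 2] * u[, 1])
  list(u = u, v = v)
}

# ---------------------------------------------------------------------------
# Mesh generators (synthetic compartments used by examples and tests)

#' Synthetic meshes: axis-aligned cube and icosphere
#'
#' `cube_mesh` builds a 12-triangle box; `icosphere` subdivides an
#' icosahedron and projects onto the sphere.
#'
#' @param L cube edge length (nm).
#' @param radius sphere radius (nm).
#' @param center center (3-vector).
#' @param subdiv number of 4-to-1 subdivisions (0 = icosahedron).
#' @return a [build_mesh()] object.
#' @export
cube_mesh <- function(L = 1, center = c(0, 0, 0)) {
  h <- L / 2
  V <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  V <- sweep(V, 2, center, "+")
  # vertices: 1(---) 2(+--) 3(-+-) 4(++-) 5(--+) 6(+-+) 7(-++) 8(+++)
  Fc <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z-), outward normal -z
    c(5, 6, 7), c(6, 8, 7),   # top (z+)
    c(1, 2, 5), c(2, 6, 5),   # front (y-)
    c(3, 7, 4), c(4, 7, 8),   # back (y+)
    c(1, 5, 3), c(3, 5, 7),   # left (x-)
    c(2, 4, 6), c(4, 8, 6))   # right (x+)
  build_mesh(V, Fc)
}

#' @rdname cube_mesh
#' @export
icosphere <- function(radius = 1, subdiv = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Fc <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
              c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
              c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    nv <- nrow(V)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      m <- V[i, ] + V[j, ]
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      nv <<- nv + 1L
      mid_cache[[key]] <- nv
      nv
    }
    newF <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(Fc))) {
      a <- Fc[t, 1]; b <- Fc[t, 2]; cc <- Fc[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    Fc <- newF
  }
  build_mesh(sweep(V * radius, 2, center, "+"), Fc)
}

# ---------------------------------------------------------------------------
# Wavefront OBJ input/output (triangles only; groups map to face groups)

#' Read / write Wavefront OBJ meshes
#'
#' Only `v`, `f` and `g` records are interpreted; faces must be triangles.
#' OBJ groups become named face groups of the mesh.
#'
#' @param file path.
#' @param mesh a [build_mesh()] object (for writing).
#' @return `read_obj`: a [build_mesh()] object.
#' @export
read_obj <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  V <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x)
    as.numeric(x[2:4])))
  Fc <- matrix(0L, 0, 3)
  groups <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "g ")) {
      cur <- trimws(substring(ln, 3))
      if (identical(cur, "default")) cur <- NULL  # ungrouped faces
    } else if (startsWith(ln, "f ")) {
      toks <- strsplit(ln, "\\s+")[[1]][-1]
      if (length(toks) != 3) stop("read_obj: only triangular faces supported")
      idx <- as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1))
      Fc <- rbind(Fc, idx)
      if (!is.null(cur)) groups[[cur]] <- c(groups[[cur]], nrow(Fc))
    }
  }
  build_mesh(V, Fc, face_groups = groups)
}

#' @rdname read_obj
#' @export
write_obj <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$V[, 1], mesh$V[, 2],
                     mesh$V[, 3]), con)
  grp_of <- rep("default", nrow(mesh$F))
  for (g in names(mesh$face_groups)) grp_of[mesh$face_groups[[g]]] <- g
  last <- ""
  for (t in seq_len(nrow(mesh$F))) {
    if (grp_of[t] != last) {
      writeLines(paste("g", grp_of[t]), con)
      last <- grp_of[t]
    }
    writeLines(sprintf("f %d %d %d", mesh$F[t, 1], mesh$F[t, 2],
                       mesh$F[t, 3]), con)
  }
  invisible(file)
}
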