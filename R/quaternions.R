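# Quaternion kernels, vectorized over rows.  Convention: q = (w, x, y, z),
# unit quaternions; world vector = rot_matrix(q) %*% body vector.

#' Quaternion utilities
#'
#' Row-vectorized unit-quaternion operations used by the rigid-body
#' propagator: Hamilton product, conversion of body-frame rotation vectors to
#' quaternions, rotation of body-frame vectors into the world frame, and
#' normalization.  Quaternions are n x 4 matrices `(w, x, y, z)`.
#'
#' @param q,q1,q2 n x 4 quaternion matrices (or length-4 vectors).
#' @param v n x 3 rotation vectors / vectors to rotate.
#' @name quaternions
NULL

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) matrix(q, ncol = 4) else q
}

#' @rdname quaternions
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- as_quat_matrix(q1); q2 <- as_quat_matrix(q2)
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  q / sqrt(rowSums(q^2))
}

#' @rdname quaternions
#' @export
quat_from_rotvec <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  ang <- sqrt(rowSums(v^2))
  half <- ang / 2
  # sin(x)/x, stable at 0
  s <- ifelse(ang < 1e-12, 0.5 - half^2 / 12, sin(half) / ang)
  cbind(cos(half), v[, 1] * s, v[, 2] * s, v[, 3] * s)
}

#' @rdname quaternions
#' @export
quat_rotate <- function(q, v) {
  # world = q (x) v (x) q*, expanded (Rodrigues form), rowwise
  q <- as_quat_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  uv <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  uuv <- cbind(u[, 2] * uv[, 3] - u[, 3] * uv[, 2],
               u[, 3] * uv[, 1] - u[, 1] * uv[, 3],
               u[, 1] * uv[, 2] - u[, 2] * uv[, 1])
  v + 2 * (w * uv + uuv)
}

#' @rdname quaternions
#' @export
quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  cbind(q[, 1], -q[, 2:4, drop = FALSE])
}

#' @rdname quaternions
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' @rdname quaternions
#' @export
quat_identity <- function(n = 1L) {
  cbind(rep(1, n), 0, 0, 0)
}

#' Uniform random orientations
#'
#' Draws unit quaternions uniformly on SO(3) (Shoemake's method).
#'
#' @param n number of quaternions.
#' @return n x 4 matrix.
#' @export
quat_random <- function(n = 1L) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  cbind(a * sin(2 * pi * u2), a * cos(2 * pi * u2),
        b * sin(2 * pi * u3), b * cos(2 * pi * u3))
}
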