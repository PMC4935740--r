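#' Rigid (SE(3)) transforms
#'
#' A `rigid_transform` is a 4x4 homogeneous matrix with a proper-rotation
#' block `R` (orthonormal, `det(R) = +1`) and a translation column `t` in
#' millimetres; the bottom row is `c(0, 0, 0, 1)`. Points are column vectors,
#' so a transform maps `p` to `R p + t` (left multiplication). Units are
#' millimetres and degrees throughout; scaling, shear and reflections are
#' rejected because the anatomy being moved is rigid bone.
#'
#' @param m A numeric 4x4 matrix.
#' @param tol Orthonormality tolerance for validation.
#' @return An object of class `rigid_transform` (a 4x4 matrix).
#' @examples
#' t1 <- rt_translate(c(1, 2, 3))
#' t2 <- rt_euler(c(10, 0, 0))
#' rt_compose(t1, t2)
#' @export
rigid_transform <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    stop("a rigid transform must be a numeric 4x4 matrix", call. = FALSE)
  if (any(!is.finite(m)))
    stop("rigid transform contains non-finite entries", call. = FALSE)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    stop("bottom row of a rigid transform must be [0, 0, 0, 1]", call. = FALSE)
  r <- m[1:3, 1:3]
  orth <- max(abs(crossprod(r) - diag(3)))
  if (orth > tol)
    stop(sprintf(
      "rotation block is not orthonormal (||R'R - I|| = %.3g): not a rigid transform",
      orth), call. = FALSE)
  if (abs(det(r) - 1) > 1e-6)
    stop(sprintf(
      "rotation block has determinant %.6f; reflections are not rigid motions",
      det(r)), call. = FALSE)
  m[4, ] <- c(0, 0, 0, 1)
  structure(m, class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(m, tol = 1e-9) {
  !inherits(try(rigid_transform(unclass(m), tol = tol), silent = TRUE), "try-error")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(diag(4))

#' Elementary transforms
#'
#' `rt_translate()` builds a pure translation; `rt_euler()` builds a pure
#' rotation from extrinsic fixed-axis X-Y-Z Euler angles in degrees, i.e.
#' the rotation matrix is `Rz(rz) %*% Ry(ry) %*% Rx(rx)`.
#'
#' @param v Length-3 translation in mm.
#' @param angles Length-3 angles `c(rx, ry, rz)` in degrees.
#' @return A `rigid_transform`.
#' @export
rt_translate <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3, all(is.finite(v)))
  m <- diag(4)
  m[1:3, 4] <- v
  rigid_transform(m)
}

#' @rdname rt_translate
#' @export
rt_euler <- function(angles) {
  euler_to_rotation(angles)
}

# Polar re-orthonormalisation: nearest proper rotation in Frobenius norm.
reorthonormalize <- function(r) {
  s <- svd(r)
  d <- diag(c(1, 1, det(s$u %*% t(s$v))))
  s$u %*% d %*% t(s$v)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` first, then `a` (matrix product `a %*% b`).
#' Accumulated floating-point drift in the rotation block is removed by polar
#' re-orthonormalisation when it exceeds `1e-9`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  a <- as_rigid_transform(a); b <- as_rigid_transform(b)
  m <- unclass(a) %*% unclass(b)
  r <- m[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > 1e-9)
    m[1:3, 1:3] <- reorthonormalize(r)
  rigid_transform(m)
}

#' Invert a rigid transform
#'
#' Uses the analytic inverse `[R', -R't]`, so the result is exactly rigid
#' rather than a generic matrix inverse.
#'
#' @param t A `rigid_transform`.
#' @return A `rigid_transform` with `rt_compose(t, rt_invert(t))` the identity.
#' @export
rt_invert <- function(t) {
  t <- as_rigid_transform(t)
  r <- t[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(r)
  m[1:3, 4] <- -crossprod(r, t[1:3, 4])
  rigid_transform(m)
}

as_rigid_transform <- function(x) {
  if (inherits(x, "rigid_transform")) x else rigid_transform(x)
}

#' Point sets
#'
#' Point sets are plain numeric matrices with 3 columns (x, y, z in mm);
#' row names, when present, are point names and must be unique.
#' `as_points()` normalises a vector of length 3, a data frame with x/y/z
#' columns (plus optional `name`), or a matrix into this form.
#'
#' @param x Points in any accepted form.
#' @return An N x 3 numeric matrix.
#' @export
as_points <- function(x) {
  if (is.data.frame(x)) {
    nm <- if ("name" %in% names(x)) as.character(x$name) else rownames(x)
    cols <- intersect(c("x", "y", "z"), names(x))
    if (length(cols) == 3) x <- as.matrix(x[, cols]) else
      x <- as.matrix(x[, vapply(x, is.numeric, logical(1))])
    if (!is.null(nm)) rownames(x) <- nm
  }
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3)
    x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3)
    stop("a point set must have exactly 3 coordinate columns", call. = FALSE)
  if (any(!is.finite(x)))
    stop("point set contains non-finite coordinates", call. = FALSE)
  nm <- rownames(x)
  if (!is.null(nm) && anyDuplicated(nm))
    stop("point names must be unique within a set", call. = FALSE)
  x
}

#' Apply a rigid transform to points
#'
#' Maps every point by homogeneous multiplication, `p -> R p + t`. Pairwise
#' distances are preserved to floating-point precision. An empty point set
#' returns an empty set.
#'
#' @param t A `rigid_transform`.
#' @param pts A point set (see [as_points()]).
#' @return The transformed point set, names preserved.
#' @export
rt_apply <- function(t, pts) {
  t <- as_rigid_transform(t)
  pts <- as_points(pts)
  if (nrow(pts) == 0) return(pts)
  out <- pts %*% t(t[1:3, 1:3]) + rep(t[1:3, 4], each = nrow(pts))
  dimnames(out) <- dimnames(pts)
  out
}

#' Euler-angle decomposition of a rotation
#'
#' Decomposes the rotation block of a transform into extrinsic fixed-axis
#' X-Y-Z Euler angles in degrees (`R = Rz(rz) Ry(ry) Rx(rx)`); the
#' translation is ignored. In the gimbal-lock neighbourhood
#' (`|cos(ry)| < 1e-9`, i.e. `ry` at +/-90 degrees) the convention is
#' deterministic: `rx` absorbs the free angle and `rz` is set to 0, and the
#' result carries attribute `gimbal_lock = TRUE`.
#'
#' All rotation summaries reported by this package use this one convention;
#' for the sub-degree rotations typical of navigation error reports every
#' common convention agrees to well under 0.001 degree.
#'
#' @param t A `rigid_transform` (or 3x3/4x4 rotation matrix).
#' @return Named numeric vector `c(rx, ry, rz)` in degrees.
#' @export
rotation_to_euler <- function(t) {
  r <- if (is.matrix(t) && all(dim(t) == 3)) t else as_rigid_transform(t)[1:3, 1:3]
  sy <- -r[3, 1]
  sy <- min(1, max(-1, sy))
  cy <- sqrt(max(0, 1 - sy^2))
  if (cy < 1e-9) {
    # ry = +/-90 deg: only rx + rz (resp. rx - rz) identifiable; set rz = 0
    rx <- atan2(sy * r[1, 2], sy * r[1, 3])
    ang <- c(rx = rx, ry = asin(sy), rz = 0) * 180 / pi
    attr(ang, "gimbal_lock") <- TRUE
    return(ang)
  }
  c(rx = atan2(r[3, 2], r[3, 3]),
    ry = asin(sy),
    rz = atan2(r[2, 1], r[1, 1])) * 180 / pi
}

#' Build a rotation from Euler angles
#'
#' Inverse of [rotation_to_euler()]: extrinsic fixed-axis X-Y-Z order,
#' degrees, zero translation.
#'
#' @param angles Length-3 numeric `c(rx, ry, rz)` in degrees.
#' @return A `rigid_transform` with zero translation.
#' @export
euler_to_rotation <- function(angles) {
  stopifnot(is.numeric(angles), length(angles) == 3, all(is.finite(angles)))
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  m <- diag(4)
  m[1:3, 1:3] <- rz %*% ry %*% rx
  rigid_transform(m)
}

#' Geometric centre of a point set or mesh region
#'
#' The unweighted arithmetic mean of the vertex coordinates — the quantity
#' used for the displacement component of the global reduction error. An
#' area-weighted variant (`weight = "area"`, triangle-area weights on the
#' per-face centroids) is available for meshes.
#'
#' @param x A point set, or a `tri_mesh`.
#' @param region For meshes, an optional region label restricting the faces.
#' @param weight `"vertex"` (default, unweighted vertex centroid) or
#'   `"area"` (triangle-area-weighted surface centroid; meshes only).
#' @return Length-3 numeric centre (mm).
#' @export
geometric_center <- function(x, region = NULL, weight = c("vertex", "area")) {
  weight <- match.arg(weight)
  if (inherits(x, "tri_mesh")) {
    faces <- mesh_region_faces(x, region)
    if (length(faces) == 0) stop("region has no faces", call. = FALSE)
    if (weight == "area") {
      v <- x$vertices
      f <- x$faces[faces, , drop = FALSE]
      a <- v[f[, 2], ] - v[f[, 1], ]
      b <- v[f[, 3], ] - v[f[, 1], ]
      cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                  a[, 3] * b[, 1] - a[, 1] * b[, 3],
                  a[, 1] * b[, 2] - a[, 2] * b[, 1])
      w <- 0.5 * sqrt(rowSums(cr^2))
      cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
      return(colSums(cent * w) / sum(w))
    }
    x <- mesh_region_vertices(x, region)
  }
  x <- as_points(x)
  if (nrow(x) == 0) stop("cannot take the centre of an empty point set", call. = FALSE)
  colMeans(x)
}

#' @export
print.rigid_transform <- function(x, digits = 6, ...) {
  ang <- rotation_to_euler(x)
  cat("Rigid transform (SE(3), mm / degrees)\n")
  print(round(unclass(x), digits))
  cat(sprintf("translation: (%.4f, %.4f, %.4f) mm, |t| = %.4f mm\n",
              x[1, 4], x[2, 4], x[3, 4], sqrt(sum(x[1:3, 4]^2))))
  cat(sprintf("rotation (extrinsic XYZ): rx = %.4f, ry = %.4f, rz = %.4f deg\n",
              ang[1], ang[2], ang[3]))
  invisible(x)
}
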