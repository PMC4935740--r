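# Shared fixtures and oracles for the suite.

# Small, fast phantom for Monte-Carlo loops; the default spec is used where
# a test needs the full-resolution guarantees.
small_phantom <- function(seed = 1L, ...) {
  make_phantom(phantom_spec(n_theta = 40L, n_phi = 60L, seed = seed, ...))
}

# Deterministic random points in a box, mm scale.
random_points <- function(n, scale = 50, seed = 1L) {
  withr::with_seed(seed, matrix(stats::runif(3 * n, -scale, scale), ncol = 3))
}

# Rotation angle (deg) and translation norm (mm) separating two transforms.
# The angle comes from ||R - I||_F = 2 sqrt(2) sin(theta / 2), which keeps
# full precision at tiny angles where acos of the trace does not.
transform_gap <- function(a, b) {
  d <- rt_compose(a, rt_invert(b))
  fro <- sqrt(sum((unclass(d)[1:3, 1:3] - diag(3))^2))
  ang <- 2 * asin(min(1, fro / (2 * sqrt(2)))) * 180 / pi
  c(rot_deg = ang, trans_mm = sqrt(sum(d[1:3, 4]^2)))
}

# Translation error of an estimated pose, evaluated at a material point of
# the fragment (the matrix translation column depends on the arbitrary image
# origin; the displacement of the fragment itself does not).
pose_error_at <- function(est, truth, at) {
  sqrt(sum((rt_apply(est, at) - rt_apply(truth, at))^2))
}

# Brute-force orientation oracle for the paired-landmark problem: evaluates
# the least-squares objective over a seeded grid of unit quaternions, with
# the translation solved in closed form per rotation (centroid matching),
# and returns the best RMS found. Independent of the SVD path under test.
quaternion_grid_rms <- function(source, target, n_quat = 4000L, seed = 99L) {
  q <- withr::with_seed(seed, matrix(stats::rnorm(4 * n_quat), ncol = 4))
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rows of R for each quaternion, column-major flattening of the 3x3
  rmats <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                 2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                 2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  s0 <- sweep(source, 2, colMeans(source))
  t0 <- sweep(target, 2, colMeans(target))
  h <- crossprod(s0, t0)                       # SSE(R) = C - 2 tr(R h)
  const <- sum(s0^2) + sum(t0^2)
  sse <- const - 2 * (rmats %*% as.vector(t(h)))
  sqrt(max(0, min(sse)) / nrow(source))
}
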