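#' ICP parameter set
#'
#' Parameters controlling the iterative-closest-point refinement. Defaults:
#' at most 100 iterations, convergence when the RMS residual changes by less
#' than `1e-6` mm between iterations (tight, because inputs are mm-scale
#' bone surfaces), no correspondence trimming, no distance gate, and a
#' 5000-point subsampling cap with a recorded seed for very dense clouds.
#'
#' @param max_iterations Maximum ICP iterations.
#' @param tol Convergence tolerance: absolute change in RMS (mm).
#' @param trim_fraction Fraction of the worst correspondences discarded each
#'   iteration (`0 <= trim < 0.5`); `0` disables trimming. Trimming guards
#'   against outliers in real marker clouds, at the cost of the monotone-RMS
#'   guarantee.
#' @param max_correspondence_distance Gate (mm) beyond which a
#'   correspondence is discarded; `Inf` disables the gate.
#' @param subsample_cap Clouds larger than this are randomly subsampled.
#' @param seed Seed used for any subsampling (recorded in the result).
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, tol = 1e-6, trim_fraction = 0,
                       max_correspondence_distance = Inf,
                       subsample_cap = 5000L, seed = 1L) {
  stopifnot(max_iterations >= 1, tol > 0,
            trim_fraction >= 0, trim_fraction < 0.5,
            max_correspondence_distance > 0, subsample_cap >= 10)
  structure(list(max_iterations = as.integer(max_iterations), tol = tol,
                 trim_fraction = trim_fraction,
                 max_correspondence_distance = max_correspondence_distance,
                 subsample_cap = as.integer(subsample_cap),
                 seed = as.integer(seed)),
            class = "icp_params")
}

#' Closed-form least-squares rigid fit to paired landmarks
#'
#' Finds the rigid transform minimising `sum ||T s_i - t_i||^2` over paired
#' source/target points by the cross-covariance SVD (Kabsch/Horn) solution,
#' with the determinant correction that restricts the answer to proper
#' rotations. The reported `rms` is the fiducial registration error (FRE)
#' after the fit. At least three non-collinear pairs are required; with
#' collinear sources the rotation about the common line is unidentifiable
#' and the fit is refused, naming the degenerate direction.
#'
#' @param source,target Paired point sets (equal row counts), or `source`
#'   may be a list with `$source` and `$target` (as from [read_landmarks()]).
#' @param min_pairs Minimum number of pairs (3 for a full rigid fit).
#' @return An object of class `c("landmark_fit", "rigid_registration")`:
#'   a list with `transform`, `rms` (mm), `n`, and per-pair `residuals` (mm).
#' @examples
#' src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
#' tgt <- rt_apply(rt_translate(c(1, 2, 3)), src)
#' fit <- landmark_fit(src, tgt)
#' fit$rms   # 0: noiseless correspondences are matched exactly
#' @export
landmark_fit <- function(source, target = NULL, min_pairs = 3L) {
  if (is.list(source) && !is.data.frame(source) && is.null(target)) {
    target <- source$target; source <- source$source
  }
  source <- as_points(source); target <- as_points(target)
  if (nrow(source) != nrow(target))
    stop("source and target must have the same number of points", call. = FALSE)
  n <- nrow(source)
  if (n < min_pairs)
    stop(sprintf("at least %d landmark pairs are required for a rigid fit, got %d",
                 min_pairs, n), call. = FALSE)
  cs <- colMeans(source); ct <- colMeans(target)
  s0 <- sweep(source, 2, cs); t0 <- sweep(target, 2, ct)
  sv <- svd(s0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    dir <- svd(s0)$v[, 1]
    stop(sprintf(
      "source landmarks are collinear along direction (%.3f, %.3f, %.3f); rotation about that line is unidentifiable",
      dir[1], dir[2], dir[3]), call. = FALSE)
  }
  h <- crossprod(s0, t0)                 # 3x3 cross-covariance
  sv <- svd(h)
  d <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% d %*% t(sv$u)
  m <- diag(4)
  m[1:3, 1:3] <- reorthonormalize(r)
  m[1:3, 4] <- ct - m[1:3, 1:3] %*% cs
  transform <- rigid_transform(m)
  res <- sqrt(rowSums((rt_apply(transform, source) - target)^2))
  structure(list(transform = transform, rms = sqrt(mean(res^2)),
                 residuals = res, n = n),
            class = c("landmark_fit", "rigid_registration"))
}

# Blocked brute-force nearest neighbour: for each query row the index of the
# closest reference row (ties broken by lowest reference index). Distances
# via the expansion ||q - r||^2 = |q|^2 + |r|^2 - 2 q.r so BLAS does the work.
nearest_neighbors <- function(query, ref, block = 512L) {
  nq <- nrow(query)
  r2 <- rowSums(ref^2)
  idx <- integer(nq)
  d2 <- numeric(nq)
  for (from in seq(1L, nq, by = block)) {
    to <- min(from + block - 1L, nq)
    q <- query[from:to, , drop = FALSE]
    dd <- outer(rowSums(q^2), r2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-dd, ties.method = "first")
    idx[from:to] <- j
    d2[from:to] <- pmax(dd[cbind(seq_len(nrow(q)), j)], 0)
  }
  list(index = idx, distance = sqrt(d2))
}

#' Iterative closest point registration
#'
#' Point-to-point ICP: each iteration matches every (transformed) source
#' point to its nearest target point, optionally discards gated or trimmed
#' correspondences, solves the closed-form rigid update ([landmark_fit()] on
#' the correspondences), and recomputes the RMS residual. Iteration stops
#' when the RMS changes by less than `params$tol` or after
#' `params$max_iterations`. The result composes the accumulated update with
#' `init`, so `rt_apply(result$transform, source)` lies on the target.
#'
#' Nearest-neighbour ties are broken towards the lowest target index and any
#' subsampling is seeded, so runs are deterministic. With `trim_fraction = 0`
#' and no distance gate the recorded `rms_trace` is non-increasing (the
#' classic ICP monotonicity argument).
#'
#' @param source Point set (or `tri_mesh`) to move.
#' @param target Point set or `tri_mesh` to match against (>= 3 points).
#' @param init Initial transform (e.g. a coarse [landmark_fit()] result).
#' @param params An [icp_params()] object.
#' @return An object of class `c("icp_fit", "rigid_registration")`: a list
#'   with `transform`, `rms` (mm), `iterations`, `converged`, `rms_trace`,
#'   `n_source`, `n_target`, `subsampled`, `seed`.
#' @export
icp <- function(source, target, init = rt_identity(), params = icp_params()) {
  if (inherits(source, "tri_mesh")) source <- mesh_region_vertices(source)
  if (inherits(target, "tri_mesh")) target <- mesh_region_vertices(target)
  source <- as_points(source); target <- as_points(target)
  if (nrow(source) == 0) stop("ICP source cloud is empty", call. = FALSE)
  if (nrow(target) < 3) stop("ICP target needs at least 3 points", call. = FALSE)
  stopifnot(inherits(params, "icp_params"))
  init <- as_rigid_transform(init)

  subsampled <- FALSE
  if (nrow(source) > params$subsample_cap) {
    rng <- local({ set.seed(params$seed); sample.int(nrow(source), params$subsample_cap) })
    source <- source[rng, , drop = FALSE]
    subsampled <- TRUE
  }

  transform <- init
  trace <- numeric(0)
  rms_prev <- Inf
  converged <- FALSE
  iterations <- 0L
  for (k in seq_len(params$max_iterations)) {
    cur <- rt_apply(transform, source)
    nn <- nearest_neighbors(cur, target)
    keep <- seq_len(nrow(source))
    if (is.finite(params$max_correspondence_distance))
      keep <- keep[nn$distance[keep] <= params$max_correspondence_distance]
    if (params$trim_fraction > 0 && length(keep) > 3) {
      nkeep <- max(3L, floor(length(keep) * (1 - params$trim_fraction)))
      keep <- keep[order(nn$distance[keep])[seq_len(nkeep)]]
    }
    if (length(keep) < 3)
      stop(sprintf(
        "ICP has only %d correspondence(s) under max_correspondence_distance = %g mm",
        length(keep), params$max_correspondence_distance), call. = FALSE)
    step <- landmark_fit(cur[keep, , drop = FALSE],
                         target[nn$index[keep], , drop = FALSE])
    transform <- rt_compose(step$transform, transform)
    # RMS over this iteration's correspondences after the update
    moved <- rt_apply(transform, source[keep, , drop = FALSE])
    rms <- sqrt(mean(rowSums((moved - target[nn$index[keep], , drop = FALSE])^2)))
    trace <- c(trace, rms)
    iterations <- k
    if (abs(rms_prev - rms) < params$tol) { converged <- TRUE; break }
    rms_prev <- rms
  }
  structure(list(transform = transform, rms = trace[length(trace)],
                 iterations = iterations, converged = converged,
                 rms_trace = trace, n_source = nrow(source),
                 n_target = nrow(target), subsampled = subsampled,
                 seed = params$seed, params = params),
            class = c("icp_fit", "rigid_registration"))
}

#' Fine surface alignment seeded by a coarse fit
#'
#' Refines a coarse landmark alignment by running ICP between surface points
#' (e.g. ~20 points picked over the un-fractured frontal skull, maxilla and
#' naso-orbital regions) and the target mesh restricted to those fixed
#' regions. At least 4 surface points are required.
#'
#' @param coarse A `rigid_registration` (or bare `rigid_transform`) from the
#'   coarse alignment.
#' @param surface_points Picked surface points (>= 4).
#' @param target_mesh A `tri_mesh`.
#' @param regions Region label(s) of `target_mesh` to match against, or
#'   `NULL` for the whole mesh.
#' @param params An [icp_params()].
#' @return An `icp_fit`, as for [icp()].
#' @export
fine_alignment <- function(coarse, surface_points, target_mesh,
                           regions = NULL, params = icp_params()) {
  init <- if (inherits(coarse, "rigid_registration")) coarse$transform
          else as_rigid_transform(coarse)
  surface_points <- as_points(surface_points)
  if (nrow(surface_points) < 4)
    stop("fine alignment needs at least 4 surface points", call. = FALSE)
  target <- if (inherits(target_mesh, "tri_mesh"))
    mesh_region_vertices(target_mesh, regions) else as_points(target_mesh)
  icp(surface_points, target, init = init, params = params)
}

#' @export
print.rigid_registration <- function(x, ...) {
  kind <- if (inherits(x, "landmark_fit")) "Landmark (closed-form) rigid fit"
          else "ICP registration"
  cat(kind, "\n")
  if (!is.null(x$iterations))
    cat(sprintf("  iterations: %d (%s)\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "max iterations reached"))
  cat(sprintf("  RMS residual: %.6f mm\n", x$rms))
  ang <- rotation_to_euler(x$transform)
  tr <- x$transform[1:3, 4]
  cat(sprintf("  translation: (%.3f, %.3f, %.3f) mm; rotation: (%.3f, %.3f, %.3f) deg\n",
              tr[1], tr[2], tr[3], ang[1], ang[2], ang[3]))
  invisible(x)
}
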