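# Run expr with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random rigid transform
#'
#' A rotation about a uniformly random axis by an angle drawn uniformly from
#' `[0, rot_max_deg]`, plus a translation drawn uniformly from the ball of
#' radius `trans_max_mm`. Deterministic per seed.
#'
#' @param rot_max_deg Maximum rotation angle (degrees).
#' @param trans_max_mm Maximum translation norm (mm).
#' @param seed Integer seed.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(rot_max_deg = 10, trans_max_mm = 8, seed = 1L) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, rot_max_deg) * pi / 180
    k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    r <- diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)   # Rodrigues
    tr <- stats::rnorm(3)
    tr <- tr / sqrt(sum(tr^2)) * trans_max_mm * stats::runif(1)^(1 / 3)
    m <- diag(4)
    m[1:3, 1:3] <- reorthonormalize(r)
    m[1:3, 4] <- tr
    rigid_transform(m)
  })
}

#' Phantom specification
#'
#' Parameters of the synthetic skull-plus-zygoma phantom. The geometry is a
#' stylised ellipsoid shell (semi-axes 70 x 90 x 80 mm; x = left,
#' y = posterior, z = superior, right-handed) with a malar-like protrusion
#' on the left cheek; it is deliberately *not* anatomical — the planning
#' method is purely geometric, so correctness tests need realistic scales
#' and curvature variation, not skull shape. The zygoma region is the patch
#' within `patch_deg` of the malar direction; an annular gap of
#' `gap_deg` separates it from the fixed skull, emulating the widened
#' fracture line of a model surgery, so the fragment shares no vertices with
#' the fixed region.
#'
#' Noise defaults: fiducial and probe picking 0.3 mm isotropic Gaussian (a
#' typical optical-tracker figure; the source method does not quantify it),
#' and drilling scatter 0.579 mm, the sigma whose Maxwell mean
#' `2 * sigma * sqrt(2 / pi)` equals the 0.924 mm mean drilling deviation of
#' the model-surgery series.
#'
#' @param n_theta,n_phi Latitude/longitude mesh resolution.
#' @param patch_deg Angular radius of the zygoma patch (degrees).
#' @param gap_deg Angular width of the fracture gap (degrees).
#' @param rot_max_deg,trans_max_mm Bounds of the ground-truth dislocation.
#' @param fiducial_sd,probe_sd,drill_sd Noise levels (mm).
#' @param seed Integer seed; all phantom randomness flows through it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_theta = 64L, n_phi = 96L, patch_deg = 30,
                         gap_deg = 4, rot_max_deg = 10, trans_max_mm = 8,
                         fiducial_sd = 0.3, probe_sd = 0.3, drill_sd = 0.579,
                         seed = 1L) {
  stopifnot(n_theta >= 8, n_phi >= 8, patch_deg > 0, gap_deg >= 0,
            rot_max_deg >= 0, trans_max_mm >= 0,
            fiducial_sd >= 0, probe_sd >= 0, drill_sd >= 0)
  structure(list(n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
                 patch_deg = patch_deg, gap_deg = gap_deg,
                 rot_max_deg = rot_max_deg, trans_max_mm = trans_max_mm,
                 fiducial_sd = fiducial_sd, probe_sd = probe_sd,
                 drill_sd = drill_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Semi-axes of the skull ellipsoid (mm) and key directions (unit vectors in
# the x = left, y = posterior, z = superior frame).
.phantom_axes <- c(70, 90, 80)
.malar_dir <- c(0.80, -0.55, -0.24)
.bump2_dir <- c(0.62, -0.75, -0.10)
# Fixed-skull surface features (brow ridges, occiput, mastoids): without
# them a smooth ellipsoid lets surface ICP slide tangentially.
.fixed_bumps <- list(
  list(dir = c(0.45, -0.80, 0.35), height = 0.06, width = 16),
  list(dir = c(-0.45, -0.80, 0.35), height = 0.06, width = 16),
  list(dir = c(0.00, 0.95, 0.20), height = 0.08, width = 22),
  list(dir = c(0.90, 0.30, -0.30), height = 0.05, width = 14),
  list(dir = c(-0.90, 0.30, -0.30), height = 0.05, width = 14))

unit <- function(v) v / sqrt(sum(v^2))

#' Build a synthetic skull-plus-zygoma phantom
#'
#' Generates a labelled planned mesh (zygoma in its reduced position), the
#' dislocated mesh (zygoma fragment moved by the inverse of the ground-truth
#' reduction transform `t_true`; the fixed region is bit-identical between
#' the two), an anatomical landmark triplet on the fixed skull (nasion-like
#' and two zygomatico-frontal-suture-like points), three candidate surface
#' marks on the zygoma, and 12 screw-hole positions (three plate sites, four
#' holes each). `t_true` maps dislocated to reduced, so it is exactly what
#' [reduction_fit()] should recover.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `planned` and `dislocated`
#'   (`tri_mesh`), `t_true`, `landmarks`, `marks` (dislocated
#'   configuration), `marks_reduced`, `holes_reduced`, `holes_dislocated`,
#'   and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  th <- seq(0, pi, length.out = spec$n_theta + 2L)[-c(1L, spec$n_theta + 2L)]
  ph <- seq(0, 2 * pi, length.out = spec$n_phi + 1L)[-(spec$n_phi + 1L)]
  grid <- expand.grid(theta = th, phi = ph)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  dirs <- rbind(dirs, c(0, 0, 1), c(0, 0, -1))
  npole <- nrow(dirs) - 1L; spole <- nrow(dirs)

  # malar protrusion: two radial bumps break the patch's rotational symmetry
  ang1 <- acos(pmin(1, pmax(-1, dirs %*% unit(.malar_dir))))
  ang2 <- acos(pmin(1, pmax(-1, dirs %*% unit(.bump2_dir))))
  radial <- 1 + 0.14 * exp(-(ang1 / (12 * pi / 180))^2) +
                0.06 * exp(-(ang2 / (9 * pi / 180))^2)
  for (b in .fixed_bumps) {
    ab <- acos(pmin(1, pmax(-1, dirs %*% unit(b$dir))))
    radial <- radial + b$height * exp(-(ab / (b$width * pi / 180))^2)
  }
  # low-frequency surface texture (~30 mm wavelength, ~1.5 mm amplitude):
  # real bone is featured everywhere, and without such relief a shell this
  # smooth gives surface registration almost no rotational gradient
  radial <- radial +
    0.020 * sin(16.7 * dirs %*% unit(c(0.30, 0.80, 0.52))) +
    0.020 * sin(16.7 * dirs %*% unit(c(-0.76, 0.36, 0.54)))
  radial <- as.vector(radial)
  verts <- dirs * as.vector(radial)
  verts <- sweep(verts, 2, .phantom_axes, `*`)

  faces <- phantom_faces(spec$n_theta, spec$n_phi, npole, spole)

  patch <- as.vector(ang1) * 180 / pi <= spec$patch_deg
  inner <- as.vector(ang1) * 180 / pi <= spec$patch_deg - spec$gap_deg
  fzy <- inner[faces[, 1]] & inner[faces[, 2]] & inner[faces[, 3]]
  ffx <- !(patch[faces[, 1]] | patch[faces[, 2]] | patch[faces[, 3]])
  keep <- rbind(faces[ffx, , drop = FALSE], faces[fzy, , drop = FALSE])
  labels <- c(rep("fixed", sum(ffx)), rep("zygoma", sum(fzy)))
  used <- sort(unique(as.vector(keep)))
  remap <- match(keep, used)
  dim(remap) <- dim(keep)
  planned <- tri_mesh(verts[used, , drop = FALSE], remap, labels)
  if (nrow(mesh_region_vertices(planned, "zygoma")) < 3)
    stop("degenerate phantom spec: zygoma patch has no area", call. = FALSE)

  t_true <- random_rigid_transform(spec$rot_max_deg, spec$trans_max_mm,
                                   seed = spec$seed)
  dislocated <- mesh_transform(planned, rt_invert(t_true), region = "zygoma")

  fx <- mesh_region_vertices(planned, "fixed")
  landmarks <- rbind(
    nasion = nearest_surface_point(fx, c(0, -1, 0.35)),
    zf_suture_left = nearest_surface_point(fx, c(0.75, -0.5, 0.35)),
    zf_suture_right = nearest_surface_point(fx, c(-0.75, -0.5, 0.35)))

  zy <- mesh_region_vertices(planned, "zygoma")
  mark_dirs <- list(zf = c(0.72, -0.5, 0.12), infraorbital = c(0.52, -0.75, -0.12),
                    buttress = c(0.78, -0.45, -0.44))
  marks_reduced <- do.call(rbind, lapply(mark_dirs, function(d)
    nearest_surface_point(zy, d)))
  rownames(marks_reduced) <- names(mark_dirs)

  holes_reduced <- do.call(rbind, lapply(seq_along(mark_dirs), function(i) {
    centre <- marks_reduced[i, ]
    d2 <- rowSums(sweep(zy, 2, centre)^2)
    idx <- order(d2)[2:5]                      # 4 holes around each plate site
    h <- zy[idx, , drop = FALSE]
    rownames(h) <- sprintf("%s_hole%d", names(mark_dirs)[i], 1:4)
    h
  }))

  structure(list(planned = planned, dislocated = dislocated, t_true = t_true,
                 landmarks = landmarks,
                 marks = rt_apply(rt_invert(t_true), marks_reduced),
                 marks_reduced = marks_reduced,
                 holes_reduced = holes_reduced,
                 holes_dislocated = rt_apply(rt_invert(t_true), holes_reduced),
                 spec = spec),
            class = "phantom")
}

# Triangulate the lat-long grid (n_theta rings of n_phi vertices + 2 poles).
phantom_faces <- function(n_theta, n_phi, npole, spole) {
  vid <- function(i, j) (((j - 1L) %% n_phi)) * n_theta + i
  i <- rep(seq_len(n_theta - 1L), n_phi)
  j <- rep(seq_len(n_phi), each = n_theta - 1L)
  quads <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  tris <- rbind(quads[, c(1L, 2L, 3L)], quads[, c(1L, 3L, 4L)])
  caps <- rbind(cbind(npole, vid(1L, seq_len(n_phi)), vid(1L, seq_len(n_phi) + 1L)),
                cbind(spole, vid(n_theta, seq_len(n_phi) + 1L),
                      vid(n_theta, seq_len(n_phi))))
  rbind(tris, caps)
}

# Vertex of `pts` closest in direction to the unit vector `dir` (on the
# unit-ellipsoid parameter sphere).
nearest_surface_point <- function(pts, dir) {
  u <- sweep(pts, 2, .phantom_axes, `/`)
  u <- u / sqrt(rowSums(u^2))
  pts[which.max(u %*% unit(dir)), ]
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic skull phantom\n")
  cat(sprintf("  planned mesh: %d vertices (%d zygoma); dislocation |t| = %.2f mm, %.2f deg\n",
              nrow(x$planned$vertices),
              nrow(mesh_region_vertices(x$planned, "zygoma")),
              sqrt(sum(x$t_true[1:3, 4]^2)),
              rotation_angle_deg(x$t_true)))
  cat(sprintf("  seed %d; noise (mm): fiducial %.2f, probe %.2f, drill %.3f\n",
              x$spec$seed, x$spec$fiducial_sd, x$spec$probe_sd, x$spec$drill_sd))
  invisible(x)
}

# Total rotation angle of a transform, degrees.
rotation_angle_deg <- function(t) {
  r <- as_rigid_transform(t)[1:3, 1:3]
  acos(min(1, max(-1, (sum(diag(r)) - 1) / 2))) * 180 / pi
}

#' Simulate the probing procedure
#'
#' Physical mark positions under the fragment's current pose are probed with
#' isotropic Gaussian picking noise: `probed = pose . mark + N(0, sd^2 I)`
#' (+ an optional fixed depth-bias vector, emulating a probe tip that cannot
#' reach the bottom of a deep hole). Readings are reported against the
#' FNRPs, as on the navigation display.
#'
#' @param fnrps An `fnrp_set` from [generate_fnrps()].
#' @param current_pose The fragment's current rigid pose (dislocated
#'   registration frame to current physical position); identity = not yet
#'   moved, the fitted reduction transform = perfectly reduced.
#' @param sd Isotropic picking noise (mm).
#' @param seed Integer seed.
#' @param depth_bias Length-3 systematic offset (mm) added to every probe.
#' @return A probe-reading data frame (see [probe_readings()]).
#' @export
simulate_probe_readings <- function(fnrps, current_pose = rt_identity(),
                                    sd = 0.3, seed = 1L,
                                    depth_bias = c(0, 0, 0)) {
  stopifnot(inherits(fnrps, "fnrp_set"), sd >= 0, length(depth_bias) == 3)
  marks <- as.matrix(fnrps[, c("xd", "yd", "zd")])
  probed <- rt_apply(current_pose, marks)
  noise <- with_seed(seed,
    matrix(stats::rnorm(3L * nrow(marks), 0, sd), ncol = 3))
  probed <- probed + noise + rep(depth_bias, each = nrow(marks))
  rownames(probed) <- fnrps$name
  probe_readings(fnrps, probed)
}

#' Simulate the drilling procedure
#'
#' Hand tremor, handpiece vibration and drill-bit wander are modelled as
#' isotropic Gaussian scatter about each planned drilling target, so each
#' simulated deviation follows a Maxwell distribution with mean
#' `2 * sd * sqrt(2 / pi)`. Pairing the output with [drilling_deviation()]
#' yields a synthetic deviation table.
#'
#' @param planned_holes Planned drilling targets (point set).
#' @param sd Per-axis scatter (mm).
#' @param seed Integer seed.
#' @return Point set of simulated drilled-hole positions.
#' @export
simulate_drilling <- function(planned_holes, sd = 0.579, seed = 1L) {
  planned_holes <- as_points(planned_holes)
  stopifnot(sd >= 0)
  noise <- with_seed(seed,
    matrix(stats::rnorm(3L * nrow(planned_holes), 0, sd), ncol = 3))
  planned_holes + noise
}

#' Maxwell-distribution helpers for isotropic 3-D scatter
#'
#' If each coordinate error is `N(0, sd^2)`, the Euclidean deviation follows
#' a Maxwell distribution with mean `2 * sd * sqrt(2 / pi)`.
#' `maxwell_mean()` maps sigma to that mean; `maxwell_sd_for_mean()` inverts
#' it, giving the per-axis sigma that reproduces a target mean deviation.
#'
#' @param sd Per-axis standard deviation (mm).
#' @param mean_deviation Target mean Euclidean deviation (mm).
#' @return A numeric scalar.
#' @export
maxwell_mean <- function(sd) 2 * sd * sqrt(2 / pi)

#' @rdname maxwell_mean
#' @export
maxwell_sd_for_mean <- function(mean_deviation) mean_deviation / (2 * sqrt(2 / pi))

#' Export a phantom to files
#'
#' Writes `planned.stl`, `dislocated.stl`, `labels.json`, `landmarks.tsv`
#' (fixed-skull registration points), `marks.tsv` (dislocated
#' configuration), `mark_pairs.tsv` (marks paired with their reduced
#' positions, a ready-made coarse-alignment landmark file), `holes.tsv`
#' (reduced configuration) and `truth_transform.txt` into a directory.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory (created if absent).
#' @param dialect STL dialect, `"binary"` or `"ascii"`.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, dialect = "binary") {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stl(phantom$planned, file.path(dir, "planned.stl"), dialect = dialect)
  write_stl(phantom$dislocated, file.path(dir, "dislocated.stl"), dialect = dialect)
  write_labels(phantom$planned, file.path(dir, "labels.json"))
  write_points(phantom$landmarks, file.path(dir, "landmarks.tsv"))
  write_points(phantom$marks, file.path(dir, "marks.tsv"))
  write_landmarks(phantom$marks, phantom$marks_reduced,
                  file.path(dir, "mark_pairs.tsv"))
  write_points(phantom$holes_reduced, file.path(dir, "holes.tsv"))
  write_transform(phantom$t_true, file.path(dir, "truth_transform.txt"))
  invisible(dir)
}
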