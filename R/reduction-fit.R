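#' Fit the dislocated-to-reduced transform of a bone fragment
#'
#' The central model of the package. Given point clouds sampled on the same
#' zygoma surface in its dislocated and its planned (reduced) configuration,
#' `reduction_fit()` estimates the rigid reduction transform `T` such that
#' `T p_dislocated` lies on the reduced surface, by ICP optionally seeded
#' with a coarse landmark fit. Everything downstream is transform algebra on
#' the fitted `T`:
#'
#' * `predict(fit, marks)` maps intraoperatively chosen surface marks on the
#'   dislocated bone to their reduced positions — the free navigation
#'   reference points (FNRPs) used as probing targets;
#' * `predict(fit, holes, direction = "dislocate")` applies the inverse
#'   transform, back-calculating screw holes planned on the reduced bone
#'   onto the dislocated bone for drilling.
#'
#' Because surgical manipulation breaks the bone-to-image registration, FNRP
#' generation is only valid for marks registered *before* the fragment is
#' freed; see [mark_reduced()].
#'
#' @param dislocated Point cloud (or `tri_mesh` region) on the dislocated
#'   fragment.
#' @param planned Point cloud (or `tri_mesh` region) of the same surface in
#'   the planned, reduced position.
#' @param init Optional initial transform, or a list of paired landmarks
#'   (`$source` on the dislocated bone, `$target` on the planned bone) for a
#'   coarse [landmark_fit()].
#' @param params [icp_params()] controlling the ICP refinement.
#' @param rms_threshold Largest acceptable final RMS (mm); a fit whose
#'   residual exceeds it, or that fails to converge, is refused rather than
#'   returned — a silently bad reduction transform would corrupt every FNRP
#'   derived from it.
#' @return An object of class `reduction_fit`: a list with `transform` (the
#'   fitted `rigid_transform`), `registration` (the `icp_fit`), `residuals`
#'   (per-source-point nearest-surface distances after reduction, mm),
#'   `dislocated`, `planned`, and the `reduced` state flag.
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 1))
#' fit <- reduction_fit(mesh_region_vertices(ph$dislocated, "zygoma"),
#'                      mesh_region_vertices(ph$planned, "zygoma"),
#'                      init = list(source = ph$marks, target = ph$marks_reduced))
#' coef(fit)
#' @export
reduction_fit <- function(dislocated, planned, init = NULL,
                          params = icp_params(), rms_threshold = 1.0) {
  if (inherits(dislocated, "tri_mesh")) dislocated <- mesh_region_vertices(dislocated)
  if (inherits(planned, "tri_mesh")) planned <- mesh_region_vertices(planned)
  dislocated <- as_points(dislocated); planned <- as_points(planned)
  init_t <- if (is.null(init)) rt_identity()
            else if (is.list(init) && !inherits(init, "rigid_transform"))
              landmark_fit(init)$transform
            else as_rigid_transform(init)
  reg <- icp(dislocated, planned, init = init_t, params = params)
  if (!reg$converged)
    stop(sprintf(
      "reduction transform did not converge within %d ICP iterations (RMS %.4f mm); no plan produced",
      params$max_iterations, reg$rms), call. = FALSE)
  if (reg$rms > rms_threshold)
    stop(sprintf(
      "reduction fit RMS %.4f mm exceeds threshold %.3f mm; the clouds do not sample the same surface",
      reg$rms, rms_threshold), call. = FALSE)
  res <- nearest_neighbors(rt_apply(reg$transform, dislocated), planned)$distance
  structure(list(transform = reg$transform, registration = reg,
                 residuals = res, dislocated = dislocated, planned = planned,
                 rms_threshold = rms_threshold, reduced = FALSE,
                 call = match.call()),
            class = "reduction_fit")
}

#' @export
print.reduction_fit <- function(x, ...) {
  cat("Reduction plan (dislocated -> reduced rigid transform)\n")
  ang <- rotation_to_euler(x$transform)
  tr <- x$transform[1:3, 4]
  cat(sprintf("  translation: (%.3f, %.3f, %.3f) mm, |t| = %.3f mm\n",
              tr[1], tr[2], tr[3], sqrt(sum(tr^2))))
  cat(sprintf("  rotation (extrinsic XYZ): (%.3f, %.3f, %.3f) deg\n",
              ang[1], ang[2], ang[3]))
  cat(sprintf("  ICP: %d iterations, RMS %.5f mm%s\n",
              x$registration$iterations, x$registration$rms,
              if (is.null(x$registration$n_source)) "" else
                sprintf(" (%d vs %d points)", x$registration$n_source,
                        x$registration$n_target)))
  cat(sprintf("  state: %s\n",
              if (x$reduced) "reduced (mark registration closed)" else "pre-reduction"))
  invisible(x)
}

#' @export
summary.reduction_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              rms = object$registration$rms,
              iterations = object$registration$iterations,
              converged = object$registration$converged,
              residual_summary = summary(object$residuals),
              n = nrow(object$dislocated))
  class(out) <- "summary.reduction_fit"
  out
}

#' @export
print.summary.reduction_fit <- function(x, ...) {
  cat("Reduction-fit summary\n\nTransform parameters:\n")
  print(round(x$coef, 4))
  cat(sprintf("\nICP RMS %.5f mm after %d iterations (%s); %d source points\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "not converged", x$n))
  cat("Per-point surface residuals (mm):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @describeIn reduction_fit Transform parameters as a named vector:
#'   translation `tx, ty, tz` (mm) and extrinsic-XYZ Euler angles
#'   `rx, ry, rz` (degrees).
#' @param object,x A `reduction_fit`.
#' @param ... Unused.
#' @export
coef.reduction_fit <- function(object, ...) {
  ang <- rotation_to_euler(object$transform)
  c(tx = object$transform[1, 4], ty = object$transform[2, 4],
    tz = object$transform[3, 4],
    rx = unname(ang[1]), ry = unname(ang[2]), rz = unname(ang[3]))
}

#' @describeIn reduction_fit Per-point distances from the reduced source
#'   cloud to the planned surface (mm).
#' @export
residuals.reduction_fit <- function(object, ...) object$residuals

#' @describeIn reduction_fit Map points through the fitted transform:
#'   `direction = "reduce"` applies `T` (mark -> FNRP), `"dislocate"`
#'   applies `T^-1` (planned hole -> drilling target).
#' @param newdata Points to transform.
#' @param direction `"reduce"` or `"dislocate"`.
#' @export
predict.reduction_fit <- function(object, newdata,
                                  direction = c("reduce", "dislocate"), ...) {
  direction <- match.arg(direction)
  t <- if (direction == "reduce") object$transform else rt_invert(object$transform)
  rt_apply(t, as_points(newdata))
}

#' @describeIn reduction_fit RMS-trace convergence plot of the underlying ICP.
#' @param y Unused.
#' @export
plot.reduction_fit <- function(x, y, ...) {
  tr <- x$registration$rms_trace
  graphics::plot(seq_along(tr), tr, type = "b", pch = 16,
                 xlab = "ICP iteration", ylab = "RMS residual (mm)",
                 main = "Reduction-fit convergence", ...)
  invisible(x)
}

#' Close mark registration after fracture reduction
#'
#' Surgical manipulation breaks the rigid relationship between the fragment
#' and the registered image, so surface marks must be selected and
#' registered before the fragment is freed. Calling `mark_reduced()` flags
#' the plan as reduced; any later [generate_fnrps()] call on it is refused.
#'
#' @param fit A [reduction_fit()].
#' @return The fit with its `reduced` flag set.
#' @export
mark_reduced <- function(fit) {
  stopifnot(inherits(fit, "reduction_fit"))
  fit$reduced <- TRUE
  fit
}

#' Generate free navigation reference points from surface marks
#'
#' Applies the fitted reduction transform to each registered surface mark on
#' the dislocated bone: the image of a mark is its FNRP, the navigation
#' target the physical mark should reach when the fragment is correctly
#' reduced. At least three FNRPs are needed to confirm a 3-D pose, so fewer
#' than three marks triggers a warning (not an error). Marks cannot be added
#' once the plan is flagged reduced (see [mark_reduced()]).
#'
#' @param fit A [reduction_fit()].
#' @param marks Point set of surface marks on the dislocated bone (named
#'   rows recommended).
#' @return A data frame of class `fnrp_set` with columns `name`,
#'   `xd, yd, zd` (mark, dislocated) and `xr, yr, zr` (FNRP, reduced).
#' @export
generate_fnrps <- function(fit, marks) {
  stopifnot(inherits(fit, "reduction_fit"))
  if (fit$reduced)
    stop(paste("plan is flagged reduced: marks must be registered before",
               "fracture reduction, so no further FNRPs can be generated"),
         call. = FALSE)
  marks <- as_points(marks)
  if (nrow(marks) == 0) stop("no marks supplied", call. = FALSE)
  if (nrow(marks) < 3)
    warning(sprintf(
      "only %d mark(s): at least three FNRPs are needed to confirm a 3-D pose",
      nrow(marks)), call. = FALSE)
  ref <- rt_apply(fit$transform, marks)
  out <- data.frame(name = rownames(marks) %||% sprintf("mark%d", seq_len(nrow(marks))),
                    xd = marks[, 1], yd = marks[, 2], zd = marks[, 3],
                    xr = ref[, 1], yr = ref[, 2], zr = ref[, 3],
                    row.names = NULL)
  class(out) <- c("fnrp_set", "data.frame")
  out
}

#' Back-calculate planned screw holes onto the dislocated bone
#'
#' Screw holes chosen on the reduced bone (e.g. registered on the
#' fabrication model carrying pre-bent plates) are mapped through the
#' inverse reduction transform to the positions where they must be drilled
#' on the still-dislocated bone. Applying the forward transform to the
#' result reproduces the input exactly.
#'
#' @param fit A [reduction_fit()].
#' @param holes_reduced Point set of screw holes in the reduced configuration.
#' @return Point set of drilling targets on the dislocated bone.
#' @export
back_calculate_holes <- function(fit, holes_reduced) {
  stopifnot(inherits(fit, "reduction_fit"))
  predict(fit, holes_reduced, direction = "dislocate")
}

#' Probe readings against FNRPs
#'
#' The probing procedure: a tracked probe touches a registered surface mark
#' and the navigation display reports its offset from the corresponding
#' FNRP. `probe_readings()` computes, per FNRP, the offset vector
#' `probed - reference` and its Euclidean norm; a distance near zero means
#' the mark has reached its reduced position.
#'
#' @param fnrps An `fnrp_set` from [generate_fnrps()].
#' @param probed Point set of probed positions, one row per FNRP (matched by
#'   row order; names checked when present).
#' @return A data frame with columns `name`, probed coordinates, offset
#'   components `dx, dy, dz` and `distance` (mm).
#' @export
probe_readings <- function(fnrps, probed) {
  stopifnot(inherits(fnrps, "fnrp_set"))
  probed <- as_points(probed)
  if (nrow(probed) != nrow(fnrps))
    stop("one probed position per FNRP is required", call. = FALSE)
  if (!is.null(rownames(probed)) && !identical(rownames(probed), fnrps$name))
    stop("probed point names do not match FNRP names", call. = FALSE)
  ref <- as.matrix(fnrps[, c("xr", "yr", "zr")])
  off <- probed - ref
  data.frame(name = fnrps$name,
             x = probed[, 1], y = probed[, 2], z = probed[, 3],
             dx = off[, 1], dy = off[, 2], dz = off[, 3],
             distance = sqrt(rowSums(off^2)), row.names = NULL)
}

#' Estimate the fragment pose from probed marks
#'
#' With three or more non-collinear marks probed, the fragment's current
#' rigid pose (the transform carrying each registered mark position to its
#' probed position) is recovered by [landmark_fit()]. Comparing the
#' recovered pose with the planned reduction transform quantifies the
#' residual malposition; at perfect reduction the two coincide.
#'
#' @param fnrps An `fnrp_set`.
#' @param probed Probed positions, one per FNRP.
#' @return A `landmark_fit` whose `transform` is the current pose (image
#'   frame, dislocated-registration coordinates to probed coordinates).
#' @export
pose_from_probes <- function(fnrps, probed) {
  stopifnot(inherits(fnrps, "fnrp_set"))
  landmark_fit(as.matrix(fnrps[, c("xd", "yd", "zd")]), as_points(probed))
}

#' FNRP table files
#'
#' Tab-separated text with columns `name, xd, yd, zd, xr, yr, zr`:
#' the registered mark on the dislocated bone and its FNRP.
#'
#' @param fnrps An `fnrp_set`.
#' @param path File path.
#' @return `read_fnrps()`: an `fnrp_set`.
#' @export
write_fnrps <- function(fnrps, path) {
  stopifnot(inherits(fnrps, "fnrp_set"))
  utils::write.table(format(as.data.frame(fnrps), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fnrps
#' @export
read_fnrps <- function(path) {
  df <- read_checked_table(path, c("name", "xd", "yd", "zd", "xr", "yr", "zr"))
  class(df) <- c("fnrp_set", "data.frame")
  df
}
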