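#' Drilling deviation
#'
#' The drilling error of one screw hole: the Euclidean distance (mm) between
#' the drilled-and-registered hole position and its planned position, both
#' in the image frame. Vectorised over matched rows.
#'
#' @param registered,planned Point sets with matching rows.
#' @return Numeric vector of distances (mm).
#' @export
drilling_deviation <- function(registered, planned) {
  registered <- as_points(registered); planned <- as_points(planned)
  if (nrow(registered) != nrow(planned))
    stop("registered and planned hole counts differ", call. = FALSE)
  sqrt(rowSums((registered - planned)^2))
}

#' Deviation tables
#'
#' Collects drilling deviations indexed by fracture site and hole, the form
#' in which a model-surgery series is reported: one column of deviations
#' (mm) per `(site, hole)` pair.
#'
#' @param site Fracture-site identifier per entry.
#' @param hole Hole identifier per entry.
#' @param deviation_mm Non-negative deviations (mm).
#' @return A data frame of class `deviation_table`.
#' @export
deviation_table <- function(site, hole, deviation_mm) {
  deviation_mm <- as.numeric(deviation_mm)
  if (length(deviation_mm) == 0) stop("empty deviation table", call. = FALSE)
  if (any(!is.finite(deviation_mm)) || any(deviation_mm < 0))
    stop("deviations must be finite and non-negative", call. = FALSE)
  df <- data.frame(site = as.character(site), hole = hole,
                   deviation_mm = deviation_mm)
  class(df) <- c("deviation_table", "data.frame")
  df
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarise a deviation table
#'
#' Per-site mean deviations plus the grand mean and grand standard
#' deviation over all holes. The default standard deviation is the
#' population (divide-by-n) form, which is what published navigation error
#' tables in this area reproduce; the sample (n-1) form is available via
#' `sd_type`.
#'
#' @param object A [deviation_table()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param ... Unused.
#' @return A list of class `summary.deviation_table` with `site_means`,
#'   `grand_mean`, `grand_sd`, `n`.
#' @export
summary.deviation_table <- function(object, sd_type = c("population", "sample"),
                                    ...) {
  sd_type <- match.arg(sd_type)
  sdf <- if (sd_type == "population") sd_pop else stats::sd
  means <- c(tapply(object$deviation_mm, object$site, mean))
  out <- list(site_means = means[order(names(means))],
              grand_mean = mean(object$deviation_mm),
              grand_sd = sdf(object$deviation_mm),
              sd_type = sd_type, n = nrow(object))
  class(out) <- "summary.deviation_table"
  out
}

#' @export
print.summary.deviation_table <- function(x, digits = 3, ...) {
  cat(sprintf("Drilling deviations: %d holes, %d sites\n", x$n,
              length(x$site_means)))
  cat("Per-site mean deviation (mm):\n")
  print(round(x$site_means, digits))
  cat(sprintf("Total mean +/- standard deviation: %.3f +/- %.3f mm (%s SD)\n",
              x$grand_mean, x$grand_sd, x$sd_type))
  invisible(x)
}

#' Global reduction error between plan and outcome
#'
#' Reproduces the whole-procedure error analysis: (1) the postoperative mesh
#' is rigidly aligned to the preoperative plan by ICP on the un-operated
#' (fixed) region only; (2) the residual rigid transform between the planned
#' zygoma and the achieved zygoma, expressed in the image frame, is
#' estimated by ICP between the two zygoma clouds; (3) the displacement is
#' the distance between the two zygoma geometric centres and the rotation is
#' the extrinsic-XYZ Euler decomposition of the residual rotation.
#'
#' @param preop Planned `tri_mesh` with region labels.
#' @param postop Achieved (postoperative) `tri_mesh` with the same labels.
#' @param fixed_label Label of the un-operated region used for alignment.
#' @param zygoma_label Label of the reduced fragment.
#' @param params [icp_params()] for both ICP stages.
#' @param align_init Optional initial transform for the fixed-region
#'   alignment. By default the centroids are matched first, which absorbs
#'   any scanner-frame translation; surface ICP then corrects rotational
#'   offsets of a few degrees, the typical frame difference between scans of
#'   the same head. Grossly rotated frames should be pre-aligned here, e.g.
#'   with a [landmark_fit()] on anatomical points.
#' @return A list of class `error_report`: `displacement` (mm), `rotation`
#'   (signed Euler angles, degrees), `transform` (planned -> achieved),
#'   `alignment` and `relative` registration diagnostics.
#' @export
global_error <- function(preop, postop, fixed_label = "fixed",
                         zygoma_label = "zygoma", params = icp_params(),
                         align_init = NULL) {
  stopifnot(inherits(preop, "tri_mesh"), inherits(postop, "tri_mesh"))
  fixed_pre <- mesh_region_vertices(preop, fixed_label)
  fixed_post <- mesh_region_vertices(postop, fixed_label)
  zy_pre <- mesh_region_vertices(preop, zygoma_label)
  zy_post <- mesh_region_vertices(postop, zygoma_label)

  if (is.null(align_init))
    align_init <- rt_translate(colMeans(fixed_pre) - colMeans(fixed_post))
  align <- icp(fixed_post, fixed_pre, init = align_init, params = params)
  if (!align$converged)
    warning("fixed-region alignment did not converge", call. = FALSE)
  zy_post_aligned <- rt_apply(align$transform, zy_post)

  rel <- icp(zy_pre, zy_post_aligned, params = params)
  if (!rel$converged)
    warning("zygoma-to-zygoma registration did not converge", call. = FALSE)

  displacement <- sqrt(sum((geometric_center(zy_post_aligned) -
                              geometric_center(zy_pre))^2))
  structure(list(displacement = displacement,
                 rotation = rotation_to_euler(rel$transform),
                 transform = rel$transform,
                 alignment = align, relative = rel),
            class = "error_report")
}

#' @export
print.error_report <- function(x, digits = 3, ...) {
  cat("Global reduction error\n")
  cat(sprintf("  geometric-centre displacement: %.3f mm\n", x$displacement))
  cat(sprintf("  rotation (extrinsic XYZ): rx = %.3f, ry = %.3f, rz = %.3f deg\n",
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Summarise a series of reduction-error reports
#'
#' Column-wise summaries over a cohort of reductions: the mean of the
#' absolute values, and their standard deviation (population form by
#' default), for the displacement and each rotation axis. Signed rotations
#' are kept in the input but only absolute-value summaries are reported —
#' sign conventions do not survive between navigation systems.
#'
#' @param reports A list of `error_report` objects, or a data frame in the
#'   [read_error_table()] layout.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list of class `error_summary` with `abs_mean` and `abs_sd`,
#'   each a named vector over
#'   `displacement_mm, rot_x_deg, rot_y_deg, rot_z_deg`, plus `n`.
#' @export
summarize_error_reports <- function(reports, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sdf <- if (sd_type == "population") sd_pop else stats::sd
  if (is.data.frame(reports)) {
    m <- as.matrix(reports[, c("displacement_mm", "rot_x_deg", "rot_y_deg",
                               "rot_z_deg")])
  } else {
    if (length(reports) == 0) stop("no error reports", call. = FALSE)
    m <- t(vapply(reports, function(r) {
      stopifnot(inherits(r, "error_report"))
      c(r$displacement, r$rotation)
    }, numeric(4)))
    colnames(m) <- c("displacement_mm", "rot_x_deg", "rot_y_deg", "rot_z_deg")
  }
  a <- abs(m)
  structure(list(abs_mean = colMeans(a), abs_sd = apply(a, 2, sdf),
                 sd_type = sd_type, n = nrow(m)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Reduction-error summary over %d cases (%s SD of absolute values)\n",
              x$n, x$sd_type))
  tab <- rbind(`absolute mean` = x$abs_mean, `SD` = x$abs_sd)
  print(round(tab, digits))
  invisible(x)
}
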