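#' Run configuration files
#'
#' A `run_config` bundles the reproducibility-relevant settings of a
#' planning/evaluation run — ICP parameters, noise levels, seeds, file
#' paths, the standard-deviation denominator and the Euler convention tag —
#' and round-trips through JSON exactly.
#'
#' @param icp An [icp_params()] object.
#' @param noise Named list of noise levels in mm (e.g. `fiducial`, `probe`,
#'   `drill`).
#' @param seed Integer master seed.
#' @param paths Named list of input/output file paths.
#' @param sd_type `"population"` or `"sample"` — the denominator used in
#'   summary tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(icp = icp_params(),
                       noise = list(fiducial = 0.3, probe = 0.3, drill = 0.579),
                       seed = 1L, paths = list(),
                       sd_type = c("population", "sample")) {
  stopifnot(inherits(icp, "icp_params"))
  structure(list(icp = unclass(icp), noise = noise, seed = as.integer(seed),
                 paths = paths, sd_type = match.arg(sd_type),
                 euler_convention = "extrinsic-xyz-degrees"),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  icp <- raw$icp
  if (is.null(icp$max_correspondence_distance))
    icp$max_correspondence_distance <- Inf
  # jsonlite writes Inf as the string "Inf"
  icp$max_correspondence_distance <- as.numeric(icp$max_correspondence_distance)
  cfg <- run_config(icp = do.call(icp_params, icp),
                    noise = as.list(raw$noise), seed = raw$seed,
                    paths = as.list(raw$paths), sd_type = raw$sd_type)
  if (!identical(raw$euler_convention, cfg$euler_convention))
    stop(sprintf("unsupported Euler convention tag '%s'", raw$euler_convention),
         call. = FALSE)
  cfg
}

#' Plan files
#'
#' Serialises a fitted reduction plan — the 4x4 transform plus convergence
#' diagnostics and the reduced-state flag — to JSON so the planning and the
#' intraoperative stages can run as separate processes. The point clouds are
#' not stored; a re-read plan supports FNRP generation, back-calculation and
#' probing, but not residual inspection.
#'
#' @param fit A [reduction_fit()].
#' @param path JSON file path.
#' @return `read_plan()`: a `reduction_fit` (without clouds).
#' @export
write_plan <- function(fit, path) {
  stopifnot(inherits(fit, "reduction_fit"))
  jsonlite::write_json(
    list(matrix = unclass(fit$transform),
         rms = fit$registration$rms,
         iterations = fit$registration$iterations,
         converged = fit$registration$converged,
         rms_threshold = fit$rms_threshold,
         reduced = fit$reduced),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(transform = rigid_transform(raw$matrix),
                 registration = list(rms = raw$rms,
                                     iterations = raw$iterations,
                                     converged = raw$converged),
                 residuals = NULL, dislocated = NULL, planned = NULL,
                 rms_threshold = raw$rms_threshold,
                 reduced = isTRUE(raw$reduced)),
            class = "reduction_fit")
}
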