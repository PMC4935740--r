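#' Plain-text point, landmark and transform files
#'
#' Point files are tab-separated text with a header `name<TAB>x<TAB>y<TAB>z`
#' (mm). Landmark files pair a source and a target position per row:
#' `name xs ys zs xt yt zt`. Transform files are 4 rows of 4
#' whitespace-separated numbers; they are validated for rigidity on read and
#' written with 17 significant digits so a round trip is bit-exact.
#' Malformed rows are rejected with the offending line number — readers
#' never silently coerce.
#'
#' @param path File path.
#' @return `read_points()`: a named point matrix; `read_landmarks()`: a list
#'   with `source` and `target` point matrices; `read_transform()`: a
#'   [rigid_transform()].
#' @export
read_points <- function(path) {
  df <- read_checked_table(path, c("name", "x", "y", "z"))
  pts <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pts) <- list(df$name, NULL)
  as_points(pts)
}

#' @rdname read_points
#' @param pts A point set.
#' @export
write_points <- function(pts, path) {
  pts <- as_points(pts)
  df <- data.frame(name = rownames(pts) %||% sprintf("p%d", seq_len(nrow(pts))),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_points
#' @export
read_landmarks <- function(path) {
  df <- read_checked_table(path, c("name", "xs", "ys", "zs", "xt", "yt", "zt"))
  src <- as.matrix(df[, c("xs", "ys", "zs")])
  tgt <- as.matrix(df[, c("xt", "yt", "zt")])
  dimnames(src) <- dimnames(tgt) <- list(df$name, NULL)
  list(source = as_points(src), target = as_points(tgt))
}

#' @rdname read_points
#' @param source,target Paired point sets (equal row counts).
#' @export
write_landmarks <- function(source, target, path) {
  source <- as_points(source); target <- as_points(target)
  if (nrow(source) != nrow(target))
    stop("source and target landmark counts differ", call. = FALSE)
  df <- data.frame(name = rownames(source) %||% sprintf("lm%d", seq_len(nrow(source))),
                   xs = source[, 1], ys = source[, 2], zs = source[, 3],
                   xt = target[, 1], yt = target[, 2], zt = target[, 3])
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_points
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4)
    stop(sprintf("%s: a transform file must have 4 rows, found %d",
                 path, length(lines)), call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 4 || anyNA(v))
      stop(sprintf("%s: line %d is not 4 numbers", path, i), call. = FALSE)
    v
  })
  rigid_transform(do.call(rbind, rows))
}

#' @rdname read_points
#' @param t A `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  t <- as_rigid_transform(t)
  writeLines(apply(unclass(t), 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' Drilling-deviation tables
#'
#' A deviation table records one drilling error (mm, the distance between a
#' drilled-and-registered screw hole and its planned position) per
#' `(fracture site, hole)` pair, as tab-separated text with columns
#' `site`, `hole`, `deviation_mm`.
#'
#' @param path File path.
#' @return A data frame of class `deviation_table`.
#' @seealso [summary.deviation_table()]
#' @export
read_deviation_table <- function(path) {
  df <- read_checked_table(path, c("site", "hole", "deviation_mm"),
                           character_cols = "site")
  deviation_table(df$site, df$hole, df$deviation_mm)
}

#' @rdname read_deviation_table
#' @param tab A `deviation_table`.
#' @export
write_deviation_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-case reduction-error table
#'
#' Tab-separated text with columns `site`, `displacement_mm`, `rot_x_deg`,
#' `rot_y_deg`, `rot_z_deg`: one row per reduction, holding the
#' geometric-centre displacement and the signed per-axis rotation of the
#' achieved zygoma relative to the plan.
#'
#' @param path File path.
#' @return A data frame.
#' @seealso [summarize_error_reports()]
#' @export
read_error_table <- function(path) {
  read_checked_table(path, c("site", "displacement_mm", "rot_x_deg",
                             "rot_y_deg", "rot_z_deg"),
                     character_cols = "site")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_checked_table <- function(path, columns, character_cols = "name") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  df <- df[, columns, drop = FALSE]
  for (col in setdiff(columns, character_cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) == 0) bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("%s: line %d: column '%s' is not numeric ('%s')",
                   path, bad[1] + 1L, col, df[[col]][bad[1]]), call. = FALSE)
    df[[col]] <- v
  }
  df
}
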