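#' Read a triangle mesh from an STL file
#'
#' Supports both the binary and the ASCII STL dialect, auto-detected: a file
#' is binary when its size matches `84 + 50 * facet_count` for the count
#' stored in its header (the leading `"solid"` keyword alone is not
#' trustworthy — many binary exporters write it too). STL stores three
#' independent vertices per facet, so coincident vertices are merged on read
#' with a tolerance of `1e-6` mm to recover shared mesh topology.
#'
#' @param path Path to an `.stl` file.
#' @param merge_tol Vertex-merge tolerance in mm.
#' @return A [tri_mesh()] (without region labels; see [read_labels()]).
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  size <- file.size(path)
  if (size < 15) stop(sprintf("%s: too short to be an STL file", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  is_binary <- FALSE
  if (size >= 84) {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && size == 84 + 50 * as.numeric(n)) is_binary <- TRUE
  }
  if (is_binary) {
    if (n == 0) stop(sprintf("%s: binary STL with zero facets", path), call. = FALSE)
    rec <- readBin(con, "raw", 50 * as.numeric(n))
    if (length(rec) < 50 * n)
      stop(sprintf("%s: truncated binary STL (expected %d facets)", path, n),
           call. = FALSE)
    rec <- matrix(rec, nrow = 50)
    vals <- readBin(as.vector(rec[1:48, ]), "double", size = 4, n = 12 * n,
                    endian = "little")
    vals <- matrix(vals, ncol = 12, byrow = TRUE)    # nx ny nz v1 v2 v3
    tris <- vals[, 4:12, drop = FALSE]
  } else {
    txt <- readLines(path, warn = FALSE)
    if (!length(txt) || !grepl("^\\s*solid", txt[1]))
      stop(sprintf("%s: not an STL file (no binary facet record, no 'solid' keyword)",
                   path), call. = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0)
      stop(sprintf("%s: ASCII STL with malformed vertex count (%d vertex lines)",
                   path, length(vlines)), call. = FALSE)
    coords <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(v)) stop(sprintf("%s: unparseable vertex line", path), call. = FALSE)
      v
    }, numeric(3)))
    tris <- matrix(t(coords), ncol = 9, byrow = TRUE)
  }
  soup_to_mesh(tris, merge_tol)
}

# tris: one row per facet, 9 columns (v1 v2 v3). Merge near-duplicate vertices.
soup_to_mesh <- function(tris, merge_tol) {
  nfaces <- nrow(tris)
  verts <- rbind(tris[, 1:3, drop = FALSE],
                 tris[, 4:6, drop = FALSE],
                 tris[, 7:9, drop = FALSE])
  key <- paste(round(verts[, 1] / merge_tol),
               round(verts[, 2] / merge_tol),
               round(verts[, 3] / merge_tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  mesh_verts <- verts[first, , drop = FALSE]
  faces <- cbind(idx[seq_len(nfaces)],
                 idx[nfaces + seq_len(nfaces)],
                 idx[2 * nfaces + seq_len(nfaces)])
  tri_mesh(mesh_verts, faces)
}

#' Write a triangle mesh to an STL file
#'
#' Facet normals are recomputed from the vertex winding. Binary STL stores
#' coordinates as little-endian float32 (so a round trip quantises to
#' roughly 7 significant digits); ASCII uses 9 significant digits.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @param name Solid name written into the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii"), name = "mesh") {
  stopifnot(inherits(mesh, "tri_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", substr(name, 1, 79)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    vals <- t(cbind(nrm, p1, p2, p3))          # 12 floats per facet, facet-major
    fl <- writeBin(as.vector(vals), raw(), size = 4, endian = "little")
    fl <- matrix(fl, nrow = 48)
    rec <- rbind(fl, matrix(as.raw(0), nrow = 2, ncol = nrow(f)))
    writeBin(as.vector(rec), con)
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c(sprintf("solid %s", name),
               as.vector(rbind(sprintf("  facet normal %s", fmt(nrm)),
                               "    outer loop",
                               sprintf("      vertex %s", fmt(p1)),
                               sprintf("      vertex %s", fmt(p2)),
                               sprintf("      vertex %s", fmt(p3)),
                               "    endloop",
                               "  endfacet")),
               sprintf("endsolid %s", name))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Region-label sidecar files
#'
#' STL has no region field, so face labels travel in a JSON sidecar mapping
#' region names to 1-based face-index ranges, e.g.
#' `{"fixed": [[1, 4000]], "zygoma": [[4001, 4400]]}`. `read_labels()`
#' attaches the labels to a mesh (ranges must cover every face exactly
#' once); `write_labels()` run-length-encodes a mesh's labels.
#'
#' @param mesh A `tri_mesh`.
#' @param path Path to the JSON sidecar.
#' @return `read_labels()`: the mesh with `face_labels` set.
#' @export
read_labels <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- rep(NA_character_, nrow(mesh$faces))
  for (region in names(spec)) {
    ranges <- spec[[region]]
    if (is.null(dim(ranges))) ranges <- matrix(unlist(ranges), ncol = 2, byrow = TRUE)
    for (i in seq_len(nrow(ranges))) {
      from <- ranges[i, 1]; to <- ranges[i, 2]
      if (from < 1 || to > nrow(mesh$faces) || from > to)
        stop(sprintf("label range [%g, %g] for region '%s' out of face range",
                     from, to, region), call. = FALSE)
      if (any(!is.na(labels[from:to])))
        stop(sprintf("label ranges overlap at region '%s'", region), call. = FALSE)
      labels[from:to] <- region
    }
  }
  if (anyNA(labels))
    stop(sprintf("label file leaves %d faces unlabelled", sum(is.na(labels))),
         call. = FALSE)
  mesh$face_labels <- labels
  mesh
}

#' @rdname read_labels
#' @export
write_labels <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (is.null(mesh$face_labels))
    stop("mesh has no face labels to write", call. = FALSE)
  rl <- rle(mesh$face_labels)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  out <- lapply(split(seq_along(rl$values), rl$values), function(i)
    lapply(i, function(j) c(starts[j], ends[j])))
  jsonlite::write_json(out, path, auto_unbox = FALSE)
  invisible(path)
}
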