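#' Labelled triangle meshes
#'
#' A `tri_mesh` holds vertices (N x 3, mm), faces (M x 3 vertex indices,
#' 1-based) and optionally one region label per face (e.g. `"fixed"` and
#' `"zygoma"` for a skull with a fracture fragment). Labels, when present,
#' must cover every face.
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates in mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param face_labels Optional character vector, one region name per face.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, face_labels = NULL) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3)
    stop("faces must have 3 vertex indices per row", call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of vertex range", call. = FALSE)
  if (!is.null(face_labels)) {
    face_labels <- as.character(face_labels)
    if (length(face_labels) != nrow(faces))
      stop("face_labels must name a region for every face", call. = FALSE)
    if (anyNA(face_labels))
      stop("face_labels may not contain NA", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, face_labels = face_labels),
            class = "tri_mesh")
}

mesh_region_faces <- function(mesh, region = NULL) {
  if (is.null(region)) return(seq_len(nrow(mesh$faces)))
  if (is.null(mesh$face_labels))
    stop("mesh carries no region labels", call. = FALSE)
  idx <- which(mesh$face_labels %in% region)
  if (length(idx) == 0)
    stop(sprintf("no faces labelled '%s' in mesh", paste(region, collapse = ", ")),
         call. = FALSE)
  idx
}

#' Extract the vertices of a labelled mesh region
#'
#' Returns the unique vertices used by the faces of one region, as a point
#' set — the point-cloud form consumed by the registration routines.
#'
#' @param mesh A `tri_mesh`.
#' @param region Region label (or `NULL` for the whole mesh).
#' @return An N x 3 point matrix.
#' @export
mesh_region_vertices <- function(mesh, region = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces[mesh_region_faces(mesh, region), , drop = FALSE]
  mesh$vertices[sort(unique(as.vector(f))), , drop = FALSE]
}

#' Rigidly transform a mesh region
#'
#' Applies a rigid transform to the vertices of one region (or the whole
#' mesh), leaving all other vertices untouched. Used by the phantom
#' generator to dislocate the zygoma fragment.
#'
#' @param mesh A `tri_mesh`.
#' @param t A `rigid_transform`.
#' @param region Region label, or `NULL` for all vertices.
#' @return The transformed `tri_mesh`.
#' @export
mesh_transform <- function(mesh, t, region = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  idx <- if (is.null(region)) seq_len(nrow(mesh$vertices)) else {
    f <- mesh$faces[mesh_region_faces(mesh, region), , drop = FALSE]
    sort(unique(as.vector(f)))
  }
  mesh$vertices[idx, ] <- rt_apply(t, mesh$vertices[idx, , drop = FALSE])
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$face_labels)) {
    tab <- table(x$face_labels)
    cat(sprintf("; regions: %s",
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
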