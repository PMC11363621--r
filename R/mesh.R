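#' Triangulated surface mesh
#'
#' A `surface_mesh` is the geometric substrate of the pipeline: an `n x 3`
#' numeric matrix of vertex coordinates in millimetres and an `m x 3` integer
#' matrix of 1-based vertex indices with consistent winding. The constructor
#' enforces the type invariants (valid indices, no zero-area faces, at least
#' 4 vertices and 4 faces, positive bounding-box diagonal); use
#' [validate_mesh()] for a non-throwing report.
#'
#' @param vertices `n x 3` numeric matrix (mm). Units are always mm; no unit
#'   metadata is read from files (STL carries none).
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @examples
#' m <- surface_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
#' )
#' mesh_area(m)
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  rep <- validate_mesh(m)
  bad <- rep$check[!rep$pass & rep$invariant]
  if (length(bad) > 0) {
    stop("invalid surface_mesh; failed invariant check(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<surface_mesh: %d vertices, %d faces, bbox diag %.2f mm>\n",
              nrow(x$vertices), nrow(x$faces),
              norm3(bb[2, ] - bb[1, ])))
  invisible(x)
}

#' Validate a surface mesh
#'
#' Runs the named integrity checks on a mesh (or a raw
#' `list(vertices=, faces=)`) and reports each as pass/fail without ever
#' raising. A report in which every `invariant` row passes implies the
#' `surface_mesh` type invariants hold. The duplicate-vertex check is
#' informational (duplicates are legal, merged on file load).
#'
#' @param mesh A `surface_mesh` or a list with `vertices` and `faces`.
#' @param duplicate_tol Distance (mm) under which two vertices count as
#'   duplicates. Default `1e-6`.
#' @return A tibble with columns `check`, `pass`, `invariant`, `detail`.
#' @examples
#' m <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'           faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
#' validate_mesh(m)
#' @export
validate_mesh <- function(mesh, duplicate_tol = 1e-6) {
  v <- as.matrix(mesh$vertices)
  f <- as.matrix(mesh$faces)
  nv <- nrow(v)
  nf <- nrow(f)

  checks <- list()
  add <- function(check, pass, invariant, detail) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, pass = pass, invariant = invariant, detail = detail)
  }

  shape_ok <- is.numeric(v) && ncol(v) == 3 && all(is.finite(v)) &&
    ncol(f) == 3 && nf > 0 && nv > 0
  add("shape", shape_ok, TRUE,
      sprintf("%d vertices x %d cols, %d faces", nv, ncol(v), nf))

  idx_ok <- shape_ok && all(f >= 1) && all(f <= nv)
  add("face_indices", idx_ok, TRUE,
      if (idx_ok) "all face indices in range" else "face index out of range")

  if (idx_ok) {
    ar <- face_areas(v, f)
    n_degenerate <- sum(ar < 1e-10)
    add("degenerate_faces", n_degenerate == 0, TRUE,
        sprintf("%d zero-area face(s)", n_degenerate))
  } else {
    add("degenerate_faces", FALSE, TRUE, "not evaluated (bad indices)")
  }

  add("min_counts", nv >= 4 && nf >= 4, TRUE,
      sprintf("need >= 4 vertices and faces, have %d / %d", nv, nf))

  if (shape_ok) {
    diag <- norm3(apply(v, 2, max) - apply(v, 2, min))
    add("bounding_box", diag > 0, TRUE, sprintf("diagonal %.6g mm", diag))
    key <- vertex_keys(v, duplicate_tol)
    ndup <- nv - length(unique(key))
    add("duplicate_vertices", ndup == 0, FALSE,
        sprintf("%d duplicate vertex/vertices within %g mm", ndup,
                duplicate_tol))
  } else {
    add("bounding_box", FALSE, TRUE, "not evaluated")
    add("duplicate_vertices", FALSE, FALSE, "not evaluated")
  }

  dplyr::bind_rows(checks)
}

# grid keys used for duplicate detection/merging
vertex_keys <- function(v, tol) {
  g <- round(v / tol)
  paste(g[, 1], g[, 2], g[, 3])
}

face_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh summary helpers
#'
#' `mesh_area()` returns the total surface area (mm^2), `mesh_centroid()` the
#' mean vertex position (mm), and `mesh_bbox()` a 2 x 3 matrix of axis-aligned
#' bounding-box corners (min row, max row).
#'
#' @param mesh A `surface_mesh`.
#' @return See description.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' @rdname mesh_area
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' @rdname mesh_area
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

# merge duplicate vertices within tol (mm) and drop degenerate faces;
# used on file load so connectivity-based operations see a welded mesh
weld_mesh <- function(vertices, faces, tol = 1e-6) {
  key <- vertex_keys(vertices, tol)
  first <- !duplicated(key)
  map <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  # drop collapsed and zero-area faces
  ok <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  faces <- faces[ok, , drop = FALSE]
  if (nrow(faces) > 0) {
    faces <- faces[face_areas(vertices, faces) >= 1e-10, , drop = FALSE]
  }
  list(vertices = vertices, faces = faces)
}
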