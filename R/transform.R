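#' Rigid transforms and reflection planes
#'
#' `rigid_transform()` builds a proper rigid-body transform (rotation
#' `R` with `det(R) = +1`, translation in mm); `reflection_plane()` a plane
#' given by a point and unit normal. `apply_transform()` maps points, meshes
#' or landmark sets; `compose_transforms(a, b)` is "apply `b`, then `a`";
#' `invert_transform()` the inverse. `transform_to_matrix4()` /
#' `matrix4_to_transform()` convert to and from the 4 x 4 homogeneous form
#' used for JSON serialization.
#'
#' @param rotation 3 x 3 orthonormal matrix, determinant +1.
#' @param translation Numeric length-3 (mm).
#' @return `rigid_transform()` returns a `rigid_transform` object.
#' @examples
#' tf <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(tf, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) >= 1e-9) {
    stop("rotation must be a 3x3 orthonormal matrix", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("rotation must be proper (det +1); reflections go through ",
         "mirror_mesh()", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = vec3(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation %.3f mm>\n",
              ang * 180 / pi, norm3(x$translation)))
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' @rdname rigid_transform
#' @param point A point on the plane (mm).
#' @param normal Plane normal; normalized internally.
#' @export
reflection_plane <- function(point, normal) {
  structure(list(point = vec3(point, "plane point"),
                 normal = unit3(normal, "plane normal")),
            class = "reflection_plane")
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @param x Numeric length-3 point, `n x 3` matrix, `surface_mesh`, or
#'   `landmark_set`.
#' @export
apply_transform <- function(tf, x) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "surface_mesh")) {
    x$vertices <- transform_points(tf, x$vertices)
    return(x)
  }
  if (inherits(x, "landmark_set")) {
    x$olecranon_tip <- drop(transform_points(tf, rbind(x$olecranon_tip)))
    x$dome_tip <- drop(transform_points(tf, rbind(x$dome_tip)))
    return(x)
  }
  if (is.matrix(x)) return(transform_points(tf, x))
  drop(transform_points(tf, rbind(vec3(x))))
}

transform_points <- function(tf, pts) {
  sweep(pts %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' @rdname rigid_transform
#' @param a,b `rigid_transform`s; the composition applies `b` first.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), drop(-t(tf$rotation) %*% tf$translation))
}

#' @rdname rigid_transform
#' @export
transform_to_matrix4 <- function(tf) {
  rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
}

#' @rdname rigid_transform
#' @param m4 4 x 4 homogeneous matrix.
#' @export
matrix4_to_transform <- function(m4) {
  m4 <- as.matrix(m4)
  stopifnot(all(dim(m4) == c(4, 4)))
  rigid_transform(m4[1:3, 1:3], m4[1:3, 4])
}

# rotation taking unit vector u onto unit vector v (Rodrigues); for
# antiparallel inputs, a 180 degree turn about an arbitrary perpendicular
rotation_between <- function(u, v) {
  u <- unit3(u); v <- unit3(v)
  c_ <- sum(u * v)
  ax <- cross3(u, v)
  s <- norm3(ax)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit3(cross3(u, p))
    return(rotation_axis_angle(ax, pi))
  }
  rotation_axis_angle(ax / s, atan2(s, c_))
}

rotation_axis_angle <- function(axis, theta) {
  axis <- unit3(axis)
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex across the plane and reverses face winding so the
#' outward surface orientation is preserved. Reflection is an isometry:
#' surface area and all pairwise vertex distances are unchanged. This is the
#' "the left ulna was mirrored" step of the measurement workflow; the choice
#' of plane is irrelevant up to the rigid registration that follows.
#'
#' @param mesh A [surface_mesh()].
#' @param plane A [reflection_plane()]; default is the y-z plane through the
#'   mesh centroid.
#' @return The mirrored `surface_mesh`.
#' @export
mirror_mesh <- function(mesh, plane = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  plane <- plane %||% reflection_plane(mesh_centroid(mesh), c(1, 0, 0))
  mesh$vertices <- reflect_points(mesh$vertices, plane)
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' @rdname mirror_mesh
#' @param landmarks A `landmark_set` to reflect with the same plane.
#' @export
mirror_landmarks <- function(landmarks, plane) {
  landmarks$olecranon_tip <- drop(reflect_points(rbind(landmarks$olecranon_tip),
                                                 plane))
  landmarks$dome_tip <- drop(reflect_points(rbind(landmarks$dome_tip), plane))
  landmarks
}

reflect_points <- function(pts, plane) {
  d <- (pts - matrix(plane$point, nrow(pts), 3, byrow = TRUE)) %*% plane$normal
  pts - 2 * drop(d) %o% plane$normal
}
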