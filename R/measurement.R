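#' Detect olecranon and dome tips on an elongated bone mesh
#'
#' The two landmarks are found as the extremal surface points along the
#' mesh's first principal axis, each refined to the vertex farthest from
#' the mesh centroid within its end cap. The olecranon end is
#' disambiguated by end girth: the maximal perpendicular distance from the
#' principal axis within each end region (the olecranon is wider than the
#' dome). The automatic end assignment can be overridden with `swap_ends`,
#' and the whole detection can be bypassed by passing ground-truth or
#' manually picked landmarks to downstream functions.
#'
#' @param mesh A [surface_mesh()] with elongated geometry (longest
#'   principal extent at least 3x the next); anything less elongated is a
#'   degenerate-geometry error.
#' @param cap_fraction Fraction of the axial extent treated as the end cap
#'   when refining each tip, default 0.08.
#' @param girth_fraction Fraction of the axial extent used to measure end
#'   girth, default 0.15.
#' @param swap_ends Set TRUE to override the girth-based olecranon/dome
#'   assignment.
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(mesh, cap_fraction = 0.08,
                             girth_fraction = 0.15, swap_ends = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  pc <- svd(crossprod(vc) / nrow(vc))
  e <- pc$u
  scores <- vc %*% e
  extents <- apply(scores, 2, function(s) diff(range(s)))
  if (extents[1] < 3 * extents[2]) {
    stop("degenerate geometry: mesh is not elongated (extent ratio ",
         sprintf("%.2f", extents[1] / extents[2]), " < 3)", call. = FALSE)
  }
  t1 <- scores[, 1]
  rng <- range(t1)
  span <- diff(rng)

  tip_at <- function(end_min) {
    cap <- if (end_min) t1 <= rng[1] + cap_fraction * span
           else t1 >= rng[2] - cap_fraction * span
    cand <- v[cap, , drop = FALSE]
    cand[which.max(rowSums(sweep(cand, 2, ctr)^2)), ]
  }
  girth_at <- function(end_min) {
    reg <- if (end_min) t1 <= rng[1] + girth_fraction * span
           else t1 >= rng[2] - girth_fraction * span
    perp <- vc[reg, , drop = FALSE] - scores[reg, 1, drop = FALSE] %*% t(e[, 1])
    max(sqrt(rowSums(perp^2)))
  }

  tip_min <- tip_at(TRUE)
  tip_max <- tip_at(FALSE)
  olecranon_at_min <- girth_at(TRUE) >= girth_at(FALSE)
  if (swap_ends) olecranon_at_min <- !olecranon_at_min
  if (olecranon_at_min) {
    landmark_set(tip_min, tip_max)
  } else {
    landmark_set(tip_max, tip_min)
  }
}

#' Pick the longer of two ulnae
#'
#' Returns `"a"` or `"b"` according to whose olecranon-tip-to-dome-tip
#' chord is longer; ties within 1e-9 mm return `"a"` (documented
#' tie-break). The longer ulna defines the standardized measurement axis.
#'
#' @param mesh_a,mesh_b [surface_mesh()] objects (unused beyond validation;
#'   the decision is landmark-based).
#' @param lm_a,lm_b Their [landmark_set()]s.
#' @return `"a"` or `"b"`.
#' @export
select_longer <- function(mesh_a, lm_a, mesh_b, lm_b) {
  la <- landmark_length(lm_a)
  lb <- landmark_length(lm_b)
  if (lb > la + 1e-9) "b" else "a"
}

#' Cut the bone halfway between the landmarks
#'
#' The cut plane passes through the midpoint of the olecranon-tip to
#' dome-tip chord, with normal parallel to the chord. The returned
#' cross-section is the intersection contour of mesh and plane; if the
#' plane produces several contours the one with the largest perimeter is
#' kept. Works on open (non-watertight) meshes, in which case the contour
#' may be an open polyline.
#'
#' @param mesh A [surface_mesh()].
#' @param lm Its [landmark_set()].
#' @return A `cross_section`: list with `points` (ordered contour points,
#'   mm), `plane` (a [reflection_plane()]-shaped cut plane), `closed`,
#'   `perimeter`.
#' @export
cut_halfway <- function(mesh, lm) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mid <- (lm$olecranon_tip + lm$dome_tip) / 2
  normal <- landmark_chord(lm)
  cross_section_at(mesh, reflection_plane(mid, normal))
}

#' @rdname cut_halfway
#' @param plane A [reflection_plane()] used as the cut plane.
#' @export
cross_section_at <- function(mesh, plane) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- drop(sweep(v, 2, plane$point) %*% plane$normal)
  # nudge exactly-on-plane vertices so every crossing is a clean sign change
  d[abs(d) < 1e-12] <- 1e-12

  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) {
    stop("empty section: cut plane does not intersect the mesh",
         call. = FALSE)
  }
  fc <- f[crossing, , drop = FALSE]

  seg_a <- matrix(NA_real_, nrow(fc), 3)
  seg_b <- matrix(NA_real_, nrow(fc), 3)
  edge_point <- function(i, j) {
    di <- d[i]; dj <- d[j]
    t <- di / (di - dj)
    v[i, , drop = FALSE] + t * (v[j, , drop = FALSE] - v[i, , drop = FALSE])
  }
  for (r in seq_len(nrow(fc))) {
    tri <- fc[r, ]
    dd <- d[tri]
    # the odd-signed vertex is alone on its side; its two edges cross
    pos <- dd > 0
    alone <- if (sum(pos) == 1) which(pos) else which(!pos)
    others <- setdiff(1:3, alone)
    seg_a[r, ] <- edge_point(tri[alone], tri[others[1]])
    seg_b[r, ] <- edge_point(tri[alone], tri[others[2]])
  }

  contours <- chain_segments(seg_a, seg_b)
  perims <- vapply(contours, function(ct) {
    pts <- ct$points
    e <- if (ct$closed) rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) -
      pts else pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
    sum(sqrt(rowSums(e^2)))
  }, numeric(1))
  best <- contours[[which.max(perims)]]

  structure(list(points = best$points, plane = plane, closed = best$closed,
                 perimeter = max(perims)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section: %d points, perimeter %.2f mm, %s>\n",
              nrow(x$points), x$perimeter,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# chain unordered segments (rows of a/b) into ordered polylines by matching
# endpoints on a 1e-7 mm grid
chain_segments <- function(a, b) {
  key <- function(m) vertex_keys(m, 1e-7)
  ka <- key(a); kb <- key(b)
  all_keys <- unique(c(ka, kb))
  ia <- match(ka, all_keys); ib <- match(kb, all_keys)
  pts <- matrix(NA_real_, length(all_keys), 3)
  pts[ia, ] <- a; pts[ib, ] <- b
  nseg <- length(ia)
  adj <- vector("list", length(all_keys))
  for (s in seq_len(nseg)) {
    adj[[ia[s]]] <- c(adj[[ia[s]]], s)
    adj[[ib[s]]] <- c(adj[[ib[s]]], s)
  }
  used <- rep(FALSE, nseg)
  contours <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    # walk forward from one endpoint
    walk <- function(start_node, start_seg) {
      nodes <- start_node
      seg <- start_seg
      node <- start_node
      repeat {
        used[seg] <<- TRUE
        node <- if (ia[seg] == node) ib[seg] else ia[seg]
        nodes <- c(nodes, node)
        nxt <- setdiff(adj[[node]][!used[adj[[node]]]], seg)
        if (length(nxt) == 0) break
        seg <- nxt[1]
      }
      nodes
    }
    nodes <- walk(ia[s0], s0)
    closed <- nodes[1] == nodes[length(nodes)]
    if (closed) {
      nodes <- nodes[-length(nodes)]
    } else {
      # extend from the other end for open chains
      first_seg_dup <- FALSE
      rest <- adj[[nodes[1]]][!used[adj[[nodes[1]]]]]
      if (length(rest) > 0) {
        more <- walk(nodes[1], rest[1])
        nodes <- c(rev(more[-1]), nodes)
      }
    }
    contours[[length(contours) + 1]] <-
      list(points = pts[nodes, , drop = FALSE], closed = closed)
  }
  contours
}

#' Least-squares circle fit to a cross-section contour
#'
#' Fits a circle to the contour points within the cut plane: points are
#' projected into the plane's 2D frame, an algebraic (Kasa) fit gives the
#' starting values, and a Gauss-Newton geometric refinement minimizes the
#' sum of squared radial residuals. This is the "arc fit" that defines the
#' centre of the halfway cut; open (partial-arc) contours are fit the same
#' way.
#'
#' @param section A `cross_section` from [cut_halfway()], or any list with
#'   `points` (n x 3, n >= 3 non-collinear) and `plane`.
#' @return A `circle_fit`: list with `center` (3D, mm), `radius` (mm),
#'   `rms_residual` (mm RMS radial misfit), `n_points`.
#' @export
fit_circle <- function(section) {
  pts <- section$points
  plane <- section$plane
  if (is.null(pts) || nrow(pts) < 3) {
    stop("degenerate fit: need at least 3 contour points", call. = FALSE)
  }
  # orthonormal in-plane frame
  n <- unit3(plane$normal)
  u <- if (abs(n[1]) < 0.9) unit3(cross3(n, c(1, 0, 0))) else
    unit3(cross3(n, c(0, 1, 0)))
  w <- cross3(n, u)
  o <- colMeans(pts)
  rel <- sweep(pts, 2, o)
  x <- drop(rel %*% u)
  y <- drop(rel %*% w)

  # collinearity: residual of best-fit line through the 2D points
  M <- cbind(x - mean(x), y - mean(y))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    stop("degenerate fit: contour points are collinear", call. = FALSE)
  }

  # Kasa algebraic fit: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  a <- sol[1]; b <- sol[2]
  r <- sqrt(max(sol[3] + a^2 + b^2, 1e-30))

  # Gauss-Newton on (a, b, r)
  for (it in 1:50) {
    dx <- x - a; dy <- y - b
    di <- sqrt(dx^2 + dy^2)
    di[di < 1e-12] <- 1e-12
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  dx <- x - a; dy <- y - b
  rms <- sqrt(mean((sqrt(dx^2 + dy^2) - r)^2))

  center <- o + a * u + b * w
  # put the centre exactly on the cut plane
  center <- center - sum((center - plane$point) * n) * n
  structure(list(center = center, radius = r, rms_residual = rms,
                 n_points = length(x)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit: radius %.3f mm, RMS residual %.4g mm (n=%d)>\n",
              x$radius, x$rms_residual, x$n_points))
  invisible(x)
}

#' The standardized length axis
#'
#' The measurement axis runs from the fitted circle centre of the halfway
#' cut (its origin) toward the dome tip of the longer ulna; the direction
#' is the unit vector from centre to dome tip, i.e. proximal to distal.
#'
#' @param arc_center Fitted circle centre (3D, mm).
#' @param dome_tip Dome tip of the longer ulna (3D, mm).
#' @return A `length_axis`: list with `origin` and unit `direction`.
#' @export
build_axis <- function(arc_center, dome_tip) {
  arc_center <- vec3(arc_center, "arc_center")
  dome_tip <- vec3(dome_tip, "dome_tip")
  d <- dome_tip - arc_center
  if (norm3(d) < 1e-9) {
    stop("degenerate geometry: arc centre and dome tip coincide",
         call. = FALSE)
  }
  structure(list(origin = arc_center, direction = d / norm3(d)),
            class = "length_axis")
}

#' @export
print.length_axis <- function(x, ...) {
  cat(sprintf(paste0("<length_axis: origin (%.2f, %.2f, %.2f), direction ",
                     "(%.3f, %.3f, %.3f)>\n"),
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Project a point onto the length axis
#'
#' Returns the signed coordinate `(point - origin) . direction` (mm).
#' Pure and linear in the point; perpendicular offsets do not change it.
#'
#' @param point 3D point (mm) or `n x 3` matrix.
#' @param axis A `length_axis`.
#' @return Scalar (or vector) projection in mm.
#' @export
project_on_axis <- function(point, axis) {
  stopifnot(inherits(axis, "length_axis"))
  if (is.matrix(point)) {
    drop(sweep(point, 2, axis$origin) %*% axis$direction)
  } else {
    sum((vec3(point) - axis$origin) * axis$direction)
  }
}

#' Signed dome-height difference along the axis
#'
#' The bilateral length difference is the difference between the axis
#' projections of the two dome tips in the common registered frame, with
#' the convention right minus left (positive = right longer).
#'
#' @param dome_long,dome_short Dome tips (3D, mm) of the longer and
#'   shorter bone in the common frame.
#' @param axis The `length_axis` built on the longer bone.
#' @param long_is_right TRUE if the longer bone is the right one.
#' @return Signed difference in mm (right minus left).
#' @export
measure_length_difference <- function(dome_long, dome_short, axis,
                                      long_is_right) {
  pl <- project_on_axis(dome_long, axis)
  ps <- project_on_axis(dome_short, axis)
  if (isTRUE(long_is_right)) pl - ps else ps - pl
}

#' Full ulnar length along the axis
#'
#' The projected olecranon-tip-to-dome-tip length of the (longer) ulna on
#' the standardized axis; the denominator of the relative difference.
#'
#' @param lm [landmark_set()] of the longer ulna (common frame).
#' @param axis Its `length_axis`.
#' @return Length in mm (positive by axis orientation).
#' @export
full_ulna_length <- function(lm, axis) {
  project_on_axis(lm$dome_tip, axis) - project_on_axis(lm$olecranon_tip, axis)
}
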