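#' Landmark set: olecranon tip and ulnar dome tip
#'
#' The two anatomical anchors of the length measurement: the tip of the
#' olecranon (proximal) and the tip of the ulnar dome (distal). Their chord
#' approximates the total bone length.
#'
#' @param olecranon_tip,dome_tip 3D points (mm).
#' @return A `landmark_set`.
#' @export
landmark_set <- function(olecranon_tip, dome_tip) {
  o <- vec3(olecranon_tip, "olecranon_tip")
  d <- vec3(dome_tip, "dome_tip")
  if (norm3(o - d) < 1e-9) {
    stop("landmark tips must be distinct", call. = FALSE)
  }
  structure(list(olecranon_tip = o, dome_tip = d), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(paste0("<landmark_set: olecranon (%.2f, %.2f, %.2f), dome ",
                     "(%.2f, %.2f, %.2f), chord %.2f mm>\n"),
              x$olecranon_tip[1], x$olecranon_tip[2], x$olecranon_tip[3],
              x$dome_tip[1], x$dome_tip[2], x$dome_tip[3],
              norm3(x$dome_tip - x$olecranon_tip)))
  invisible(x)
}

#' @rdname landmark_set
#' @param lm A `landmark_set`.
#' @export
landmark_length <- function(lm) norm3(lm$dome_tip - lm$olecranon_tip)

#' Parameters of the synthetic ulna generator
#'
#' The synthetic ulna is a parametric lofted tube: circular rings along a
#' bowed centerline, with a proximal spherical bulge (olecranon analogue)
#' and a distal hemispherical cap (ulnar dome analogue), closed by apex
#' vertices at both ends. It is not anatomically faithful; it has exactly
#' the features the measurement pipeline relies on - two detectable
#' extremal landmarks with different end girths and a roughly circular
#' shaft cross-section. Defaults approximate an adult ulna (~260 mm long,
#' ~7 mm shaft radius, wider olecranon than dome).
#'
#' @param total_length Olecranon tip to dome tip distance (mm), default 260.
#' @param shaft_radius Shaft tube radius (mm), default 7.
#' @param shaft_curvature Bow amplitude as a fraction of length, default 0.015 (the ulna is a nearly straight bone with a slight lateral bow).
#' @param olecranon_bulge Extra radius of the proximal bulge over the shaft
#'   (mm), default 6.
#' @param dome_radius Radius of the distal hemispherical cap (mm), default 9.
#' @param side `"right"` or `"left"`; the left bone is the exact mirror image
#'   (x negated) of the right bone generated with the same parameters/seed.
#' @param axial_resolution Number of rings along the bone (>= 8), default 96.
#' @param radial_resolution Points per ring (>= 8), default 28.
#' @param surface_noise_sd SD of radial Gaussian surface noise (mm),
#'   default 0. Apex (landmark) vertices are left noise-free so the
#'   returned landmarks are exact ground truth.
#' @param seed Integer seed for the noise draws; `NULL` uses the ambient RNG.
#' @return An `ulna_params` object.
#' @export
ulna_params <- function(total_length = 260, shaft_radius = 7,
                        shaft_curvature = 0.015, olecranon_bulge = 6,
                        dome_radius = 9, side = c("right", "left"),
                        axial_resolution = 96, radial_resolution = 28,
                        surface_noise_sd = 0, seed = NULL) {
  side <- match.arg(side)
  p <- list(total_length = total_length, shaft_radius = shaft_radius,
            shaft_curvature = shaft_curvature,
            olecranon_bulge = olecranon_bulge, dome_radius = dome_radius,
            side = side, axial_resolution = as.integer(axial_resolution),
            radial_resolution = as.integer(radial_resolution),
            surface_noise_sd = surface_noise_sd, seed = seed)
  validate_ulna_params(p)
  structure(p, class = "ulna_params")
}

validate_ulna_params <- function(p) {
  if (!is.numeric(p$total_length) || p$total_length <= 0) {
    stop("total_length must be > 0", call. = FALSE)
  }
  if (p$shaft_radius <= 0 || p$dome_radius <= 0 || p$olecranon_bulge < 0) {
    stop("radii must be positive (olecranon_bulge >= 0)", call. = FALSE)
  }
  cap <- p$shaft_radius + p$olecranon_bulge + p$dome_radius
  if (p$total_length <= 2 * cap) {
    stop("total_length too short for the end caps (need > ",
         2 * cap, " mm)", call. = FALSE)
  }
  if (p$axial_resolution < 8 || p$radial_resolution < 8) {
    stop("resolutions must be >= 8", call. = FALSE)
  }
  if (p$surface_noise_sd < 0) stop("surface_noise_sd must be >= 0",
                                   call. = FALSE)
  invisible(p)
}

# radius profile along the bone: proximal spherical bulge -> smoothstep
# taper -> cylindrical shaft -> smoothstep rise -> distal hemispherical cap
ulna_profile <- function(z, p) {
  L <- p$total_length
  r_p <- p$shaft_radius + p$olecranon_bulge
  zc1 <- r_p
  z_taper <- min(0.35 * L, zc1 + 4 * r_p)
  zc2 <- L - p$dome_radius
  z_rise <- zc2 - 2 * p$dome_radius
  smoothstep <- function(t) {
    t <- pmin(1, pmax(0, t))
    t * t * (3 - 2 * t)
  }
  rho <- numeric(length(z))
  # proximal cap (sphere of radius r_p centred at z = r_p)
  i <- z <= zc1
  rho[i] <- sqrt(pmax(0, r_p^2 - (r_p - z[i])^2))
  # taper from bulge to shaft
  i <- z > zc1 & z < z_taper
  s <- smoothstep((z_taper - z[i]) / (z_taper - zc1))
  rho[i] <- p$shaft_radius + (r_p - p$shaft_radius) * s
  # shaft
  i <- z >= z_taper & z <= z_rise
  rho[i] <- p$shaft_radius
  # rise from shaft to dome radius
  i <- z > z_rise & z < zc2
  s <- smoothstep((z[i] - z_rise) / (zc2 - z_rise))
  rho[i] <- p$shaft_radius + (p$dome_radius - p$shaft_radius) * s
  # distal hemispherical cap (sphere of radius dome_radius centred at zc2)
  i <- z >= zc2
  rho[i] <- sqrt(pmax(0, p$dome_radius^2 - (z[i] - zc2)^2))
  rho
}

# centerline lateral bow (+x), zero at both apexes so the landmark chord
# has exactly the requested length
ulna_bow <- function(z, p) {
  p$shaft_curvature * p$total_length * sin(pi * z / p$total_length)
}

# ring positions along the bone: rings are concentrated in the curved end
# regions (proximal bulge/taper, distal cap) at fixed absolute offsets
# from the respective apex, with the remainder spread over the shaft;
# bones differing only in length then have identical end geometry
ulna_ring_z <- function(p) {
  L <- p$total_length
  r_p <- p$shaft_radius + p$olecranon_bulge
  z_taper <- min(0.35 * L, 5 * r_p)
  z_dist0 <- L - 3 * p$dome_radius
  nr <- p$axial_resolution
  n_prox <- max(4, round(0.3 * nr))
  n_dist <- max(4, round(0.2 * nr))
  n_mid <- nr - n_prox - n_dist
  zp <- seq(0, z_taper, length.out = n_prox + 1)[-1]
  zd <- seq(z_dist0, L, length.out = n_dist + 1)[-(n_dist + 1)]
  zm <- seq(z_taper, z_dist0, length.out = n_mid + 2)[-c(1, n_mid + 2)]
  sort(c(zp, zm, zd))
}

#' Generate a synthetic ulna with exact landmark ground truth
#'
#' Builds the parametric ulna analogue described in [ulna_params()] and
#' returns it with its exact generator landmarks: the proximal apex
#' (olecranon tip) and the distal apex (dome tip), separated by exactly
#' `total_length` (both apexes lie on the long axis because the bow
#' vanishes at the ends, and neither receives surface noise).
#'
#' @param params An [ulna_params()] object.
#' @return List with elements `mesh` ([surface_mesh()]) and `landmarks`
#'   ([landmark_set()]).
#' @examples
#' u <- generate_ulna(ulna_params(total_length = 260))
#' landmark_length(u$landmarks) # exactly 260
#' @export
generate_ulna <- function(params) {
  stopifnot(inherits(params, "ulna_params"))
  validate_ulna_params(params)
  p <- params
  L <- p$total_length
  nr <- p$axial_resolution
  nc <- p$radial_resolution

  z <- ulna_ring_z(p)
  rho <- ulna_profile(z, p)
  bow <- ulna_bow(z, p)
  ang <- 2 * pi * (seq_len(nc) - 1) / nc

  ca <- cos(ang)
  sa <- sin(ang)
  vx <- as.vector(outer(ca, rho) + matrix(bow, nc, nr, byrow = TRUE))
  vy <- as.vector(outer(sa, rho))
  vz <- as.vector(matrix(z, nc, nr, byrow = TRUE))
  verts <- cbind(vx, vy, vz)

  if (p$surface_noise_sd > 0) {
    noise <- with_seed(p$seed, stats::rnorm(nrow(verts), 0,
                                            p$surface_noise_sd))
    # radial displacement within each ring plane
    dir <- cbind(rep(ca, nr), rep(sa, nr), 0)
    verts <- verts + noise * dir
  }

  apex_prox <- c(0, 0, 0)
  apex_dist <- c(0, 0, L)
  verts <- rbind(verts, apex_prox, apex_dist)
  i_prox <- nrow(verts) - 1L
  i_dist <- nrow(verts)

  ring <- function(i) (i - 1L) * nc + seq_len(nc)  # vertex ids of ring i
  faces <- vector("list", nr + 1)
  # side quads between consecutive rings, CCW seen from outside
  for (i in seq_len(nr - 1)) {
    a <- ring(i)
    b <- ring(i + 1)
    a2 <- c(a[-1], a[1])
    b2 <- c(b[-1], b[1])
    faces[[i]] <- rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }
  # apex fans
  r1 <- ring(1)
  r1n <- c(r1[-1], r1[1])
  faces[[nr]] <- cbind(i_prox, r1n, r1)
  rn <- ring(nr)
  rnn <- c(rn[-1], rn[1])
  faces[[nr + 1]] <- cbind(i_dist, rn, rnn)
  faces <- do.call(rbind, faces)

  if (p$side == "left") {
    verts[, 1] <- -verts[, 1]
    faces <- faces[, c(1, 3, 2), drop = FALSE]
  }
  dimnames(verts) <- NULL
  dimnames(faces) <- NULL

  list(mesh = surface_mesh(verts, faces),
       landmarks = landmark_set(apex_prox, apex_dist))
}

#' Generate a left/right pair with an imposed length difference
#'
#' The requested signed difference (right minus left, mm) is split
#' symmetrically: the right bone gets `total_length + signed_diff/2`, the
#' left `total_length - signed_diff/2`, so the pair's ground-truth length
#' difference equals `signed_diff` exactly while shaft radius and
#' cross-section stay comparable. All non-length shape parameters and the
#' seed are shared; with `signed_diff = 0` the left bone is the exact
#' mirror image of the right.
#'
#' @param base An [ulna_params()] object (its `side` is ignored).
#' @param signed_diff Right-minus-left length difference (mm).
#' @return List with `left` and `right`, each a list of `mesh` and
#'   `landmarks`, plus `signed_diff`.
#' @export
generate_pair <- function(base, signed_diff) {
  stopifnot(inherits(base, "ulna_params"), is.numeric(signed_diff),
            length(signed_diff) == 1, is.finite(signed_diff))
  len_r <- base$total_length + signed_diff / 2
  len_l <- base$total_length - signed_diff / 2
  if (min(len_r, len_l) <= 0) {
    stop("infeasible lengths: |signed_diff| too large for base length",
         call. = FALSE)
  }
  mod <- function(len, side) {
    q <- unclass(base)
    q$total_length <- len
    q$side <- side
    do.call(ulna_params, q)
  }
  list(left = generate_ulna(mod(len_l, "left")),
       right = generate_ulna(mod(len_r, "right")),
       signed_diff = signed_diff)
}
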