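# programmatic fixtures shared across test files

# smallest closed mesh: unit tetrahedron, outward winding
tetra_mesh <- function() {
  surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  )
}

# closed cylinder of radius r, height h along +z, with apex-fan caps
cylinder_mesh <- function(r = 5, h = 40, n_ring = 24, n_axial = 16) {
  z <- seq(0, h, length.out = n_axial)
  ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  verts <- do.call(rbind, lapply(z, function(zz) {
    cbind(r * cos(ang), r * sin(ang), zz)
  }))
  ring <- function(i) (i - 1L) * n_ring + seq_len(n_ring)
  faces <- do.call(rbind, lapply(seq_len(n_axial - 1), function(i) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }))
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, h))
  i_bot <- nrow(verts) - 1L
  i_top <- nrow(verts)
  r1 <- ring(1); rn <- ring(n_axial)
  faces <- rbind(faces,
                 cbind(i_bot, c(r1[-1], r1[1]), r1),
                 cbind(i_top, rn, c(rn[-1], rn[1])))
  surface_mesh(verts, faces)
}

# UV sphere (no elongation -> degenerate for landmark detection)
sphere_mesh <- function(r = 10, n_lat = 12, n_lon = 18) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[-c(1, n_lat + 2)]
  lon <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  verts <- do.call(rbind, lapply(lat, function(la) {
    cbind(r * cos(la) * cos(lon), r * cos(la) * sin(lon), r * sin(la))
  }))
  ring <- function(i) (i - 1L) * n_lon + seq_len(n_lon)
  faces <- do.call(rbind, lapply(seq_len(n_lat - 1), function(i) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }))
  verts <- rbind(verts, c(0, 0, -r), c(0, 0, r))
  i_s <- nrow(verts) - 1L; i_n <- nrow(verts)
  r1 <- ring(1); rn <- ring(n_lat)
  faces <- rbind(faces,
                 cbind(i_s, c(r1[-1], r1[1]), r1),
                 cbind(i_n, rn, c(rn[-1], rn[1])))
  surface_mesh(verts, faces)
}

# low-resolution ulna parameters for fast pipeline tests
small_ulna <- function(...) {
  ulna_params(axial_resolution = 48, radial_resolution = 16, ...)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  ulnadiff:::rotation_axis_angle(ax / sqrt(sum(ax^2)),
                                 stats::runif(1, 0, pi))
}

# vertex sets equal as point clouds (order-independent)
expect_same_point_set <- function(a, b, tol = 1e-6) {
  key <- function(m) {
    g <- round(m / max(tol, 1e-12))
    order(g[, 1], g[, 2], g[, 3])
  }
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a[key(a), ] - b[key(b), ])), tol)
}
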