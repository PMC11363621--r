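test_that("landmarks are detected at the generator tips and ends disambiguated", {
  u <- generate_ulna(small_ulna())
  lm <- detect_landmarks(u$mesh)
  expect_lt(ulnadiff:::norm3(lm$olecranon_tip - u$landmarks$olecranon_tip), 1)
  expect_lt(ulnadiff:::norm3(lm$dome_tip - u$landmarks$dome_tip), 1)

  # frame independence: landmarks transform covariantly
  tf <- rigid_transform(ulnadiff:::rotation_axis_angle(c(1, 2, 0.5), 1.1),
                        c(30, -12, 4))
  lm2 <- detect_landmarks(apply_transform(tf, u$mesh))
  expect_lt(ulnadiff:::norm3(lm2$olecranon_tip -
                               apply_transform(tf, u$landmarks)$olecranon_tip),
            1e-6)
  expect_lt(ulnadiff:::norm3(lm2$dome_tip -
                               apply_transform(tf, u$landmarks)$dome_tip),
            1e-6)

  # override of the girth-based end assignment
  sw <- detect_landmarks(u$mesh, swap_ends = TRUE)
  expect_equal(sw$olecranon_tip, lm$dome_tip)

  expect_error(detect_landmarks(sphere_mesh()), "degenerate geometry")
})

test_that("select_longer picks the longer chord with documented tie-break", {
  u <- generate_ulna(small_ulna())
  lm_a <- landmark_set(c(0, 0, 0), c(0, 0, 261.5))
  lm_b <- landmark_set(c(0, 0, 0), c(0, 0, 258.5))
  expect_equal(select_longer(u$mesh, lm_a, u$mesh, lm_b), "a")
  expect_equal(select_longer(u$mesh, lm_b, u$mesh, lm_a), "b")
  expect_equal(select_longer(u$mesh, lm_a, u$mesh, lm_a), "a")

  p <- generate_pair(small_ulna(), 3)
  expect_equal(select_longer(p$right$mesh, p$right$landmarks,
                             p$left$mesh, p$left$landmarks), "a")
})

test_that("cut_halfway sections at the chord midpoint with shaft-sized contour", {
  prm <- small_ulna()
  u <- generate_ulna(prm)
  sec <- cut_halfway(u$mesh, u$landmarks)
  expect_equal(sec$plane$point, c(0, 0, 130))
  expect_gte(nrow(sec$points), 8)
  # all contour points on the plane
  d <- abs((sec$points - matrix(sec$plane$point, nrow(sec$points), 3,
                                byrow = TRUE)) %*% sec$plane$normal)
  expect_lt(max(d), 1e-6)
  expect_equal(sec$perimeter, 2 * pi * prm$shaft_radius, tolerance = 0.1)

  # analytic cylinder: contour is the circle of the cylinder radius
  cyl <- cylinder_mesh(r = 5, h = 40)
  lm <- landmark_set(c(0, 0, 0), c(0, 0, 40))
  sc <- cut_halfway(cyl, lm)
  expect_equal(sc$plane$point, c(0, 0, 20))
  cf <- fit_circle(sc)
  expect_equal(cf$radius, 5, tolerance = 0.01)
  expect_lt(ulnadiff:::norm3(cf$center - c(0, 0, 20)), 0.01)

  # plane outside the bounding box
  expect_error(cross_section_at(cyl, reflection_plane(c(0, 0, 100),
                                                      c(0, 0, 1))),
               "empty section")
})

test_that("fit_circle is exact on exact data and matches the circumcircle", {
  plane <- reflection_plane(c(0, 0, 0), c(0, 0, 1))
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- cbind(1 + 5 * cos(th), 2 + 5 * sin(th), 0)
  f <- fit_circle(list(points = pts, plane = plane))
  expect_lt(ulnadiff:::norm3(f$center - c(1, 2, 0)), 1e-9)
  expect_equal(f$radius, 5, tolerance = 1e-12)
  expect_lt(f$rms_residual, 1e-9)

  # circumcircle of (0,0), (2,0), (1,1): centre (1,0), radius 1
  tri <- cbind(c(0, 2, 1), c(0, 0, 1), 0)
  f3 <- fit_circle(list(points = tri, plane = plane))
  expect_equal(f3$center, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(f3$radius, 1, tolerance = 1e-9)

  line <- cbind(0:4, 0, 0)
  expect_error(fit_circle(list(points = line, plane = plane)),
               "collinear")
  expect_error(fit_circle(list(points = tri[1:2, ], plane = plane)),
               "at least 3")
})

test_that("fit_circle agrees with a brute-force grid-search fit on noisy contours", {
  # independent oracle: centre over a fine 2D grid, radius = mean distance
  # the grid must be centred where the optimum can lie; with uneven
  # angular coverage the data centroid can sit far from the circle
  # centre, so centre the search window on the simulated truth
  brute_circle <- function(x, y, c0, half_window = 0.5, step = 0.005) {
    cx <- seq(c0[1] - half_window, c0[1] + half_window, by = step)
    cy <- seq(c0[2] - half_window, c0[2] + half_window, by = step)
    best <- c(Inf, NA, NA, NA)
    for (a in cx) for (b in cy) {
      d <- sqrt((x - a)^2 + (y - b)^2)
      r <- mean(d)
      obj <- sum((d - r)^2)
      if (obj < best[1]) best <- c(obj, a, b, r)
    }
    best
  }
  withr::local_seed(31)
  for (rep in 1:3) {
    th <- sort(runif(50, 0, 2 * pi))
    r_true <- 7
    noise <- rnorm(50, 0, 0.1)
    x <- 2 + (r_true + noise) * cos(th)
    y <- -1 + (r_true + noise) * sin(th)
    f <- fit_circle(list(points = cbind(x, y, 0),
                         plane = reflection_plane(c(0, 0, 0), c(0, 0, 1))))
    b <- brute_circle(x, y, c(2, -1))
    expect_lt(ulnadiff:::norm3(f$center[1:2] - b[2:3]), 0.05)
    expect_lt(abs(f$radius - b[4]), 0.05)
  }
})

test_that("fitted centre of the halfway cut lies on the generator centerline", {
  prm <- small_ulna()
  u <- generate_ulna(prm)
  cf <- fit_circle(cut_halfway(u$mesh, u$landmarks))
  truth <- c(ulnadiff:::ulna_bow(130, prm), 0, 130)
  expect_lt(ulnadiff:::norm3(cf$center - truth), 0.1)
})

test_that("the measurement axis obeys its orientation contract", {
  ax <- build_axis(c(0, 0, 0), c(0, 0, 130))
  expect_equal(ax$direction, c(0, 0, 1))
  expect_equal(ax$origin, c(0, 0, 0))

  # swapped arguments negate the direction; any point beyond the circle
  # centre on the dome side then projects non-positive
  sw <- build_axis(c(0, 0, 130), c(0, 0, 0))
  expect_equal(sw$direction, -ax$direction)
  expect_lte(sum(sw$direction * (c(0, 0, 130) - sw$origin)), 0)
  expect_lt(project_on_axis(c(0, 0, 200), sw), 0)

  expect_error(build_axis(c(1, 2, 3), c(1, 2, 3)), "coincide")

  # synthetic ulna: axis within 2 degrees of the landmark chord
  u <- generate_ulna(small_ulna())
  cf <- fit_circle(cut_halfway(u$mesh, u$landmarks))
  ax2 <- build_axis(cf$center, u$landmarks$dome_tip)
  chord <- ulnadiff:::landmark_chord(u$landmarks)
  ang <- acos(min(1, sum(ax2$direction * chord))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("axis projection is linear, pure and blind to perpendicular offsets", {
  ax <- build_axis(c(1, 1, 1), c(1, 1, 131))
  expect_equal(project_on_axis(ax$origin, ax), 0)
  expect_equal(project_on_axis(ax$origin + 7.23 * ax$direction, ax), 7.23)
  p <- ax$origin + 12 * ax$direction
  expect_equal(project_on_axis(p + c(3, -4, 0), ax),
               project_on_axis(p, ax))
})

test_that("dome-height difference follows the right-minus-left convention", {
  ax <- build_axis(c(0, 0, 0), c(0, 0, 130))
  d_long <- c(0, 0, 261)
  d_short <- c(0.5, 0, 258)
  expect_equal(measure_length_difference(d_long, d_long, ax, TRUE), 0)
  r_longer <- measure_length_difference(d_long, d_short, ax, TRUE)
  l_longer <- measure_length_difference(d_long, d_short, ax, FALSE)
  expect_equal(r_longer, 3)
  expect_equal(l_longer, -3)
})

test_that("full ulnar length is the projected landmark chord", {
  lm <- landmark_set(c(0, 0, 0), c(0, 0, 40))
  ax <- build_axis(c(0, 0, 20), c(0, 0, 40))
  expect_equal(full_ulna_length(lm, ax), 40)

  u <- generate_ulna(small_ulna())
  cf <- fit_circle(cut_halfway(u$mesh, u$landmarks))
  ax2 <- build_axis(cf$center, u$landmarks$dome_tip)
  expect_equal(full_ulna_length(u$landmarks, ax2), 260, tolerance = 2 / 260)
})

test_that("measure_pair recovers imposed differences and their symmetries", {
  prm <- small_ulna()

  p0 <- generate_pair(prm, 0)
  m0 <- measure_pair(p0$left$mesh, p0$right$mesh,
                     left_landmarks = p0$left$landmarks,
                     right_landmarks = p0$right$landmarks)
  expect_lt(m0$abs_diff, 0.1)
  expect_true(m0$alignment_ok)

  p3 <- generate_pair(prm, 3)
  m3 <- measure_pair(p3$left$mesh, p3$right$mesh,
                     left_landmarks = p3$left$landmarks,
                     right_landmarks = p3$right$landmarks)
  expect_equal(m3$signed_diff, 3, tolerance = 0.2 / 3)
  expect_equal(m3$abs_diff, abs(m3$signed_diff))
  expect_equal(m3$relative_diff,
               100 * m3$abs_diff / m3$full_length_longer)
  expect_equal(m3$longer_side, "right")
  expect_true(m3$alignment_ok)

  # swapping which bone is called left/right negates the signed value
  m3s <- measure_pair(p3$right$mesh, p3$left$mesh,
                      left_landmarks = p3$right$landmarks,
                      right_landmarks = p3$left$landmarks)
  expect_lt(abs(m3s$abs_diff - m3$abs_diff), 0.05)
  expect_lt(m3s$signed_diff, 0)

  # one-row tidy record
  td <- tidy(m3)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("signed_diff_mm", "abs_diff_mm", "relative_diff_pct",
                     "longer_side", "full_length_mm", "alignment_ok",
                     "icp_rms_mm"))
})

test_that("measure_pair is invariant under a common rigid transform", {
  prm <- small_ulna()
  p <- generate_pair(prm, 2)
  base <- measure_pair(p$left$mesh, p$right$mesh,
                       left_landmarks = p$left$landmarks,
                       right_landmarks = p$right$landmarks)
  tf <- rigid_transform(ulnadiff:::rotation_axis_angle(c(1, 0.4, 2), 0.8),
                        c(25, -40, 12))
  moved <- measure_pair(apply_transform(tf, p$left$mesh),
                        apply_transform(tf, p$right$mesh),
                        left_landmarks = apply_transform(tf,
                                                         p$left$landmarks),
                        right_landmarks = apply_transform(tf,
                                                          p$right$landmarks))
  expect_lt(abs(moved$abs_diff - base$abs_diff), 0.05)
})

test_that("measure_pair stage errors carry the stage name", {
  u <- generate_ulna(small_ulna())
  expect_error(measure_pair(sphere_mesh(), u$mesh),
               "detect_landmarks/left")
})
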