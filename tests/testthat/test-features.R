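arena <- test_arena()

test_that("radial position features follow their definitions", {
  # points at radii 10, 20, 30 with R = 100
  s <- as_segment(cbind(c(10, 0, -30), c(0, 20, 0)))
  expect_equal(median_distance_to_centre(s, arena), 0.20)
  wall <- as_segment(100 * cbind(cos(1:5), sin(1:5)))
  expect_equal(median_distance_to_centre(wall, arena), 1.0)

  const <- as_segment(40 * cbind(cos(1:8), sin(1:8)))
  expect_equal(iqr_distance_to_centre(const, arena), 0)
  # radii on a uniform grid 0..100 (101 points)
  grid <- as_segment(cbind(0:100, 0))
  expect_equal(iqr_distance_to_centre(grid, arena), 0.50)

  # dimensionless: doubling radii and R leaves both unchanged
  big <- arena_geometry(c(0, 0), 200, c(0, 100), 12)
  s2 <- as_segment(2 * s$points)
  expect_equal(median_distance_to_centre(s2, big),
               median_distance_to_centre(s, arena))
  expect_equal(iqr_distance_to_centre(s2, big),
               iqr_distance_to_centre(s, arena))

  # median/quartiles agree with a sort-based oracle
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(60, sd = 20), 30, 2)
    s3 <- as_segment(P)
    r <- sort(sqrt(rowSums(P^2)))
    expect_equal(median_distance_to_centre(s3, arena),
                 median(r) / 100, tolerance = 1e-12)
    expect_equal(iqr_distance_to_centre(s3, arena),
                 (quantile(r, 0.75) - quantile(r, 0.25))[[1]] / 100,
                 tolerance = 1e-12)
  }
})

test_that("focus is one minus the normalised ellipse area, clipped", {
  straight <- segment_at(straight_traj(11, 10), 0, 100)
  ell <- min_enclosing_ellipse(straight$points)
  expect_equal(focus(straight, ell), 1, tolerance = 2e-3)

  # a = b = d/2 makes the raw formula exactly zero
  s <- as_segment(cbind(c(0, 50), c(0, 0)))
  expect_equal(focus(s, fake_ellipse(c(25, 0), 25, 25)), 0)
  # negative raw values are clipped to zero
  expect_equal(focus(s, fake_ellipse(c(25, 0), 40, 40)), 0)

  for (seed in 1:5) {
    tr <- random_traj(80, seed = seed)
    s4 <- segment_at(tr, 0, path_length(tr) * 0.6)
    e4 <- min_enclosing_ellipse(s4$points)
    raw <- 1 - 4 * e4$area / (pi * s4$actual_length^2)
    expect_equal(focus(s4, e4), min(max(raw, 0), 1), tolerance = 1e-9)
  }
})

test_that("target proximity is the arc-length fraction inside the zone", {
  # zone: circle of radius 36 about (0, 50)
  inside <- as_segment(cbind(seq(-10, 10, 2), 50))
  expect_equal(target_proximity(inside, arena), 1)
  outside <- as_segment(cbind(seq(-90, -60, 2), 0))
  expect_equal(target_proximity(outside, arena), 0)

  # straight chord y = 50 from x = -60 to 60: inside length = 2 * 36
  chord <- as_segment(cbind(seq(-60, 60, length.out = 41), 50))
  expect_equal(target_proximity(chord, arena), 72 / 120, tolerance = 1e-9)

  # off-centre chord: analytic half-chord sqrt(r^2 - dy^2)
  chord2 <- as_segment(cbind(seq(-60, 60, length.out = 41), 70))
  expect_equal(target_proximity(chord2, arena),
               2 * sqrt(36^2 - 20^2) / 120, tolerance = 1e-9)

  expect_equal(target_proximity(inside, arena, method = "samples"), 1)
})

test_that("eccentricity covers circle, elongated and degenerate cases", {
  expect_equal(eccentricity(fake_ellipse(c(0, 0), 2, 2)), 0)
  expect_equal(eccentricity(fake_ellipse(c(0, 0), 2, 1)), sqrt(3) / 2)
  expect_equal(eccentricity(fake_ellipse(c(0, 0), 1, 1e-3)),
               sqrt(1 - 1e-6))
})

test_that("maximum loop length matches the exhaustive pair oracle", {
  mono <- as_segment(cbind(0:20, 0))
  expect_equal(max_loop_length(mono), 0)

  # closed square: the loop is the whole path
  sq <- as_segment(cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)))
  expect_equal(max_loop_length(sq), 1, tolerance = 1e-9)

  # figure-eight polyline
  fig8 <- as_segment(cbind(c(0, 2, 2, 0, 0, -2, -2, 0),
                           c(0, 2, -2, 0.5, -0.5, 2, -2, 0)))
  expect_gt(max_loop_length(fig8), 0)
  expect_equal(max_loop_length(fig8), loop_oracle(fig8$points),
               tolerance = 1e-9)

  for (seed in 1:8) {
    set.seed(seed)
    P <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
    expect_equal(max_loop_length(as_segment(P)), loop_oracle(P),
                 tolerance = 1e-9)
  }
})

test_that("inner radius variation is a robust coefficient of variation", {
  circ <- as_segment(30 * cbind(cos(seq(0, 2 * pi, length.out = 33)),
                                sin(seq(0, 2 * pi, length.out = 33))))
  expect_equal(inner_radius_variation(circ, fake_ellipse(c(0, 0), 30, 30)),
               0, tolerance = 1e-12)

  # radii 1, 1, 1, 3 about the ellipse centre: IQR/median per type-7 oracle
  s <- as_segment(cbind(c(1, -1, 0, 0), c(0, 0, 1, 3)))
  e <- fake_ellipse(c(0, 0), 3, 3)
  r <- c(1, 1, 1, 3)
  expect_equal(inner_radius_variation(s, e),
               (quantile(r, .75) - quantile(r, .25))[[1]] / median(r))

  centre_only <- as_segment(matrix(c(5, 5), 4, 2, byrow = TRUE))
  expect_equal(inner_radius_variation(centre_only,
                                      fake_ellipse(c(5, 5), 1, 1)), 0)
})

test_that("central displacement is the normalised ellipse-centre offset", {
  expect_equal(central_displacement(fake_ellipse(c(0, 0), 1, 1), arena), 0)
  expect_equal(central_displacement(fake_ellipse(c(100, 0), 1, 1), arena),
               1)
  expect_equal(central_displacement(fake_ellipse(c(0, 50), 1, 1), arena,
                                    reference = "platform"), 0)
  for (seed in 1:5) {
    set.seed(seed)
    c0 <- rnorm(2, sd = 30)
    expect_equal(central_displacement(fake_ellipse(c0, 1, 1), arena),
                 sqrt(sum(c0^2)) / 100, tolerance = 1e-12)
  }
})

test_that("all eight features are rotation invariant about the centre", {
  for (seed in 1:4) {
    tr <- random_traj(90, seed = seed)
    s <- segment_at(tr, 0, path_length(tr) * 0.7)
    f0 <- compute_features(s, arena, ellipse_tol = 1e-9)
    th <- pi / 3 + seed
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s_rot <- as_segment(s$points %*% t(R))
    arena_rot <- arena_geometry(c(0, 0), 100,
                                drop(R %*% c(0, 50)), 6)
    f1 <- compute_features(s_rot, arena_rot, ellipse_tol = 1e-9)
    expect_equal(f1, f0, tolerance = 1e-6)
  }
})

test_that("shape features are translation invariant", {
  tr <- random_traj(90, seed = 9)
  s <- segment_at(tr, 0, path_length(tr) * 0.7)
  shift <- c(13.5, -7.25)
  s_sh <- as_segment(sweep(s$points, 2, shift, "+"))
  arena_sh <- arena_geometry(shift, 100, c(0, 50) + shift, 6)
  f0 <- compute_features(s, arena, ellipse_tol = 1e-9)
  f1 <- compute_features(s_sh, arena_sh, ellipse_tol = 1e-9)
  keep <- c("focus", "eccentricity", "max_loop_length",
            "inner_radius_variation")
  expect_equal(f1[keep], f0[keep], tolerance = 1e-6)
})

test_that("features depend only weakly on the segment length", {
  # population of swim-like segments; compare d = 250 against +/-10%
  set.seed(21)
  rel <- matrix(NA_real_, 0, 8)
  cls <- c("thigmotaxis", "scanning", "chaining_response",
           "target_scanning", "incursion")
  for (i in seq_along(cls)) {
    tr <- generate_trial(list(list(class = cls[i], duration = 45)),
                         arena, seed = 70 + i)$trajectory
    L <- path_length(tr)
    for (off in c(0, L * 0.2, L * 0.4)) {
      f0 <- compute_features(segment_at(tr, off, 250), arena)
      for (fac in c(0.9, 1.1)) {
        f1 <- compute_features(segment_at(tr, off, 250 * fac), arena)
        rel <- rbind(rel, abs(f1 - f0) / pmax(abs(f0), 0.05))
      }
    }
  }
  expect_lt(median(rel), 0.05)
})
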