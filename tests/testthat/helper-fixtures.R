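# Shared fixtures and independent oracles, built in code.

test_arena <- function() arena_geometry(c(0, 0), 100, c(0, 50), 6)

# straight path along +x: n samples spaced `by` cm. Uses a huge arena so
# long straight fixtures are never clamped at a wall.
straight_traj <- function(n = 11, by = 10,
                          arena = arena_geometry(c(0, 0), 1e5,
                                                 c(0, 50), 6),
                          y = 0, dt = 1) {
  trajectory(seq_len(n) * dt, (seq_len(n) - 1) * by, rep(y, n), arena,
             id = "straight")
}

# random wandering path kept well inside the arena
random_traj <- function(n = 100, seed = 1, arena = test_arena(),
                        scale = 3) {
  set.seed(seed)
  x <- cumsum(rnorm(n, sd = scale)); y <- cumsum(rnorm(n, sd = scale))
  r <- sqrt(x^2 + y^2)
  f <- 0.8 * arena$arena_radius / max(r, 1)
  if (f < 1) { x <- x * f; y <- y * f }
  trajectory(seq_len(n), x, y, arena, id = paste0("rnd", seed))
}

as_segment <- function(pts, id = "seg", traj = "traj", offset = 0) {
  pts <- as.matrix(pts)
  structure(list(segment_id = id, trajectory_id = traj,
                 start_offset = offset, points = pts,
                 actual_length = sum(sqrt(diff(pts[, 1])^2 +
                                            diff(pts[, 2])^2))),
            class = "path_segment")
}

fake_ellipse <- function(centre, a, b, orientation = 0) {
  structure(list(centre = centre, a = a, b = b, orientation = orientation,
                 area = pi * a * b, degenerate = FALSE),
            class = "min_ellipse")
}

# O(n^2) plain double-loop oracle for the longest self-intersection loop,
# independent of the vectorised implementation
loop_oracle <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(0)
  ex <- diff(pts[, 1]); ey <- diff(pts[, 2])
  el <- sqrt(ex^2 + ey^2)
  cum <- cumsum(c(0, el))
  best <- 0
  for (i in 1:(n - 3)) for (j in (i + 2):(n - 1)) {
    den <- ex[i] * ey[j] - ey[i] * ex[j]
    if (abs(den) <= 1e-12) next
    rx <- pts[j, 1] - pts[i, 1]; ry <- pts[j, 2] - pts[i, 2]
    ti <- (rx * ey[j] - ry * ex[j]) / den
    sj <- (rx * ey[i] - ry * ex[i]) / den
    if (ti < 0 || ti > 1 || sj < 0 || sj > 1) next
    loop <- (1 - ti) * el[i] + (cum[j] - cum[i + 1]) + sj * el[j]
    best <- max(best, loop)
  }
  best / cum[n]
}

# kernel-free hand construction of a segment-class table
seg_table <- function(offsets, len, classes, traj = "t1") {
  n <- length(offsets)
  data.frame(segment_id = sprintf("%s_s%02d", traj, seq_len(n)),
             trajectory_id = rep_len(traj, n), start_offset_cm = offsets,
             actual_length_cm = rep_len(len, n), class = classes,
             stringsAsFactors = FALSE)
}

# pure-bout trials for each behaviour class with class-typical durations
class_bout_segments <- function(n_rep = 6, overlap = 0.7,
                                arena = test_arena()) {
  durs <- c(thigmotaxis = 60, incursion = 60, scanning = 60,
            focused_search = 45, chaining_response = 45,
            self_orienting = 30, scanning_surroundings = 45,
            target_scanning = 45)
  params <- segmentation_params(250, overlap)
  segs <- list(); cls <- character()
  for (cl in behaviour_classes()) {
    for (s in seq_len(n_rep)) {
      tr <- generate_trial(list(list(class = cl, duration = durs[[cl]])),
                           arena,
                           seed = s * 100 + match(cl, behaviour_classes()),
                           id = paste0(cl, s))
      sg <- segment_trajectory(tr$trajectory, params)
      if (length(sg)) {
        segs <- c(segs, sg)
        cls <- c(cls, rep(cl, length(sg)))
      }
    }
  }
  list(segments = segs, classes = cls, params = params)
}

# interval-level agreement of a classification against generative truth
truth_agreement <- function(classification, cohort) {
  hits <- 0L; total <- 0L
  for (id in names(classification$paths)) {
    p <- classification$paths[[id]]
    if (p$direct) next
    tr <- cohort$trials[[id]]
    for (j in seq_along(p$classes)) {
      if (p$classes[j] == "undefined") next
      tru <- truth_of_range(tr, (j - 1) * p$interval_length,
                            j * p$interval_length)
      total <- total + 1L
      hits <- hits + (p$classes[j] == tru)
    }
  }
  list(agreement = hits / total, n = total)
}
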