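arena <- test_arena()

test_that("bout generation is reproducible and stays inside the arena", {
  for (cl in behaviour_classes()) {
    b1 <- generate_behaviour(cl, 20, arena, start = c(0, -80),
                             heading = 1, seed = 99)
    b2 <- generate_behaviour(cl, 20, arena, start = c(0, -80),
                             heading = 1, seed = 99)
    expect_identical(b1, b2)
    r <- sqrt(rowSums(sweep(b1$points, 2, arena$centre)^2))
    expect_true(all(r < arena$arena_radius))
    expect_equal(length(b1$labels), 20 * 25)
  }
  expect_error(generate_behaviour("backflip", 10, arena, c(0, 0)),
               "unknown behaviour")
})

test_that("wall-bound and annulus behaviours hold their radial bands", {
  for (seed in 1:5) {
    th <- generate_behaviour("thigmotaxis", 40, arena,
                             start = c(0, -92), heading = 0, seed = seed)
    r <- sqrt(rowSums(th$points^2))
    expect_gte(mean(r > 0.85 * 100), 0.90)

    ch <- generate_behaviour("chaining_response", 40, arena,
                             start = c(50, 0), heading = 1.5, seed = seed)
    rc <- sqrt(rowSums(ch$points^2))
    # annulus at the platform's distance from the wall (radius 50)
    expect_lt(median(abs(rc - 50)), 10)
  }
})

test_that("trials concatenate bouts continuously with aligned truth", {
  specs <- list(list(class = "thigmotaxis", duration = 30),
                list(class = "scanning", duration = 30),
                list(class = "target_scanning", duration = 30))
  tr <- generate_trial(specs, arena, seed = 3, id = "t1")
  expect_s3_class(tr, "synthetic_trial")
  n <- nrow(tr$trajectory$points)
  expect_equal(length(tr$truth), n)
  expect_equal(rle(tr$truth)$values,
               c("thigmotaxis", "scanning", "target_scanning"))
  # dwell lengths match the requested bout durations to within one sample
  expect_equal(unname(rle(tr$truth)$lengths[2:3]), c(750, 750))
  # continuity: no jump larger than a plausible single step
  steps <- sqrt(diff(tr$trajectory$points$x)^2 +
                  diff(tr$trajectory$points$y)^2)
  expect_lt(max(steps), 5)
  # determinism
  tr2 <- generate_trial(specs, arena, seed = 3, id = "t1")
  expect_identical(tr$trajectory$points, tr2$trajectory$points)

  uni <- generate_trial(list(list(class = "scanning", duration = 90)),
                        arena, seed = 5)
  expect_equal(unique(uni$truth), "scanning")
})

test_that("cohorts are reproducible and carry the declared design", {
  co <- generate_cohort(n_control = 3, n_stress = 2, n_trials = 4,
                        trial_duration = 20, seed = 31)
  expect_equal(nrow(co$manifest), 20)
  expect_equal(sum(!duplicated(co$manifest$animal_id)), 5)
  expect_setequal(unique(co$manifest$group), c("control", "stress"))
  co2 <- generate_cohort(n_control = 3, n_stress = 2, n_trials = 4,
                         trial_duration = 20, seed = 31)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$trials[[7]]$trajectory$points,
                   co2$trials[[7]]$trajectory$points)
  # every sample of every trial is inside the arena
  for (t in co$trials[1:5]) {
    r <- sqrt(t$trajectory$points$x^2 + t$trajectory$points$y^2)
    expect_true(all(r <= 100))
  }
})

test_that("generated classes separate in rescaled feature space", {
  cb <- class_bout_segments(n_rep = 4)
  f01 <- rescale_features(compute_feature_table(cb$segments, arena))
  X <- as.matrix(f01[, -1])
  cls <- cb$classes
  D <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- mean(D[i, cls == cls[i] & seq_len(nrow(X)) != i])
    oth <- min(tapply(D[i, cls != cls[i]], cls[cls != cls[i]], mean))
    (oth - own) / max(own, oth)
  }, 0)
  expect_gt(mean(sil), 0.2)
})

test_that("ground-truth range queries label segments by majority", {
  specs <- list(list(class = "thigmotaxis", duration = 30),
                list(class = "scanning", duration = 30))
  tr <- generate_trial(specs, arena, seed = 8)
  cum <- cumsum(c(0, sqrt(diff(tr$trajectory$points$x)^2 +
                            diff(tr$trajectory$points$y)^2)))
  border <- cum[750]                         # arc length of the switch
  expect_equal(truth_of_range(tr, 0, border * 0.5), "thigmotaxis")
  expect_equal(truth_of_range(tr, border * 1.2, cum[length(cum)]),
               "scanning")

  co <- generate_cohort(n_control = 1, n_stress = 1, n_trials = 1,
                        trial_duration = 60, seed = 13)
  prep <- prepare_classification(co, segmentation_params(250, 0.7))
  lab <- truth_labels(co, prep$index, fraction = 0.5, seed = 2)
  expect_equal(length(unique(lab$segment_id)),
               round(0.5 * nrow(prep$index)))
  expect_true(all(lab$class %in% behaviour_classes()))
  # deterministic
  lab2 <- truth_labels(co, prep$index, fraction = 0.5, seed = 2)
  expect_identical(lab, lab2)
})
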