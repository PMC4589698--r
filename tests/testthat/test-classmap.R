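fake_model <- function(assignment) list(assignment = assignment)

test_that("the label quorum shrinks with cluster size, floored at 1%", {
  n <- 10^(1:6)
  p <- required_label_proportion(n)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0.01))
  expect_equal(required_label_proportion(1e6), 0.01)
  # gamma raises the demand
  expect_gte(min_labels_required(100, gamma = 1.4),
             min_labels_required(100, gamma = 0.7))
})

test_that("clusters map only with enough unanimous labels", {
  assign <- setNames(rep(1:3, each = 30), paste0("s", 1:90))
  m <- fake_model(assign)
  m_req <- min_labels_required(30)   # quorum for n = 30

  # cluster 1: unanimous, enough labels -> mapped
  # cluster 2: mixed labels -> undefined
  # cluster 3: unanimous but below quorum -> undefined
  lab <- data.frame(
    segment_id = c(paste0("s", 1:(m_req + 1)),
                   paste0("s", 31:34),
                   paste0("s", 61:(60 + m_req - 1))),
    class = c(rep("thigmotaxis", m_req + 1),
              c("scanning", "scanning", "incursion", "scanning"),
              rep("chaining_response", m_req - 1)))
  cm <- map_clusters_to_classes(m, lab)
  expect_equal(cm$class, c("thigmotaxis", "undefined", "undefined"))
  expect_equal(cm$m_required, rep(m_req, 3))

  # no labels at all -> everything undefined
  cm0 <- map_clusters_to_classes(m, lab[0, ])
  expect_true(all(cm0$class == "undefined"))
})

test_that("a class is never assigned below 100% label purity", {
  set.seed(2)
  for (rep in 1:10) {
    n <- 40
    assign <- setNames(rep(1L, n), paste0("s", 1:n))
    n_lab <- sample(5:20, 1)
    cls <- sample(behaviour_classes(), sample(2:3, 1))
    lab <- data.frame(segment_id = paste0("s", 1:n_lab),
                      class = sample(cls, n_lab, replace = TRUE))
    cm <- map_clusters_to_classes(fake_model(assign), lab)
    if (length(unique(lab$class)) > 1)
      expect_equal(cm$class, "undefined")
  }
})

test_that("stage two splits mixed undefined clusters into pure ones", {
  # three tight blobs; k1 = 2 forces two labelled classes into one cluster
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 0, .05), 30),
             sweep(matrix(rnorm(60, 0, .05), 30), 2, c(1, 0), "+"),
             sweep(matrix(rnorm(60, 0, .05), 30), 2, c(0.5, 1), "+"))
  rownames(X) <- paste0("s", 1:90)
  lab <- data.frame(
    segment_id = paste0("s", c(1:10, 31:40, 61:70)),
    class = rep(c("thigmotaxis", "scanning", "incursion"), each = 10))
  con <- generate_constraints(lab, as.data.frame(X) |>
                                (\(d) { d$segment_id <- rownames(X); d })())
  ts <- two_stage_cluster(X, 2, con, lab, seed = 6, min_split_size = 5)
  expect_gte(ts$model$k, 2)
  expect_gte(length(ts$subdivided), 1)
  mapped <- ts$class_map$class[ts$class_map$class != "undefined"]
  expect_setequal(unique(mapped), c("thigmotaxis", "scanning", "incursion"))
  # every labelled segment sits in a cluster mapped to its own class
  sc <- segment_classes(ts$model, ts$class_map)
  hit <- sc$class[match(lab$segment_id, sc$segment_id)] == lab$class
  expect_gte(mean(hit), 0.95)
})

test_that("pure, sufficiently labelled stage-1 clusters are untouched", {
  set.seed(14)
  X <- rbind(matrix(rnorm(80, 0, .05), 40),
             sweep(matrix(rnorm(80, 0, .05), 40), 2, c(1, 1), "+"))
  rownames(X) <- paste0("s", 1:80)
  lab <- data.frame(segment_id = paste0("s", c(1:10, 41:50)),
                    class = rep(c("thigmotaxis", "scanning"), each = 10))
  ts <- two_stage_cluster(X, 2, NULL, lab, seed = 14)
  expect_length(ts$subdivided, 0)
  expect_equal(ts$model$k, 2)
  expect_setequal(ts$class_map$class, c("thigmotaxis", "scanning"))
})

test_that("cross-validation is clean on separable classes", {
  set.seed(10)
  X <- rbind(matrix(rnorm(120, 0, .05), 60),
             sweep(matrix(rnorm(120, 0, .05), 60), 2, c(1, 0), "+"),
             sweep(matrix(rnorm(120, 0, .05), 60), 2, c(0, 1), "+"))
  rownames(X) <- paste0("s", 1:180)
  lab <- data.frame(
    segment_id = paste0("s", c(1:20, 61:80, 121:140)),
    class = rep(c("thigmotaxis", "scanning", "incursion"), each = 20))
  cv <- cross_validate(X, 3, lab, folds = 5, seed = 10)
  expect_equal(cv$error, 0)
  expect_true(all(cv$confusion[upper.tri(cv$confusion)] == 0))
  expect_true(all(cv$confusion[lower.tri(cv$confusion)] == 0))
  # folds partition the labels
  expect_equal(sum(cv$per_fold$correct) + sum(cv$per_fold$incorrect) +
                 cv$unknown, nrow(lab))
})

test_that("random labels on structureless data never look accurate", {
  # permutation baseline: with arbitrary labels the pipeline must either
  # misclassify heavily or refuse to classify (undefined clusters)
  set.seed(20)
  X <- matrix(runif(200 * 4), 200)
  rownames(X) <- paste0("s", 1:200)
  lab <- data.frame(segment_id = paste0("s", 1:60),
                    class = sample(behaviour_classes()[1:4], 60,
                                   replace = TRUE))
  cv <- cross_validate(X, 5, lab, folds = 5, seed = 20)
  accuracy <- sum(cv$per_fold$correct) / nrow(lab)
  expect_lt(accuracy, 0.4)
  expect_true(is.na(cv$error) || cv$error > 0.2 ||
                cv$unknown / nrow(lab) > 0.6)
  expect_error(cross_validate(X, 5, lab[1:3, ], folds = 5, seed = 1),
               "fewer labelled")
})
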