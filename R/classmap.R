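#' Minimum label quorum for mapping a cluster to a class
#'
#' A cluster of size \code{n} is mapped to a behavioural class only if it
#' holds at least \code{m(n)} labels, all of one class. The quorum is
#' \deqn{m(n) = \lceil \max(2,\; p_{min}\, n,\;
#'   \gamma (1 + \log_{10} n)^2) \rceil,}
#' so a mapping always needs at least two corroborating labels, the
#' \emph{required label proportion} m(n)/n is large for small
#' clusters, shrinks as clusters grow, and never falls below the floor
#' \code{p_min} (1% by default): about 3 labels for a 10-segment cluster,
#' 7 at 100, 12 at 1000, and the proportional floor beyond. Raising
#' \code{gamma} demands more labels
#' per cluster (fewer classification errors, more undefined clusters);
#' \code{p_min} sets the large-cluster floor. The quorum rule is a
#' replaceable strategy: any function of (n, gamma, p_min) can be passed to
#' \code{\link{map_clusters_to_classes}}.
#'
#' @param n cluster size(s).
#' @param gamma label-demand parameter (default 0.7).
#' @param p_min minimum required label proportion (default 0.01).
#' @return Integer vector of required label counts.
#' @examples
#' min_labels_required(c(10, 100, 1000))
#' required_label_proportion(10^(1:6))
#' @export
min_labels_required <- function(n, gamma = 0.7, p_min = 0.01) {
  as.integer(ceiling(pmax(2, p_min * n, gamma * (1 + log10(n))^2)))
}

#' @rdname min_labels_required
#' @export
required_label_proportion <- function(n, gamma = 0.7, p_min = 0.01) {
  min_labels_required(n, gamma, p_min) / n
}

#' Map clusters to behavioural classes
#'
#' Each cluster is mapped to the class of the labelled segments it contains.
#' Clusters whose labels disagree (more than one class present) or that hold
#' fewer than the quorum \code{m_i} labels are marked \code{undefined};
#' their segments are excluded from further analysis. Multi-label segments
#' do not vote.
#'
#' @param model an \code{mpckm} fit (or any object with an
#'   \code{assignment} vector named by segment id).
#' @param labels data.frame \code{segment_id, class}.
#' @param gamma,p_min quorum parameters, see
#'   \code{\link{min_labels_required}}.
#' @param quorum_fn quorum strategy \code{function(n, gamma, p_min)}.
#' @return Object of class \code{class_map}: data.frame with one row per
#'   cluster — \code{cluster, n, n_labels, n_label_classes, m_required,
#'   class} (\code{class == "undefined"} where no mapping was possible) —
#'   and the label tally in \code{attr(, "tally")}.
#' @export
map_clusters_to_classes <- function(model, labels, gamma = 0.7,
                                    p_min = 0.01,
                                    quorum_fn = min_labels_required) {
  assign <- model$assignment
  lab <- single_labels(labels)
  lab <- lab[lab$segment_id %in% names(assign), , drop = FALSE]
  clusters <- sort(unique(assign))
  tally <- table(factor(assign[lab$segment_id], levels = clusters),
                 lab$class)
  n <- as.integer(table(factor(assign, levels = clusters)))
  n_labels <- as.integer(rowSums(tally))
  n_classes <- as.integer(rowSums(tally > 0))
  m_req <- quorum_fn(n, gamma, p_min)
  cls <- rep("undefined", length(clusters))
  ok <- n_classes == 1L & n_labels >= m_req
  if (any(ok)) {
    cls[ok] <- colnames(tally)[apply(tally[ok, , drop = FALSE], 1,
                                     which.max)]
  }
  out <- data.frame(cluster = clusters, n = n, n_labels = n_labels,
                    n_label_classes = n_classes, m_required = m_req,
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "tally") <- tally
  class(out) <- c("class_map", "data.frame")
  out
}

#' @export
print.class_map <- function(x, ...) {
  nd <- sum(x$class != "undefined")
  cat(sprintf("Cluster-class map: %d cluster(s), %d mapped, %d undefined\n",
              nrow(x), nd, nrow(x) - nd))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Per-segment classes implied by a fit and its class map
#'
#' @param model an \code{mpckm} fit (stage 1 or combined two-stage).
#' @param class_map a \code{class_map}.
#' @param index segment index (see \code{\link{segment_index}}); when given,
#'   offsets and lengths are joined in.
#' @param params optional \code{segmentation_params}; stored as the nominal
#'   segment length attribute used by
#'   \code{\link{combine_classifications}}.
#' @return data.frame \code{segment_id, class} (+ index columns when
#'   supplied), attribute \code{segment_length} when params given.
#' @export
segment_classes <- function(model, class_map, index = NULL, params = NULL) {
  cls <- class_map$class[match(model$assignment, class_map$cluster)]
  out <- data.frame(segment_id = names(model$assignment), class = cls,
                    stringsAsFactors = FALSE)
  if (!is.null(index)) {
    out <- merge(index, out, by = "segment_id", sort = FALSE)
  }
  if (!is.null(params)) attr(out, "segment_length") <- params$segment_length
  out
}

#' Two-stage semi-supervised clustering
#'
#' Stage 1 clusters all segments with cannot-link constraints only: the
#' feature space is not cleanly separable, several clusters may share one
#' behavioural class, and forcing must-links across such clusters degrades
#' the fit. Stage 2 then revisits every stage-1 cluster that came out
#' \code{undefined} (mixed or insufficient labels) and is large enough, and
#' re-clusters its points in isolation with \emph{both} constraint kinds,
#' aiming for one more cluster than the number of label classes present.
#' Defined stage-1 clusters are kept untouched; the final model is the union
#' and its class map is recomputed. Subdivision can only add clusters, and
#' it reduces the sensitivity of the result to the initial choice of
#' \code{k1}.
#'
#' @param features01 rescaled feature table or matrix (rownames = ids).
#' @param k1 stage-1 cluster count.
#' @param constraints constraint data.frame (both kinds; the stage split is
#'   handled internally).
#' @param labels data.frame \code{segment_id, class}.
#' @param seed integer seed.
#' @param gamma,p_min,quorum_fn quorum parameters.
#' @param w_violation,metric_learn,max_iter passed to \code{\link{mpckm}}.
#' @param min_split_size only undefined clusters with at least
#'   \code{2 * min_split_size} points are subdivided (default 10).
#' @return List of class \code{mwm_two_stage}: \code{model} (combined
#'   \code{mpckm}-like fit, stage 2), \code{class_map}, \code{stage1},
#'   \code{stage1_map}, \code{subdivided} (stage-1 cluster ids that were
#'   split).
#' @export
two_stage_cluster <- function(features01, k1, constraints, labels,
                              seed = 1L, gamma = 0.7, p_min = 0.01,
                              quorum_fn = min_labels_required,
                              w_violation = 10, metric_learn = TRUE,
                              max_iter = 300L, min_split_size = 10L) {
  X <- feature_matrix(features01)
  cl_only <- if (is.null(constraints)) NULL else
    constraints[constraints$kind == "cannot_link", , drop = FALSE]
  stage1 <- mpckm(X, k1, cl_only, seed = seed, w_violation = w_violation,
                  metric_learn = metric_learn, max_iter = max_iter)
  map1 <- map_clusters_to_classes(stage1, labels, gamma, p_min, quorum_fn)
  lab1 <- single_labels(labels)

  assign <- stage1$assignment
  final <- assign
  centroids <- list(); metrics <- list()
  next_id <- 0L
  subdivided <- integer(0)
  for (ci in map1$cluster) {
    idx <- which(assign == ci)
    row <- map1[map1$cluster == ci, ]
    split_it <- row$class == "undefined" && length(idx) >= 2L * min_split_size
    if (!split_it) {
      next_id <- next_id + 1L
      final[idx] <- next_id
      centroids[[next_id]] <- stage1$centroids[ci, ]
      metrics[[next_id]] <- stage1$metrics[ci, ]
      next
    }
    subdivided <- c(subdivided, ci)
    ids <- names(assign)[idx]
    n_cls <- length(unique(lab1$class[lab1$segment_id %in% ids]))
    sub_k <- min(max(2L, n_cls + 1L), length(idx) - 1L)
    sub_con <- if (is.null(constraints)) NULL else
      constraints[constraints$id_a %in% ids & constraints$id_b %in% ids,
                  , drop = FALSE]
    sub <- mpckm(X[idx, , drop = FALSE], sub_k, sub_con,
                 seed = seed + ci, w_violation = w_violation,
                 metric_learn = metric_learn, max_iter = max_iter)
    for (h in seq_len(sub$k)) {
      next_id <- next_id + 1L
      final[idx[sub$assignment == h]] <- next_id
      centroids[[next_id]] <- sub$centroids[h, ]
      metrics[[next_id]] <- sub$metrics[h, ]
    }
  }
  model <- structure(list(k = next_id, assignment = final,
                          centroids = do.call(rbind, centroids),
                          metrics = do.call(rbind, metrics),
                          objective = stage1$objective,
                          iterations = stage1$iterations,
                          converged = stage1$converged,
                          violations = NA_integer_,
                          seed = seed, w_violation = w_violation,
                          metric_learn = metric_learn, stage = 2L),
                     class = "mpckm")
  map2 <- map_clusters_to_classes(model, labels, gamma, p_min, quorum_fn)
  structure(list(model = model, class_map = map2, stage1 = stage1,
                 stage1_map = map1, subdivided = subdivided),
            class = "mwm_two_stage")
}

#' @export
print.mwm_two_stage <- function(x, ...) {
  cat(sprintf(
    "Two-stage clustering: %d -> %d clusters (%d subdivided), %d mapped\n",
    x$stage1$k, x$model$k, length(x$subdivided),
    sum(x$class_map$class != "undefined")))
  invisible(x)
}

#' Cross-validated classification error
#'
#' The labelled segments are split into \code{folds} folds. In each run the
#' held-out fold contributes no constraints and no votes in the cluster-
#' class mapping; its segments are then compared against the class of the
#' cluster they landed in. Held-out segments in undefined clusters are
#' counted separately as unknown. The reported \code{error} follows the
#' convention of dividing the number of incorrectly classified segments by
#' the number of correct ones (mean over folds); the conventional rate
#' incorrect / (incorrect + correct) is also returned, together with the
#' pooled class-by-class confusion matrix.
#'
#' @param features01 rescaled feature table or matrix.
#' @param k1 stage-1 cluster count.
#' @param labels data.frame \code{segment_id, class}.
#' @param folds number of folds (default 10).
#' @param seed integer seed (fold shuffling and clustering).
#' @param d_max constraint distance cutoff.
#' @param ... passed to \code{\link{two_stage_cluster}}.
#' @return List: \code{error} (incorrect/correct, mean over folds),
#'   \code{error_rate} (pooled conventional rate), \code{confusion}
#'   (true x predicted), \code{unknown} (held-out segments in undefined
#'   clusters), \code{per_fold} data.frame.
#' @export
cross_validate <- function(features01, k1, labels, folds = 10L, seed = 1L,
                           d_max = 0.25, ...) {
  lab <- single_labels(labels)
  X <- feature_matrix(features01)
  lab <- lab[lab$segment_id %in% rownames(X), , drop = FALSE]
  if (nrow(lab) < folds) stop("fewer labelled segments than folds")
  ord <- with_seed(seed, sample.int(nrow(lab)))
  fold_of <- rep_len(seq_len(folds), nrow(lab))[order(ord)]
  classes <- sort(unique(lab$class))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  per_fold <- data.frame(fold = seq_len(folds), correct = 0L,
                         incorrect = 0L, unknown = 0L)
  for (f in seq_len(folds)) {
    test <- lab[fold_of == f, , drop = FALSE]
    train <- lab[fold_of != f, , drop = FALSE]
    cons <- generate_constraints(train, features01, d_max = d_max)
    ts <- two_stage_cluster(features01, k1, cons, train, seed = seed, ...)
    pred_cls <- segment_classes(ts$model, ts$class_map)
    pred <- pred_cls$class[match(test$segment_id, pred_cls$segment_id)]
    unknown <- pred == "undefined" | is.na(pred)
    hit <- !unknown & pred == test$class
    miss <- !unknown & pred != test$class
    per_fold$correct[f] <- sum(hit)
    per_fold$incorrect[f] <- sum(miss)
    per_fold$unknown[f] <- sum(unknown)
    for (i in which(!unknown)) {
      if (pred[i] %in% classes)
        conf[test$class[i], pred[i]] <- conf[test$class[i], pred[i]] + 1L
    }
  }
  ratio <- ifelse(per_fold$correct > 0,
                  per_fold$incorrect / per_fold$correct, NA_real_)
  list(error = mean(ratio, na.rm = TRUE),
       error_rate = sum(per_fold$incorrect) /
         max(1L, sum(per_fold$incorrect) + sum(per_fold$correct)),
       confusion = conf, unknown = sum(per_fold$unknown),
       per_fold = per_fold)
}
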