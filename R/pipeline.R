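#' Segment and featurise a set of trials
#'
#' The deterministic, label-independent front half of the pipeline:
#' segmentation of every trajectory and the rescaled feature table. The
#' result can be passed to \code{\link{classify_trials}} (argument
#' \code{prep}) to avoid recomputing features when the same trials are
#' clustered repeatedly, e.g. during a \code{\link{sweep_k1}} over the
#' target cluster count.
#'
#' @param trajectories list of \code{trajectory} objects or an
#'   \code{mwm_cohort}.
#' @param params a \code{segmentation_params}.
#' @param ... passed to \code{\link{compute_feature_table}}.
#' @return List with \code{trajectories}, \code{segments},
#'   \code{index}, \code{features}, \code{features01}.
#' @export
prepare_classification <- function(trajectories, params, ...) {
  if (inherits(trajectories, "mwm_cohort"))
    trajectories <- lapply(trajectories$trials, `[[`, "trajectory")
  seg_lists <- lapply(trajectories, segment_trajectory, params = params)
  direct <- vapply(seg_lists, function(s) isTRUE(attr(s, "direct")),
                   logical(1))
  segments <- do.call(c, seg_lists[!direct])
  if (!length(segments)) stop("no trajectory was long enough to segment")
  index <- segment_index(segments)
  feats <- compute_feature_table(segments,
                                 arena = trajectories[[1]]$arena, ...)
  list(trajectories = trajectories, segments = segments, index = index,
       features = feats, features01 = rescale_features(feats))
}

#' End-to-end segment classification of a set of trials
#'
#' Runs the full pipeline on a list of trajectories: overlapping
#' constant-length segmentation, the eight features per segment, min-max
#' rescaling, constraint generation from the partial labels, two-stage
#' semi-supervised clustering, cluster-class mapping, and the mapping of
#' segment classes back onto discrete path intervals. Short trajectories
#' (below one segment length) are flagged direct and carried through
#' unsegmented.
#'
#' @param trajectories list of \code{trajectory} objects (an
#'   \code{mwm_cohort} is also accepted).
#' @param labels data.frame \code{segment_id, class} of partial labels.
#' @param params a \code{segmentation_params}.
#' @param k1 stage-1 cluster count.
#' @param seed integer seed.
#' @param sigma interval kernel bandwidth (interval units).
#' @param d_max constraint distance cutoff.
#' @param gamma,p_min label quorum parameters.
#' @param w_violation constraint violation weight.
#' @param prep optional precomputed \code{\link{prepare_classification}}
#'   result for these trajectories and params.
#' @param ... further arguments to \code{\link{two_stage_cluster}}.
#' @return Object of class \code{mwm_classification}: list with
#'   \code{segments} (index), \code{features01}, \code{fit}
#'   (\code{mwm_two_stage}), \code{class_map}, \code{segment_classes},
#'   \code{paths} (named list of \code{classified_path}s, direct paths
#'   included), \code{coverage}, \code{params}, plus the inputs needed by
#'   the methods.
#' @seealso \code{\link{sweep_k1}} for choosing \code{k1} by coverage.
#' @export
classify_trials <- function(trajectories, labels, params, k1, seed = 1L,
                            sigma = 4, d_max = 0.25, gamma = 0.7,
                            p_min = 0.01, w_violation = 10, prep = NULL,
                            ...) {
  if (is.null(prep)) prep <- prepare_classification(trajectories, params)
  trajectories <- prep$trajectories
  index <- prep$index
  feats <- prep$features
  features01 <- prep$features01
  cons <- generate_constraints(labels, features01, d_max = d_max)
  fit <- two_stage_cluster(features01, k1, cons, labels, seed = seed,
                           gamma = gamma, p_min = p_min,
                           w_violation = w_violation, ...)
  sc <- segment_classes(fit$model, fit$class_map, index = index,
                        params = params)
  w_k <- run_length_weights(sc)
  paths <- lapply(trajectories, function(tr) {
    classify_intervals(tr, sc[sc$trajectory_id == tr$id, , drop = FALSE],
                       params, sigma = sigma, class_weights = w_k)
  })
  names(paths) <- vapply(trajectories, `[[`, "", "id")
  structure(list(segments = index, features = feats,
                 features01 = features01, constraints = cons, fit = fit,
                 class_map = fit$class_map, segment_classes = sc,
                 paths = paths, coverage = coverage(paths),
                 params = params, sigma = sigma, seed = seed,
                 trajectories = trajectories, labels = labels),
            class = "mwm_classification")
}

#' @export
print.mwm_classification <- function(x, ...) {
  n_dir <- sum(vapply(x$paths, `[[`, logical(1), "direct"))
  cat("MWM segment classification\n")
  cat(sprintf("  %d trajectories (%d direct), %d segments of %g cm (step %g cm)\n",
              length(x$paths), n_dir, nrow(x$segments),
              x$params$segment_length, x$params$step))
  cat(sprintf("  clusters: %d (stage 1: %d), %d mapped to classes\n",
              x$fit$model$k, x$fit$stage1$k,
              sum(x$class_map$class != "undefined")))
  cat(sprintf("  coverage: %.1f%%\n", 100 * x$coverage))
  invisible(x)
}

#' @export
summary.mwm_classification <- function(object, ...) {
  cls <- unlist(lapply(object$paths, `[[`, "classes"))
  tab <- table(factor(cls, levels = c(behaviour_classes(), "undefined")))
  structure(list(classification = object, interval_table = tab,
                 class_map = object$class_map,
                 coverage = object$coverage),
            class = "summary.mwm_classification")
}

#' @export
print.summary.mwm_classification <- function(x, ...) {
  print(x$classification)
  cat("\nInterval class distribution:\n")
  print(x$interval_table)
  cat("\n")
  print(x$class_map)
  invisible(x)
}

#' Plot a classified trajectory
#'
#' Draws the trajectory inside its arena with each minimum path interval
#' coloured by its behavioural class (grey = undefined).
#'
#' @param x an \code{mwm_classification}.
#' @param trajectory_id which trajectory to draw (default: the first).
#' @param palette named colours per class.
#' @param ... unused.
#' @export
plot.mwm_classification <- function(x, trajectory_id = NULL,
                                    palette = NULL, ...) {
  ids <- vapply(x$trajectories, `[[`, "", "id")
  if (is.null(trajectory_id)) trajectory_id <- ids[1]
  tr <- x$trajectories[[match(trajectory_id, ids)]]
  cp <- x$paths[[trajectory_id]]
  if (is.null(palette)) {
    palette <- stats::setNames(grDevices::hcl.colors(8, "Dark 3"),
                               behaviour_classes())
  }
  palette <- c(palette, undefined = "grey70")
  a <- tr$arena
  th <- seq(0, 2 * pi, length.out = 256)
  plot(a$centre[1] + a$arena_radius * cos(th),
       a$centre[2] + a$arena_radius * sin(th), type = "l", asp = 1,
       xlab = "x (cm)", ylab = "y (cm)", main = trajectory_id)
  lines(a$platform_centre[1] + a$platform_radius * cos(th),
        a$platform_centre[2] + a$platform_radius * sin(th), col = "grey40")
  cum <- arc_lengths(tr)
  iv <- pmin(floor(cum / cp$interval_length) + 1, length(cp$classes))
  cols <- palette[cp$classes[iv]]
  segments(tr$points$x[-nrow(tr$points)], tr$points$y[-nrow(tr$points)],
           tr$points$x[-1], tr$points$y[-1], col = cols[-length(cols)])
  invisible(x)
}

#' Choose the stage-1 cluster count by coverage and held-out error
#'
#' Runs the two-stage pipeline over a grid of k1 values. Coverage is the
#' main selection criterion (fewest unclassified path stretches); with
#' \code{cv_folds > 0} each candidate is additionally cross-validated on
#' the labelled segments, and the selection maximises coverage among the
#' candidates whose held-out error rate stays within
#' \code{cv_slack} times the sweep minimum — a high-coverage clustering
#' bought with misclassification is no bargain.
#'
#' @param trajectories,labels,params,seed,... as
#'   \code{\link{classify_trials}}.
#' @param k1_values integer grid of stage-1 cluster counts.
#' @param cv_folds folds for the per-candidate cross-validation
#'   (0 = skip, select on coverage alone).
#' @param cv_slack admissible multiple of the minimal cross-validated
#'   error rate (default 2).
#' @return List: \code{results} (data.frame \code{k1, coverage,
#'   n_clusters, n_mapped, cv_error}), \code{best} (the selected
#'   \code{mwm_classification}), \code{k1} (the selected value).
#' @export
sweep_k1 <- function(trajectories, labels, params, k1_values, seed = 1L,
                     cv_folds = 0L, cv_slack = 2, ...) {
  prep <- prepare_classification(trajectories, params)
  fits <- vector("list", length(k1_values))
  res <- data.frame(k1 = k1_values, coverage = NA_real_,
                    n_clusters = NA_integer_, n_mapped = NA_integer_,
                    cv_error = NA_real_)
  for (i in seq_along(k1_values)) {
    cl <- classify_trials(trajectories, labels, params, k1_values[i],
                          seed = seed, prep = prep, ...)
    fits[[i]] <- cl
    res$coverage[i] <- cl$coverage
    res$n_clusters[i] <- cl$fit$model$k
    res$n_mapped[i] <- sum(cl$class_map$class != "undefined")
    if (cv_folds > 0L) {
      cv <- cross_validate(prep$features01, k1_values[i], labels,
                           folds = cv_folds, seed = seed, ...)
      res$cv_error[i] <- cv$error_rate
    }
  }
  ok <- if (cv_folds > 0L) {
    res$cv_error <= cv_slack * min(res$cv_error) + 1e-12
  } else rep(TRUE, nrow(res))
  pick <- which(ok)[which.max(res$coverage[ok])]
  list(results = res, best = fits[[pick]], k1 = k1_values[pick])
}
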