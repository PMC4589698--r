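#' Arc length spent in each strategy during one trial
#'
#' Counts classified intervals per behavioural class and multiplies by the
#' interval lengths; undefined intervals are excluded (they contribute to no
#' class, so the per-class sum is at most the path length).
#'
#' @param path a \code{classified_path}.
#' @param classes class vocabulary defining the output order.
#' @return Named numeric vector of arc lengths (cm) per class.
#' @export
strategy_lengths <- function(path, classes = behaviour_classes()) {
  out <- stats::setNames(numeric(length(classes)), classes)
  keep <- path$classes %in% classes
  if (any(keep)) {
    s <- tapply(path$interval_lengths[keep], path$classes[keep], sum)
    out[names(s)] <- s
  }
  out
}

#' Number of strategy switches within a trial
#'
#' Counts changes between consecutive \emph{defined} interval classes;
#' undefined intervals are skipped (bridged), not treated as a class.
#'
#' @param path a \code{classified_path}.
#' @return Integer switch count.
#' @export
count_transitions <- function(path) {
  cls <- path$classes[path$classes != "undefined"]
  if (length(cls) < 2L) return(0L)
  sum(cls[-1] != cls[-length(cls)])
}

#' Within-trial strategy transition matrix
#'
#' Transitions are counted between consecutive distinct defined classes
#' within each trial (undefined intervals bridged, trials never
#' concatenated). Rows are the starting strategy, columns the ending one;
#' the diagonal is structurally absent (self-transitions are not changes)
#' and reported as NA in the probability matrix. Each row with at least one
#' transition is normalised to sum to 1.
#'
#' @param paths list of \code{classified_path}s.
#' @param classes class vocabulary (matrix dimensions).
#' @return Object of class \code{transition_matrix}: list with integer
#'   \code{counts}, row-normalised \code{probabilities} (diagonal NA), and
#'   \code{n_transitions}.
#' @export
transition_matrix <- function(paths, classes = behaviour_classes()) {
  if (inherits(paths, "classified_path")) paths <- list(paths)
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(from = classes, to = classes))
  for (p in paths) {
    cls <- p$classes[p$classes %in% classes]
    cls <- rle(cls)$values              # collapse runs -> distinct sequence
    if (length(cls) < 2L) next
    for (i in seq_len(length(cls) - 1L))
      counts[cls[i], cls[i + 1L]] <- counts[cls[i], cls[i + 1L]] + 1L
  }
  probs <- counts
  rs <- rowSums(counts)
  probs <- sweep(counts, 1, pmax(rs, 1L), "/")
  diag(probs) <- NA_real_
  structure(list(counts = counts, probabilities = probs,
                 n_transitions = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("Within-trial strategy transitions:", x$n_transitions, "total\n")
  print(round(x$probabilities, digits))
  invisible(x)
}

#' Friedman rank test for matched complete blocks
#'
#' Nonparametric test for k matched treatments over n blocks, with average
#' ranks for ties and the standard tie correction
#' \eqn{\chi^2 = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (A - C)} where A is the
#' sum of squared ranks and \eqn{C = nk(k+1)^2/4}. Fully tied data give
#' statistic 0 and p = 1. Without ties this reduces exactly to the
#' classical Friedman statistic.
#'
#' @param y numeric matrix, blocks in rows, treatments in columns. No
#'   missing values (complete blocks required).
#' @return List of class \code{htest}: \code{statistic}, \code{parameter}
#'   (df), \code{p.value}, \code{method}.
#' @export
friedman_rank_test <- function(y) {
  y <- as.matrix(y)
  if (any(is.na(y))) stop("incomplete blocks: missing values in y")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(y, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  S <- sum((Rj - n * (k + 1) / 2)^2)
  stat <- if (A - C <= 0) 0 else (k - 1) * S / (A - C)
  p <- if (stat == 0) 1 else stats::pchisq(stat, df = k - 1,
                                           lower.tail = FALSE)
  structure(list(statistic = c(`Friedman chi-squared` = stat),
                 parameter = c(df = k - 1), p.value = p,
                 method = "Friedman rank sum test (tie-corrected)",
                 data.name = deparse(substitute(y))),
            class = "htest")
}

#' Friedman comparison of two (or more) animal groups
#'
#' The study design compares treatment groups over a fixed set of matched
#' trials. With \code{blocking = "trial"} (default) the trials are the
#' blocks and each group's per-trial summary (median over its animals) the
#' treatment values — the variability between trials, common to all
#' animals, is removed by the ranking. With \code{blocking = "animal"},
#' animals are rank-paired across groups (i-th animal of each group after
#' sorting by id) and each pair is one block, using the animal's measure
#' totalled over trials; this alternative keeps per-animal variation but
#' imposes an arbitrary pairing.
#'
#' @param values data.frame with columns \code{animal_id, group, trial} and
#'   the measure in \code{value}.
#' @param blocking \code{"trial"} or \code{"animal"}.
#' @return \code{htest} result from \code{\link{friedman_rank_test}}.
#' @export
compare_groups <- function(values, blocking = c("trial", "animal")) {
  blocking <- match.arg(blocking)
  need <- c("animal_id", "group", "trial", "value")
  miss <- setdiff(need, names(values))
  if (length(miss)) stop("values missing columns: ",
                         paste(miss, collapse = ", "))
  groups <- sort(unique(values$group))
  if (length(groups) < 2L) stop("need at least two groups")
  if (blocking == "trial") {
    trials <- sort(unique(values$trial))
    y <- sapply(groups, function(g)
      sapply(trials, function(tr)
        stats::median(values$value[values$group == g &
                                     values$trial == tr])))
    if (any(is.na(y))) stop("incomplete blocks: a group is missing a trial")
  } else {
    per_animal <- stats::aggregate(value ~ animal_id + group, values, sum)
    split_g <- split(per_animal, per_animal$group)
    n_pairs <- min(vapply(split_g, nrow, 0L))
    y <- sapply(split_g, function(g)
      g$value[order(g$animal_id)][seq_len(n_pairs)])
  }
  friedman_rank_test(as.matrix(y))
}
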