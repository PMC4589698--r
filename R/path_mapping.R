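#' Classified path constructor
#'
#' The per-trial product of the pipeline: one behavioural class (or
#' \code{"undefined"}) per minimum path interval. Interval j spans arc
#' lengths [(j-1) step, j step]; the last interval may be shorter.
#'
#' @param trajectory_id identifier.
#' @param interval_length the segmentation step (cm).
#' @param classes character vector of per-interval classes.
#' @param interval_lengths actual interval arc lengths (cm); defaults to
#'   \code{interval_length} for all but computed callers may pass the exact
#'   trailing length.
#' @param direct logical; TRUE for short paths that were never segmented.
#' @return Object of class \code{classified_path}.
#' @export
classified_path <- function(trajectory_id, interval_length, classes,
                            interval_lengths = NULL, direct = FALSE) {
  n <- length(classes)
  if (is.null(interval_lengths))
    interval_lengths <- rep(interval_length, n)
  stopifnot(length(interval_lengths) == n)
  structure(list(trajectory_id = as.character(trajectory_id),
                 interval_length = interval_length,
                 classes = as.character(classes),
                 interval_lengths = as.numeric(interval_lengths),
                 direct = isTRUE(direct)),
            class = "classified_path")
}

#' @export
print.classified_path <- function(x, ...) {
  cat("Classified path", x$trajectory_id, "-", length(x$classes),
      sprintf("intervals of %g cm", x$interval_length),
      if (x$direct) "(direct, not segmented)" else "", "\n")
  defined <- x$classes != "undefined"
  cat(sprintf("  %.0f%% of intervals classified\n", 100 * mean(defined)))
  if (any(defined)) print(table(x$classes[defined]))
  invisible(x)
}

# Gaussian interval kernel: d in interval units, bandwidth sigma
gaussian_interval_kernel <- function(d, sigma) exp(-d^2 / (2 * sigma^2))

#' Run-length class weights
#'
#' For each behavioural class k, \code{L_max,k} is the longest run of
#' consecutive same-class segments (per trajectory, maximised over
#' trajectories when the table spans several); the weight is
#' \code{w_k = L_max / L_max,k} with \code{L_max} the largest run over all
#' classes. Transient behaviours with short runs receive large weights so
#' that longer-lasting classes do not overshadow them in the interval vote.
#'
#' @param seg_classes segment-class data.frame with
#'   \code{trajectory_id, start_offset_cm, class}.
#' @return Named weight vector over the defined classes present.
#' @export
run_length_weights <- function(seg_classes) {
  lmax_k <- c()
  for (g in split(seg_classes, seg_classes$trajectory_id)) {
    g <- g[order(g$start_offset_cm), ]
    runs <- rle(g$class)
    lk <- tapply(runs$lengths, runs$values, max)
    for (nm in names(lk))
      lmax_k[nm] <- max(lmax_k[nm], lk[[nm]], na.rm = TRUE)
  }
  lmax_k <- lmax_k[names(lmax_k) != "undefined"]
  if (!length(lmax_k)) return(numeric(0))
  max(lmax_k) / lmax_k
}

#' Map segment classes onto discrete path intervals
#'
#' Every interval of the path (width = segmentation step) receives the class
#' with the highest total weight among the classified segments overlapping
#' it. A segment of class k overlapping interval i contributes
#' \eqn{w_k \exp(-d_{ij}^2 / (2\sigma^2))}, where \eqn{d_{ij}} is the
#' distance from the segment centre to the interval centre in interval
#' units. The class weight \eqn{w_k = L_{max}/L_{max,k}} — the longest
#' same-class segment run in this trajectory over the longest run of class k
#' — boosts transient behaviours (e.g. self-orienting) that would otherwise
#' be overshadowed by long-lasting ones (e.g. thigmotaxis). Ties go to the
#' class of the nearest segment centre, then to the previous interval's
#' class. Intervals overlapped by no classified segment are undefined;
#' unsegmented (direct) paths come back all-undefined with the direct flag.
#'
#' @param traj a \code{trajectory}, or a single numeric path length (cm).
#' @param seg_classes data.frame for this trajectory with columns
#'   \code{start_offset_cm, actual_length_cm, class} (as from
#'   \code{\link{segment_classes}} with an index).
#' @param params the \code{segmentation_params} used.
#' @param sigma kernel bandwidth in interval units (default 4).
#' @param kernel kernel function \code{function(d, sigma)}; the Gaussian is
#'   the default and can be swapped.
#' @param class_weights optional named vector of class weights \code{w_k}.
#'   By default weights are computed from this trajectory's own segment
#'   runs; a classification spanning many trials (see
#'   \code{\link{classify_trials}}) computes them cohort-wide, which keeps
#'   the transient boost while preventing a single stray segment (run
#'   length 1 nowhere else) from dominating its neighbourhood.
#' @return A \code{classified_path}.
#' @export
classify_intervals <- function(traj, seg_classes, params, sigma = 4,
                               kernel = gaussian_interval_kernel,
                               class_weights = NULL) {
  L <- if (inherits(traj, "trajectory")) path_length(traj) else
    as.numeric(traj)
  id <- if (inherits(traj, "trajectory")) traj$id else
    if (nrow(seg_classes)) seg_classes$trajectory_id[1] else "path"
  step <- params$step
  n_int <- max(1L, ceiling(L / step - 1e-9))
  int_len <- pmin(step, L - (seq_len(n_int) - 1) * step)
  if (is.null(seg_classes) || nrow(seg_classes) == 0L) {
    return(classified_path(id, step, rep("undefined", n_int), int_len,
                           direct = TRUE))
  }
  sc <- seg_classes[order(seg_classes$start_offset_cm), , drop = FALSE]
  s0 <- sc$start_offset_cm
  s1 <- s0 + sc$actual_length_cm
  centre <- (s0 + s1) / 2 / step            # in interval units
  cls <- sc$class
  defined <- cls != "undefined"

  # class weights from maximum runs of consecutive same-class segments
  w_k <- if (is.null(class_weights)) run_length_weights(sc) else
    class_weights

  out <- rep("undefined", n_int)
  for (j in seq_len(n_int)) {
    lo <- (j - 1) * step; hi <- j * step
    ov <- which(defined & s0 < hi - 1e-9 & s1 > lo + 1e-9)
    if (!length(ov)) next
    dij <- abs(centre[ov] - (j - 0.5))
    kw <- kernel(dij, sigma)
    score <- tapply(kw, cls[ov], sum)
    wj <- w_k[names(score)]
    wj[is.na(wj)] <- 1
    score <- score * wj
    best <- names(score)[score == max(score)]
    if (length(best) > 1L) {
      nearest <- cls[ov][which.min(dij)]
      best <- if (nearest %in% best) nearest else
        if (j > 1L && out[j - 1L] %in% best) out[j - 1L] else best[1L]
    }
    out[j] <- best
  }
  classified_path(id, step, out, int_len, direct = FALSE)
}

#' Coverage of a set of classified paths
#'
#' Fraction of the total arc length of all segmented trajectories that lies
#' in intervals overlapped by at least one segment of known class (i.e.
#' intervals that received a class). Direct, unsegmented paths are excluded
#' from both numerator and denominator.
#'
#' @param paths list of \code{classified_path}s (a single one is accepted).
#' @return Coverage fraction in [0, 1] (NA when no path was segmented).
#' @export
coverage <- function(paths) {
  if (inherits(paths, "classified_path")) paths <- list(paths)
  paths <- Filter(function(p) !p$direct, paths)
  if (!length(paths)) return(NA_real_)
  covered <- sum(vapply(paths, function(p)
    sum(p$interval_lengths[p$classes != "undefined"]), 0))
  total <- sum(vapply(paths, function(p) sum(p$interval_lengths), 0))
  covered / total
}

#' Combine two classifications of the same trajectories
#'
#' Consistency device: the clustering is run more than once (e.g. with
#' different overlaps, same segment length) and the resulting segment
#' classes are merged. Segments are matched across classifications by
#' trajectory and nearest start offset (within half of the finer step);
#' matched segments with conflicting defined classes are discarded (set to
#' undefined), agreeing ones keep their class, and a defined class beats an
#' undefined partner. Unmatched segments pass through unchanged. Both
#' inputs must use the same nominal segment length.
#'
#' @param a,b segment-class data.frames (from \code{\link{segment_classes}}
#'   with an index and params, so that \code{attr(, "segment_length")} is
#'   set).
#' @return Combined segment-class data.frame (rows of \code{a} plus
#'   unmatched rows of \code{b}), same attributes as \code{a}.
#' @export
combine_classifications <- function(a, b) {
  da <- attr(a, "segment_length"); db <- attr(b, "segment_length")
  if (is.null(da) || is.null(db))
    stop("inputs must carry a segment_length attribute")
  if (!isTRUE(all.equal(da, db)))
    stop("refusing to combine classifications with different segment lengths")
  step_of <- function(z) {
    s <- sort(unique(z$start_offset_cm))
    if (length(s) > 1L) min(diff(s)) else Inf
  }
  tol <- min(step_of(a), step_of(b)) / 2
  out <- a
  used_b <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) {
    j <- which(b$trajectory_id == a$trajectory_id[i] & !is.na(b$class))
    if (!length(j)) next
    dd <- abs(b$start_offset_cm[j] - a$start_offset_cm[i])
    jm <- j[which.min(dd)]
    if (min(dd) > tol) next
    used_b[jm] <- TRUE
    ca <- a$class[i]; cb <- b$class[jm]
    out$class[i] <- if (ca == cb) ca
      else if (ca == "undefined") cb
      else if (cb == "undefined") ca
      else "undefined"
  }
  extra <- b[!used_b, , drop = FALSE]
  if (nrow(extra)) {
    common <- intersect(names(out), names(extra))
    out <- rbind(out[, common, drop = FALSE], extra[, common, drop = FALSE])
  }
  attr(out, "segment_length") <- da
  out
}
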