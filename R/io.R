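#' The eight behavioural classes
#'
#' Stereotyped swimming behaviours used for segment classification:
#' thigmotaxis (wall hugging), incursion (wall contact with inward
#' excursions), scanning (search of central regions), focused search (random
#' search of a very small area), chaining response (concentric paths at the
#' platform's distance from the wall), self orienting (a single full turn),
#' scanning surroundings (open paths crossing the region around the
#' platform), and target scanning (search focused on the platform region).
#' The sentinel \code{"undefined"} marks segments or intervals without a
#' known class and is not itself a behavioural class.
#'
#' @param extra optional character vector of additional class names.
#' @return Character vector of class names.
#' @export
behaviour_classes <- function(extra = NULL) {
  cls <- c("thigmotaxis", "incursion", "scanning", "focused_search",
           "chaining_response", "self_orienting", "scanning_surroundings",
           "target_scanning")
  unique(c(cls, extra))
}

#' Read a segment label file
#'
#' CSV with columns \code{segment_id,class}. A segment may appear on several
#' rows (multi-label: the annotator saw traits of more than one behaviour).
#' Unknown class tokens are rejected with their row number.
#'
#' @param path labels CSV path.
#' @param classes allowed class vocabulary.
#' @return data.frame \code{segment_id, class} (zero rows for an empty file).
#' @export
read_labels <- function(path, classes = behaviour_classes()) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) data.frame(segment_id = character(),
                                               class = character()))
  if (nrow(d) == 0L)
    return(data.frame(segment_id = character(), class = character()))
  need <- c("segment_id", "class")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("labels file missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!(d$class %in% classes))
  if (length(bad))
    stop("unknown class token(s) in labels file at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(d$class[bad]), collapse = ", "))
  d[, need]
}

#' @rdname read_labels
#' @param labels data.frame \code{segment_id, class}.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, c("segment_id", "class")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only unambiguously labelled segments
#'
#' Multi-label segments mark annotator ambiguity; they are excluded from
#' constraint generation and cluster-class mapping (but retained in the label
#' file for reporting).
#'
#' @param labels data.frame \code{segment_id, class}.
#' @return data.frame with one row per single-label segment.
#' @export
single_labels <- function(labels) {
  if (nrow(labels) == 0L) return(labels)
  u <- unique(labels[, c("segment_id", "class")])
  n <- table(u$segment_id)
  keep <- names(n)[n == 1L]
  u[u$segment_id %in% keep, , drop = FALSE]
}

#' Write / read a segment feature table
#'
#' CSV with \code{segment_id} followed by the eight feature columns.
#' Round-trips losslessly at full double precision.
#'
#' @param features data.frame as returned by \code{\link{compute_feature_table}}.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"segment_id" %in% names(d)) stop("feature file lacks segment_id")
  d
}

#' Write / read classified paths
#'
#' Long-format CSV: \code{trajectory_id,interval_index,offset_cm,class} plus
#' an \code{interval_length_cm} column so the object round-trips exactly.
#'
#' @param paths list of \code{classified_path} objects.
#' @param path CSV path.
#' @export
write_classified_paths <- function(paths, path) {
  rows <- do.call(rbind, lapply(paths, function(p) {
    n <- length(p$classes)
    data.frame(trajectory_id = p$trajectory_id,
               interval_index = seq_len(n),
               offset_cm = (seq_len(n) - 1) * p$interval_length,
               class = p$classes,
               interval_length_cm = p$interval_lengths,
               stringsAsFactors = FALSE)
  }))
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_classified_paths
#' @param classes class vocabulary for validation.
#' @export
read_classified_paths <- function(path, classes = behaviour_classes()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "interval_index", "offset_cm", "class",
            "interval_length_cm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("classified-path file missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!(d$class %in% c(classes, "undefined")))
  if (length(bad)) stop("unknown class token at row(s) ",
                        paste(bad, collapse = ", "))
  lapply(split(d, d$trajectory_id), function(g) {
    g <- g[order(g$interval_index), ]
    step <- if (nrow(g) > 1L) g$offset_cm[2] - g$offset_cm[1] else
      g$interval_length_cm[1]
    classified_path(g$trajectory_id[1], step, g$class,
                    interval_lengths = g$interval_length_cm)
  })
}
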