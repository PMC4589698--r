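#' Min-max rescale a feature table to [0, 1]
#'
#' Each feature column is rescaled independently to the unit interval, the
#' common scale on which constraint distances and the clustering metric are
#' defined. Constant columns map to 0. Rescaling is idempotent.
#'
#' @param features data.frame with \code{segment_id} plus numeric feature
#'   columns, or a plain numeric matrix/data.frame.
#' @return Object of the same shape with features in [0, 1]; the original
#'   per-column ranges are kept in \code{attr(, "ranges")}.
#' @export
rescale_features <- function(features) {
  has_id <- is.data.frame(features) && "segment_id" %in% names(features)
  ids <- if (has_id) features$segment_id
  X <- as.matrix(if (has_id) features[, setdiff(names(features),
                                                "segment_id"), drop = FALSE]
                 else features)
  if (nrow(X) < 2L) stop("need at least 2 rows to rescale")
  if (any(!is.finite(X))) stop("non-finite feature values")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo
  Y <- sweep(X, 2, lo)
  pos <- span > 0
  Y[, pos] <- sweep(Y[, pos, drop = FALSE], 2, span[pos], "/")
  Y[, !pos] <- 0
  out <- if (has_id) data.frame(segment_id = ids, Y,
                                stringsAsFactors = FALSE) else as.data.frame(Y)
  attr(out, "ranges") <- rbind(min = lo, max = hi)
  out
}

# numeric matrix of the feature columns, rownames = segment ids
feature_matrix <- function(features01) {
  if (is.matrix(features01)) return(features01)
  if ("segment_id" %in% names(features01)) {
    X <- as.matrix(features01[, setdiff(names(features01), "segment_id"),
                              drop = FALSE])
    rownames(X) <- features01$segment_id
    X
  } else as.matrix(features01)
}

#' Generate pairwise clustering constraints from partial labels
#'
#' Every pair of unambiguously labelled segments closer than \code{d_max} in
#' the rescaled feature space (plain Euclidean distance, the same function
#' the clustering uses) produces a constraint: must-link if the labels
#' agree, cannot-link if they differ. Restricting constraints to nearby
#' pairs keeps the constraint count tractable without affecting the
#' clustering outcome materially. Multi-label segments are excluded (they
#' mark ambiguity and would generate contradictory constraints).
#'
#' @param labels data.frame \code{segment_id, class}.
#' @param features01 rescaled feature table (see
#'   \code{\link{rescale_features}}).
#' @param d_max distance cutoff below which a pair generates a constraint
#'   (default 0.25).
#' @return data.frame \code{id_a, id_b, kind, weight} with unordered,
#'   deduplicated pairs (\code{id_a < id_b}), \code{kind} in
#'   \code{must_link, cannot_link}, weight 1.
#' @export
generate_constraints <- function(labels, features01, d_max = 0.25) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      kind = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  lab <- single_labels(labels)
  if (nrow(lab) < 2L) return(empty)
  X <- feature_matrix(features01)
  lab <- lab[lab$segment_id %in% rownames(X), , drop = FALSE]
  if (nrow(lab) < 2L) return(empty)
  lab <- lab[order(lab$segment_id), ]
  XL <- X[lab$segment_id, , drop = FALSE]
  D <- as.matrix(stats::dist(XL))
  idx <- which(upper.tri(D) & D < d_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  same <- lab$class[idx[, 1]] == lab$class[idx[, 2]]
  data.frame(id_a = lab$segment_id[idx[, 1]],
             id_b = lab$segment_id[idx[, 2]],
             kind = ifelse(same, "must_link", "cannot_link"),
             weight = 1, stringsAsFactors = FALSE)
}

#' @rdname generate_constraints
#' @param constraints constraint data.frame to write.
#' @param path CSV path.
#' @export
write_constraints <- function(constraints, path) {
  utils::write.csv(constraints, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname generate_constraints
#' @export
read_constraints <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "kind", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("constraints file missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!(d$kind %in% c("must_link", "cannot_link")))
  if (length(bad)) stop("unknown constraint kind at row(s) ",
                        paste(bad, collapse = ", "))
  d$weight <- as.numeric(d$weight)
  d
}
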