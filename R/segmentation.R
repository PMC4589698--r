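#' Segmentation parameters
#'
#' A trajectory is divided into overlapping windows of constant arc length
#' \code{d}. Consecutive windows are shifted by the step
#' \code{d * (1 - overlap)} — the \emph{minimum path interval}, which is also
#' the resolution of the final per-path class sequence. The classifications
#' this package emulates use d = 250 cm with 70% / 90% overlap (steps 75 and
#' 25 cm) and d = 300 cm with 70% overlap (step 90 cm).
#'
#' @param segment_length window arc length d (cm), > 0.
#' @param overlap fraction in (0, 1).
#' @return Object of class \code{segmentation_params} with fields
#'   \code{segment_length}, \code{overlap}, \code{step}.
#' @examples
#' segmentation_params(250, 0.9)$step  # 25 cm
#' @export
segmentation_params <- function(segment_length = 250, overlap = 0.7) {
  if (!is.finite(segment_length) || segment_length <= 0)
    stop("segment_length must be > 0")
  if (!is.finite(overlap) || overlap <= 0 || overlap >= 1)
    stop("overlap must lie strictly between 0 and 1")
  structure(list(segment_length = segment_length, overlap = overlap,
                 step = segment_length * (1 - overlap)),
            class = "segmentation_params")
}

#' @export
print.segmentation_params <- function(x, ...) {
  cat(sprintf("Segmentation: d = %g cm, overlap = %g%%, step = %g cm\n",
              x$segment_length, 100 * x$overlap, x$step))
  invisible(x)
}

# Interpolate the point at arc length s along the path (cum = arc_lengths).
point_at_arc <- function(p, cum, s) {
  if (s <= 0) return(c(p$x[1], p$y[1]))
  n <- length(cum)
  if (s >= cum[n]) return(c(p$x[n], p$y[n]))
  i <- findInterval(s, cum)            # cum[i] <= s < cum[i+1]
  seg <- cum[i + 1] - cum[i]
  f <- if (seg > 0) (s - cum[i]) / seg else 0
  c(p$x[i] + f * (p$x[i + 1] - p$x[i]),
    p$y[i] + f * (p$y[i + 1] - p$y[i]))
}

#' Extract a constant-arc-length sub-path
#'
#' Returns the contiguous sub-path starting at arc length \code{start_offset}
#' and extending for \code{d} cm. Endpoints falling between samples are
#' linearly interpolated, so the actual length tracks \code{d} to within one
#' inter-sample spacing (exactly, up to floating point, in the interior of
#' the path).
#'
#' @param traj a \code{trajectory}.
#' @param start_offset arc length (cm) from the path start.
#' @param d window arc length (cm).
#' @param segment_id identifier for the new segment.
#' @return Object of class \code{path_segment}: list with \code{segment_id},
#'   \code{trajectory_id}, \code{start_offset}, \code{points} (n x 2 matrix),
#'   \code{actual_length}.
#' @export
segment_at <- function(traj, start_offset, d, segment_id = NULL) {
  p <- traj$points
  cum <- arc_lengths(traj)
  L <- cum[length(cum)]
  tol <- max(diff(cum))
  if (start_offset < -1e-9 || start_offset > L - d + tol + 1e-9)
    stop("start_offset out of range")
  s0 <- max(0, start_offset)
  s1 <- min(L, start_offset + d)
  inside <- which(cum > s0 + 1e-12 & cum < s1 - 1e-12)
  pts <- rbind(point_at_arc(p, cum, s0),
               if (length(inside)) cbind(p$x[inside], p$y[inside]),
               point_at_arc(p, cum, s1))
  actual <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
  structure(list(segment_id = if (is.null(segment_id))
                   sprintf("%s_o%g", traj$id, round(s0, 6)) else segment_id,
                 trajectory_id = traj$id,
                 start_offset = s0, points = pts, actual_length = actual),
            class = "path_segment")
}

#' Divide a trajectory into overlapping constant-length segments
#'
#' Segments start at arc offsets 0, step, 2*step, ... If the residual beyond
#' the last regular window exceeds step/2, a final segment anchored at the
#' path end is added so that the whole path is covered; a smaller residual is
#' absorbed by the last regular window (avoiding a near-duplicate segment).
#' Trajectories shorter than one segment length — direct paths to the
#' platform — are not segmented: an empty list is returned carrying
#' \code{attr(, "direct") = TRUE}.
#'
#' @param traj a \code{trajectory}.
#' @param params a \code{segmentation_params}.
#' @return List of \code{path_segment}s (possibly empty, with attribute
#'   \code{direct} set when the path was too short to segment).
#' @export
segment_trajectory <- function(traj, params) {
  stopifnot(inherits(params, "segmentation_params"))
  d <- params$segment_length; step <- params$step
  L <- path_length(traj)
  if (L < d) {
    out <- list()
    attr(out, "direct") <- TRUE
    return(out)
  }
  m <- floor((L - d) / step)               # last regular start index
  offsets <- step * (0:m)
  resid <- L - d - m * step
  if (resid > step / 2) offsets <- c(offsets, L - d)
  segs <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    segs[[i]] <- segment_at(traj, offsets[i], d,
                            segment_id = sprintf("%s_s%03d", traj$id, i))
  }
  attr(segs, "direct") <- FALSE
  segs
}

#' Index table for a list of segments
#'
#' @param segments list of \code{path_segment}s.
#' @return data.frame \code{segment_id, trajectory_id, start_offset_cm,
#'   actual_length_cm}.
#' @export
segment_index <- function(segments) {
  data.frame(
    segment_id = vapply(segments, `[[`, "", "segment_id"),
    trajectory_id = vapply(segments, `[[`, "", "trajectory_id"),
    start_offset_cm = vapply(segments, `[[`, 0, "start_offset"),
    actual_length_cm = vapply(segments, `[[`, 0, "actual_length"),
    stringsAsFactors = FALSE)
}
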