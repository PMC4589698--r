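#' @name segment-features
#' @title Eight dimensionless segment features
#'
#' @description
#' Each swimming-path segment is summarised by eight dimensionless features
#' capturing geometric (focus, eccentricity, radial spread, loops, inner
#' radius variation) and positional (median distance to centre, target
#' proximity, central displacement) aspects of the sub-path. Radial
#' quantities are normalised by the arena radius; ellipse-derived quantities
#' come from the minimum enclosing ellipse of the segment. Quartiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param seg a \code{path_segment}.
#' @param arena an \code{arena_geometry}.
#' @param ellipse a \code{min_ellipse} (computed once per segment).
NULL

seg_pts <- function(seg) {
  if (inherits(seg, "path_segment")) seg$points else as.matrix(seg)
}

radii_to <- function(pts, centre) {
  sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2)
}

#' @rdname segment-features
#' @details \code{median_distance_to_centre}: median over samples of the
#'   distance to the arena centre, divided by the arena radius. The median
#'   (not the mean) is used for robustness against the few extreme samples
#'   at segment edges.
#' @export
median_distance_to_centre <- function(seg, arena) {
  stats::median(radii_to(seg_pts(seg), arena$centre)) / arena$arena_radius
}

#' @rdname segment-features
#' @details \code{iqr_distance_to_centre}: (r75 - r25) / R_arena, the
#'   interquartile range of the radial distance.
#' @export
iqr_distance_to_centre <- function(seg, arena) {
  r <- radii_to(seg_pts(seg), arena$centre)
  q <- stats::quantile(r, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) / arena$arena_radius
}

#' @rdname segment-features
#' @details \code{focus}: f = 1 - 4 A / (pi d^2) where A = pi a b is the
#'   area of the minimum enclosing ellipse and d the segment arc length
#'   (the actual, per-segment length). Values are clipped to [0, 1]: the raw
#'   formula can dip below 0 for near-degenerate windows whose enclosing
#'   ellipse is large relative to the arc. A focus near 1 marks a tightly
#'   closed path, low focus a spread-out one.
#' @export
focus <- function(seg, ellipse) {
  d <- if (inherits(seg, "path_segment")) seg$actual_length else
    sum(sqrt(rowSums(diff(seg_pts(seg))^2)))
  f <- 1 - 4 * ellipse$a * ellipse$b / d^2
  min(max(f, 0), 1)
}

# Fraction of a single edge p->q lying inside the disk (centre, radius).
# Solves |p + t(q-p) - c|^2 = r^2 for t in [0,1].
edge_fraction_in_disk <- function(p1, p2, centre, radius) {
  d <- p2 - p1
  f <- p1 - centre
  a <- sum(d^2)
  if (a == 0) return(as.numeric(sum(f^2) <= radius^2))
  b <- 2 * sum(f * d)
  c0 <- sum(f^2) - radius^2
  disc <- b^2 - 4 * a * c0
  if (disc <= 0) return(if (c0 <= 0) 1 else 0)  # tangent or no crossing
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a); t2 <- (-b + sq) / (2 * a)
  lo <- max(0, t1); hi <- min(1, t2)
  if (hi <= lo) return(if (c0 <= 0) 1 else 0)
  hi - lo
}

#' @rdname segment-features
#' @details \code{target_proximity}: fraction of the segment arc length lying
#'   inside the circle centred on the platform with radius 6 times the
#'   platform radius. Edges crossing the circle are split analytically at the
#'   boundary.
#' @param method \code{"arc"} (default, arc-length fraction) or
#'   \code{"samples"} (fraction of samples inside the zone).
#' @export
target_proximity <- function(seg, arena, method = c("arc", "samples")) {
  method <- match.arg(method)
  pts <- seg_pts(seg)
  zone_r <- 6 * arena$platform_radius
  if (method == "samples") {
    r <- radii_to(pts, arena$platform_centre)
    return(mean(r <= zone_r))
  }
  n <- nrow(pts)
  if (n < 2L) return(0)
  dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
  el <- sqrt(dx^2 + dy^2)
  tot <- sum(el)
  if (tot == 0) {
    return(as.numeric(sum((pts[1, ] - arena$platform_centre)^2) <= zone_r^2))
  }
  fx <- pts[-n, 1] - arena$platform_centre[1]
  fy <- pts[-n, 2] - arena$platform_centre[2]
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  c0 <- fx^2 + fy^2 - zone_r^2
  disc <- b^2 - 4 * a * c0
  # default by midpoint: robust when an edge only touches the boundary
  mid_in <- (fx + 0.5 * dx)^2 + (fy + 0.5 * dy)^2 <= zone_r^2
  frac <- as.numeric(mid_in)
  cross <- disc > 0 & a > 0
  if (any(cross)) {
    sq <- sqrt(disc[cross])
    lo <- pmax(0, (-b[cross] - sq) / (2 * a[cross]))
    hi <- pmin(1, (-b[cross] + sq) / (2 * a[cross]))
    frac[cross] <- ifelse(hi > lo, hi - lo, frac[cross])
  }
  sum(el * frac) / tot
}

#' @rdname segment-features
#' @details \code{eccentricity}: e = sqrt(1 - b^2/a^2) of the enclosing
#'   ellipse; 0 for a circle, approaching 1 for elongated paths.
#' @export
eccentricity <- function(ellipse) {
  sqrt(max(0, 1 - (ellipse$b / ellipse$a)^2))
}

#' @rdname segment-features
#' @details \code{max_loop_length}: every pair of non-adjacent edges of the
#'   polyline is tested for intersection; for an intersecting pair the loop
#'   length is the arc length travelled from the intersection point on the
#'   earlier edge, through the intermediate vertices, back to the
#'   intersection point on the later edge. The longest such loop divided by
#'   the segment length is returned; 0 if the path never self-intersects.
#'   Adjacent edges sharing a vertex do not count as intersections.
#' @export
max_loop_length <- function(seg) {
  pts <- seg_pts(seg)
  n <- nrow(pts)
  if (n < 4L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  ex <- diff(x); ey <- diff(y)                 # edge vectors, m = n-1 edges
  m <- n - 1L
  el <- sqrt(ex^2 + ey^2)
  cum <- cumsum(c(0, el))                      # arc length at vertices
  tot <- cum[n]
  if (tot == 0) return(0)
  best <- 0
  # vectorised over the later edge j for each earlier edge i
  for (i in 1:(m - 2L)) {
    j <- (i + 2L):m
    # solve p_i + t*e_i = p_j + s*e_j
    rx <- x[j] - x[i]; ry <- y[j] - y[i]
    den <- ex[i] * ey[j] - ey[i] * ex[j]
    ok <- abs(den) > 1e-12
    if (!any(ok)) next
    t_i <- (rx * ey[j] - ry * ex[j]) / den
    s_j <- (rx * ey[i] - ry * ex[i]) / den
    hit <- ok & t_i >= 0 & t_i <= 1 & s_j >= 0 & s_j <= 1
    if (!any(hit)) next
    jj <- j[hit]
    loop <- (1 - t_i[hit]) * el[i] + (cum[jj] - cum[i + 1L]) +
      s_j[hit] * el[jj]
    best <- max(best, max(loop))
  }
  min(best / tot, 1)
}

#' @rdname segment-features
#' @details \code{inner_radius_variation}: with the inner radius defined as
#'   the median distance of the samples to the centre of the enclosing
#'   ellipse, this is IQR(distances) / median(distances) — a robust
#'   coefficient of variation. A perfect circle about the ellipse centre
#'   gives 0; a zero median (all points at the centre) is defined as 0.
#' @export
inner_radius_variation <- function(seg, ellipse) {
  r <- radii_to(seg_pts(seg), ellipse$centre)
  med <- stats::median(r)
  if (med == 0) return(0)
  q <- stats::quantile(r, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) / med
}

#' @rdname segment-features
#' @details \code{central_displacement}: distance from the enclosing-ellipse
#'   centre to the arena centre (default) or the platform centre, divided by
#'   the arena radius. The arena reference identifies paths concentric with
#'   the arena (chaining response); the platform reference is available as an
#'   alternative convention.
#' @param reference \code{"arena"} or \code{"platform"}.
#' @export
central_displacement <- function(ellipse, arena,
                                 reference = c("arena", "platform")) {
  reference <- match.arg(reference)
  ref <- if (reference == "arena") arena$centre else arena$platform_centre
  sqrt(sum((ellipse$centre - ref)^2)) / arena$arena_radius
}

#' Compute all eight features for one segment
#'
#' @param seg a \code{path_segment}.
#' @param arena an \code{arena_geometry}.
#' @param central_displacement_reference passed to
#'   \code{\link{central_displacement}}.
#' @param proximity_method passed to \code{\link{target_proximity}}.
#' @param ellipse_tol tolerance of the enclosing-ellipse fit.
#' @return Named numeric vector of the eight features.
#' @seealso \link{segment-features}
#' @export
compute_features <- function(seg, arena,
                             central_displacement_reference = "arena",
                             proximity_method = "arc",
                             ellipse_tol = 1e-4) {
  ell <- min_enclosing_ellipse(seg_pts(seg), tol = ellipse_tol)
  c(median_distance_centre = median_distance_to_centre(seg, arena),
    iqr_distance_centre = iqr_distance_to_centre(seg, arena),
    focus = focus(seg, ell),
    target_proximity = target_proximity(seg, arena,
                                        method = proximity_method),
    eccentricity = eccentricity(ell),
    max_loop_length = max_loop_length(seg),
    inner_radius_variation = inner_radius_variation(seg, ell),
    central_displacement = central_displacement(
      ell, arena, reference = central_displacement_reference))
}

#' Feature table for a list of segments
#'
#' @param segments list of \code{path_segment}s.
#' @param arena an \code{arena_geometry}.
#' @param ... passed to \code{\link{compute_features}}.
#' @return data.frame: \code{segment_id} plus the eight feature columns.
#' @export
compute_feature_table <- function(segments, arena, ...) {
  fv <- t(vapply(segments, compute_features, numeric(8), arena = arena, ...))
  out <- data.frame(segment_id = vapply(segments, `[[`, "", "segment_id"),
                    fv, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
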