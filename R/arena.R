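#' Arena geometry for a Morris Water Maze experiment
#'
#' Describes the circular pool and the (hidden) escape platform. All
#' coordinates are Cartesian centimetres; by convention the origin is placed
#' at the arena centre, which simplifies the radial features, but any origin
#' is accepted.
#'
#' @param centre numeric length-2, arena centre (cm).
#' @param arena_radius positive arena radius (cm). The study design this
#'   package emulates uses a 2 m diameter pool, i.e. radius 100 cm.
#' @param platform_centre numeric length-2, platform centre (cm).
#' @param platform_radius positive platform radius (cm); 6 cm for a 12 cm
#'   diameter platform.
#' @return An object of class \code{arena_geometry}.
#' @examples
#' arena_geometry()
#' @export
arena_geometry <- function(centre = c(0, 0), arena_radius = 100,
                           platform_centre = c(0, 50), platform_radius = 6) {
  centre <- as.numeric(centre)
  platform_centre <- as.numeric(platform_centre)
  stopifnot(length(centre) == 2L, length(platform_centre) == 2L,
            is.finite(arena_radius), is.finite(platform_radius))
  if (arena_radius <= 0) stop("arena_radius must be > 0")
  if (platform_radius <= 0) stop("platform_radius must be > 0")
  off <- sqrt(sum((platform_centre - centre)^2))
  if (off + platform_radius > arena_radius + 1e-9)
    stop("platform must lie fully inside the arena")
  structure(list(centre = centre, arena_radius = arena_radius,
                 platform_centre = platform_centre,
                 platform_radius = platform_radius),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Arena: centre (", x$centre[1], ",", x$centre[2], ") cm, radius",
      x$arena_radius, "cm\n")
  cat("Platform: centre (", x$platform_centre[1], ",", x$platform_centre[2],
      ") cm, radius", x$platform_radius, "cm\n")
  invisible(x)
}

#' Read an arena configuration from a YAML file
#'
#' Expected keys: \code{centre} (2 numbers), \code{arena_radius},
#' \code{platform_centre} (2 numbers), \code{platform_radius}.
#'
#' @param path file path to a YAML arena description.
#' @return An \code{arena_geometry} object.
#' @export
read_arena <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("centre", "arena_radius", "platform_centre", "platform_radius")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("arena config missing keys: ",
                         paste(miss, collapse = ", "))
  arena_geometry(cfg$centre, cfg$arena_radius, cfg$platform_centre,
                 cfg$platform_radius)
}

#' Construct a swimming trajectory
#'
#' A trajectory is one trial's time-stamped 2-D path plus trial metadata and
#' a reference to the arena geometry. Time must be strictly increasing and at
#' least two samples are required. Samples outside the arena are clamped
#' radially to the wall (tracking jitter routinely places a wall-hugging
#' animal a little outside the nominal radius); a warning is raised only if
#' any sample exceeds the radius by more than \code{clamp_tol}.
#'
#' @param t numeric vector of sample times (seconds), strictly increasing.
#' @param x,y numeric coordinate vectors (cm).
#' @param arena an \code{arena_geometry}.
#' @param id trajectory identifier (string).
#' @param animal_id,group,day,trial trial metadata.
#' @param clamp_tol tolerance (cm) beyond the wall before clamping warns.
#' @return Object of class \code{trajectory}: a list with \code{points}
#'   (data.frame \code{t,x,y}), metadata fields, the arena, and
#'   \code{n_clamped}, the number of samples moved onto the wall.
#' @export
trajectory <- function(t, x, y, arena, id = "traj", animal_id = NA,
                       group = NA, day = NA, trial = NA, clamp_tol = 2) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (n != length(x) || n != length(y)) stop("t, x, y lengths differ")
  if (n < 2L) stop("empty trajectory: need at least 2 samples")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in trajectory")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  stopifnot(inherits(arena, "arena_geometry"))
  dx <- x - arena$centre[1]; dy <- y - arena$centre[2]
  r <- sqrt(dx^2 + dy^2)
  out <- r > arena$arena_radius
  n_clamped <- sum(out)
  if (any(r > arena$arena_radius + clamp_tol))
    warning(sum(r > arena$arena_radius + clamp_tol),
            " sample(s) more than ", clamp_tol,
            " cm outside the arena; clamped to the wall")
  if (n_clamped > 0L) {
    s <- arena$arena_radius / r[out]
    x[out] <- arena$centre[1] + dx[out] * s
    y[out] <- arena$centre[2] + dy[out] * s
  }
  structure(list(points = data.frame(t = t, x = x, y = y),
                 id = as.character(id), animal_id = animal_id, group = group,
                 day = day, trial = trial, arena = arena,
                 n_clamped = n_clamped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory", x$id, "-", nrow(x$points), "samples,",
      sprintf("%.1f s,", diff(range(x$points$t))),
      sprintf("path length %.1f cm\n", path_length(x)))
  if (!is.na(x$animal_id))
    cat("  animal", x$animal_id, "group", x$group, "day", x$day,
        "trial", x$trial, "\n")
  invisible(x)
}

#' Plot a trajectory inside its arena
#'
#' @param x a \code{trajectory}.
#' @param col path colour.
#' @param ... passed to \code{lines}.
#' @export
plot.trajectory <- function(x, col = "steelblue", ...) {
  a <- x$arena
  th <- seq(0, 2 * pi, length.out = 256)
  plot(a$centre[1] + a$arena_radius * cos(th),
       a$centre[2] + a$arena_radius * sin(th),
       type = "l", asp = 1, xlab = "x (cm)", ylab = "y (cm)",
       main = x$id)
  lines(a$platform_centre[1] + a$platform_radius * cos(th),
        a$platform_centre[2] + a$platform_radius * sin(th), col = "grey40")
  lines(x$points$x, x$points$y, col = col, ...)
  points(x$points$x[1], x$points$y[1], pch = 16)
  invisible(x)
}

#' Total arc length of a trajectory
#'
#' Sum of consecutive Euclidean point distances, in cm.
#'
#' @param traj a \code{trajectory} (or anything holding \code{points$x,y}).
#' @return Non-negative path length (cm).
#' @export
path_length <- function(traj) {
  p <- traj$points
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

# Cumulative arc length at each sample (starting at 0). Internal.
arc_lengths <- function(traj) {
  p <- traj$points
  cumsum(c(0, sqrt(diff(p$x)^2 + diff(p$y)^2)))
}

#' Read a tracked trajectory from CSV
#'
#' The CSV must carry the header \code{time_s,x_cm,y_cm}. Rows are validated
#' and points outside the arena clamped as in \code{\link{trajectory}}.
#'
#' @param path CSV file path.
#' @param arena an \code{arena_geometry}.
#' @param meta optional list / one-row data.frame with fields
#'   \code{animal_id, group, day, trial} and optionally \code{id}.
#' @param clamp_tol see \code{\link{trajectory}}.
#' @return A \code{trajectory}.
#' @export
read_trajectory <- function(path, arena, meta = NULL, clamp_tol = 2) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trajectory file ", path, " missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(d) < 2L) stop("empty trajectory: ", path, " has fewer than 2 rows")
  if (any(diff(d$time_s) <= 0))
    stop("non-monotone time in ", path)
  id <- if (!is.null(meta$id)) meta$id else
    sub("\\.csv$", "", basename(path))
  trajectory(d$time_s, d$x_cm, d$y_cm, arena, id = id,
             animal_id = if (is.null(meta$animal_id)) NA else meta$animal_id,
             group = if (is.null(meta$group)) NA else meta$group,
             day = if (is.null(meta$day)) NA else meta$day,
             trial = if (is.null(meta$trial)) NA else meta$trial,
             clamp_tol = clamp_tol)
}

#' Write a trajectory to CSV
#'
#' Inverse of \code{\link{read_trajectory}} for the point data.
#'
#' @param traj a \code{trajectory}.
#' @param path output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  d <- data.frame(time_s = traj$points$t, x_cm = traj$points$x,
                  y_cm = traj$points$y)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial manifest
#'
#' Columns: \code{id, animal_id, group, day, trial, file}. The combination
#' (animal_id, day, trial) must be unique.
#'
#' @param path manifest CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "animal_id", "group", "day", "trial", "file")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(m$animal_id, m$day, m$trial)
  if (anyDuplicated(key))
    stop("duplicate (animal_id, day, trial) rows in manifest")
  m
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
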