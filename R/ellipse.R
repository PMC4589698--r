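#' Minimum enclosing ellipse of a 2-D point set
#'
#' Computes the minimum-area (minimum-volume in 2-D) enclosing ellipse by the
#' Khachiyan barycentric-coordinate ascent. The returned ellipse is rescaled
#' so that every input point is contained (within \code{1e-6 * a} numerical
#' slack); at the default tolerance its area exceeds the true optimum by at
#' most a factor (1 + tol).
#'
#' Degenerate inputs: identical points raise an error; (near-)collinear
#' points yield a declared degenerate ellipse with semi-major axis spanning
#' half the point range and semi-minor axis floored at \code{1e-3 * a}, so
#' that downstream features (eccentricity, focus, inner radius) stay finite.
#'
#' @param points n x 2 numeric matrix, n >= 2.
#' @param tol relative convergence tolerance of the Khachiyan iteration.
#' @param max_iter iteration cap.
#' @return Object of class \code{min_ellipse}: list with \code{centre},
#'   semi-axes \code{a >= b > 0}, \code{orientation} (radians, direction of
#'   the major axis), \code{area}, and logical \code{degenerate}.
#' @references Khachiyan-type minimum-volume enclosing ellipsoid; see also
#'   the \code{cluster::ellipsoidhull} implementation of the same problem.
#' @export
min_enclosing_ellipse <- function(points, tol = 1e-4, max_iter = 1000L) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  if (ncol(P) != 2L) stop("points must be n x 2")
  P <- P[stats::complete.cases(P), , drop = FALSE]
  n <- nrow(P)
  if (n < 2L) stop("need at least 2 points")
  rng <- apply(P, 2, function(z) diff(range(z)))
  scale0 <- max(rng)
  if (scale0 == 0) stop("degenerate input: all points identical")

  # collinearity check via the smaller singular value of centred coordinates
  C0 <- sweep(P, 2, colMeans(P))
  sv <- svd(C0, nu = 0, nv = 2)
  if (sv$d[2] <= 1e-9 * sv$d[1] || n == 2L)
    return(degenerate_ellipse(P, sv$v[, 1]))

  # the enclosing ellipse depends only on the convex hull
  hull <- grDevices::chull(P)
  if (length(hull) >= 3L) P <- P[hull, , drop = FALSE]
  n <- nrow(P)
  Q <- t(cbind(P, 1))                       # 3 x n lifted points
  Qt <- t(Q)
  u <- rep(1 / n, n)
  # Frank-Wolfe ascent with away (drop) steps: far faster than the plain
  # Khachiyan update at tight tolerances
  ok <- tryCatch({
    for (it in seq_len(max_iter)) {
      X <- Q %*% (u * Qt)                   # 3 x 3
      Xi <- solve(X)
      M <- colSums(Q * (Xi %*% Q))          # Mahalanobis of lifted points
      jp <- which.max(M)
      pos <- u > 0
      jm <- which(pos)[which.min(M[pos])]
      eps_p <- M[jp] / 3 - 1
      eps_m <- 1 - M[jm] / 3
      if (max(eps_p, eps_m) <= tol) break
      if (eps_p >= eps_m) {
        j <- jp
        step <- (M[j] - 3) / (3 * (M[j] - 1))
      } else {
        j <- jm
        step <- max((M[j] - 3) / (3 * (M[j] - 1)), -u[j] / (1 - u[j]))
      }
      u <- (1 - step) * u
      u[j] <- u[j] + step
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(degenerate_ellipse(P, sv$v[, 1]))
  c_e <- drop(crossprod(u, P))              # centre
  S <- crossprod(P, u * P) - tcrossprod(c_e)
  A <- tryCatch(solve(S) / 2, error = function(e) NULL)
  if (is.null(A)) return(degenerate_ellipse(P, sv$v[, 1]))
  # guarantee containment: scale by the worst point
  D <- sweep(P, 2, c_e)
  m2 <- max(rowSums((D %*% A) * D))
  A <- A / m2
  eg <- eigen(A, symmetric = TRUE)
  ax <- 1 / sqrt(pmax(eg$values, .Machine$double.eps))
  a <- max(ax); b <- min(ax)
  v <- eg$vectors[, which.min(eg$values)]   # small eigenvalue -> long axis
  if (b < 1e-3 * a) b <- 1e-3 * a
  new_min_ellipse(c_e, a, b, atan2(v[2], v[1]), degenerate = FALSE)
}

# Collinear / two-point fallback: a thin ellipse along the principal axis.
degenerate_ellipse <- function(P, dir) {
  dir <- dir / sqrt(sum(dir^2))
  s <- drop(P %*% dir)
  a <- (max(s) - min(s)) / 2
  if (a == 0) stop("degenerate input: all points identical")
  mid <- colMeans(P[c(which.min(s), which.max(s)), , drop = FALSE])
  new_min_ellipse(mid, a, 1e-3 * a, atan2(dir[2], dir[1]), degenerate = TRUE)
}

new_min_ellipse <- function(centre, a, b, orientation, degenerate) {
  structure(list(centre = as.numeric(centre), a = a, b = b,
                 orientation = orientation, area = pi * a * b,
                 degenerate = degenerate),
            class = "min_ellipse")
}

#' @export
print.min_ellipse <- function(x, ...) {
  cat(sprintf(
    "Minimum enclosing ellipse: centre (%.2f, %.2f), a = %.2f, b = %.2f,\n",
    x$centre[1], x$centre[2], x$a, x$b))
  cat(sprintf("  orientation %.3f rad, area %.2f%s\n", x$orientation, x$area,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Test point containment in an ellipse
#'
#' @param ellipse a \code{min_ellipse}.
#' @param points n x 2 matrix.
#' @param tol relative slack on the unit Mahalanobis radius.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points, tol = 1e-6) {
  P <- as.matrix(points)
  co <- cos(ellipse$orientation); si <- sin(ellipse$orientation)
  D <- sweep(P, 2, ellipse$centre)
  u <- (D[, 1] * co + D[, 2] * si) / ellipse$a
  v <- (-D[, 1] * si + D[, 2] * co) / ellipse$b
  u^2 + v^2 <= 1 + tol
}
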