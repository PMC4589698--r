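#' Metric pairwise-constrained k-means (MPCK-means)
#'
#' Semi-supervised k-means with pairwise must-link / cannot-link constraints
#' and per-cluster diagonal metric learning, so clusters may take different
#' shapes and sizes. The objective minimised is
#' \deqn{\sum_i \big[ \|x_i - \mu_{l_i}\|^2_{A_{l_i}} - \log\det A_{l_i} \big]
#'   + \sum_{ML viol.} w\,\omega_{ij} \|x_i-x_j\|^2
#'   + \sum_{CL viol.} w\,\omega_{ij} (D^2_{max} - \|x_i-x_j\|^2)}
#' with diagonal positive metrics \eqn{A_h}, violation weight \code{w},
#' constraint weights \eqn{\omega_{ij}}, and \eqn{D^2_{max}} the maximal
#' squared distance in the unit feature cube. Violation penalties are scaled
#' by the (Euclidean) pair distance: a violated must-link costs more the
#' farther apart the pair, a violated cannot-link more the closer. Keeping
#' the penalties metric-independent preserves a closed-form monotone metric
#' update, so the objective is non-increasing at every iteration.
#'
#' Points are assigned greedily in index order (constraint-involved points
#' after a vectorised pass over the rest), centroids are cluster means, and
#' the metric update \eqn{a_{hd} = n_h / S_{hd}} (inverse per-dimension
#' scatter, capped) is the exact minimiser. Iteration stops when assignments
#' no longer change. Centroids are initialised by farthest-point sampling
#' from a seeded random start, which maximally separates initial centres.
#' An emptied cluster is re-seeded at the point currently farthest from its
#' centroid.
#'
#' @param x numeric matrix (rows = observations, typically rescaled to
#'   [0, 1]) or a feature data.frame with a \code{segment_id} column.
#' @param k number of clusters, 2 <= k <= nrow(x).
#' @param constraints data.frame \code{id_a, id_b, kind, weight} (ids match
#'   rownames of \code{x}), or NULL for unconstrained clustering.
#' @param seed integer seed controlling initialisation; the fit is
#'   deterministic given (x, k, constraints, seed).
#' @param w_violation violation weight \code{w} (default 10, in rescaled
#'   feature units).
#' @param metric_learn logical; FALSE fixes all metrics to the identity
#'   (plain constrained k-means).
#' @param max_iter iteration cap (default 300).
#' @param init optional integer vector of k row indices used as initial
#'   centroids (overrides the seeded initialisation).
#' @return Object of class \code{mpckm}: list with \code{k},
#'   \code{assignment} (named integer vector), \code{centroids},
#'   \code{metrics} (k x d positive weights), \code{objective},
#'   \code{objective_trace}, \code{iterations}, \code{converged},
#'   \code{violations}, \code{seed}, \code{stage}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
#' rownames(x) <- paste0("p", 1:40)
#' fit <- mpckm(x, k = 2, seed = 7)
#' table(fitted(fit))
#' @export
mpckm <- function(x, k, constraints = NULL, seed = 1L, w_violation = 10,
                  metric_learn = TRUE, max_iter = 300L, init = NULL) {
  X <- feature_matrix(x)
  n <- nrow(X); d <- ncol(X)
  if (k > n) stop("k must not exceed the number of points")
  if (k < 1L) stop("k must be >= 1")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(n))

  con <- prepare_constraints(constraints, X, w_violation)
  if (is.null(init)) init <- farthest_point_init(X, k, seed)
  centroids <- X[init, , drop = FALSE]
  metrics <- matrix(1, k, d)
  logdet <- rep(0, k)
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  a_cap <- 1e4

  for (iter in seq_len(max_iter)) {
    cost <- point_cluster_costs(X, centroids, metrics, logdet)
    lab <- max.col(-cost, ties.method = "first")
    # greedy (ICM) passes over constraint-involved points, starting from
    # their previous assignment so each single-point move can only lower
    # the objective (the batch argmin above ignores penalties); repeated
    # until a fixpoint so points are not stuck with a stale first choice
    if (length(con$touched)) {
      if (iter > 1L) lab[con$touched] <- assign_old[con$touched]
      for (pass in 1:20) {
        changed <- FALSE
        for (i in con$touched) {
          pen <- constraint_penalties(i, lab, con, k)
          new_l <- which.min(cost[i, ] + pen)
          if (new_l != lab[i]) { lab[i] <- new_l; changed <- TRUE }
        }
        if (!changed) break
      }
    }
    # re-seed emptied clusters at the point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(lab))
    if (length(empty)) {
      dmin <- cost[cbind(seq_len(n), lab)]
      for (h in empty) {
        far <- which.max(dmin)
        lab[far] <- h
        dmin[far] <- -Inf
      }
    }
    # M-step: centroids and diagonal metrics
    for (h in seq_len(k)) {
      idx <- which(lab == h)
      centroids[h, ] <- colMeans(X[idx, , drop = FALSE])
      if (metric_learn) {
        S <- colSums(sweep(X[idx, , drop = FALSE], 2, centroids[h, ])^2)
        metrics[h, ] <- length(idx) / pmax(S, length(idx) / a_cap)
        logdet[h] <- sum(log(metrics[h, ]))
      }
    }
    trace <- c(trace, mpckm_objective(X, lab, centroids, metrics, logdet, con))
    if (identical(lab, assign_old)) { converged <- TRUE; break }
    assign_old <- lab
    converged <- FALSE
  }
  names(lab) <- rownames(X)
  structure(list(k = k, assignment = lab, centroids = centroids,
                 metrics = metrics, objective = trace[length(trace)],
                 objective_trace = trace, iterations = length(trace),
                 converged = converged,
                 violations = count_violations(lab, con),
                 seed = seed, w_violation = w_violation,
                 metric_learn = metric_learn, stage = 1L),
            class = "mpckm")
}

# ---- internals -----------------------------------------------------------

# map constraint ids to row indices; precompute per-pair penalty magnitudes.
# dmax2 = ncol(X) is the largest possible squared distance in the unit cube.
prepare_constraints <- function(constraints, X, w) {
  if (is.null(constraints) || nrow(constraints) == 0L)
    return(list(ia = integer(), ib = integer(), must = logical(),
                pen2 = numeric(), pen_cl = numeric(), touched = integer()))
  ids <- rownames(X)
  ia <- match(constraints$id_a, ids)
  ib <- match(constraints$id_b, ids)
  keep <- !is.na(ia) & !is.na(ib) & ia != ib
  ia <- ia[keep]; ib <- ib[keep]
  must <- constraints$kind[keep] == "must_link"
  wt <- constraints$weight[keep]
  key <- paste(pmin(ia, ib), pmax(ia, ib), must)   # dedupe unordered pairs
  dup <- duplicated(key)
  ia <- ia[!dup]; ib <- ib[!dup]; must <- must[!dup]; wt <- wt[!dup]
  dsq <- rowSums((X[ia, , drop = FALSE] - X[ib, , drop = FALSE])^2)
  dmax2 <- ncol(X)
  adj <- vector("list", nrow(X))            # point -> constraint rows
  sp <- split(rep(seq_along(ia), 2L), c(ia, ib))
  adj[as.integer(names(sp))] <- sp
  list(ia = ia, ib = ib, must = must,
       pen2 = w * wt * dsq,
       pen_cl = w * wt * pmax(dmax2 - dsq, 0),
       adj = adj,
       touched = sort(unique(c(ia, ib))))
}

# per-cluster assignment costs: metric distance minus log det
point_cluster_costs <- function(X, centroids, metrics, logdet) {
  n <- nrow(X); k <- nrow(centroids)
  cost <- matrix(0, n, k)
  for (h in seq_len(k)) {
    D2 <- sweep(X, 2, centroids[h, ])^2
    cost[, h] <- D2 %*% metrics[h, ] - logdet[h]
  }
  cost
}

# penalty vector over candidate clusters for point i given current labels
constraint_penalties <- function(i, lab, con, k) {
  pen <- numeric(k)
  sel <- con$adj[[i]]
  for (s in sel) {
    j <- if (con$ia[s] == i) con$ib[s] else con$ia[s]
    lj <- lab[j]
    if (con$must[s]) {
      pen[-lj] <- pen[-lj] + con$pen2[s]          # violated unless same
    } else {
      pen[lj] <- pen[lj] + con$pen_cl[s]          # violated if same
    }
  }
  pen
}

count_violations <- function(lab, con) {
  if (!length(con$ia)) return(0L)
  same <- lab[con$ia] == lab[con$ib]
  sum(con$must & !same) + sum(!con$must & same)
}

mpckm_objective <- function(X, lab, centroids, metrics, logdet, con) {
  obj <- 0
  for (h in unique(lab)) {
    idx <- which(lab == h)
    D2 <- sweep(X[idx, , drop = FALSE], 2, centroids[h, ])^2
    obj <- obj + sum(D2 %*% metrics[h, ]) - length(idx) * logdet[h]
  }
  if (length(con$ia)) {
    same <- lab[con$ia] == lab[con$ib]
    obj <- obj + sum(con$pen2[con$must & !same]) +
      sum(con$pen_cl[!con$must & same])
  }
  obj
}

# farthest-point initial centroids; the first centre is a seeded random draw
farthest_point_init <- function(X, k, seed) {
  n <- nrow(X)
  first <- with_seed(seed, sample.int(n, 1L))
  chosen <- integer(k)
  chosen[1L] <- first
  dmin <- rowSums(sweep(X, 2, X[first, ])^2)
  if (k > 1L) for (j in 2:k) {
    nxt <- which.max(dmin)
    chosen[j] <- nxt
    dmin <- pmin(dmin, rowSums(sweep(X, 2, X[nxt, ])^2))
  }
  chosen
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# ---- methods -------------------------------------------------------------

#' @export
print.mpckm <- function(x, ...) {
  cat(sprintf("MPCK-means fit: %d clusters, %d points, %d iteration(s)%s\n",
              x$k, length(x$assignment), x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  objective %.4f, %d constraint violation(s)\n",
              x$objective, x$violations))
  sz <- sort(table(x$assignment), decreasing = TRUE)
  cat("  cluster sizes:", paste(utils::head(as.integer(sz), 10),
                                collapse = " "),
      if (length(sz) > 10) "...\n" else "\n")
  invisible(x)
}

#' @export
fitted.mpckm <- function(object, ...) object$assignment

#' Assign new points to the nearest learned cluster
#'
#' @param object an \code{mpckm} fit.
#' @param newdata matrix or feature data.frame on the same (rescaled) scale.
#' @param ... unused.
#' @return Integer cluster indices, named by row.
#' @export
predict.mpckm <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  logdet <- rowSums(log(object$metrics))
  cost <- point_cluster_costs(X, object$centroids, object$metrics, logdet)
  lab <- max.col(-cost, ties.method = "first")
  names(lab) <- rownames(X)
  lab
}
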