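#' Euclidean distance between two points
#'
#' Plain Euclidean distance in feature space. Coordinates are raw measurement
#' values (one entry per vital, in that vital's native units), so the metric
#' mixes units unless the caller standardizes first (see [featurize()]).
#'
#' @param a,b Numeric vectors of equal length; all entries must be finite.
#' @return A single non-negative number; zero iff `a` and `b` coincide.
#' @examples
#' point_distance(c(0, 0), c(3, 4)) # 5
#' @export
point_distance <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("point_distance(): dimensionality mismatch (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("point_distance(): coordinates must be finite", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' Coerce input to a point matrix
#'
#' Points are represented as a numeric matrix with one row per point and
#' row names as point ids (assigned "1".."n" when absent).
#' @param x Numeric matrix or data frame of coordinates.
#' @return Numeric matrix with row names.
#' @keywords internal
as_point_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1)
  storage.mode(x) <- "double"
  if (nrow(x) == 0) stop("empty dataset: no points supplied", call. = FALSE)
  if (!all(is.finite(x))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) {
    stop("point ids (row names) must be unique", call. = FALSE)
  }
  x
}

#' Clustering parameters
#'
#' Bundles the neighborhood radius and the minimum neighborhood population
#' that control density-based cluster formation.
#'
#' @param eps Neighborhood radius (same units as [point_distance()]); > 0.
#' @param min_pts Minimum number of points (including the point itself) an
#'   eps-neighborhood must contain for the point to be a core point; >= 1.
#' @return An object of class `dbscan_params`.
#' @export
dbscan_params <- function(eps, min_pts) {
  eps <- as.numeric(eps)
  min_pts <- as.integer(min_pts)
  if (length(eps) != 1 || !is.finite(eps) || eps <= 0) {
    stop("eps must be a single finite number > 0", call. = FALSE)
  }
  if (length(min_pts) != 1 || is.na(min_pts) || min_pts < 1) {
    stop("min_pts must be a single integer >= 1", call. = FALSE)
  }
  structure(list(eps = eps, min_pts = min_pts), class = "dbscan_params")
}

#' @export
print.dbscan_params <- function(x, ...) {
  cat(sprintf("dbscan_params: eps = %g, min_pts = %d\n", x$eps, x$min_pts))
  invisible(x)
}

# Pairwise-distance matrix restricted to the rows of x; kept internal so the
# neighborhood convention (closed ball, self-inclusive) lives in one place.
neighbor_list <- function(x, eps) {
  d <- as.matrix(stats::dist(x))
  lapply(seq_len(nrow(x)), function(i) which(d[i, ] <= eps))
}

#' Epsilon-neighborhood of a point
#'
#' All points within `eps` of point `id`, inclusive of the boundary
#' (closed ball) and of the query point itself.
#'
#' @param x Point matrix or data frame (rows = points, row names = ids).
#' @param id Point id (row name) of the query point.
#' @param eps Neighborhood radius, > 0.
#' @return Character vector of point ids, always containing `id`.
#' @export
eps_neighborhood <- function(x, id, eps) {
  x <- as_point_matrix(x)
  id <- as.character(id)
  if (!(id %in% rownames(x))) {
    stop("unknown point id: ", id, call. = FALSE)
  }
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  d <- sqrt(colSums((t(x) - x[id, ])^2))
  rownames(x)[d <= eps]
}

#' Role of a point under given clustering parameters
#'
#' A point is CORE when its eps-neighborhood holds at least `min_pts` points,
#' BORDER when it is not core but lies within eps of some core point, and
#' NOISE otherwise. Noise points are the readings the pipeline treats as
#' anomalous.
#'
#' @inheritParams eps_neighborhood
#' @param params A [dbscan_params()] object.
#' @return One of `"CORE"`, `"BORDER"`, `"NOISE"`.
#' @export
point_role <- function(x, id, params) {
  stopifnot(inherits(params, "dbscan_params"))
  x <- as_point_matrix(x)
  id <- as.character(id)
  if (!(id %in% rownames(x))) stop("unknown point id: ", id, call. = FALSE)
  nb <- neighbor_list(x, params$eps)
  core <- lengths(nb) >= params$min_pts
  i <- match(id, rownames(x))
  if (core[i]) return("CORE")
  if (any(core[nb[[i]]])) return("BORDER")
  "NOISE"
}

#' Density-based clustering (DBSCAN)
#'
#' Grows maximal density-connected clusters from core points and labels
#' everything unreachable as noise, so that an isolated abnormal reading
#' never forms a cluster of its own. Expansion scans points in ascending
#' row order and explores seeds breadth-first in ascending order, which
#' fixes border-point ties deterministically; core and noise status do not
#' depend on input order at all.
#'
#' @param x Point matrix or data frame (rows = points, row names = ids).
#' @param params A [dbscan_params()] object.
#' @return An object of class `vc_clustering`: a list with
#'   \describe{
#'     \item{ids}{character vector of point ids, in input order}
#'     \item{labels}{named integer vector; cluster ids `1..k` in
#'       first-seed order, `0` for noise}
#'     \item{roles}{named character vector, `"CORE"`/`"BORDER"`/`"NOISE"`}
#'     \item{params}{the parameters used}
#'   }
#' @examples
#' x <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
#'            matrix(rnorm(40, 5, 0.1), ncol = 2),
#'            c(20, 20))
#' cl <- dbscan(x, dbscan_params(eps = 1, min_pts = 4))
#' table(cl$labels) # two clusters plus one noise point
#' @export
dbscan <- function(x, params) {
  stopifnot(inherits(params, "dbscan_params"))
  x <- as_point_matrix(x)
  n <- nrow(x)
  nb <- neighbor_list(x, params$eps)
  is_core <- lengths(nb) >= params$min_pts

  labels <- integer(n) # 0 = unassigned; stays 0 for noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]][labels[nb[[i]]] == 0L]
    while (length(frontier) > 0) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (is_core[j]) {
        frontier <- c(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }

  roles <- ifelse(is_core, "CORE", ifelse(labels > 0L, "BORDER", "NOISE"))
  ids <- rownames(x)
  names(labels) <- ids
  names(roles) <- ids
  structure(
    list(ids = ids, labels = labels, roles = roles, params = params),
    class = "vc_clustering"
  )
}

#' @export
print.vc_clustering <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf(
    "vc_clustering: %d points, %d cluster%s, %d noise (eps = %g, min_pts = %d)\n",
    length(x$ids), k, if (k == 1) "" else "s", sum(x$labels == 0L),
    x$params$eps, x$params$min_pts
  ))
  invisible(x)
}

#' Ids of noise points in a clustering
#' @param result A `vc_clustering` object.
#' @return Character vector of point ids labelled noise.
#' @export
noise_ids <- function(result) {
  stopifnot(inherits(result, "vc_clustering"))
  result$ids[result$labels == 0L]
}

#' Cluster membership lists
#' @param result A `vc_clustering` object.
#' @return Named list, one character vector of point ids per cluster id.
#' @export
cluster_members <- function(result) {
  stopifnot(inherits(result, "vc_clustering"))
  k <- max(result$labels)
  if (k == 0L) return(list())
  out <- lapply(seq_len(k), function(cl) result$ids[result$labels == cl])
  names(out) <- as.character(seq_len(k))
  out
}
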