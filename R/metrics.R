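# Point-cloud comparison metrics for predicted vs ground-truth geometries.
# All distances in mm; overlap in percent. Nearest neighbours are exact
# (brute force with partial selection).

as_points <- function(x) {
  if (inherits(x, "surface_cloud")) x <- x$points
  x <- as.matrix(x)
  if (ncol(x) != 3) stop_invariant("point sets must be N x 3")
  if (nrow(x) == 0) stop_invariant("point set is empty")
  storage.mode(x) <- "double"
  x
}

nn_dist <- function(A, B) .knn_bf(B, A, 1L)$dist[, 1]

#' Symmetric Hausdorff distance between two point sets
#'
#' `max(max_a min_b d(a,b), max_b min_a d(a,b))`.
#'
#' @param A,B point matrices (N x 3) or `surface_cloud`s.
#' @return distance in mm.
#' @export
hausdorff_distance <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  max(max(nn_dist(A, B)), max(nn_dist(B, A)))
}

#' Directed average nearest-neighbour distance
#'
#' Mean over points of `A` of the distance to the closest point of `B`
#' (directed, predicted to true, as reported by default); set
#' `symmetric = TRUE` to average both directions.
#'
#' @param A,B point matrices (N x 3) or `surface_cloud`s.
#' @param symmetric average the two directed values.
#' @return distance in mm.
#' @export
avg_distance <- function(A, B, symmetric = FALSE) {
  A <- as_points(A); B <- as_points(B)
  d <- mean(nn_dist(A, B))
  if (symmetric) d <- (d + mean(nn_dist(B, A))) / 2
  d
}

#' Point-cloud overlap percentage
#'
#' Percentage of points of `A` within `threshold` (boundary inclusive) of
#' their nearest point in `B`.
#'
#' @param A,B point matrices (N x 3) or `surface_cloud`s.
#' @param threshold distance threshold in mm (default 2).
#' @return overlap in percent (0-100).
#' @export
overlap_percentage <- function(A, B, threshold = 2.0) {
  if (threshold <= 0) stop_invariant("threshold must be > 0")
  A <- as_points(A); B <- as_points(B)
  100 * mean(nn_dist(A, B) <= threshold)
}

#' Mean and maximum displacement magnitude
#'
#' @param u displacement matrix (N x 3), mm.
#' @return named vector `c(mean, max)` of per-point Euclidean norms, mm.
#' @export
displacement_stats <- function(u) {
  u <- as.matrix(u)
  if (nrow(u) == 0) stop_invariant("displacement field is empty")
  nn <- vec_norms(u)
  c(mean = mean(nn), max = max(nn))
}

#' All geometric agreement metrics between two corresponding clouds
#'
#' @param pred,true point matrices (N x 3) or `surface_cloud`s; rows are
#'   assumed to correspond for the RMS error.
#' @param threshold overlap threshold, mm.
#' @return named list: `hausdorff`, `avg_dist`, `overlap`, `rms_error`
#'   (corresponding-point root-mean-square distance, mm).
#' @export
geometric_metrics <- function(pred, true, threshold = 2.0) {
  P <- as_points(pred); T <- as_points(true)
  rms <- if (nrow(P) == nrow(T))
    sqrt(mean(rowSums((P - T)^2))) else NA_real_
  list(hausdorff = hausdorff_distance(P, T),
       avg_dist = avg_distance(P, T),
       overlap = overlap_percentage(P, T, threshold),
       rms_error = rms)
}
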