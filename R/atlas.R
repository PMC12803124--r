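# Statistical shape atlas: PCA point-distribution model over concatenated
# ED + ES point clouds with fixed correspondence.

#' Flatten an ED/ES cloud pair into an atlas vector
#'
#' @param ed,es `surface_cloud`s sharing point count, ordering and labels.
#' @return numeric vector of length 6N: `[ED xyz...; ES xyz...]`
#'   (point-major, x/y/z interleaved per point).
#' @export
flatten_pair <- function(ed, es) {
  if (nrow(ed$points) != nrow(es$points) || !identical(ed$labels, es$labels))
    stop_invariant("ED and ES clouds must share point count, ordering and labels")
  c(t(ed$points), t(es$points))
}

#' Rebuild the ED/ES cloud pair from an atlas vector
#'
#' @param v atlas vector of length 6N.
#' @param reference a `surface_cloud` carrying the layout (labels, spec).
#' @return list with `surface_cloud`s `ed` and `es`.
#' @export
unflatten_pair <- function(v, reference) {
  n <- nrow(reference$points)
  if (length(v) != 6 * n)
    stop_invariant(sprintf("atlas vector length %d does not match 6N = %d", length(v), 6 * n))
  ed_pts <- matrix(v[seq_len(3 * n)], n, 3, byrow = TRUE)
  es_pts <- matrix(v[3 * n + seq_len(3 * n)], n, 3, byrow = TRUE)
  list(ed = new_surface_cloud(ed_pts, reference$labels, "ED", reference$spec),
       es = new_surface_cloud(es_pts, reference$labels, "ES", reference$spec))
}

#' Build a PCA shape atlas from a cohort of atlas vectors
#'
#' Principal component analysis of the mean-centred cohort: modes are the
#' unit-norm, mutually orthogonal principal directions; the explained
#' variance per mode is the variance of the cohort's projections onto it.
#'
#' @param cohort list of atlas vectors (equal length 6N).
#' @param reference a `surface_cloud` defining the point layout.
#' @param n_modes number of retained modes (default 25).
#' @return an object of class `shape_atlas` with fields `mean`, `modes`
#'   (6N x M), `explained_variance`, `n_points`, `labels`, `reference`.
#' @export
build_atlas <- function(cohort, reference, n_modes = 25) {
  lens <- lengths(cohort)
  if (length(unique(lens)) != 1)
    stop_invariant("all cohort vectors must have the same length")
  n <- length(cohort)
  if (n <= n_modes)
    stop_invariant(sprintf("cohort size (%d) must exceed n_modes (%d)", n, n_modes))
  X <- do.call(rbind, cohort)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = n_modes)
  ev <- (sv$d[seq_len(n_modes)]^2) / (n - 1)
  atlas <- structure(list(mean = mu, modes = sv$v,
                          explained_variance = ev,
                          n_points = length(mu) / 6,
                          labels = reference$labels,
                          reference = reference),
                     class = "shape_atlas")
  atlas
}

#' @export
print.shape_atlas <- function(x, ...) {
  cum <- cumsum(x$explained_variance) / max(sum(x$explained_variance), .Machine$double.eps)
  cat(sprintf("shape_atlas: %d points (6N = %d), %d modes\n",
              x$n_points, length(x$mean), ncol(x$modes)))
  cat(sprintf("  cumulative explained variance: mode 1 %.1f%%, first 5 %.1f%%, all %.1f%%\n",
              100 * cum[1], 100 * cum[min(5, length(cum))], 100 * cum[length(cum)]))
  invisible(x)
}

#' Project an atlas vector onto the atlas modes
#'
#' Scores are reported in per-mode standard-deviation units: score 1 is a
#' displacement of one cohort SD along that mode. Modes with zero variance
#' yield score 0.
#'
#' @param atlas a `shape_atlas`.
#' @param v atlas vector of length 6N.
#' @param k number of leading scores (default: all modes).
#' @return numeric score vector of length `k`.
#' @export
project_to_scores <- function(atlas, v, k = ncol(atlas$modes)) {
  if (length(v) != length(atlas$mean))
    stop_invariant("atlas vector length does not match the atlas")
  if (k > ncol(atlas$modes)) stop_invariant("k exceeds the number of atlas modes")
  raw <- drop(crossprod(atlas$modes[, seq_len(k), drop = FALSE], v - atlas$mean))
  sdv <- sqrt(atlas$explained_variance[seq_len(k)])
  s <- ifelse(sdv > 0, raw / pmax(sdv, .Machine$double.eps), 0)
  as.numeric(s)
}

#' Reconstruct an atlas vector from PC scores
#'
#' Inverse of [project_to_scores()] on the retained subspace:
#' `v = mean + sum_i s_i * sd_i * mode_i`.
#'
#' @param atlas a `shape_atlas`.
#' @param s score vector (SD units), length <= number of modes.
#' @return atlas vector of length 6N.
#' @export
reconstruct_from_scores <- function(atlas, s) {
  k <- length(s)
  if (k > ncol(atlas$modes)) stop_invariant("more scores than atlas modes")
  if (k == 0) return(atlas$mean)
  sdv <- sqrt(atlas$explained_variance[seq_len(k)])
  atlas$mean + drop(atlas$modes[, seq_len(k), drop = FALSE] %*% (s * sdv))
}

#' Reconstruct the ED/ES cloud pair at given PC scores
#'
#' @inheritParams reconstruct_from_scores
#' @return list with `surface_cloud`s `ed` and `es`.
#' @export
reconstruct_pair <- function(atlas, s) {
  unflatten_pair(reconstruct_from_scores(atlas, s), atlas$reference)
}

#' Sample a cohort of PC scores
#'
#' Independent standard-normal scores per mode, truncated to
#' `|s| <= truncation` by resampling; deterministic given the seed.
#'
#' @param atlas a `shape_atlas`.
#' @param n cohort size.
#' @param seed integer RNG seed.
#' @param truncation symmetric truncation bound in SD units (default 3).
#' @param k number of modes sampled (default: all).
#' @return list of `n` score vectors.
#' @export
sample_cohort_scores <- function(atlas, n, seed, truncation = 3,
                                 k = ncol(atlas$modes)) {
  if (n < 1) stop_invariant("n must be >= 1")
  if (truncation <= 0)
    stop_invariant("truncation must be > 0 (a zero bound would degenerate every score to 0)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- rnorm(k)
    bad <- abs(s) > truncation
    while (any(bad)) {
      s[bad] <- rnorm(sum(bad))
      bad <- abs(s) > truncation
    }
    out[[i]] <- s
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic atlas-building cohort of template pairs
#'
#' Draws template parameters around the defaults (isotropic scale, semi-axis
#' and wall-thickness jitter, contraction variability) and returns the
#' flattened ED+ES atlas vectors plus the reference cloud.
#'
#' @param n cohort size.
#' @param seed integer RNG seed.
#' @param resolution an [atlas_resolution()].
#' @param base_params a [template_params()] object for the family centre.
#' @param spread multiplier on all jitter SDs (default 1).
#' @return list with `vectors` (list of atlas vectors), `reference`
#'   (`surface_cloud` of the family centre at ED), and `params` (per-member
#'   `template_params`).
#' @export
generate_atlas_cohort <- function(n, seed, resolution = atlas_resolution(),
                                  base_params = template_params(),
                                  spread = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bp <- base_params
  vectors <- vector("list", n)
  params <- vector("list", n)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (i in seq_len(n)) {
    p <- template_params(
      lv_endo_semi_axes = bp$lv_endo_semi_axes * (1 + spread * rnorm(3, 0, 0.04)),
      lv_wall_thickness = bp$lv_wall_thickness * (1 + spread * rnorm(1, 0, 0.08)),
      rv_endo_semi_axes = bp$rv_endo_semi_axes * (1 + spread * rnorm(3, 0, 0.04)),
      rv_center_offset = bp$rv_center_offset * (1 + spread * abs(rnorm(1, 0, 0.03))),
      rv_wall_thickness = bp$rv_wall_thickness * (1 + spread * rnorm(1, 0, 0.08)),
      base_truncation_fraction = clamp(bp$base_truncation_fraction +
                                         spread * rnorm(1, 0, 0.03), 0.3, 0.7),
      global_scale = bp$global_scale * exp(spread * rnorm(1, 0, 0.08)),
      systolic_contraction = clamp(bp$systolic_contraction +
                                     spread * rnorm(1, 0, 0.04), 0.12, 0.5))
    pair <- generate_template_pair(p, resolution)
    vectors[[i]] <- flatten_pair(pair$ed, pair$es)
    params[[i]] <- p
  }
  reference <- generate_template_pair(bp, resolution)$ed
  list(vectors = vectors, reference = reference, params = params)
}
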