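# Mapping FE displacement fields back onto the ordered atlas cloud and
# recovering deformed PC scores. Correspondence is inherited from the
# atlas ordering, never estimated: displacements are interpolated at the
# unloaded cloud coordinates by inverse-distance weighting of the k
# nearest mesh nodes and added to the unloaded cloud, preserving point
# count, ordering and labels.

#' Interpolate nodal displacements onto an ordered point cloud
#'
#' Inverse-distance weighting (power `p`, default 1) of the `k` nearest
#' mesh nodes; a query point coinciding with a node (distance < 1e-9 mm)
#' takes that node's displacement exactly.
#'
#' @param unloaded_cloud a `surface_cloud` in the mesh frame.
#' @param mesh_nodes node coordinate matrix (n x 3).
#' @param u nodal displacement matrix (n x 3).
#' @param k number of neighbours (default 4).
#' @param power inverse-distance exponent.
#' @return a `surface_cloud` with displaced points (same ordering/labels).
#' @export
map_displacements <- function(unloaded_cloud, mesh_nodes, u, k = 4, power = 1) {
  if (nrow(mesh_nodes) == 0) stop_invariant("mesh node set is empty")
  if (nrow(mesh_nodes) != nrow(u))
    stop_invariant("mesh_nodes and u must have matching rows")
  nn <- .knn_bf(as_points(mesh_nodes), as_points(unloaded_cloud$points), as.integer(k))
  d <- nn$dist
  w <- 1 / pmax(d, 1e-12)^power
  exact <- d[, 1] < 1e-9
  if (any(exact)) {
    w[exact, ] <- 0
    w[exact, 1] <- 1
  }
  w <- w / rowSums(w)
  disp <- matrix(0, nrow(unloaded_cloud$points), 3)
  for (j in seq_len(ncol(d)))
    disp <- disp + w[, j] * u[nn$idx[, j], , drop = FALSE]
  out <- unloaded_cloud
  out$points <- unloaded_cloud$points + disp
  out
}

#' Recover deformed PC scores from an ED/ES cloud pair
#'
#' Concatenates the atlas-ordered pair into an atlas vector, projects it
#' onto the atlas and truncates to the first `k` scores.
#'
#' @param atlas a `shape_atlas`.
#' @param ed_cloud,es_cloud atlas-ordered `surface_cloud`s.
#' @param k number of deformed scores (default 5).
#' @return numeric score vector of length `k`.
#' @export
recover_def_scores <- function(atlas, ed_cloud, es_cloud, k = 5) {
  if (!identical(ed_cloud$labels, atlas$labels) ||
      !identical(es_cloud$labels, atlas$labels))
    stop_invariant("cloud ordering/labels do not match the atlas")
  v <- flatten_pair(ed_cloud, es_cloud)
  project_to_scores(atlas, v, k)
}

#' Build the deformed ED/ES pair for one converged simulation
#'
#' Interpolates the ED and ES displacement fields onto the unloaded cloud
#' coordinates and recovers the deformed PC scores.
#'
#' @param atlas a `shape_atlas`.
#' @param unloaded a `surface_cloud` (frame UNLOADED) used to build the mesh.
#' @param prob the [fe_problem()] the solution was computed on.
#' @param solution a converged `mechanics_solution`.
#' @param k number of deformed scores.
#' @param geometry_id,material identifiers carried into the record.
#' @return a `deformed_pair`: `ed_cloud`, `es_cloud`, `def_scores`, `case`,
#'   `geometry_id`, `material`.
#' @export
deformed_pair <- function(atlas, unloaded, prob, solution, k = 5,
                          geometry_id = NA, material = NULL) {
  if (!isTRUE(solution$converged))
    stop_invariant("cannot project a non-converged solution")
  nodes <- prob$p2$nodes_p2
  ed_cloud <- map_displacements(unloaded, nodes, solution$u_ed)
  es_cloud <- map_displacements(unloaded, nodes, solution$u_es)
  ed_cloud$frame <- "ED"; es_cloud$frame <- "ES"
  structure(list(ed_cloud = ed_cloud, es_cloud = es_cloud,
                 def_scores = recover_def_scores(atlas, ed_cloud, es_cloud, k),
                 case = solution$case,
                 cavity_volumes = solution$cavity_volumes,
                 geometry_id = geometry_id,
                 material = material),
            class = "deformed_pair")
}

#' Cohort-level chamber metrics grouped by end-systolic pressure
#'
#' Computes per-case LV (and RV, when present) ED/ES volumes and ejection
#' fractions from the deformed clouds and summarizes them by prescribed
#' LVESP level. Cases with non-positive EDV are flagged, excluded and
#' reported in the `excluded` attribute.
#'
#' @param pairs list of `deformed_pair`s.
#' @return data frame with one row per case (volumes in mL, EF in percent)
#'   plus a `summary` attribute with per-LVESP group means and SDs.
#' @export
cohort_metrics <- function(pairs) {
  if (!length(pairs)) stop_invariant("no deformed pairs supplied")
  rows <- lapply(pairs, function(p) {
    lvedv <- chamber_volume(p$ed_cloud, "LV")
    lvesv <- chamber_volume(p$es_cloud, "LV")
    rvedv <- tryCatch(chamber_volume(p$ed_cloud, "RV"), error = function(e) NA_real_)
    rvesv <- tryCatch(chamber_volume(p$es_cloud, "RV"), error = function(e) NA_real_)
    data.frame(geometry_id = p$geometry_id,
               lvesp = p$case$lvesp, lvedp = p$case$lvedp,
               LV_EDV = lvedv, LV_ESV = lvesv,
               RV_EDV = rvedv, RV_ESV = rvesv,
               LV_EF = 100 * (lvedv - lvesv) / lvedv,
               RV_EF = 100 * (rvedv - rvesv) / rvedv)
  })
  df <- do.call(rbind, rows)
  bad <- df$LV_EDV <= 0
  excluded <- df[bad, , drop = FALSE]
  if (any(bad)) {
    warning(sprintf("%d case(s) with non-positive LV EDV excluded", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  agg_mean <- aggregate(cbind(LV_EDV, LV_ESV, LV_EF) ~ lvesp, df, mean)
  agg_sd <- aggregate(cbind(LV_EDV, LV_ESV, LV_EF) ~ lvesp, df, sd)
  names(agg_sd)[-1] <- paste0(names(agg_sd)[-1], "_sd")
  summary <- merge(agg_mean, agg_sd, by = "lvesp")
  attr(df, "summary") <- summary
  attr(df, "excluded") <- excluded
  df
}
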