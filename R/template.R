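# Synthetic biventricular template family.
#
# The template wall is the region between star-shaped inner and outer
# surfaces built from truncated ellipsoids: the LV cavity is a coaxial
# ellipsoid about the long (z) axis, the RV cavity is a laterally offset
# ellipsoid clipped to lie outside the LV epicardial ellipsoid (so the
# septum is LV wall), and the outer (epicardial) surface is the union of
# the LV epicardial ellipsoid and the RV outer ellipsoid, with the crease
# between them filled radially. One base truncation plane carries all four
# valve rings as labelled circles. Every surface is sampled on a fixed
# (longitude x z-level) grid plus an apex point, so point correspondence
# across shapes is by construction.

SURFACE_LABELS <- c("LV_ENDO", "RV_ENDO", "EPI")
RING_LABELS <- c("MV_RING", "AV_RING", "TV_RING", "PV_RING")
ALL_LABELS <- c(SURFACE_LABELS, RING_LABELS)

#' Template parameters for the synthetic biventricular shape family
#'
#' Defaults are adult-scale (millimetres) and give a left-ventricular
#' end-diastolic volume near 110 mL with an ejection fraction around 55%
#' for the paired end-systolic shape.
#'
#' @param lv_endo_semi_axes LV endocardial ellipsoid semi-axes (x, y, z), mm.
#' @param lv_wall_thickness LV wall thickness, mm (added to all semi-axes).
#' @param rv_endo_semi_axes RV endocardial ellipsoid semi-axes, mm.
#' @param rv_center_offset lateral (+x) offset of the RV cavity centre, mm.
#' @param rv_wall_thickness RV free wall thickness, mm.
#' @param base_truncation_fraction base plane height as a fraction of the LV
#'   endocardial long semi-axis, in `[0.2, 0.8)`.
#' @param global_scale overall isotropic scale factor (> 0).
#' @param systolic_contraction fractional radial cavity reduction defining
#'   the paired end-systolic shape, in `[0, 1)`.
#' @return an object of class `template_params`.
#' @export
template_params <- function(lv_endo_semi_axes = c(25, 25, 50),
                            lv_wall_thickness = 10,
                            rv_endo_semi_axes = c(26, 22, 44),
                            rv_center_offset = 42,
                            rv_wall_thickness = 9,
                            base_truncation_fraction = 0.5,
                            global_scale = 1,
                            systolic_contraction = 0.3) {
  p <- list(lv_endo_semi_axes = as.numeric(lv_endo_semi_axes),
            lv_wall_thickness = as.numeric(lv_wall_thickness),
            rv_endo_semi_axes = as.numeric(rv_endo_semi_axes),
            rv_center_offset = as.numeric(rv_center_offset),
            rv_wall_thickness = as.numeric(rv_wall_thickness),
            base_truncation_fraction = as.numeric(base_truncation_fraction),
            global_scale = as.numeric(global_scale),
            systolic_contraction = as.numeric(systolic_contraction))
  class(p) <- "template_params"
  validate_template_params(p)
  p
}

validate_template_params <- function(p) {
  if (any(p$lv_endo_semi_axes <= 0) || any(p$rv_endo_semi_axes <= 0))
    stop_invariant("invalid template: all semi-axes must be > 0")
  if (p$lv_wall_thickness <= 0 || p$rv_wall_thickness <= 0)
    stop_invariant("invalid template: wall thicknesses must be > 0")
  if (p$lv_wall_thickness >= min(p$lv_endo_semi_axes))
    stop_invariant("invalid template: lv_wall_thickness must be smaller than the smallest LV endocardial semi-axis")
  if (p$rv_wall_thickness >= min(p$rv_endo_semi_axes))
    stop_invariant("invalid template: rv_wall_thickness must be smaller than the smallest RV endocardial semi-axis")
  if (p$base_truncation_fraction < 0.2 || p$base_truncation_fraction >= 0.8)
    stop_invariant("invalid template: base_truncation_fraction must lie in [0.2, 0.8)")
  if (p$global_scale <= 0)
    stop_invariant("invalid template: global_scale must be > 0")
  if (p$systolic_contraction < 0 || p$systolic_contraction >= 1)
    stop_invariant("invalid template: systolic_contraction must lie in [0, 1)")
  # the RV cavity centre must sit outside the LV epicardial ellipsoid so the
  # clipped cavity stays star-shaped about its own axis (and outside the LV)
  epi_a <- p$lv_endo_semi_axes[1] + p$lv_wall_thickness
  if (p$rv_center_offset <= epi_a)
    stop_invariant("invalid template: rv_center_offset must exceed the LV epicardial x semi-axis (RV cavity would intersect the LV wall)")
  invisible(p)
}

#' Surface sampling resolution of an atlas specification
#'
#' Point counts are frozen per atlas: every cloud generated under the same
#' resolution has identical length, ordering and labels.
#'
#' @param lv_endo,epi,rv_endo integer vectors `c(n_theta, n_z)` per surface.
#' @param n_ring points per valve ring.
#' @return an object of class `atlas_resolution`.
#' @export
atlas_resolution <- function(lv_endo = c(24, 14), epi = c(28, 16),
                             rv_endo = c(20, 12), n_ring = 16) {
  r <- list(LV_ENDO = as.integer(lv_endo), EPI = as.integer(epi),
            RV_ENDO = as.integer(rv_endo), n_ring = as.integer(n_ring))
  if (any(unlist(r) < 3)) stop_invariant("resolution entries must be >= 3")
  class(r) <- "atlas_resolution"
  r
}

# index layout: LV_ENDO, RV_ENDO, EPI (apex point then z-row-major grid),
# then rings MV, AV, TV, PV
cloud_layout <- function(resolution) {
  idx <- list(); at <- 0L
  for (s in c("LV_ENDO", "RV_ENDO", "EPI")) {
    n <- 1L + resolution[[s]][1] * resolution[[s]][2]
    idx[[s]] <- seq.int(at + 1L, at + n); at <- at + n
  }
  for (rg in RING_LABELS) {
    idx[[rg]] <- seq.int(at + 1L, at + resolution$n_ring)
    at <- at + resolution$n_ring
  }
  attr(idx, "n_points") <- at
  idx
}

new_surface_cloud <- function(points, labels, frame, spec) {
  structure(list(points = points, labels = labels, frame = frame, spec = spec),
            class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("surface_cloud: %d points, frame %s\n", nrow(x$points), x$frame))
  print(table(x$labels))
  invisible(x)
}

# ---- closed-form slice radii of the template ----

ellipse_polar_radius <- function(theta, A, B) {
  1 / sqrt((cos(theta) / A)^2 + (sin(theta) / B)^2)
}

# largest / smallest positive ray parameter from axis point (px, py) along
# (cos theta, sin theta) to the ellipse centred at (ex, ey), semi-axes A, B;
# NA when the ray misses
ray_ellipse <- function(theta, px, py, ex, ey, A, B, which = c("max", "min")) {
  which <- match.arg(which)
  cth <- cos(theta); sth <- sin(theta)
  u <- (px - ex) / A; v <- (py - ey) / B
  a2 <- (cth / A)^2 + (sth / B)^2
  b2 <- 2 * (u * cth / A + v * sth / B)
  c2 <- u^2 + v^2 - 1
  disc <- b2^2 - 4 * a2 * c2
  out <- rep(NA_real_, length(theta))
  ok <- disc >= 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-b2[ok] - sq) / (2 * a2[ok])
    t2 <- (-b2[ok] + sq) / (2 * a2[ok])
    val <- if (which == "max") t2 else t1
    val[val <= 0] <- NA_real_
    out[ok] <- val
  }
  out
}

ell_slice <- function(z, semi) {
  # in-plane semi-axes of an ellipsoid slice at height z (centre z = 0)
  f <- 1 - (z / semi[3])^2
  f[f < 0] <- NA_real_
  list(A = semi[1] * sqrt(f), B = semi[2] * sqrt(f))
}

# radius functions of the three wall surfaces, all at ED, for a template
template_radius_funs <- function(p) {
  s <- p$global_scale
  lv <- p$lv_endo_semi_axes * s
  epi <- (p$lv_endo_semi_axes + p$lv_wall_thickness) * s
  rvi <- p$rv_endo_semi_axes * s
  rvo <- (p$rv_endo_semi_axes + p$rv_wall_thickness) * s
  x0 <- p$rv_center_offset * s
  list(
    lv_endo = function(theta, z) {
      sl <- ell_slice(z, lv)
      ellipse_polar_radius(theta, sl$A, sl$B)
    },
    rv_endo = function(theta, z) {
      sl <- ell_slice(z, rvi)
      r <- ellipse_polar_radius(theta, sl$A, sl$B)
      se <- ell_slice(z, epi)
      if (!is.na(se$A)) {
        hit <- ray_ellipse(theta, x0, 0, 0, 0, se$A, se$B, "min")
        r <- pmin(r, hit, na.rm = TRUE)
      }
      r
    },
    epi = function(theta, z) {
      se <- ell_slice(z, epi)
      r1 <- if (is.na(se$A)) rep(NA_real_, length(theta)) else
        ellipse_polar_radius(theta, se$A, se$B)
      so <- ell_slice(z, rvo)
      r2 <- if (is.na(so$A)) rep(NA_real_, length(theta)) else
        ray_ellipse(theta, 0, 0, x0, 0, so$A, so$B, "max")
      r1[is.na(r1)] <- 0; r2[is.na(r2)] <- 0
      # smooth p-norm union: pads the concave crease between the LV
      # ellipsoid and the RV bulge (the epicardial fat-pad region), which
      # keeps the wall thickness bounded away from zero at the junction
      out <- (r1^8 + r2^8)^(1 / 8)
      out[out <= 0] <- NA_real_
      out
    },
    z_apex = c(lv_endo = -lv[3], rv_endo = -rvi[3], epi = -epi[3]),
    z_base = p$base_truncation_fraction * lv[3],
    rv_axis = c(x0, 0),
    lv_axis = c(0, 0)
  )
}

# cosine-spaced z rows from just above the apex up to the base plane
surface_z_rows <- function(z_apex, z_base, nz) {
  sfrac <- (1 - cos(pi * seq_len(nz) / nz)) / 2
  s0 <- (1 - cos(pi * 0.45 / nz)) / 2 # first row off the apex
  sfrac <- s0 + (1 - s0) * (sfrac - sfrac[1]) / (1 - sfrac[1])
  z_apex + sfrac * (z_base - z_apex)
}

make_star_surface <- function(radius_fun, axis, z_apex, z_base, n_theta, n_z) {
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  zs <- surface_z_rows(z_apex, z_base, n_z)
  pts <- matrix(0, 1 + n_theta * n_z, 3)
  pts[1, ] <- c(axis[1], axis[2], z_apex)
  row <- 2L
  for (j in seq_len(n_z)) {
    r <- radius_fun(theta, zs[j])
    r[is.na(r)] <- 0
    pts[row:(row + n_theta - 1L), ] <-
      cbind(axis[1] + r * cos(theta), axis[2] + r * sin(theta), zs[j])
    row <- row + n_theta
  }
  pts
}

ring_circle <- function(center, radius, z, n) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), rep(z, n))
}

#' Generate the paired ED/ES surface point clouds of a template
#'
#' The end-systolic cloud is derived from the end-diastolic one by a
#' fractional radial contraction of both cavities about their own axes,
#' an epicardial radial reduction that approximately conserves wall area
#' per horizontal slice (incompressible wall-thickening heuristic), and a
#' mild longitudinal shortening towards the fixed base plane. Point count,
#' ordering and labels are identical between the two frames.
#'
#' @param params a [template_params()] object.
#' @param resolution an [atlas_resolution()] object.
#' @return list with elements `ed` and `es`, both `surface_cloud`s.
#' @export
generate_template_pair <- function(params = template_params(),
                                   resolution = atlas_resolution()) {
  validate_template_params(params)
  rf <- template_radius_funs(params)
  layout <- cloud_layout(resolution)
  n <- attr(layout, "n_points")
  pts <- matrix(0, n, 3)
  labels <- character(n)

  surf_args <- list(
    LV_ENDO = list(fun = rf$lv_endo, axis = rf$lv_axis, z_apex = rf$z_apex[["lv_endo"]]),
    RV_ENDO = list(fun = rf$rv_endo, axis = rf$rv_axis, z_apex = rf$z_apex[["rv_endo"]]),
    EPI     = list(fun = rf$epi,     axis = rf$lv_axis, z_apex = rf$z_apex[["epi"]]))
  for (s in names(surf_args)) {
    a <- surf_args[[s]]
    pts[layout[[s]], ] <- make_star_surface(a$fun, a$axis, a$z_apex, rf$z_base,
                                            resolution[[s]][1], resolution[[s]][2])
    labels[layout[[s]]] <- s
  }

  # valve rings on the base plane; radii tied to the cavity rims
  r_lv_rim <- mean(rf$lv_endo(2 * pi * (0:31) / 32, rf$z_base * 0.999))
  r_rv_rim <- mean(rf$rv_endo(2 * pi * (0:31) / 32, rf$z_base * 0.999), na.rm = TRUE)
  ring_spec <- list(
    MV_RING = list(center = c(-0.15, 0) * r_lv_rim, radius = 0.72 * r_lv_rim, axis = rf$lv_axis),
    AV_RING = list(center = c(0, 0.62) * r_lv_rim, radius = 0.26 * r_lv_rim, axis = rf$lv_axis),
    TV_RING = list(center = rf$rv_axis + c(-0.10, 0) * r_rv_rim, radius = 0.68 * r_rv_rim, axis = rf$rv_axis),
    PV_RING = list(center = rf$rv_axis + c(0, 0.62) * r_rv_rim, radius = 0.24 * r_rv_rim, axis = rf$rv_axis))
  for (rg in RING_LABELS) {
    sp <- ring_spec[[rg]]
    pts[layout[[rg]], ] <- ring_circle(sp$center, sp$radius, rf$z_base, resolution$n_ring)
    labels[layout[[rg]]] <- rg
  }

  spec <- list(resolution = resolution, layout = layout,
               axes = list(LV_ENDO = rf$lv_axis, RV_ENDO = rf$rv_axis, EPI = rf$lv_axis),
               ring_axes = lapply(ring_spec, `[[`, "axis"),
               z_base = rf$z_base,
               z_apex = c(LV_ENDO = rf$z_apex[["lv_endo"]],
                          RV_ENDO = rf$z_apex[["rv_endo"]],
                          EPI = rf$z_apex[["epi"]]))
  ed <- new_surface_cloud(pts, factor(labels, levels = ALL_LABELS), "ED", spec)
  es <- contract_cloud(ed, params$systolic_contraction)
  list(ed = ed, es = es)
}

# radial cavity contraction + slice-area-conserving epicardial reduction +
# longitudinal shortening (base plane fixed)
contract_cloud <- function(ed, ct) {
  if (ct == 0) {
    es <- ed; es$frame <- "ES"
    return(es)
  }
  spec <- ed$spec
  pts <- ed$points
  lay <- spec$layout

  scale_about <- function(idx, axis, f) {
    pts[idx, 1] <<- axis[1] + (pts[idx, 1] - axis[1]) * f
    pts[idx, 2] <<- axis[2] + (pts[idx, 2] - axis[2]) * f
  }

  # mean squared cavity slice radius per z, before/after contraction
  cav_area <- function(lbl) {
    g <- star_grid(ed, lbl)
    zr <- rowMeans(g$z)
    a_ed <- pi * rowMeans(g$rho^2)
    list(z = zr, dA = a_ed * (1 - (1 - ct)^2))
  }
  lv_a <- cav_area("LV_ENDO"); rv_a <- cav_area("RV_ENDO")

  scale_about(lay$LV_ENDO, spec$axes$LV_ENDO, 1 - ct)
  scale_about(lay$RV_ENDO, spec$axes$RV_ENDO, 1 - ct)

  # epicardium: shrink each slice so slice wall area is approximately conserved
  g_epi <- star_grid(ed, "EPI")
  z_epi <- rowMeans(g_epi$z)
  a_epi <- pi * rowMeans(g_epi$rho^2)
  interp0 <- function(xq, x, y) {
    out <- approx(x, y, xout = xq, rule = 1)$y
    out[is.na(out)] <- 0
    out
  }
  dA <- interp0(z_epi, lv_a$z, lv_a$dA) + interp0(z_epi, rv_a$z, rv_a$dA)
  fac <- sqrt(pmax(0.25, 1 - dA / a_epi))
  n_theta <- spec$resolution$EPI[1]
  epi_idx <- lay$EPI[-1]
  fac_pt <- rep(fac, each = n_theta)
  ax <- spec$axes$EPI
  pts[epi_idx, 1] <- ax[1] + (pts[epi_idx, 1] - ax[1]) * fac_pt
  pts[epi_idx, 2] <- ax[2] + (pts[epi_idx, 2] - ax[2]) * fac_pt

  for (rg in RING_LABELS) scale_about(lay[[rg]], spec$ring_axes[[rg]], 1 - ct)

  # longitudinal shortening about the (fixed) base plane; rings stay put
  ls <- 0.45 * ct
  surf_idx <- c(lay$LV_ENDO, lay$RV_ENDO, lay$EPI)
  pts[surf_idx, 3] <- spec$z_base - (spec$z_base - pts[surf_idx, 3]) * (1 - ls)

  new_surface_cloud(pts, ed$labels, "ES", spec)
}

# ---- star-grid extraction and radius interpolation ----

# rho/z grids (n_z x n_theta) of one labelled surface of a cloud
star_grid <- function(cloud, surface) {
  spec <- cloud$spec
  res <- spec$resolution[[surface]]
  idx <- spec$layout[[surface]]
  axis <- spec$axes[[surface]]
  apex <- cloud$points[idx[1], ]
  grid_pts <- cloud$points[idx[-1], , drop = FALSE]
  n_theta <- res[1]; n_z <- res[2]
  rho <- matrix(sqrt((grid_pts[, 1] - axis[1])^2 + (grid_pts[, 2] - axis[2])^2),
                n_z, n_theta, byrow = TRUE)
  z <- matrix(grid_pts[, 3], n_z, n_theta, byrow = TRUE)
  list(rho = rho, z = z, axis = axis, apex_z = apex[3],
       n_theta = n_theta, n_z = n_z)
}

# vectorized surface radius at query angles/heights (nominal uniform theta
# columns; linear in z between row means, tapering to zero at the apex)
star_radius_at <- function(grid, theta, z) {
  n_theta <- grid$n_theta
  th <- theta %% (2 * pi)
  step <- 2 * pi / n_theta
  i0 <- floor(th / step)
  tw <- th / step - i0
  i0 <- (i0 %% n_theta) + 1L
  i1 <- (i0 %% n_theta) + 1L
  zbar <- rowMeans(grid$z)
  if (is.unsorted(zbar)) {
    # strongly extrapolated shapes can disorder rows locally; interpolate
    # on the sorted row order
    ord <- order(zbar)
    zbar <- zbar[ord]
    grid$rho <- grid$rho[ord, , drop = FALSE]
  }
  j <- findInterval(z, zbar)
  n_z <- grid$n_z
  out <- numeric(length(z))

  low <- j < 1L
  if (any(low)) { # apex cone: radius tapers linearly to 0 at the apex
    f <- (z[low] - grid$apex_z) / (zbar[1] - grid$apex_z)
    f[f < 0] <- 0
    r1 <- grid$rho[cbind(1L, i0[low])] * (1 - tw[low]) +
      grid$rho[cbind(1L, i1[low])] * tw[low]
    out[low] <- r1 * f
  }
  high <- j >= n_z
  if (any(high)) {
    out[high] <- grid$rho[cbind(n_z, i0[high])] * (1 - tw[high]) +
      grid$rho[cbind(n_z, i1[high])] * tw[high]
  }
  mid <- !(low | high)
  if (any(mid)) {
    jm <- j[mid]
    zw <- (z[mid] - zbar[jm]) / (zbar[jm + 1L] - zbar[jm])
    ra <- grid$rho[cbind(jm, i0[mid])] * (1 - tw[mid]) + grid$rho[cbind(jm, i1[mid])] * tw[mid]
    rb <- grid$rho[cbind(jm + 1L, i0[mid])] * (1 - tw[mid]) + grid$rho[cbind(jm + 1L, i1[mid])] * tw[mid]
    out[mid] <- ra * (1 - zw) + rb * zw
  }
  out
}

# ---- chamber volumes ----

star_surface_triangles <- function(n_theta, n_z) {
  # triangle vertex indices (local to the surface block: 1 = apex,
  # 2..(1+n_theta*n_z) = grid, z-row-major)
  tri <- matrix(0L, n_theta + 2 * n_theta * (n_z - 1), 3)
  at <- 0L
  g <- function(j, i) 1L + (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  for (i in seq_len(n_theta)) {
    at <- at + 1L
    tri[at, ] <- c(1L, g(1L, i + 1L), g(1L, i))
  }
  for (j in seq_len(n_z - 1L)) {
    for (i in seq_len(n_theta)) {
      a <- g(j, i); b <- g(j, i + 1L); cc <- g(j + 1L, i); d <- g(j + 1L, i + 1L)
      tri[at + 1L, ] <- c(a, b, d)
      tri[at + 2L, ] <- c(a, d, cc)
      at <- at + 2L
    }
  }
  tri
}

closed_cavity_triangles <- function(cloud, surface) {
  res <- cloud$spec$resolution[[surface]]
  idx <- cloud$spec$layout[[surface]]
  tri <- star_surface_triangles(res[1], res[2])
  pts <- cloud$points[idx, , drop = FALSE]
  # cap: fan from the rim-row centroid
  rim <- (1L + (res[2] - 1L) * res[1] + 1L):(1L + res[2] * res[1])
  centroid <- colMeans(pts[rim, , drop = FALSE])
  pts <- rbind(pts, centroid)
  cid <- nrow(pts)
  cap <- cbind(rim, c(rim[-1], rim[1]), rep(cid, length(rim)))
  list(points = pts, tri = rbind(tri, cap))
}

#' Cavity volume of a labelled chamber from a surface point cloud
#'
#' Closes the endocardial surface with a fan-triangulated cap from the rim
#' centroid on the base plane and evaluates the divergence theorem over the
#' closed triangulation.
#'
#' @param cloud a `surface_cloud`.
#' @param chamber `"LV"` or `"RV"`.
#' @return cavity volume in mL.
#' @export
chamber_volume <- function(cloud, chamber = c("LV", "RV")) {
  chamber <- match.arg(chamber)
  surface <- paste0(chamber, "_ENDO")
  if (!any(cloud$labels == surface))
    stop_invariant(sprintf("open surface: no %s points in cloud", surface))
  ct <- closed_cavity_triangles(cloud, surface)
  v <- triangulation_volume(ct$points, ct$tri)
  if (v < 1e-9)
    stop_invariant("degenerate surface: enclosed volume is zero (coplanar points?)")
  v / 1000 # mm^3 -> mL
}

triangulation_volume <- function(points, tri) {
  p1 <- points[tri[, 1], , drop = FALSE]
  p2 <- points[tri[, 2], , drop = FALSE]
  p3 <- points[tri[, 3], , drop = FALSE]
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  abs(sum(p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz) / 6)
}
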