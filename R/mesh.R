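# Tetrahedral meshing.
#
# Structured generators (boxes, spherical shells, cylinder annuli) serve the
# verification problems. Anatomical wall meshes are built from the ordered
# surface cloud by an implicit-domain approach: a Cartesian lattice is split
# into tetrahedra (Kuhn subdivision, conforming across cells), elements are
# kept when their centroid lies inside the wall -- tested against the
# star-shaped surface radius functions interpolated from the cloud grids --
# and boundary vertices are then snapped onto the nearest surface with an
# inversion guard.

new_tet_mesh <- function(nodes, tets, char_length = NA_real_, z_base = NA_real_) {
  v6 <- tet_signed_volumes(nodes, tets)
  flip <- v6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  m <- structure(list(nodes = nodes, tets = tets,
                      char_length = char_length, z_base = z_base),
                 class = "tet_mesh")
  bf <- boundary_faces(m)
  m$faces <- bf$faces
  m$face_owner <- bf$owner
  m$face_tags <- rep(NA_character_, nrow(bf$faces))
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d boundary facets, volume %.2f mL\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$faces), mesh_volume(x) / 1000))
  if (!all(is.na(x$face_tags))) print(table(x$face_tags, useNA = "ifany"))
  invisible(x)
}

tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
}

#' Total mesh volume
#' @param mesh a `tet_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(abs(tet_signed_volumes(mesh$nodes, mesh$tets))) / 6

boundary_faces <- function(mesh) {
  tets <- mesh$tets
  nt <- nrow(tets)
  # local faces opposite each vertex
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
             tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  owner <- rep(seq_len(nt), 4)
  s1 <- pmin(f[, 1], f[, 2], f[, 3])
  s3 <- pmax(f[, 1], f[, 2], f[, 3])
  s2 <- f[, 1] + f[, 2] + f[, 3] - s1 - s3
  nv <- nrow(mesh$nodes)
  key <- (s1 - 1) * nv * nv + (s2 - 1) * nv + s3
  ord <- order(key)
  ks <- key[ord]
  n <- length(ks)
  dup <- c(ks[-1] == ks[-n], FALSE) | c(FALSE, ks[-1] == ks[-n])
  keep <- logical(n)
  keep[ord] <- !dup
  faces <- f[keep, , drop = FALSE]
  owner <- owner[keep]
  # orient outward: normal . (centroid_opposite - p1) < 0
  p1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  n <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
             (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
             (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  cen <- (mesh$nodes[mesh$tets[owner, 1], , drop = FALSE] +
            mesh$nodes[mesh$tets[owner, 2], , drop = FALSE] +
            mesh$nodes[mesh$tets[owner, 3], , drop = FALSE] +
            mesh$nodes[mesh$tets[owner, 4], , drop = FALSE]) / 4
  inward <- rowSums(n * (cen - p1)) > 0
  faces[inward, c(2, 3)] <- faces[inward, c(3, 2)]
  list(faces = faces, owner = owner)
}

# ---- structured generators (verification meshes) ----

lattice_tets <- function(nx, ny, nz) {
  vid <- function(i, j, k) (k - 1L) * (nx + 1L) * (ny + 1L) + (j - 1L) * (nx + 1L) + i
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  c000 <- vid(cells$i, cells$j, cells$k)
  dx <- 1L; dy <- nx + 1L; dz <- (nx + 1L) * (ny + 1L)
  corner <- function(bx, by, bz) c000 + bx * dx + by * dy + bz * dz
  v <- list(corner(0,0,0), corner(1,0,0), corner(0,1,0), corner(1,1,0),
            corner(0,0,1), corner(1,0,1), corner(0,1,1), corner(1,1,1))
  names(v) <- c("000","100","010","110","001","101","011","111")
  paths <- list(c("100","110"), c("100","101"), c("010","110"),
                c("010","011"), c("001","101"), c("001","011"))
  tets <- do.call(rbind, lapply(paths, function(p)
    cbind(v[["000"]], v[[p[1]]], v[[p[2]]], v[["111"]])))
  storage.mode(tets) <- "integer"
  tets
}

#' Structured tetrahedral box mesh
#'
#' @param lx,ly,lz box edge lengths, mm.
#' @param nx,ny,nz cells per direction.
#' @return a `tet_mesh`.
#' @export
tet_box_mesh <- function(lx = 1, ly = 1, lz = 1, nx = 1, ny = 1, nz = 1) {
  g <- expand.grid(x = seq(0, lx, length.out = nx + 1),
                   y = seq(0, ly, length.out = ny + 1),
                   z = seq(0, lz, length.out = nz + 1))
  nodes <- as.matrix(g[, c("x", "y", "z")])
  dimnames(nodes) <- NULL
  new_tet_mesh(nodes, lattice_tets(nx, ny, nz), char_length = lx / nx)
}

#' Structured spherical-shell mesh (polar band)
#'
#' A band between two concentric spheres, excluding the poles; useful for
#' harmonic-profile verification.
#'
#' @param r_inner,r_outer shell radii, mm.
#' @param n_r,n_theta,n_phi cells radially, azimuthally and in latitude.
#' @param phi_range latitude limits (radians from the north pole).
#' @return a `tet_mesh`; attribute `r` gives nodal radii.
#' @export
tet_shell_mesh <- function(r_inner = 10, r_outer = 20, n_r = 4,
                           n_theta = 16, n_phi = 6,
                           phi_range = c(0.5, pi - 0.5)) {
  rs <- seq(r_inner, r_outer, length.out = n_r + 1)
  ths <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  phs <- seq(phi_range[1], phi_range[2], length.out = n_phi + 1)
  # lattice in (theta, phi, r); theta wraps
  vid <- function(i, j, k) (k - 1L) * n_theta * (n_phi + 1L) + (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  nodes <- matrix(0, n_theta * (n_phi + 1) * (n_r + 1), 3)
  for (k in seq_len(n_r + 1)) for (j in seq_len(n_phi + 1)) for (i in seq_len(n_theta)) {
    nodes[vid(i, j, k), ] <- rs[k] * c(sin(phs[j]) * cos(ths[i]),
                                       sin(phs[j]) * sin(ths[i]), cos(phs[j]))
  }
  cells <- expand.grid(i = seq_len(n_theta), j = seq_len(n_phi), k = seq_len(n_r))
  v <- list()
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1)
    v[[paste0(bx, by, bz)]] <- vid(cells$i + bx, cells$j + by, cells$k + bz)
  paths <- list(c("100","110"), c("100","101"), c("010","110"),
                c("010","011"), c("001","101"), c("001","011"))
  tets <- do.call(rbind, lapply(paths, function(p)
    cbind(v[["000"]], v[[p[1]]], v[[p[2]]], v[["111"]])))
  storage.mode(tets) <- "integer"
  m <- new_tet_mesh(nodes, tets, char_length = (r_outer - r_inner) / n_r)
  attr(m, "r") <- sqrt(rowSums(nodes^2))
  m
}

#' Structured cylinder-annulus mesh
#'
#' @param r_inner,r_outer annulus radii, mm.
#' @param height cylinder height, mm.
#' @param n_r,n_theta,n_z cells per direction.
#' @return a `tet_mesh`.
#' @export
tet_annulus_mesh <- function(r_inner = 10, r_outer = 15, height = 20,
                             n_r = 2, n_theta = 16, n_z = 4) {
  rs <- seq(r_inner, r_outer, length.out = n_r + 1)
  ths <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, height, length.out = n_z + 1)
  vid <- function(i, j, k) (k - 1L) * n_theta * (n_r + 1L) + (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  nodes <- matrix(0, n_theta * (n_r + 1) * (n_z + 1), 3)
  for (k in seq_len(n_z + 1)) for (j in seq_len(n_r + 1)) for (i in seq_len(n_theta))
    nodes[vid(i, j, k), ] <- c(rs[j] * cos(ths[i]), rs[j] * sin(ths[i]), zs[k])
  cells <- expand.grid(i = seq_len(n_theta), j = seq_len(n_r), k = seq_len(n_z))
  v <- list()
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1)
    v[[paste0(bx, by, bz)]] <- vid(cells$i + bx, cells$j + by, cells$k + bz)
  paths <- list(c("100","110"), c("100","101"), c("010","110"),
                c("010","011"), c("001","101"), c("001","011"))
  tets <- do.call(rbind, lapply(paths, function(p)
    cbind(v[["000"]], v[[p[1]]], v[[p[2]]], v[["111"]])))
  storage.mode(tets) <- "integer"
  new_tet_mesh(nodes, tets, char_length = (r_outer - r_inner) / n_r)
}

# ---- implicit wall membership from a surface cloud ----

wall_geometry <- function(cloud, min_rv_wall = 0) {
  spec <- cloud$spec
  has_rv <- "RV_ENDO" %in% names(spec$layout) &&
    any(cloud$labels == "RV_ENDO")
  geom <- list(g_lv = star_grid(cloud, "LV_ENDO"),
               g_epi = star_grid(cloud, "EPI"),
               g_rv = if (has_rv) star_grid(cloud, "RV_ENDO") else NULL,
               z_base = max(cloud$points[, 3]))
  if (has_rv && min_rv_wall > 0) {
    # guard the RV free wall: clip the cavity radius so it stays at least
    # min_rv_wall inside the epicardial surface (strongly extrapolated
    # shapes can otherwise pinch the wall to a membrane at the junction)
    g <- geom$g_rv
    nz <- g$n_z; nth <- g$n_theta
    th <- rep(2 * pi * (seq_len(nth) - 1) / nth, each = nz)
    zq <- as.vector(g$z)
    lo <- numeric(length(th))
    hi <- rep(2 * max(geom$g_epi$rho) + abs(g$axis[1]) + abs(g$axis[2]), length(th))
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      px <- g$axis[1] + mid * cos(th)
      py <- g$axis[2] + mid * sin(th)
      th_lv <- atan2(py - geom$g_epi$axis[2], px - geom$g_epi$axis[1])
      rho_lv <- sqrt((px - geom$g_epi$axis[1])^2 + (py - geom$g_epi$axis[2])^2)
      inside <- rho_lv <= star_radius_at(geom$g_epi, th_lv, zq)
      lo[inside] <- mid[inside]
      hi[!inside] <- mid[!inside]
    }
    r_epi_ray <- matrix(lo, nz, nth)
    geom$g_rv$rho <- pmin(g$rho, pmax(r_epi_ray - min_rv_wall, 0.2 * g$rho))
  }
  geom
}

wall_signed_depths <- function(geom, pts) {
  # positive = inside the wall for every component
  th_lv <- atan2(pts[, 2] - geom$g_lv$axis[2], pts[, 1] - geom$g_lv$axis[1])
  rho_lv <- sqrt((pts[, 1] - geom$g_lv$axis[1])^2 + (pts[, 2] - geom$g_lv$axis[2])^2)
  z <- pts[, 3]
  d_epi <- star_radius_at(geom$g_epi, th_lv, z) - rho_lv
  d_lv <- rho_lv - star_radius_at(geom$g_lv, th_lv, z)
  d_base <- geom$z_base - z
  out <- list(epi = d_epi, lv = d_lv, base = d_base,
              theta_lv = th_lv, rho_lv = rho_lv)
  if (!is.null(geom$g_rv)) {
    th_rv <- atan2(pts[, 2] - geom$g_rv$axis[2], pts[, 1] - geom$g_rv$axis[1])
    rho_rv <- sqrt((pts[, 1] - geom$g_rv$axis[1])^2 + (pts[, 2] - geom$g_rv$axis[2])^2)
    out$rv <- rho_rv - star_radius_at(geom$g_rv, th_rv, z)
    out$theta_rv <- th_rv; out$rho_rv <- rho_rv
  }
  out
}

inside_wall <- function(geom, pts) {
  d <- wall_signed_depths(geom, pts)
  ok <- d$epi > 0 & d$lv > 0 & d$base > 0
  if (!is.null(d$rv)) ok <- ok & d$rv > 0
  ok
}

#' Tetrahedral wall mesh from an ordered surface cloud
#'
#' Builds a conforming tetrahedral mesh of the wall volume enclosed by the
#' labelled surfaces: Cartesian lattice cells are split into tetrahedra,
#' kept when the element centroid is inside the wall, and boundary vertices
#' are snapped onto the nearest surface (base plane or radial surfaces)
#' with a guard against element inversion. Boundary facets are tagged
#' `LV_ENDO`, `RV_ENDO`, `EPI`, valve-ring tags (`MV`, `AV`, `TV`, `PV`,
#' for base facets adjacent to a ring circle) or `BASE`.
#'
#' @param cloud a `surface_cloud` (typically the unloaded frame).
#' @param char_length target element characteristic length, mm.
#' @return a `tet_mesh` with tagged boundary facets.
#' @export
mesh_from_surfaces <- function(cloud, char_length = 5.0) {
  if (char_length <= 0) stop_invariant("char_length must be > 0")
  geom <- wall_geometry(cloud, min_rv_wall = 0.5 * char_length)
  h <- char_length
  # anchor the lattice to the LV axis and the base plane so that the
  # discretization is consistently phased across geometries of one family
  anchor <- c(geom$g_lv$axis, geom$z_base)
  lo <- apply(cloud$points, 2, min) - 0.6 * h
  hi <- apply(cloud$points, 2, max) + 0.6 * h
  hi[3] <- geom$z_base
  lo <- anchor - h * ceiling((anchor - lo) / h)
  hi <- anchor + h * ceiling((hi - anchor) / h)
  hi[3] <- geom$z_base
  nxyz <- pmax(2L, as.integer(round((hi - lo) / h)))
  xs <- seq(lo[1], hi[1], length.out = nxyz[1] + 1)
  ys <- seq(lo[2], hi[2], length.out = nxyz[2] + 1)
  zs <- seq(lo[3], hi[3], length.out = nxyz[3] + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  # warp lattice vertices near a surface onto it before element selection
  # (avoids sliver elements: the surface then passes through lattice nodes)
  nodes <- warp_to_surfaces(nodes, geom, 0.45 * h)
  tets <- lattice_tets(nxyz[1], nxyz[2], nxyz[3])

  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  keep <- inside_wall(geom, cen)
  tets <- tets[keep, , drop = FALSE]
  if (nrow(tets) == 0)
    stop_invariant("meshing failed: no lattice element centroid fell inside the wall (char_length too large?)")
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4)

  m <- new_tet_mesh(nodes, tets, char_length = h, z_base = geom$z_base)
  m <- snap_boundary(m, geom)
  m <- tag_boundary(m, geom, cloud)
  check_mesh(m)
  m
}

surface_projection <- function(geom, pts, d, which) {
  # move each point onto the named surface (base plane or radial surface)
  out <- pts
  for (w in unique(which)) {
    ii <- which == w
    if (!any(ii)) next
    if (w == "base") {
      out[ii, 3] <- geom$z_base
    } else {
      g <- switch(w, epi = geom$g_epi, lv = geom$g_lv, rv = geom$g_rv)
      th <- if (w == "rv") d$theta_rv[ii] else d$theta_lv[ii]
      rho <- if (w == "rv") d$rho_rv[ii] else d$rho_lv[ii]
      r <- star_radius_at(g, th, pts[ii, 3])
      f <- ifelse(rho > 1e-9 & r > 0, r / rho, 1)
      out[ii, 1] <- g$axis[1] + (pts[ii, 1] - g$axis[1]) * f
      out[ii, 2] <- g$axis[2] + (pts[ii, 2] - g$axis[2]) * f
    }
  }
  out
}

warp_to_surfaces <- function(nodes, geom, band) {
  d <- wall_signed_depths(geom, nodes)
  cand <- cbind(base = abs(d$base), epi = abs(d$epi), lv = abs(d$lv),
                rv = if (is.null(d$rv)) rep(Inf, nrow(nodes)) else abs(d$rv))
  wmin <- max.col(-cand, ties.method = "first")
  dmin <- cand[cbind(seq_len(nrow(nodes)), wmin)]
  sel <- which(dmin < band)
  if (!length(sel)) return(nodes)
  moved <- surface_projection(geom, nodes[sel, , drop = FALSE],
                              lapply(d, function(v) if (is.null(dim(v))) v[sel] else v),
                              colnames(cand)[wmin[sel]])
  shift <- sqrt(rowSums((moved - nodes[sel, , drop = FALSE])^2))
  ok <- shift <= 1.5 * band
  old <- nodes
  nodes[sel[ok], ] <- moved[ok, , drop = FALSE]
  revert_close_pairs(nodes, old, sel[ok], 0.8 * band)
}

# undo moves that left two nodes closer than minsep (sliver guard)
revert_close_pairs <- function(nodes, old, moved_idx, minsep) {
  for (pass in 1:3) {
    if (!length(moved_idx)) break
    nn <- .knn_bf(nodes, nodes[moved_idx, , drop = FALSE], 2L)
    close <- nn$dist[, 2] < minsep
    if (!any(close)) break
    bad <- moved_idx[close]
    nodes[bad, ] <- old[bad, , drop = FALSE]
    moved_idx <- setdiff(moved_idx, bad)
  }
  nodes
}

snap_boundary <- function(m, geom) {
  bverts <- sort(unique(as.vector(m$faces)))
  pts <- m$nodes[bverts, , drop = FALSE]
  d <- wall_signed_depths(geom, pts)
  h <- m$char_length
  cand <- cbind(base = d$base, epi = d$epi, lv = d$lv,
                rv = if (is.null(d$rv)) rep(Inf, nrow(pts)) else d$rv)
  # snap boundary vertices onto the closest surface: always when outside
  # (negative depth), and within three quarters of a cell when inside
  snap_which <- apply(cand, 1, which.min)
  snap_depth <- cand[cbind(seq_len(nrow(pts)), snap_which)]
  do_snap <- snap_depth < 0.6 * h
  new_pts <- pts
  for (i in which(do_snap)) {
    w <- colnames(cand)[snap_which[i]]
    p <- pts[i, ]
    if (w == "base") {
      p[3] <- geom$z_base
    } else if (w == "epi" || w == "lv") {
      g <- if (w == "epi") geom$g_epi else geom$g_lv
      r <- star_radius_at(g, d$theta_lv[i], p[3])
      if (d$rho_lv[i] > 1e-9 && r > 0) {
        f <- r / d$rho_lv[i]
        p[1] <- g$axis[1] + (p[1] - g$axis[1]) * f
        p[2] <- g$axis[2] + (p[2] - g$axis[2]) * f
      }
    } else if (w == "rv") {
      g <- geom$g_rv
      r <- star_radius_at(g, d$theta_rv[i], p[3])
      if (d$rho_rv[i] > 1e-9 && r > 0) {
        f <- r / d$rho_rv[i]
        p[1] <- g$axis[1] + (p[1] - g$axis[1]) * f
        p[2] <- g$axis[2] + (p[2] - g$axis[2]) * f
      }
    }
    # cap displacement
    if (sqrt(sum((p - pts[i, ])^2)) <= 1.2 * h) new_pts[i, ] <- p
  }
  nodes <- m$nodes
  nodes[bverts, ] <- new_pts
  nodes <- revert_close_pairs(nodes, m$nodes, bverts[do_snap], 0.3 * h)
  # inversion guard: revert snapped vertices adjacent to degenerate tets
  vmin <- 1e-3 * h^3
  for (pass in 1:5) {
    v6 <- tet_signed_volumes(nodes, m$tets)
    bad <- which(v6 < vmin * 6)
    if (length(bad) == 0) break
    bad_verts <- intersect(unique(as.vector(m$tets[bad, , drop = FALSE])), bverts)
    nodes[bad_verts, ] <- m$nodes[bad_verts, ]
  }
  m$nodes <- nodes
  m
}

tag_boundary <- function(m, geom, cloud) {
  cen <- (m$nodes[m$faces[, 1], , drop = FALSE] +
            m$nodes[m$faces[, 2], , drop = FALSE] +
            m$nodes[m$faces[, 3], , drop = FALSE]) / 3
  d <- wall_signed_depths(geom, cen)
  h <- m$char_length
  tags <- character(nrow(cen))
  on_base <- abs(geom$z_base - cen[, 3]) < 0.3 * h
  radial <- cbind(EPI = abs(d$epi), LV_ENDO = abs(d$lv),
                  RV_ENDO = if (is.null(d$rv)) rep(Inf, nrow(cen)) else abs(d$rv))
  tags <- colnames(radial)[apply(radial, 1, which.min)]
  if (any(on_base)) {
    tags[on_base] <- "BASE"
    # valve tags: base facets adjacent to a labelled ring circle
    ring_map <- c(MV_RING = "MV", AV_RING = "AV", TV_RING = "TV", PV_RING = "PV")
    for (rg in names(ring_map)) {
      rp <- cloud$points[cloud$labels == rg, , drop = FALSE]
      if (nrow(rp) == 0) next
      dd <- nn_dist(cen[on_base, , drop = FALSE], rp)
      hit <- which(on_base)[dd < 1.0 * h]
      tags[hit] <- ring_map[[rg]]
    }
  }
  m$face_tags <- tags
  m
}

check_mesh <- function(m) {
  v6 <- tet_signed_volumes(m$nodes, m$tets)
  if (any(v6 <= 0))
    stop_invariant("mesh invariant violated: non-positive element volume")
  if (!any(m$face_tags == "LV_ENDO"))
    stop_invariant("mesh invariant violated: empty LV_ENDO facet group")
  if (!any(m$face_tags == "EPI"))
    stop_invariant("mesh invariant violated: empty EPI facet group")
  invisible(m)
}

#' Nodes lying on facets with given tags
#' @param mesh a `tet_mesh`.
#' @param tags character vector of facet tags.
#' @return integer vector of vertex ids.
#' @export
nodes_on_tags <- function(mesh, tags) {
  sort(unique(as.vector(mesh$faces[mesh$face_tags %in% tags, , drop = FALSE])))
}
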