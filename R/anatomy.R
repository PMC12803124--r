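# Rule-based anatomy on the volumetric mesh: a single transmural Laplace
# coordinate (0 on the endocardial surfaces, 1 on the epicardium) and a
# linear helix-angle fiber rule built on the local frame spanned by the
# transmural gradient, the projected long axis and their cross product.
# The constitutive law is transversely isotropic, so only the fiber
# direction f0 is needed (no sheet architecture).

p1_grad_basis <- function(mesh) {
  n <- mesh$nodes; t4 <- mesh$tets
  a <- n[t4[, 2], , drop = FALSE] - n[t4[, 1], , drop = FALSE]
  b <- n[t4[, 3], , drop = FALSE] - n[t4[, 1], , drop = FALSE]
  cc <- n[t4[, 4], , drop = FALSE] - n[t4[, 1], , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  det <- rowSums(a * cross(b, cc))
  g2 <- cross(b, cc) / det
  g3 <- cross(cc, a) / det
  g4 <- cross(a, b) / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = abs(det) / 6)
}

laplace_stiffness <- function(mesh) {
  gb <- p1_grad_basis(mesh)
  nv <- nrow(mesh$nodes)
  nt <- nrow(mesh$tets)
  ii <- jj <- integer(0); xx <- numeric(0)
  ii <- vector("list", 16); jj <- vector("list", 16); xx <- vector("list", 16)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    ii[[k]] <- mesh$tets[, i]
    jj[[k]] <- mesh$tets[, j]
    xx[[k]] <- gb$vol * rowSums(gb$g[[i]] * gb$g[[j]])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

#' Transmural Laplace coordinate
#'
#' Solves Laplace's equation on the wall mesh with t = 0 on the
#' endocardial facet groups, t = 1 on the epicardium, and natural
#' conditions elsewhere (base, valve rings).
#'
#' @param mesh a tagged `tet_mesh`.
#' @return numeric vector of nodal values in `[0, 1]`.
#' @export
transmural_coordinate <- function(mesh) {
  endo <- nodes_on_tags(mesh, c("LV_ENDO", "RV_ENDO"))
  epi <- nodes_on_tags(mesh, "EPI")
  if (length(endo) == 0 || length(epi) == 0)
    stop_invariant("transmural solve needs non-empty endocardial and epicardial facet groups")
  nv <- nrow(mesh$nodes)
  K <- laplace_stiffness(mesh)
  t <- numeric(nv)
  t[epi] <- 1
  fixed <- c(endo, epi)
  free <- setdiff(seq_len(nv), fixed)
  rhs <- as.numeric(-(K[free, fixed, drop = FALSE] %*% t[fixed]))
  t[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                                      Matrix::Matrix(rhs, ncol = 1)))
  pmin(pmax(t, 0), 1)
}

#' Rule-based myofiber directions
#'
#' The helix angle varies linearly with the transmural coordinate,
#' `alpha = alpha_endo * (1 - t) + alpha_epi * t`, in the local frame
#' built per element from the transmural gradient (normalized), the long
#' axis projected orthogonal to it (longitudinal), and their cross product
#' (circumferential): `f0 = cos(alpha) c + sin(alpha) l`, normalized.
#' Elements with a degenerate transmural gradient inherit the fiber of the
#' nearest regular element (with a warning).
#'
#' @param mesh a `tet_mesh`.
#' @param t nodal transmural coordinate from [transmural_coordinate()].
#' @param alpha_endo,alpha_epi helix angles at endo/epicardium, degrees.
#' @param long_axis reference long-axis direction (default +z, the base
#'   plane normal of the template family).
#' @return matrix (n_tets x 3) of unit fiber vectors, class `fiber_field`.
#' @export
assign_fibers <- function(mesh, t, alpha_endo = 60, alpha_epi = -60,
                          long_axis = c(0, 0, 1)) {
  gb <- p1_grad_basis(mesh)
  t4 <- mesh$tets
  ge <- gb$g[[1]] * t[t4[, 1]] + gb$g[[2]] * t[t4[, 2]] +
    gb$g[[3]] * t[t4[, 3]] + gb$g[[4]] * t[t4[, 4]]
  # nodal gradient recovery (volume-weighted) smooths the piecewise-constant
  # element gradients; curved coarse shells otherwise produce constant-t
  # elements with vanishing gradients
  nv <- nrow(mesh$nodes)
  gnod <- rowsum(rbind(ge * gb$vol, ge * gb$vol, ge * gb$vol, ge * gb$vol),
                 group = c(t4[, 1], t4[, 2], t4[, 3], t4[, 4]),
                 reorder = TRUE)
  wnod <- rowsum(rep(gb$vol, 4), group = c(t4[, 1], t4[, 2], t4[, 3], t4[, 4]),
                 reorder = TRUE)
  gfull <- matrix(0, nv, 3); wfull <- numeric(nv)
  gid <- as.integer(rownames(gnod))
  gfull[gid, ] <- gnod / as.numeric(wnod)
  gt <- (gfull[t4[, 1], ] + gfull[t4[, 2], ] + gfull[t4[, 3], ] + gfull[t4[, 4], ]) / 4
  tbar <- (t[t4[, 1]] + t[t4[, 2]] + t[t4[, 3]] + t[t4[, 4]]) / 4
  gn <- vec_norms(gt)
  l <- long_axis / sqrt(sum(long_axis^2))
  et <- gt / pmax(gn, .Machine$double.eps)
  ldot <- et %*% l
  el <- matrix(l, nrow(et), 3, byrow = TRUE) - et * as.numeric(ldot)
  eln <- vec_norms(el)
  degenerate <- gn < 1e-8 | eln < 1e-8
  el <- el / pmax(eln, .Machine$double.eps)
  ec <- cbind(el[, 2] * et[, 3] - el[, 3] * et[, 2],
              el[, 3] * et[, 1] - el[, 1] * et[, 3],
              el[, 1] * et[, 2] - el[, 2] * et[, 1])
  alpha <- (alpha_endo * (1 - tbar) + alpha_epi * tbar) * pi / 180
  f0 <- ec * cos(alpha) + el * sin(alpha)
  f0 <- f0 / pmax(vec_norms(f0), .Machine$double.eps)
  if (any(degenerate)) {
    ok <- which(!degenerate)
    if (length(ok) == 0) stop_invariant("all transmural gradients degenerate")
    cen <- (mesh$nodes[t4[, 1], ] + mesh$nodes[t4[, 2], ] +
              mesh$nodes[t4[, 3], ] + mesh$nodes[t4[, 4], ]) / 4
    nn <- .knn_bf(cen[ok, , drop = FALSE], cen[degenerate, , drop = FALSE], 1L)
    f0[degenerate, ] <- f0[ok[nn$idx[, 1]], , drop = FALSE]
    warning(sprintf("%d element(s) with degenerate transmural gradient: nearest-neighbour fiber fallback", sum(degenerate)))
  }
  structure(f0, class = c("fiber_field", class(f0)), tbar = tbar)
}
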