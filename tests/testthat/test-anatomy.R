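# Transmural Laplace coordinate and rule-based fibers.

# tag a structured annulus/shell mesh by boundary-facet centroid radius
tag_by_radius <- function(m, r_in, r_out, axial = FALSE) {
  # structured meshes place surface nodes exactly on the radii, so a facet
  # belongs to a surface iff all three vertices sit on it
  vr <- if (axial) sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2) else
    sqrt(rowSums(m$nodes^2))
  fr <- matrix(vr[m$faces], ncol = 3)
  tol <- 1e-8 * r_out
  tags <- rep("BASE", nrow(m$faces))
  tags[apply(abs(fr - r_in) < tol, 1, all)] <- "LV_ENDO"
  tags[apply(abs(fr - r_out) < tol, 1, all)] <- "EPI"
  m$face_tags <- tags
  m
}

test_that("transmural coordinate honours its Dirichlet data and maximum principle", {
  m <- tag_by_radius(tet_shell_mesh(10, 20, 4, 16, 6), 10, 20)
  t <- transmural_coordinate(m)
  endo <- nodes_on_tags(m, "LV_ENDO")
  epi <- nodes_on_tags(m, "EPI")
  expect_equal(t[endo], rep(0, length(endo)))
  expect_equal(t[epi], rep(1, length(epi)))
  interior <- setdiff(seq_len(nrow(m$nodes)), c(endo, epi))
  expect_true(all(t[interior] > 0 & t[interior] < 1))
})

test_that("transmural coordinate matches the harmonic profile between spheres", {
  m <- tag_by_radius(tet_shell_mesh(10, 20, 6, 24, 8), 10, 20)
  t <- transmural_coordinate(m)
  r <- attr(m, "r")
  exact <- (1 / 10 - 1 / r) / (1 / 10 - 1 / 20)
  expect_lt(max(abs(t - exact)), 0.02)
})

test_that("solving without an endocardial tag group fails loudly", {
  m <- tet_shell_mesh(10, 20, 3, 12, 5)
  m$face_tags <- rep("EPI", nrow(m$faces))
  expect_error(transmural_coordinate(m), "endocardial")
})

test_that("fibers follow the linear helix law in the cylinder tangent plane", {
  m <- tag_by_radius(tet_annulus_mesh(10, 16, 24, 3, 24, 5), 10, 16, axial = TRUE)
  t <- transmural_coordinate(m)
  f <- assign_fibers(m, t)
  expect_lt(max(abs(sqrt(rowSums(f^2)) - 1)), 1e-8)
  tbar <- attr(f, "tbar")
  cen <- (m$nodes[m$tets[, 1], ] + m$nodes[m$tets[, 2], ] +
            m$nodes[m$tets[, 3], ] + m$nodes[m$tets[, 4], ]) / 4
  rho <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  circ <- cbind(-cen[, 2], cen[, 1], 0) / rho
  measured <- atan2(f[, 3], rowSums(f * circ)) * 180 / pi
  expected <- 60 * (1 - tbar) - 60 * tbar
  # measured within the tangent plane, away from the flat end caps
  interior <- cen[, 3] > 5 & cen[, 3] < 19
  expect_lt(max(abs(measured[interior] - expected[interior])), 3)
  # inner-layer elements lean towards +60 degrees
  inner <- interior & tbar < 1 / 3
  expect_true(all(measured[inner] > 20))
})

test_that("midwall fibers are circumferential and adjacent fibers vary smoothly", {
  m <- tag_by_radius(tet_annulus_mesh(10, 16, 24, 4, 24, 5), 10, 16, axial = TRUE)
  t <- transmural_coordinate(m)
  f <- assign_fibers(m, t)
  tbar <- attr(f, "tbar")
  mid <- which(abs(tbar - 0.5) < 0.04)
  if (length(mid)) {
    expect_lt(max(abs(f[mid, 3])), 0.2)
  }
  # smoothness: fibers of elements sharing a face differ by < 30 degrees
  # (orientation-insensitive)
  nt <- nrow(m$tets)
  fface <- rbind(m$tets[, c(2, 3, 4)], m$tets[, c(1, 3, 4)],
                 m$tets[, c(1, 2, 4)], m$tets[, c(1, 2, 3)])
  key <- apply(t(apply(fface, 1, sort)), 1, paste, collapse = "-")
  own <- rep(seq_len(nt), 4)
  dup <- split(own, key)
  pairs <- do.call(rbind, lapply(dup[lengths(dup) == 2], identity))
  cosang <- abs(rowSums(f[pairs[, 1], ] * f[pairs[, 2], ]))
  expect_gt(min(cosang), cos(30 * pi / 180))
})
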