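# Meshing: structured generators and the implicit wall mesher.

test_that("structured box mesh has exact volume and positive orientation", {
  m <- tet_box_mesh(2, 3, 4, 2, 3, 2)
  expect_equal(mesh_volume(m), 24, tolerance = 1e-12)
  expect_true(all(shapemech:::tet_signed_volumes(m$nodes, m$tets) > 0))
  # a box has 2*(2*(2*3 + 3*2 + 2*2)) triangles on its surface
  expect_equal(nrow(m$faces), 2 * 2 * (2 * 3 + 3 * 2 + 2 * 2))
})

test_that("wall mesh covers all principal facet tags", {
  pair <- generate_template_pair(template_params(global_scale = 0.5),
                                 small_resolution())
  m <- mesh_from_surfaces(pair$ed, char_length = 6)
  tags <- table(m$face_tags)
  expect_gt(tags[["LV_ENDO"]], 0)
  expect_gt(tags[["RV_ENDO"]], 0)
  expect_gt(tags[["EPI"]], 0)
  expect_gt(sum(m$face_tags %in% c("MV", "AV", "TV", "PV")), 0)
  expect_true(all(shapemech:::tet_signed_volumes(m$nodes, m$tets) > 0))
})

test_that("halving the characteristic length refines the mesh consistently", {
  pair <- generate_template_pair(template_params(global_scale = 0.5))
  m1 <- mesh_from_surfaces(pair$ed, char_length = 3)
  m2 <- mesh_from_surfaces(pair$ed, char_length = 1.5)
  expect_gt(nrow(m2$tets), nrow(m1$tets))
  expect_lt(abs(mesh_volume(m2) - mesh_volume(m1)) / mesh_volume(m2), 0.02)
})

test_that("mesh volume approaches the implicit-solid quadrature volume", {
  p <- template_params(global_scale = 0.5)
  pair <- generate_template_pair(p)
  geom <- shapemech:::wall_geometry(pair$ed)
  h <- 0.5
  lo <- apply(pair$ed$points, 2, min) - 1
  hi <- apply(pair$ed$points, 2, max) + 1
  pts <- as.matrix(expand.grid(seq(lo[1], hi[1], by = h),
                               seq(lo[2], hi[2], by = h),
                               seq(lo[3], hi[3], by = h)))
  vox <- sum(shapemech:::inside_wall(geom, pts)) * h^3
  m <- mesh_from_surfaces(pair$ed, char_length = 2.5)
  expect_lt(abs(mesh_volume(m) - vox) / vox, 0.03)
})

test_that("an over-coarse characteristic length raises a clear error", {
  pair <- generate_template_pair(template_params(global_scale = 0.5),
                                 small_resolution())
  expect_error(mesh_from_surfaces(pair$ed, char_length = 200), "char_length")
  expect_error(mesh_from_surfaces(pair$ed, char_length = -1), "> 0")
})
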