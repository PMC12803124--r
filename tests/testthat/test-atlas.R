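# Synthetic template family, chamber volumes and the PCA shape atlas.

test_that("template pair generation is deterministic with consistent layout", {
  res <- small_resolution()
  p1 <- generate_template_pair(resolution = res)
  p2 <- generate_template_pair(resolution = res)
  expect_identical(p1$ed$points, p2$ed$points)
  expect_identical(p1$es$points, p2$es$points)
  expect_identical(p1$ed$labels, p1$es$labels)
  expect_equal(nrow(p1$ed$points), nrow(p1$es$points))
  expect_true(all(table(p1$ed$labels) > 0))
  # ring points lie on the base truncation plane
  for (rg in c("MV_RING", "AV_RING", "TV_RING", "PV_RING")) {
    zr <- p1$ed$points[p1$ed$labels == rg, 3]
    expect_equal(zr, rep(p1$ed$spec$z_base, length(zr)))
  }
})

test_that("zero systolic contraction leaves the ES cloud identical to ED", {
  p <- generate_template_pair(template_params(systolic_contraction = 0),
                              small_resolution())
  expect_identical(p$ed$points, p$es$points)
})

test_that("default contraction yields a physiological LV ejection fraction", {
  p <- generate_template_pair(template_params(systolic_contraction = 0.3))
  edv <- chamber_volume(p$ed, "LV")
  esv <- chamber_volume(p$es, "LV")
  ef <- (edv - esv) / edv
  expect_lt(esv, edv)
  expect_gt(ef, 0.20)
  expect_lt(ef, 0.75)
})

test_that("invalid template parameters are rejected with the violated invariant named", {
  expect_error(template_params(lv_wall_thickness = -1), "thickness")
  expect_error(template_params(lv_wall_thickness = 30), "smaller than")
  expect_error(template_params(base_truncation_fraction = 0.9), "base_truncation")
  expect_error(template_params(systolic_contraction = 1.2), "systolic_contraction")
  expect_error(template_params(rv_center_offset = 10), "rv_center_offset")
})

test_that("chamber volume matches a slice-quadrature oracle for a truncated ellipsoid", {
  p <- template_params(lv_endo_semi_axes = c(25, 25, 45),
                       base_truncation_fraction = 0.6)
  fine <- atlas_resolution(lv_endo = c(64, 40), epi = c(64, 40),
                           rv_endo = c(32, 20), n_ring = 16)
  pair <- generate_template_pair(p, fine)
  v <- chamber_volume(pair$ed, "LV")
  v_oracle <- ellipsoid_cavity_volume_oracle(25, 25, 45, 0.6)
  expect_lt(abs(v - v_oracle) / v_oracle, 0.005)
})

test_that("chamber volume is translation invariant and scales cubically", {
  pair <- generate_template_pair(resolution = small_resolution())
  v0 <- chamber_volume(pair$ed, "LV")
  shifted <- pair$ed
  shifted$points <- sweep(shifted$points, 2, c(13.5, -7.2, 4.4), `+`)
  expect_equal(chamber_volume(shifted, "LV"), v0, tolerance = 1e-9)
  scaled <- pair$ed
  scaled$points <- scaled$points * 2
  expect_equal(chamber_volume(scaled, "LV"), 8 * v0, tolerance = 1e-9)
})

test_that("PCA atlas satisfies orthonormality and round-trip identities", {
  gac <- generate_atlas_cohort(20, seed = 5, resolution = small_resolution())
  atl <- build_atlas(gac$vectors, gac$reference, n_modes = 8)
  G <- crossprod(atl$modes)
  expect_lt(max(abs(G - diag(ncol(atl$modes)))), 1e-10)
  expect_true(all(diff(atl$explained_variance) <= 1e-12))
  # full-rank round trip on a cohort member
  v <- gac$vectors[[7]]
  atl_full <- build_atlas(gac$vectors, gac$reference, n_modes = 19)
  s <- project_to_scores(atl_full, v)
  vr <- reconstruct_from_scores(atl_full, s)
  expect_lt(max(abs(vr - v)) / max(abs(v)), 1e-8)
  # residual orthogonal to every mode
  resid <- v - reconstruct_from_scores(atl_full, project_to_scores(atl_full, v))
  expect_lt(max(abs(crossprod(atl_full$modes, resid))), 1e-8)
})

test_that("projection conventions: mean maps to origin, unit-SD step to unit score", {
  fx <- fixture_small()
  atl <- fx$atlas
  expect_equal(project_to_scores(atl, atl$mean), rep(0, 8))
  v1 <- atl$mean + sqrt(atl$explained_variance[1]) * atl$modes[, 1]
  s <- project_to_scores(atl, v1)
  expect_equal(s[1], 1, tolerance = 1e-10)
  expect_lt(max(abs(s[-1])), 1e-10)
  # linearity: doubling a score doubles the offset from the mean
  d1 <- reconstruct_from_scores(atl, c(0.5, 0, 0)) - atl$mean
  d2 <- reconstruct_from_scores(atl, c(1.0, 0, 0)) - atl$mean
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("degenerate and rank-1 cohorts are decomposed correctly", {
  fx <- fixture_small()
  ref <- fx$atlas$reference
  base <- c(t(ref$points), t(ref$points))
  same <- replicate(10, base, simplify = FALSE)
  atl0 <- build_atlas(same, ref, n_modes = 4)
  expect_equal(atl0$explained_variance, rep(0, 4), tolerance = 1e-18)
  expect_equal(atl0$mean, base)
  # rank-1 family: mean + c * direction
  dir <- sin(seq_along(base))
  dir <- dir / sqrt(sum(dir^2))
  cs <- seq(-2, 2, length.out = 9)
  fam <- lapply(cs, function(ci) base + ci * dir)
  atl1 <- build_atlas(fam, ref, n_modes = 4)
  expect_equal(abs(sum(atl1$modes[, 1] * dir)), 1, tolerance = 1e-10)
  expect_equal(atl1$explained_variance[1], var(cs), tolerance = 1e-10)
  expect_lt(max(atl1$explained_variance[-1]), 1e-16)
})

test_that("build_atlas validates cohort size and vector lengths", {
  fx <- fixture_small()
  ref <- fx$atlas$reference
  base <- c(t(ref$points), t(ref$points))
  expect_error(build_atlas(replicate(5, base, simplify = FALSE), ref, 8),
               "exceed")
  bad <- replicate(10, base, simplify = FALSE)
  bad[[3]] <- bad[[3]][-1]
  expect_error(build_atlas(bad, ref, 4), "same length")
})

test_that("cohort score sampling is seeded and matches truncated-normal moments", {
  fx <- fixture_small()
  a <- sample_cohort_scores(fx$atlas, 5, seed = 99)
  b <- sample_cohort_scores(fx$atlas, 5, seed = 99)
  expect_identical(a, b)
  expect_error(sample_cohort_scores(fx$atlas, 5, seed = 1, truncation = 0),
               "truncation")
  big <- sample_cohort_scores(fx$atlas, 10000, seed = 7, truncation = 3, k = 1)
  x <- vapply(big, `[`, numeric(1), 1)
  expect_true(all(abs(x) <= 3))
  expect_lt(abs(mean(x)), 0.05)
  sd_trunc <- sqrt(1 - 2 * 3 * dnorm(3) / (2 * pnorm(3) - 1))
  expect_lt(abs(sd(x) - sd_trunc), 0.05)
})
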