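# Displacement mapping onto the ordered cloud and score recovery.

test_that("a cloud point coincident with a mesh node takes that node's displacement", {
  fx <- fixture_small()
  cl <- fx$atlas$reference
  nodes <- rbind(cl$points[17, ], cl$points[17, ] + c(5, 0, 0),
                 cl$points[17, ] + c(0, 5, 0), cl$points[17, ] + c(0, 0, 5),
                 matrix(rnorm(30, sd = 30), ncol = 3))
  u <- matrix(rnorm(nrow(nodes) * 3), ncol = 3)
  out <- map_displacements(cl, nodes, u, k = 4)
  expect_equal(out$points[17, ], cl$points[17, ] + u[1, ], tolerance = 1e-10)
})

test_that("a uniform displacement field maps exactly (partition of unity)", {
  fx <- fixture_small()
  cl <- fx$atlas$reference
  set.seed(3)
  nodes <- matrix(rnorm(600, sd = 40), ncol = 3)
  cshift <- c(2.5, -1, 4)
  u <- matrix(rep(cshift, nrow(nodes)), ncol = 3, byrow = TRUE)
  out <- map_displacements(cl, nodes, u, k = 4)
  expect_equal(out$points, sweep(cl$points, 2, cshift, `+`), tolerance = 1e-10)
})

test_that("a linear displacement field interpolates to sub-0.1 mm accuracy", {
  fx <- fixture_small()
  cl <- fx$atlas$reference
  set.seed(9)
  # dense random nodes with ~2 mm spacing inside the cloud bounding box
  lo <- apply(cl$points, 2, min) - 2
  hi <- apply(cl$points, 2, max) + 2
  vol_box <- prod(hi - lo)
  n_nodes <- ceiling(vol_box / 2^3)
  nodes <- cbind(runif(n_nodes, lo[1], hi[1]), runif(n_nodes, lo[2], hi[2]),
                 runif(n_nodes, lo[3], hi[3]))
  A <- matrix(c(0.01, 0.002, 0, -0.003, 0.015, 0.001, 0, 0.002, 0.012), 3)
  u <- nodes %*% t(A)
  out <- map_displacements(cl, nodes, u, k = 4)
  exact <- cl$points + cl$points %*% t(A)
  err <- sqrt(rowSums((out$points - exact)^2))
  expect_lt(max(err), 0.1)
})

test_that("score recovery round-trips pairs synthesized from known scores", {
  fx <- fixture_small()
  atl <- fx$atlas
  s <- c(0.8, -1.2, 0.3, 0.9, -0.4)
  pr <- reconstruct_pair(atl, s)
  rec <- recover_def_scores(atl, pr$ed, pr$es, k = 5)
  expect_equal(rec, s, tolerance = 1e-8)
  # all-mean pair projects to the origin
  pm <- unflatten_pair(atl$mean, atl$reference)
  expect_equal(recover_def_scores(atl, pm$ed, pm$es, 5), rep(0, 5),
               tolerance = 1e-10)
  # truncation consistency: leading 5 of an 8-score recovery
  rec8 <- recover_def_scores(atl, pr$ed, pr$es, k = 8)
  expect_equal(rec8[1:5], rec, tolerance = 1e-12)
})

test_that("ordering mismatches are rejected", {
  fx <- fixture_small()
  atl <- fx$atlas
  pr <- reconstruct_pair(atl, c(1, 0))
  bad <- pr$ed
  bad$labels <- factor(rev(as.character(bad$labels)),
                       levels = levels(bad$labels))
  expect_error(recover_def_scores(atl, bad, pr$es), "ordering")
})

test_that("cohort metrics compute EF per case and group by LVESP", {
  fx <- fixture_small()
  pairs <- fx$pairs
  df <- cohort_metrics(pairs)
  expect_equal(nrow(df), length(pairs))
  expect_equal(df$LV_EF, 100 * (df$LV_EDV - df$LV_ESV) / df$LV_EDV)
  expect_true(all(c("lvesp", "LV_EF", "LV_EF_sd") %in%
                    names(attr(df, "summary"))))
  # EDV = ESV implies EF = 0 (construct a static pair)
  static <- pairs[[1]]
  static$es_cloud <- static$ed_cloud
  df0 <- cohort_metrics(list(static))
  expect_equal(df0$LV_EF, 0, tolerance = 1e-9)
})
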