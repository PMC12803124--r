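# Point-cloud metrics against brute-force double-loop oracles.

test_that("hausdorff, average distance and overlap match brute force", {
  set.seed(31)
  A <- matrix(rnorm(300, sd = 5), ncol = 3)
  B <- matrix(rnorm(450, sd = 5), ncol = 3)
  dab <- brute_nn(A, B)
  dba <- brute_nn(B, A)
  expect_equal(hausdorff_distance(A, B), max(max(dab), max(dba)), tolerance = 1e-12)
  expect_equal(avg_distance(A, B), mean(dab), tolerance = 1e-12)
  expect_equal(avg_distance(A, B, symmetric = TRUE),
               (mean(dab) + mean(dba)) / 2, tolerance = 1e-12)
  expect_equal(overlap_percentage(A, B, 2), 100 * mean(dab <= 2), tolerance = 1e-12)
})

test_that("identical clouds give zero distances and full overlap", {
  set.seed(5)
  A <- matrix(runif(90), ncol = 3)
  expect_equal(hausdorff_distance(A, A), 0)
  expect_equal(avg_distance(A, A), 0)
  expect_equal(overlap_percentage(A, A), 100)
})

test_that("translation by a known offset is measured exactly", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  B <- sweep(corners, 2, c(3, 0, 0), `+`)
  expect_equal(hausdorff_distance(corners, B), 3.0)
  # boundary-inclusive overlap at exactly the threshold
  C <- sweep(corners, 2, c(2, 0, 0), `+`)
  expect_equal(overlap_percentage(corners, C, threshold = 2.0), 100)
})

test_that("a far outlier drives the Hausdorff distance", {
  set.seed(8)
  A <- matrix(rnorm(150), ncol = 3)
  B <- A
  A2 <- rbind(A, c(50, 0, 0))
  h <- hausdorff_distance(A2, B)
  expect_equal(h, min(sqrt(colSums((t(B) - c(50, 0, 0))^2))), tolerance = 1e-12)
})

test_that("metrics are invariant under a common rigid motion", {
  set.seed(12)
  A <- matrix(rnorm(240, sd = 3), ncol = 3)
  B <- matrix(rnorm(150, sd = 3), ncol = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(4, -2, 9)
  A2 <- sweep(A %*% t(R), 2, tr, `+`)
  B2 <- sweep(B %*% t(R), 2, tr, `+`)
  expect_equal(hausdorff_distance(A2, B2), hausdorff_distance(A, B), tolerance = 1e-9)
  expect_equal(avg_distance(A2, B2), avg_distance(A, B), tolerance = 1e-9)
  expect_equal(overlap_percentage(A2, B2, 2), overlap_percentage(A, B, 2))
})

test_that("directed average distance never exceeds the Hausdorff distance", {
  set.seed(77)
  for (i in 1:5) {
    A <- matrix(rnorm(60 + 9 * i), ncol = 3)
    B <- matrix(rnorm(120), ncol = 3)
    expect_lte(avg_distance(A, B), hausdorff_distance(A, B))
  }
})

test_that("displacement statistics are the mean and max point norms", {
  expect_equal(unname(displacement_stats(matrix(0, 10, 3))), c(0, 0))
  u345 <- matrix(rep(c(3, 4, 0), 7), ncol = 3, byrow = TRUE)
  expect_equal(unname(displacement_stats(u345)), c(5, 5))
  set.seed(2)
  u <- matrix(rnorm(99), ncol = 3)
  nn <- sqrt(rowSums(u^2))
  expect_equal(unname(displacement_stats(u)), c(mean(nn), max(nn)), tolerance = 1e-12)
})

test_that("empty inputs are rejected", {
  A <- matrix(rnorm(9), 3)
  expect_error(hausdorff_distance(A, matrix(numeric(0), 0, 3)), "empty")
  expect_error(overlap_percentage(A, A, threshold = 0), "threshold")
})
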