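# Dataset assembly, geometry-level splitting, and the MLP surrogate.

test_that("parameter counting follows the dense-layer rule", {
  cfg <- surrogate_config()
  expect_identical(count_parameters(cfg, by_layer = TRUE),
                   c(2176L, 8256L, 325L))
  expect_identical(count_parameters(cfg), 10757L)
  # degenerate linear map 16 -> 5
  expect_identical(count_parameters(surrogate_config(hidden = integer(0))), 85L)
})

test_that("dataset assembly maps case fields into the input slots", {
  fx <- fixture_small()
  us <- setNames(lapply(fx$pairs, function(p) seq(0.1, 1.2, length.out = 12)),
                 vapply(fx$pairs, `[[`, character(1), "geometry_id"))
  recs <- assemble_dataset(fx$pairs, us)
  expect_length(recs, length(fx$pairs))
  r <- recs[[1]]
  expect_length(r$x, 16)
  expect_length(r$y, 5)
  expect_equal(r$x[11:14], c(1.20, 18.0, 0.533, 3.0)) # NORMAL/NORMAL case
  expect_equal(r$x[15:16], c(1.28, 1.7))
  expect_equal(r$x[1:10], seq(0.1, 1.2, length.out = 12)[1:10])
  # records with missing metadata are skipped with a warning
  expect_warning(out <- assemble_dataset(fx$pairs, us[-1]), "skipped")
  expect_length(out, length(fx$pairs) - 1)
})

test_that("geometry-level split is disjoint, seeded, and falls back proportionally", {
  recs <- list()
  for (g in 1:10) for (r in 1:3) {
    recs[[length(recs) + 1L]] <- structure(
      list(x = rnorm(16), y = rnorm(5), geometry_id = sprintf("g%02d", g)),
      class = "training_record")
  }
  expect_warning(sp <- split_by_geometry(recs, 40, 10, seed = 3), "fewer")
  expect_length(intersect(sp$train_geoms, sp$test_geoms), 0)
  expect_equal(length(sp$train_geoms) + length(sp$test_geoms), 10)
  sp2 <- suppressWarnings(split_by_geometry(recs, 40, 10, seed = 3))
  expect_identical(sp$test_geoms, sp2$test_geoms)
  sp8 <- split_by_geometry(recs, 8, 2, seed = 1)
  expect_length(sp8$train_geoms, 8)
  expect_length(sp8$test_geoms, 2)
  expect_error(split_by_geometry(recs[1:3], 8, 2), "2 distinct")
})

make_linear_records <- function(n, seed, W, noise = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- rnorm(16)
    y <- as.numeric(W %*% x) + rnorm(5, 0, noise)
    structure(list(x = x, y = y, geometry_id = sprintf("g%02d", i %% 12)),
              class = "training_record")
  })
}

test_that("the network recovers a noiseless linear map to low validation loss", {
  set.seed(1)
  W <- matrix(rnorm(5 * 16, sd = 0.5), 5, 16)
  recs <- make_linear_records(600, 7, W)
  cfg <- surrogate_config(lr = 2e-3, max_epochs = 400, weight_decay = 1e-4,
                          seed = 5)
  model <- train_surrogate(recs, cfg)
  # per-component validation MSE in normalized units (loss sums 5 components)
  expect_lt(model$best_val_loss / 5, 1e-2)
  # curves recorded per epoch; running best is non-increasing
  expect_equal(nrow(model$curves), 400)
  expect_true(all(diff(cummin(model$curves[, "validation"])) <= 0))
})

test_that("training is reproducible and inference is deterministic", {
  W <- diag(1, 5, 16)
  recs <- make_linear_records(120, 3, W)
  cfg <- surrogate_config(lr = 1e-3, max_epochs = 15, seed = 11)
  m1 <- train_surrogate(recs, cfg)
  m2 <- train_surrogate(recs, cfg)
  expect_identical(m1$par, m2$par)
  X <- matrix(rnorm(80), 5, 16)
  expect_identical(predict_surrogate(m1, X), predict_surrogate(m1, X))
})

test_that("evaluation statistics follow their definitions", {
  W <- matrix(rnorm(5 * 16, sd = 0.3), 5, 16)
  recs <- make_linear_records(80, 9, W)
  cfg <- surrogate_config(lr = 1e-3, max_epochs = 60, seed = 2)
  model <- train_surrogate(recs[1:60], cfg)
  rep <- evaluate_surrogate(model, recs[61:80])
  d <- shapemech:::records_xy(recs[61:80])
  Yhat <- predict_surrogate(model, d$X)
  # independent two-pass R^2 and MSE
  for (k in 1:5) {
    mse_k <- mean((Yhat[, k] - d$Y[, k])^2)
    r2_k <- 1 - sum((Yhat[, k] - d$Y[, k])^2) /
      sum((d$Y[, k] - mean(d$Y[, k]))^2)
    expect_equal(unname(rep$mse[k]), mse_k, tolerance = 1e-10)
    expect_equal(unname(rep$r2[k]), r2_k, tolerance = 1e-10)
  }
  # perfect predictions give R^2 = 1, MSE = 0: records whose targets are
  # the model's own outputs
  perfect_recs <- lapply(recs[61:80], function(r) {
    r$y <- as.numeric(predict_surrogate(model, r$x))
    r
  })
  prep <- evaluate_surrogate(model, perfect_recs)
  expect_equal(unname(prep$mse), rep(0, 5), tolerance = 1e-20)
  expect_equal(unname(prep$r2), rep(1, 5), tolerance = 1e-10)
  # zero-variance component reports NA
  recs_const <- lapply(recs[1:20], function(r) { r$y[3] <- 1.5; r })
  rep2 <- evaluate_surrogate(model, recs_const)
  expect_true(is.na(rep2$r2[3]))
})

test_that("predicting the per-component test mean yields R^2 of zero", {
  W <- matrix(rnorm(5 * 16, sd = 0.3), 5, 16)
  recs <- make_linear_records(40, 13, W)
  d <- shapemech:::records_xy(recs)
  mu <- colMeans(d$Y)
  res <- sweep(d$Y, 2, mu) * -1
  r2 <- 1 - colSums(res^2) / colSums(sweep(d$Y, 2, mu)^2)
  expect_equal(unname(r2), rep(0, 5))
})
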