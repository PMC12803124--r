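# Multilayer-perceptron surrogate: 16 inputs (first 10 unloaded shape
# scores, four chamber pressures, two passive material parameters) to the
# first 5 deformed shape scores. Hand-rolled dense network with ReLU +
# dropout hidden layers, mean-squared-error loss, and AdamW (decoupled
# weight decay); inputs and outputs are z-scored with training-set
# statistics stored in the model.

#' Surrogate network configuration
#'
#' Defaults are the reference architecture and optimizer settings: hidden
#' layers of 128 and 64 units with ReLU and dropout p = 0.1, AdamW with
#' learning rate 5e-6 and weight decay 1e-2, mini-batches of 32, up to
#' 10,000 epochs, keeping the lowest-validation-loss state.
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param dropout dropout probability after each hidden activation.
#' @param lr learning rate.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch mini-batch size.
#' @param max_epochs training epochs.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param n_restarts independent training restarts (seeds `seed`,
#'   `seed + 1`, ...); the state with the lowest validation loss across
#'   restarts is kept.
#' @param validation_fraction fraction of training geometries held out for
#'   validation monitoring.
#' @param n_inputs,n_outputs network width at the ends.
#' @return a list of class `surrogate_config`.
#' @export
surrogate_config <- function(hidden = c(128, 64), dropout = 0.1,
                             lr = 5e-6, weight_decay = 1e-2,
                             batch = 32, max_epochs = 10000, seed = 1,
                             n_restarts = 1,
                             validation_fraction = 0.2,
                             n_inputs = 16, n_outputs = 5) {
  structure(list(hidden = as.integer(hidden), dropout = dropout, lr = lr,
                 weight_decay = weight_decay, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs), seed = seed,
                 n_restarts = as.integer(n_restarts),
                 validation_fraction = validation_fraction,
                 n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs)),
            class = "surrogate_config")
}

#' Trainable parameter count of the surrogate network
#'
#' Each dense layer contributes `(n_in + 1) * n_out` parameters.
#'
#' @param config a [surrogate_config()].
#' @param by_layer return the per-layer counts instead of the total.
#' @return integer total (default) or vector of per-layer counts.
#' @export
count_parameters <- function(config = surrogate_config(), by_layer = FALSE) {
  dims <- c(config$n_inputs, config$hidden, config$n_outputs)
  per <- (head(dims, -1) + 1L) * dims[-1]
  if (by_layer) per else sum(per)
}

#' Assemble the regression dataset from deformed pairs
#'
#' One record per converged simulation: inputs are the first 10 unloaded
#' shape scores, the four prescribed pressures (LVEDP, LVESP, RVEDP,
#' RVESP) and the passive material parameters `a` and `af` (the active
#' tension is constant across simulations and therefore excluded); targets
#' are the first 5 deformed shape scores. Pairs whose geometry id has no
#' unloaded-score entry are skipped with a warning.
#'
#' @param pairs list of `deformed_pair`s.
#' @param unloaded_scores named list mapping geometry id to its unloaded
#'   PC score vector.
#' @return list of `training_record`s (fields `x` (16), `y` (5),
#'   `geometry_id`).
#' @export
assemble_dataset <- function(pairs, unloaded_scores) {
  out <- list()
  skipped <- 0L
  for (p in pairs) {
    gid <- as.character(p$geometry_id)
    us <- unloaded_scores[[gid]]
    if (is.null(us) || is.null(p$material)) { skipped <- skipped + 1L; next }
    x <- c(us[1:10], p$case$lvedp, p$case$lvesp, p$case$rvedp, p$case$rvesp,
           p$material$a, p$material$af)
    y <- p$def_scores[1:5]
    if (any(!is.finite(c(x, y)))) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- structure(
      list(x = as.numeric(x), y = as.numeric(y), geometry_id = gid),
      class = "training_record")
  }
  if (skipped > 0)
    warning(sprintf("%d pair(s) skipped (missing metadata or non-finite values)", skipped))
  out
}

records_xy <- function(records) {
  X <- do.call(rbind, lapply(records, `[[`, "x"))
  Y <- do.call(rbind, lapply(records, `[[`, "y"))
  g <- vapply(records, `[[`, character(1), "geometry_id")
  list(X = X, Y = Y, g = g)
}

#' Geometry-level train/test split
#'
#' Splits whole geometries (never records) between train and test; when
#' fewer geometries are available than requested the 4:1 proportion is
#' kept with a warning.
#'
#' @param records list of `training_record`s.
#' @param n_train_geoms,n_test_geoms requested geometry counts.
#' @param seed RNG seed.
#' @return list with `train` and `test` record lists and the geometry id
#'   assignment.
#' @export
split_by_geometry <- function(records, n_train_geoms = 40, n_test_geoms = 10,
                              seed = 1) {
  g <- vapply(records, `[[`, character(1), "geometry_id")
  ug <- unique(g)
  if (length(ug) < 2) stop_invariant("need at least 2 distinct geometry ids")
  if (length(ug) < n_train_geoms + n_test_geoms) {
    frac_test <- n_test_geoms / (n_train_geoms + n_test_geoms)
    n_test_geoms <- max(1L, round(frac_test * length(ug)))
    n_train_geoms <- length(ug) - n_test_geoms
    warning(sprintf("fewer geometries than requested: using %d train / %d test",
                    n_train_geoms, n_test_geoms))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_g <- sample(ug, n_test_geoms)
  train_g <- setdiff(ug, test_g)[seq_len(n_train_geoms)]
  list(train = records[g %in% train_g], test = records[g %in% test_g],
       train_geoms = train_g, test_geoms = test_g)
}

# ---- network internals ----

mlp_init <- function(config) {
  dims <- c(config$n_inputs, config$hidden, config$n_outputs)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout = 0, training = FALSE) {
  nl <- length(par$W)
  A <- X
  cache <- list(A0 = X)
  for (l in seq_len(nl - 1)) {
    Z <- sweep(A %*% par$W[[l]], 2, par$b[[l]], `+`)
    A <- pmax(Z, 0)
    if (training && dropout > 0) {
      mask <- matrix(runif(length(A)) >= dropout, nrow(A), ncol(A)) / (1 - dropout)
      A <- A * mask
      cache[[paste0("M", l)]] <- mask
    }
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("A", l)]] <- A
  }
  Y <- sweep(A %*% par$W[[nl]], 2, par$b[[nl]], `+`)
  cache$out <- Y
  cache
}

mlp_backward <- function(par, cache, dY, dropout = 0, training = TRUE) {
  nl <- length(par$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- dY
  for (l in rev(seq_len(nl))) {
    A_prev <- if (l == 1) cache$A0 else cache[[paste0("A", l - 1)]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(par$W[[l]])
      if (training && dropout > 0) delta <- delta * cache[[paste0("M", l - 1)]]
      delta <- delta * (cache[[paste0("Z", l - 1)]] > 0)
    }
  }
  list(W = gW, b = gb)
}

zscore_stats <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

zapply <- function(M, st) sweep(sweep(M, 2, st$mu), 2, st$sd, `/`)
zinvert <- function(M, st) sweep(sweep(M, 2, st$sd, `*`), 2, st$mu, `+`)

#' Train the surrogate network
#'
#' Minimizes the mean squared error between predicted and simulated
#' deformed shape scores with AdamW; a geometry-stratified validation
#' split is monitored every epoch and the lowest-validation-loss state is
#' returned. Fully reproducible given the config seed.
#'
#' @param records list of `training_record`s (training geometries only).
#' @param config a [surrogate_config()].
#' @param verbose print progress every few hundred epochs.
#' @return an `mlp_surrogate`: parameters, normalization statistics,
#'   config, `best_epoch`, and per-epoch `curves` (train/validation loss).
#' @export
train_surrogate <- function(records, config = surrogate_config(),
                            verbose = FALSE) {
  if (length(records) < 2) stop_invariant("need at least 2 records to train")
  n_restarts <- config$n_restarts %||% 1L
  if (n_restarts > 1) {
    best <- NULL
    for (r in seq_len(n_restarts) - 1L) {
      cfg_r <- config
      cfg_r$seed <- config$seed + r
      cfg_r$n_restarts <- 1L
      mdl <- train_surrogate(records, cfg_r, verbose)
      if (is.null(best) || mdl$best_val_loss < best$best_val_loss) best <- mdl
    }
    return(best)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- records_xy(records)
  ug <- unique(d$g)
  n_val_g <- max(1L, round(config$validation_fraction * length(ug)))
  val_g <- if (length(ug) > 1) sample(ug, n_val_g) else character(0)
  is_val <- d$g %in% val_g
  if (all(is_val) || !any(is_val)) {
    idx <- sample(nrow(d$X))
    n_val <- max(1L, round(config$validation_fraction * nrow(d$X)))
    is_val <- seq_len(nrow(d$X)) %in% idx[seq_len(n_val)]
  }
  xst <- zscore_stats(d$X[!is_val, , drop = FALSE])
  yst <- zscore_stats(d$Y[!is_val, , drop = FALSE])
  Xtr <- zapply(d$X[!is_val, , drop = FALSE], xst)
  Ytr <- zapply(d$Y[!is_val, , drop = FALSE], yst)
  Xva <- zapply(d$X[is_val, , drop = FALSE], xst)
  Yva <- zapply(d$Y[is_val, , drop = FALSE], yst)

  par <- mlp_init(config)
  mom <- lapply(par, function(g) lapply(g, function(p) p * 0))
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  tstep <- 0
  ntr <- nrow(Xtr)
  best <- list(loss = Inf, par = par, epoch = 0L)
  curves <- matrix(NA_real_, config$max_epochs, 2,
                   dimnames = list(NULL, c("train", "validation")))
  batch_loss <- function(Yhat, Y) sum((Yhat - Y)^2) / nrow(Y)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(ntr)
    tl <- 0
    for (start in seq(1, ntr, by = config$batch)) {
      rows <- ord[start:min(start + config$batch - 1, ntr)]
      Xb <- Xtr[rows, , drop = FALSE]; Yb <- Ytr[rows, , drop = FALSE]
      cache <- mlp_forward(par, Xb, config$dropout, training = TRUE)
      dY <- 2 * (cache$out - Yb) / nrow(Yb)
      gr <- mlp_backward(par, cache, dY, config$dropout)
      tstep <- tstep + 1
      bc1 <- 1 - beta1^tstep; bc2 <- 1 - beta2^tstep
      for (g in c("W", "b")) for (l in seq_along(par[[g]])) {
        mom[[g]][[l]] <- beta1 * mom[[g]][[l]] + (1 - beta1) * gr[[g]][[l]]
        vel[[g]][[l]] <- beta2 * vel[[g]][[l]] + (1 - beta2) * gr[[g]][[l]]^2
        upd <- (mom[[g]][[l]] / bc1) / (sqrt(vel[[g]][[l]] / bc2) + adam_eps)
        wd <- if (g == "W") config$weight_decay * par[[g]][[l]] else 0
        par[[g]][[l]] <- par[[g]][[l]] - config$lr * (upd + wd)
      }
      tl <- tl + batch_loss(cache$out, Yb) * length(rows)
    }
    trl <- tl / ntr
    vl <- batch_loss(mlp_forward(par, Xva)$out, Yva)
    if (!is.finite(vl) || !is.finite(trl))
      stop_invariant(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
    curves[epoch, ] <- c(trl, vl)
    if (vl < best$loss) best <- list(loss = vl, par = par, epoch = epoch)
    if (verbose && epoch %% 200 == 0)
      message(sprintf("epoch %d: train %.4g, val %.4g (best %.4g @ %d)",
                      epoch, trl, vl, best$loss, best$epoch))
  }
  structure(list(par = best$par, x_stats = xst, y_stats = yst,
                 config = config, best_epoch = best$epoch,
                 best_val_loss = best$loss,
                 curves = curves[seq_len(config$max_epochs), , drop = FALSE]),
            class = "mlp_surrogate")
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat(sprintf("mlp_surrogate: %d -> %s -> %d, %d parameters, best epoch %d (val MSE %.4g)\n",
              x$config$n_inputs, paste(x$config$hidden, collapse = " -> "),
              x$config$n_outputs, count_parameters(x$config),
              x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict deformed scores for new inputs
#'
#' Deterministic inference pass (dropout disabled); inputs are normalized
#' with the stored training statistics and predictions returned in
#' original score units.
#'
#' @param model an `mlp_surrogate`.
#' @param X input matrix (n x 16) or a single input vector.
#' @return prediction matrix (n x 5).
#' @export
predict_surrogate <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  Z <- mlp_forward(model$par, zapply(X, model$x_stats))$out
  zinvert(Z, model$y_stats)
}

#' Evaluate the surrogate on test records
#'
#' Per-component mean squared error and coefficient of determination
#' (`R^2 = 1 - SS_res / SS_tot`) in original score units; components with
#' zero test variance report `R^2 = NA`. When an atlas is supplied, the
#' predicted and true score vectors are reconstructed to 3-D clouds and
#' compared with [geometric_metrics()] separately at ED and ES.
#'
#' @param model an `mlp_surrogate`.
#' @param records test `training_record`s.
#' @param atlas optional `shape_atlas` for geometric validation.
#' @param threshold overlap threshold, mm.
#' @return an `eval_report`: `mse`, `r2` (per component), `overall_mse`,
#'   `residuals`, and (with atlas) `geometry` (per-record data frame) and
#'   `geometry_summary`.
#' @export
evaluate_surrogate <- function(model, records, atlas = NULL, threshold = 2.0) {
  if (!length(records)) stop_invariant("empty test set")
  d <- records_xy(records)
  Yhat <- predict_surrogate(model, d$X)
  res <- Yhat - d$Y
  mse <- colMeans(res^2)
  sst <- colSums(sweep(d$Y, 2, colMeans(d$Y))^2)
  ssr <- colSums(res^2)
  r2 <- ifelse(sst > 1e-12, 1 - ssr / sst, NA_real_)
  out <- list(mse = mse, r2 = r2, overall_mse = mean(rowSums(res^2)),
              residuals = res, predictions = Yhat, truth = d$Y)
  if (!is.null(atlas)) {
    rows <- list()
    for (i in seq_len(nrow(d$X))) {
      vp <- reconstruct_from_scores(atlas, Yhat[i, ])
      vt <- reconstruct_from_scores(atlas, d$Y[i, ])
      pp <- unflatten_pair(vp, atlas$reference)
      pt <- unflatten_pair(vt, atlas$reference)
      ged <- geometric_metrics(pp$ed, pt$ed, threshold)
      ges <- geometric_metrics(pp$es, pt$es, threshold)
      rows[[i]] <- data.frame(record = i, geometry_id = d$g[i],
                              frame = c("ED", "ES"),
                              hausdorff = c(ged$hausdorff, ges$hausdorff),
                              avg_dist = c(ged$avg_dist, ges$avg_dist),
                              overlap = c(ged$overlap, ges$overlap),
                              rms_error = c(ged$rms_error, ges$rms_error))
    }
    geo <- do.call(rbind, rows)
    gs_mean <- aggregate(cbind(hausdorff, avg_dist, overlap, rms_error) ~ frame, geo, mean)
    gs_sd <- aggregate(cbind(hausdorff, avg_dist, overlap, rms_error) ~ frame, geo, sd)
    names(gs_sd)[-1] <- paste0(names(gs_sd)[-1], "_sd")
    out$geometry <- geo
    out$geometry_summary <- merge(gs_mean, gs_sd, by = "frame")
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("surrogate evaluation\n  per-component MSE:", signif(x$mse, 4), "\n")
  cat("  per-component R2: ", signif(x$r2, 4), "\n")
  if (!is.null(x$geometry_summary)) {
    cat("  geometric agreement (mean):\n")
    print(x$geometry_summary, digits = 4)
  }
  invisible(x)
}
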