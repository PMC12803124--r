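# End-to-end orchestration: synthetic atlas -> cohort sampling -> unloading
# -> meshing/fibers -> two-phase FE simulation -> atlas projection ->
# surrogate training -> evaluation, with per-stage caching and JSON/CSV
# artifacts.

#' Pipeline configuration
#'
#' `preset = "reference"` is the full-scale study configuration (50
#' geometries, the full 2 x 3 material grid, 5 mm elements). `preset =
#' "coarse"` is the scaled-down configuration used for desk-scale runs and
#' continuous testing: fewer geometries, two material pairs, 10 mm
#' elements, and a surrogate optimizer sized to the smaller dataset.
#'
#' @param preset `"reference"` or `"coarse"`.
#' @param ... named overrides of any config field.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("reference", "coarse"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    resolution = atlas_resolution(),
    base_params = template_params(),
    n_atlas = 120, n_modes = 25,
    n_geoms = 50, truncation = 3,
    material_grid = expand.grid(a = c(0.50, 1.28), af = c(1.7, 10.0, 20.0)),
    ed_levels = c("LOW", "NORMAL", "HIGH"),
    es_levels = c("LOW", "NORMAL", "HIGH"),
    ed_assignment = "all",
    material_assignment = "all",
    char_length = 5.0,
    mechanics = mechanics_config(),
    unload_max_iters = 150,
    unload_lambda = 0.1,
    unload_free_modes = NULL,
    n_unloaded_pc = 10, n_def_pc = 5,
    surrogate = surrogate_config(),
    n_train_geoms = 40, n_test_geoms = 10)
  if (preset == "coarse") {
    cfg$n_atlas <- 40
    cfg$n_geoms <- 32
    cfg$material_grid <- data.frame(a = c(1.28, 1.28), af = c(1.7, 10.0))
    cfg$material_assignment <- "round_robin"
    cfg$char_length <- 13.0
    cfg$mechanics <- mechanics_config(n_fill = 5, n_eject = 14, n_es_step = 3,
                                      newton_rtol = 1e-6, newton_atol = 1e-8,
                                      newton_max_iter = 40, max_phase_iters = 900)
    cfg$unload_max_iters <- 60
    cfg$unload_free_modes <- 10
    cfg$ed_assignment <- "round_robin"
    cfg$surrogate <- surrogate_config(lr = 1e-3, max_epochs = 6000,
                                      weight_decay = 2, dropout = 0, batch = 8,
                                      n_restarts = 5)
    cfg$n_train_geoms <- 26
    cfg$n_test_geoms <- 6
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

config_fingerprint <- function(cfg, stage) {
  paste(stage, paste(deparse(cfg[setdiff(names(cfg), "preset")]), collapse = ""),
        sep = "::")
}

stage_cached <- function(outdir, stage, fingerprint) {
  meta <- file.path(outdir, paste0(stage, ".fingerprint"))
  dat <- file.path(outdir, paste0(stage, ".rds"))
  if (file.exists(meta) && file.exists(dat) &&
      identical(readLines(meta, warn = FALSE), fingerprint))
    readRDS(dat) else NULL
}

stage_store <- function(outdir, stage, fingerprint, value) {
  saveRDS(value, file.path(outdir, paste0(stage, ".rds")))
  writeLines(fingerprint, file.path(outdir, paste0(stage, ".fingerprint")))
  value
}

#' Run the full surrogate-building pipeline
#'
#' Executes every stage in order, caching per-stage results in `outdir`
#' (re-running with an identical configuration and seed reuses cached
#' outputs). Non-converged simulations are logged and excluded from the
#' training data.
#'
#' @param config a [pipeline_config()].
#' @param outdir output/cache directory (created if needed).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param verbose print stage progress.
#' @return a list with the atlas, cohort, unloading results, deformed
#'   pairs, cohort metrics, trained surrogate, evaluation report and a
#'   run manifest.
#' @export
run_pipeline <- function(config = pipeline_config("coarse"),
                         outdir = tempfile("shapemech_run_"),
                         seed = 1, verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- seed + c(atlas = 101L, cohort = 202L, split = 303L, surrogate = 404L)

  # stage 1: atlas
  fp <- config_fingerprint(config[c("resolution", "base_params", "n_atlas", "n_modes")],
                           paste0("atlas", seeds[["atlas"]]))
  atl <- stage_cached(outdir, "atlas", fp)
  if (is.null(atl)) {
    say("stage atlas: generating %d-member cohort, %d modes", config$n_atlas, config$n_modes)
    gac <- generate_atlas_cohort(config$n_atlas, seeds[["atlas"]], config$resolution,
                                 config$base_params)
    atl <- build_atlas(gac$vectors, gac$reference, config$n_modes)
    stage_store(outdir, "atlas", fp, atl)
  }

  # stage 2: cohort scores + hemodynamic/material grid
  fp <- config_fingerprint(config[c("n_geoms", "truncation", "n_modes")],
                           paste0("cohort", seeds[["cohort"]]))
  cohort <- stage_cached(outdir, "cohort", fp)
  if (is.null(cohort)) {
    say("stage cohort: sampling %d geometries", config$n_geoms)
    scores <- sample_cohort_scores(atl, config$n_geoms, seeds[["cohort"]],
                                   config$truncation)
    names(scores) <- sprintf("g%03d", seq_along(scores))
    cohort <- list(scores = scores)
    stage_store(outdir, "cohort", fp, cohort)
  }

  # stage 3: unloading
  fp <- config_fingerprint(config[c("n_geoms", "unload_max_iters", "unload_lambda",
                                    "unload_free_modes")],
                           paste0("unload", seeds[["cohort"]]))
  unload <- stage_cached(outdir, "unload", fp)
  if (is.null(unload)) {
    say("stage unload: estimating unloaded geometries")
    unload <- lapply(cohort$scores, function(s) {
      lvedv <- lv_volume_of_scores(atl, s)
      v0 <- estimate_unloaded_volume(lvedv)
      unload_scores(atl, s, v0, tolerance = 0.1,
                    max_iters = config$unload_max_iters,
                    lambda = config$unload_lambda,
                    free_modes = config$unload_free_modes %||% length(s))
    })
    stage_store(outdir, "unload", fp, unload)
  }

  # stage 4-6: mesh, simulate, project (per geometry)
  fp <- config_fingerprint(config[c("char_length", "material_grid", "ed_levels",
                                    "es_levels", "ed_assignment",
                                    "material_assignment", "mechanics",
                                    "n_def_pc")],
                           paste0("simulate", seeds[["cohort"]]))
  sim <- stage_cached(outdir, "simulate", fp)
  if (is.null(sim)) {
    pairs <- list(); failures <- list()
    gi <- 0L
    for (gid in names(unload)) {
      gi <- gi + 1L
      if (!unload[[gid]]$converged) {
        failures[[length(failures) + 1L]] <- list(geometry = gid, stage = "unload")
        next
      }
      ucl <- unloaded_cloud(atl, unload[[gid]])
      # characteristic length scales with geometry size (the config value
      # refers to the family-centre template, unloaded V0 ~ 60 mL)
      cl_g <- config$char_length * (unload[[gid]]$v0_achieved / 60)^(1 / 3)
      mesh <- tryCatch(mesh_from_surfaces(ucl, cl_g),
                       error = function(e) e)
      if (inherits(mesh, "error")) {
        failures[[length(failures) + 1L]] <- list(geometry = gid, stage = "mesh",
                                                  message = conditionMessage(mesh))
        next
      }
      anat <- tryCatch({
        tcoord <- transmural_coordinate(mesh)
        list(fib = assign_fibers(mesh, tcoord))
      }, error = function(e) e)
      if (inherits(anat, "error")) {
        failures[[length(failures) + 1L]] <- list(geometry = gid, stage = "anatomy",
                                                  message = conditionMessage(anat))
        next
      }
      fib <- anat$fib
      mat_rows <- seq_len(nrow(config$material_grid))
      if (identical(config$material_assignment, "round_robin"))
        mat_rows <- (gi - 1L) %% nrow(config$material_grid) + 1L
      for (mi in mat_rows) {
        mat <- material_params(a = config$material_grid$a[mi],
                               af = config$material_grid$af[mi])
        ed_levels <- config$ed_levels
        if (identical(config$ed_assignment, "round_robin"))
          ed_levels <- config$ed_levels[(gi + mi - 2L) %% length(config$ed_levels) + 1L]
        else if (identical(config$ed_assignment, "round_robin_pair"))
          ed_levels <- config$ed_levels[-((gi + mi - 2L) %% length(config$ed_levels) + 1L)]
        say("stage simulate: %s, a=%.2f af=%.1f, ED %s", gid, mat$a, mat$af,
            paste(ed_levels, collapse = "/"))
        sols <- tryCatch({
          prob <- fe_problem(mesh, fib, mat)
          run_case_family(prob, ed_levels, config$es_levels, config$mechanics)
        }, error = function(e) e)
        if (inherits(sols, "error")) {
          failures[[length(failures) + 1L]] <-
            list(geometry = gid, stage = "mechanics", message = conditionMessage(sols),
                 material = c(a = mat$a, af = mat$af))
          next
        }
        for (nm in names(sols)) {
          s <- sols[[nm]]
          if (!s$converged) {
            failures[[length(failures) + 1L]] <-
              list(geometry = gid, stage = "mechanics", case = nm,
                   material = c(a = mat$a, af = mat$af))
            next
          }
          pairs[[length(pairs) + 1L]] <-
            deformed_pair(atl, ucl, prob, s, config$n_def_pc,
                          geometry_id = gid, material = mat)
        }
      }
    }
    sim <- list(pairs = pairs, failures = failures)
    stage_store(outdir, "simulate", fp, sim)
  }
  say("stage simulate: %d converged pairs, %d failures",
      length(sim$pairs), length(sim$failures))

  # stage 7: cohort metrics
  metrics <- cohort_metrics(sim$pairs)
  write.csv(metrics, file.path(outdir, "cohort_metrics.csv"), row.names = FALSE)
  write.csv(attr(metrics, "summary"), file.path(outdir, "cohort_metrics_by_lvesp.csv"),
            row.names = FALSE)

  # stage 8: surrogate
  unloaded_scores <- lapply(unload, `[[`, "unloaded_scores")
  records <- assemble_dataset(sim$pairs, unloaded_scores)
  split <- split_by_geometry(records, config$n_train_geoms, config$n_test_geoms,
                             seeds[["split"]])
  scfg <- config$surrogate
  scfg$seed <- seeds[["surrogate"]]
  fp <- config_fingerprint(config[c("surrogate", "n_train_geoms", "n_test_geoms")],
                           paste0("train", seeds[["surrogate"]], length(records)))
  model <- stage_cached(outdir, "model", fp)
  if (is.null(model)) {
    say("stage train: %d records (%d train geoms / %d test geoms)",
        length(records), length(split$train_geoms), length(split$test_geoms))
    model <- train_surrogate(split$train, scfg)
    stage_store(outdir, "model", fp, model)
  }
  report <- evaluate_surrogate(model, split$test, atl)
  write.csv(report$geometry, file.path(outdir, "geometry_metrics.csv"),
            row.names = FALSE)

  manifest <- list(seed = seed, preset = config$preset,
                   n_geoms = config$n_geoms,
                   n_pairs = length(sim$pairs),
                   n_failures = length(sim$failures),
                   n_records = length(records),
                   train_geoms = split$train_geoms,
                   test_geoms = split$test_geoms,
                   best_epoch = model$best_epoch)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(atlas = atl, cohort = cohort, unloading = unload,
       pairs = sim$pairs, failures = sim$failures, metrics = metrics,
       records = records, split = split, model = model, report = report,
       manifest = manifest, outdir = outdir)
}

#' Deterministic miniature fixtures for tests and examples
#'
#' A reduced-resolution atlas (8 modes), a 4-geometry score cohort, and
#' synthetic deformed pairs generated in score space (no FE solve), all
#' reproducible from the seed.
#'
#' @param seed integer seed.
#' @return list with `atlas`, `cohort_scores`, `pairs`.
#' @export
make_fixtures <- function(seed = 42) {
  res <- atlas_resolution(lv_endo = c(12, 7), epi = c(14, 8),
                          rv_endo = c(10, 6), n_ring = 8)
  gac <- generate_atlas_cohort(20, seed, res)
  atl <- build_atlas(gac$vectors, gac$reference, 8)
  scores <- sample_cohort_scores(atl, 4, seed + 1, truncation = 3)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 2)
  pairs <- lapply(seq_along(scores), function(i) {
    def <- scores[[i]][1:5] * 0.9 + rnorm(5, 0, 0.05)
    pr <- reconstruct_pair(atl, def)
    structure(list(ed_cloud = pr$ed, es_cloud = pr$es,
                   def_scores = recover_def_scores(atl, pr$ed, pr$es, 5),
                   case = make_hemodynamic_case("NORMAL", "NORMAL"),
                   geometry_id = sprintf("f%02d", i),
                   material = material_params()),
              class = "deformed_pair")
  })
  list(atlas = atl, cohort_scores = scores, pairs = pairs)
}
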