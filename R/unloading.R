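# Unloaded-geometry estimation: an empirical linear end-diastolic
# pressure-volume heuristic maps LVEDV to the unloaded LV volume V0, and a
# gradient descent in atlas score space finds modified shape-mode scores
# whose ED LV cavity volume matches V0 within tolerance. Scores modify the
# ED and ES halves of the atlas vector jointly (as the modes dictate); only
# the ED LV volume enters the objective.

#' Estimate the unloaded LV volume from LVEDV
#'
#' Linear heuristic `V0 = 0.5025 * LVEDV + 5.7574` (mL), derived from an
#' empirical end-diastolic pressure-volume relationship.
#'
#' @param lvedv LV end-diastolic volume, mL (> 0).
#' @return unloaded volume V0, mL.
#' @export
estimate_unloaded_volume <- function(lvedv) {
  if (any(lvedv <= 0)) stop_invariant("lvedv must be > 0")
  0.5025 * lvedv + 5.7574
}

lv_volume_of_scores <- function(atlas, s) {
  pair <- reconstruct_pair(atlas, s)
  chamber_volume(pair$ed, "LV")
}

#' Find modified PC scores matching a target unloaded ED LV volume
#'
#' Minimizes `(V(s) - v0)^2 + lambda * ||s - s0||^2` by gradient descent
#' with backtracking line search; the gradient is computed by central
#' finite differences in score space. The quadratic penalty (small by
#' default) keeps the unloaded shape near the subject's ED shape, making
#' the otherwise under-determined volume constraint unique; set
#' `lambda = 0` to disable it.
#'
#' @param atlas a `shape_atlas`.
#' @param scores starting PC scores (SD units).
#' @param v0 target ED LV cavity volume, mL.
#' @param tolerance convergence tolerance on the achieved volume, mL.
#' @param max_iters maximum descent iterations.
#' @param lambda regularization weight (mL^2 per SD^2).
#' @param free_modes number of leading modes allowed to move
#'   (default: all supplied scores).
#' @param fd_step central-difference step in SD units.
#' @return an `unloading_result`: `unloaded_scores`, `v0_target`,
#'   `v0_achieved`, `iterations`, `converged`, `objective_trace`.
#' @export
unload_scores <- function(atlas, scores, v0, tolerance = 0.1,
                          max_iters = 200, lambda = 0.1,
                          free_modes = length(scores), fd_step = 1e-3) {
  s0 <- as.numeric(scores)
  s <- s0
  free <- seq_len(min(free_modes, length(s)))
  vol <- lv_volume_of_scores(atlas, s)
  obj <- function(sv) {
    v <- lv_volume_of_scores(atlas, sv)
    list(f = (v - v0)^2 + lambda * sum((sv - s0)^2), v = v)
  }
  trace <- numeric(0)
  iter <- 0L
  converged <- abs(vol - v0) <= tolerance
  cur <- list(f = (vol - v0)^2, v = vol)
  step <- 1
  while (!converged && iter < max_iters) {
    iter <- iter + 1L
    g <- numeric(length(s))
    for (i in free) {
      sp <- s; sp[i] <- sp[i] + fd_step
      sm <- s; sm[i] <- sm[i] - fd_step
      g[i] <- (obj(sp)$f - obj(sm)$f) / (2 * fd_step)
    }
    gn2 <- sum(g^2)
    if (gn2 < 1e-20) break
    # trust-region-style cap: never move more than 0.5 SD (in norm) per
    # iteration, so the descent stays in the basin of the subject's shape
    step <- min(step, 0.5 / sqrt(gn2))
    # backtracking line search (Armijo)
    accepted <- FALSE
    for (bt in 1:30) {
      cand <- s - step * g
      res <- obj(cand)
      if (res$f <= cur$f - 1e-4 * step * gn2) {
        s <- cand; cur <- res; accepted <- TRUE
        step <- step * 1.5
        break
      }
      step <- step / 2
    }
    trace <- c(trace, cur$f)
    if (!accepted) break
    converged <- abs(cur$v - v0) <= tolerance
  }
  structure(list(unloaded_scores = s, v0_target = v0, v0_achieved = cur$v,
                 iterations = iter, converged = converged,
                 lambda = lambda, objective_trace = trace),
            class = "unloading_result")
}

#' @export
print.unloading_result <- function(x, ...) {
  cat(sprintf("unloading_result: target %.3f mL, achieved %.3f mL in %d iterations (%s)\n",
              x$v0_target, x$v0_achieved, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Unloaded surface cloud at the optimized scores
#'
#' The ED half of the reconstructed atlas vector, re-tagged with frame
#' `"UNLOADED"`.
#'
#' @param atlas a `shape_atlas`.
#' @param result an `unloading_result` (or a score vector).
#' @return a `surface_cloud`.
#' @export
unloaded_cloud <- function(atlas, result) {
  s <- if (inherits(result, "unloading_result")) result$unloaded_scores else result
  cl <- reconstruct_pair(atlas, s)$ed
  cl$frame <- "UNLOADED"
  cl
}
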