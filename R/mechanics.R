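# Quasi-static incompressible transversely isotropic hyperelasticity with
# additive active stress, on P2/P1 (Taylor-Hood type) tetrahedra.
#
# Loading follows the two-phase protocol: passive filling from the unloaded
# state to end-diastolic pressures with zero active tension, then active
# loading to end-systole with pressure and active tension ramped linearly to
# the lowest end-systolic case, after which end-systolic pressures are
# stepped further at constant active tension. Cavity pressures act as
# follower loads (deformed-configuration normals) on the endocardial facet
# groups; all valve-ring facet nodes carry homogeneous Dirichlet conditions.

#' Solver configuration for the mechanics simulations
#'
#' @param n_fill load steps from unloaded to ED.
#' @param n_eject load steps from ED to the lowest ES case (with the active
#'   tension ramp).
#' @param n_es_step load steps per subsequent ES pressure increment.
#' @param newton_rtol,newton_atol relative/absolute Newton residual
#'   tolerances (relative to the first residual of each load step).
#' @param newton_max_iter maximum Newton iterations per load step.
#' @param min_step_frac smallest allowed load-step fraction when halving on
#'   divergence.
#' @param max_phase_iters total Newton-iteration budget per loading leg;
#'   exhausting it marks the leg non-converged (the case is then excluded
#'   and logged, like any other convergence failure).
#' @return a list of class `mechanics_config`.
#' @export
mechanics_config <- function(n_fill = 10, n_eject = 20, n_es_step = 4,
                             newton_rtol = 1e-8, newton_atol = 1e-10,
                             newton_max_iter = 25, min_step_frac = 1 / 64,
                             max_phase_iters = 4000) {
  structure(list(n_fill = n_fill, n_eject = n_eject, n_es_step = n_es_step,
                 newton_rtol = newton_rtol, newton_atol = newton_atol,
                 newton_max_iter = newton_max_iter,
                 min_step_frac = min_step_frac,
                 max_phase_iters = max_phase_iters),
            class = "mechanics_config")
}

# ---- P2/P1 connectivity ----

p2_connectivity <- function(mesh) {
  t4 <- mesh$tets
  nv <- nrow(mesh$nodes)
  pr1 <- c(1L, 1L, 1L, 2L, 2L, 3L); pr2 <- c(2L, 3L, 4L, 3L, 4L, 4L)
  ea <- t4[, pr1]; eb <- t4[, pr2] # nt x 6
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- (as.numeric(lo) - 1) * nv + as.numeric(hi)
  uk <- sort(unique(key))
  eidx <- match(key, uk)
  tet_edges <- matrix(eidx, nrow(t4), 6)
  e_lo <- as.integer((uk - 1) %/% nv + 1)
  e_hi <- as.integer(uk - (e_lo - 1) * nv)
  edges <- cbind(e_lo, e_hi)
  mid <- (mesh$nodes[e_lo, , drop = FALSE] + mesh$nodes[e_hi, , drop = FALSE]) / 2
  nodes_p2 <- rbind(mesh$nodes, mid)
  conn10 <- cbind(t4, nv + tet_edges)
  storage.mode(conn10) <- "integer"
  # boundary faces as quadratic triangles (v1 v2 v3 m12 m13 m23)
  f <- mesh$faces
  ekey <- function(a, b) (pmin(a, b) - 1) * nv + pmax(a, b)
  m12 <- nv + match(ekey(f[, 1], f[, 2]), uk)
  m13 <- nv + match(ekey(f[, 1], f[, 3]), uk)
  m23 <- nv + match(ekey(f[, 2], f[, 3]), uk)
  faces6 <- cbind(f, m12, m13, m23)
  storage.mode(faces6) <- "integer"
  list(nodes_p2 = nodes_p2, conn10 = conn10, faces6 = faces6,
       edges = edges, nv = nv, n_p2 = nrow(nodes_p2))
}

#' Assemble a mechanics problem
#'
#' Precomputes the quadratic connectivity, Dirichlet dof set (all valve
#' ring tags by default) and the pressure facet groups.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param fibers per-element unit fiber directions ([assign_fibers()]).
#' @param material a [material_params()] object.
#' @param dirichlet_tags facet tags whose nodes are fully fixed.
#' @param pressure_tags named list mapping load names (`lv`, `rv`) to facet
#'   tags.
#' @param stabilization artificial-compressibility stabilization of the
#'   multiplier block (1/kPa): the weak incompressibility constraint
#'   becomes `J - 1 = stabilization * p`, removing spurious pressure modes
#'   on coarse meshes while keeping `|J - 1|` at the 1e-5 level for
#'   physiological multiplier magnitudes. Set 0 for the pure constraint.
#' @return a list of class `fe_problem`.
#' @export
fe_problem <- function(mesh, fibers, material,
                       dirichlet_tags = c("MV", "AV", "TV", "PV"),
                       pressure_tags = list(lv = "LV_ENDO", rv = "RV_ENDO"),
                       stabilization = 1e-6) {
  if (nrow(fibers) != nrow(mesh$tets))
    stop_invariant("fiber field size does not match element count")
  p2 <- p2_connectivity(mesh)
  # Dirichlet: vertex and mid-edge nodes of the fixed facets
  fixed_faces <- which(mesh$face_tags %in% dirichlet_tags)
  fixed_nodes <- sort(unique(as.vector(p2$faces6[fixed_faces, , drop = FALSE])))
  fixed_dofs <- as.vector(t(outer(3 * (fixed_nodes - 1), 1:3, `+`)))
  # elements whose whole node set is Dirichlet-fixed leave their multiplier
  # dofs decoupled; fix the multiplier of vertices seen only by such elements
  locked <- rowSums(matrix(p2$conn10 %in% fixed_nodes, nrow(p2$conn10))) == 10L
  if (any(locked)) {
    v_unlocked <- unique(as.vector(mesh$tets[!locked, , drop = FALSE]))
    v_locked_only <- setdiff(unique(as.vector(mesh$tets[locked, , drop = FALSE])),
                             v_unlocked)
    fixed_dofs <- c(fixed_dofs, 3 * p2$n_p2 + v_locked_only)
  }
  press <- list()
  for (nm in names(pressure_tags)) {
    fi <- which(mesh$face_tags %in% pressure_tags[[nm]])
    if (length(fi)) press[[nm]] <- p2$faces6[fi, , drop = FALSE]
  }
  scale <- max(1, mean(vec_norms(mesh$nodes[mesh$tets[, 2], , drop = FALSE] -
                                   mesh$nodes[mesh$tets[, 1], , drop = FALSE])))
  stab_M <- NULL; stab_trip <- NULL
  if (stabilization > 0) {
    vol <- abs(tet_signed_volumes(mesh$nodes, mesh$tets)) / 6
    ii <- jj <- vector("list", 16); xx <- vector("list", 16)
    k <- 0L
    for (i in 1:4) for (j in 1:4) {
      k <- k + 1L
      ii[[k]] <- mesh$tets[, i]; jj[[k]] <- mesh$tets[, j]
      xx[[k]] <- vol / 20 * (1 + (i == j))
    }
    stab_M <- stabilization *
      Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                           dims = c(p2$nv, p2$nv))
    # triplet form of -stab_M on the global dof numbering, appended to the
    # tangent triplets at assembly time (cheaper than sparse subassignment)
    stab_T <- Matrix::mat2triplet(stab_M)
    stab_trip <- list(i = 3L * p2$n_p2 + stab_T$i, j = 3L * p2$n_p2 + stab_T$j,
                      x = -stab_T$x)
  }
  structure(list(mesh = mesh, p2 = p2, fibers = unclass(fibers),
                 material = material,
                 fixed_nodes = fixed_nodes, fixed_dofs = fixed_dofs,
                 press = press, stab_M = stab_M,
                 stab_trip = if (stabilization > 0) stab_trip else NULL,
                 ndof = 3 * p2$n_p2 + p2$nv,
                 eps_u = 1e-6 * scale, eps_p = 1e-6,
                 du_cap = 0.5 * scale),
            class = "fe_problem")
}

zero_state <- function(prob) {
  # the isotropic exponential term carries a reference stress a*I at F = I;
  # p = -a makes the unloaded state exactly self-equilibrated
  list(u = matrix(0, prob$p2$n_p2, 3),
       p = rep(-prob$material$a, prob$p2$nv),
       loads = c(lv = 0, rv = 0, ta = 0), converged = TRUE,
       history = list())
}

assemble_system <- function(prob, u, pmult, loads, tangent = TRUE) {
  m <- prob$material
  out <- .fe_assemble(prob$p2$nodes_p2, prob$p2$conn10, u, pmult,
                      prob$fibers, c(m$a, m$b, m$af, m$bf, m$eta),
                      loads[["ta"]], m$fiber_compression, prob$p2$nv,
                      tangent, prob$eps_u, prob$eps_p)
  res <- out$res
  ti <- if (tangent) list(out$ti) else NULL
  tj <- if (tangent) list(out$tj) else NULL
  tx <- if (tangent) list(out$tx) else NULL
  for (nm in names(prob$press)) {
    pv <- loads[[nm]]
    if (abs(pv) < 1e-14) next
    faces <- prob$press[[nm]]
    ps <- .fe_assemble_pressure(prob$p2$nodes_p2, faces,
                                rep(pv, nrow(faces)), u, prob$ndof,
                                tangent, prob$eps_u)
    res <- res + ps$res
    if (tangent) { ti <- c(ti, list(ps$ti)); tj <- c(tj, list(ps$tj)); tx <- c(tx, list(ps$tx)) }
  }
  if (!is.null(prob$stab_M)) {
    pidx <- 3 * prob$p2$n_p2 + seq_len(prob$p2$nv)
    res[pidx] <- res[pidx] - as.numeric(prob$stab_M %*% pmult)
  }
  K <- NULL
  if (tangent) {
    if (!is.null(prob$stab_trip)) {
      ti <- c(ti, list(prob$stab_trip$i)); tj <- c(tj, list(prob$stab_trip$j))
      tx <- c(tx, list(prob$stab_trip$x))
    }
    K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                              dims = c(prob$ndof, prob$ndof))
  }
  list(res = res, K = K, ok = out$ok, mean_abs_Jm1 = out$mean_abs_Jm1,
       min_detF = out$min_detF, volume = out$volume,
       mean_cauchy = out$mean_cauchy)
}

# Linear-operator factory for the Newton updates. The stabilized system is
# quasi-definite, so an LDL' factorization of the symmetrized tangent (fast,
# no pivoting) serves as the modified-Newton operator; the mild asymmetry of
# the follower-pressure tangent only affects the iteration count, never the
# converged solution. Sparse LU of the full tangent is the fallback.
factor_operator <- function(K) {
  f <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric((K + Matrix::t(K)) / 2),
                           LDL = TRUE, perm = TRUE, super = FALSE)
    function(b) as.numeric(Matrix::solve(ch, b, system = "A"))
  }, error = function(e) NULL)
  if (!is.null(f)) {
    probe <- tryCatch(f(rep(1, nrow(K))), error = function(e) NULL)
    if (!is.null(probe) && all(is.finite(probe))) return(f)
  }
  lf <- tryCatch(Matrix::lu(K), error = function(e) NULL)
  if (is.null(lf)) return(NULL)
  function(b) as.numeric(Matrix::solve(lf, b))
}

# One Newton solve at fixed loads. The tangent is factored once and reused
# across iterations (modified Newton with damping); it is refactored when
# convergence stalls. Residual-only reassemblies keep the per-iteration
# cost low. Returns converged state or ok = FALSE.
newton_solve <- function(prob, state, loads, cfg,
                         fixed_dofs = prob$fixed_dofs,
                         fixed_vals = NULL) {
  u <- state$u; pm <- state$p
  if (!is.null(fixed_vals)) {
    uf <- as.vector(t(u))
    uf[fixed_dofs] <- fixed_vals
    u <- matrix(uf, ncol = 3, byrow = TRUE)
  }
  free <- setdiff(seq_len(prob$ndof), fixed_dofs)
  nu <- prob$p2$n_p2
  resid_norm <- function(u, pm) {
    sys <- assemble_system(prob, u, pm, loads, tangent = FALSE)
    list(rn = sqrt(sum(sys$res[free]^2)), sys = sys)
  }
  fac <- NULL
  need_tan <- TRUE
  r0 <- NA_real_
  rn_prev <- Inf
  hist <- numeric(0)
  sysR <- NULL
  for (it in seq_len(cfg$newton_max_iter)) {
    sys <- assemble_system(prob, u, pm, loads, tangent = need_tan)
    r <- sys$res[free]
    rn <- sqrt(sum(r * r))
    hist <- c(hist, rn)
    if (!is.finite(rn)) return(list(ok = FALSE, hist = hist))
    if (is.na(r0)) r0 <- max(rn, 1e-30)
    if (rn <= max(cfg$newton_atol, cfg$newton_rtol * r0))
      return(list(ok = TRUE, u = u, p = pm, hist = hist,
                  diag = if (is.null(sys$mean_abs_Jm1)) resid_norm(u, pm)$sys else sys))
    if (rn > 1e6 * r0) return(list(ok = FALSE, hist = hist))
    if (need_tan) {
      fac <- factor_operator(sys$K[free, free, drop = FALSE])
      if (is.null(fac)) return(list(ok = FALSE, hist = hist))
      need_tan <- FALSE
    }
    delta <- tryCatch(as.numeric(fac(-r)), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) return(list(ok = FALSE, hist = hist))
    full <- numeric(prob$ndof)
    full[free] <- delta
    du <- matrix(full[seq_len(3 * nu)], ncol = 3, byrow = TRUE)
    dp <- full[3 * nu + seq_len(prob$p2$nv)]
    # trust-region-style cap: never move a node by more than half an
    # element per update (exponential stiffening punishes overshoot)
    mdu <- sqrt(max(rowSums(du * du)))
    if (is.finite(mdu) && mdu > prob$du_cap) {
      sc <- prob$du_cap / mdu
      du <- du * sc; dp <- dp * sc
    }
    # damped update: full step when it reduces the residual, otherwise the
    # best of a few halved steps (transient residual growth is normal for
    # exponential materials, so a finite increase is still accepted)
    best <- NULL
    alpha <- 1
    for (ls in 1:4) {
      trial <- resid_norm(u + alpha * du, pm + alpha * dp)
      if (is.finite(trial$rn)) {
        if (is.null(best) || trial$rn < best$rn) best <- list(rn = trial$rn, alpha = alpha)
        if (alpha == 1 && trial$rn < rn) break
      }
      alpha <- alpha / 2
    }
    if (is.null(best)) return(list(ok = FALSE, hist = hist))
    u <- u + best$alpha * du; pm <- pm + best$alpha * dp
    # keep the factorization while it still contracts; refactor on stall
    if (best$rn > 0.6 * rn) need_tan <- TRUE
    rn_prev <- rn
  }
  list(ok = FALSE, hist = hist)
}

#' Solve one loading leg by linear load stepping
#'
#' Ramps the loads linearly from the state's current loads to `target`
#' over `n_steps`, with automatic step halving on Newton divergence down
#' to a floor; on exhaustion returns a state flagged not converged (with
#' the Newton history) rather than raising an error.
#'
#' @param prob an [fe_problem()].
#' @param state solver state (from [zero_state()] or a previous leg).
#' @param target named load vector `c(lv=, rv=, ta=)`, kPa.
#' @param n_steps number of linear load steps.
#' @param cfg a [mechanics_config()].
#' @return updated state.
#' @export
solve_phase <- function(prob, state, target, n_steps,
                        cfg = mechanics_config()) {
  start <- state$loads
  target <- c(lv = unname(target[["lv"]]), rv = unname(target[["rv"]]),
              ta = unname(target[["ta"]]))
  frac_done <- 0
  frac_step <- 1 / n_steps
  iters_used <- 0
  while (frac_done < 1 - 1e-12) {
    frac_try <- min(frac_step, 1 - frac_done)
    loads <- start + (frac_done + frac_try) * (target - start)
    sol <- newton_solve(prob, state, loads, cfg)
    iters_used <- iters_used + length(sol$hist)
    if (iters_used > cfg$max_phase_iters %||% Inf) {
      state$converged <- FALSE
      state$history <- c(state$history, list(list(loads = loads,
                                                  residuals = sol$hist,
                                                  failed = TRUE,
                                                  budget_exhausted = TRUE)))
      return(state)
    }
    if (sol$ok) {
      state$u <- sol$u; state$p <- sol$p; state$loads <- loads
      state$history <- c(state$history,
                         list(list(loads = loads, residuals = sol$hist,
                                   mean_abs_Jm1 = sol$diag$mean_abs_Jm1,
                                   min_detF = sol$diag$min_detF)))
      frac_done <- frac_done + frac_try
      frac_step <- min(frac_step * 1.5, 1 / n_steps * 2)
    } else {
      frac_step <- frac_try / 2
      if (frac_step < cfg$min_step_frac / n_steps) {
        state$converged <- FALSE
        state$history <- c(state$history, list(list(loads = loads,
                                                    residuals = sol$hist,
                                                    failed = TRUE)))
        return(state)
      }
    }
  }
  state
}

#' Deformed cavity volume from the mesh
#'
#' Closes the deformed endocardial facet group with a fan cap over its rim
#' and applies the divergence theorem. Quadratic facets are evaluated via
#' their four-triangle midpoint subdivision.
#'
#' @param prob an [fe_problem()].
#' @param u nodal displacement matrix (P2 nodes x 3).
#' @param chamber `"LV"` or `"RV"`.
#' @return cavity volume, mL.
#' @export
mesh_cavity_volume <- function(prob, u, chamber = c("LV", "RV")) {
  chamber <- match.arg(chamber)
  tag <- paste0(chamber, "_ENDO")
  fi <- which(prob$mesh$face_tags == tag)
  if (!length(fi)) stop_invariant(sprintf("no facets tagged %s", tag))
  f6 <- prob$p2$faces6[fi, , drop = FALSE]
  x <- prob$p2$nodes_p2 + u
  # subdivide each quadratic face into 4 linear triangles
  tri <- rbind(f6[, c(1, 4, 5)], f6[, c(4, 2, 6)], f6[, c(5, 6, 3)], f6[, c(4, 6, 5)])
  # rim: boundary half-edges of the vertex triangulation
  he <- rbind(f6[, c(1, 2)], f6[, c(2, 3)], f6[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  rim <- he[!(key %in% rkey), , drop = FALSE]
  if (nrow(rim) > 0) {
    cen <- colMeans(x[unique(as.vector(rim)), , drop = FALSE])
    x <- rbind(x, cen)
    cid <- nrow(x)
    tri <- rbind(tri, cbind(cid, rim[, 2], rim[, 1]))
  }
  triangulation_volume(x, tri) / 1000
}

#' Run the two-phase loading protocol for one geometry and material
#'
#' Shares phase 1 (filling) and the active ramp across end-systolic levels
#' as in the protocol: for each requested ED level the model is filled
#' passively, then ramped with active tension to the lowest requested ES
#' case, after which ES pressures are stepped further at constant peak
#' tension. One `mechanics_solution` is returned per ED/ES combination.
#'
#' @param prob an [fe_problem()].
#' @param ed_levels,es_levels pressure level names.
#' @param cfg a [mechanics_config()].
#' @return named list (`"ED/ES"`) of `mechanics_solution` objects with
#'   fields `u_ed`, `u_es`, `cavity_volumes`, `converged`,
#'   `newton_history`, `case`.
#' @export
run_case_family <- function(prob, ed_levels = c("LOW", "NORMAL", "HIGH"),
                            es_levels = c("LOW", "NORMAL", "HIGH"),
                            cfg = mechanics_config()) {
  lv_order <- c("LOW", "NORMAL", "HIGH")
  es_levels <- lv_order[lv_order %in% es_levels]
  out <- list()
  for (ed in ed_levels) {
    case0 <- make_hemodynamic_case(ed, es_levels[1])
    st <- solve_phase(prob, zero_state(prob),
                      c(lv = case0$lvedp, rv = case0$rvedp, ta = 0),
                      cfg$n_fill, cfg)
    ed_state <- st
    if (!st$converged) {
      for (es in es_levels)
        out[[paste(ed, es, sep = "/")]] <- incomplete_solution(ed, es, st)
      next
    }
    vols_ed <- c(LV = mesh_cavity_volume(prob, st$u, "LV"),
                 RV = if (!is.null(prob$press$rv)) mesh_cavity_volume(prob, st$u, "RV") else NA_real_)
    st_es <- solve_phase(prob, ed_state,
                         c(lv = case0$lvesp, rv = case0$rvesp, ta = case0$ta_max),
                         cfg$n_eject, cfg)
    for (k in seq_along(es_levels)) {
      es <- es_levels[k]
      case <- make_hemodynamic_case(ed, es)
      if (k > 1 && st_es$converged) {
        st_es <- solve_phase(prob, st_es,
                             c(lv = case$lvesp, rv = case$rvesp, ta = case$ta_max),
                             cfg$n_es_step, cfg)
      }
      if (!st_es$converged) {
        out[[paste(ed, es, sep = "/")]] <- incomplete_solution(ed, es, st_es)
        next
      }
      vols <- rbind(ED = vols_ed,
                    ES = c(LV = mesh_cavity_volume(prob, st_es$u, "LV"),
                           RV = if (!is.null(prob$press$rv)) mesh_cavity_volume(prob, st_es$u, "RV") else NA_real_))
      out[[paste(ed, es, sep = "/")]] <- structure(
        list(u_ed = ed_state$u, u_es = st_es$u, p_ed = ed_state$p, p_es = st_es$p,
             cavity_volumes = vols, converged = TRUE,
             newton_history = st_es$history, case = case),
        class = "mechanics_solution")
    }
  }
  out
}

incomplete_solution <- function(ed, es, state) {
  structure(list(u_ed = NULL, u_es = NULL, cavity_volumes = NULL,
                 converged = FALSE, newton_history = state$history,
                 case = make_hemodynamic_case(ed, es)),
            class = "mechanics_solution")
}

#' Run a single hemodynamic case
#'
#' @param prob an [fe_problem()].
#' @param case a `hemodynamic_case`.
#' @param cfg a [mechanics_config()].
#' @return a `mechanics_solution`.
#' @export
run_case <- function(prob, case, cfg = mechanics_config()) {
  run_case_family(prob, case$level_ed, case$level_es, cfg)[[1]]
}

#' @export
print.mechanics_solution <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("mechanics_solution %s/%s: NOT converged\n",
                x$case$level_ed, x$case$level_es))
  } else {
    v <- x$cavity_volumes
    cat(sprintf("mechanics_solution %s/%s: LV EDV %.1f mL, ESV %.1f mL (EF %.1f%%)\n",
                x$case$level_ed, x$case$level_es, v["ED", "LV"], v["ES", "LV"],
                100 * (v["ED", "LV"] - v["ES", "LV"]) / v["ED", "LV"]))
  }
  invisible(x)
}
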