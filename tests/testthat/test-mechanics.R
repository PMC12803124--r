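# Constitutive law, active stress, and the FE solver on verification
# problems with closed-form solutions.

test_that("strain energy vanishes at the reference state and validates inputs", {
  m <- material_params()
  expect_equal(strain_energy(diag(3), c(1, 0, 0), m), 0)
  expect_error(strain_energy(diag(c(1, 1, -1)), c(1, 0, 0), m), "positive-definite")
  expect_error(strain_energy(matrix(rnorm(9), 3), c(1, 0, 0), m), "symmetric")
  expect_error(strain_energy(diag(3), c(2, 0, 0), m), "unit")
})

test_that("strain energy matches an independent scalar evaluation", {
  # C chosen to carry I1 = 3.2, I4 = 1.1 exactly with f0 along x
  C <- diag(c(1.1, 1.05, 1.05))
  f0 <- c(1, 0, 0)
  m <- material_params(a = 1.28, b = 9.726, af = 1.7, bf = 15.779)
  direct <- 1.28 / (2 * 9.726) * (exp(9.726 * (3.2 - 3)) - 1) +
    1.7 / (2 * 15.779) * (exp(15.779 * (1.1 - 1)^2) - 1)
  expect_equal(strain_energy(C, f0, m), direct, tolerance = 1e-12)
  # monotone in I1 at fixed I4
  C2 <- diag(c(1.1, 1.10, 1.05))
  expect_gt(strain_energy(C2, f0, m), strain_energy(C, f0, m))
})

test_that("fiber-compression switch disables the fiber term below I4 = 1", {
  C <- diag(c(0.9, 1.1, 1.05))
  f0 <- c(1, 0, 0)
  on <- strain_energy(C, f0, material_params(fiber_compression = TRUE))
  off <- strain_energy(C, f0, material_params(fiber_compression = FALSE))
  iso <- material_params()$a / (2 * material_params()$b) *
    (exp(material_params()$b * (sum(diag(C)) - 3)) - 1)
  expect_equal(off, iso, tolerance = 1e-12)
  expect_gt(on, off)
})

test_that("passive second Piola-Kirchhoff stress matches differentiation of the energy", {
  set.seed(21)
  m <- material_params(a = 0.8, af = 2.2)
  for (rep in 1:4) {
    A <- diag(3) + 0.1 * matrix(rnorm(9), 3)
    C <- t(A) %*% A
    f0 <- rnorm(3); f0 <- f0 / sqrt(sum(f0^2))
    I1 <- sum(diag(C)); I4 <- as.numeric(t(f0) %*% C %*% f0)
    S_analytic <- m$a * exp(m$b * (I1 - 3)) * diag(3) +
      2 * m$af * (I4 - 1) * exp(m$bf * (I4 - 1)^2) * tcrossprod(f0)
    # S = 2 dPsi/dC by symmetric central differences
    S_fd <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      dC <- matrix(0, 3, 3); dC[i, j] <- dC[i, j] + h / 2; dC[j, i] <- dC[j, i] + h / 2
      S_fd[i, j] <- (strain_energy(C + dC, f0, m) - strain_energy(C - dC, f0, m)) / h
    }
    # the +/- h/2 symmetric perturbation spreads a full step of h, so the
    # quotient above is already 2 * dPsi/dC_ij = S_ij
    expect_lt(max(abs(S_fd - S_analytic)) / max(abs(S_analytic)), 1e-5)
  }
})

test_that("active stress has the prescribed eigenstructure", {
  expect_equal(active_cauchy_stress(0, c(0, 1, 0)), matrix(0, 3, 3))
  s <- active_cauchy_stress(200, c(1, 0, 0), eta = 0.2)
  expect_equal(s, diag(c(200, 40, 40)))
  set.seed(4)
  for (i in 1:5) {
    f <- rnorm(3); f <- f / sqrt(sum(f^2))
    sa <- active_cauchy_stress(123, f, eta = 0.3)
    expect_equal(sum(diag(sa)), 123 * (1 + 2 * 0.3), tolerance = 1e-10)
    ev <- sort(eigen(sa, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(ev, c(0.3 * 123, 0.3 * 123, 123), tolerance = 1e-9)
  }
  expect_error(active_cauchy_stress(-1, c(1, 0, 0)), ">= 0")
})

test_that("uniaxial fiber-aligned stretch matches the incompressible closed form", {
  mat <- material_params(a = 1.28, b = 9.726, af = 1.7, bf = 15.779)
  out <- cube_uniaxial(1.1, mat)
  expect_lt(abs(out$sigma[1] - closed_form_uniaxial(1.1, mat)) /
              closed_form_uniaxial(1.1, mat), 0.01)
  expect_equal(out$lateral, 1 / sqrt(1.1), tolerance = 1e-3)
  expect_lt(abs(out$sigma[2]), 0.01 * closed_form_uniaxial(1.1, mat))
  expect_lt(out$J_err, 1e-4)
})

test_that("the solution is objective under a coordinate permutation", {
  mat <- material_params()
  ox <- cube_uniaxial(1.08, mat, axis = 1)
  oy <- cube_uniaxial(1.08, mat, axis = 2)
  # axial stresses agree, roles of components swap
  expect_equal(ox$sigma[1], oy$sigma[2], tolerance = 1e-8)
  expect_equal(ox$sigma[2], oy$sigma[1], tolerance = 1e-8)
})

test_that("uniform external pressure on a fully loaded cube leaves it undeformed", {
  mesh <- tet_box_mesh(1, 1, 1, 2, 2, 2)
  mesh$face_tags <- rep("LV_ENDO", nrow(mesh$faces)) # pressurize every face
  fib <- matrix(rep(c(1, 0, 0), nrow(mesh$tets)), ncol = 3, byrow = TRUE)
  mat <- material_params()
  prob <- fe_problem(mesh, fib, mat, dirichlet_tags = character(0),
                     pressure_tags = list(lv = "LV_ENDO"))
  np2 <- prob$p2$nodes_p2
  tol <- 1e-9
  # pin rigid modes only: one corner fully, one edge partially
  c0 <- which(rowSums(abs(np2)) < tol)
  cx <- which(abs(np2[, 1] - 1) < tol & abs(np2[, 2]) < tol & abs(np2[, 3]) < tol)
  cy <- which(abs(np2[, 2] - 1) < tol & abs(np2[, 1]) < tol & abs(np2[, 3]) < tol)
  fd <- c(3 * (c0 - 1) + 1, 3 * (c0 - 1) + 2, 3 * (c0 - 1) + 3,
          3 * (cx - 1) + 2, 3 * (cx - 1) + 3, 3 * (cy - 1) + 3)
  cfg <- mechanics_config()
  sol <- shapemech:::newton_solve(prob, shapemech:::zero_state(prob),
                                  c(lv = 2.5, rv = 0, ta = 0), cfg,
                                  fixed_dofs = fd)
  expect_true(sol$ok)
  expect_lt(max(abs(sol$u)), 1e-5)
  # multiplier absorbs reference stress plus external pressure
  expect_equal(mean(sol$p), -(mat$a + 2.5), tolerance = 1e-3)
})

test_that("follower-pressure virtual work equals pressure times enclosed volume change", {
  # closed surface: pressurize every face of a cube and compare the
  # traction virtual work with the change of the enclosed volume
  mesh <- tet_box_mesh(1, 1, 1, 2, 2, 2)
  mesh$face_tags <- rep("LV_ENDO", nrow(mesh$faces))
  fib <- matrix(rep(c(1, 0, 0), nrow(mesh$tets)), ncol = 3, byrow = TRUE)
  prob <- fe_problem(mesh, fib, material_params(),
                     dirichlet_tags = character(0),
                     pressure_tags = list(lv = "LV_ENDO"))
  np2 <- prob$p2$nodes_p2
  smooth_field <- function(amp) {
    amp * cbind(sin(np2[, 1] + 0.3 * np2[, 2]),
                cos(np2[, 2]) * np2[, 3],
                np2[, 1] * np2[, 2] + 0.5 * sin(np2[, 3]))
  }
  u1 <- smooth_field(0.04)
  u2 <- u1 + smooth_field(0.002)
  closed_volume <- function(u) {
    f6 <- prob$press$lv
    x <- np2 + u
    tri <- rbind(f6[, c(1, 4, 5)], f6[, c(4, 2, 6)], f6[, c(5, 6, 3)],
                 f6[, c(4, 6, 5)])
    shapemech:::triangulation_volume(x, tri)
  }
  dV <- closed_volume(u2) - closed_volume(u1)
  pmag <- 0.8
  ps <- shapemech:::.fe_assemble_pressure(np2, prob$press$lv,
                                          rep(pmag, nrow(prob$press$lv)),
                                          (u1 + u2) / 2, prob$ndof, FALSE,
                                          prob$eps_u)
  w_ext <- -sum(ps$res[seq_len(3 * prob$p2$n_p2)] * as.vector(t(u2 - u1)))
  expect_lt(abs(abs(w_ext) - pmag * dV) / (pmag * dV), 0.02)
})

test_that("passive inflation of the ventricles is monotone in cavity volume", {
  pair <- generate_template_pair(resolution = small_resolution())
  mesh <- mesh_from_surfaces(pair$ed, char_length = 14)
  tc <- transmural_coordinate(mesh)
  fib <- suppressWarnings(assign_fibers(mesh, tc))
  prob <- fe_problem(mesh, fib, material_params())
  cfg <- mechanics_config(n_fill = 4, newton_rtol = 1e-6, newton_atol = 1e-8,
                          newton_max_iter = 40)
  st <- shapemech:::zero_state(prob)
  v0 <- mesh_cavity_volume(prob, st$u, "LV")
  vols <- v0
  for (p in c(0.4, 0.8, 1.2)) {
    st <- solve_phase(prob, st, c(lv = p, rv = p * 4 / 9, ta = 0), 2, cfg)
    expect_true(st$converged)
    vols <- c(vols, mesh_cavity_volume(prob, st$u, "LV"))
    # incompressibility diagnostic
    expect_lt(tail(st$history, 1)[[1]]$mean_abs_Jm1, 5e-2)
  }
  expect_true(all(diff(vols) > 0))
})

test_that("zero loads leave the unloaded state in equilibrium", {
  pair <- generate_template_pair(resolution = small_resolution())
  mesh <- mesh_from_surfaces(pair$ed, char_length = 14)
  tc <- transmural_coordinate(mesh)
  fib <- suppressWarnings(assign_fibers(mesh, tc))
  # pure multiplier form (no stabilization) so p = -a is exact equilibrium
  prob <- fe_problem(mesh, fib, material_params(), stabilization = 0)
  st <- shapemech:::zero_state(prob)
  sys <- shapemech:::assemble_system(prob, st$u, st$p, c(lv = 0, rv = 0, ta = 0),
                                     tangent = FALSE)
  free <- setdiff(seq_len(prob$ndof), prob$fixed_dofs)
  expect_lt(sqrt(sum(sys$res[free]^2)), 1e-6)
})
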