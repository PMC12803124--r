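# Closed-form verification helpers for the FE mechanics checks.

# helper: fiber-aligned uniaxial stretch of a unit cube, returns mean
# Cauchy stress and lateral stretch
cube_uniaxial <- function(lambda, mat, n = 2, axis = 1) {
  mesh <- tet_box_mesh(1, 1, 1, n, n, n)
  mesh$face_tags <- rep("FREE", nrow(mesh$faces))
  f0 <- c(0, 0, 0); f0[axis] <- 1
  fib <- matrix(rep(f0, nrow(mesh$tets)), ncol = 3, byrow = TRUE)
  prob <- fe_problem(mesh, fib, mat, dirichlet_tags = character(0),
                     pressure_tags = list())
  np2 <- prob$p2$nodes_p2
  tol <- 1e-9
  oth <- setdiff(1:3, axis)
  fd <- c(3 * (which(abs(np2[, axis]) < tol) - 1) + axis,
          3 * (which(abs(np2[, axis] - 1) < tol) - 1) + axis,
          3 * (which(abs(np2[, oth[1]]) < tol) - 1) + oth[1],
          3 * (which(abs(np2[, oth[2]]) < tol) - 1) + oth[2])
  fv0 <- c(rep(0, sum(abs(np2[, axis]) < tol)),
           rep(1, sum(abs(np2[, axis] - 1) < tol)),
           rep(0, sum(abs(np2[, oth[1]]) < tol)),
           rep(0, sum(abs(np2[, oth[2]]) < tol)))
  cfg <- mechanics_config()
  st <- shapemech:::zero_state(prob)
  for (f in seq(0.25, 1, by = 0.25)) {
    sol <- shapemech:::newton_solve(prob, st, c(lv = 0, rv = 0, ta = 0), cfg,
                                    fixed_dofs = fd,
                                    fixed_vals = fv0 * (lambda - 1) * f)
    expect_true(sol$ok)
    st$u <- sol$u; st$p <- sol$p
  }
  sys <- shapemech:::assemble_system(prob, st$u, st$p, c(lv = 0, rv = 0, ta = 0),
                                     tangent = FALSE)
  lat <- 1 + mean(st$u[abs(np2[, oth[1]] - 1) < tol, oth[1]])
  list(sigma = sys$mean_cauchy, lateral = lat, state = st, prob = prob,
       J_err = sys$mean_abs_Jm1)
}

closed_form_uniaxial <- function(lambda, mat) {
  I1 <- lambda^2 + 2 / lambda
  I4 <- lambda^2
  p1 <- mat$a / 2 * exp(mat$b * (I1 - 3))
  p4 <- mat$af * (I4 - 1) * exp(mat$bf * (I4 - 1)^2)
  2 * p1 * (lambda^2 - 1 / lambda) + 2 * p4 * lambda^2
}

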