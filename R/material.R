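# Transversely isotropic Holzapfel-Ogden passive law and additive active
# stress. Energy density and stresses in kPa.

#' Material parameters of the passive and active myocardium model
#'
#' The exponents default to biaxial-testing values (`b = 9.726`,
#' `bf = 15.779`); the stress scales `a` and `af` are the tunable passive
#' stiffness parameters. `eta` is the fraction of active fiber tension
#' developed transversely; `ta_max` the peak active tension.
#'
#' @param a isotropic stress scale, kPa.
#' @param b isotropic exponent (dimensionless).
#' @param af fiber stress scale, kPa.
#' @param bf fiber exponent (dimensionless).
#' @param eta transverse active-tension fraction in `[0, 1]`.
#' @param ta_max peak active tension, kPa.
#' @param fiber_compression if `FALSE`, the fiber term is disabled for
#'   compressed fibers (I4 < 1); default `TRUE` (term active as written).
#' @return an object of class `material_params`.
#' @export
material_params <- function(a = 1.28, b = 9.726, af = 1.7, bf = 15.779,
                            eta = 0.2, ta_max = 200.0,
                            fiber_compression = TRUE) {
  if (a <= 0 || af <= 0) stop_invariant("stress scales a, af must be > 0")
  if (b <= 0 || bf <= 0) stop_invariant("exponents b, bf must be > 0")
  if (eta < 0 || eta > 1) stop_invariant("eta must lie in [0, 1]")
  structure(list(a = a, b = b, af = af, bf = bf, eta = eta,
                 ta_max = ta_max, fiber_compression = fiber_compression),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("material_params: a=%.3g b=%.4g af=%.3g bf=%.4g kPa, eta=%.2f, Ta_max=%.1f kPa\n",
              x$a, x$b, x$af, x$bf, x$eta, x$ta_max))
  invisible(x)
}

#' Passive strain-energy density
#'
#' `Psi = a/(2b) (exp(b (I1 - 3)) - 1) + af/(2bf) (exp(bf (I4 - 1)^2) - 1)`
#' with `I1 = tr(C)` and `I4 = f0 . (C f0)`.
#'
#' @param C right Cauchy-Green tensor (3 x 3, symmetric positive-definite).
#' @param f0 unit reference fiber direction.
#' @param m a [material_params()] object.
#' @return energy density, kPa.
#' @export
strain_energy <- function(C, f0, m = material_params()) {
  C <- as.matrix(C)
  if (any(abs(C - t(C)) > 1e-8)) stop_invariant("C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop_invariant("C must be positive-definite")
  if (abs(sqrt(sum(f0^2)) - 1) > 1e-6) stop_invariant("f0 must be a unit vector")
  I1 <- sum(diag(C))
  I4 <- as.numeric(t(f0) %*% C %*% f0)
  iso <- m$a / (2 * m$b) * (exp(m$b * (I1 - 3)) - 1)
  fib <- if (!m$fiber_compression && I4 < 1) 0 else
    m$af / (2 * m$bf) * (exp(m$bf * (I4 - 1)^2) - 1)
  iso + fib
}

#' Active Cauchy stress tensor
#'
#' `sigma_a = Ta (f x f + eta (I - f x f))` for the deformed unit fiber
#' direction `f`; eigenvalues are `(Ta, eta Ta, eta Ta)`.
#'
#' @param ta active tension magnitude, kPa (>= 0).
#' @param f deformed unit fiber direction.
#' @param eta transverse fraction.
#' @return 3 x 3 symmetric stress tensor, kPa.
#' @export
active_cauchy_stress <- function(ta, f, eta = 0.2) {
  if (ta < 0) stop_invariant("ta must be >= 0")
  f <- f / sqrt(sum(f^2))
  ff <- tcrossprod(f)
  ta * (ff + eta * (diag(3) - ff))
}
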