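#' Viscoelastic solid material specification
#'
#' Defines an isotropic, near-incompressible tissue material. `E` is the
#' long-term (relaxed) Young's modulus; the time dependence is carried by a
#' Prony series of relative moduli `p_i` and relaxation times `T_i`, so the
#' instantaneous modulus is `E / (1 - sum(p_i))`.
#'
#' @param E long-term Young's modulus (Pa).
#' @param nu Poisson ratio, in (0, 0.5).
#' @param rho density (kg m^-3).
#' @param prony list of `(p, T)` pairs: relative modulus (dimensionless) and
#'   relaxation time (s). `NULL` or empty for a purely elastic material.
#' @return an object of class `material_spec`.
#' @examples
#' material_spec(E = 14.58e3, nu = 0.499, rho = 1160,
#'               prony = list(list(p = 0.1, T = 1e-3)))
#' @export
material_spec <- function(E, nu, rho, prony = NULL) {
  if (!is.numeric(E) || E <= 0) stop("material_spec: E must be > 0")
  if (!is.numeric(nu) || nu <= 0 || nu >= 0.5)
    stop("material_spec: nu must lie in (0, 0.5)")
  if (!is.numeric(rho) || rho <= 0) stop("material_spec: rho must be > 0")
  prony <- normalise_prony(prony)
  structure(list(E = E, nu = nu, rho = rho, prony = prony),
            class = "material_spec")
}

normalise_prony <- function(prony) {
  if (is.null(prony) || length(prony) == 0) return(list())
  if (!is.null(prony$p)) prony <- list(prony)   # single term given flat
  prony <- lapply(prony, function(tm) {
    if (is.null(tm$p) || is.null(tm$T))
      stop("material_spec: each Prony term needs fields p and T")
    if (tm$p <= 0) stop("material_spec: Prony relative modulus must be > 0")
    if (tm$T <= 0) stop("material_spec: Prony relaxation time must be > 0")
    list(p = tm$p, T = tm$T)
  })
  if (sum(vapply(prony, `[[`, 0, "p")) >= 1)
    stop("material_spec: sum of Prony relative moduli must be < 1")
  prony
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("material_spec: E = %.4g kPa, nu = %.4g, rho = %.4g kg/m^3\n",
              x$E / 1e3, x$nu, x$rho))
  for (tm in x$prony)
    cat(sprintf("  Prony term: p = %.3g, T = %.3g ms\n", tm$p, tm$T * 1e3))
  invisible(x)
}

#' Acoustic fluid specification
#'
#' Properties of the ocular humours modelled as a lossless acoustic fluid.
#' The dynamic viscosity is carried as metadata only; the acoustic elements
#' are lossless and no absorption is derived from it.
#'
#' @param rho density (kg m^-3).
#' @param c sonic velocity (m s^-1).
#' @param mu dynamic viscosity (kg s^-1 m^-1), metadata.
#' @param fsi_range distance from solid tissue (m) within which
#'   fluid-structure coupling is active on wetted edges.
#' @return an object of class `fluid_spec`.
#' @export
fluid_spec <- function(rho = 1000, c = 1480, mu = 8.94e-4, fsi_range = 2.8e-3) {
  if (rho <= 0 || c <= 0) stop("fluid_spec: rho and c must be > 0")
  if (fsi_range < 0) stop("fluid_spec: fsi_range must be >= 0")
  structure(list(rho = rho, c = c, mu = mu, fsi_range = fsi_range),
            class = "fluid_spec")
}

#' Complex frequency-dependent modulus of a Prony-series material
#'
#' Evaluates `E*(f) = E_inst * (1 - sum_i p_i / (1 + i * Omega * T_i))` with
#' `Omega = 2 * pi * f` and `E_inst = E / (1 - sum_i p_i)` the instantaneous
#' modulus. At `f = 0` this is the (purely real) long-term modulus `E`; for
#' `f -> Inf` it tends to `E_inst`. The imaginary part is the loss modulus
#' and is non-negative for all valid materials.
#'
#' @param mat a [material_spec()].
#' @param f imposed frequency (Hz), scalar or vector, `>= 0`.
#' @return complex modulus (Pa), same length as `f`.
#' @examples
#' m <- material_spec(14.58e3, 0.499, 1160, list(list(p = 0.1, T = 1e-3)))
#' complex_modulus(m, 0)                  # = E, purely real
#' complex_modulus(m, 1 / (2 * pi * 1e-3)) # Omega*T = 1
#' @export
complex_modulus <- function(mat, f) {
  stopifnot(inherits(mat, "material_spec"))
  if (any(f < 0)) stop("complex_modulus: f must be >= 0")
  psum <- if (length(mat$prony)) sum(vapply(mat$prony, `[[`, 0, "p")) else 0
  E_inst <- mat$E / (1 - psum)
  g <- rep(1 + 0i, length(f))
  for (tm in mat$prony)
    g <- g - tm$p / (1 + 1i * 2 * pi * f * tm$T)
  E_inst * g
}

## Internal: complex stiffness scale factor K(f) / K(0) for one material.
modulus_scale <- function(mat, f) complex_modulus(mat, f) / mat$E

## Internal: isotropic elasticity matrix blocks for the axisymmetric strain
## vector (e_rr, e_zz, e_theta, g_rz). Returns full, volumetric and
## deviatoric parts; the split is used for selective-reduced integration.
dmat_axi <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu  <- E / (2 * (1 + nu))
  D <- matrix(0, 4, 4)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  D[4, 4] <- mu
  Kb <- lam + 2 * mu / 3
  m <- c(1, 1, 1, 0)
  Dvol <- Kb * (m %o% m)
  list(full = D, vol = Dvol, dev = D - Dvol, mu = mu, lambda = lam)
}
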