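## Cached fixtures: the globe models are expensive to build and sweep, so
## every test file shares one instance through this memoising environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(make())
  .fixtures[[name]]
}

nominal_flap <- function() fixture("flap", function() build_flap(flap_config()))

nominal_flap_frf <- function() fixture("flap_frf", function()
  frf_sweep(nominal_flap(), 50, 750, 5))

nominal_globe <- function() fixture("globe", function() build_globe(globe_config()))

nominal_globe_frf <- function() fixture("globe_frf", function()
  frf_sweep(nominal_globe(), 50, 510, 5))

nominal_globe_peaks <- function() fixture("globe_peaks", function()
  peaks_with_modes(nominal_globe(), nominal_globe_frf()))

## nominal globe peaks from a 1 Hz locally refined sweep, with mode shapes
nominal_globe_peaks_fine <- function() fixture("globe_peaks_fine", function() {
  frf <- frf_sweep(nominal_globe(), 50, 510, 5, refine_peaks = TRUE,
                   refine_step = 1)
  peaks_with_modes(nominal_globe(), frf)
})

## Tension-dominated clamped circular membrane: analytic first resonance
## f1 = (2.405 / (2 pi a)) sqrt(sigma0 / rho).
membrane_config <- function(sigma0_kPa = 5, E_kPa = 0.05) {
  flap_config(E_kPa = E_kPa, prestress_kPa = sigma0_kPa, refine = 2)
}

membrane_f1 <- function(a = 2e-3, sigma0 = 5e3, rho = 1160)
  2.404826 / (2 * pi * a) * sqrt(sigma0 / rho)

## 1-dof oscillator expressed as a harmonic_system (m, k, optional Prony)
one_dof_system <- function(m = 1, k = 1e4, mat = NULL, F = 1) {
  if (is.null(mat)) mat <- material_spec(E = k, nu = 0.3, rho = 1)
  K <- Matrix::sparseMatrix(i = 1, j = 1, x = k, dims = c(1, 1))
  attr(K, "material") <- mat
  solid <- list(K_parts = list(dof = K),
                M = Matrix::sparseMatrix(i = 1, j = 1, x = m, dims = c(1, 1)),
                Kg = Matrix::sparseMatrix(i = integer(), j = integer(),
                                          x = numeric(), dims = c(1, 1)))
  harmonic_system(solid, NULL, load = complex(real = F, imaginary = 0),
                  constrained = integer())
}
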