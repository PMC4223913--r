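## Sparse complex solves for the harmonic system.
##
## The coupled (u, p) pencil is unsymmetric; each frequency is solved by a
## direct sparse factorisation. Complex systems are embedded as the real
## 2n x 2n block form [[Ar, -Ai], [Ai, Ar]], which Matrix's sparse LU
## handles without a complex factorisation.

## Direct sparse solve with one step of iterative refinement (the factors
## are reused, so the extra accuracy is nearly free).
solve_refined <- function(A, b, iters = 2L) {
  fac <- Matrix::lu(A)
  x <- as.vector(Matrix::solve(fac, b))
  for (i in seq_len(iters)) {
    r <- b - as.vector(A %*% x)
    x <- x + as.vector(Matrix::solve(fac, r))
  }
  x
}

solve_sparse_complex <- function(Ar, Ai, b) {
  if (is.null(Ai) || length(Ai@x) == 0 || all(Ai@x == 0)) {
    if (all(Im(b) == 0)) return(solve_refined(Ar, Re(b)) + 0i)
    fac <- Matrix::lu(Ar)
    xr <- as.vector(Matrix::solve(fac, Re(b)))
    xi <- as.vector(Matrix::solve(fac, Im(b)))
    return(xr + 1i * xi)
  }
  big <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(Re(b), Im(b))
  x <- solve_refined(big, rhs)
  n <- length(b)
  x[seq_len(n)] + 1i * x[n + seq_len(n)]
}

## Assemble the complex system matrix split into real/imaginary sparse parts.
system_matrix_parts <- function(system, f) {
  om <- 2 * pi * f
  Ar <- system$B0 - om^2 * system$B2
  Ai <- NULL
  for (K in system$K_parts) {
    g <- modulus_scale(attr(K, "material"), f)
    Ar <- Ar + Re(g) * K
    if (abs(Im(g)) > 0) Ai <- if (is.null(Ai)) Im(g) * K else Ai + Im(g) * K
  }
  if (!is.null(system$C)) {
    Ai <- if (is.null(Ai)) om * system$C else Ai + om * system$C
  }
  list(Ar = methods::as(Ar, "CsparseMatrix"),
       Ai = if (is.null(Ai)) NULL else methods::as(Ai, "CsparseMatrix"))
}

#' Solve the harmonic system at one imposed frequency
#'
#' Direct sparse solve of the complex linear system at circular frequency
#' `Omega = 2 * pi * f`. With zero damping and purely elastic materials the
#' response is real up to solver tolerance.
#'
#' @param system a [harmonic_system()].
#' @param f imposed frequency (Hz).
#' @param load_scale real or complex scale applied to the load vector.
#' @return an object of class `harmonic_solution` with fields `f`, `omega`,
#'   `u` (complex solid displacements, full dof numbering, zeros at
#'   constraints) and `p` (complex nodal pressures).
#' @export
solve_harmonic <- function(system, f, load_scale = 1) {
  stopifnot(inherits(system, "harmonic_system"))
  parts <- system_matrix_parts(system, f)
  b <- system$load * load_scale
  if (isTRUE(system$load_omega2)) b <- b * (2 * pi * f)^2
  x <- tryCatch(
    solve_sparse_complex(parts$Ar, parts$Ai, b),
    error = function(e)
      stop(sprintf(paste0("solve_harmonic: singular system at f = %g Hz ",
                          "(undamped solve at an eigenfrequency?); add damping ",
                          "or offset the frequency [%s]"), f, conditionMessage(e))))
  if (!all(is.finite(Re(x))) || !all(is.finite(Im(x))))
    stop(sprintf(paste0("solve_harmonic: non-finite response at f = %g Hz ",
                        "(undamped solve at an eigenfrequency?); add damping ",
                        "or offset the frequency"), f))
  full <- complex(system$ntot)
  full[system$free] <- x
  structure(list(f = f, omega = 2 * pi * f,
                 u = full[seq_len(system$ns)],
                 p = if (system$np > 0) full[system$ns + seq_len(system$np)] else complex(0)),
            class = "harmonic_solution")
}

#' @export
print.harmonic_solution <- function(x, ...) {
  cat(sprintf("harmonic_solution at f = %g Hz: max |u| = %.3g m\n",
              x$f, max(Mod(x$u))))
  invisible(x)
}

## Static solve of the solid subsystem (long-term moduli, f = 0):
## K u = F on the free solid dofs. Used for the IOP prestress state.
solve_static <- function(solid, load, constrained) {
  ns <- nrow(solid$M)
  K <- Reduce(`+`, solid$K_parts) + solid$Kg
  free <- setdiff(seq_len(ns), constrained[constrained <= ns])
  u <- numeric(ns)
  u[free] <- as.vector(Matrix::solve(K[free, free, drop = FALSE], load[free]))
  u
}

## Centroid stress recovery consistent with the selective-reduced element:
## the deviatoric stress uses the centroid strain, while the volumetric
## stress uses the dilatation averaged over the element's reduced-order
## quadrature points -- at nu = 0.499 the raw centroid dilatation is
## polluted by parasitic volumetric strain times the near-infinite bulk
## modulus, which would swamp the recovered stress.
recover_stresses <- function(mesh, materials, dofs, u) {
  m <- nrow(mesh$elements)
  sig <- matrix(0, m, 4)
  mvec <- c(1, 1, 1, 0)
  for (e in seq_len(m)) {
    rg <- mesh$region[e]
    mat <- materials[[rg]]
    if (is.null(mat)) next
    conn <- mesh$elements[e, ]
    nn <- n_elem_nodes(conn)
    nid <- conn[1:nn]
    xy <- mesh$nodes[nid, , drop = FALSE]
    edof <- as.vector(t(dofs$sdof[nid, , drop = FALSE]))
    ue <- u[edof]
    D <- dmat_axi(mat$E, mat$nu)
    sh <- shape_quad(nn, 0, 0)
    sc <- shape_cart(sh, xy)
    eps_c <- as.vector(bmat_axi(sh, sc) %*% ue)
    ## mean dilatation over the reduced rule (1-pt for Q4, 2x2 for Q8)
    gp <- gauss_2d(if (nn == 4L) 1L else 2L)
    vol <- 0; wsum <- 0
    for (k in seq_along(gp$w)) {
      shk <- shape_quad(nn, gp$xi[k], gp$eta[k])
      sck <- shape_cart(shk, xy)
      epsk <- as.vector(bmat_axi(shk, sck) %*% ue)
      w <- gp$w[k] * sck$detJ * sck$r
      vol <- vol + w * sum(epsk[1:3])
      wsum <- wsum + w
    }
    vol <- vol / wsum
    Kb <- D$lambda + 2 * D$mu / 3
    eps_dev <- eps_c - sum(eps_c[1:3]) / 3 * mvec
    sig[e, ] <- as.vector(D$dev %*% eps_dev) + Kb * vol * mvec
  }
  sig
}
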