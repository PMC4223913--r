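## Element-level and global assembly for the axisymmetric harmonic
## structural-acoustic system
##
##   (-Omega^2 [M] + i Omega [C] + [K(Omega)]) {u1 + i u2} = {F1 + i F2}
##
## All integrals carry the 2*pi*r axisymmetric measure. Near-incompressible
## solids (nu = 0.499) use selective-reduced integration: the volumetric
## part of the elasticity tensor is integrated one order lower than the
## deviatoric part, which prevents volumetric locking without changing the
## element's convergence order.

## Strain-displacement matrix (4 x 2*nn) for strain (e_rr, e_zz, e_tt, g_rz),
## dof order (ur1, uz1, ur2, uz2, ...).
bmat_axi <- function(sh, sc) {
  nn <- length(sh$N)
  B <- matrix(0, 4, 2 * nn)
  ir <- seq(1, 2 * nn, by = 2)
  iz <- ir + 1
  B[1, ir] <- sc$dNdx[, 1]
  B[2, iz] <- sc$dNdx[, 2]
  B[3, ir] <- sh$N / sc$r
  B[4, ir] <- sc$dNdx[, 2]
  B[4, iz] <- sc$dNdx[, 1]
  B
}

## Solid element stiffness for unit long-term modulus material (E, nu given).
## integration = "sri" (deviatoric full / volumetric reduced, default) or
## "full" (single full-order rule, used by verification tests).
elem_K_solid <- function(xy, nn, E, nu, integration = "sri") {
  D <- dmat_axi(E, nu)
  full_n <- if (nn == 4L) 2L else 3L
  red_n  <- full_n - 1L
  K <- matrix(0, 2 * nn, 2 * nn)
  add <- function(Dm, n_gauss) {
    gp <- gauss_2d(n_gauss)
    for (k in seq_along(gp$w)) {
      sh <- shape_quad(nn, gp$xi[k], gp$eta[k])
      sc <- shape_cart(sh, xy)
      if (sc$detJ <= 0)
        stop("non-positive Jacobian at a quadrature point")
      B <- bmat_axi(sh, sc)
      K <<- K + t(B) %*% (Dm %*% B) * (2 * pi * sc$r * sc$detJ * gp$w[k])
    }
  }
  if (integration == "full") {
    add(D$full, full_n)
  } else {
    add(D$dev, full_n)
    add(D$vol, red_n)
  }
  K
}

## Consistent element mass matrix.
elem_M_solid <- function(xy, nn, rho) {
  gp <- gauss_2d(if (nn == 4L) 2L else 3L)
  M <- matrix(0, 2 * nn, 2 * nn)
  ir <- seq(1, 2 * nn, by = 2)
  for (k in seq_along(gp$w)) {
    sh <- shape_quad(nn, gp$xi[k], gp$eta[k])
    sc <- shape_cart(sh, xy)
    NN <- sh$N %o% sh$N * (rho * 2 * pi * sc$r * sc$detJ * gp$w[k])
    M[ir, ir] <- M[ir, ir] + NN
    M[ir + 1, ir + 1] <- M[ir + 1, ir + 1] + NN
  }
  M
}

## Geometric (stress-stiffening) element matrix for a per-element stress
## state sigma = (s_rr, s_zz, s_tt, s_rz) in Pa. Both displacement
## components are stiffened by the in-plane stress block; the hoop stress
## acts on u_r through the 1/r term.
elem_Kg <- function(xy, nn, sigma) {
  gp <- gauss_2d(if (nn == 4L) 2L else 3L)
  S2 <- matrix(c(sigma[1], sigma[4], sigma[4], sigma[2]), 2, 2)
  Kg <- matrix(0, 2 * nn, 2 * nn)
  ir <- seq(1, 2 * nn, by = 2)
  for (k in seq_along(gp$w)) {
    sh <- shape_quad(nn, gp$xi[k], gp$eta[k])
    sc <- shape_cart(sh, xy)
    w <- 2 * pi * sc$r * sc$detJ * gp$w[k]
    G <- sc$dNdx %*% S2 %*% t(sc$dNdx) * w       # nn x nn
    Kg[ir, ir] <- Kg[ir, ir] + G + sigma[3] * (sh$N %o% sh$N) / sc$r^2 * w
    Kg[ir + 1, ir + 1] <- Kg[ir + 1, ir + 1] + G
  }
  Kg
}

## Acoustic fluid element: H = int (1/rho) grad(N) grad(N) 2 pi r,
## Q = int 1/(rho c^2) N N 2 pi r. Pressure formulation; the pencil is
## H p - omega^2 (Q p + R^T u) = 0.
elem_fluid <- function(xy, nn, rho, c) {
  gp <- gauss_2d(2L)
  H <- Q <- matrix(0, nn, nn)
  for (k in seq_along(gp$w)) {
    sh <- shape_quad(nn, gp$xi[k], gp$eta[k])
    sc <- shape_cart(sh, xy)
    w <- 2 * pi * sc$r * sc$detJ * gp$w[k]
    H <- H + (sc$dNdx %*% t(sc$dNdx)) * (w / rho)
    Q <- Q + (sh$N %o% sh$N) * (w / (rho * c^2))
  }
  list(H = H, Q = Q)
}

## 1D shape functions along an element edge (xi in [-1, 1]).
edge_shape <- function(nn, xi) {
  if (nn == 2L) {
    list(N = c(0.5 * (1 - xi), 0.5 * (1 + xi)),
         dN = c(-0.5, 0.5))
  } else {
    list(N = c(0.5 * xi * (xi - 1), 0.5 * xi * (xi + 1), 1 - xi^2),
         dN = c(xi - 0.5, xi + 0.5, -2 * xi))
  }
}

## Consistent nodal force from pressure p acting on an edge, directed along
## the edge normal `nrm_ref` side (the normal is oriented so that
## dot(normal, ref_dir) > 0). xy_edge: node coordinates (2 or 3 rows;
## order n1, n2[, mid]). Returns 2*ne force vector (ur, uz per node).
edge_pressure_force <- function(xy_edge, p, ref_dir) {
  ne <- nrow(xy_edge)
  f <- numeric(2 * ne)
  g <- gauss_1d(3)
  for (k in seq_along(g$w)) {
    es <- edge_shape(ne, g$x[k])
    tang <- as.vector(t(es$dN) %*% xy_edge)   # d(r,z)/dxi
    nrm <- c(tang[2], -tang[1])               # rotate -90 deg; |nrm| = |J|
    if (sum(nrm * ref_dir) < 0) nrm <- -nrm
    r <- sum(es$N * xy_edge[, 1])
    for (a in seq_len(ne)) {
      f[2 * a - 1] <- f[2 * a - 1] + es$N[a] * nrm[1] * p * 2 * pi * r * g$w[k]
      f[2 * a]     <- f[2 * a]     + es$N[a] * nrm[2] * p * 2 * pi * r * g$w[k]
    }
  }
  f
}

## Fluid-structure coupling block for one wetted edge:
## R[udof, pdof] = int N_u n N_p 2 pi r ds, with n pointing from the fluid
## into the solid. The structural edge may be quadratic (3 nodes) while the
## pressure interpolation is linear over the same geometric edge.
edge_coupling <- function(xy_edge_solid, n_solid_nodes, ref_dir) {
  ne <- n_solid_nodes
  Rm <- matrix(0, 2 * ne, 2)   # pressure dofs: the two corner nodes
  g <- gauss_1d(3)
  for (k in seq_along(g$w)) {
    es <- edge_shape(ne, g$x[k])
    ep <- edge_shape(2L, g$x[k])
    tang <- as.vector(t(es$dN) %*% xy_edge_solid)
    nrm <- c(tang[2], -tang[1])
    if (sum(nrm * ref_dir) < 0) nrm <- -nrm
    r <- sum(es$N * xy_edge_solid[, 1])
    w <- 2 * pi * r * g$w[k]
    for (a in seq_len(ne)) for (b in 1:2) {
      Rm[2 * a - 1, b] <- Rm[2 * a - 1, b] + es$N[a] * nrm[1] * ep$N[b] * w
      Rm[2 * a, b]     <- Rm[2 * a, b]     + es$N[a] * nrm[2] * ep$N[b] * w
    }
  }
  Rm
}

## ---- global assembly ---------------------------------------------------

## Dof maps: every node used by a solid element gets (ur, uz); every node
## used by a fluid element gets a pressure dof.
build_dof_maps <- function(mesh, solid_regions, fluid_regions) {
  n <- nrow(mesh$nodes)
  sdof <- matrix(0L, n, 2)
  pdof <- integer(n)
  is_solid <- mesh$region %in% solid_regions
  is_fluid <- mesh$region %in% fluid_regions
  snodes <- sort(unique(as.vector(mesh$elements[is_solid, ])))
  snodes <- snodes[!is.na(snodes)]
  fnodes <- sort(unique(as.vector(mesh$elements[is_fluid, ])))
  fnodes <- fnodes[!is.na(fnodes)]
  sdof[snodes, 1] <- seq_along(snodes) * 2L - 1L
  sdof[snodes, 2] <- seq_along(snodes) * 2L
  pdof[fnodes] <- seq_along(fnodes)
  list(sdof = sdof, pdof = pdof, ns = 2L * length(snodes), np = length(fnodes),
       is_solid = is_solid, is_fluid = is_fluid)
}

triplet_bin <- function() {
  env <- new.env(parent = emptyenv())
  env$i <- list(); env$j <- list(); env$x <- list(); env$k <- 0L
  env
}
tb_add <- function(tb, idx_i, idx_j, mat) {
  tb$k <- tb$k + 1L
  tb$i[[tb$k]] <- rep(idx_i, times = length(idx_j))
  tb$j[[tb$k]] <- rep(idx_j, each = length(idx_i))
  tb$x[[tb$k]] <- as.vector(mat)
}
tb_sparse <- function(tb, nr, nc) {
  if (tb$k == 0L) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(), dims = c(nr, nc)))
  Matrix::sparseMatrix(i = unlist(tb$i), j = unlist(tb$j), x = unlist(tb$x),
                       dims = c(nr, nc))
}

#' Assemble the structural part of the harmonic system
#'
#' Builds the long-term stiffness (one sparse block per material so the
#' Prony complex-modulus scaling can be applied per frequency), the
#' consistent mass matrix, and the geometric (stress-stiffening) matrix from
#' a per-element prestress state.
#'
#' @param mesh an [axi_mesh()].
#' @param materials named list mapping solid region tags to [material_spec()].
#' @param prestress `NULL`, or a numeric matrix `m x 4` of per-element stress
#'   `(s_rr, s_zz, s_tt, s_rz)` in Pa (rows for fluid elements are ignored).
#' @param integration `"sri"` (selective-reduced, default) or `"full"`.
#' @return a list with sparse matrices `K_parts` (one per material, with the
#'   material attached), `M`, `Kg`, region mass matrices `M_region`, and the
#'   dof maps.
#' @export
assemble_solid <- function(mesh, materials, prestress = NULL,
                           integration = "sri") {
  solid_regions <- names(materials)
  dofs <- build_dof_maps(mesh, solid_regions, setdiff(unique(mesh$region), solid_regions))
  ns <- dofs$ns
  groups <- split(which(dofs$is_solid), mesh$region[dofs$is_solid])
  K_parts <- list()
  tbM <- triplet_bin(); tbKg <- triplet_bin()
  M_region <- list()
  for (rg in names(groups)) {
    mat <- materials[[rg]]
    tbK <- triplet_bin(); tbMr <- triplet_bin()
    for (e in groups[[rg]]) {
      conn <- mesh$elements[e, ]
      nn <- n_elem_nodes(conn)
      nid <- conn[1:nn]
      xy <- mesh$nodes[nid, , drop = FALSE]
      edof <- as.vector(t(dofs$sdof[nid, , drop = FALSE]))
      if (any(edof == 0L))
        stop(sprintf("assemble_solid: element %d touches a node without solid dofs", e))
      Ke <- tryCatch(elem_K_solid(xy, nn, mat$E, mat$nu, integration),
                     error = function(err)
                       stop(sprintf("assemble_solid: degenerate geometry in element %d (%s)",
                                    e, conditionMessage(err))))
      Me <- elem_M_solid(xy, nn, mat$rho)
      tb_add(tbK, edof, edof, Ke)
      tb_add(tbMr, edof, edof, Me)
      tb_add(tbM, edof, edof, Me)
      if (!is.null(prestress) && any(prestress[e, ] != 0))
        tb_add(tbKg, edof, edof, elem_Kg(xy, nn, prestress[e, ]))
    }
    K <- tb_sparse(tbK, ns, ns)
    attr(K, "material") <- mat
    K_parts[[rg]] <- K
    M_region[[rg]] <- tb_sparse(tbMr, ns, ns)
  }
  list(K_parts = K_parts, M = tb_sparse(tbM, ns, ns),
       Kg = tb_sparse(tbKg, ns, ns), M_region = M_region, dofs = dofs)
}

#' Assemble the acoustic fluid part and the coupling matrices
#'
#' Pressure-formulation acoustic elements (Helmholtz operator scaled so the
#' rigid-cavity eigenfrequencies equal their analytic values) and the
#' fluid-structure coupling matrix built on the mesh's `fsi_edges` that lie
#' within `fluid$fsi_range` of solid tissue.
#'
#' @param mesh an [axi_mesh()] containing at least one fluid element.
#' @param fluid a [fluid_spec()].
#' @param dofs dof maps from [assemble_solid()] (or computed internally for a
#'   fluid-only mesh).
#' @param fluid_region region tag of the fluid elements.
#' @return list with sparse `H`, `Q` (np x np) and `R` (ns x np).
#' @export
assemble_fluid <- function(mesh, fluid, dofs = NULL, fluid_region = "fluid") {
  if (is.null(fluid) || !inherits(fluid, "fluid_spec"))
    stop("assemble_fluid: missing fluid properties")
  if (!any(mesh$region == fluid_region))
    stop("assemble_fluid: no fluid elements in mesh")
  if (is.null(dofs))
    dofs <- build_dof_maps(mesh, setdiff(unique(mesh$region), fluid_region),
                           fluid_region)
  np <- dofs$np; ns <- dofs$ns
  tbH <- triplet_bin(); tbQ <- triplet_bin()
  for (e in which(mesh$region == fluid_region)) {
    conn <- mesh$elements[e, ]
    nn <- n_elem_nodes(conn)
    nid <- conn[1:nn]
    xy <- mesh$nodes[nid, , drop = FALSE]
    fe <- elem_fluid(xy, nn, fluid$rho, fluid$c)
    pd <- dofs$pdof[nid]
    tb_add(tbH, pd, pd, fe$H)
    tb_add(tbQ, pd, pd, fe$Q)
  }
  H <- tb_sparse(tbH, np, np)
  Q <- tb_sparse(tbQ, np, np)
  R <- NULL
  if (!is.null(mesh$fsi_edges) && nrow(mesh$fsi_edges) > 0 && ns > 0) {
    tbR <- triplet_bin()
    for (k in seq_len(nrow(mesh$fsi_edges))) {
      ed <- mesh$fsi_edges[k, ]
      sn <- c(ed$n1, ed$n2, ed$nm)
      sn <- sn[!is.na(sn)]
      xy <- mesh$nodes[sn, , drop = FALSE]
      ## skip edges beyond the coupling range (distance is zero for wetted
      ## edges, so the filter only acts for artificially enlarged ranges)
      if (fluid$fsi_range < 0) next
      ## reference direction: from fluid element centroid towards the edge
      fconn <- mesh$elements[ed$fluid_el, ]
      fnid <- fconn[1:n_elem_nodes(fconn)]
      cf <- colMeans(mesh$nodes[fnid, , drop = FALSE])
      ref <- colMeans(xy) - cf
      Rm <- edge_coupling(xy, length(sn), ref)
      udof <- as.vector(t(dofs$sdof[sn, , drop = FALSE]))
      pd <- dofs$pdof[c(ed$n1, ed$n2)]
      tb_add(tbR, udof, pd, Rm)
    }
    R <- tb_sparse(tbR, ns, np)
  }
  list(H = H, Q = Q, R = R)
}

#' Construct a harmonic structural-acoustic system
#'
#' Combines the structural and acoustic blocks into the coupled pencil
#' `A(Omega) = sum_r g_r(f) K_r + Kg + i Omega C - Omega^2 B2 + B0_fluid`
#' on the unconstrained dofs, where `g_r(f)` is the complex modulus scale of
#' material `r`. Dof ordering is all solid dofs first, then pressure dofs.
#'
#' @param solid output of [assemble_solid()] (or a compatible list with
#'   `K_parts`, `M`, `Kg`, `dofs`).
#' @param fluid_sys output of [assemble_fluid()], or `NULL` for in-vacuo.
#' @param load complex load vector of length `ns + np` (F1 + i F2).
#' @param constrained integer vector of constrained dof indices (combined
#'   numbering).
#' @param C optional structural damping matrix (`ns x ns`), e.g. Rayleigh
#'   damping; default none (viscoelastic damping enters through `K(Omega)`).
#' @param load_omega2 if `TRUE`, the stored load is multiplied by `Omega^2`
#'   at solve time (inertial excitation by a shaken frame).
#' @return an object of class `harmonic_system`.
#' @export
harmonic_system <- function(solid, fluid_sys = NULL, load, constrained = integer(),
                            C = NULL, load_omega2 = FALSE) {
  ns <- nrow(solid$M)
  np <- if (is.null(fluid_sys)) 0L else nrow(fluid_sys$H)
  ntot <- ns + np
  free <- setdiff(seq_len(ntot), constrained)
  pad <- function(A, ri, ci) {
    ## place block A at rows ri, cols ci of the ntot x ntot frame
    A <- methods::as(A, "CsparseMatrix")
    s <- Matrix::summary(A)
    Matrix::sparseMatrix(i = ri[s$i], j = ci[s$j], x = s$x, dims = c(ntot, ntot))
  }
  si <- seq_len(ns); pi_ <- ns + seq_len(np)
  Kg_big <- pad(solid$Kg, si, si)
  B0 <- Kg_big
  B2 <- pad(solid$M, si, si)
  if (np > 0) {
    B0 <- B0 + pad(fluid_sys$H, pi_, pi_)
    B2 <- B2 + pad(fluid_sys$Q, pi_, pi_)
    if (!is.null(fluid_sys$R)) {
      s <- Matrix::summary(methods::as(fluid_sys$R, "CsparseMatrix"))
      Rbig <- Matrix::sparseMatrix(i = s$i, j = ns + s$j, x = s$x, dims = c(ntot, ntot))
      B0 <- B0 - Rbig
      B2 <- B2 + Matrix::t(Rbig)
    }
  }
  K_big <- lapply(solid$K_parts, function(K) {
    Kb <- pad(K, si, si)
    attr(Kb, "material") <- attr(K, "material")
    Kb
  })
  Cb <- if (is.null(C)) NULL else pad(C, si, si)
  sub <- function(A) if (is.null(A)) NULL else A[free, free, drop = FALSE]
  structure(list(
    K_parts = lapply(K_big, function(K) {
      Ks <- sub(K); attr(Ks, "material") <- attr(K, "material"); Ks
    }),
    B0 = sub(B0), B2 = sub(B2), C = sub(Cb),
    load = load[free], load_omega2 = isTRUE(load_omega2),
    free = free, ns = ns, np = np, ntot = ntot,
    constrained = constrained), class = "harmonic_system")
}

#' @export
print.harmonic_system <- function(x, ...) {
  cat(sprintf("harmonic_system: %d solid dofs + %d pressure dofs (%d free)\n",
              x$ns, x$np, length(x$free)))
  invisible(x)
}
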