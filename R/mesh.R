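#' Axisymmetric cross-section mesh
#'
#' Container for the (r, z) cross-section discretisation. Elements are 4-node
#' bilinear or 8-node serendipity quadrilaterals stored in one connectivity
#' matrix (8 columns, `NA` in columns 5:8 for 4-node elements). Region tags
#' partition the element set; `fsi_edges` lists element edges shared by one
#' solid and one fluid element on which fluid-structure coupling acts.
#'
#' @param nodes numeric matrix `n x 2` of (r, z) coordinates in metres, r >= 0.
#' @param elements integer matrix `m x 8` of node indices (`NA`-padded for
#'   4-node elements). Corner nodes first (counter-clockwise), then midside.
#' @param region character vector of length `m` of region tags.
#' @param fsi_edges optional data frame with columns `solid_el`, `fluid_el`,
#'   `n1`, `n2`, `nm` (corner and midside node ids of the wetted edge).
#' @param check if `TRUE`, verify node/element invariants (positive Jacobian
#'   at all quadrature points, r >= 0).
#' @return an object of class `axi_mesh`.
#' @export
axi_mesh <- function(nodes, elements, region, fsi_edges = NULL, check = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  if (ncol(elements) == 4) elements <- cbind(elements, matrix(NA_integer_, nrow(elements), 4))
  storage.mode(elements) <- "integer"
  if (length(region) != nrow(elements))
    stop("axi_mesh: one region tag per element required")
  m <- structure(list(nodes = nodes, elements = elements,
                      region = as.character(region), fsi_edges = fsi_edges),
                 class = "axi_mesh")
  if (check) check_mesh(m)
  m
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("axi_mesh: %d nodes, %d elements\n", nrow(x$nodes), nrow(x$elements)))
  print(table(x$region))
  invisible(x)
}

n_elem_nodes <- function(conn_row) if (anyNA(conn_row)) 4L else 8L

## Gauss-Legendre rules on [-1, 1]
gauss_1d <- function(n) {
  switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    stop("unsupported Gauss order"))
}

gauss_2d <- function(n) {
  g <- gauss_1d(n)
  pts <- expand.grid(xi = g$x, eta = g$x)
  w <- as.vector(outer(g$w, g$w))
  list(xi = pts$xi, eta = pts$eta, w = w)
}

## Shape functions: returns list(N = nn-vector, dN = nn x 2 matrix of
## derivatives wrt (xi, eta)).
shape_quad <- function(nn, xi, eta) {
  if (nn == 4L) {
    xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
    N <- 0.25 * (1 + xi * xs) * (1 + eta * es)
    dN <- cbind(0.25 * xs * (1 + eta * es), 0.25 * es * (1 + xi * xs))
  } else {
    xs <- c(-1, 1, 1, -1, 0, 1, 0, -1)
    es <- c(-1, -1, 1, 1, -1, 0, 1, 0)
    N <- numeric(8); dN <- matrix(0, 8, 2)
    for (i in 1:4) {
      N[i] <- 0.25 * (1 + xi * xs[i]) * (1 + eta * es[i]) * (xi * xs[i] + eta * es[i] - 1)
      dN[i, 1] <- 0.25 * xs[i] * (1 + eta * es[i]) * (2 * xi * xs[i] + eta * es[i])
      dN[i, 2] <- 0.25 * es[i] * (1 + xi * xs[i]) * (xi * xs[i] + 2 * eta * es[i])
    }
    for (i in c(5, 7)) {   # midside nodes at eta = +-1, xi = 0
      N[i] <- 0.5 * (1 - xi^2) * (1 + eta * es[i])
      dN[i, 1] <- -xi * (1 + eta * es[i])
      dN[i, 2] <- 0.5 * (1 - xi^2) * es[i]
    }
    for (i in c(6, 8)) {   # midside nodes at xi = +-1, eta = 0
      N[i] <- 0.5 * (1 - eta^2) * (1 + xi * xs[i])
      dN[i, 1] <- 0.5 * (1 - eta^2) * xs[i]
      dN[i, 2] <- -eta * (1 + xi * xs[i])
    }
  }
  list(N = N, dN = dN)
}

## Jacobian and cartesian shape derivatives at one quadrature point.
## xy: nn x 2 element node coordinates.
shape_cart <- function(sh, xy) {
  J <- t(sh$dN) %*% xy          # 2x2: d(r,z)/d(xi,eta)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  dNdx <- sh$dN %*% t(solve(J)) # nn x 2: derivatives wrt (r, z)
  list(detJ = detJ, dNdx = dNdx, r = sum(sh$N * xy[, 1]))
}

check_mesh <- function(mesh) {
  if (any(mesh$nodes[, 1] < -1e-12))
    stop("axi_mesh: node radii must be >= 0")
  gp <- gauss_2d(2)
  for (e in seq_len(nrow(mesh$elements))) {
    conn <- mesh$elements[e, ]
    nn <- n_elem_nodes(conn)
    xy <- mesh$nodes[conn[1:nn], , drop = FALSE]
    for (k in seq_along(gp$w)) {
      sh <- shape_quad(nn, gp$xi[k], gp$eta[k])
      J <- t(sh$dN) %*% xy
      if (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1] <= 0)
        stop(sprintf("axi_mesh: element %d has non-positive Jacobian", e))
    }
  }
  invisible(TRUE)
}

## Structured mapped grid of quadrilaterals.
##
## map(s, t) with s, t in [0, 1] must return c(r, z). For order = 2 the
## midside nodes are placed through the same mapping, so curved boundaries
## (spherical surfaces) are represented quadratically.
## Returns list(nodes, elements (8 col), node_id function(i, j)).
structured_grid <- function(ns, nt, map, order = 1L) {
  if (order == 1L) {
    si <- seq(0, 1, length.out = ns + 1)
    tj <- seq(0, 1, length.out = nt + 1)
    idx <- function(i, j) as.integer((j - 1L) * (ns + 1L) + i)
    nodes <- matrix(0, (ns + 1) * (nt + 1), 2)
    for (j in seq_len(nt + 1)) for (i in seq_len(ns + 1))
      nodes[idx(i, j), ] <- map(si[i], tj[j])
    el <- matrix(NA_integer_, ns * nt, 8)
    e <- 0L
    for (j in seq_len(nt)) for (i in seq_len(ns)) {
      e <- e + 1L
      el[e, 1:4] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
    list(nodes = nodes, elements = el,
         corner_id = function(i, j) idx(i, j))
  } else {
    ## serendipity grid on half-steps; skip (odd, odd) interior nodes
    si <- seq(0, 1, length.out = 2 * ns + 1)
    tj <- seq(0, 1, length.out = 2 * nt + 1)
    id <- matrix(0L, 2 * ns + 1, 2 * nt + 1)
    nodes <- matrix(0, 0, 2)
    cnt <- 0L
    coords <- vector("list", (2 * ns + 1) * (2 * nt + 1))
    for (j in seq_len(2 * nt + 1)) for (i in seq_len(2 * ns + 1)) {
      if (i %% 2 == 0 && j %% 2 == 0) next  # element-centre node not used
      cnt <- cnt + 1L
      id[i, j] <- cnt
      coords[[cnt]] <- map(si[i], tj[j])
    }
    nodes <- do.call(rbind, coords[seq_len(cnt)])
    el <- matrix(NA_integer_, ns * nt, 8)
    e <- 0L
    for (j in seq_len(nt)) for (i in seq_len(ns)) {
      e <- e + 1L
      i0 <- 2L * i - 1L; j0 <- 2L * j - 1L
      el[e, ] <- c(id[i0, j0], id[i0 + 2, j0], id[i0 + 2, j0 + 2], id[i0, j0 + 2],
                   id[i0 + 1, j0], id[i0 + 2, j0 + 1], id[i0 + 1, j0 + 2], id[i0, j0 + 1])
    }
    list(nodes = nodes, elements = el,
         corner_id = function(i, j) id[2L * i - 1L, 2L * j - 1L],
         id_grid = id)
  }
}

## Element cross-section area by quadrature (used for mesh/region checks).
element_area <- function(mesh, e) {
  conn <- mesh$elements[e, ]
  nn <- n_elem_nodes(conn)
  xy <- mesh$nodes[conn[1:nn], , drop = FALSE]
  gp <- gauss_2d(2)
  a <- 0
  for (k in seq_along(gp$w)) {
    sh <- shape_quad(nn, gp$xi[k], gp$eta[k])
    sc <- shape_cart(sh, xy)
    a <- a + gp$w[k] * sc$detJ
  }
  a
}

#' Cross-section area of each mesh region
#'
#' @param mesh an [axi_mesh()].
#' @return named numeric vector of region areas (m^2, meridional section).
#' @export
region_areas <- function(mesh) {
  a <- vapply(seq_len(nrow(mesh$elements)), function(e) element_area(mesh, e), 0)
  tapply(a, mesh$region, sum)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Quadrilaterals are written as Gmsh element type 3 (4-node) or 16 (8-node);
#' region tags become physical/elementary tags in file order of the unique
#' region names.
#'
#' @param mesh an [axi_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines(c("$Nodes", nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.9g %.9g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", nrow(mesh$elements)), con)
  regs <- unique(mesh$region)
  for (e in seq_len(nrow(mesh$elements))) {
    conn <- mesh$elements[e, ]
    nn <- n_elem_nodes(conn)
    typ <- if (nn == 4L) 3L else 16L
    tag <- match(mesh$region[e], regs)
    writeLines(paste(c(e, typ, 2, tag, tag, conn[1:nn]), collapse = " "), con)
  }
  writeLines("$EndElements", con)
  invisible(path)
}

#' Export a harmonic solution as CSV
#'
#' Writes one row per node: `node, r, z, re_ur, im_ur, re_uz, im_uz`
#' (and `re_p, im_p` where a pressure dof exists).
#'
#' @param model a model built by [build_flap()] or [build_globe()].
#' @param sol a solution from [solve_harmonic()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(model, sol, path) {
  nd <- model$mesh$nodes
  ur <- uz <- p <- rep(NA_complex_, nrow(nd))
  sd <- model$dofs$sdof
  has <- sd[, 1] > 0
  ur[has] <- sol$u[sd[has, 1]]
  uz[has] <- sol$u[sd[has, 2]]
  pd <- model$dofs$pdof
  hasp <- pd > 0
  p[hasp] <- sol$p[pd[hasp]]
  df <- data.frame(node = seq_len(nrow(nd)), r = nd[, 1], z = nd[, 2],
                   re_ur = Re(ur), im_ur = Im(ur),
                   re_uz = Re(uz), im_uz = Im(uz),
                   re_p = Re(p), im_p = Im(p))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
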