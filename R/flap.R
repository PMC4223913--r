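#' Build the corneal flap model
#'
#' Rectangular r-z cross-section of the circular flap, meshed with 4-node
#' axisymmetric elements (default 27 x 2 = 54). All displacements at the
#' outer rim are constrained (holder clamp); the mounting stress is applied
#' as a uniform equi-biaxial in-plane tension entering through the geometric
#' stiffness. The default excitation is the rigid-frame inertial drive;
#' `excitation = "pressure"` applies a unit uniform pressure on the lower
#' face instead.
#'
#' @param cfg a [flap_config()].
#' @return an `ocuvib_model`.
#' @examples
#' m <- build_flap(flap_config())
#' nrow(m$mesh$elements)   # 54
#' @export
build_flap <- function(cfg) {
  stopifnot(inherits(cfg, "flap_config"))
  a <- cfg$diameter_mm / 2 * 1e-3
  h <- cfg$thickness_um * 1e-6
  nr <- cfg$n_radial * cfg$refine
  nz <- cfg$n_thickness * cfg$refine
  grid <- structured_grid(nr, nz, function(s, t) c(a * s, h * t), order = 1L)
  mesh <- axi_mesh(grid$nodes, grid$elements,
                   rep("cornea", nr * nz), check = FALSE)
  materials <- list(cornea = cfg_material(cfg))
  p0 <- cfg$prestress_kPa * 1e3
  sigma <- if (p0 != 0)
    matrix(rep(c(p0, 0, p0, 0), each = nr * nz), ncol = 4) else NULL
  tol <- a * 1e-9
  rim <- which(abs(mesh$nodes[, 1] - a) < tol)
  axis <- which(mesh$nodes[, 1] < tol)
  ## excitation: unit pressure on the lower face (z = 0), pushing upward
  le <- data.frame(n1 = vapply(seq_len(nr), function(i) grid$corner_id(i, 1), 0L),
                   n2 = vapply(seq_len(nr), function(i) grid$corner_id(i + 1, 1), 0L),
                   nm = NA_integer_, ref_r = 0, ref_z = 1)
  probe <- grid$corner_id(1, nz + 1)   # apex node on the anterior (upper) face
  top <- vapply(seq_len(nr + 1), function(i) grid$corner_id(i, nz + 1), 0L)
  finalize_model("flap", cfg, mesh, materials, fluid = NULL,
                 prestress_sigma = sigma, constrained_nodes_fixed = rim,
                 axis_nodes = axis, load_edges = le, probe_node = probe,
                 arc_nodes = top, arc_coord = mesh$nodes[top, 1])
}
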