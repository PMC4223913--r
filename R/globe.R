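#' Build the whole eye globe model
#'
#' Axisymmetric cross-section of a whole eye globe: a spherical-cap cornea
#' of two through-thickness layers (independent anterior/posterior moduli),
#' a limbus wedge, a scleral shell and an acoustic-fluid fill representing
#' the aqueous and vitreous humours. The corneal anterior surface and the
#' scleral outer surface are spheres of the configured radii; the corneal
#' posterior sphere is placed so the central thickness is exact, and the
#' corneal anterior edge lies on the scleral sphere so that cornea, limbus
#' and sclera join smoothly. Tissue elements are 8-node serendipity quads
#' (default 80 + 12 + 182); the humour mesh is 4-node acoustic quads
#' (default 1233) sharing the tissue's inner-surface corner nodes, with
#' fluid-structure coupling on every wetted edge within the configured
#' range -- by default a coupled layer of rings marching `fsi_range_mm`
#' inward from the wetted surface (pressure-release inner boundary), or a
#' full polar-fan cavity when `fluid_region = "cavity"`. The globe is held
#' by a fixed circular ring on the outer sclera; the default excitation is
#' the rigid-frame inertial drive (see [globe_config()]).
#'
#' @param cfg a [globe_config()].
#' @return an `ocuvib_model`. Extra fields: `geom` (derived geometry),
#'   `theta_deg` (per-element centroid angle, 0 at the scleral equator, 90
#'   at the corneal apex).
#' @export
build_globe <- function(cfg) {
  stopifnot(inherits(cfg, "globe_config"))
  mm <- 1e-3
  Ra <- cfg$anterior_curvature_mm * mm
  Rp <- cfg$posterior_curvature_mm * mm
  cct <- cfg$cct_um * 1e-6
  rc <- cfg$cornea_diameter_mm / 2 * mm
  Rs <- cfg$sclera_diameter_mm / 2 * mm
  ts <- cfg$sclera_thickness_mm * mm
  if (rc >= Ra) stop("build_globe: corneal cap does not close (diameter too large)")
  ## centres on the optical axis; corneal apex (anterior) at the origin
  Ca <- c(0, -Ra)
  Cp <- c(0, -(cct + Rp))
  alpha_c <- asin(rc / Ra)
  A_edge <- Ca + Ra * c(sin(alpha_c), cos(alpha_c))
  zs <- A_edge[2] - sqrt(Rs^2 - rc^2)         # scleral centre depth
  Cs <- c(0, zs)
  psi_edge <- asin(rc / Rs)
  d <- Ca - Cp
  post_u <- function(alpha) {                  # ray length Ca -> posterior sphere
    e <- c(sin(alpha), cos(alpha))
    de <- sum(d * e)
    disc <- de^2 - sum(d * d) + Rp^2
    if (disc < 0) stop("build_globe: corneal cap does not meet the posterior sphere")
    -de + sqrt(disc)
  }
  P_edge <- Ca + post_u(alpha_c) * c(sin(alpha_c), cos(alpha_c))
  if (post_u(alpha_c) >= Ra)
    stop("build_globe: posterior surface crosses the anterior at the limbus")

  nc <- cfg$n_arc_cornea * cfg$refine
  nl <- cfg$n_arc_limbus * cfg$refine
  nsc <- cfg$n_arc_sclera * cfg$refine
  nt <- cfg$n_thickness * cfg$refine
  ns_arc <- nc + nl + nsc
  s1 <- nc / ns_arc; s2 <- (nc + nl) / ns_arc
  ## limbus + sclera share a uniform arc on the scleral sphere
  psi_start <- psi_edge + (pi - psi_edge) * nl / (nl + nsc)
  S_outer <- function(psi) Cs + Rs * c(sin(psi), cos(psi))
  S_inner <- function(psi) Cs + (Rs - ts) * c(sin(psi), cos(psi))
  Si_start <- S_inner(psi_start)
  ## outer (t = 1) and inner (t = 0) boundary curves of the tissue band
  outer_pt <- function(s) {
    if (s <= s1) {
      al <- alpha_c * s / s1
      Ca + Ra * c(sin(al), cos(al))
    } else {
      S_outer(psi_edge + (s - s1) / (1 - s1) * (pi - psi_edge))
    }
  }
  inner_pt <- function(s) {
    if (s <= s1) {
      al <- alpha_c * s / s1
      Ca + post_u(al) * c(sin(al), cos(al))
    } else if (s <= s2) {
      sl <- (s - s1) / (s2 - s1)
      (1 - sl) * P_edge + sl * Si_start
    } else {
      S_inner(psi_edge + (s - s1) / (1 - s1) * (pi - psi_edge))
    }
  }
  tissue_map <- function(s, t) {
    p <- (1 - t) * inner_pt(s) + t * outer_pt(s)
    if (abs(p[1]) < 1e-12) p[1] <- 0
    p
  }
  grid <- structured_grid(ns_arc, nt, tissue_map, order = 2L)
  tnodes <- grid$nodes
  tel <- grid$elements
  n_tel <- nrow(tel)
  arc_index <- rep(seq_len(ns_arc), times = nt)
  layer <- rep(seq_len(nt), each = ns_arc)
  region <- character(n_tel)
  region[arc_index <= nc] <- ifelse(layer[arc_index <= nc] > nt / 2,
                                    "cornea_ant", "cornea_post")
  region[arc_index > nc & arc_index <= nc + nl] <- "limbus"
  region[arc_index > nc + nl] <- "sclera"

  nodes <- tnodes
  elements <- tel
  fsi <- NULL
  free_surface_ids <- integer()
  if (cfg$include_fluid) {
    nrad <- cfg$n_fluid_radial * cfg$refine
    inner_ids <- vapply(seq_len(ns_arc + 1), function(i) grid$corner_id(i, 1), 0L)
    Pb <- tnodes[inner_ids, , drop = FALSE]
    if (identical(cfg$fluid_region %||% "layer", "cavity")) {
      ## full humour cavity: polar fan about the scleral centre;
      ## fluid nodes are centre + rings 1..nrad-1; ring nrad = tissue corners
      centre_id <- nrow(nodes) + 1L
      nodes <- rbind(nodes, Cs)
      ring_id <- matrix(0L, nrad - 1, ns_arc + 1)
      for (k in seq_len(nrad - 1)) {
        frac <- k / nrad
        pts <- sweep(Pb, 2, Cs, "-") * frac
        pts <- sweep(pts, 2, Cs, "+")
        pts[abs(pts[, 1]) < 1e-12, 1] <- 0
        ring_id[k, ] <- nrow(nodes) + seq_len(ns_arc + 1)
        nodes <- rbind(nodes, pts)
      }
      fid <- function(k, i) {             # k = 0 centre .. nrad = boundary
        if (k == 0L) rep(centre_id, length(i))
        else if (k == nrad) inner_ids[i]
        else ring_id[k, i]
      }
    } else {
      ## humour modelled as the coupled layer within fsi_range of the
      ## tissue: rings march inward from the wetted surface; the innermost
      ## ring is a pressure-release surface towards the deep humour
      depth <- cfg$fluid$fsi_range_mm * mm
      dirs <- sweep(-Pb, 2, -Cs, "-")          # towards the scleral centre
      dlen <- sqrt(rowSums(dirs^2))
      dirs <- dirs / pmax(dlen, 1e-12)
      depth_i <- pmin(depth, 0.9 * dlen)       # never cross the centre
      ring_id <- matrix(0L, nrad, ns_arc + 1)
      for (k in seq_len(nrad)) {
        pts <- Pb + dirs * (depth_i * k / nrad)
        pts[abs(pts[, 1]) < 1e-12, 1] <- 0
        pts[, 1] <- pmax(pts[, 1], 0)
        ring_id[k, ] <- nrow(nodes) + seq_len(ns_arc + 1)
        nodes <- rbind(nodes, pts)
      }
      ## ring index runs 0 (wetted surface) .. nrad (free surface): flip so
      ## the shared element loop below still sees k = nrad at the tissue
      fid <- function(k, i) {
        if (k == nrad) inner_ids[i] else ring_id[nrad - k, i]
      }
      free_surface_ids <- ring_id[nrad, ]
    }
    fel <- matrix(NA_integer_, nrad * ns_arc, 8)
    e <- 0L
    for (k in seq_len(nrad)) for (i in seq_len(ns_arc)) {
      e <- e + 1L
      fel[e, 1:4] <- c(fid(k - 1L, i), fid(k - 1L, i + 1L),
                       fid(k, i + 1L), fid(k, i))
    }
    elements <- rbind(elements, fel)
    region <- c(region, rep("fluid", nrad * ns_arc))
    ## wetted edges: tissue inner-surface edges (layer 1, t = 0 side)
    fsi_range <- cfg$fluid$fsi_range_mm * mm
    fsi <- data.frame(
      solid_el = seq_len(ns_arc),                         # layer-1 tissue els
      fluid_el = n_tel + (nrad - 1L) * ns_arc + seq_len(ns_arc),
      n1 = inner_ids[seq_len(ns_arc)],
      n2 = inner_ids[seq_len(ns_arc) + 1L],
      nm = grid$id_grid[2L * seq_len(ns_arc), 1L])
    ## the wetted edges touch the tissue, distance 0 <= fsi_range always;
    ## keep the filter explicit for completeness
    fsi <- fsi[rep(TRUE, nrow(fsi)) & fsi_range >= 0, , drop = FALSE]
  }
  mesh <- axi_mesh(nodes, elements, region, fsi_edges = fsi, check = FALSE)

  prony <- cfg_prony(cfg$prony)
  prony_ls <- if (isTRUE(cfg$prony_all_tissues)) prony else NULL
  materials <- list(
    cornea_ant = material_spec(cfg$E_anterior_kPa * 1e3, cfg$nu,
                               cfg$density_kg_m3, prony),
    cornea_post = material_spec(cfg$E_posterior_kPa * 1e3, cfg$nu,
                                cfg$density_kg_m3, prony),
    limbus = material_spec(cfg$limbus_E_kPa * 1e3, cfg$nu, cfg$density_kg_m3,
                           prony_ls),
    sclera = material_spec(cfg$sclera_E_kPa * 1e3, cfg$nu, cfg$density_kg_m3,
                           prony_ls))

  ## per-element centroid angle theta (0 = scleral equator, 90 = apex)
  theta <- rep(NA_real_, nrow(elements))
  for (e in seq_len(n_tel)) {
    conn <- elements[e, ]
    nid <- conn[1:n_elem_nodes(conn)]
    cen <- colMeans(nodes[nid, , drop = FALSE])
    psi <- atan2(cen[1], cen[2] - zs)
    theta[e] <- 90 - psi * 180 / pi
  }
  ## optional weak zone: retag corneal elements inside the angular interval
  if (!is.null(cfg$weak_zone)) {
    wz <- cfg$weak_zone
    in_zone <- which(startsWith(region[seq_len(n_tel)], "cornea") &
                     theta[seq_len(n_tel)] >= wz$theta1_deg &
                     theta[seq_len(n_tel)] <= wz$theta2_deg)
    if (length(in_zone) == 0)
      stop("build_globe: weak zone misses the cornea")
    ## only elements whose modulus actually changes are retagged, so a
    ## no-op zone (reduced E equal to the local E) leaves the model intact
    curE <- ifelse(region[in_zone] == "cornea_ant",
                   cfg$E_anterior_kPa, cfg$E_posterior_kPa)
    changed <- in_zone[abs(curE - wz$E_kPa) > 0]
    if (length(changed)) {
      mesh$region[changed] <- "cornea_weak"
      materials$cornea_weak <- material_spec(wz$E_kPa * 1e3, cfg$nu,
                                             cfg$density_kg_m3, prony)
    }
  }

  ## holder ring: outer scleral nodes whose arc distance from the posterior
  ## pole (along the outer surface) falls within the ring
  outer_row <- grid$id_grid[, 2L * nt + 1L]
  outer_row <- outer_row[outer_row > 0]
  psi_n <- atan2(nodes[outer_row, 1], nodes[outer_row, 2] - zs)
  arc_from_pole <- Rs * (pi - psi_n)
  hd <- cfg$holder_distance_mm * mm; hw <- cfg$holder_width_mm * mm
  holder <- outer_row[arc_from_pole >= hd - hw / 2 & arc_from_pole <= hd + hw / 2]
  if (length(holder) == 0)
    stop("build_globe: holder ring selects no scleral nodes")
  axis_nodes <- which(mesh$nodes[, 1] <= 1e-12 &
                      seq_len(nrow(mesh$nodes)) <= nrow(tnodes))

  ## excitation: unit pressure on the anterior corneal surface, inward
  le_list <- lapply(seq_len(nc), function(i) {
    n1 <- grid$corner_id(i, nt + 1L); n2 <- grid$corner_id(i + 1L, nt + 1L)
    nm <- grid$id_grid[2L * i, 2L * nt + 1L]
    mid <- colMeans(nodes[c(n1, n2), , drop = FALSE])
    refd <- Cs - mid           # inward
    data.frame(n1 = n1, n2 = n2, nm = nm, ref_r = refd[1], ref_z = refd[2])
  })
  le <- do.call(rbind, le_list)

  fl <- if (cfg$include_fluid)
    fluid_spec(rho = cfg$fluid$density_kg_m3, c = cfg$fluid$sonic_velocity_m_s,
               mu = cfg$fluid$viscosity,
               fsi_range = cfg$fluid$fsi_range_mm * mm) else NULL

  ## prestress state
  sigma <- NULL
  iop <- cfg$iop_kPa * 1e3
  if (cfg$prestress != "none" && iop > 0) {
    if (cfg$prestress == "uniform") {
      sigma <- matrix(0, nrow(elements), 4)
      sigma[seq_len(n_tel), 1] <- iop
      sigma[seq_len(n_tel), 2] <- iop
      sigma[seq_len(n_tel), 3] <- iop
    } else {
      sigma <- iop_static_prestress(mesh, materials, grid, ns_arc, nt, nc,
                                    holder, axis_nodes, iop, Cs)
    }
  }

  ## apex probe and anterior corneal arc (outer surface, apex -> limbus)
  probe <- grid$corner_id(1L, nt + 1L)
  arc_ids <- grid$id_grid[seq_len(2L * nc + 1L), 2L * nt + 1L]
  arc_ids <- arc_ids[arc_ids > 0]
  arc_s <- atan2(nodes[arc_ids, 1], nodes[arc_ids, 2] - Ca[2])  # angle about Ca

  geom <- list(Ca = Ca, Cp = Cp, Cs = Cs, Ra = Ra, Rp = Rp, Rs = Rs, ts = ts,
               alpha_c = alpha_c, psi_edge = psi_edge, psi_start = psi_start,
               rc = rc)
  finalize_model("globe", cfg, mesh, materials, fluid = fl,
                 prestress_sigma = sigma, constrained_nodes_fixed = holder,
                 axis_nodes = axis_nodes, load_edges = le, probe_node = probe,
                 arc_nodes = arc_ids, arc_coord = arc_s,
                 pressure_zero_nodes = free_surface_ids,
                 extra = list(geom = geom, theta_deg = theta,
                              grid_corner = grid$corner_id))
}

## Preliminary linear static solve under IOP pressure on the wetted inner
## surface; returns the per-element centroid stress field used for stress
## stiffening.
iop_static_prestress <- function(mesh, materials, grid, ns_arc, nt, nc,
                                 holder, axis_nodes, iop, Cs) {
  solid <- assemble_solid(mesh, materials)
  dofs <- solid$dofs
  ns <- dofs$ns
  load <- numeric(ns)
  for (i in seq_len(ns_arc)) {
    n1 <- grid$corner_id(i, 1L); n2 <- grid$corner_id(i + 1L, 1L)
    nm <- grid$id_grid[2L * i, 1L]
    sn <- c(n1, n2, nm)
    xy <- mesh$nodes[sn, , drop = FALSE]
    mid <- colMeans(xy[1:2, , drop = FALSE])
    refd <- mid - Cs                      # outward push from the cavity
    fe <- edge_pressure_force(xy, p = iop, ref_dir = refd)
    udof <- as.vector(t(dofs$sdof[sn, , drop = FALSE]))
    load[udof] <- load[udof] + fe
  }
  cd <- c(as.vector(dofs$sdof[holder, , drop = FALSE]), dofs$sdof[axis_nodes, 1])
  cd <- sort(unique(cd[cd > 0]))
  u <- solve_static(solid, load, cd)
  recover_stresses(mesh, materials, dofs, u)
}

#' Apply a local corneal weakening to a globe model
#'
#' Rebuilds the globe with the corneal elements whose centroid angle lies in
#' the zone set to the reduced modulus; all other properties are untouched.
#'
#' @param model a globe `ocuvib_model` (or a `globe_config`).
#' @param zone a [weak_zone()].
#' @return the weakened model.
#' @export
apply_weak_zone <- function(model, zone) {
  stopifnot(inherits(zone, "weak_zone"))
  cfg <- if (inherits(model, "ocuvib_model")) model$cfg else model
  if (!inherits(cfg, "globe_config"))
    stop("apply_weak_zone: weak zones apply to globe models")
  cfg$weak_zone <- zone
  build_globe(cfg)
}

#' Static displacement response of the globe to its IOP
#'
#' Solves the linear static problem with the IOP applied as a pressure on
#' the wetted inner surface and returns the full nodal displacement field;
#' mainly a diagnostic (positive apex z-displacement checks the load sign
#' convention).
#'
#' @param model a globe `ocuvib_model`.
#' @return list with `u` (solid dof vector) and `apex_uz` (m).
#' @export
globe_static_iop <- function(model) {
  stopifnot(inherits(model, "ocuvib_model"), model$type == "globe")
  cfg <- model$cfg
  iop <- cfg$iop_kPa * 1e3
  mesh <- model$mesh
  dofs <- model$dofs
  ns <- dofs$ns
  load <- numeric(ns)
  fsi <- mesh$fsi_edges
  if (is.null(fsi)) stop("globe_static_iop: model has no wetted surface")
  for (k in seq_len(nrow(fsi))) {
    sn <- c(fsi$n1[k], fsi$n2[k], fsi$nm[k])
    xy <- mesh$nodes[sn, , drop = FALSE]
    mid <- colMeans(xy[1:2, , drop = FALSE])
    refd <- mid - model$geom$Cs
    fe <- edge_pressure_force(xy, p = iop, ref_dir = refd)
    udof <- as.vector(t(dofs$sdof[sn, , drop = FALSE]))
    load[udof] <- load[udof] + fe
  }
  u <- solve_static(model$solid, load, model$constrained)
  list(u = u, apex_uz = u[model$probe_dof])
}
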