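## Shared model-assembly plumbing for the flap and globe builders.

finalize_model <- function(type, cfg, mesh, materials, fluid = NULL,
                           prestress_sigma = NULL, constrained_nodes_fixed,
                           axis_nodes, load_edges, probe_node, arc_nodes,
                           arc_coord, pressure_zero_nodes = integer(),
                           extra = list()) {
  solid <- assemble_solid(mesh, materials, prestress = prestress_sigma)
  dofs <- solid$dofs
  fluid_sys <- NULL
  if (!is.null(fluid) && any(dofs$is_fluid))
    fluid_sys <- assemble_fluid(mesh, fluid, dofs = dofs)
  ntot <- dofs$ns + dofs$np
  ## constraints: fixed nodes lose both dofs; axis nodes lose u_r
  cd <- c(as.vector(dofs$sdof[constrained_nodes_fixed, , drop = FALSE]),
          dofs$sdof[axis_nodes, 1])
  cd <- cd[cd > 0]
  if (length(pressure_zero_nodes)) {
    pz <- dofs$pdof[pressure_zero_nodes]
    cd <- c(cd, dofs$ns + pz[pz > 0])
  }
  cd <- sort(unique(cd))
  excitation <- cfg$excitation %||% "base"
  load <- complex(ntot)
  if (excitation == "pressure") {
    ## consistent unit-pressure load on the excitation edges
    for (k in seq_len(nrow(load_edges))) {
      ed <- load_edges[k, ]
      sn <- c(ed$n1, ed$n2, ed$nm)
      sn <- sn[!is.na(sn)]
      xy <- mesh$nodes[sn, , drop = FALSE]
      fe <- edge_pressure_force(xy, p = 1, ref_dir = c(ed$ref_r, ed$ref_z))
      udof <- as.vector(t(dofs$sdof[sn, , drop = FALSE]))
      load[udof] <- load[udof] + fe
    }
  } else {
    ## rigid-frame harmonic excitation: every structural node driven at the
    ## imposed frequency; in the frame of the mount the load is the inertial
    ## force -rho*a per unit volume, i.e. omega^2 * M * (unit z), applied at
    ## solve time with the omega^2 factor
    d <- numeric(dofs$ns)
    d[seq(2, dofs$ns, by = 2)] <- 1
    load[seq_len(dofs$ns)] <- as.vector(solid$M %*% d)
  }
  system <- harmonic_system(solid, fluid_sys, load = load, constrained = cd,
                            load_omega2 = identical(excitation, "base"))
  structure(c(list(
    type = type, cfg = cfg, mesh = mesh, materials = materials, fluid = fluid,
    solid = solid, fluid_sys = fluid_sys, dofs = dofs, system = system,
    prestress = prestress_sigma, constrained = cd, load = load,
    probe_node = probe_node,
    probe_dof = dofs$sdof[probe_node, 2],
    arc_nodes = arc_nodes, arc_coord = arc_coord,
    M_region = solid$M_region), extra), class = "ocuvib_model")
}

#' @export
print.ocuvib_model <- function(x, ...) {
  cat(sprintf("ocuvib_model (%s): %d nodes, %d elements, %d free dofs\n",
              x$type, nrow(x$mesh$nodes), nrow(x$mesh$elements),
              length(x$system$free)))
  invisible(x)
}

#' Rescale the corneal elasticity of a built model
#'
#' Returns a model identical to `model` but with the corneal long-term
#' modulus set to `E_Pa` (globe: anterior-layer value, with the posterior
#' layer co-scaled by the configured anterior/posterior ratio). Because the
#' stiffness blocks are linear in E, this is a sparse rescaling and avoids
#' re-meshing, which makes the iterative elasticity inversion cheap.
#'
#' @param model a model from [build_flap()] or [build_globe()].
#' @param E_Pa new corneal long-term Young's modulus (Pa).
#' @return the updated model.
#' @export
set_corneal_E <- function(model, E_Pa) {
  regions <- switch(model$type,
                    flap = c(cornea = 1),
                    globe = c(cornea_ant = 1,
                              cornea_post = model$cfg$E_posterior_kPa /
                                            model$cfg$E_anterior_kPa))
  for (rg in names(regions)) {
    K <- model$system$K_parts[[rg]]
    if (is.null(K)) next
    mat <- attr(K, "material")
    sc <- E_Pa * regions[[rg]] / mat$E
    K <- K * sc
    mat$E <- E_Pa * regions[[rg]]
    attr(K, "material") <- mat
    model$system$K_parts[[rg]] <- K
    model$materials[[rg]]$E <- mat$E
  }
  if (model$type == "flap") model$cfg$E_kPa <- E_Pa / 1e3
  else {
    ratio <- model$cfg$E_posterior_kPa / model$cfg$E_anterior_kPa
    model$cfg$E_anterior_kPa <- E_Pa / 1e3
    model$cfg$E_posterior_kPa <- E_Pa * ratio / 1e3
  }
  model
}

#' Build a model from a configuration
#'
#' Dispatches to [build_flap()] or [build_globe()].
#' @param cfg a `flap_config` or `globe_config`.
#' @return an `ocuvib_model`.
#' @export
build_model <- function(cfg) {
  if (inherits(cfg, "flap_config")) build_flap(cfg)
  else if (inherits(cfg, "globe_config")) build_globe(cfg)
  else stop("build_model: unsupported configuration")
}
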