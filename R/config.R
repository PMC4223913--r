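#' Corneal flap model configuration
#'
#' Geometric and material parameters of the circular corneal flap clamped in
#' its holder. Units follow the conventions of the configuration tables
#' (mm, um, kPa); they are converted to SI when the model is built.
#'
#' @param diameter_mm flap diameter (mm).
#' @param thickness_um flap thickness (um).
#' @param E_kPa long-term corneal Young's modulus (kPa).
#' @param prestress_kPa in-plane mounting stress (kPa), applied as a uniform
#'   equi-biaxial tension.
#' @param density_kg_m3 tissue density (kg m^-3).
#' @param nu Poisson ratio.
#' @param prony list with `p` (relative modulus) and `T_ms` (relaxation time,
#'   ms); `NULL` for a purely elastic flap.
#' @param n_radial,n_thickness element grid (default 27 x 2 = 54 elements).
#' @param refine integer mesh-refinement factor applied to both directions.
#' @param excitation `"base"` (rigid-frame inertial drive: all nodes forced
#'   at the imposed frequency, default) or `"pressure"` (unit pressure on
#'   the lower face).
#' @return an object of class `flap_config`.
#' @export
flap_config <- function(diameter_mm = 4, thickness_um = 120, E_kPa = 14.58,
                        prestress_kPa = 0.67, density_kg_m3 = 1160, nu = 0.499,
                        prony = list(p = 0.1, T_ms = 1),
                        n_radial = 27, n_thickness = 2, refine = 1,
                        excitation = c("base", "pressure")) {
  excitation <- match.arg(excitation)
  if (diameter_mm <= 0 || thickness_um <= 0)
    stop("flap_config: diameter and thickness must be > 0")
  cfg <- list(diameter_mm = diameter_mm, thickness_um = thickness_um,
              E_kPa = E_kPa, prestress_kPa = prestress_kPa,
              density_kg_m3 = density_kg_m3, nu = nu, prony = prony,
              n_radial = as.integer(n_radial),
              n_thickness = as.integer(n_thickness),
              refine = as.integer(refine), excitation = excitation)
  ## validate material invariants early
  invisible(cfg_material(cfg))
  structure(cfg, class = "flap_config")
}

cfg_prony <- function(prony) {
  if (is.null(prony)) return(NULL)
  list(list(p = prony$p, T = prony$T_ms * 1e-3))
}

cfg_material <- function(cfg) {
  material_spec(E = cfg$E_kPa * 1e3, nu = cfg$nu, rho = cfg$density_kg_m3,
                prony = cfg_prony(cfg$prony))
}

#' Whole eye globe model configuration
#'
#' Geometry and materials of the axisymmetric whole-globe model: spherical
#' two-layer cornea, limbus wedge, scleral shell and acoustic humour fill.
#' The anterior and posterior corneal layers carry independent moduli; the
#' holder is a circular ring constraint on the outer sclera.
#'
#' @param cct_um central corneal thickness (um).
#' @param anterior_curvature_mm,posterior_curvature_mm corneal surface radii
#'   of curvature (mm); the posterior radius must be the smaller.
#' @param cornea_diameter_mm corneal (limbus chord) diameter (mm).
#' @param sclera_diameter_mm outer scleral diameter (mm).
#' @param sclera_thickness_mm scleral shell thickness (mm).
#' @param E_anterior_kPa,E_posterior_kPa corneal layer moduli (kPa).
#' @param limbus_E_kPa,sclera_E_kPa limbus and sclera moduli (kPa). The
#'   default limbus is a compliant hinge ring (37.2 kPa) and the default
#'   sclera the normal-sclera value (744 kPa); a soft-sclera variant near
#'   74-79 kPa adds low-frequency sclera-dominated resonances.
#' @param density_kg_m3 tissue density (kg m^-3).
#' @param nu Poisson ratio for all tissues.
#' @param prony corneal Prony term (`p`, `T_ms`).
#' @param prony_all_tissues if `TRUE` (default) the limbus and sclera carry
#'   the same Prony term as the cornea; `FALSE` leaves them purely elastic.
#' @param iop_kPa intraocular pressure (kPa).
#' @param prestress `"uniform"` (homogeneous isotropic initial stress equal
#'   to the IOP in all ocular tissues), `"static"` (stress field from a
#'   preliminary linear static solve under IOP pressure loading), or
#'   `"none"`.
#' @param fluid list: `density_kg_m3`, `sonic_velocity_m_s`, `viscosity`,
#'   `fsi_range_mm`.
#' @param fluid_region `"layer"` (default): the humour is the coupled fluid
#'   layer within `fsi_range_mm` of the ocular tissues, terminated by a
#'   pressure-release surface towards the deep humour; `"cavity"`: the full
#'   closed humour volume (adds the cavity-compressibility stiffness to
#'   every volume-changing mode).
#' @param include_fluid set `FALSE` for an in-vacuo model.
#' @param holder_distance_mm arc distance of the holder ring centre from the
#'   posterior pole, measured along the outer scleral surface (mm).
#' @param holder_width_mm holder ring width (mm).
#' @param n_arc_cornea,n_arc_limbus,n_arc_sclera arc element counts per
#'   region (through-thickness count is `n_thickness`); defaults give the
#'   region element counts 80 / 12 / 182.
#' @param n_thickness through-thickness element count (2 layers).
#' @param n_fluid_radial radial rings in the humour mesh (default 9, giving
#'   1233 fluid elements).
#' @param refine integer mesh-refinement factor.
#' @param weak_zone optional [weak_zone()] of locally reduced corneal
#'   elasticity.
#' @param excitation `"base"` (rigid-frame inertial drive, default) or
#'   `"pressure"` (unit pressure on the anterior cornea).
#' @return an object of class `globe_config`.
#' @export
globe_config <- function(cct_um = 865, anterior_curvature_mm = 6.8,
                         posterior_curvature_mm = 5.57,
                         cornea_diameter_mm = 10.40, sclera_diameter_mm = 19,
                         sclera_thickness_mm = 1.0,
                         E_anterior_kPa = 24.8, E_posterior_kPa = 19.8,
                         limbus_E_kPa = 37.2, sclera_E_kPa = 744,
                         density_kg_m3 = 1160, nu = 0.499,
                         prony = list(p = 0.1, T_ms = 1),
                         prony_all_tissues = TRUE,
                         iop_kPa = 2.2, prestress = "none",
                         fluid = list(density_kg_m3 = 1000,
                                      sonic_velocity_m_s = 1480,
                                      viscosity = 8.94e-4, fsi_range_mm = 2.8),
                         fluid_region = c("layer", "cavity"),
                         include_fluid = TRUE,
                         holder_distance_mm = 5, holder_width_mm = 1,
                         n_arc_cornea = 40, n_arc_limbus = 6, n_arc_sclera = 91,
                         n_thickness = 2, n_fluid_radial = 9, refine = 1,
                         weak_zone = NULL, excitation = c("base", "pressure")) {
  excitation <- match.arg(excitation)
  if (posterior_curvature_mm >= anterior_curvature_mm)
    stop("globe_config: posterior curvature must be smaller than anterior")
  if (cornea_diameter_mm >= sclera_diameter_mm)
    stop("globe_config: corneal diameter must be smaller than scleral")
  if (iop_kPa < 0) stop("globe_config: IOP must be >= 0")
  prestress <- match.arg(prestress, c("none", "uniform", "static"))
  fluid_region <- match.arg(fluid_region)
  cfg <- list(cct_um = cct_um, anterior_curvature_mm = anterior_curvature_mm,
              posterior_curvature_mm = posterior_curvature_mm,
              cornea_diameter_mm = cornea_diameter_mm,
              sclera_diameter_mm = sclera_diameter_mm,
              sclera_thickness_mm = sclera_thickness_mm,
              E_anterior_kPa = E_anterior_kPa, E_posterior_kPa = E_posterior_kPa,
              limbus_E_kPa = limbus_E_kPa, sclera_E_kPa = sclera_E_kPa,
              density_kg_m3 = density_kg_m3, nu = nu, prony = prony,
              prony_all_tissues = isTRUE(prony_all_tissues),
              iop_kPa = iop_kPa, prestress = prestress, fluid = fluid,
              fluid_region = fluid_region,
              include_fluid = isTRUE(include_fluid),
              holder_distance_mm = holder_distance_mm,
              holder_width_mm = holder_width_mm,
              n_arc_cornea = as.integer(n_arc_cornea),
              n_arc_limbus = as.integer(n_arc_limbus),
              n_arc_sclera = as.integer(n_arc_sclera),
              n_thickness = as.integer(n_thickness),
              n_fluid_radial = as.integer(n_fluid_radial),
              refine = as.integer(refine), weak_zone = weak_zone,
              excitation = excitation)
  structure(cfg, class = "globe_config")
}

#' Angular zone of locally reduced corneal elasticity
#'
#' The angular coordinate runs from 0 degrees at the scleral equator to 90
#' degrees at the corneal apex (measured about the scleral centre). Corneal
#' elements whose centroid angle lies in `[theta1, theta2]` receive the
#' reduced modulus; a simple model of a keratoconus-like local weakening.
#'
#' @param theta1_deg,theta2_deg zone limits in degrees, `0 <= theta1 <
#'   theta2 <= 90`.
#' @param E_kPa reduced Young's modulus in the zone (kPa).
#' @return an object of class `weak_zone`.
#' @export
weak_zone <- function(theta1_deg, theta2_deg, E_kPa) {
  if (!(theta1_deg >= 0 && theta1_deg < theta2_deg && theta2_deg <= 90))
    stop("weak_zone: need 0 <= theta1 < theta2 <= 90")
  if (E_kPa <= 0) stop("weak_zone: reduced modulus must be > 0")
  structure(list(theta1_deg = theta1_deg, theta2_deg = theta2_deg,
                 E_kPa = E_kPa), class = "weak_zone")
}

#' Read a model configuration from a YAML file
#'
#' The file has a top-level `model:` key (`flap` or `globe`) and sections
#' `geometry`, `materials`, `fluid`, `loading` and `mesh` whose keys are the
#' arguments of [flap_config()] / [globe_config()] (e.g. `cct_um`,
#' `anterior_curvature_mm`, `E_anterior_kPa`, `iop_kPa`).
#'
#' @param path YAML file path.
#' @return a `flap_config` or `globe_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$model)) stop("read_config: missing top-level 'model' key")
  args <- c(y$geometry, y$materials, y$loading, y$mesh)
  if (!is.null(y$fluid)) args$fluid <- y$fluid
  if (identical(y$model, "flap")) {
    do.call(flap_config, args[names(args) %in% names(formals(flap_config))])
  } else if (identical(y$model, "globe")) {
    if (!is.null(y$weak_zone)) args$weak_zone <- do.call(weak_zone, y$weak_zone)
    do.call(globe_config, args[names(args) %in% names(formals(globe_config))])
  } else stop("read_config: model must be 'flap' or 'globe'")
}

## Set a named scalar parameter on a config; used by the sensitivity sweeps.
## Returns list(cfg, unit) where unit is the display unit of the parameter.
set_config_param <- function(cfg, param, value) {
  if (inherits(cfg, "flap_config")) {
    map <- c(E = "E_kPa", stiffness = "E_kPa", density = "density_kg_m3",
             thickness = "thickness_um", diameter = "diameter_mm",
             radius = "diameter_mm", prestress = "prestress_kPa")
    unit <- c(E_kPa = "Hz kPa^-1", density_kg_m3 = "Hz (kg m^-3)^-1",
              thickness_um = "Hz um^-1", diameter_mm = "Hz mm^-1",
              prestress_kPa = "Hz kPa^-1")
    if (!param %in% names(map)) stop("unknown flap parameter: ", param)
    key <- map[[param]]
    if (param == "radius") value <- 2 * value
    cfg[[key]] <- value
    return(list(cfg = structure(cfg, class = "flap_config"), key = key,
                unit = unit[[key]]))
  }
  if (inherits(cfg, "globe_config")) {
    if (param %in% c("E", "stiffness")) {
      ## corneal elasticity: anterior value; posterior co-scaled
      ratio <- cfg$E_posterior_kPa / cfg$E_anterior_kPa
      cfg$E_anterior_kPa <- value
      cfg$E_posterior_kPa <- value * ratio
      return(list(cfg = structure(cfg, class = "globe_config"),
                  key = "E_anterior_kPa", unit = "Hz kPa^-1"))
    }
    if (param == "curvature") {
      ## joint scaling of both corneal radii, thickness preserved
      sc <- value / cfg$anterior_curvature_mm
      cfg$anterior_curvature_mm <- value
      cfg$posterior_curvature_mm <- cfg$posterior_curvature_mm * sc
      return(list(cfg = structure(cfg, class = "globe_config"),
                  key = "anterior_curvature_mm", unit = "Hz mm^-1"))
    }
    map <- c(density = "density_kg_m3", thickness = "cct_um",
             IOP = "iop_kPa", iop = "iop_kPa", sclera_E = "sclera_E_kPa",
             sclera_diameter = "sclera_diameter_mm",
             cornea_diameter = "cornea_diameter_mm")
    unit <- c(density_kg_m3 = "Hz (kg m^-3)^-1", cct_um = "Hz um^-1",
              iop_kPa = "Hz kPa^-1", sclera_E_kPa = "Hz kPa^-1",
              sclera_diameter_mm = "Hz mm^-1", cornea_diameter_mm = "Hz mm^-1")
    if (!param %in% names(map)) stop("unknown globe parameter: ", param)
    key <- map[[param]]
    cfg[[key]] <- value
    return(list(cfg = structure(cfg, class = "globe_config"), key = key,
                unit = unit[[key]]))
  }
  stop("set_config_param: unsupported config")
}

get_config_param <- function(cfg, param) {
  s <- set_config_param(cfg, param, 1)   # just to resolve the key
  cfg[[s$key]]
}
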