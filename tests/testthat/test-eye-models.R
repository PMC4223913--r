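test_that("default flap mesh has 54 clamped elements and scales with refinement", {
  m <- nominal_flap()
  expect_equal(nrow(m$mesh$elements), 54L)
  expect_true(all(m$mesh$region == "cornea"))
  ## all rim dofs constrained
  a <- m$cfg$diameter_mm / 2 * 1e-3
  rim <- which(abs(m$mesh$nodes[, 1] - a) < 1e-12)
  rim_dofs <- as.vector(m$dofs$sdof[rim, ])
  expect_true(all(rim_dofs %in% m$constrained))
  ## refinement factor 2 -> 4x elements, same boundary semantics
  m2 <- build_flap(flap_config(refine = 2))
  expect_equal(nrow(m2$mesh$elements), 4L * 54L)
  rim2 <- which(abs(m2$mesh$nodes[, 1] - a) < 1e-12)
  expect_true(all(as.vector(m2$dofs$sdof[rim2, ]) %in% m2$constrained))
  ## zero prestress -> exactly no prestress state
  m0 <- build_flap(flap_config(prestress_kPa = 0))
  expect_null(m0$prestress)
  expect_equal(Matrix::norm(m0$solid$Kg, "F"), 0)
})

test_that("mesh generation is deterministic", {
  m1 <- build_flap(flap_config())
  m2 <- build_flap(flap_config())
  expect_identical(m1$mesh$nodes, m2$mesh$nodes)
  expect_identical(m1$mesh$elements, m2$mesh$elements)
  g1 <- build_globe(globe_config())
  expect_identical(g1$mesh$nodes, nominal_globe()$mesh$nodes)
  expect_identical(g1$mesh$elements, nominal_globe()$mesh$elements)
})

test_that("globe regions carry the prescribed element counts", {
  m <- nominal_globe()
  counts <- table(m$mesh$region)
  expect_equal(unname(counts[["cornea_ant"]] + counts[["cornea_post"]]), 80L)
  expect_equal(unname(counts[["limbus"]]), 12L)
  expect_equal(unname(counts[["sclera"]]), 182L)
  ## fluid count within 10 percent of 1234
  expect_lt(abs(counts[["fluid"]] - 1234) / 1234, 0.10)
  ## all Jacobians positive (includes the degenerate-looking polar fan)
  expect_true(ocuvib:::check_mesh(m$mesh))
})

test_that("globe region cross-section areas match the analytic shell segments", {
  m <- nominal_globe()
  areas <- region_areas(m$mesh)
  g <- m$geom
  ## independent oracle: fine polygonal integration of the bounding spheres
  band_area <- function(outer_fun, inner_fun, s0, s1, n = 4000) {
    s <- seq(s0, s1, length.out = n)
    op <- t(vapply(s, outer_fun, c(0, 0)))
    ip <- t(vapply(s, inner_fun, c(0, 0)))
    poly_r <- c(op[, 1], rev(ip[, 1]))
    poly_z <- c(op[, 2], rev(ip[, 2]))
    abs(sum(poly_r * c(poly_z[-1], poly_z[1]) - c(poly_r[-1], poly_r[1]) * poly_z)) / 2
  }
  cornea_outer <- function(s) g$Ca + g$Ra * c(sin(s * g$alpha_c), cos(s * g$alpha_c))
  post_u <- function(al) {
    d <- g$Ca - g$Cp; e <- c(sin(al), cos(al)); de <- sum(d * e)
    -de + sqrt(de^2 - sum(d * d) + g$Rp^2)
  }
  cornea_inner <- function(s) {
    al <- s * g$alpha_c
    g$Ca + post_u(al) * c(sin(al), cos(al))
  }
  a_cornea <- band_area(cornea_outer, cornea_inner, 0, 1)
  psi_start <- g$psi_start
  scl_outer <- function(s) g$Cs + g$Rs * c(sin(psi_start + s * (pi - psi_start)),
                                           cos(psi_start + s * (pi - psi_start)))
  scl_inner <- function(s) g$Cs + (g$Rs - g$ts) *
    c(sin(psi_start + s * (pi - psi_start)), cos(psi_start + s * (pi - psi_start)))
  a_sclera <- band_area(scl_outer, scl_inner, 0, 1)
  expect_equal(unname(areas[["cornea_ant"]] + areas[["cornea_post"]]), a_cornea,
               tolerance = 0.02)
  expect_equal(unname(areas[["sclera"]]), a_sclera, tolerance = 0.02)
})

test_that("corneal layers partition the thickness with distinct moduli", {
  m <- nominal_globe()
  expect_equal(m$materials$cornea_ant$E, 24.8e3)
  expect_equal(m$materials$cornea_post$E, 19.8e3)
  counts <- table(m$mesh$region)
  expect_equal(unname(counts[["cornea_ant"]]), unname(counts[["cornea_post"]]))
  ## anterior-layer elements lie outside (farther from the scleral centre
  ## than) the posterior-layer elements at matching arc positions
  els <- m$mesh$elements
  cen_rad <- function(e) {
    nid <- els[e, 1:8]
    cen <- colMeans(m$mesh$nodes[nid, ])
    sqrt(cen[1]^2 + (cen[2] - m$geom$Cs[2])^2)
  }
  ant <- which(m$mesh$region == "cornea_ant")
  post <- which(m$mesh$region == "cornea_post")
  expect_true(mean(vapply(ant, cen_rad, 0)) > mean(vapply(post, cen_rad, 0)))
})

test_that("IOP prestress behaves physically", {
  ## zero IOP -> no prestress state at all
  m0 <- build_globe(globe_config(iop_kPa = 0))
  expect_null(m0$prestress)
  ## static IOP solve pushes the corneal apex outward (positive z)
  m <- nominal_globe()
  st <- globe_static_iop(m)
  expect_gt(st$apex_uz, 0)
  ## the static-solve prestress field is tensile in the hoop direction on
  ## average (wall tension of the inflated shell), at the pR/2t scale
  ms <- build_globe(globe_config(prestress = "static"))
  tissue <- which(ms$mesh$region != "fluid")
  hoop <- mean(ms$prestress[tissue, 3])
  expect_gt(hoop, 0)
  p <- 2.2e3; R <- 9.5e-3; t <- 1e-3
  expect_gt(hoop, 0.2 * p * R / (2 * t))
  expect_lt(hoop, 5 * p * R / (2 * t))
})

test_that("weak zones select the prescribed corneal elements", {
  cfg <- globe_config()
  ## central cone: only apex-region corneal elements are modified
  mc <- apply_weak_zone(cfg, weak_zone(70, 90, 2.48))
  wk <- which(mc$mesh$region == "cornea_weak")
  expect_gt(length(wk), 0)
  expect_true(all(mc$theta_deg[wk] >= 70 - 1e-9))
  expect_equal(mc$materials$cornea_weak$E, 2.48e3)
  ## apex elements (theta near 90) are in the zone
  expect_true(any(mc$theta_deg[wk] > 85))
  ## peripheral ring: apex untouched
  mp <- apply_weak_zone(cfg, weak_zone(50, 70, 2.48))
  wkp <- which(mp$mesh$region == "cornea_weak")
  expect_gt(length(wkp), 0)
  expect_true(all(mp$theta_deg[wkp] <= 70 + 1e-9))
  expect_false(any(mp$theta_deg[wkp] > 85))
  ## a zone that misses the cornea errors
  expect_error(apply_weak_zone(cfg, weak_zone(0, 20, 2.48)), "misses the cornea")
  ## zone invariants
  expect_error(weak_zone(80, 70, 2.48), "theta")
  expect_error(weak_zone(70, 90, -1), "modulus")
})

test_that("no-op weakening reproduces the nominal response bitwise", {
  cfg <- globe_config(n_arc_cornea = 10, n_arc_limbus = 4, n_arc_sclera = 20,
                      n_fluid_radial = 4, E_posterior_kPa = 24.8)
  m0 <- build_globe(cfg)
  m1 <- apply_weak_zone(cfg, weak_zone(70, 90, cfg$E_anterior_kPa))
  f0 <- frf_sweep(m0, 50, 250, 10)
  f1 <- frf_sweep(m1, 50, 250, 10)
  expect_identical(f0$amplitude, f1$amplitude)
})
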