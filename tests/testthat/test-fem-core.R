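test_that("single element reproduces the constant-stress patch solution", {
  ## uniform radial stretch u_r = c*r on one axisymmetric 4-node element:
  ## e_rr = e_tt = c everywhere, so the strain energy must match the
  ## closed-form constant-stress value exactly (linear completeness)
  nodes <- rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1)) * 1e-3
  E <- 1e4; nu <- 0.3; cc <- 1e-3
  K <- ocuvib:::elem_K_solid(nodes, 4L, E, nu, "sri")
  u <- as.vector(t(cbind(cc * nodes[, 1], 0)))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  srr <- (lam + 2 * mu) * cc + lam * cc
  V <- 2 * pi * 1.5e-3 * 1e-6
  expect_equal(as.numeric(t(u) %*% K %*% u / 2), srr * cc * V, tolerance = 1e-10)
  ## rigid axial translation is strain-free
  uz <- as.vector(t(cbind(0, rep(1, 4))))
  expect_lt(max(abs(K %*% uz)), 1e-8 * max(abs(K)))
})

test_that("assembled element stiffness matches brute-force quadrature", {
  ## independent oracle: dense 12x12 Gauss integration of B' D B r,
  ## written from the definitions rather than the element routine
  nodes <- rbind(c(0.8, 0.1), c(2.1, 0), c(2.2, 1.2), c(1.0, 0.9)) * 1e-3
  E <- 2.3e4; nu <- 0.32
  brute <- matrix(0, 8, 8)
  ## Gauss-Legendre nodes via eigen decomposition of the Jacobi matrix;
  ## the 2-point rule matches the element's full-integration rule, so the
  ## comparison isolates the B/D assembly from quadrature differences
  ng <- 2
  beta <- (1:(ng - 1)) / sqrt(4 * (1:(ng - 1))^2 - 1)
  J <- diag(0, ng); J[cbind(1:(ng - 1), 2:ng)] <- beta
  J[cbind(2:ng, 1:(ng - 1))] <- beta
  ev <- eigen(J, symmetric = TRUE)
  xg <- ev$values; wg <- 2 * ev$vectors[1, ]^2
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(lam, 4, 4); diag(D)[1:3] <- lam + 2 * mu
  D[4, ] <- D[, 4] <- 0; D[4, 4] <- mu
  shp <- function(xi, eta) {
    xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
    list(N = 0.25 * (1 + xi * xs) * (1 + eta * es),
         dN = cbind(0.25 * xs * (1 + eta * es), 0.25 * es * (1 + xi * xs)))
  }
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    sh <- shp(xg[i], xg[j])
    Jm <- t(sh$dN) %*% nodes
    dJ <- det(Jm)
    dN <- sh$dN %*% t(solve(Jm))
    r <- sum(sh$N * nodes[, 1])
    B <- matrix(0, 4, 8)
    ir <- seq(1, 8, 2)
    B[1, ir] <- dN[, 1]; B[2, ir + 1] <- dN[, 2]
    B[3, ir] <- sh$N / r; B[4, ir] <- dN[, 2]; B[4, ir + 1] <- dN[, 1]
    brute <- brute + t(B) %*% D %*% B * (2 * pi * r * dJ * wg[i] * wg[j])
  }
  K <- ocuvib:::elem_K_solid(nodes, 4L, E, nu, "full")
  expect_equal(K, brute, tolerance = 1e-12)
})

test_that("1-dof oscillator follows the closed-form response", {
  k <- 1e4; m <- 1
  sys <- one_dof_system(m = m, k = k)
  f0 <- sqrt(k / m) / (2 * pi)
  for (f in c(0.5, 0.9, 1.1, 2) * f0) {
    om <- 2 * pi * f
    sol <- solve_harmonic(sys, f)
    expect_equal(Re(sol$u[1]), 1 / (k - m * om^2), tolerance = 1e-10)
    expect_lt(abs(Im(sol$u[1])), 1e-12)
  }
  ## sign flips across the resonance
  below <- Re(solve_harmonic(sys, 0.9 * f0)$u[1])
  above <- Re(solve_harmonic(sys, 1.1 * f0)$u[1])
  expect_gt(below, 0); expect_lt(above, 0)
  ## undamped solve exactly at the eigenfrequency is singular, with advice
  expect_error(solve_harmonic(sys, f0), "damping")
})

test_that("Prony damping keeps the resonance finite with phase lag in (0, pi)", {
  mat <- material_spec(E = 0.9e4, nu = 0.3, rho = 1,
                       prony = list(list(p = 0.1, T = 1e-3)))
  sys <- one_dof_system(m = 1, k = 0.9e4, mat = mat)
  f0 <- 1 / (2 * pi * 1e-3)          # OmegaT = 1
  sol <- solve_harmonic(sys, f0)
  expect_true(is.finite(Mod(sol$u[1])))
  lag <- -Arg(sol$u[1])
  expect_gt(lag, 0); expect_lt(lag, pi)
})

test_that("coupled piston-cavity response matches the 2-dof analytic oracle", {
  ## piston (m, k) closing an acoustic cavity: the coupled pencil reduces to
  ## u * [(k - om^2 m) - om^2 R^2 / (H - om^2 Q)] = F, and the added mass
  ## strictly lowers the structural resonance relative to vacuum
  m <- 0.002; k <- 5e4; H <- 2e-4; Q <- 1.1e-12; Rc <- 1e-4
  mkmat <- function(x) Matrix::sparseMatrix(i = 1, j = 1, x = x, dims = c(1, 1))
  Kp <- mkmat(k); attr(Kp, "material") <- material_spec(k, 0.3, 1)
  solid <- list(K_parts = list(s = Kp), M = mkmat(m), Kg = mkmat(0))
  fl <- list(H = mkmat(H), Q = mkmat(Q), R = mkmat(Rc))
  sys <- harmonic_system(solid, fl, load = c(1 + 0i, 0i), constrained = integer())
  anal <- function(f) {
    om <- 2 * pi * f
    1 / ((k - om^2 * m) - om^2 * Rc^2 / (H - om^2 * Q))
  }
  for (f in c(100, 300, 700)) {
    sol <- solve_harmonic(sys, f)
    expect_equal(Re(sol$u[1]), anal(f), tolerance = 1e-10)
  }
  ## coupled resonance: root of the real denominator, below vacuum sqrt(k/m)
  f_vac <- sqrt(k / m) / (2 * pi)
  den <- function(f) {
    om <- 2 * pi * f
    (k - om^2 * m) - om^2 * Rc^2 / (H - om^2 * Q)
  }
  f_cpl <- stats::uniroot(den, c(10, f_vac * 0.999))$root
  expect_lt(f_cpl, f_vac)
  below <- Re(solve_harmonic(sys, f_cpl * 0.98)$u[1])
  above <- Re(solve_harmonic(sys, f_cpl * 1.02)$u[1])
  expect_gt(below, 0); expect_lt(above, 0)
})

test_that("rigid cylindrical cavity reproduces the analytic axial mode", {
  L <- 0.02; a <- 0.005; c0 <- 1480
  grid <- ocuvib:::structured_grid(4, 12, function(s, t) c(a * s, L * t))
  msh <- axi_mesh(grid$nodes, grid$elements, rep("fluid", 48))
  fs <- assemble_fluid(msh, fluid_spec(rho = 1000, c = c0))
  ev <- eigen(solve(as.matrix(fs$Q), as.matrix(fs$H)), only.values = TRUE)$values
  ev <- sort(Re(ev[Re(ev) > 1]))
  f1 <- sqrt(ev[1]) / (2 * pi)
  expect_equal(f1, c0 / (2 * L), tolerance = 0.02)
})

test_that("degenerate fluid mesh geometry is rejected", {
  nodes <- rbind(c(0, 0), c(0, 1e-3), c(0, 2e-3), c(1e-3, 1e-3))
  el <- matrix(c(1L, 2L, 3L, 4L), 1, 4)    # zero-radius collapsed strip
  expect_error(axi_mesh(nodes, el, "fluid"), "Jacobian")
})

test_that("prestress tension raises the first flap resonance", {
  f_pre <- find_peaks(nominal_flap_frf())$frequency[1]
  flap0 <- build_flap(flap_config(prestress_kPa = 0))
  f_0 <- find_peaks(frf_sweep(flap0, 50, 750, 5))$frequency[1]
  expect_gt(f_pre, f_0)
})

test_that("undamped solid response is reciprocal to 1e-10", {
  ## receptance submatrix G[a, b] = u_b under unit load at a must be
  ## symmetric for the undamped elastic solid
  cfg <- flap_config(prony = NULL, nu = 0.3, thickness_um = 500,
                     n_radial = 8, n_thickness = 2)
  model <- build_flap(cfg)
  sys <- model$system
  set.seed(7)
  dofs <- sample(length(sys$free), 5)
  f <- 120
  G <- matrix(0, 5, 5)
  for (a in seq_along(dofs)) {
    s <- sys
    s$load <- complex(length(sys$load)); s$load[dofs[a]] <- 1
    s$load_omega2 <- FALSE
    u <- solve_harmonic(s, f)
    G[a, ] <- Re(c(u$u, u$p)[sys$free][dofs])
  }
  expect_lt(norm(G - t(G), "F") / norm(G, "F"), 1e-10)
})

test_that("first flap frequency is mesh-converged below 1 percent", {
  f1 <- find_peaks(nominal_flap_frf())$frequency[1]
  fine <- build_flap(flap_config(refine = 2))   # 4x the elements
  frf_fine <- frf_sweep(fine, 100, 250, 5, refine_peaks = TRUE, refine_step = 1)
  f1_fine <- find_peaks(frf_fine)$frequency[1]
  expect_lt(abs(f1 - f1_fine) / f1_fine, 0.01)
})

test_that("near-incompressible flap does not lock relative to nu = 0.49", {
  ## pure-bending configuration (no prestress); the analytic plate frequency
  ## scales with sqrt(D) ~ 1/sqrt(1 - nu^2)
  f_of <- function(nu) {
    m <- build_flap(flap_config(prestress_kPa = 0, nu = nu))
    find_peaks(frf_sweep(m, 30, 200, 2))$frequency[1]
  }
  f499 <- f_of(0.499); f49 <- f_of(0.49)
  ratio_analytic <- sqrt((1 - 0.49^2) / (1 - 0.499^2))
  expect_equal(f499 / f49, ratio_analytic, tolerance = 0.05)
})

test_that("clamped prestressed membrane matches the analytic first resonance", {
  cfg <- membrane_config()
  model <- build_flap(cfg)
  f_th <- membrane_f1()
  frf <- frf_sweep(model, max(50, f_th - 120), f_th + 120, 2,
                   refine_peaks = TRUE, refine_step = 1)
  f1 <- find_peaks(frf)$frequency[1]
  expect_equal(f1, f_th, tolerance = 0.02)
})

test_that("degenerate solid geometry fails assembly naming the element", {
  ## second element is twisted (bow-tie) -> negative Jacobian
  nodes <- rbind(c(0, 0), c(1, 0), c(2, 0),
                 c(0, 1), c(1, 1), c(2, 1)) * 1e-3
  el <- rbind(c(1L, 2L, 5L, 4L), c(2L, 3L, 5L, 6L))
  msh <- axi_mesh(nodes, el, c("cornea", "cornea"), check = FALSE)
  mats <- list(cornea = material_spec(1e4, 0.3, 1000))
  expect_error(assemble_solid(msh, mats), "element 2")
})
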