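test_that("fit_slope recovers an exactly linear relation with R^2 = 1", {
  sw <- data.frame(value = rep(c(10, 12, 14, 16, 18), each = 2),
                   mode = rep(c("nc0.1", "nc1.1"), 5),
                   frequency = c(rbind(100 + 3.5 * c(10, 12, 14, 16, 18),
                                       200 - 1.25 * c(10, 12, 14, 16, 18))),
                   nodal_circles = rep(c(0L, 1L), 5))
  attr(sw, "parameter") <- "E"; attr(sw, "unit") <- "Hz kPa^-1"
  attr(sw, "nominal") <- 14
  class(sw) <- c("sensitivity_sweep", "data.frame")
  s1 <- fit_slope(sw, "nc0.1")
  expect_equal(s1$slope, 3.5, tolerance = 1e-12)
  expect_equal(s1$r_squared, 1)
  s2 <- fit_slope(sw, 2)          # numeric index resolves by modal frequency
  expect_equal(s2$slope, -1.25, tolerance = 1e-12)
  expect_error(fit_slope(sw[sw$value > 15, ], "nc0.1"), "3 levels")
})

test_that("degenerate sweep specifications are rejected", {
  expect_error(sweep_spec("E", levels = 1), "3 levels")
  expect_error(sweep_spec("E", rel_range = 0), "rel_range")
  expect_error(sensitivity_sweep(flap_config(), sweep_spec("bogus")),
               "unknown flap parameter")
})

test_that("membrane prestress slope matches the analytic square-root law", {
  ## for a tension-dominated membrane f ~ sqrt(sigma0): df/dsigma0 = f0/(2 sigma0)
  cfg <- membrane_config()
  sw <- sensitivity_sweep(cfg, sweep_spec("prestress", rel_range = 0.1,
                                          levels = 3),
                          f_min = 250, f_max = 550, step = 5)
  s <- fit_slope(sw, 1)
  f0 <- membrane_f1()
  expect_equal(s$slope, f0 / (2 * 5), tolerance = 0.1)   # Hz per kPa
  expect_gt(s$r_squared, 0.99)
})

test_that("flap frequencies respond to parameters with the expected signs and ordering", {
  specs <- list(E = sweep_spec("E", levels = 3),
                density = sweep_spec("density", levels = 3),
                thickness = sweep_spec("thickness", levels = 3),
                radius = sweep_spec("radius", levels = 3))
  slopes <- lapply(specs, function(sp) {
    sw <- sensitivity_sweep(flap_config(), sp, f_min = 50, f_max = 760,
                            step = 5)
    ## the reference slope table reports the first and second resonances;
    ## the third leaves the sweep window during a +-20% radius change
    utils::head(slope_table(sw), 2)
  })
  ## density: both tracked modes soften with added mass
  expect_true(all(slopes$density$slope < 0))
  ## radius: larger flap -> lower frequencies
  expect_true(all(slopes$radius$slope < 0))
  ## stiffness and thickness stiffen
  expect_true(all(slopes$E$slope > 0))
  expect_true(all(slopes$thickness$slope > 0))
  ## the second resonance is more sensitive than the first for all four
  for (nm in names(slopes)) {
    st <- slopes[[nm]]
    expect_gt(abs(st$slope[2]), abs(st$slope[1]))
  }
})

test_that("flap frequencies are monotone in stiffness and density over the sweep", {
  for (par in c("E", "density")) {
    sw <- sensitivity_sweep(flap_config(), sweep_spec(par, levels = 3),
                            f_min = 50, f_max = 760, step = 5)
    for (k in unique(sw$mode)) {
      d <- sw[sw$mode == k, ]
      d <- d[order(d$value), ]
      if (nrow(d) < 3) next
      if (par == "E") expect_true(all(diff(d$frequency) > -1e-6))
      else expect_true(all(diff(d$frequency) < 1e-6))
    }
  }
})

test_that("local corneal weakening creates new resonances and shifts others", {
  cfg <- globe_config()
  ## central cone (70-90 deg, 2.48 kPa): new peaks appear alongside shifts
  central <- compare_weakened(cfg, weak_zone(70, 90, 2.48), step = 5,
                              refine_peaks = FALSE)
  expect_gt(sum(central$report$status == "new"), 0)
  expect_gt(sum(central$report$status == "shifted"), 0)
  ## the new resonances emerge inside the band, below the top nominal mode
  new_c <- central$report$frequency[central$report$status == "new"]
  expect_true(any(new_c < max(central$peaks_nominal$frequency)))
  ## peripheral ring (50-70 deg): a different new/shift pattern
  periph <- compare_weakened(cfg, weak_zone(50, 70, 2.48), step = 5,
                             refine_peaks = FALSE)
  new_p <- periph$report$frequency[periph$report$status == "new"]
  expect_gt(length(new_p), 0)
  expect_false(isTRUE(all.equal(sort(new_c), sort(new_p))))
  ## identical grids by construction
  expect_identical(central$frf_nominal$frequencies,
                   central$frf_weak$frequencies)
})
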