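test_that("sweep grid arithmetic and linearity hold", {
  m <- nominal_flap()
  frf <- nominal_flap_frf()            # 50-750 Hz, step 5
  expect_length(frf$frequencies, 141)
  expect_equal(frf$frequencies[1], 50)
  expect_equal(frf$frequencies[141], 750)
  ## linear system: doubling the excitation doubles every amplitude
  sub <- frf_sweep(m, 100, 200, 10)
  sub2 <- frf_sweep(m, 100, 200, 10, load_scale = 2)
  expect_equal(sub2$amplitude, 2 * sub$amplitude, tolerance = 1e-12)
})

test_that("frequency_response enforces its invariants", {
  expect_error(frequency_response(c(100, 90), c(1, 1)), "strictly increasing")
  expect_error(frequency_response(c(100, 100.5), c(1, 1)), "grid step")
  expect_error(frequency_response(c(100, 200), c(1, 1)), "grid step")
  expect_error(frequency_response(c(100, 110), c(1, -1)), "amplitudes")
  expect_silent(frequency_response(seq(50, 750, 5), rep(1, 141)))
})

test_that("find_peaks recovers the centres of a Lorentzian triplet", {
  f <- seq(50, 600, 1)
  lor <- function(f0, w) 1 / (1 + ((f - f0) / (w / 2))^2)
  a <- lor(150, 20) + 0.8 * lor(300, 20) + 0.6 * lor(450, 20)
  pk <- find_peaks(frequency_response(f, a))
  expect_equal(nrow(pk), 3)
  expect_equal(pk$frequency, c(150, 300, 450), tolerance = 1e-2)
  ## half-prominence widths close to the Lorentzian FWHM
  expect_equal(pk$width, rep(20, 3), tolerance = 0.25)
  ## constant and monotone FRFs yield no peaks, not an error
  expect_equal(nrow(find_peaks(frequency_response(f, rep(1, length(f))))), 0)
  expect_equal(nrow(find_peaks(frequency_response(f, seq_along(f)))), 0)
  expect_error(find_peaks(frequency_response(c(50, 60, 70), c(1, 2, 1))),
               "at least 5")
})

test_that("flap mode shapes are successive harmonics of the fundamental", {
  m <- nominal_flap()
  pk <- find_peaks(nominal_flap_frf())
  expect_gte(nrow(pk), 3)
  shapes <- lapply(seq_len(nrow(pk)), function(i) classify_mode(m, pk[i, ]))
  nc <- vapply(shapes, `[[`, 0L, "nodal_circles")
  ## fundamental has no interior nodal circle; counts strictly increase
  expect_equal(nc[1], 0L)
  expect_equal(nc[2], 1L)
  expect_true(all(diff(nc) > 0))
  ## no sclera in a flap
  expect_equal(shapes[[1]]$scleral_participation, 0)
})

test_that("refining the sweep step never loses peaks", {
  m <- nominal_flap()
  coarse <- frf_sweep(m, 50, 750, 20)
  fine <- frf_sweep(m, 50, 750, 5)
  n_coarse <- nrow(find_peaks(coarse))
  n_fine <- nrow(find_peaks(fine))
  expect_gte(n_fine, n_coarse)
})

test_that("peak frequencies are invariant to the excitation profile", {
  ## smooth symmetric load change (pressure vs rigid-frame inertial drive)
  ## moves every detected peak by less than 0.5 percent
  f_base <- find_peaks(nominal_flap_frf())$frequency
  mp <- build_flap(flap_config(excitation = "pressure"))
  f_press <- find_peaks(frf_sweep(mp, 50, 750, 5), prominence = 0.02)$frequency
  for (fb in f_base) {
    fp <- f_press[which.min(abs(f_press - fb))]
    expect_lt(abs(fp - fb) / fb, 0.005)
  }
})

test_that("removing the Prony term collapses peak widths but not positions", {
  me <- build_flap(flap_config(prony = NULL))
  frf_e <- frf_sweep(me, 50, 750, 5)
  pk_e <- find_peaks(frf_e)
  pk_v <- find_peaks(nominal_flap_frf())
  n <- min(nrow(pk_e), nrow(pk_v))
  expect_gte(n, 2)
  ## elastic-limit peak frequencies within 3 percent of the damped ones
  expect_equal(pk_e$frequency[1:n], pk_v$frequency[1:n], tolerance = 0.03)
  ## locate the true response maximum by ternary search around the first peak
  peak_amp <- function(model, f0) {
    amp <- function(f) Mod(solve_harmonic(model$system, f)$u[model$probe_dof])
    lo <- f0 - 3; hi <- f0 + 3
    for (it in 1:40) {
      m1 <- lo + (hi - lo) / 3; m2 <- hi - (hi - lo) / 3
      if (amp(m1) < amp(m2)) lo <- m1 else hi <- m2
    }
    amp((lo + hi) / 2)
  }
  mv <- nominal_flap()
  ## undamped: the response grows without bound as the grid approaches the
  ## resonance; damped: the Prony loss modulus caps it
  expect_gt(peak_amp(me, pk_e$frequency[1]), 50 * max(frf_e$amplitude))
  expect_lt(peak_amp(mv, pk_v$frequency[1]), 3 * max(nominal_flap_frf()$amplitude))
  ## at matched 1 Hz resolution the elastic resonance width collapses
  frf_e1 <- frf_sweep(me, pk_e$frequency[1] - 20, pk_e$frequency[1] + 20, 1)
  frf_v1 <- frf_sweep(mv, pk_v$frequency[1] - 20, pk_v$frequency[1] + 20, 1)
  expect_lt(find_peaks(frf_e1)$width[1], 0.5 * find_peaks(frf_v1)$width[1])
})
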