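make_tone <- function(f, fs = 48e3, n_periods = 25, A = 1e-7, phase = 0.4,
                      dc = 0) {
  t <- (0:(ceiling(n_periods * fs / f) - 1)) / fs
  A * cos(2 * pi * f * t + phase) + dc
}

test_that("amplitude extraction is exact for pure tones, any phase or DC", {
  for (f in c(240, 313.7, 520)) for (ph in c(0, 1.1, -2.5)) {
    x <- make_tone(f, A = 3.3e-8, phase = ph, dc = 5e-7)
    rec <- vibration_record(f, 48e3, x)
    ex <- extract_amplitude(rec)
    expect_equal(ex$amplitude, 3.3e-8, tolerance = 1e-9)
    expect_equal(Arg(exp(1i * (ex$phase - ph))), 0, tolerance = 1e-6)
  }
})

test_that("reference motion cancels exactly", {
  f <- 360; fs <- 48e3
  t <- (0:5999) / fs
  ref <- 4e-7 * cos(2 * pi * f * t + 0.9)
  x <- 1e-7 * cos(2 * pi * f * t - 0.3) + ref
  rec <- vibration_record(f, fs, x, reference = ref)
  expect_equal(extract_amplitude(rec)$amplitude, 1e-7, tolerance = 1e-12)
})

test_that("second-harmonic contamination does not bias the drive amplitude", {
  f <- 280; fs <- 48e3
  t <- (0:7999) / fs
  x <- 2e-7 * cos(2 * pi * f * t + 0.2) + 1e-7 * cos(2 * pi * 2 * f * t + 1.3)
  rec <- vibration_record(f, fs, x)
  ## oracle: direct DFT of the constructed signal at f over whole periods
  keep <- 1:round(floor(length(t) * f / fs) * fs / f)
  oracle <- Mod(2 * mean(x[keep] * exp(-2i * pi * f * t[keep])))
  ex <- extract_amplitude(rec)
  expect_equal(ex$amplitude, oracle, tolerance = 1e-6)
  expect_equal(ex$amplitude, 2e-7, tolerance = 1e-4)
})

test_that("record invariants reject bad acquisitions", {
  expect_error(vibration_record(400, 700, numeric(100)), "Nyquist")
  expect_error(vibration_record(100, 48e3, numeric(500)), "2 periods")
  x <- make_tone(300, n_periods = 3)
  rec <- vibration_record(300, 48e3, x)
  rec$drive_frequency <- 3e5            # corrupt after construction
  expect_error(extract_amplitude(rec), "Nyquist")
})

test_that("extraction error stays below 1 percent at 20 dB SNR", {
  set.seed(11)
  f <- 320; A <- 1e-7
  snr_amp <- A / 10^(20 / 20)           # 20 dB amplitude ratio
  errs <- replicate(40, {
    x <- make_tone(f, A = A, phase = stats::runif(1, 0, 2 * pi), n_periods = 50)
    x <- x + stats::rnorm(length(x), sd = snr_amp)
    extract_amplitude(vibration_record(f, 48e3, x))$amplitude
  })
  expect_lt(stats::median(abs(errs - A) / A), 0.01)
})

test_that("assemble_frf sorts, averages duplicates and rejects empty input", {
  f_list <- c(400, 240, 280, 320, 360)
  recs <- lapply(f_list, function(f)
    vibration_record(f, 48e3, make_tone(f, A = f * 1e-10)))
  frf <- assemble_frf(recs)
  expect_equal(frf$frequencies, sort(f_list))
  expect_equal(frf$amplitude, sort(f_list) * 1e-10, tolerance = 1e-9)
  ## duplicates averaged
  recs2 <- c(recs, list(vibration_record(240, 48e3, make_tone(240, A = 3 * 240e-10))))
  frf2 <- assemble_frf(recs2)
  expect_equal(frf2$amplitude[1], 2 * 240e-10, tolerance = 1e-9)
  expect_error(assemble_frf(list()), "no records")
})

test_that("records survive the CSV container round trip", {
  f <- c(240, 280)
  recs <- lapply(f, function(ff) {
    tr <- rbind(make_tone(ff, n_periods = 4), make_tone(ff, n_periods = 4, A = 2e-7))
    vibration_record(ff, 48e3, tr, positions = c(0, 1e-3),
                     reference = make_tone(ff, n_periods = 4, A = 5e-8))
  })
  path <- tempfile(fileext = ".csv")
  write_records_csv(recs, path)
  back <- read_records_csv(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$trace, recs[[1]]$trace, tolerance = 1e-12)
  expect_equal(back[[2]]$reference, recs[[2]]$reference, tolerance = 1e-12)
  expect_equal(back[[1]]$positions, recs[[1]]$positions)
})
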