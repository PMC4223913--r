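#' Synthetic vibrography specification
#'
#' Ground-truth description for generating synthetic displacement records
#' and noisy frequency-response functions: the forward model provides the
#' apex response at each drive frequency; traces add optional reference
#' (set-up) motion, second-harmonic loudspeaker contamination and seeded
#' Gaussian displacement noise.
#'
#' @param cfg ground-truth model configuration (`flap_config` or
#'   `globe_config`).
#' @param drive_frequencies drive frequency list (Hz).
#' @param amplitude_scale peak displacement scale (m): the forward FRF is
#'   rescaled so its maximum over the drive list equals this value
#'   (default 300 nm, the flap scale; use ~10 um for whole globes). `NA`
#'   keeps the raw forward amplitudes.
#' @param noise_sd additive Gaussian displacement noise SD (m).
#' @param reference_amplitude amplitude of the common-mode set-up motion
#'   added to the trace and recorded in the reference channel (m).
#' @param harmonic_fraction second-harmonic contamination as a fraction of
#'   the local amplitude (default 0.1), in [0, 1).
#' @param sampling_rate sampling rate (Hz, default 48 kHz).
#' @param n_periods trace length in drive periods (default 20).
#' @param noise_frac multiplicative log-normal noise (sdlog) used by
#'   [make_noisy_frf()].
#' @param seed integer seed fixing all randomness.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(cfg, drive_frequencies, amplitude_scale = 300e-9,
                       noise_sd = 0, reference_amplitude = 0,
                       harmonic_fraction = 0.1, sampling_rate = 48e3,
                       n_periods = 20, noise_frac = 0, seed = 1) {
  if (noise_sd < 0) stop("synth_spec: noise SD must be >= 0")
  if (harmonic_fraction < 0 || harmonic_fraction >= 1)
    stop("synth_spec: harmonic fraction must lie in [0, 1)")
  if (noise_frac < 0) stop("synth_spec: noise_frac must be >= 0")
  structure(list(cfg = cfg, drive_frequencies = sort(drive_frequencies),
                 amplitude_scale = amplitude_scale, noise_sd = noise_sd,
                 reference_amplitude = reference_amplitude,
                 harmonic_fraction = harmonic_fraction,
                 sampling_rate = sampling_rate, n_periods = n_periods,
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "synth_spec")
}

## forward apex response (complex) at the given frequencies
forward_response <- function(model, freqs) {
  vapply(freqs, function(f) {
    sol <- solve_harmonic(model$system, f)
    sol$u[model$probe_dof]
  }, complex(1))
}

#' Generate synthetic vibrography records
#'
#' For each drive frequency, builds a sinusoidal displacement trace whose
#' amplitude and phase are the forward model's apex response (rescaled to
#' `amplitude_scale`), adds the configured reference motion,
#' second-harmonic contamination and Gaussian noise, and packs it into a
#' [vibration_record()] with the reference channel filled in. The ground
#' truth is stored in the `ground_truth` attribute of the returned list.
#'
#' @param spec a [synth_spec()].
#' @return list of [vibration_record()]s, with attribute `ground_truth`
#'   (data frame: `f_hz`, `amplitude_m`, `phase_rad`).
#' @export
make_records <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  model <- build_model(spec$cfg)
  resp <- forward_response(model, spec$drive_frequencies)
  amp <- Mod(resp); phs <- Arg(resp)
  if (!is.na(spec$amplitude_scale) && max(amp) > 0)
    amp <- amp * spec$amplitude_scale / max(amp)
  set.seed(spec$seed)
  fs <- spec$sampling_rate
  recs <- vector("list", length(spec$drive_frequencies))
  for (k in seq_along(spec$drive_frequencies)) {
    f <- spec$drive_frequencies[k]
    if (fs <= 2 * f)
      stop("make_records: drive frequency above Nyquist for the sampling rate")
    n_t <- ceiling(spec$n_periods * fs / f)
    t <- (seq_len(n_t) - 1) / fs
    x <- amp[k] * cos(2 * pi * f * t + phs[k])
    if (spec$harmonic_fraction > 0) {
      ph2 <- stats::runif(1, 0, 2 * pi)
      x <- x + spec$harmonic_fraction * amp[k] * cos(2 * pi * 2 * f * t + ph2)
    }
    ref <- NULL
    if (spec$reference_amplitude > 0) {
      phr <- stats::runif(1, 0, 2 * pi)
      ref <- spec$reference_amplitude * cos(2 * pi * f * t + phr)
      x <- x + ref
    }
    if (spec$noise_sd > 0)
      x <- x + stats::rnorm(n_t, sd = spec$noise_sd)
    recs[[k]] <- vibration_record(drive_frequency = f, sampling_rate = fs,
                                  trace = x, reference = ref,
                                  meta = list(synthetic = TRUE))
  }
  attr(recs, "ground_truth") <- data.frame(
    f_hz = spec$drive_frequencies, amplitude_m = amp, phase_rad = phs)
  recs
}

#' Generate a noisy frequency response function
#'
#' The forward FRF sampled on the spec's drive grid with multiplicative
#' log-normal amplitude noise (`sdlog = noise_frac`); used for
#' fit-robustness studies. Zero noise returns the forward FRF exactly.
#'
#' @param spec a [synth_spec()].
#' @return a [frequency_response()] with attribute `ground_truth` (the
#'   noiseless amplitudes).
#' @export
make_noisy_frf <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  model <- build_model(spec$cfg)
  resp <- forward_response(model, spec$drive_frequencies)
  amp <- Mod(resp)
  if (!is.na(spec$amplitude_scale) && max(amp) > 0)
    amp <- amp * spec$amplitude_scale / max(amp)
  set.seed(spec$seed)
  noisy <- if (spec$noise_frac > 0)
    amp * stats::rlnorm(length(amp), meanlog = 0, sdlog = spec$noise_frac)
  else amp
  frf <- frequency_response(spec$drive_frequencies, noisy, Arg(resp))
  attr(frf, "ground_truth") <- amp
  frf
}
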