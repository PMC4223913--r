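#' Vibrography displacement record
#'
#' One acquisition at a single drive frequency: vertical displacement time
#' series per lateral position, optionally with the rigid-glass reference
#' trace recorded at the border of each scan to cancel set-up motion.
#'
#' @param drive_frequency drive (loudspeaker) frequency (Hz).
#' @param sampling_rate sampling rate (Hz); must exceed twice the drive
#'   frequency.
#' @param trace numeric matrix `n_pos x n_t` (or a vector for a single
#'   position) of displacements (m).
#' @param positions lateral positions (m) of the trace rows; defaults to a
#'   single apex position at 0.
#' @param reference optional reference displacement trace (m), length `n_t`.
#' @param meta optional metadata list (sound pressure level, specimen id, ...).
#' @return an object of class `vibration_record`.
#' @export
vibration_record <- function(drive_frequency, sampling_rate, trace,
                             positions = NULL, reference = NULL, meta = list()) {
  if (is.vector(trace)) trace <- matrix(trace, nrow = 1)
  if (is.null(positions)) positions <- numeric(nrow(trace))
  if (length(positions) != nrow(trace))
    stop("vibration_record: one position per trace row required")
  if (sampling_rate <= 2 * drive_frequency)
    stop("vibration_record: sampling rate must exceed twice the drive frequency (Nyquist)")
  n_t <- ncol(trace)
  if (n_t < 2 * sampling_rate / drive_frequency)
    stop("vibration_record: trace must span at least 2 periods of the drive frequency")
  if (!is.null(reference) && length(reference) != n_t)
    stop("vibration_record: reference length must match the trace")
  structure(list(drive_frequency = drive_frequency,
                 sampling_rate = sampling_rate, trace = trace,
                 positions = positions, reference = reference, meta = meta),
            class = "vibration_record")
}

#' @export
print.vibration_record <- function(x, ...) {
  cat(sprintf("vibration_record: f = %g Hz, fs = %g Hz, %d position(s) x %d samples%s\n",
              x$drive_frequency, x$sampling_rate, nrow(x$trace), ncol(x$trace),
              if (is.null(x$reference)) "" else ", with reference"))
  invisible(x)
}

#' Extract the oscillation amplitude at the drive frequency
#'
#' Reference subtraction followed by Fourier amplitude extraction at the
#' known drive frequency: the trace is truncated to (the nearest whole
#' number of samples spanning) an integer number of drive periods, then the
#' single-sided amplitude and phase at the drive frequency are obtained by
#' least-squares projection onto `cos/sin(2 pi f t)` -- identical to the
#' DFT bin on an exact integer-period window, and exact for a pure tone on
#' any window. This removes contamination from higher loudspeaker
#' harmonics and is invariant to start phase and DC offset.
#'
#' @param rec a [vibration_record()].
#' @param position index of the trace row to analyse; default the row whose
#'   lateral position is closest to the apex (0).
#' @return list with `amplitude` (m), `phase` (rad), `frequency` (Hz).
#' @export
extract_amplitude <- function(rec, position = NULL) {
  stopifnot(inherits(rec, "vibration_record"))
  f <- rec$drive_frequency; fs <- rec$sampling_rate
  if (fs <= 2 * f)
    stop("extract_amplitude: drive frequency above Nyquist")
  if (is.null(position)) position <- which.min(abs(rec$positions))
  x <- rec$trace[position, ]
  if (!is.null(rec$reference)) x <- x - rec$reference
  n <- length(x)
  periods <- floor(n * f / fs)
  if (periods < 2)
    stop("extract_amplitude: trace shorter than 2 periods of the drive frequency")
  keep <- min(n, round(periods * fs / f))
  x <- x[seq_len(keep)]
  t <- (seq_len(keep) - 1) / fs
  C <- cos(2 * pi * f * t); S <- sin(2 * pi * f * t)
  X <- cbind(1, C, S)
  cf <- stats::lm.fit(X, x)$coefficients
  a <- cf[2]; b <- cf[3]
  list(amplitude = unname(sqrt(a^2 + b^2)),
       phase = unname(atan2(-b, a)),   # x ~ A cos(2 pi f t + phase)
       frequency = f)
}

#' Assemble a measured frequency response function from records
#'
#' Extracts the apex amplitude of each record and assembles the amplitudes
#' as a function of drive frequency, sorted ascending; records at duplicate
#' frequencies are averaged.
#'
#' @param records list of [vibration_record()]s at (mostly) distinct drive
#'   frequencies.
#' @return a [frequency_response()].
#' @export
assemble_frf <- function(records) {
  if (length(records) == 0) stop("assemble_frf: no records given")
  ext <- lapply(records, extract_amplitude)
  f <- vapply(ext, `[[`, 0, "frequency")
  a <- vapply(ext, `[[`, 0, "amplitude")
  ph <- vapply(ext, `[[`, 0, "phase")
  ## average duplicates
  key <- as.character(round(f, 9))
  fu <- tapply(f, key, mean); au <- tapply(a, key, mean)
  pu <- tapply(ph, key, function(p) Arg(mean(exp(1i * p))))
  ord <- order(fu)
  frequency_response(as.numeric(fu[ord]), as.numeric(au[ord]),
                     as.numeric(pu[ord]), probe = "apex")
}

#' Write vibrography records to the flat CSV container
#'
#' One file per run with columns `record, f_hz, fs_hz, pos_m, t_s,
#' displacement_m`; the reference trace uses the sentinel position
#' `pos_m = NA`.
#'
#' @param records list of [vibration_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  rows <- list()
  for (k in seq_along(records)) {
    r <- records[[k]]
    t <- (seq_len(ncol(r$trace)) - 1) / r$sampling_rate
    for (i in seq_len(nrow(r$trace)))
      rows[[length(rows) + 1]] <- data.frame(
        record = k, f_hz = r$drive_frequency, fs_hz = r$sampling_rate,
        pos_m = r$positions[i], t_s = t, displacement_m = r$trace[i, ])
    if (!is.null(r$reference))
      rows[[length(rows) + 1]] <- data.frame(
        record = k, f_hz = r$drive_frequency, fs_hz = r$sampling_rate,
        pos_m = NA_real_, t_s = t, displacement_m = r$reference)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read vibrography records from the flat CSV container
#'
#' @param path CSV path as written by [write_records_csv()].
#' @return list of [vibration_record()]s.
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$record), function(dr) {
    ref_rows <- is.na(dr$pos_m)
    body <- dr[!ref_rows, ]
    pos <- sort(unique(body$pos_m))
    tt <- sort(unique(body$t_s))
    tr <- matrix(0, length(pos), length(tt))
    for (i in seq_along(pos)) {
      bi <- body[body$pos_m == pos[i], ]
      tr[i, ] <- bi$displacement_m[order(bi$t_s)]
    }
    ref <- NULL
    if (any(ref_rows)) {
      br <- dr[ref_rows, ]
      ref <- br$displacement_m[order(br$t_s)]
    }
    vibration_record(drive_frequency = dr$f_hz[1], sampling_rate = dr$fs_hz[1],
                     trace = tr, positions = pos, reference = ref)
  })
}
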