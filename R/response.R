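#' Frequency response function container
#'
#' Apex oscillation amplitude (and phase) versus imposed frequency, the
#' object produced both by the simulation sweep and by processing measured
#' vibrography records.
#'
#' @param frequencies strictly increasing frequency grid (Hz); successive
#'   spacings must lie in the tested 1-50 Hz range.
#' @param amplitude non-negative oscillation amplitudes (m).
#' @param phase phases (rad); defaults to zeros.
#' @param probe probe location identifier (default `"apex"`).
#' @return an object of class `frequency_response`.
#' @export
frequency_response <- function(frequencies, amplitude, phase = NULL,
                               probe = "apex") {
  if (length(frequencies) != length(amplitude))
    stop("frequency_response: frequency and amplitude lengths differ")
  if (any(diff(frequencies) <= 0))
    stop("frequency_response: frequencies must be strictly increasing")
  if (length(frequencies) > 1) {
    st <- diff(frequencies)
    if (any(st < 1 - 1e-9) || any(st > 50 + 1e-9))
      stop("frequency_response: grid step must lie within [1, 50] Hz")
  }
  if (any(amplitude < 0)) stop("frequency_response: amplitudes must be >= 0")
  if (is.null(phase)) phase <- numeric(length(frequencies))
  structure(list(frequencies = as.numeric(frequencies),
                 amplitude = as.numeric(amplitude),
                 phase = as.numeric(phase), probe = probe),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("frequency_response: %d points, %g-%g Hz, max amplitude %.3g m\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              max(x$amplitude)))
  invisible(x)
}

#' @export
plot.frequency_response <- function(x, ..., log = "y") {
  graphics::plot(x$frequencies, x$amplitude, type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "apex amplitude (m)", ...)
  invisible(x)
}

#' @export
as.data.frame.frequency_response <- function(x, ...) {
  data.frame(f_hz = x$frequencies, amplitude_m = x$amplitude,
             phase_rad = x$phase)
}

#' Sweep the imposed frequency and record the apex response
#'
#' Performs one harmonic solve per grid point and records the vertical apex
#' oscillation amplitude `|u_z|` and phase at the probe node. Optionally the
#' grid is refined locally around detected peaks (down to `refine_step`),
#' emulating the finer sampling used to pin down resonance positions
#' without paying for a fine grid everywhere.
#'
#' @param model an `ocuvib_model`.
#' @param f_min,f_max sweep range (Hz).
#' @param step grid step (Hz), within [1, 50].
#' @param load_scale scale factor applied to the unit excitation.
#' @param refine_peaks if `TRUE`, re-solve on a `refine_step` grid within
#'   `refine_halfwidth` of each detected peak and merge the points.
#' @param refine_step,refine_halfwidth local refinement parameters (Hz).
#' @return a [frequency_response()].
#' @export
frf_sweep <- function(model, f_min = 50, f_max = 750, step = 5,
                      load_scale = 1, refine_peaks = FALSE, refine_step = 1,
                      refine_halfwidth = NULL) {
  stopifnot(inherits(model, "ocuvib_model"))
  if (!(f_min < f_max)) stop("frf_sweep: need f_min < f_max")
  if (step < 1 || step > 50) stop("frf_sweep: step must lie within [1, 50] Hz")
  freqs <- seq(f_min, f_max, by = step)
  amp_phase <- function(fs) {
    out <- matrix(0, length(fs), 2)
    for (k in seq_along(fs)) {
      sol <- tryCatch(solve_harmonic(model$system, fs[k], load_scale),
                      error = function(e)
                        stop(sprintf("frf_sweep failed at f = %g Hz: %s",
                                     fs[k], conditionMessage(e))))
      uz <- sol$u[model$probe_dof]
      out[k, ] <- c(Mod(uz), Arg(uz))
    }
    out
  }
  ap <- amp_phase(freqs)
  if (refine_peaks) {
    if (is.null(refine_halfwidth)) refine_halfwidth <- 2 * step
    base <- frequency_response(freqs, ap[, 1], ap[, 2], probe = "apex")
    pk <- find_peaks(base)
    extra <- unique(unlist(lapply(pk$frequency, function(f0) {
      ## snap the refinement window to the f_min + k*refine_step lattice so
      ## the merged grid never contains sub-refine_step spacings
      k0 <- ceiling((max(f_min, f0 - refine_halfwidth) - f_min) / refine_step)
      k1 <- floor((min(f_max, f0 + refine_halfwidth) - f_min) / refine_step)
      if (k1 < k0) numeric() else f_min + (k0:k1) * refine_step
    })))
    extra <- setdiff(round(extra, 9), round(freqs, 9))
    keep <- vapply(extra, function(x) min(abs(x - freqs)) >= refine_step * 0.999,
                   TRUE)
    extra <- extra[keep]
    if (length(extra)) {
      ap2 <- amp_phase(extra)
      ord <- order(c(freqs, extra))
      freqs <- c(freqs, extra)[ord]
      ap <- rbind(ap, ap2)[ord, , drop = FALSE]
    }
  }
  frequency_response(freqs, ap[, 1], ap[, 2], probe = "apex")
}

#' Detect resonance peaks in a frequency response function
#'
#' Local maxima whose topographic prominence exceeds a configurable
#' fraction of the global maximum; each peak frequency is refined by
#' three-point quadratic interpolation and the width is the half-prominence
#' width. A monotone FRF yields an empty peak list.
#'
#' @param frf a [frequency_response()].
#' @param prominence fraction of the global maximum (default 0.05).
#' @return a data frame of class `resonance_peaks` with columns `mode`,
#'   `frequency`, `amplitude`, `width` (Hz).
#' @export
find_peaks <- function(frf, prominence = 0.05) {
  stopifnot(inherits(frf, "frequency_response"))
  f <- frf$frequencies; a <- frf$amplitude
  n <- length(a)
  if (n < 5) stop("find_peaks: need at least 5 grid points")
  thr <- prominence * max(a)
  out <- list()
  for (i in 2:(n - 1)) {
    if (!(a[i] > a[i - 1] && a[i] >= a[i + 1])) next
    ## prominence: walk out to the first higher point on each side
    lmin <- a[i]; j <- i - 1
    while (j >= 1 && a[j] < a[i]) { lmin <- min(lmin, a[j]); j <- j - 1 }
    if (j < 1) lmin <- min(a[1:i])
    rmin <- a[i]; j <- i + 1
    while (j <= n && a[j] < a[i]) { rmin <- min(rmin, a[j]); j <- j + 1 }
    if (j > n) rmin <- min(a[i:n])
    prom <- a[i] - max(lmin, rmin)
    if (prom < thr) next
    ## quadratic refinement on the three-point neighbourhood
    y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
    h1 <- f[i] - f[i - 1]; h2 <- f[i + 1] - f[i]
    h <- (h1 + h2) / 2
    fpk <- f[i] + delta * h
    apk <- y2 - 0.25 * (y1 - y3) * delta
    ## half-prominence width by linear interpolation
    half <- a[i] - prom / 2
    fl <- f[i]; j <- i
    while (j > 1 && a[j - 1] < a[j]) {
      j <- j - 1
      if (a[j] <= half) {
        fl <- f[j] + (half - a[j]) / (a[j + 1] - a[j]) * (f[j + 1] - f[j])
        break
      }
      fl <- f[j]
    }
    fr <- f[i]; j <- i
    while (j < n && a[j + 1] < a[j]) {
      j <- j + 1
      if (a[j] <= half) {
        fr <- f[j - 1] + (a[j - 1] - half) / (a[j - 1] - a[j]) * (f[j] - f[j - 1])
        break
      }
      fr <- f[j]
    }
    out[[length(out) + 1]] <- data.frame(frequency = fpk, amplitude = apk,
                                         width = max(fr - fl, .Machine$double.eps))
  }
  if (length(out) == 0) {
    res <- data.frame(mode = integer(), frequency = numeric(),
                      amplitude = numeric(), width = numeric())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$frequency), , drop = FALSE]
    res <- cbind(mode = seq_len(nrow(res)), res)
    rownames(res) <- NULL
  }
  class(res) <- c("resonance_peaks", "data.frame")
  res
}

#' Classify the mode shape at a resonance peak
#'
#' Solves at the refined peak frequency, counts the zero crossings of the
#' (phase-aligned) real part of the vertical displacement along the
#' anterior corneal arc (the nodal-circle count of the axisymmetric mode),
#' and computes the scleral participation ratio as the scleral share of the
#' mass-weighted deformation energy. Flap models have no sclera and report
#' zero participation.
#'
#' @param model the `ocuvib_model` the peak was detected on.
#' @param peak one row of a `resonance_peaks` frame (or a list with a
#'   `frequency` field).
#' @param participation_threshold scleral participation below which a globe
#'   mode is flagged `cornea_dominated`.
#' @return an object of class `mode_shape`: fields `frequency`,
#'   `nodal_circles`, `scleral_participation`, `cornea_dominated`, `u`, `p`.
#' @export
classify_mode <- function(model, peak, participation_threshold = 0.2) {
  f0 <- if (is.data.frame(peak)) peak$frequency[1] else peak$frequency
  sol <- solve_harmonic(model$system, f0)
  uz <- sol$u[model$dofs$sdof[model$arc_nodes, 2]]
  ord <- order(model$arc_coord)
  uz <- uz[ord]
  ## align the dominant response with the real axis before sign counting
  ph <- Arg(uz[which.max(Mod(uz))])
  w <- Re(uz * exp(-1i * ph))
  wmax <- max(abs(w))
  mask <- abs(w) > 1e-3 * wmax
  s <- sign(w[mask])
  crossings <- sum(diff(s) != 0 & s[-length(s)] != 0)
  part <- 0
  if (!is.null(model$M_region$sclera)) {
    quad <- function(M, v)
      sum(Re(v) * as.vector(M %*% Re(v))) + sum(Im(v) * as.vector(M %*% Im(v)))
    part <- quad(model$M_region$sclera, sol$u) / quad(model$solid$M, sol$u)
  }
  structure(list(frequency = f0, nodal_circles = as.integer(crossings),
                 scleral_participation = part,
                 cornea_dominated = part < participation_threshold,
                 u = sol$u, p = sol$p),
            class = "mode_shape")
}

#' @export
print.mode_shape <- function(x, ...) {
  cat(sprintf("mode_shape at %.1f Hz: %d nodal circle(s), scleral participation %.3f%s\n",
              x$frequency, x$nodal_circles, x$scleral_participation,
              if (x$cornea_dominated) " (cornea-dominated)" else ""))
  invisible(x)
}

#' Detect peaks and classify their mode shapes in one pass
#'
#' @param model an `ocuvib_model`.
#' @param frf a [frequency_response()] computed on this model.
#' @param prominence passed to [find_peaks()].
#' @return a `resonance_peaks` frame with additional columns
#'   `nodal_circles` and `scleral_participation`.
#' @export
peaks_with_modes <- function(model, frf, prominence = 0.05) {
  pk <- find_peaks(frf, prominence)
  if (nrow(pk) == 0) {
    pk$nodal_circles <- integer()
    pk$scleral_participation <- numeric()
    return(pk)
  }
  ms <- lapply(seq_len(nrow(pk)), function(i) classify_mode(model, pk[i, ]))
  pk$nodal_circles <- vapply(ms, `[[`, 0L, "nodal_circles")
  pk$scleral_participation <- vapply(ms, `[[`, 0, "scleral_participation")
  pk
}
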