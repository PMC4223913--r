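#' One-at-a-time parameter sweep specification
#'
#' @param parameter parameter name: for flaps `"E"`, `"density"`,
#'   `"thickness"`, `"diameter"`/`"radius"`; for globes additionally
#'   `"curvature"`, `"IOP"`, `"sclera_E"`, `"sclera_diameter"`,
#'   `"cornea_diameter"`.
#' @param nominal nominal value in the configuration unit (kPa, um, mm,
#'   kg m^-3); `NULL` to take it from the model configuration.
#' @param rel_range relative half-range of the sweep (default 0.2, i.e.
#'   +/-20 percent).
#' @param levels number of levels (>= 3).
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, nominal = NULL, rel_range = 0.2, levels = 5) {
  if (rel_range <= 0) stop("sweep_spec: rel_range must be > 0")
  if (levels < 3) stop("sweep_spec: need at least 3 levels")
  structure(list(parameter = parameter, nominal = nominal,
                 rel_range = rel_range, levels = as.integer(levels)),
            class = "sweep_spec")
}

#' Run a one-at-a-time parameter sensitivity sweep
#'
#' Rebuilds and sweeps the model at each parameter level; resonance peaks
#' are matched across levels by mode shape (nodal-circle count), not by raw
#' peak index. Levels at which a mode is not detected are recorded as
#' missing, never silently re-indexed.
#'
#' @param cfg a `flap_config` or `globe_config` (the nominal model).
#' @param spec a [sweep_spec()].
#' @param f_min,f_max,step frequency sweep settings (Hz).
#' @param refine_peaks,refine_step local peak refinement (see [frf_sweep()]);
#'   defaults to 1 Hz refinement so slopes are resolved below the grid step.
#' @param prominence peak-detection threshold.
#' @return an object of class `sensitivity_sweep`: a data frame with columns
#'   `value` (parameter level, config units), `mode` (key), `frequency`,
#'   plus attributes `parameter`, `unit`, `nominal`.
#' @export
sensitivity_sweep <- function(cfg, spec, f_min = 50, f_max = NULL, step = 5,
                              refine_peaks = TRUE, refine_step = 1,
                              prominence = 0.05) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (is.null(f_max)) f_max <- if (inherits(cfg, "flap_config")) 750 else 510
  nominal <- spec$nominal %||% get_config_param(cfg, spec$parameter)
  values <- nominal * seq(1 - spec$rel_range, 1 + spec$rel_range,
                          length.out = spec$levels)
  unit <- set_config_param(cfg, spec$parameter, values[1])$unit
  peaks_by_level <- lapply(values, function(v) {
    s <- set_config_param(cfg, spec$parameter, v)
    model <- build_model(s$cfg)
    frf <- frf_sweep(model, f_min, f_max, step,
                     refine_peaks = refine_peaks, refine_step = refine_step)
    peaks_with_modes(model, frf, prominence = prominence)
  })
  ## mode identity: pair every level against the reference (middle) level,
  ## so a mode is tracked by shape-aware alignment, not by raw peak index
  ref_lv <- which.min(abs(values - nominal))
  ref <- peaks_by_level[[ref_lv]]
  rows <- list()
  if (nrow(ref)) {
    keys <- paste0("m", seq_len(nrow(ref)), ".nc", ref$nodal_circles)
    for (lv in seq_along(values)) {
      pm <- pair_modes(ref, peaks_by_level[[lv]])
      if (nrow(pm) == 0) next
      ridx <- match(pm$f_nominal, ref$frequency)
      rows[[length(rows) + 1]] <- data.frame(
        value = values[lv], mode = keys[ridx], frequency = pm$f_changed,
        nodal_circles = pm$nc_changed)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(), mode = character(), frequency = numeric(),
               nodal_circles = integer())
  attr(out, "parameter") <- spec$parameter
  attr(out, "unit") <- unit
  attr(out, "nominal") <- nominal
  class(out) <- c("sensitivity_sweep", "data.frame")
  out
}

#' Linear-regression sensitivity slope of one mode
#'
#' Ordinary least-squares slope of the tracked peak frequency versus the
#' parameter value, in Hz per configuration unit (e.g. Hz kPa^-1 for
#' elasticity, Hz um^-1 for thickness).
#'
#' @param sweep a [sensitivity_sweep()] result.
#' @param mode mode key (e.g. `"nc1.1"`) or integer index into the nominal
#'   mode ordering.
#' @return an object of class `sensitivity_slope`: list with `parameter`,
#'   `mode`, `slope`, `r_squared`, `unit`, `n_levels`.
#' @export
fit_slope <- function(sweep, mode) {
  stopifnot(inherits(sweep, "sensitivity_sweep"))
  if (is.numeric(mode)) {
    keys <- unique(sweep$mode[order(sweep$value, sweep$frequency)])
    ## order keys by their frequency at the lowest value present
    med <- vapply(keys, function(k) stats::median(sweep$frequency[sweep$mode == k]), 0)
    keys <- keys[order(med)]
    if (mode > length(keys)) stop("fit_slope: no such mode")
    mode <- keys[mode]
  }
  d <- sweep[sweep$mode == mode, , drop = FALSE]
  if (nrow(d) < 3)
    stop(sprintf("fit_slope: mode %s tracked at %d < 3 levels", mode, nrow(d)))
  fit <- stats::lm(frequency ~ value, data = d)
  res <- stats::residuals(fit)
  sst <- sum((d$frequency - mean(d$frequency))^2)
  r2 <- if (sst > 0) max(0, 1 - sum(res^2) / sst) else 1
  structure(list(parameter = attr(sweep, "parameter"), mode = mode,
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 unit = attr(sweep, "unit"), n_levels = nrow(d)),
            class = "sensitivity_slope")
}

#' @export
print.sensitivity_slope <- function(x, ...) {
  cat(sprintf("sensitivity of mode %s to %s: slope %.4g %s (R^2 = %.4f, %d levels)\n",
              x$mode, x$parameter, x$slope, x$unit, x$r_squared, x$n_levels))
  invisible(x)
}

#' Slope table across all tracked modes
#'
#' @param sweep a [sensitivity_sweep()] result.
#' @return data frame with one row per mode: `mode`, `slope`, `r_squared`,
#'   `unit`, `n_levels`, ordered by modal frequency.
#' @export
slope_table <- function(sweep) {
  keys <- unique(sweep$mode)
  med <- vapply(keys, function(k) stats::median(sweep$frequency[sweep$mode == k]), 0)
  keys <- keys[order(med)]
  rows <- lapply(keys, function(k) {
    s <- tryCatch(fit_slope(sweep, k), error = function(e) NULL)
    if (is.null(s)) return(NULL)
    data.frame(mode = k, slope = s$slope, r_squared = s$r_squared,
               unit = s$unit, n_levels = s$n_levels)
  })
  do.call(rbind, rows)
}

#' Compare a locally weakened globe against the nominal model
#'
#' Computes frequency-response functions of the nominal and the weakened
#' model on an identical grid and classifies each weakened-model peak as
#' `"shifted"` (a nominal counterpart lies within `match_tol`) or `"new"`.
#'
#' @param cfg a `globe_config` (nominal).
#' @param zone a [weak_zone()].
#' @param f_min,f_max,step sweep grid (Hz).
#' @param match_tol matching tolerance (Hz, default 15).
#' @param prominence peak-detection threshold.
#' @param refine_peaks,refine_step local refinement (see [frf_sweep()]).
#' @return list with `frf_nominal`, `frf_weak`, `peaks_nominal`,
#'   `peaks_weak`, and `report` (one row per weakened-model peak: frequency,
#'   status, matched nominal frequency and shift).
#' @export
compare_weakened <- function(cfg, zone, f_min = 50, f_max = 510, step = 5,
                             match_tol = 15, prominence = 0.05,
                             refine_peaks = TRUE, refine_step = 1) {
  m0 <- build_globe(cfg)
  m1 <- apply_weak_zone(cfg, zone)
  frf0 <- frf_sweep(m0, f_min, f_max, step, refine_peaks = refine_peaks,
                    refine_step = refine_step)
  frf1 <- frf_sweep(m1, f_min, f_max, step, refine_peaks = refine_peaks,
                    refine_step = refine_step)
  pk0 <- find_peaks(frf0, prominence)
  pk1 <- find_peaks(frf1, prominence)
  report <- NULL
  if (nrow(pk1)) {
    rows <- lapply(seq_len(nrow(pk1)), function(i) {
      f <- pk1$frequency[i]
      if (nrow(pk0)) {
        j <- which.min(abs(pk0$frequency - f))
        d <- f - pk0$frequency[j]
        if (abs(d) <= match_tol)
          return(data.frame(frequency = f, status = "shifted",
                            nominal_frequency = pk0$frequency[j], shift = d))
      }
      data.frame(frequency = f, status = "new",
                 nominal_frequency = NA_real_, shift = NA_real_)
    })
    report <- do.call(rbind, rows)
  } else {
    report <- data.frame(frequency = numeric(), status = character(),
                         nominal_frequency = numeric(), shift = numeric())
  }
  list(frf_nominal = frf0, frf_weak = frf1,
       peaks_nominal = pk0, peaks_weak = pk1, report = report)
}

#' Maximum per-mode frequency shift under a parameter change
#'
#' Rebuilds the model at a modified parameter value, pairs resonances by
#' mode shape and returns the largest per-mode natural-frequency shift.
#'
#' @param cfg a model configuration.
#' @param parameter parameter name (see [sweep_spec()]).
#' @param factor multiplicative change of the nominal value (e.g. 1.4).
#' @param f_min,f_max,step,refine_peaks,refine_step,prominence sweep options.
#' @return list with `shifts` (paired frequencies and shifts per mode key)
#'   and `max_shift` (Hz).
#' @export
mode_shift <- function(cfg, parameter, factor, f_min = 50, f_max = NULL,
                       step = 5, refine_peaks = TRUE, refine_step = 1,
                       prominence = 0.05) {
  if (is.null(f_max)) f_max <- if (inherits(cfg, "flap_config")) 750 else 510
  peaks_of <- function(cc) {
    m <- build_model(cc)
    frf <- frf_sweep(m, f_min, f_max, step, refine_peaks = refine_peaks,
                     refine_step = refine_step)
    peaks_with_modes(m, frf, prominence = prominence)
  }
  pk0 <- peaks_of(cfg)
  v0 <- get_config_param(cfg, parameter)
  pk1 <- peaks_of(set_config_param(cfg, parameter, v0 * factor)$cfg)
  shifts <- pair_modes(pk0, pk1)
  list(shifts = shifts,
       max_shift = if (nrow(shifts)) max(abs(shifts$shift)) else NA_real_)
}

#' Pair resonance peaks of two related models by mode
#'
#' Order-preserving alignment of two peak lists that minimises the summed
#' relative frequency distance plus a penalty for nodal-circle-count
#' mismatches; peaks without a plausible counterpart (relative shift beyond
#' `max_rel`) are left unmatched rather than force-paired. This is the
#' mode-shape-aware matching used when tracking natural frequencies across
#' parameter changes.
#'
#' @param pkA,pkB `resonance_peaks` frames with `nodal_circles` columns
#'   (see [peaks_with_modes()]).
#' @param max_rel largest admissible relative frequency shift for a pair.
#' @param nc_penalty alignment cost per nodal-circle-count difference,
#'   expressed in relative-frequency units.
#' @return data frame with one row per matched pair: `f_nominal`,
#'   `f_changed`, `shift`, `nc_nominal`, `nc_changed`.
#' @export
pair_modes <- function(pkA, pkB, max_rel = 0.35, nc_penalty = 0.12) {
  nA <- nrow(pkA); nB <- nrow(pkB)
  empty <- data.frame(f_nominal = numeric(), f_changed = numeric(),
                      shift = numeric(), nc_nominal = integer(),
                      nc_changed = integer())
  if (nA == 0 || nB == 0) return(empty)
  skip <- max_rel / 2
  cost <- function(i, j) {
    d <- abs(pkB$frequency[j] - pkA$frequency[i]) / pkA$frequency[i]
    if (d > max_rel) return(Inf)
    d + nc_penalty * min(abs(pkA$nodal_circles[i] - pkB$nodal_circles[j]), 3)
  }
  D <- matrix(Inf, nA + 1, nB + 1)
  D[1, ] <- (0:nB) * skip
  D[, 1] <- (0:nA) * skip
  choice <- matrix(0L, nA + 1, nB + 1)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    cand <- c(D[i, j] + cost(i, j), D[i, j + 1] + skip, D[i + 1, j] + skip)
    k <- which.min(cand)
    D[i + 1, j + 1] <- cand[k]
    choice[i + 1, j + 1] <- k
  }
  ## traceback
  i <- nA + 1; j <- nB + 1
  pairs <- list()
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 && choice[i, j] == 1L) {
      pairs[[length(pairs) + 1]] <- c(i - 1, j - 1)
      i <- i - 1; j <- j - 1
    } else if (i > 1 && (j == 1 || choice[i, j] == 2L)) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  if (length(pairs) == 0) return(empty)
  idx <- do.call(rbind, rev(pairs))
  data.frame(f_nominal = pkA$frequency[idx[, 1]],
             f_changed = pkB$frequency[idx[, 2]],
             shift = pkB$frequency[idx[, 2]] - pkA$frequency[idx[, 1]],
             nc_nominal = pkA$nodal_circles[idx[, 1]],
             nc_changed = pkB$nodal_circles[idx[, 2]])
}
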