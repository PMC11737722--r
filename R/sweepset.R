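#' Construct a set of repeated-stimulus voltage sweeps
#'
#' The unit of acquisition: `n_sweeps` equal-length voltage traces
#' recorded on a common time grid, time-locked to the flash at t = 0
#' (negative times are the pre-stimulus window used for baseline
#' estimation).
#'
#' @param data numeric matrix, samples in rows, sweeps in columns.
#' @param time numeric vector of sample times in ms since flash onset;
#'   strictly increasing, uniformly spaced, length `nrow(data)`.
#' @param sampling_rate sampling rate in Hz.
#' @param modality one of `"erg"`, `"fvep"`, `"flicker"`.
#' @param units voltage units label (`"uV"` for ERG, `"mV"` for fVEP).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(data, time, sampling_rate,
                      modality = c("erg", "fvep", "flicker"),
                      units = "uV") {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("sweep_set: 'data' must be numeric")
  if (length(time) != nrow(data))
    stop("sweep_set: 'time' length must equal the number of samples")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-8 * mean(dt))
    stop("sweep_set: 'time' must be strictly increasing and uniform")
  if (sampling_rate <= 0) stop("sweep_set: 'sampling_rate' must be > 0")
  structure(list(data = data, time = as.numeric(time),
                 sampling_rate = sampling_rate, modality = modality,
                 units = units),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples, %s, %.0f Hz, t = [%g, %g] ms\n",
              ncol(x$data), nrow(x$data), x$modality, x$sampling_rate,
              min(x$time), max(x$time)))
  invisible(x)
}

#' Average repeated sweeps into a single waveform
#'
#' Pointwise arithmetic mean across sweeps.  The baseline value is the
#' mean voltage over the pre-stimulus window (up to `baseline_ms` ms
#' before flash onset); the pre-stimulus standard deviation is kept so
#' that downstream peak detection can set its noise floor.
#'
#' @param s a [sweep_set()].
#' @param baseline_ms length of the pre-onset baseline window in ms.
#' @return An object of class `waveform`: fields `time`, `voltage`,
#'   `modality`, `units`, `baseline`, `baseline_sd`, `has_baseline`.
#' @export
average_sweeps <- function(s, baseline_ms = 20) {
  stopifnot(inherits(s, "sweep_set"))
  if (ncol(s$data) < 1L) stop("average_sweeps: no sweeps")
  v <- rowMeans(s$data)
  new_waveform(s$time, v, s$modality, s$units, baseline_ms)
}

new_waveform <- function(time, voltage, modality, units,
                         baseline_ms = 20) {
  pre <- time < 0 & time >= -baseline_ms
  if (any(pre)) {
    baseline <- mean(voltage[pre])
    baseline_sd <- stats::sd(voltage[pre])
    if (is.na(baseline_sd)) baseline_sd <- 0
    has_baseline <- TRUE
  } else {
    # no pre-stimulus samples (e.g. steady-state flicker): reference 0
    baseline <- 0
    baseline_sd <- 0
    has_baseline <- FALSE
  }
  structure(list(time = as.numeric(time), voltage = as.numeric(voltage),
                 modality = modality, units = units,
                 baseline = baseline, baseline_sd = baseline_sd,
                 has_baseline = has_baseline, baseline_ms = baseline_ms),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s, %d samples, t = [%g, %g] ms, baseline %.3g %s\n",
              x$modality, length(x$voltage), min(x$time), max(x$time),
              x$baseline, x$units))
  invisible(x)
}

#' Subtract an averaged no-flash control waveform from a signal
#'
#' Removes common-mode activity (amplifier drift, ambient pickup) by
#' pointwise subtraction of a control trace recorded identically but
#' without the flash.  The baseline is recomputed on the difference.
#'
#' @param signal,control [average_sweeps()] results on identical time
#'   grids, same modality.
#' @return A `waveform` with `voltage = signal - control`.
#' @export
subtract_control <- function(signal, control) {
  stopifnot(inherits(signal, "waveform"), inherits(control, "waveform"))
  if (length(signal$voltage) != length(control$voltage) ||
      max(abs(signal$time - control$time)) > 1e-9)
    stop("subtract_control: signal and control grids do not match")
  if (signal$modality != control$modality)
    stop("subtract_control: modality mismatch")
  new_waveform(signal$time, signal$voltage - control$voltage,
               signal$modality, signal$units, signal$baseline_ms)
}
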