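# Waveform scoring: the clinical measurement conventions.
#
# All amplitudes are reported as non-negative magnitudes referenced to
# the pre-stimulus baseline (or to another component where the
# convention says so); peak times are ms from flash onset.  A feature
# that cannot be located is reported "absent" with a reason, never as a
# silent zero.

feature_absent <- function(reason) {
  list(absent = TRUE, reason = reason)
}

#' Test whether a measured feature is absent
#' @param x a feature result from one of the `measure_*` functions.
#' @return `TRUE` if the feature could not be located.
#' @export
is_absent <- function(x) isTRUE(x$absent)

# indices of strict local minima / maxima (interior samples only)
local_minima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] < v[i - 1L] & v[i] <= v[i + 1L]]
}
local_maxima <- function(v) local_minima(-v)

# parabolic (3-point) refinement of an extremum's time
refine_time <- function(time, v, i) {
  if (i <= 1L || i >= length(v)) return(time[i])
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(time[i])
  delta <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  time[i] + delta * (time[2] - time[1])
}

# detection floor: peaks must clear k x the pre-stimulus residual SD
detection_floor <- function(w, floor_k) floor_k * w$baseline_sd

# keep only extremum candidates that dominate their +/- window_ms
# neighbourhood (noise wiggles on a steep limb are local minima but
# not neighbourhood minima, so they are rejected)
dominant <- function(idx, v, time, window_ms, minima = TRUE) {
  if (window_ms <= 0 || length(idx) == 0L) return(idx)
  ok <- vapply(idx, function(i) {
    win <- abs(time - time[i]) <= window_ms
    if (minima) v[i] <= min(v[win]) else v[i] >= max(v[win])
  }, logical(1))
  idx[ok]
}

#' Measure the a-wave: baseline to the first negative trough
#'
#' The a-wave is the first local minimum after flash onset that falls
#' below baseline by more than the detection floor; its amplitude is
#' the drop from baseline to the trough.
#'
#' @param w an ERG [average_sweeps()] waveform.
#' @param floor_k detection floor in multiples of the pre-stimulus
#'   residual SD.
#' @param refine parabolic 3-point refinement of the reported time.
#' @param prominence_ms a qualifying trough must also be the minimum of
#'   its `+/- prominence_ms` neighbourhood, so noise dips on a steep
#'   limb do not register as the "first" trough.
#' @return List with `amp` (>= 0), `time`, `index`; or an absent
#'   feature (see [is_absent()]).
#' @export
measure_a_wave <- function(w, floor_k = 3, refine = TRUE,
                           prominence_ms = 5) {
  stopifnot(inherits(w, "waveform"))
  if (w$modality != "erg") stop("measure_a_wave: ERG modality required")
  floor <- detection_floor(w, floor_k)
  cand <- local_minima(w$voltage)
  cand <- cand[w$time[cand] > 0]
  cand <- cand[w$baseline - w$voltage[cand] > floor]
  cand <- dominant(cand, w$voltage, w$time, prominence_ms, minima = TRUE)
  if (length(cand) == 0L)
    return(feature_absent("no trough below baseline clears the detection floor"))
  i <- cand[1L]  # earliest qualifying trough
  list(absent = FALSE,
       amp = w$baseline - w$voltage[i],
       time = if (refine) refine_time(w$time, w$voltage, i) else w$time[i],
       index = i)
}

#' Measure the b-wave: a-wave trough to the highest peak
#'
#' The b-wave peak is the global maximum after the a-wave trough; its
#' amplitude is measured from the a-wave trough voltage (or from
#' baseline, flagged, when no a-wave was found).
#'
#' @param w an ERG waveform.
#' @param a the [measure_a_wave()] result (may be absent).
#' @inheritParams measure_a_wave
#' @return List with `amp`, `time`, `index`, `reference` (`"a-wave"` or
#'   `"baseline"`), `boundary` (`TRUE` when the maximum sits at the end
#'   of the trace); or an absent feature.
#' @export
measure_b_wave <- function(w, a, floor_k = 3, refine = TRUE) {
  stopifnot(inherits(w, "waveform"))
  if (w$modality != "erg") stop("measure_b_wave: ERG modality required")
  if (is_absent(a)) {
    win <- which(w$time > 0)
    ref_v <- w$baseline
    reference <- "baseline"
  } else {
    win <- which(w$time > w$time[a$index])
    ref_v <- w$voltage[a$index]
    reference <- "a-wave"
  }
  if (length(win) == 0L) return(feature_absent("empty search window"))
  i <- win[which.max(w$voltage[win])]
  list(absent = FALSE,
       amp = w$voltage[i] - ref_v,
       time = if (refine) refine_time(w$time, w$voltage, i) else w$time[i],
       index = i, reference = reference,
       boundary = i == length(w$voltage))
}

# Zero-phase band-pass via FFT with raised-cosine transition bands.
# H(f) is real and symmetric, so no phase distortion; transitions of
# width `transition` Hz are centred on the band edges.
bandpass <- function(v, sampling_rate, lo = 75, hi = 300,
                     transition = 15) {
  n <- length(v)
  f <- seq(0, n - 1) / n * sampling_rate
  f <- pmin(f, sampling_rate - f)       # two-sided frequency axis
  ramp <- function(x) ifelse(x <= -1, 0, ifelse(x >= 1, 1,
                                                (1 + sin(pi * x / 2)) / 2))
  H <- ramp((f - lo) / (transition / 2)) * ramp((hi - f) / (transition / 2))
  Re(stats::fft(stats::fft(v) * H, inverse = TRUE)) / n
}

#' Extract oscillatory potentials from the b-wave's ascending limb
#'
#' The trace is band-pass filtered (zero-phase, default 75-300 Hz) to
#' remove the slow a/b lobes, then peak-picked: each OP amplitude is a
#' filtered-trace peak minus its immediately preceding trough.  Peaks
#' at or after the b-wave peak time are discarded, and at most four
#' wavelets are labelled OP1-2, OP3, OP4, OP5 in temporal order.
#'
#' @param w an ERG waveform.
#' @param b_time b-wave peak time in ms; OPs at or after it are
#'   excluded.
#' @param band two-element numeric, the OP isolation pass-band in Hz.
#' @param min_time earliest admissible OP peak time (ms); defaults to
#'   just after flash onset.
#' @param rel_floor wavelets smaller than this fraction of the largest
#'   qualifying wavelet are treated as residual filter ripple and
#'   dropped.
#' @inheritParams measure_a_wave
#' @return List with `amps` (named numeric, temporal order), `times`,
#'   and `low_confidence` (`TRUE` when no wavelet qualified).
#' @export
extract_ops <- function(w, b_time, band = c(75, 300), floor_k = 3,
                        min_time = 0, rel_floor = 0.05) {
  stopifnot(inherits(w, "waveform"))
  if (w$modality != "erg") stop("extract_ops: ERG modality required")
  filt <- bandpass(w$voltage, w$sampling_rate %||% infer_rate(w),
                   band[1], band[2])
  pre <- w$time < 0 & w$time >= -w$baseline_ms
  floor <- if (any(pre)) floor_k * stats::sd(filt[pre]) else 0
  if (is.na(floor)) floor <- 0
  peaks <- local_maxima(filt)
  peaks <- peaks[w$time[peaks] > min_time & w$time[peaks] < b_time]
  start <- max(which(w$time <= min_time), 1L)
  # pair each peak with the deepest trough since the previous retained
  # peak, then drop sub-threshold wavelets and re-pair; iterating makes
  # the pairing robust to residual filter ripple between wavelets
  measure_train <- function(pk) {
    amp <- numeric(length(pk))
    prev <- start
    for (k in seq_along(pk)) {
      seg <- seq(prev, pk[k])
      amp[k] <- filt[pk[k]] - min(filt[seg])
      prev <- pk[k]
    }
    amp
  }
  for (pass in 1:6) {
    if (length(peaks) == 0L) break
    amps <- measure_train(peaks)
    keep <- amps > max(floor, 0) & amps > rel_floor * max(amps)
    if (all(keep)) break
    peaks <- peaks[keep]
  }
  amps <- if (length(peaks)) measure_train(peaks) else numeric(0)
  times <- w$time[peaks]
  if (length(amps) > 4L) {
    # keep the four largest wavelets (residual filter ripple is always
    # smaller than a genuine OP), then restore temporal order
    keep <- sort(order(amps, decreasing = TRUE)[1:4])
    peaks <- peaks[keep]
    amps <- measure_train(peaks)
    times <- w$time[peaks]
  }
  labels <- c("OP1-2", "OP3", "OP4", "OP5")[seq_along(amps)]
  names(amps) <- labels
  list(amps = amps, times = times,
       low_confidence = length(amps) == 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_rate <- function(w) 1000 / (w$time[2] - w$time[1])

#' Sum of oscillatory potentials (SOP = OP1-2 + OP3 + OP4 + OP5)
#'
#' @param op_amps numeric vector of OP amplitudes as returned in
#'   `extract_ops()$amps` (possibly fewer than four).
#' @return The arithmetic sum, with attribute `missing_labels` naming
#'   any of the four canonical wavelets that were not measured.
#' @export
compute_sop <- function(op_amps) {
  all_labels <- c("OP1-2", "OP3", "OP4", "OP5")
  present <- if (is.null(names(op_amps)) || all(names(op_amps) == "")) {
    all_labels[seq_along(op_amps)]
  } else names(op_amps)
  sop <- sum(op_amps)
  attr(sop, "missing_labels") <- setdiff(all_labels, present)
  sop
}

#' Measure the photopic negative response (PhNR)
#'
#' The PhNR trough is the minimum after the b-wave peak; its amplitude
#' is the drop from baseline to the trough.  When the trough stays
#' above baseline the magnitude is still reported (>= 0) with
#' `above_baseline = TRUE`.
#'
#' @param w an ERG waveform.
#' @param b_time b-wave peak time (ms).
#' @inheritParams measure_a_wave
#' @return List with `amp` (>= 0), `time`, `index`, `above_baseline`;
#'   or an absent feature when no samples follow `b_time`.
#' @export
measure_phnr <- function(w, b_time, refine = TRUE) {
  stopifnot(inherits(w, "waveform"))
  if (w$modality != "erg") stop("measure_phnr: ERG modality required")
  win <- which(w$time > b_time)
  if (length(win) == 0L) return(feature_absent("no samples after b-wave"))
  i <- win[which.min(w$voltage[win])]
  drop <- w$baseline - w$voltage[i]
  list(absent = FALSE,
       amp = abs(drop),
       time = if (refine) refine_time(w$time, w$voltage, i) else w$time[i],
       index = i,
       above_baseline = drop < 0)
}

#' Measure the steady-state flicker amplitude
#'
#' Mean trough-to-following-peak excursion across complete cycles of
#' the 20 Hz steady-state response.
#'
#' @param w a flicker waveform spanning at least one full 20 Hz cycle
#'   after onset.
#' @param stim_freq stimulation frequency in Hz.
#' @inheritParams measure_a_wave
#' @return Single non-negative amplitude (same units as the trace);
#'   0 for a flat trace.
#' @export
measure_flicker <- function(w, stim_freq = 20, floor_k = 3) {
  stopifnot(inherits(w, "waveform"))
  if (w$modality != "flicker")
    stop("measure_flicker: flicker modality required")
  if (max(w$time) < 1000 / stim_freq)
    stop("measure_flicker: trace shorter than one stimulus cycle")
  floor <- detection_floor(w, floor_k)
  post <- w$time >= 0
  v <- w$voltage
  # one dominant extremum per half-cycle: noise ripple within a
  # quarter-cycle of a larger extremum is not a cycle boundary
  qc <- 1000 / stim_freq / 4
  peaks <- local_maxima(v); peaks <- peaks[post[peaks]]
  peaks <- dominant(peaks, v, w$time, qc, minima = FALSE)
  troughs <- local_minima(v); troughs <- troughs[post[troughs]]
  troughs <- dominant(troughs, v, w$time, qc, minima = TRUE)
  exc <- numeric(0)
  for (tr in troughs) {
    nxt <- peaks[peaks > tr]
    if (length(nxt) == 0L) next
    e <- v[nxt[1L]] - v[tr]
    if (e > max(floor, 0)) exc <- c(exc, e)
  }
  if (length(exc) == 0L) return(0)
  mean(exc)
}

#' Measure fVEP N1-P1 amplitude and latency
#'
#' N1 is the first prominent post-onset negative trough, P1 the first
#' prominent positive peak after N1.  The endpoint metrics are the
#' voltage difference and the time difference from N1 to P1; component
#' times are referenced to flash onset.
#'
#' @param w a control-subtracted fVEP waveform.
#' @inheritParams measure_a_wave
#' @return List with `n1_time`, `p1_time`, `amplitude_n1p1` (>= 0),
#'   `latency_n1p1`; or an absent feature naming the missing component.
#' @export
measure_fvep <- function(w, floor_k = 3, refine = TRUE,
                         prominence_ms = 10) {
  stopifnot(inherits(w, "waveform"))
  if (w$modality != "fvep") stop("measure_fvep: fVEP modality required")
  floor <- detection_floor(w, floor_k)
  v <- w$voltage
  n1_cand <- local_minima(v)
  n1_cand <- n1_cand[w$time[n1_cand] > 0 &
                       w$baseline - v[n1_cand] > floor]
  n1_cand <- dominant(n1_cand, v, w$time, prominence_ms, minima = TRUE)
  if (length(n1_cand) == 0L)
    return(feature_absent("no N1 trough clears the detection floor"))
  n1 <- n1_cand[1L]
  p1_cand <- local_maxima(v)
  p1_cand <- p1_cand[p1_cand > n1 & v[p1_cand] - w$baseline > floor]
  p1_cand <- dominant(p1_cand, v, w$time, prominence_ms, minima = FALSE)
  if (length(p1_cand) == 0L)
    return(feature_absent("no P1 peak after N1 clears the detection floor"))
  p1 <- p1_cand[1L]
  n1_t <- if (refine) refine_time(w$time, v, n1) else w$time[n1]
  p1_t <- if (refine) refine_time(w$time, v, p1) else w$time[p1]
  list(absent = FALSE,
       n1_time = n1_t, p1_time = p1_t,
       n1_index = n1, p1_index = p1,
       amplitude_n1p1 = v[p1] - v[n1],
       latency_n1p1 = p1_t - n1_t)
}

#' Baseline-normalised change in an endpoint
#'
#' `difference` mode reports the raw change `post - pre` in native
#' units (the default; slopes per degree then keep voltage units);
#' `relative` mode reports `(post - pre)/|pre|`, dimensionless.
#'
#' @param pre_value,post_value endpoint values before / after injury.
#' @param mode `"difference"` or `"relative"`.
#' @return The change `dy`.
#' @export
normalize_change <- function(pre_value, post_value,
                             mode = c("difference", "relative")) {
  mode <- match.arg(mode)
  if (!all(is.finite(pre_value)))
    stop("normalize_change: 'pre_value' must be finite")
  if (mode == "difference") return(post_value - pre_value)
  if (any(pre_value == 0))
    stop("normalize_change: relative mode requires a non-zero baseline")
  (post_value - pre_value) / abs(pre_value)
}

#' Score a full ERG waveform into its endpoint features
#'
#' Convenience wrapper running the a-wave, b-wave, OP, SOP and PhNR
#' measurements in sequence with shared settings.
#'
#' @param w an ERG waveform.
#' @inheritParams measure_a_wave
#' @param band OP isolation band (Hz), see [extract_ops()].
#' @return An `erg_features` list: `a`, `b`, `ops`, `sop`, `phnr`.
#' @export
score_erg <- function(w, floor_k = 3, band = c(75, 300), refine = TRUE) {
  a <- measure_a_wave(w, floor_k, refine)
  b <- measure_b_wave(w, a, floor_k, refine)
  if (is_absent(b)) {
    ops <- list(amps = numeric(0), times = numeric(0),
                low_confidence = TRUE)
    phnr <- feature_absent("no b-wave")
  } else {
    min_t <- if (is_absent(a)) 0 else w$time[a$index]
    ops <- extract_ops(w, b_time = w$time[b$index], band = band,
                       floor_k = floor_k, min_time = min_t)
    phnr <- measure_phnr(w, b_time = w$time[b$index], refine = refine)
  }
  structure(list(a = a, b = b, ops = ops, sop = compute_sop(ops$amps),
                 phnr = phnr),
            class = "erg_features")
}

#' Flatten scored features into the tidy output contract
#'
#' @param feats an `erg_features` (from [score_erg()]) or the
#'   [measure_fvep()] result.
#' @param subject_id,eye,timepoint identifying metadata.
#' @param units voltage units of the source trace.
#' @return Data frame with columns `subject_id`, `eye`, `timepoint`,
#'   `feature`, `value`, `units`, `quality_flag`.
#' @export
features_to_rows <- function(feats, subject_id, eye = "OS",
                             timepoint = "D0", units = "uV") {
  row <- function(feature, value, unit = units, flag = "ok") {
    data.frame(subject_id = subject_id, eye = eye, timepoint = timepoint,
               feature = feature, value = value, units = unit,
               quality_flag = flag, stringsAsFactors = FALSE)
  }
  out <- list()
  if (inherits(feats, "erg_features")) {
    out <- c(out, list(
      if (is_absent(feats$a)) row("a_amp", NA_real_, flag = "absent")
      else rbind(row("a_amp", feats$a$amp), row("a_time", feats$a$time, "ms")),
      if (is_absent(feats$b)) row("b_amp", NA_real_, flag = "absent")
      else rbind(row("b_amp", feats$b$amp,
                     flag = if (isTRUE(feats$b$boundary)) "boundary" else "ok"),
                 row("b_time", feats$b$time, "ms")),
      row("sop", as.numeric(feats$sop),
          flag = if (isTRUE(feats$ops$low_confidence)) "low_confidence" else "ok"),
      if (is_absent(feats$phnr)) row("phnr_amp", NA_real_, flag = "absent")
      else rbind(row("phnr_amp", feats$phnr$amp,
                     flag = if (isTRUE(feats$phnr$above_baseline))
                       "above_baseline" else "ok"),
                 row("phnr_time", feats$phnr$time, "ms"))))
  } else if (!is.null(feats$amplitude_n1p1) || is_absent(feats)) {
    if (is_absent(feats)) {
      out <- list(row("amplitude_n1p1", NA_real_, flag = "absent"))
    } else {
      out <- list(row("amplitude_n1p1", feats$amplitude_n1p1),
                  row("latency_n1p1", feats$latency_n1p1, "ms"),
                  row("n1_time", feats$n1_time, "ms"),
                  row("p1_time", feats$p1_time, "ms"))
    }
  } else stop("features_to_rows: unrecognised feature object")
  do.call(rbind, out)
}
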