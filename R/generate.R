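# Synthetic waveform generation: smooth phenomenological templates with
# known component amplitudes/times, so that the scoring conventions in
# features.R have planted answers.

# Smooth cosine-bell lobe: compact support [center - hw, center + hw],
# unimodal, exactly `amp` at `center`, identically zero outside.  The
# 4th power makes the lobe C^3 at its edges, so its spectrum decays
# fast enough (~f^-5) that slow lobes leak negligibly into the
# oscillatory-potential isolation band.
cos_lobe <- function(t, center, hw, amp) {
  u <- (t - center) / hw
  v <- numeric(length(t))
  inside <- abs(u) < 1
  v[inside] <- amp * cos(pi * u[inside] / 2)^4
  v
}

# Piecewise half-cosine interpolation through control points: smooth,
# monotone between points, zero slope at each point.
interp_controls <- function(t, pts_t, pts_v) {
  v <- numeric(length(t))
  for (k in seq_len(length(pts_t) - 1L)) {
    seg <- t >= pts_t[k] & t <= pts_t[k + 1L]
    if (!any(seg)) next
    frac <- (t[seg] - pts_t[k]) / (pts_t[k + 1L] - pts_t[k])
    v[seg] <- pts_v[k] + (pts_v[k + 1L] - pts_v[k]) * (1 - cos(pi * frac)) / 2
  }
  v
}

# Oscillatory-potential train: alternating trough/peak control points
# spaced 1/(2 f), interpolated with half-cosine segments.  The control
# extrema are calibrated (deterministic fixed point) so that on the
# band-pass filtered composite trace -- the trace the OP scoring
# convention actually measures -- wavelet i's trough-to-peak excursion
# equals the planted amplitude A_i exactly.  Without calibration the
# filter's removal of the train's low-frequency edge content would
# bias the first wavelet by ~10%.
op_train <- function(t, onset, freq, amps, slow = 0,
                     band = c(75, 300), calibrate = TRUE) {
  m <- length(amps)
  if (m == 0L || all(amps == 0)) return(numeric(length(t)))
  sp <- 1000 / (2 * freq)                       # extrema spacing, ms
  ex_t <- onset + sp * seq_len(2 * m)
  vals <- as.vector(rbind(-amps / 2, amps / 2)) # trough, peak, ...
  pts_t <- c(onset, ex_t, onset + sp * (2 * m + 1))
  build <- function(vals) interp_controls(t, pts_t, c(0, vals, 0))
  train <- build(vals)
  if (!calibrate) return(train)
  rate <- 1000 / (t[2] - t[1])
  for (iter in 1:40) {
    filt <- bandpass(slow + train, rate, band[1], band[2])
    err <- numeric(m)
    for (i in seq_len(m)) {
      if (amps[i] == 0) next
      wtr <- abs(t - ex_t[2 * i - 1L]) <= sp / 2
      wpk <- abs(t - ex_t[2 * i]) <= sp / 2
      err[i] <- (max(filt[wpk]) - min(filt[wtr])) - amps[i]
    }
    if (max(abs(err)) < 1e-9) break
    vals[2 * seq_len(m) - 1L] <- vals[2 * seq_len(m) - 1L] + err / 2
    vals[2 * seq_len(m)] <- vals[2 * seq_len(m)] - err / 2
    train <- build(vals)
  }
  train
}

# Geometry of the planted components for one truth/kind combination.
# Lobe half-widths are scaled off the inter-component gaps so that
# compact supports never collide and every planted amplitude/time is
# recovered exactly on the noise-free trace.
template_geometry <- function(truth, kind) {
  if (kind == "erg") {
    op_onset <- truth$a_time + 0.25 * (truth$b_time - truth$a_time)
    m <- length(truth$op_amps)
    sp <- 1000 / (2 * truth$op_freq)
    op_end <- op_onset + sp * (2 * m + 1)
    if (m > 0L && any(truth$op_amps > 0) && op_end > truth$b_time)
      stop("generate_waveform: OP train (ends ", round(op_end, 1),
           " ms) would extend past b_time; raise op_freq or b_time",
           call. = FALSE)
    # widths are as large as the component geometry allows (so lobes
    # stay slow and band-limited below the OP band) while keeping each
    # planted peak free of the other components' support
    list(
      a_hw = min(truth$a_time, 0.95 * (truth$b_time - truth$a_time)),
      b_hw = 0.95 * min(truth$b_time - truth$a_time,
                        truth$phnr_time - truth$b_time),
      phnr_hw = 0.95 * min(truth$phnr_time - truth$b_time,
                           truth$duration_ms - truth$phnr_time),
      op_onset = op_onset
    )
  } else if (kind == "fvep") {
    list(
      n1_hw = 0.95 * min(truth$n1_time, truth$p1_time - truth$n1_time),
      p1_hw = 0.95 * min(truth$p1_time - truth$n1_time,
                         truth$duration_ms - truth$p1_time)
    )
  } else list()
}

# Deterministic noise-free component sum on a time grid (ms).
waveform_template <- function(truth, kind, t) {
  geo <- template_geometry(truth, kind)
  post <- t >= 0
  v <- numeric(length(t))
  if (kind == "erg") {
    v <- v - cos_lobe(t, truth$a_time, geo$a_hw, truth$a_amp)
    v <- v + cos_lobe(t, truth$b_time, geo$b_hw, truth$b_amp)
    v <- v - cos_lobe(t, truth$phnr_time, geo$phnr_hw, truth$phnr_amp)
    v[!post] <- 0
    v <- v + op_train(t, geo$op_onset, truth$op_freq, truth$op_amps,
                      slow = v)
  } else if (kind == "fvep") {
    v <- v - cos_lobe(t, truth$n1_time, geo$n1_hw, truth$n1_amp)
    v <- v + cos_lobe(t, truth$p1_time, geo$p1_hw, truth$p1_amp)
    v[!post] <- 0
  } else if (kind == "flicker") {
    # steady-state response at 20 Hz; b_amp is the trough-to-peak size
    v[post] <- (truth$b_amp / 2) * sin(2 * pi * 20 * t[post] / 1000)
  } else stop("unknown kind: ", kind)
  v
}

#' Generate synthetic evoked-potential sweeps with planted components
#'
#' Each sweep is the deterministic component sum (a smooth negative
#' a-wave lobe, positive b-wave lobe, an oscillatory-potential wavelet
#' train confined to the b-wave's ascending limb, and a PhNR trough for
#' ERG; N1/P1 lobes for fVEP; a steady 20 Hz sinusoid for flicker) plus
#' i.i.d. Gaussian noise of standard deviation `truth$noise_sd`.  Runs
#' are bit-reproducible for a fixed `truth$seed`, and the noise-free
#' average equals the component sum exactly.
#'
#' @param truth a [waveform_truth()].
#' @param kind which modality to synthesise: `"erg"`, `"fvep"` or
#'   `"flicker"`.
#' @return A [sweep_set()] of `truth$n_sweeps` sweeps spanning
#'   `[-pre_ms, duration_ms]` ms around flash onset.
#' @examples
#' s <- generate_waveform(waveform_truth(noise_sd = 0, n_sweeps = 1), "erg")
#' w <- average_sweeps(s)
#' min(w$voltage)  # -a_amp at the planted a-wave time
#' @export
generate_waveform <- function(truth, kind = c("erg", "fvep", "flicker")) {
  kind <- match.arg(kind)
  validate_waveform_truth(truth)
  dt <- 1000 / truth$sampling_rate
  t <- seq(-round(truth$pre_ms / dt), round(truth$duration_ms / dt)) * dt
  template <- waveform_template(truth, kind, t)
  units <- if (kind == "fvep") "mV" else "uV"
  set.seed(truth$seed)
  noise <- matrix(stats::rnorm(length(t) * truth$n_sweeps,
                               sd = truth$noise_sd),
                  nrow = length(t))
  sweep_set(template + noise, t, truth$sampling_rate, kind, units)
}

#' Generate matched no-flash control sweeps
#'
#' Same acquisition geometry and noise level as [generate_waveform()]
#' but with every component amplitude forced to zero: pure noise,
#' emulating a control recording in which the eye saw no flash.  Uses
#' an independent noise stream (seed offset by 1) so signal and control
#' noise are uncorrelated.
#'
#' @inheritParams generate_waveform
#' @return A [sweep_set()] of noise-only sweeps.
#' @export
generate_control_sweeps <- function(truth, kind = c("erg", "fvep", "flicker")) {
  kind <- match.arg(kind)
  validate_waveform_truth(truth)
  dt <- 1000 / truth$sampling_rate
  t <- seq(-round(truth$pre_ms / dt), round(truth$duration_ms / dt)) * dt
  units <- if (kind == "fvep") "mV" else "uV"
  set.seed(truth$seed + 1L)
  noise <- matrix(stats::rnorm(length(t) * truth$n_sweeps,
                               sd = truth$noise_sd),
                  nrow = length(t))
  sweep_set(noise, t, truth$sampling_rate, kind, units)
}

#' Simulate a dose-response table from hinge-model truth
#'
#' For every design point the response change is the piecewise linear
#' threshold mean [eq1_mean()] plus Gaussian(0, `sigma`) noise.  All
#' four branches of the model are honoured exactly and the draw is
#' reproducible for a fixed `truth$seed`.  An optional second truth
#' generates the latency outcome from the same design (independent
#' noise drawn from the same stream).
#'
#' @param truth a [dose_truth()]; generates the `dy_amplitude` column.
#' @param latency_truth optional [dose_truth()] sharing the same design,
#'   for the `dy_latency` column; `NULL` leaves latency `NA`.
#' @return Data frame with columns `subject_id`, `eye`, `timepoint`,
#'   `theta_deg`, `phi_deg_s`, `dy_amplitude`, `dy_latency`.
#' @export
generate_dose_response <- function(truth, latency_truth = NULL) {
  validate_dose_truth(truth)
  n <- nrow(truth$design)
  if (!is.null(latency_truth)) {
    validate_dose_truth(latency_truth)
    if (nrow(latency_truth$design) != n)
      stop("generate_dose_response: designs differ in size", call. = FALSE)
  }
  set.seed(truth$seed)
  mu <- eq1_mean(truth$design$theta, truth$design$phi,
                 theta0 = truth$theta0, phi0 = truth$phi0,
                 c1 = truth$c1, c2 = truth$c2)
  dy_amp <- mu + stats::rnorm(n, sd = truth$sigma)
  if (is.null(latency_truth)) {
    dy_lat <- rep(NA_real_, n)
  } else {
    mu_l <- eq1_mean(latency_truth$design$theta, latency_truth$design$phi,
                     theta0 = latency_truth$theta0,
                     phi0 = latency_truth$phi0,
                     c1 = latency_truth$c1, c2 = latency_truth$c2)
    dy_lat <- mu_l + stats::rnorm(n, sd = latency_truth$sigma)
  }
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             eye = "OS", timepoint = "D7",
             theta_deg = truth$design$theta,
             phi_deg_s = truth$design$phi,
             dy_amplitude = dy_amp, dy_latency = dy_lat,
             stringsAsFactors = FALSE)
}

#' Write sweeps as long-format CSV with a YAML truth sidecar
#'
#' @param s a [sweep_set()].
#' @param path output CSV path (columns `sweep_id`, `time_ms`,
#'   `voltage`).
#' @param truth optional [waveform_truth()] written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(s, path, truth = NULL) {
  stopifnot(inherits(s, "sweep_set"))
  df <- data.frame(
    sweep_id = rep(seq_len(ncol(s$data)), each = nrow(s$data)),
    time_ms = rep(s$time, ncol(s$data)),
    voltage = as.vector(s$data))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth)) {
    meta <- unclass(truth)
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a long-format sweeps CSV back into a sweep_set
#'
#' @param path CSV written by [write_sweeps_csv()].
#' @param sampling_rate,modality,units acquisition metadata (the CSV
#'   itself carries only the samples).
#' @return A [sweep_set()].
#' @export
read_sweeps_csv <- function(path, sampling_rate,
                            modality = c("erg", "fvep", "flicker"),
                            units = "uV") {
  modality <- match.arg(modality)
  df <- utils::read.csv(path)
  need <- c("sweep_id", "time_ms", "voltage")
  if (!all(need %in% names(df)))
    stop("read_sweeps_csv: expected columns ", paste(need, collapse = ", "))
  ids <- sort(unique(df$sweep_id))
  time <- sort(unique(df$time_ms))
  mat <- matrix(NA_real_, nrow = length(time), ncol = length(ids))
  for (j in seq_along(ids)) {
    sub <- df[df$sweep_id == ids[j], ]
    mat[, j] <- sub$voltage[order(sub$time_ms)]
  }
  sweep_set(mat, time, sampling_rate, modality, units)
}

#' Write / read the dose-response table CSV
#'
#' Column contract: `subject_id`, `eye`, `timepoint`, `theta_deg`,
#' `phi_deg_s`, `dy_amplitude`, `dy_latency`.
#'
#' @param records data frame as produced by [generate_dose_response()].
#' @param path CSV path.
#' @return `path` (write) or the records data frame (read).
#' @export
write_dose_csv <- function(records, path) {
  need <- c("subject_id", "eye", "timepoint", "theta_deg", "phi_deg_s",
            "dy_amplitude", "dy_latency")
  if (!all(need %in% names(records)))
    stop("write_dose_csv: missing columns ",
         paste(setdiff(need, names(records)), collapse = ", "))
  utils::write.csv(records[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_csv
#' @export
read_dose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "theta_deg", "phi_deg_s", "dy_amplitude")
  if (!all(need %in% names(df)))
    stop("read_dose_csv: expected columns ", paste(need, collapse = ", "))
  if (is.null(df$eye)) df$eye <- NA_character_
  if (is.null(df$timepoint)) df$timepoint <- NA_character_
  if (is.null(df$dy_latency)) df$dy_latency <- NA_real_
  df
}
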