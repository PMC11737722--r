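#' Ground-truth specification for a synthetic evoked-potential recording
#'
#' Describes the planted component structure of a synthetic flash ERG,
#' flash VEP or 20 Hz flicker recording: where each component peaks, how
#' large it is, how much i.i.d. Gaussian sweep noise is added, and how
#' many sweeps are acquired.  Amplitudes are magnitudes: `a_amp` and
#' `phnr_amp` are the depth of a negative deflection below baseline,
#' `b_amp` the height of the positive peak above baseline.  ERG
#' components are in microvolts, fVEP components in millivolts; all
#' times are milliseconds from flash onset.
#'
#' @param a_amp,a_time a-wave trough depth (uV, >= 0) and time (ms).
#' @param b_amp,b_time b-wave peak height above baseline (uV, >= 0) and
#'   time (ms).  For the flicker modality `b_amp` doubles as the
#'   steady-state trough-to-peak excursion.
#' @param op_amps trough-to-peak amplitudes (uV, >= 0) of up to five
#'   oscillatory-potential wavelets planted on the ascending limb of the
#'   b-wave, in temporal order.
#' @param op_freq oscillation frequency of the OP train (Hz).
#' @param phnr_amp,phnr_time photopic-negative-response trough depth
#'   below baseline (uV, >= 0) and time (ms); must follow the b-wave.
#' @param n1_amp,p1_amp fVEP N1 trough depth and P1 peak height (mV,
#'   >= 0).
#' @param n1_time,p1_time fVEP component times (ms), `n1_time <
#'   p1_time`.
#' @param noise_sd per-sweep Gaussian noise SD (uV for ERG/flicker, mV
#'   for fVEP).
#' @param n_sweeps number of repeated-stimulus sweeps to average.
#' @param sampling_rate sampling rate in Hz.
#' @param duration_ms post-onset sweep length (ms).
#' @param pre_ms pre-stimulus window length (ms) used downstream for
#'   baseline estimation.
#' @param seed integer seed; every generator call is reproducible.
#'
#' @return An object of class `waveform_truth`.
#' @seealso [generate_waveform()], [generate_control_sweeps()]
#' @export
waveform_truth <- function(a_amp = 120, a_time = 20,
                           b_amp = 240, b_time = 60,
                           op_amps = c(12, 8, 6, 4), op_freq = 150,
                           phnr_amp = 35, phnr_time = 95,
                           n1_amp = 0.04, p1_amp = 0.06,
                           n1_time = 35, p1_time = 75,
                           noise_sd = 5, n_sweeps = 64,
                           sampling_rate = 2000,
                           duration_ms = 300, pre_ms = 20,
                           seed = 1L) {
  truth <- list(
    a_amp = a_amp, a_time = a_time,
    b_amp = b_amp, b_time = b_time,
    op_amps = op_amps, op_freq = op_freq,
    phnr_amp = phnr_amp, phnr_time = phnr_time,
    n1_amp = n1_amp, p1_amp = p1_amp,
    n1_time = n1_time, p1_time = p1_time,
    noise_sd = noise_sd, n_sweeps = as.integer(n_sweeps),
    sampling_rate = sampling_rate,
    duration_ms = duration_ms, pre_ms = pre_ms,
    seed = as.integer(seed)
  )
  class(truth) <- "waveform_truth"
  validate_waveform_truth(truth)
  truth
}

validate_waveform_truth <- function(truth) {
  stopifnot(inherits(truth, "waveform_truth"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("a_amp", "b_amp", "phnr_amp", "n1_amp", "p1_amp")) {
    if (!num1(truth[[f]]) || truth[[f]] < 0)
      stop("waveform_truth: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (!is.numeric(truth$op_amps) || any(truth$op_amps < 0))
    stop("waveform_truth: 'op_amps' must be non-negative", call. = FALSE)
  if (length(truth$op_amps) > 5L)
    stop("waveform_truth: at most 5 OP wavelets are supported", call. = FALSE)
  if (!(truth$a_time < truth$b_time && truth$b_time < truth$phnr_time))
    stop("waveform_truth: component times must satisfy ",
         "a_time < b_time < phnr_time", call. = FALSE)
  if (!(truth$n1_time < truth$p1_time))
    stop("waveform_truth: component times must satisfy n1_time < p1_time",
         call. = FALSE)
  if (truth$n_sweeps < 1L)
    stop("waveform_truth: 'n_sweeps' must be >= 1", call. = FALSE)
  if (!num1(truth$sampling_rate) || truth$sampling_rate <= 0)
    stop("waveform_truth: 'sampling_rate' must be > 0", call. = FALSE)
  if (!num1(truth$noise_sd) || truth$noise_sd < 0)
    stop("waveform_truth: 'noise_sd' must be >= 0", call. = FALSE)
  if (truth$op_freq <= 0)
    stop("waveform_truth: 'op_freq' must be > 0", call. = FALSE)
  if (truth$duration_ms <= truth$phnr_time)
    stop("waveform_truth: 'duration_ms' must exceed 'phnr_time'",
         call. = FALSE)
  invisible(truth)
}

#' Ground-truth specification for a synthetic dose-response table
#'
#' Encodes the piecewise linear threshold (hinge) dose-response model:
#' the mean change is 0 while both the rotation amplitude Theta and the
#' peak angular velocity Phi stay below their thresholds, and grows
#' linearly in each supra-threshold excess,
#' \deqn{E[\Delta y] = c_1 (\Theta - \Theta_0)_+ + c_2 (\Phi - \Phi_0)_+,}
#' with Gaussian residual noise of standard deviation `sigma`.  The
#' boundary `Theta == theta0` belongs to the supra-threshold branch
#' (zero excess, so the convention is observationally null).
#'
#' @param theta0 amplitude threshold Theta0 (degrees, >= 0).
#' @param phi0 velocity threshold Phi0 (degrees/s, >= 0).
#' @param c1 slope per degree of supra-threshold rotation amplitude.
#' @param c2 slope per degree/s of supra-threshold angular velocity.
#' @param sigma residual standard deviation of the response (>= 0).
#' @param design data frame (or 2-column matrix) of dose points with
#'   columns `theta` (degrees) and `phi` (degrees/s); see
#'   [pilot_design()] for the default 27-animal layout.
#' @param seed integer seed.
#'
#' @return An object of class `dose_truth`.
#' @seealso [generate_dose_response()], [eq1_mean()]
#' @export
dose_truth <- function(theta0 = 20.5, phi0 = 1475,
                       c1 = -0.0221, c2 = 0, sigma = 0.05,
                       design = pilot_design(), seed = 1L) {
  design <- as.data.frame(design)
  if (is.null(design$theta) || is.null(design$phi))
    stop("dose_truth: 'design' needs columns 'theta' and 'phi'",
         call. = FALSE)
  truth <- list(theta0 = theta0, phi0 = phi0, c1 = c1, c2 = c2,
                sigma = sigma, design = design, seed = as.integer(seed))
  class(truth) <- "dose_truth"
  validate_dose_truth(truth)
  truth
}

validate_dose_truth <- function(truth) {
  stopifnot(inherits(truth, "dose_truth"))
  if (truth$theta0 < 0 || truth$phi0 < 0)
    stop("dose_truth: thresholds must be >= 0", call. = FALSE)
  if (truth$sigma < 0)
    stop("dose_truth: 'sigma' must be >= 0", call. = FALSE)
  if (nrow(truth$design) == 0L)
    stop("dose_truth: 'design' must be non-empty", call. = FALSE)
  if (any(!is.finite(truth$design$theta)) || any(truth$design$theta < 0) ||
      any(!is.finite(truth$design$phi)) || any(truth$design$phi < 0))
    stop("dose_truth: design doses must be finite and >= 0", call. = FALSE)
  invisible(truth)
}

#' Crossed dose design with independently varied amplitude and velocity
#'
#' Unlike the pilot's proportional dosing (which couples Phi to Theta
#' and leaves the velocity threshold structurally unidentifiable when
#' the velocity slope is zero), this design varies rotation amplitude
#' at saccade-level velocity, velocity at saccade-level amplitude, and
#' both together, so both thresholds are identifiable.  27 animals by
#' default, mirroring the pilot cohort size.
#'
#' @param n_neg,n_pos,n_arm group sizes: negative controls, saccade
#'   positive controls, and each of the three dosed arms.
#' @return Data frame with columns `group`, `theta`, `phi`.
#' @export
crossed_design <- function(n_neg = 3, n_pos = 3, n_arm = 7) {
  theta_arm <- seq(24, 47, length.out = n_arm)
  phi_arm <- seq(1600, 3320, length.out = n_arm)
  data.frame(
    group = rep(c("negative", "positive", "amplitude", "velocity",
                  "combined"), c(n_neg, n_pos, n_arm, n_arm, n_arm)),
    theta = c(rep(0, n_neg), rep(10, n_pos), theta_arm,
              rep(10, n_arm), theta_arm),
    phi = c(rep(0, n_neg), rep(500, n_pos), rep(500, n_arm),
            phi_arm, phi_arm),
    stringsAsFactors = FALSE)
}

#' Reconstruction of the 27-animal pilot dose design
#'
#' The pilot cohort comprised negative controls (no rotation, n = 3),
#' positive controls at saccade level (10 degrees at 500 degrees/s,
#' n = 3), and low (n = 4), medium (n = 8) and high (n = 10) dose
#' groups spanning rotations up to 47 degrees at peak velocities up to
#' 3320 degrees/s.  Exact per-animal doses were not published, so this
#' reconstruction spaces doses evenly within each group's range and
#' couples velocity to amplitude near-proportionally (nominal ratio
#' Phi ~ 72 Theta, the value implied by the 20.5 degree / 1475
#' degree-per-second threshold pair) with a fixed per-animal spread,
#' capped at the 3320 degrees/s actuator limit.
#'
#' @param n_neg,n_pos,n_low,n_med,n_high group sizes.
#' @param velocity_ratio nominal proportionality constant Phi / Theta
#'   for the dosed groups (degrees/s per degree).
#' @param ratio_spread fractional spread of the achieved per-animal
#'   ratio around the nominal (the actuator does not realise a perfect
#'   amplitude-velocity coupling); assigned as a fixed cyclic pattern
#'   so the design stays deterministic.
#' @param phi_cap actuator velocity ceiling (degrees/s).
#' @return Data frame with columns `group`, `theta`, `phi`.
#' @export
pilot_design <- function(n_neg = 3, n_pos = 3, n_low = 4, n_med = 8,
                         n_high = 10, velocity_ratio = 72,
                         ratio_spread = 0.12, phi_cap = 3320) {
  theta <- c(rep(0, n_neg),
             rep(10, n_pos),
             seq(12, 20, length.out = n_low),
             seq(21, 38, length.out = n_med),
             seq(38.5, 47, length.out = n_high))
  n_dosed <- n_low + n_med + n_high
  ratios <- velocity_ratio *
    (1 + ratio_spread * rep_len(c(-1, 1, 0, 0.5, -0.5), n_dosed))
  phi <- c(rep(0, n_neg),
           rep(500, n_pos),
           pmin(ratios * theta[-seq_len(n_neg + n_pos)], phi_cap))
  group <- rep(c("negative", "positive", "low", "medium", "high"),
               c(n_neg, n_pos, n_low, n_med, n_high))
  data.frame(group = group, theta = theta, phi = phi,
             stringsAsFactors = FALSE)
}
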