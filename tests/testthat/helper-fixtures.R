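# Shared fixtures: all synthetic, built in code at test time.

# a waveform object from a raw voltage vector on a uniform grid
make_waveform <- function(voltage, dt = 0.5, pre_ms = 20,
                          modality = "erg", units = "uV") {
  n_pre <- round(pre_ms / dt)
  time <- (seq_along(voltage) - n_pre - 1L) * dt
  ergthresh:::new_waveform(time, voltage, modality, units)
}

# smooth test lobe on a time grid (ms)
test_lobe <- function(time, center, hw, amp) {
  u <- (time - center) / hw
  v <- numeric(length(time))
  i <- abs(u) < 1
  v[i] <- amp * cos(pi * u[i] / 2)^2
  v
}

# random waveform truth within physiologic-ish ranges; geometry chosen
# so the OP train always fits the ascending limb
random_truth <- function(seed) {
  set.seed(seed)
  # a_time >= 17 keeps the a-lobe slow enough to stay out of the OP
  # isolation band (a narrower a-wave genuinely bleeds into it)
  a_time <- runif(1, 17, 22)
  b_time <- runif(1, a_time + 40, a_time + 52)
  waveform_truth(
    a_amp = runif(1, 60, 150), a_time = a_time,
    b_amp = runif(1, 150, 300), b_time = b_time,
    op_amps = runif(4, 5, 15), op_freq = runif(1, 155, 175),
    phnr_amp = runif(1, 20, 50),
    phnr_time = b_time + runif(1, 30, 40),
    n1_amp = runif(1, 0.02, 0.06), n1_time = runif(1, 30, 40),
    p1_amp = runif(1, 0.03, 0.08), p1_time = runif(1, 70, 85),
    noise_sd = 0, n_sweeps = 1, seed = seed)
}

# dose-response records straight from a design + response vector
make_records <- function(theta, phi, dy) {
  data.frame(subject_id = sprintf("S%02d", seq_along(theta)),
             eye = "OS", timepoint = "D7",
             theta_deg = theta, phi_deg_s = phi,
             dy_amplitude = dy, dy_latency = NA_real_,
             stringsAsFactors = FALSE)
}

# truth used throughout the threshold tests (the pilot-study values)
pilot_truth <- function(sigma = 0, seed = 1, design = pilot_design()) {
  dose_truth(theta0 = 20.5, phi0 = 1475, c1 = -0.0221, c2 = 0,
             sigma = sigma, design = design, seed = seed)
}
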