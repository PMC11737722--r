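# Waveform scoring: averaging, control subtraction and the clinical
# measurement conventions.

dt <- 0.5  # ms, 2000 Hz

test_that("average_sweeps is the pointwise mean with a baseline", {
  time <- seq(-20, 100, by = dt)
  s <- sweep_set(cbind(rep(4, length(time)), rep(-4, length(time))),
                 time, 2000, "erg")
  w <- average_sweeps(s)
  expect_true(all(w$voltage == 0))

  one <- sweep_set(matrix(sin(time / 5)), time, 2000, "erg")
  expect_equal(average_sweeps(one)$voltage, sin(time / 5))

  expect_error(sweep_set(matrix(1, 5, 2), time = 1:4, 2000, "erg"),
               "length")
  expect_error(average_sweeps(structure(list(data = matrix(numeric(0), 3, 0)),
                                        class = "sweep_set")),
               "no sweeps")
})

test_that("sweep averaging approaches the template at the MC bound", {
  tr <- waveform_truth(noise_sd = 5, n_sweeps = 64, seed = 5)
  tr0 <- tr; tr0$noise_sd <- 0; tr0$n_sweeps <- 1L
  tmpl <- average_sweeps(generate_waveform(tr0, "erg"))$voltage
  frac_in <- vapply(1:30, function(s) {
    tr$seed <- s
    w <- average_sweeps(generate_waveform(tr, "erg"))
    mean(abs(w$voltage - tmpl) <= 3 * 5 / sqrt(64))
  }, numeric(1))
  expect_gte(mean(frac_in), 0.99)
})

test_that("subtract_control cancels common-mode activity", {
  time <- seq(-20, 150, by = dt)
  planted <- test_lobe(time, 75, 15, 0.06) - test_lobe(time, 35, 12, 0.04)
  drift <- 0.02 * sin(2 * pi * 3 * time / 1000) + 0.01
  sig <- ergthresh:::new_waveform(time, planted + drift, "fvep", "mV")
  ctl <- ergthresh:::new_waveform(time, drift, "fvep", "mV")
  out <- subtract_control(sig, ctl)
  expect_equal(out$voltage, planted)

  # control == signal -> zero; zero control -> identity
  expect_true(all(subtract_control(sig, sig)$voltage == 0))
  zero <- ergthresh:::new_waveform(time, numeric(length(time)), "fvep", "mV")
  expect_equal(subtract_control(sig, zero)$voltage, sig$voltage)

  short <- ergthresh:::new_waveform(time[-1], drift[-1], "fvep", "mV")
  expect_error(subtract_control(sig, short), "grids")
  erg <- ergthresh:::new_waveform(time, drift, "erg", "uV")
  expect_error(subtract_control(sig, erg), "modality")
})

test_that("a-wave: first qualifying trough, magnitude from baseline", {
  time <- seq(-20, 150, by = dt)
  # two negative troughs at 15 and 90 ms: earliest is chosen, and a
  # brute-force scan over all local minima agrees
  v <- -test_lobe(time, 15, 8, 120) - test_lobe(time, 90, 8, 80)
  w <- make_waveform(v)
  a <- measure_a_wave(w)
  mins <- ergthresh:::local_minima(v)
  mins <- mins[time[mins] > 0 & v[mins] < 0]
  expect_equal(a$time, min(time[mins]))
  expect_equal(a$time, 15)
  expect_equal(a$amp, 120)

  expect_true(is_absent(measure_a_wave(make_waveform(numeric(length(time))))))
  # positive-only trace has no qualifying trough
  expect_true(is_absent(measure_a_wave(make_waveform(test_lobe(time, 50, 10, 30)))))
  expect_error(measure_a_wave(make_waveform(v, modality = "fvep")), "ERG")
})

test_that("b-wave: measured from the a-trough to the highest peak", {
  time <- seq(-20, 150, by = dt)
  v <- -test_lobe(time, 15, 8, 120) + test_lobe(time, 60, 12, 240) +
    test_lobe(time, 100, 10, 180)
  w <- make_waveform(v)
  a <- measure_a_wave(w)
  b <- measure_b_wave(w, a)
  expect_equal(b$amp, 360)         # 240 - (-120)
  expect_equal(b$time, 60)
  expect_identical(b$reference, "a-wave")

  # two positive peaks (180 at 100, 240 at 60): higher one wins even
  # though it comes first; brute-force max agrees
  win <- which(time > 15)
  expect_equal(b$time, time[win[which.max(v[win])]])

  # absent a-wave: referenced to baseline and flagged
  v2 <- test_lobe(time, 60, 12, 200)
  b2 <- measure_b_wave(make_waveform(v2), measure_a_wave(make_waveform(v2)))
  expect_identical(b2$reference, "baseline")
  expect_equal(b2$amp, 200)

  # monotone rise -> boundary peak flagged
  v3 <- seq(0, 50, length.out = length(time))
  b3 <- measure_b_wave(make_waveform(v3), feature_absent("x"))
  expect_true(b3$boundary)
})

test_that("OPs: trough-to-peak on the filtered trace, before b-peak", {
  tr <- waveform_truth(noise_sd = 0, n_sweeps = 1)
  w <- average_sweeps(generate_waveform(tr, "erg"))
  b <- measure_b_wave(w, measure_a_wave(w))
  ops <- extract_ops(w, b_time = w$time[b$index], min_time = 20)
  expect_equal(unname(ops$amps), c(12, 8, 6, 4), tolerance = 1e-5)
  expect_identical(names(ops$amps), c("OP1-2", "OP3", "OP4", "OP5"))
  expect_true(all(diff(ops$times) > 0))
  expect_true(all(ops$times < w$time[b$index]))

  # a wavelet planted after b_time is excluded
  time <- w$time
  late <- 6 * sin(2 * pi * 150 * (time - 150) / 1000) *
    exp(-((time - 150) / 8)^2)
  w2 <- make_waveform(w$voltage + late)
  ops2 <- extract_ops(w2, b_time = w$time[b$index], min_time = 20)
  expect_equal(unname(ops2$amps), c(12, 8, 6, 4), tolerance = 1e-3)

  # flat trace -> empty, flagged low confidence
  ops0 <- extract_ops(make_waveform(numeric(length(time))), b_time = 60)
  expect_length(ops0$amps, 0)
  expect_true(ops0$low_confidence)
})

test_that("SOP sums available wavelets and annotates missing labels", {
  expect_equal(as.numeric(compute_sop(c(12, 8, 6, 4))), 30)
  expect_equal(as.numeric(compute_sop(numeric(0))), 0)
  partial <- compute_sop(c("OP1-2" = 12, "OP3" = 8))
  expect_equal(as.numeric(partial), 20)
  expect_identical(attr(partial, "missing_labels"), c("OP4", "OP5"))
})

test_that("PhNR: deepest trough after the b-wave, from baseline", {
  time <- seq(-20, 200, by = dt)
  v <- test_lobe(time, 60, 12, 240) - test_lobe(time, 90, 8, 35) -
    test_lobe(time, 150, 8, 20)
  ph <- measure_phnr(make_waveform(v), b_time = 60)
  expect_equal(ph$amp, 35)
  expect_equal(ph$time, 90)
  expect_false(ph$above_baseline)
  # brute-force: deeper of the two post-b troughs
  win <- which(time > 60)
  expect_equal(ph$time, time[win[which.min(v[win])]])

  # clamped at baseline after b -> amplitude 0
  v2 <- test_lobe(time, 60, 12, 240)
  v2[time > 72] <- 0
  expect_equal(measure_phnr(make_waveform(v2), b_time = 60)$amp, 0)

  # trough above baseline -> magnitude with sign flag
  v3 <- test_lobe(time, 60, 12, 240)
  v3[time > 66] <- 10 - test_lobe(time[time > 66], 90, 8, 6)
  ph3 <- measure_phnr(make_waveform(v3), b_time = 60)
  expect_true(ph3$above_baseline)
  expect_gte(ph3$amp, 0)
})

test_that("flicker: mean trough-to-following-peak over cycles", {
  time <- seq(-20, 300, by = dt)
  v <- 25 * sin(2 * pi * 20 * time / 1000)
  v[time < 0] <- 0
  w <- make_waveform(v, modality = "flicker")
  expect_equal(measure_flicker(w), 50, tolerance = 1e-3)
  expect_equal(measure_flicker(make_waveform(numeric(length(time)),
                                             modality = "flicker")), 0)
  short <- make_waveform(rep(0, 60), modality = "flicker")
  expect_error(measure_flicker(short), "cycle")

  # per-sweep SNR 10 (excursion 50, noise_sd 5), averaged over the
  # protocol 64 sweeps: recovery within 10 %
  amps <- vapply(1:50, function(s) {
    tr <- waveform_truth(b_amp = 50, noise_sd = 5, n_sweeps = 64,
                         seed = s)
    measure_flicker(average_sweeps(generate_waveform(tr, "flicker")))
  }, numeric(1))
  expect_equal(mean(amps), 50, tolerance = 0.1)
})

test_that("fVEP: N1 to P1 difference metrics", {
  time <- seq(-20, 300, by = dt)
  v <- -test_lobe(time, 35, 12, 0.04) + test_lobe(time, 75, 15, 0.06)
  fv <- measure_fvep(make_waveform(v, modality = "fvep", units = "mV"))
  expect_equal(fv$amplitude_n1p1, 0.10)
  expect_equal(fv$latency_n1p1, 40)
  expect_equal(fv$n1_time, 35)
  expect_equal(fv$p1_time, 75)

  flat <- make_waveform(numeric(length(time)), modality = "fvep")
  expect_true(is_absent(measure_fvep(flat)))
  # N1 present but no positive P1 after it
  neg <- make_waveform(-test_lobe(time, 35, 12, 0.04), modality = "fvep")
  out <- measure_fvep(neg)
  expect_true(is_absent(out))
  expect_match(out$reason, "P1")
})

test_that("normalize_change supports both modes and guards zero", {
  expect_equal(normalize_change(0.10, 0.10, "difference"), 0)
  expect_equal(normalize_change(0.10, 0.10, "relative"), 0)
  expect_equal(normalize_change(0.10, 0.06, "difference"), -0.04)
  expect_equal(normalize_change(0.10, 0.06, "relative"), -0.4)
  expect_error(normalize_change(0, 0.06, "relative"), "non-zero")
  expect_error(normalize_change(NA_real_, 1), "finite")
})

test_that("property: noise-free round trip recovers randomized truths", {
  for (seed in 1:12) {
    tr <- random_truth(seed)
    w <- average_sweeps(generate_waveform(tr, "erg"))
    f <- score_erg(w)
    # amplitudes to sample resolution: an off-grid extremum is read at
    # the nearest sample, a relative error of order (pi*dt/2/hw)^2
    expect_equal(f$a$amp, tr$a_amp, tolerance = 3e-3)
    expect_lt(abs(f$a$time - tr$a_time), dt)
    expect_equal(f$b$amp, tr$b_amp + tr$a_amp, tolerance = 3e-3)
    expect_lt(abs(f$b$time - tr$b_time), dt)
    expect_equal(unname(f$ops$amps), tr$op_amps, tolerance = 5e-3)
    expect_equal(as.numeric(f$sop), sum(tr$op_amps), tolerance = 5e-3)
    expect_equal(f$phnr$amp, tr$phnr_amp, tolerance = 3e-3)
    expect_lt(abs(f$phnr$time - tr$phnr_time), dt)

    wv <- average_sweeps(generate_waveform(tr, "fvep"))
    fv <- measure_fvep(wv)
    expect_equal(fv$amplitude_n1p1, tr$n1_amp + tr$p1_amp,
                 tolerance = 3e-3)
    expect_lt(abs(fv$n1_time - tr$n1_time), dt)
    expect_lt(abs(fv$p1_time - tr$p1_time), dt)
  }
})

test_that("property: measurements are invariant to a constant offset", {
  tr <- waveform_truth(noise_sd = 3, n_sweeps = 16, seed = 8)
  w <- average_sweeps(generate_waveform(tr, "erg"))
  w_off <- ergthresh:::new_waveform(w$time, w$voltage + 57, "erg", "uV")
  f1 <- score_erg(w); f2 <- score_erg(w_off)
  expect_equal(f2$a$amp, f1$a$amp)
  expect_equal(f2$a$time, f1$a$time)
  expect_equal(f2$b$amp, f1$b$amp)
  expect_equal(as.numeric(f2$sop), as.numeric(f1$sop))
  expect_equal(f2$phnr$amp, f1$phnr$amp)
})

test_that("property: amplitudes non-negative, times inside the trace", {
  for (seed in 13:18) {
    tr <- random_truth(seed)
    tr$noise_sd <- 4; tr$n_sweeps <- 32L
    w <- average_sweeps(generate_waveform(tr, "erg"))
    f <- score_erg(w)
    for (feat in list(f$a, f$b, f$phnr)) {
      if (is_absent(feat)) next
      expect_gte(feat$amp, 0)
      expect_gte(feat$time, min(w$time))
      expect_lte(feat$time, max(w$time))
    }
    expect_true(all(f$ops$amps >= 0))
    expect_gte(as.numeric(f$sop), 0)
  }
})

test_that("features_to_rows emits the tidy column contract", {
  tr <- waveform_truth(noise_sd = 0, n_sweeps = 1)
  f <- score_erg(average_sweeps(generate_waveform(tr, "erg")))
  rows <- features_to_rows(f, "S01", "OD", "D1", units = "uV")
  expect_identical(names(rows),
                   c("subject_id", "eye", "timepoint", "feature",
                     "value", "units", "quality_flag"))
  expect_true(all(c("a_amp", "b_amp", "sop", "phnr_amp") %in% rows$feature))
  expect_equal(rows$value[rows$feature == "sop"], 30, tolerance = 1e-5)
})
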