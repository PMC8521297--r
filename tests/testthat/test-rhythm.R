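test_that("detrending removes a linear trend away from the edges", {
  t <- seq(0, 96, 0.5)
  tr <- data.frame(time_h = t, signal = 2 + 0.3 * t)
  out <- detrend_and_smooth(tr)
  interior <- t > 15 & t < 81
  expect_lt(max(abs(out$signal[interior])), 1e-9)
  expect_error(detrend_and_smooth(tr, baseline_window_h = 200), "duration")
  expect_error(detrend_and_smooth(tr, smooth_window_h = 0.4), "sampling")
})

test_that("moving-average smoothing preserves period and attenuates as sinc", {
  t <- seq(0, 120, 0.25)
  tr <- data.frame(time_h = t, signal = 1 + 0.1 * t + cos(2 * pi * t / 24))
  out <- detrend_and_smooth(tr, baseline_window_h = 24, smooth_window_h = 2.5)
  f <- fit_rhythm(out)
  expect_equal(f$period_h, 24, tolerance = 0.2)
  # 2.5-h boxcar on a 24-h cosine attenuates by sinc(pi*2.5/24) ~ 0.982;
  # the 24-h baseline window removes none of the cosine in the interior
  att <- sin(pi * 2.5 / 24) / (pi * 2.5 / 24)
  expect_equal(f$amplitude, att, tolerance = 0.04)
  # second smoothing pass changes the signal less than the first did
  again <- detrend_and_smooth(out, baseline_window_h = 24,
                              smooth_window_h = 2.5)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(again$signal - out$signal), rms(out$signal - tr$signal))
})

test_that("noiseless damped cosine is recovered to high precision", {
  tr <- simulate_biolum_trace(rhythm_config(period_h = 24, amplitude = 1,
                                            noise_sd = 0, duration_h = 120))
  f <- fit_rhythm(tr)
  expect_equal(f$period_h, 24, tolerance = 0.01)
  expect_lt(f$rae, 0.01)
  expect_gt(f$gof, 0.999)
  expect_true(f$initiated)

  trd <- simulate_biolum_trace(rhythm_config(period_h = 26, amplitude = 2,
                                             damping_per_h = 0.01,
                                             phase_h = 5, noise_sd = 0,
                                             duration_h = 144))
  fd <- fit_rhythm(trd)
  expect_equal(fd$period_h, 26, tolerance = 0.01)
  expect_equal(fd$phase_h, 5, tolerance = 0.05)
  expect_equal(fd$damping_per_h, 0.01, tolerance = 1e-3)
})

test_that("RAE grows with noise and pure noise is rarely called initiated", {
  rae_at <- function(noise, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_biolum_trace(rhythm_config(amplitude = 1,
                                                noise_sd = noise,
                                                duration_h = 120, seed = s))
      fit_rhythm(tr)$rae
    }, numeric(1))
  }
  seeds <- 1:25
  m <- vapply(c(0.05, 0.3, 1.0), function(ns) mean(rae_at(ns, seeds)),
              numeric(1))
  expect_true(all(diff(m) > 0))

  fp <- vapply(1:40, function(s) {
    tr <- simulate_biolum_trace(rhythm_config(amplitude = 0, noise_sd = 1,
                                              duration_h = 120, seed = s))
    fit_rhythm(detrend_and_smooth(tr))$initiated
  }, logical(1))
  expect_lte(mean(fp), 0.05)
})

test_that("initiated classification uses inclusive period and strict RAE bounds", {
  f <- function(tau, rae) list(period_h = tau, rae = rae)
  expect_true(classify_initiated(f(24.0, 0.1)))
  expect_false(classify_initiated(f(22.0, 0.1)))
  expect_true(classify_initiated(f(23.5, 0.29)))
  expect_true(classify_initiated(f(34.5, 0.29)))
  expect_false(classify_initiated(f(24.0, 0.3)))   # strict RAE inequality
  expect_false(classify_initiated(f(NA, 0.1)))
  expect_false(classify_initiated(list(period_h = 24, rae = Inf)))
})

test_that("Rayleigh statistics match hand-computed vector sums", {
  expect_equal(rayleigh_test(c(3, 3, 3, 3), 24)$R, 1)
  expect_equal(rayleigh_test(c(0, 12), 24)$R, 0, tolerance = 1e-12)
  # angles {0, 0, pi/2}: R = |2 + i| / 3 = sqrt(5)/3
  expect_equal(rayleigh_test(c(0, 0, 6), 24)$R, sqrt(5) / 3)
  # invariance to a common phase offset; R always in [0, 1]
  set.seed(5)
  ph <- runif(50, 0, 24)
  r1 <- rayleigh_test(ph, 24)
  r2 <- rayleigh_test(ph + 7.3, 24)
  expect_equal(r1$R, r2$R, tolerance = 1e-12)
  expect_true(r1$R >= 0 && r1$R <= 1)
  # coherent phases give a tiny p, uniform phases a large one
  expect_lt(rayleigh_test(rep(c(2, 2.5), 10), 24)$p, 1e-6)
  expect_gt(rayleigh_test(seq(0, 23.9, length.out = 24), 24)$p, 0.5)
  expect_error(rayleigh_test(3), "at least 2")
})

test_that("peak detection finds cosine peaks and their 24-h spacing", {
  tr <- simulate_biolum_trace(rhythm_config(period_h = 24, amplitude = 1,
                                            noise_sd = 0, duration_h = 96,
                                            phase_h = 0))
  pk <- detect_peaks(tr)
  expect_equal(pk, c(24, 48, 72), tolerance = 0.5)
  expect_equal(diff(pk), c(24, 24), tolerance = 0.1)

  # damped noisy cosine (SNR 5): single peak-to-peak intervals carry ~0.5 h
  # jitter at 30-min sampling, so individual intervals are only loosely
  # constrained while their mean tracks the period much more tightly
  devs <- sapply(1:10, function(s) {
    trn <- simulate_biolum_trace(rhythm_config(period_h = 24, amplitude = 1,
                                               damping_per_h = 0.005,
                                               noise_sd = 0.2,
                                               duration_h = 120, seed = s))
    iv <- diff(detect_peaks(detrend_and_smooth(trn)))
    c(each = max(abs(iv - 24)), mean = abs(mean(iv) - 24))
  })
  expect_lt(max(devs["each", ]), 2.5)
  expect_lt(mean(devs["mean", ]), 0.5)

  expect_length(detect_peaks(data.frame(time_h = 0:10, signal = rep(1, 11))),
                0)
})

test_that("imposed phase shifts are recovered with the correct sign", {
  run <- function(shift, seed) {
    tr <- simulate_biolum_trace(rhythm_config(
      period_h = 24, amplitude = 1, noise_sd = 0.05, baseline_offset = 10,
      duration_h = 264, treatment = list(time_h = 130, phase_shift_h = shift),
      seed = seed))
    phase_shift(tr, 130)$shift_h
  }
  expect_equal(run(0, 61), 0, tolerance = 0.15)
  expect_equal(run(2, 62), 2, tolerance = 0.25)
  expect_equal(run(-1, 63), -1, tolerance = 0.25)
  # amplitude-only change leaves phase untouched
  tr <- simulate_biolum_trace(rhythm_config(
    period_h = 24, amplitude = 1, noise_sd = 0.05, baseline_offset = 10,
    duration_h = 264, treatment = list(time_h = 130, amplitude_scale = 0.5),
    seed = 64))
  expect_equal(phase_shift(tr, 130)$shift_h, 0, tolerance = 0.25)
  # too few peaks is an explicit error
  short <- simulate_biolum_trace(rhythm_config(duration_h = 72, noise_sd = 0))
  expect_error(phase_shift(short, 36), "peaks")
})

test_that("waveform changes recover baseline and amplitude manipulations", {
  mk <- function(treatment, seed) simulate_biolum_trace(rhythm_config(
    period_h = 24, amplitude = 2, noise_sd = 0.05, baseline_offset = 4,
    duration_h = 240, treatment = treatment, seed = seed))
  w0 <- waveform_changes(mk(NULL, 71), 120)
  expect_equal(w0$delta_baseline_rel, 0, tolerance = 0.05)
  expect_equal(w0$delta_amplitude_rel, 0, tolerance = 0.1)
  expect_equal(w0$delta_period_h, 0, tolerance = 0.3)

  wb <- waveform_changes(mk(list(time_h = 120, baseline_shift = 4), 72), 120)
  expect_equal(wb$delta_baseline_rel, 1, tolerance = 0.15)

  wa <- waveform_changes(mk(list(time_h = 120, amplitude_scale = 0.5), 73),
                         120)
  expect_equal(wa$delta_amplitude_rel, -0.5, tolerance = 0.12)

  wp <- waveform_changes(mk(list(time_h = 120, period_h = 26), 74), 120)
  expect_equal(wp$delta_period_h, 2, tolerance = 0.5)
})

test_that("PRC binning anchors at CT0 with fixed-width bins", {
  ct <- c(10, 10.5, 1, 23.9, 0.5)
  sh <- c(-2, -2, 0, 0.4, 0.2)
  prc <- assemble_prc(ct, sh, bin_width_h = 3)
  expect_equal(nrow(prc), 8)
  b10 <- prc[prc$bin_start_ct == 9, ]
  expect_equal(b10$mean_shift_h, -2)
  expect_equal(b10$n, 2)
  # CT 23.9 and CT 0.5 land in different bins (anchored at CT0)
  expect_equal(prc$n[prc$bin_start_ct == 21], 1)
  expect_equal(prc$n[prc$bin_start_ct == 0], 2)
  # empty bins reported with n = 0
  expect_true(any(prc$n == 0))
  expect_true(all(is.na(prc$mean_shift_h[prc$n == 0])))
  expect_error(assemble_prc(c(25), 0), "\\[0, 24\\)")
})

test_that("CT mapping is a modular phase translation", {
  expect_equal(map_ct(5, 5, 7.2), 7.2)
  expect_equal(map_ct(6.9, 6.0, 7.2), 8.1)    # +0.9 h from CT 7.2
  expect_equal(map_ct(1, 23, 23), 1)          # wraps past CT 24
  f1 <- list(period_h = 24, phase_h = 3); class(f1) <- "rhythm_fit"
  f2 <- list(period_h = 26, phase_h = 3); class(f2) <- "rhythm_fit"
  expect_warning(map_ct(f1, f2, 7), "periods differ")
})

test_that("phase maps recover the planted fraction and gradient", {
  base <- rhythm_config(period_h = 24, amplitude = 1, noise_sd = 0.2,
                        baseline_offset = 5, duration_h = 120, seed = 31)
  g <- simulate_roi_grid(6, 10, 0.7, 4, base)
  pm <- build_phase_map(g, signal_threshold = 0)
  expect_lt(abs(pm$initiated_fraction - 0.7), 0.07)
  tab <- pm$table[pm$table$initiated, ]
  slope <- coef(lm(rel_phase_h ~ col, data = tab))[[2]] * 9
  expect_lt(abs(slope - 4), 0.25)

  # zero gradient: relative phases collapse and R ~ 1
  g1 <- simulate_roi_grid(4, 6, 1, 0, base)
  pm1 <- build_phase_map(g1, signal_threshold = 0)
  expect_equal(pm1$initiated_fraction, 1)
  expect_gt(pm1$rayleigh_R, 0.99)
  expect_lt(max(abs(pm1$table$rel_phase_h)), 0.5)

  # signal threshold excludes dim ROIs; all-excluded errors
  expect_error(build_phase_map(g1, signal_threshold = 1e6), "excluded")
})
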