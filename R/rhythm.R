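# centered moving average with edge truncation; width in samples (odd)
.moving_average <- function(y, width) {
  n <- length(y)
  half <- width %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.check_trace <- function(trace) {
  stopifnot(all(c("time_h", "signal") %in% names(trace)))
  t <- trace$time_h
  if (length(t) < 2) stop("trace needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  invisible(t)
}

.window_to_samples <- function(window_h, dt) {
  w <- max(1L, round(window_h / dt))
  if (w %% 2 == 0) w <- w + 1L
  w
}

#' Detrend and smooth a trace
#'
#' Subtracts a centered moving-average baseline (default 24-h window) and then
#' smooths with a centered 2.5-h moving average. Edge windows are truncated.
#'
#' @param trace data.frame with `time_h`, `signal` (uniformly sampled).
#' @param baseline_window_h baseline window in hours (default 24).
#' @param smooth_window_h smoothing window in hours (default 2.5).
#' @return The trace with `signal` replaced by the detrended, smoothed signal.
#' @export
detrend_and_smooth <- function(trace, baseline_window_h = 24,
                               smooth_window_h = 2.5) {
  t <- .check_trace(trace)
  dt <- stats::median(diff(t))
  dur <- t[length(t)] - t[1]
  if (baseline_window_h >= dur || smooth_window_h >= dur)
    stop("windows must be shorter than the trace duration")
  if (baseline_window_h <= dt || smooth_window_h <= dt)
    stop("windows must exceed the sampling interval")
  y <- trace$signal
  y <- y - .moving_average(y, .window_to_samples(baseline_window_h, dt))
  y <- .moving_average(y, .window_to_samples(smooth_window_h, dt))
  out <- trace
  out$signal <- y
  out
}

# dominant FFT component with period inside the window; NULL when none
.fft_init <- function(t, y, period_window) {
  n <- length(y)
  dt <- stats::median(diff(t))
  yc <- y - mean(y)
  z <- stats::fft(yc)
  k <- seq_len(floor(n / 2))          # positive frequencies, skip DC
  freq <- k / (n * dt)
  per <- 1 / freq
  ok <- per >= period_window[1] & per <= period_window[2]
  if (!any(ok)) return(NULL)
  pw <- Mod(z[k + 1])^2
  kk <- k[ok][which.max(pw[ok])]
  zz <- z[kk + 1]
  f <- kk / (n * dt)
  amp <- 2 * Mod(zz) / n
  # y ~ A cos(2 pi f (t - phi)): coefficient phase -2 pi f (t1 + phi)
  phi <- (-Arg(zz) / (2 * pi * f)) - t[1]
  list(tau = 1 / f, A = amp, phi = phi %% (1 / f))
}

#' Fit a damped cosine by FFT-initialized nonlinear least squares
#'
#' Fits `y = c + A * exp(-lambda * t) * cos(2 * pi * (t - phi) / tau)` by
#' Levenberg-Marquardt least squares, initialized from the dominant Fourier
#' component whose period lies in `period_window`. The relative amplitude
#' error (RAE) is the half-width of the amplitude's 95% confidence interval
#' (from the NLLS covariance) divided by the amplitude estimate; goodness of
#' fit is `1 - SSR/SST`. When no Fourier peak falls in the window or the fit
#' fails, a non-initiated fit with `RAE = Inf` is returned.
#'
#' @param trace data.frame with `time_h`, `signal` (detrended/smoothed or
#'   raw; a constant offset is absorbed by `c`).
#' @param period_window admissible period range (h) for the initialization
#'   (default 18-40 h).
#' @param tau_bounds hard bounds on the fitted period (default 12-48 h).
#' @return A list of class `rhythm_fit`: `period_h`, `phase_h` (time of
#'   fitted peak in \[0, tau)), `amplitude`, `damping_per_h`, `offset`,
#'   `rae`, `gof`, `initiated` (see [classify_initiated()]), `n`.
#' @export
fit_rhythm <- function(trace, period_window = c(18, 40),
                       tau_bounds = c(12, 48)) {
  t <- .check_trace(trace)
  y <- trace$signal
  dur <- t[length(t)] - t[1]
  if (dur < 2 * period_window[1])
    stop("trace must span at least two putative periods")

  failed <- function() {
    f <- list(period_h = NA_real_, phase_h = NA_real_, amplitude = NA_real_,
              damping_per_h = NA_real_, offset = mean(y), rae = Inf,
              gof = 0, initiated = FALSE, n = length(y))
    class(f) <- "rhythm_fit"
    f
  }
  init <- .fft_init(t, y, period_window)
  if (is.null(init) || init$A == 0) return(failed())

  d <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c0 + A * exp(-lam * t) * cos(2 * pi * (t - phi) / tau),
      data = d,
      start = list(c0 = mean(y), A = init$A, lam = 0.001,
                   tau = init$tau, phi = init$phi),
      lower = c(c0 = -Inf, A = 0, lam = 0, tau = tau_bounds[1],
                phi = -2 * tau_bounds[2]),
      upper = c(c0 = Inf, A = Inf, lam = 1, tau = tau_bounds[2],
                phi = 2 * tau_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())

  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  if (is.null(se) || !is.finite(se["A"]) || cf[["A"]] <= 0) return(failed())
  dfree <- length(y) - length(cf)
  rae <- stats::qt(0.975, dfree) * se[["A"]] / cf[["A"]]
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  out <- list(period_h = cf[["tau"]],
              phase_h = cf[["phi"]] %% cf[["tau"]],
              amplitude = cf[["A"]],
              damping_per_h = cf[["lam"]],
              offset = cf[["c0"]],
              rae = rae,
              gof = if (sst > 0) 1 - ssr / sst else 0,
              initiated = FALSE,
              n = length(y))
  out$initiated <- classify_initiated(out)
  class(out) <- "rhythm_fit"
  out
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf(
    "rhythm_fit: tau = %.2f h, phase = %.2f h, A = %.3g, lambda = %.4f /h,\n  RAE = %.3f, GOF = %.3f, initiated = %s\n",
    x$period_h, x$phase_h, x$amplitude, x$damping_per_h, x$rae, x$gof,
    x$initiated))
  invisible(x)
}

#' Classify a fit as initiated (rhythmic)
#'
#' A fit is initiated when the fitted period lies within the admissible range
#' (bounds inclusive, default 23.5-34.5 h) and the relative amplitude error is
#' strictly below the cutoff (default 0.3).
#'
#' @param fit a `rhythm_fit` (or a list with `period_h` and `rae`).
#' @param period_range inclusive period bounds in hours.
#' @param rae_max strict RAE upper bound.
#' @return Logical.
#' @export
classify_initiated <- function(fit, period_range = c(23.5, 34.5),
                               rae_max = 0.3) {
  tau <- fit$period_h
  isTRUE(!is.na(tau) && tau >= period_range[1] && tau <= period_range[2] &&
           is.finite(fit$rae) && fit$rae < rae_max)
}

#' Rayleigh test of phase coherence
#'
#' Converts phases (hours) to angles `theta = 2 * pi * phase / period`,
#' computes the mean resultant length `R = |sum(exp(i * theta))| / n`, and the
#' Rayleigh p-value with Z = n R^2 using the finite-n corrected approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2))`.
#'
#' @param phases_h numeric vector of phases in hours (n >= 2).
#' @param period_h period defining the circle (default 24).
#' @return List: `R` in \[0, 1\], `p`, `n`, `mean_phase_h` (circular mean in
#'   \[0, period)).
#' @export
rayleigh_test <- function(phases_h, period_h = 24) {
  if (length(phases_h) < 2) stop("need at least 2 phases")
  theta <- 2 * pi * phases_h / period_h
  z <- sum(exp(1i * theta)) / length(theta)
  R <- Mod(z)
  n <- length(theta)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(1, max(0, p))
  list(R = R, p = p, n = n,
       mean_phase_h = (Arg(z) * period_h / (2 * pi)) %% period_h)
}

# signed circular difference a - b in (-period/2, period/2]
.circ_diff <- function(a, b, period) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Build a phase map from a grid of ROI traces
#'
#' Excludes ROIs whose mean raw signal falls below `signal_threshold` (removes
#' extra-tissue signal), detrends/smooths and fits the rest, classifies each
#' as initiated or not, and expresses initiated ROIs' phases relative to their
#' circular mean phase. Reports the initiated fraction over included ROIs and
#' the Rayleigh statistics of the initiated phases.
#'
#' @param grid an `roi_grid` from [simulate_roi_grid()], or a list of traces.
#' @param signal_threshold minimum mean raw signal for an ROI to be analysed.
#' @param baseline_window_h,smooth_window_h detrending parameters.
#' @param period_window period window for [fit_rhythm()].
#' @return A list of class `phase_map`: `fits` (per included ROI),
#'   `table` (data.frame: roi, row, col, included, initiated, period_h,
#'   phase_h, rel_phase_h, rae, gof), `initiated_fraction`, `rayleigh_R`,
#'   `rayleigh_p`, `mean_phase_h`.
#' @export
build_phase_map <- function(grid, signal_threshold,
                            baseline_window_h = 24, smooth_window_h = 2.5,
                            period_window = c(18, 40)) {
  traces <- if (inherits(grid, "roi_grid")) grid$traces else grid
  layout <- if (inherits(grid, "roi_grid")) grid$layout
            else data.frame(roi = seq_along(traces), row = NA, col = NA)
  if (!length(traces)) stop("empty ROI grid")

  mean_sig <- vapply(traces, function(tr) mean(tr$signal), numeric(1))
  included <- mean_sig >= signal_threshold
  if (!any(included)) stop("all ROIs excluded by the signal threshold")

  fits <- vector("list", length(traces))
  tab <- data.frame(roi = layout$roi, row = layout$row, col = layout$col,
                    included = included, initiated = FALSE,
                    period_h = NA_real_, phase_h = NA_real_,
                    rel_phase_h = NA_real_, rae = NA_real_, gof = NA_real_)
  for (i in which(included)) {
    f <- fit_rhythm(detrend_and_smooth(traces[[i]], baseline_window_h,
                                       smooth_window_h),
                    period_window = period_window)
    fits[[i]] <- f
    tab$initiated[i] <- f$initiated
    tab$period_h[i] <- f$period_h
    tab$phase_h[i] <- f$phase_h
    tab$rae[i] <- f$rae
    tab$gof[i] <- f$gof
  }
  init <- which(tab$initiated)
  ray <- list(R = NA_real_, p = NA_real_, mean_phase_h = NA_real_)
  if (length(init) >= 2) {
    per <- stats::median(tab$period_h[init])
    ray <- rayleigh_test(tab$phase_h[init], per)
    tab$rel_phase_h[init] <- .circ_diff(tab$phase_h[init], ray$mean_phase_h,
                                        per)
  }
  structure(list(fits = fits, table = tab,
                 initiated_fraction = mean(tab$initiated[included]),
                 rayleigh_R = ray$R, rayleigh_p = ray$p,
                 mean_phase_h = ray$mean_phase_h),
            class = "phase_map")
}

#' Detect peaks in a detrended trace
#'
#' Local maxima with prominence at least `prominence_frac` of the trace's
#' amplitude range and a minimum separation (default 16 h, suited to
#' circadian rhythms). Prominence is measured against the higher of the two
#' minima flanking the peak out to the nearest higher points.
#'
#' @param trace data.frame with `time_h`, `signal` (detrended/smoothed).
#' @param prominence_frac minimum prominence as a fraction of the signal
#'   range (default 0.2).
#' @param min_separation_h minimum spacing between reported peaks (h).
#' @param troughs detect minima instead of maxima.
#' @return Numeric vector of peak times (possibly empty).
#' @export
detect_peaks <- function(trace, prominence_frac = 0.2, min_separation_h = 16,
                         troughs = FALSE) {
  t <- .check_trace(trace)
  y <- if (troughs) -trace$signal else trace$signal
  n <- length(y)
  rng <- diff(range(y))
  if (rng == 0) return(numeric(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L   # strict local maxima
  if (!length(cand)) return(numeric(0))

  prom <- vapply(cand, function(i) {
    left <- y[seq_len(i - 1)]
    right <- y[seq.int(i + 1, n)]
    hl <- which(left > y[i]); lo_l <- if (length(hl)) min(left[seq.int(max(hl), i - 1)]) else min(left)
    hr <- which(right > y[i]); lo_r <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
    y[i] - max(lo_l, lo_r)
  }, numeric(1))

  keep <- cand[prom >= prominence_frac * rng]
  if (!length(keep)) return(numeric(0))
  # enforce separation, keeping higher peaks first
  keep <- keep[order(-y[keep])]
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel) || all(abs(t[i] - t[sel]) >= min_separation_h))
      sel <- c(sel, i)
  }
  sel <- sort(sel)
  # sub-sample refinement: least-squares quadratic over a +/- 2.5 h window
  # around each detected maximum (robust to sample-level noise)
  dt <- stats::median(diff(t))
  win <- max(3.5, 2 * dt)
  vapply(sel, function(i) {
    # symmetric window (shrunk near trace edges to avoid vertex bias)
    win_i <- min(win, t[i] - t[1], t[n] - t[i])
    if (win_i < 2 * dt) return(t[i])
    w <- which(t >= t[i] - win_i & t <= t[i] + win_i)
    if (length(w) < 5) return(t[i])
    tc <- t[w] - t[i]
    fit <- stats::lm.fit(cbind(1, tc, tc^2), y[w])
    b <- fit$coefficients
    if (!is.finite(b[3]) || b[3] >= 0) return(t[i])
    vertex <- -b[2] / (2 * b[3])
    if (abs(vertex) > win_i) return(t[i])
    t[i] + vertex
  }, numeric(1))
}

#' Phase shift induced by a treatment
#'
#' Detrends/smooths the trace, detects peaks, regresses the pre-treatment
#' peak times on their cycle index (slope = free-running period), projects
#' the expected peak schedule past the treatment, and returns the mean
#' deviation (observed - expected) over the first three post-treatment peaks.
#' Positive values are phase delays.
#'
#' @param trace data.frame with `time_h`, `signal` (raw).
#' @param treatment_time_h time of treatment (h).
#' @param n_post number of post-treatment peaks averaged (default 3).
#' @param ... passed to [detect_peaks()].
#' @return List: `shift_h`, `period_pre_h`, `peaks_pre`, `peaks_post`.
#' @export
phase_shift <- function(trace, treatment_time_h, n_post = 3, ...) {
  dtr <- detrend_and_smooth(trace)
  pk <- detect_peaks(dtr, ...)
  pre <- pk[pk < treatment_time_h]
  post <- pk[pk >= treatment_time_h]
  if (length(pre) < 3 || length(post) < 3)
    stop("need at least 3 peaks before and after treatment (found ",
         length(pre), " and ", length(post), ")")
  # free-running period: NLLS on the raw pre-treatment segment (uses every
  # sample, so much tighter than a regression on a handful of peak times);
  # peak-time regression is the fallback when the fit is unusable
  sel <- trace$time_h < treatment_time_h
  pre_fit <- tryCatch(
    fit_rhythm(data.frame(time_h = trace$time_h[sel],
                          signal = trace$signal[sel])),
    error = function(e) NULL)
  idx <- round((pre - pre[1]) / stats::median(diff(pre)))
  per <- if (!is.null(pre_fit) && is.finite(pre_fit$period_h))
    pre_fit$period_h else stats::coef(stats::lm(pre ~ idx))[[2]]
  anchor <- mean(pre - per * idx)
  post <- utils::head(post, n_post)
  expected <- anchor + per * round((post - anchor) / per)
  shifts <- post - expected
  list(shift_h = mean(shifts), period_pre_h = per,
       peaks_pre = pre, peaks_post = post)
}

#' Baseline, amplitude and period changes across a treatment
#'
#' Cycles are anchored at troughs of the detrended/smoothed signal: the last
#' full pre-treatment cycle is the interval between the last two troughs
#' before treatment, and the first post-treatment cycle starts at the first
#' trough after treatment (spanning one such trough-to-trough interval).
#' Baseline is the cycle mean of the raw signal, amplitude is (peak - trough)
#' / 2 of the raw signal within the cycle, and relative changes are
#' (post - pre) / pre. The period change comes from [fit_rhythm()] on the
#' detrended pre- and post-treatment segments.
#'
#' @param trace data.frame with `time_h`, `signal` (raw).
#' @param treatment_time_h time of treatment (h).
#' @param ... passed to [detect_peaks()] for trough detection.
#' @return List: `delta_baseline_rel`, `delta_amplitude_rel`,
#'   `delta_period_h`, `baseline_pre`, `baseline_post`, `amplitude_pre`,
#'   `amplitude_post`, `period_pre_h`, `period_post_h`.
#' @export
waveform_changes <- function(trace, treatment_time_h, ...) {
  t <- .check_trace(trace)
  dtr <- detrend_and_smooth(trace)
  tr <- detect_peaks(dtr, troughs = TRUE, ...)
  pre_tr <- tr[tr < treatment_time_h]
  post_tr <- tr[tr >= treatment_time_h]
  if (length(pre_tr) < 2 || length(post_tr) < 2)
    stop("need at least one full cycle (two troughs) on each side of treatment")

  cyc_pre <- c(pre_tr[length(pre_tr) - 1], pre_tr[length(pre_tr)])
  cyc_post <- c(post_tr[1], post_tr[2])
  stat_cycle <- function(cyc) {
    sel <- t >= cyc[1] & t <= cyc[2]
    y <- trace$signal[sel]
    c(baseline = mean(y), amplitude = (max(y) - min(y)) / 2)
  }
  s_pre <- stat_cycle(cyc_pre)
  s_post <- stat_cycle(cyc_post)
  if (s_pre["baseline"] == 0 || s_pre["amplitude"] == 0)
    stop("pre-treatment baseline/amplitude is zero; relative change undefined")

  # detrend each side separately so the treatment step does not leak into
  # the moving-average baseline of the other segment
  seg <- function(lo, hi) {
    sel <- t >= lo & t <= hi
    detrend_and_smooth(data.frame(time_h = t[sel], signal = trace$signal[sel]))
  }
  f_pre <- fit_rhythm(seg(t[1], treatment_time_h))
  f_post <- fit_rhythm(seg(treatment_time_h, t[length(t)]))

  list(delta_baseline_rel = (s_post[["baseline"]] - s_pre[["baseline"]]) /
         s_pre[["baseline"]],
       delta_amplitude_rel = (s_post[["amplitude"]] - s_pre[["amplitude"]]) /
         s_pre[["amplitude"]],
       delta_period_h = f_post$period_h - f_pre$period_h,
       baseline_pre = s_pre[["baseline"]], baseline_post = s_post[["baseline"]],
       amplitude_pre = s_pre[["amplitude"]],
       amplitude_post = s_post[["amplitude"]],
       period_pre_h = f_pre$period_h, period_post_h = f_post$period_h)
}

#' Assemble a phase-response curve
#'
#' Bins phase shifts by the circadian time of treatment into fixed-width bins
#' anchored at CT0 (`[0, w), [w, 2w), ...`) and reports the per-bin mean, SEM
#' and n. Empty bins are reported with n = 0.
#'
#' @param treatment_ct treatment circadian times in \[0, 24).
#' @param shift_h phase shifts (h), aligned with `treatment_ct`.
#' @param bin_width_h bin width in hours (default 3; must divide 24).
#' @return data.frame: `bin_start_ct`, `bin_end_ct`, `n`, `mean_shift_h`,
#'   `sem_shift_h`.
#' @export
assemble_prc <- function(treatment_ct, shift_h, bin_width_h = 3) {
  if (length(treatment_ct) != length(shift_h))
    stop("treatment_ct and shift_h must align")
  if (any(treatment_ct < 0 | treatment_ct >= 24))
    stop("treatment CT values must lie in [0, 24)")
  if (24 %% bin_width_h != 0) stop("bin width must divide 24")
  starts <- seq(0, 24 - bin_width_h, by = bin_width_h)
  bin <- findInterval(treatment_ct, c(starts, 24))
  out <- lapply(seq_along(starts), function(b) {
    s <- shift_h[bin == b]
    data.frame(bin_start_ct = starts[b], bin_end_ct = starts[b] + bin_width_h,
               n = length(s),
               mean_shift_h = if (length(s)) mean(s) else NA_real_,
               sem_shift_h = if (length(s) > 1)
                 stats::sd(s) / sqrt(length(s)) else NA_real_)
  })
  do.call(rbind, out)
}

#' Map a phase to circadian time via a reference
#'
#' Given a reference oscillation whose peak phase has been assigned a
#' circadian time, converts another phase on the same cycle:
#' `CT = (reference_ct + (phase_h - reference_phase_h)) mod period`.
#' Warns when the two fits' periods differ by more than 1 h.
#'
#' @param phase_h phase to convert (h), or a `rhythm_fit`.
#' @param reference_phase_h reference phase (h), or a `rhythm_fit`.
#' @param reference_ct circadian time assigned to the reference phase.
#' @param period_h cycle length for the modulus (default 24; ignored when two
#'   fits are supplied, in which case the reference fit's period is used).
#' @return Circadian time in \[0, period).
#' @export
map_ct <- function(phase_h, reference_phase_h, reference_ct, period_h = 24) {
  if (inherits(phase_h, "rhythm_fit") &&
      inherits(reference_phase_h, "rhythm_fit")) {
    if (abs(phase_h$period_h - reference_phase_h$period_h) > 1)
      warning("periods differ by more than 1 h; CT mapping is approximate")
    period_h <- reference_phase_h$period_h
    phase_h <- phase_h$phase_h
    reference_phase_h <- reference_phase_h$phase_h
  }
  (reference_ct + (phase_h - reference_phase_h)) %% period_h
}

#' Write fitted-rhythm and phase-map result tables
#'
#' @param pm a `phase_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_map_csv <- function(pm, path) {
  stopifnot(inherits(pm, "phase_map"))
  utils::write.csv(pm$table, path, row.names = FALSE)
  invisible(path)
}
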