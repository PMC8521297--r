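#' Configuration for a synthetic bioluminescence trace
#'
#' Parameterizes a damped-cosine reporter trace,
#' \deqn{y(t) = b_0 + b_1 t (\mathrm{or}\; b_0 e^{b_1 t}) +
#'       A e^{-\lambda t} \cos(2\pi (t - \phi)/\tau) + \epsilon_t,}
#' with Gaussian noise of standard deviation `noise_sd`, sampled every
#' `sampling_interval_h` hours (the 30-min default mirrors typical long-term
#' imaging resolution). An optional `treatment` block changes parameters from
#' `treatment_time_h` onward: a phase shift (positive = delay), an amplitude
#' scale factor, an additive baseline shift, and/or a new period.
#'
#' @param period_h free-running period tau in hours.
#' @param phase_h phase phi in hours (time of first cosine peak).
#' @param amplitude amplitude A (arbitrary units).
#' @param damping_per_h exponential damping rate lambda (1/h, >= 0).
#' @param baseline_offset baseline intercept.
#' @param trend_slope linear trend slope (units/h) or exponential rate (1/h)
#'   depending on `trend`.
#' @param trend one of "linear", "exponential".
#' @param noise_sd additive Gaussian noise SD (>= 0).
#' @param sampling_interval_h sampling step (h); must be <= period/8.
#' @param duration_h total duration (h); must be >= 2 periods.
#' @param treatment optional list: `time_h`, and any of `phase_shift_h`,
#'   `amplitude_scale`, `baseline_shift`, `period_h`.
#' @param seed integer seed for the noise.
#' @return A list of class `rhythm_config`.
#' @export
rhythm_config <- function(period_h = 24, phase_h = 0, amplitude = 1,
                          damping_per_h = 0, baseline_offset = 0,
                          trend_slope = 0, trend = c("linear", "exponential"),
                          noise_sd = 0, sampling_interval_h = 0.5,
                          duration_h = 120, treatment = NULL, seed = 1L) {
  trend <- match.arg(trend)
  if (duration_h <= 0) stop("duration must be positive")
  if (period_h <= 0 || sampling_interval_h <= 0)
    stop("period and sampling interval must be positive")
  if (duration_h < 2 * period_h)
    stop("duration must be at least two periods for fit identifiability")
  if (sampling_interval_h > period_h / 8)
    stop("sampling interval must be <= period/8")
  if (damping_per_h < 0 || noise_sd < 0)
    stop("damping and noise_sd must be non-negative")
  structure(list(period_h = period_h, phase_h = phase_h, amplitude = amplitude,
                 damping_per_h = damping_per_h,
                 baseline_offset = baseline_offset, trend_slope = trend_slope,
                 trend = trend, noise_sd = noise_sd,
                 sampling_interval_h = sampling_interval_h,
                 duration_h = duration_h, treatment = treatment,
                 seed = as.integer(seed)),
            class = "rhythm_config")
}

# deterministic (noise-free) part of the configured trace
.rhythm_mean <- function(cfg, t) {
  base <- if (cfg$trend == "linear") {
    cfg$baseline_offset + cfg$trend_slope * t
  } else {
    cfg$baseline_offset * exp(cfg$trend_slope * t)
  }
  tau <- rep(cfg$period_h, length(t))
  phi <- rep(cfg$phase_h, length(t))
  amp <- rep(cfg$amplitude, length(t))
  off <- rep(0, length(t))
  tr <- cfg$treatment
  if (!is.null(tr)) {
    post <- t >= tr$time_h
    if (!is.null(tr$period_h)) tau[post] <- tr$period_h
    if (!is.null(tr$phase_shift_h)) phi[post] <- phi[post] + tr$phase_shift_h
    if (!is.null(tr$amplitude_scale)) amp[post] <- amp[post] * tr$amplitude_scale
    if (!is.null(tr$baseline_shift)) off[post] <- tr$baseline_shift
  }
  base + off + amp * exp(-cfg$damping_per_h * t) * cos(2 * pi * (t - phi) / tau)
}

#' Simulate a bioluminescence trace
#'
#' @param cfg a [rhythm_config].
#' @return A data.frame of class `biolum_trace` with columns `time_h` and
#'   `signal`; attributes `config` (the generating configuration) and
#'   `noiseless` (the deterministic component).
#' @export
simulate_biolum_trace <- function(cfg) {
  stopifnot(inherits(cfg, "rhythm_config"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration_h, by = cfg$sampling_interval_h)
  mu <- .rhythm_mean(cfg, t)
  y <- mu + stats::rnorm(length(t), 0, cfg$noise_sd)
  out <- data.frame(time_h = t, signal = y)
  attr(out, "config") <- cfg
  attr(out, "noiseless") <- mu
  class(out) <- c("biolum_trace", "data.frame")
  out
}

#' Simulate a grid of ROI traces with a planted phase gradient
#'
#' Emulates a CCD recording segmented into a rows x cols grid of regions of
#' interest (ROIs). A fixed fraction of ROIs is rhythmic; rhythmic ROIs follow
#' `base_cfg` with a phase offset linear in the column index spanning
#' `phase_gradient_h` hours from the first to the last column. Non-rhythmic
#' ROIs carry only baseline, trend and noise (zero amplitude). Each ROI gets
#' an independent noise stream derived from `base_cfg$seed`.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param rhythmic_fraction fraction of ROIs that oscillate, in \[0, 1\].
#' @param phase_gradient_h total phase span (h) across columns.
#' @param base_cfg a [rhythm_config] used for every ROI (per-ROI phase/seed
#'   adjusted as described).
#' @return A list of class `roi_grid`: `traces` (list of `biolum_trace`),
#'   `layout` (data.frame: roi, row, col, rhythmic, true_phase_h),
#'   `config` = base_cfg.
#' @export
simulate_roi_grid <- function(n_rows, n_cols, rhythmic_fraction,
                              phase_gradient_h = 0, base_cfg) {
  stopifnot(inherits(base_cfg, "rhythm_config"))
  if (rhythmic_fraction < 0 || rhythmic_fraction > 1)
    stop("rhythmic_fraction must be in [0, 1]")
  n <- n_rows * n_cols
  set.seed(base_cfg$seed)
  n_rhythmic <- round(rhythmic_fraction * n)
  rhythmic <- rep(FALSE, n)
  rhythmic[sample.int(n, n_rhythmic)] <- TRUE
  row <- rep(seq_len(n_rows), times = n_cols)
  col <- rep(seq_len(n_cols), each = n_rows)
  col_off <- if (n_cols > 1) (col - 1) / (n_cols - 1) * phase_gradient_h else 0
  traces <- vector("list", n)
  true_phase <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cfg_i <- base_cfg
    cfg_i$seed <- base_cfg$seed + i
    if (rhythmic[i]) {
      cfg_i$phase_h <- base_cfg$phase_h + col_off[i]
      true_phase[i] <- cfg_i$phase_h
    } else {
      cfg_i$amplitude <- 0
    }
    class(cfg_i) <- "rhythm_config"
    tr <- simulate_biolum_trace(cfg_i)
    tr$roi <- i
    traces[[i]] <- tr
  }
  structure(list(traces = traces,
                 layout = data.frame(roi = seq_len(n), row = row, col = col,
                                     rhythmic = rhythmic,
                                     true_phase_h = true_phase),
                 config = base_cfg),
            class = "roi_grid")
}

#' Read / write trace CSV files
#'
#' Traces are exchanged as CSV with columns `time_h`, `signal` and optionally
#' `roi_id`.
#'
#' @param path CSV path.
#' @return `read_trace_csv`: a `biolum_trace` data.frame (or a list of them,
#'   one per ROI, when `roi_id` is present).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "signal") %in% names(d)))
    stop("trace CSV must have columns time_h and signal: ", path)
  if ("roi_id" %in% names(d)) {
    out <- lapply(split(d, d$roi_id), function(x) {
      tr <- data.frame(time_h = x$time_h, signal = x$signal, roi = x$roi_id[1])
      class(tr) <- c("biolum_trace", "data.frame")
      tr
    })
    return(out)
  }
  class(d) <- c("biolum_trace", "data.frame")
  d
}

#' @rdname read_trace_csv
#' @param trace a trace data.frame (or list of them with `roi` columns).
#' @export
write_trace_csv <- function(trace, path) {
  if (is.list(trace) && !is.data.frame(trace)) {
    d <- do.call(rbind, lapply(trace, function(x)
      data.frame(time_h = x$time_h, signal = x$signal,
                 roi_id = if ("roi" %in% names(x)) x$roi else NA)))
  } else {
    d <- as.data.frame(trace)[, intersect(c("time_h", "signal", "roi"),
                                          names(trace))]
    names(d)[names(d) == "roi"] <- "roi_id"
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
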