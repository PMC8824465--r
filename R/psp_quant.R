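# Quality control, baselining, exponential deconvolution, PSP detection
# windows and metrics (amplitude, CV, rise time, paired-pulse ratio, rundown).
#
# The central tool is the exponential deconvolution D(t) = V(t) + tau dV/dt
# (tau = 20 ms by default), which collapses a PSP with decay constant tau to
# an impulse at its onset and so sharpens the timing of superposed synaptic
# events. Derivatives use central differences (forward/backward at the
# edges). All detection operates on one polarity: IPSP trains recorded at
# depolarized holding are sign-flipped upstream so a single pipeline serves
# both polarities.

#' Deconvolution and detection parameters
#'
#' @param tau deconvolution time constant (ms); 20 ms by default
#' @param threshold_multiple detection threshold in multiples of the
#'   pre-stimulus SD of the deconvolved trace (default 5)
#' @param search_window_ms window after stimulus onset searched for
#'   deconvolved peaks (default 0-50 ms)
#' @param baseline_window_ms pre-onset window for the baseline SD (default 20)
#' @return list of class `deconv_params`
#' @export
deconv_params <- function(tau = 20, threshold_multiple = 5,
                          search_window_ms = 50, baseline_window_ms = 20) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  structure(list(tau = tau, threshold_multiple = threshold_multiple,
                 search_window_ms = search_window_ms,
                 baseline_window_ms = baseline_window_ms),
            class = "deconv_params")
}

#' Quality-control sweeps before PSP measurement
#'
#' A sweep is rejected if the median voltage in the 50 ms preceding the
#' photostimulus differs from the target holding potential by more than
#' 5 mV, or if the voltage drifts by more than 1 mV within that window
#' (measured as the difference between the medians of its last and first
#' 10 ms, which is robust to sample noise but catches ramps and large
#' spontaneous events).
#'
#' @param epochs list of [trace_epoch()]
#' @param holding_target target holding potential (mV); defaults to the
#'   epochs' recorded target
#' @param max_offset_mv rejection threshold on the holding offset
#' @param max_drift_mv rejection threshold on the within-window drift
#' @return the accepted epochs, with attribute `n_rejected`
#' @export
qc_sweeps <- function(epochs, holding_target = NULL, max_offset_mv = 5,
                      max_drift_mv = 1) {
  keep <- vapply(epochs, function(ep) {
    dt_ms <- ep$sample_interval * 1000
    n50 <- ms_to_samples(50, ep$sample_interval)
    n10 <- ms_to_samples(10, ep$sample_interval)
    pre <- ep$voltage[(ep$stim_onset_index - n50):(ep$stim_onset_index - 1L)]
    target <- holding_target %||% ep$holding_target
    offset_ok <- abs(stats::median(pre) - target) <= max_offset_mv
    drift_ok <- abs(stats::median(utils::tail(pre, n10)) -
                      stats::median(utils::head(pre, n10))) <= max_drift_mv
    offset_ok && drift_ok
  }, logical(1))
  out <- epochs[keep]
  if (!length(out)) warning("all sweeps rejected by QC", call. = FALSE)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Baseline-subtract a sweep
#'
#' Subtracts the median membrane potential of the 20 ms window preceding
#' stimulus onset, so the baselined pre-stimulus median is exactly zero.
#'
#' @param epoch a [trace_epoch()]
#' @return the epoch with baselined voltage
#' @export
baseline_subtract <- function(epoch) {
  n20 <- ms_to_samples(20, epoch$sample_interval)
  win <- epoch$voltage[(epoch$stim_onset_index - n20):
                         (epoch$stim_onset_index - 1L)]
  epoch$voltage <- epoch$voltage - stats::median(win)
  epoch
}

#' Average baselined sweeps into one response
#'
#' @param epochs list of [trace_epoch()] of equal length
#' @return a [trace_epoch()] whose voltage is the pointwise mean of the
#'   baselined sweeps
#' @export
average_response <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  b <- lapply(epochs, baseline_subtract)
  v <- rowMeans(do.call(cbind, lapply(b, `[[`, "voltage")))
  out <- b[[1]]
  out$voltage <- v
  out$sweep_index <- NA_integer_
  out
}

#' Exponential deconvolution of a voltage trace
#'
#' Computes `D(t) = V(t) + tau * dV/dt` with central differences in the
#' interior and one-sided differences at the edges. For a pure exponential
#' decay with matching tau the result is zero except at the onset, so
#' overlapping PSPs are separated into distinct impulses.
#'
#' @param voltage numeric vector (mV), uniformly sampled
#' @param tau deconvolution time constant (ms)
#' @param dt sample interval (s)
#' @return numeric vector, same length as `voltage`
#' @export
deconvolve <- function(voltage, tau, dt) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  n <- length(voltage)
  dt_ms <- dt * 1000
  dv <- numeric(n)
  dv[2:(n - 1)] <- (voltage[3:n] - voltage[1:(n - 2)]) / (2 * dt_ms)
  dv[1] <- (voltage[2] - voltage[1]) / dt_ms
  dv[n] <- (voltage[n] - voltage[n - 1]) / dt_ms
  voltage + tau * dv
}

# deconvolved baseline SD over the pre-onset window (params$baseline_window_ms)
deconv_baseline_sd <- function(dec, epoch, params) {
  nb <- ms_to_samples(params$baseline_window_ms, epoch$sample_interval)
  stats::sd(dec[(epoch$stim_onset_index - nb):(epoch$stim_onset_index - 1L)])
}

# centered boxcar smoothing; at high sampling rates the derivative term of
# the deconvolution amplifies sample-scale noise, so detection operates on a
# lightly smoothed copy (the deconvolved trace itself is never altered)
boxcar_smooth <- function(x, width_ms, dt_s) {
  w <- max(1L, ms_to_samples(width_ms, dt_s))
  if (w %% 2 == 0) w <- w + 1L
  if (w <= 1) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  as.numeric(sm)
}

# merge local maxima closer than min_sep_ms, keeping the larger
merge_close_peaks <- function(peaks, values, min_sep_ms, dt_s) {
  if (length(peaks) < 2) return(peaks)
  min_sep <- ms_to_samples(min_sep_ms, dt_s)
  keep <- peaks[order(values[peaks], decreasing = TRUE)]
  chosen <- integer(0)
  for (p in keep) {
    if (!length(chosen) || all(abs(chosen - p) >= min_sep)) {
      chosen <- c(chosen, p)
    }
  }
  sort(chosen)
}

# indices of strict local maxima of x restricted to idx (first sample wins ties)
local_maxima <- function(x, idx) {
  n <- length(x)
  keep <- idx[idx > 1 & idx < n]
  keep[x[keep] >= x[keep - 1] & x[keep] > x[keep + 1]]
}

#' Detect PSP windows from an averaged response
#'
#' The averaged, baselined trace is deconvolved and searched for peaks in the
#' 0-50 ms post-onset window exceeding `threshold_multiple` times the
#' pre-stimulus SD of the deconvolved trace. With a single peak the
#' measurement window runs from the first threshold crossing to 20 ms later;
#' with multiple peaks the windows are truncated at the inter-peak minima of
#' the deconvolved trace. No crossing returns an empty result.
#'
#' @param avg an averaged, baselined [trace_epoch()] (see
#'   [average_response()]); expected polarity positive (flip IPSPs first)
#' @param params a [deconv_params()]
#' @param smooth_ms boxcar width (ms) applied to the deconvolved trace for
#'   detection only; 0 disables
#' @param min_peak_sep_ms local maxima closer than this are treated as one
#'   peak
#' @return list of class `psp_windows`: elements `windows` (list of
#'   `c(start, end)` sample indices), `peak_times_ms`, `threshold`,
#'   `deconvolved` (the smoothed deconvolved average used for detection),
#'   `onset_index`
#' @export
detect_psp_window <- function(avg, params = deconv_params(),
                              smooth_ms = 0.5, min_peak_sep_ms = 2) {
  dec <- deconvolve(avg$voltage, params$tau, avg$sample_interval)
  if (smooth_ms > 0) dec <- boxcar_smooth(dec, smooth_ms, avg$sample_interval)
  sd0 <- deconv_baseline_sd(dec, avg, params)
  thr <- params$threshold_multiple * sd0
  on <- avg$stim_onset_index
  n_search <- ms_to_samples(params$search_window_ms, avg$sample_interval)
  search <- on:min(length(dec), on + n_search)
  above <- search[dec[search] > thr]
  empty <- structure(list(windows = list(), peak_times_ms = numeric(0),
                          threshold = thr, deconvolved = dec,
                          onset_index = on), class = "psp_windows")
  if (!length(above)) return(empty)
  first_cross <- above[1]
  peaks <- local_maxima(dec, search)
  peaks <- peaks[dec[peaks] > thr]
  if (!length(peaks)) peaks <- search[which.max(dec[search])]
  peaks <- merge_close_peaks(peaks, dec, min_peak_sep_ms, avg$sample_interval)
  # keep only peaks separated by a valley that falls at least half-way back
  # to threshold relative to the smaller peak (distinct deconvolved events)
  if (length(peaks) > 1) {
    keep <- peaks[which.max(dec[peaks])]
    for (p in peaks[order(dec[peaks], decreasing = TRUE)][-1]) {
      ok <- all(vapply(keep, function(q) {
        seg <- min(p, q):max(p, q)
        valley <- min(dec[seg])
        valley < thr + 0.5 * (min(dec[p], dec[q]) - thr)
      }, logical(1)))
      if (ok) keep <- c(keep, p)
    }
    peaks <- sort(keep)
  }
  dt_ms <- avg$sample_interval * 1000
  n20 <- ms_to_samples(20, avg$sample_interval)
  windows <- list()
  if (length(peaks) == 1) {
    windows[[1]] <- c(first_cross, min(length(dec), first_cross + n20))
  } else {
    bounds <- first_cross
    for (k in seq_len(length(peaks) - 1)) {
      seg <- peaks[k]:peaks[k + 1]
      bounds <- c(bounds, seg[which.min(dec[seg])])
    }
    bounds <- c(bounds, min(length(dec), peaks[length(peaks)] + n20,
                            on + n_search))
    for (k in seq_along(peaks)) {
      windows[[k]] <- c(bounds[k], bounds[k + 1])
    }
  }
  structure(list(windows = windows,
                 peak_times_ms = (peaks - on) * dt_ms,
                 threshold = thr, deconvolved = dec, onset_index = on),
            class = "psp_windows")
}

#' Measure PSP amplitude and CV in a detection window
#'
#' Amplitude is the peak of the averaged response within the window; the CV
#' is the SD/mean of the per-sweep peaks measured in the same window.
#'
#' @param epochs list of [trace_epoch()] (QC'd; baselining is applied here)
#' @param window `c(start, end)` sample indices from [detect_psp_window()]
#' @return list with `amplitude` (mV), `cv`, `peak_index`,
#'   `per_sweep_peaks`, `n_accepted_sweeps`
#' @export
measure_amplitude_cv <- function(epochs, window) {
  if (is.null(window) || length(window) < 2) {
    return(list(amplitude = NA_real_, cv = NA_real_, peak_index = NA_integer_,
                per_sweep_peaks = numeric(0), n_accepted_sweeps = 0L))
  }
  idx <- window[1]:window[2]
  avg <- average_response(epochs)
  pk <- idx[which.max(avg$voltage[idx])]
  sweeps <- vapply(epochs, function(ep) {
    max(baseline_subtract(ep)$voltage[idx])
  }, numeric(1))
  list(amplitude = avg$voltage[pk],
       cv = stats::sd(sweeps) / mean(sweeps),
       peak_index = pk,
       per_sweep_peaks = sweeps,
       n_accepted_sweeps = length(epochs))
}

#' 20-80% rise time of the averaged response
#'
#' Linear interpolation between the samples bracketing the 20% and 80%
#' crossings on the rising phase before the window peak. Responses of
#' 0.1 mV or less are considered too close to the spontaneous background
#' and return NA.
#'
#' @param avg averaged baselined [trace_epoch()]
#' @param window `c(start, end)` sample indices
#' @param min_amplitude_mv minimum amplitude for a defined rise time
#' @return rise time in ms, or NA
#' @export
rise_time <- function(avg, window, min_amplitude_mv = 0.1) {
  idx <- window[1]:window[2]
  v <- avg$voltage
  pk <- idx[which.max(v[idx])]
  amp <- v[pk]
  if (!is.finite(amp) || amp <= min_amplitude_mv) return(NA_real_)
  dt_ms <- avg$sample_interval * 1000
  cross_time <- function(frac) {
    level <- frac * amp
    i <- pk
    while (i > 1 && v[i - 1] > level) i <- i - 1
    if (i == 1 || v[i] < level) return(NA_real_)
    # interpolate between i-1 (below) and i (at/above)
    (i - 1 + (level - v[i - 1]) / (v[i] - v[i - 1])) * dt_ms
  }
  t20 <- cross_time(0.2); t80 <- cross_time(0.8)
  t80 - t20
}

#' Paired-pulse ratio via per-sweep deconvolution
#'
#' For photoresponses with two distinct PSPs, each sweep is deconvolved and
#' the peaks inside two operator-set, non-overlapping windows are measured;
#' the sweep PPR is peak2/peak1 and the inter-PSP interval is the difference
#' of peak times. When `tau = NULL` the time constant is chosen from
#' {5, 10, 15, 20} ms to minimize the absolute mean of the deconvolved trace
#' in the 10 ms after the second peak (avoiding baseline overshoot or
#' undershoot). Population summaries use only sweeps with an estimated
#' interval between `interval_range` (5-10 ms by default).
#'
#' @param epochs list of [trace_epoch()]
#' @param window_1,window_2 `c(start, end)` sample indices; must not overlap
#' @param tau deconvolution tau (ms) or NULL for the automatic grid
#' @param interval_range inter-PSP interval filter (ms) for the summary PPR
#' @return list of class `psp_train`: per-sweep `ppr`, `interval_ms`,
#'   `peak_1`, `peak_2`; summary `ppr_mean` over interval-filtered sweeps;
#'   `tau_used`
#' @export
paired_pulse_ratio <- function(epochs, window_1, window_2, tau = NULL,
                               interval_range = c(5, 10)) {
  if (max(window_1) > min(window_2)) {
    stop("windows must be non-overlapping and ordered", call. = FALSE)
  }
  dt <- epochs[[1]]$sample_interval
  dt_ms <- dt * 1000
  b <- lapply(epochs, baseline_subtract)
  taus <- if (is.null(tau)) c(5, 10, 15, 20) else tau
  score <- function(tt) {
    # mean |D| in a 10 ms window after the second deconvolved peak (skipping
    # the peak itself): overshoot and undershoot of the baseline both raise
    # the score, so the grid picks the tau closest to the true decay
    avg <- rowMeans(do.call(cbind, lapply(b, `[[`, "voltage")))
    dec <- deconvolve(avg, tt, dt)
    i2 <- window_2[1]:window_2[2]
    pk2 <- i2[which.max(dec[i2])]
    after <- min(length(dec), pk2 + ms_to_samples(3, dt)):
      min(length(dec), pk2 + ms_to_samples(13, dt))
    mean(abs(dec[after]))
  }
  tau_used <- if (length(taus) == 1) taus else taus[which.min(vapply(taus, score, numeric(1)))]
  i1 <- window_1[1]:window_1[2]; i2 <- window_2[1]:window_2[2]
  per <- vapply(b, function(ep) {
    dec <- deconvolve(ep$voltage, tau_used, dt)
    p1i <- i1[which.max(dec[i1])]; p2i <- i2[which.max(dec[i2])]
    c(peak_1 = dec[p1i], peak_2 = dec[p2i],
      interval_ms = (p2i - p1i) * dt_ms)
  }, numeric(3))
  peak_1 <- per["peak_1", ]; peak_2 <- per["peak_2", ]
  ppr <- ifelse(peak_1 > 0, peak_2 / peak_1, NA_real_)
  interval <- per["interval_ms", ]
  in_range <- is.finite(ppr) & interval >= interval_range[1] &
    interval <= interval_range[2]
  structure(list(peak_1 = peak_1, peak_2 = peak_2, ppr = ppr,
                 interval_ms = interval,
                 ppr_mean = if (any(in_range)) mean(ppr[in_range]) else NA_real_,
                 n_in_range = sum(in_range), tau_used = tau_used),
            class = "psp_train")
}

#' Amplitude rundown over repeated photostimulation
#'
#' Ordinary least-squares slope of PSP amplitude against stimulus number,
#' expressed as percent of the initial (fitted) amplitude per stimulus, so a
#' linear 1%-per-sweep decay reads exactly -1.0.
#'
#' @param amplitudes per-sweep PSP amplitudes, in stimulus order
#' @return percent change per stimulus (negative = rundown)
#' @export
rundown <- function(amplitudes) {
  ok <- is.finite(amplitudes)
  if (sum(ok) < 5) stop("need at least 5 sweeps with defined amplitudes",
                        call. = FALSE)
  x <- seq_along(amplitudes)[ok] - 1
  y <- amplitudes[ok]
  co <- stats::coef(stats::lm(y ~ x))
  ref <- if (co[[1]] > 0) co[[1]] else mean(y)
  100 * co[[2]] / ref
}

#' Full PSP quantification for one probed pair
#'
#' Convenience wrapper running QC, baselining, detection and measurement,
#' returning the metrics recorded in the connection table.
#'
#' @param epochs list of [trace_epoch()]
#' @param polarity +1 for EPSPs, -1 for IPSPs
#' @param params a [deconv_params()]
#' @return list with amplitude, cv, rise_time_ms, onset_ms,
#'   n_accepted_sweeps, windows
#' @export
quantify_psp <- function(epochs, polarity = 1, params = deconv_params()) {
  acc <- qc_sweeps(epochs)
  if (!length(acc)) {
    return(list(amplitude = NA_real_, cv = NA_real_, rise_time_ms = NA_real_,
                onset_ms = NA_real_, n_accepted_sweeps = 0L, windows = list()))
  }
  if (polarity < 0) {
    acc <- lapply(acc, function(ep) { ep$voltage <- -ep$voltage; ep })
  }
  avg <- average_response(acc)
  det <- detect_psp_window(avg, params)
  if (!length(det$windows)) {
    return(list(amplitude = NA_real_, cv = NA_real_, rise_time_ms = NA_real_,
                onset_ms = NA_real_, n_accepted_sweeps = length(acc),
                windows = det))
  }
  w <- det$windows[[1]]
  m <- measure_amplitude_cv(acc, w)
  dt_ms <- avg$sample_interval * 1000
  list(amplitude = m$amplitude, cv = m$cv,
       rise_time_ms = rise_time(avg, w),
       onset_ms = (w[1] - avg$stim_onset_index) * dt_ms,
       n_accepted_sweeps = m$n_accepted_sweeps, windows = det)
}
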