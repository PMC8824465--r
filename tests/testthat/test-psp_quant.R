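# QC, baselining, deconvolution, detection windows, amplitude/CV, rise time,
# paired-pulse ratio and rundown.

test_that("QC rejects holding offsets beyond 5 mV and pre-stimulus drift", {
  good <- flat_epoch()
  off6 <- flat_epoch(value = -64)            # 6 mV above target
  ramp <- flat_epoch()
  n50 <- round(0.05 / DT25)
  ramp$voltage[(2501 - n50):2500] <-
    -70 + seq(0, 1.5, length.out = n50 + 1)[-1]  # 1.5 mV ramp
  acc <- qc_sweeps(list(good, off6, ramp), holding_target = -70)
  expect_length(acc, 1)
  expect_equal(attr(acc, "n_rejected"), 2L)
  expect_warning(qc_sweeps(list(off6), holding_target = -70), "rejected")
})

test_that("baseline subtraction zeroes the 20 ms pre-stimulus median", {
  expect_true(all(baseline_subtract(flat_epoch())$voltage == 0))
  # DC shifts are removed exactly
  e1 <- flat_epoch(add = psp_trace(0.6))
  e2 <- flat_epoch(add = psp_trace(0.6) + 3)
  expect_equal(baseline_subtract(e1)$voltage, baseline_subtract(e2)$voltage)
  # noisy fixture: recomputed median of the window is exactly 0
  set.seed(2)
  noisy <- flat_epoch(add = stats::rnorm(6250, 0, 0.3))
  b <- baseline_subtract(noisy)
  n20 <- round(0.02 / DT25)
  expect_equal(stats::median(b$voltage[(2501 - n20):2500]), 0)
})

test_that("deconvolution is exact on constants and matched exponentials", {
  dt <- DT25
  expect_equal(deconvolve(rep(3.2, 1000), 20, dt), rep(3.2, 1000))
  # A exp(-t/tau) deconvolved with the same tau vanishes after onset
  t_ms <- (0:4999) * dt * 1000
  v <- 2 * exp(-t_ms / 20)
  d <- deconvolve(v, 20, dt)
  expect_lt(max(abs(d[10:4990])), 1e-4)
  expect_error(deconvolve(v, 0, dt), "positive")
})

test_that("deconvolution is linear and matches the analytic derivative", {
  dt <- DT25
  set.seed(5)
  v1 <- stats::rnorm(2000); v2 <- stats::rnorm(2000)
  expect_equal(deconvolve(2 * v1 - 3 * v2, 20, dt),
               2 * deconvolve(v1, 20, dt) - 3 * deconvolve(v2, 20, dt),
               tolerance = 1e-12)
  # closed-form derivative oracle for a double exponential
  t_ms <- (0:6249 - 2500) * dt * 1000
  r <- 1.5; dc <- 18
  tstar <- log(dc / r) * r * dc / (dc - r)
  peak <- exp(-tstar / dc) - exp(-tstar / r)
  v <- ifelse(t_ms >= 0, (exp(-t_ms / dc) - exp(-t_ms / r)) / peak, 0)
  dv <- ifelse(t_ms >= 0, (-exp(-t_ms / dc) / dc + exp(-t_ms / r) / r) / peak, 0)
  d_oracle <- v + 20 * dv
  d <- deconvolve(v, 20, dt)
  # central differences are second-order accurate: the residual against the
  # closed form is bounded by dt^2/6 * max|f'''| * tau, about 2e-3 mV here
  interior <- 2510:6240  # away from the onset kink
  expect_lt(max(abs(d[interior] - d_oracle[interior])), 2e-3)
  # deconvolved peak lands within one sample of the analytic maximum
  i_pk <- which.max(d[2501:6250])
  i_or <- which.max(d_oracle[2501:6250])
  expect_lte(abs(i_pk - i_or), 1)
})

test_that("detection finds no window on noise and one window on a PSP", {
  set.seed(9)
  hits <- vapply(1:100, function(i) {
    eps <- lapply(1:10, function(s) {
      flat_epoch(add = as.numeric(stats::filter(
        stats::rnorm(6250, 0, 0.05 * sqrt(1 - exp(-2 * DT25 * 1000 / 5))),
        exp(-DT25 * 1000 / 5), method = "recursive")))
    })
    length(detect_psp_window(average_response(eps))$windows) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.01)
  # a 1 mV PSP at 5 ms latency gives one window starting within 1 ms of 5 ms
  eps <- gen_photoresponse(quantal_synapse(1, 1, 1),
                           spiking_model(latency_mean = 3.5, jitter_sd = 0,
                                         n_spikes_prob = c(1, 0, 0)),
                           noise_model(baseline_sd = 0.05, spont_rate = 0),
                           n_sweeps = 10, seed = 4)
  # synaptic latency 1.5 ms -> PSP onset at 5 ms
  det <- detect_psp_window(average_response(eps))
  expect_length(det$windows, 1)
  onset_ms <- (det$windows[[1]][1] - det$onset_index) * DT25 * 1000
  expect_lt(abs(onset_ms - 5), 1)
})

test_that("two PSPs 8 ms apart produce windows split at the minimum", {
  v <- psp_trace(1, 5) + psp_trace(0.8, 13)
  det <- detect_psp_window(average_response(list(flat_epoch(add = v))))
  expect_length(det$windows, 2)
  expect_equal(det$windows[[1]][2], det$windows[[2]][1])
  sep_ms <- diff(det$peak_times_ms)
  expect_equal(sep_ms, 8, tolerance = 1.5)
})

test_that("amplitude and CV come from the right windows", {
  eps <- lapply(1:5, function(s) flat_epoch(add = psp_trace(0.3)))
  det <- detect_psp_window(average_response(eps))
  m <- measure_amplitude_cv(eps, det$windows[[1]])
  expect_equal(m$amplitude, 0.3, tolerance = 1e-3)
  expect_equal(m$cv, 0)          # identical sweeps
  expect_equal(m$n_accepted_sweeps, 5L)
})

test_that("rise time interpolates 20-80% crossings", {
  # linear ramp 0 -> 1 over 10 ms: rise = 6 ms
  n <- 6250; onset <- 2501
  v <- rep(0, n)
  ramp <- onset:(onset + 250)
  v[ramp] <- seq(0, 1, length.out = 251)
  v[(onset + 251):n] <- 1
  avg <- average_response(list(flat_epoch(add = v)))
  expect_equal(rise_time(avg, c(onset, onset + 300)), 6, tolerance = 0.05)
  # closed-form crossings of the double-exponential kernel
  v2 <- psp_trace(1, 5)
  avg2 <- average_response(list(flat_epoch(add = v2)))
  det <- detect_psp_window(avg2)
  rt <- rise_time(avg2, det$windows[[1]])
  f <- function(t) optomap:::psp_kernel(t, 1.5, 18)
  t20 <- stats::uniroot(function(t) f(t) - 0.2, c(0, 3))$root
  t80 <- stats::uniroot(function(t) f(t) - 0.8, c(0.5, 6))$root
  expect_equal(rt, t80 - t20, tolerance = 2 * DT25 * 1000)
  # small responses are undefined
  v3 <- psp_trace(0.05, 5)
  avg3 <- average_response(list(flat_epoch(add = v3)))
  expect_true(is.na(rise_time(avg3, c(onset, onset + 300))))
})

test_that("deconvolved PPR undoes temporal summation", {
  # two identical, well-separated PSPs: PPR exactly 1
  v <- psp_trace(0.5, 5) + psp_trace(0.5, 60)
  eps <- list(flat_epoch(n = 8750, onset = 2501, add = v[1:8750]))
  w1 <- c(2501, 2501 + 500); w2 <- c(2501 + 1251, 2501 + 1900)
  pp <- paired_pulse_ratio(eps, w1, w2, tau = 18)
  expect_equal(unname(pp$ppr), 1, tolerance = 1e-6)
  # second PSP at half amplitude riding on the first's decay, 7 ms apart
  v <- psp_trace(1, 5) + psp_trace(0.5, 12)
  eps <- list(flat_epoch(add = v))
  w1 <- c(2501, 2501 + round(6.5 / 1000 / DT25))
  w2 <- c(w1[2] + 1, w1[2] + round(10 / 1000 / DT25))
  raw_peak2 <- max(v[w2[1]:w2[2]])
  expect_gt(raw_peak2 / max(v[w1[1]:w1[2]]), 0.55)  # raw ratio is inflated
  pp <- paired_pulse_ratio(eps, w1, w2, tau = 18)
  expect_equal(unname(pp$ppr), 0.5, tolerance = 0.02)
  expect_equal(unname(pp$interval_ms), 7, tolerance = 0.5)
  expect_equal(pp$n_in_range, 1L)
  # a 12 ms interval is excluded from the 5-10 ms population PPR
  v <- psp_trace(1, 5) + psp_trace(0.5, 17)
  eps <- list(flat_epoch(add = v))
  w2b <- c(w1[2] + 1, w1[2] + round(14 / 1000 / DT25))
  pp <- paired_pulse_ratio(eps, w1, w2b, tau = 18)
  expect_equal(pp$n_in_range, 0L)
  expect_true(is.na(pp$ppr_mean))
  expect_error(paired_pulse_ratio(eps, c(2501, 3000), c(2900, 3500), 18),
               "overlap")
})

test_that("the automatic tau grid avoids baseline overshoot", {
  v <- psp_trace(1, 5, rise = 0.8, decay = 8) +
    psp_trace(0.7, 12, rise = 0.8, decay = 8)
  eps <- list(flat_epoch(add = v))
  w1 <- c(2501, 2501 + round(6.5 / 1000 / DT25))
  w2 <- c(w1[2] + 1, w1[2] + round(10 / 1000 / DT25))
  pp <- paired_pulse_ratio(eps, w1, w2)  # tau = NULL -> grid
  expect_true(pp$tau_used %in% c(5, 10, 15, 20))
  expect_lte(pp$tau_used, 10)  # fast kinetics pick a small tau
})

test_that("rundown reports percent change per stimulus", {
  expect_equal(rundown(rep(0.8, 10)), 0)
  expect_equal(rundown(1 - 0.01 * (0:19)), -1, tolerance = 1e-9)
  set.seed(6)
  amp <- 1 - 0.01 * (0:39) + stats::rnorm(40, 0, 0.05)
  fit <- stats::lm(amp ~ I(0:39))
  se <- summary(fit)$coefficients[2, 2] / stats::coef(fit)[[1]] * 100
  expect_lt(abs(rundown(amp) - (-1)), 2 * abs(se))
  expect_error(rundown(c(1, 2, 3)), "at least 5")
})

test_that("amplitude recovery through the full pipeline stays accurate", {
  set.seed(31)
  errs <- vapply(1:40, function(i) {
    amp <- stats::runif(1, 0.2, 1.5)
    p <- stats::runif(1, 0.4, 0.9)
    N <- 1L + stats::rpois(1, 4)
    syn <- quantal_synapse(N, p, amp / (N * p))
    eps <- gen_photoresponse(syn, spiking_model(),
                             noise_model(baseline_sd = 0.1), 20,
                             seed = 9000 + i)
    gt <- attr(eps, "ground_truth")
    q <- quantify_psp(eps)
    if (!length(q$windows$windows)) return(1)
    w <- q$windows$windows[[1]]
    truth <- max(gt$clean_mean[w[1]:w[2]])
    abs(q$amplitude - truth) / truth
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("IPSPs at depolarized holding are measured after polarity flip", {
  syn <- quantal_synapse(4, 0.8, 0.15, rise_tau = 2, decay_tau = 22)
  eps <- gen_photoresponse(syn, spiking_model(), noise_model(baseline_sd = 0.05),
                           n_sweeps = 10, seed = 3, holding_target = -55,
                           polarity = -1)
  q <- quantify_psp(eps, polarity = -1)
  expect_gt(q$amplitude, 0.2)  # amplitude reported on the flipped trace
})
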