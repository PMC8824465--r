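# Generators: Poisson cell maps, Bernoulli networks, quantal photoresponses,
# intrinsic sweeps, full experiments.

test_that("cell maps follow the Poisson point process they claim", {
  bounds <- list(x = c(0, 300), y = c(0, 300), z = c(0, 300))  # 0.027 mm^3
  expect_equal(nrow(gen_cell_map(0, bounds, 1)$positions), 0L)
  counts <- vapply(1:200, function(s) {
    nrow(gen_cell_map(10000, bounds, s)$positions)
  }, numeric(1))
  # Poisson mean 270: the mean of 200 draws is within 4 SE
  expect_lt(abs(mean(counts) - 270), 4 * sqrt(270 / 200))
  expect_identical(gen_cell_map(5000, bounds, 42)$positions,
                   gen_cell_map(5000, bounds, 42)$positions)
  expect_error(gen_cell_map(1000, list(x = c(0, 0), y = c(0, 1), z = c(0, 1)),
                            1), "degenerate")
})

test_that("network generation follows the distance kernel", {
  bounds <- list(x = c(-200, 200), y = c(0, 600), z = c(-50, 50))
  cm <- gen_cell_map(25000, bounds, 2)
  patched <- data.frame(x = 0, y = 250, z = 0)
  expect_true(all(!gen_network(cm, patched, function(d) d * 0, 1)))
  expect_true(all(gen_network(cm, patched, function(d) d * 0 + 1, 1)))
  expect_error(gen_network(cm, patched, function(d) d / 100, 1), "\\[0, 1\\]")
  kern <- function(d) 0.3 * exp(-d / 100)
  adj <- c(); dd <- c()
  for (s in 1:12) {
    a <- gen_network(cm, patched, kern, s)
    adj <- c(adj, as.vector(a)); dd <- c(dd, as.vector(attr(a, "distance")))
  }
  bins <- cut(dd, seq(0, 400, 50))
  emp <- tapply(adj, bins, mean)
  n_b <- tapply(adj, bins, length)
  mid <- seq(25, 375, 50)
  for (b in which(n_b > 200)) {
    p0 <- kern(mid[b])
    expect_lt(abs(emp[b] - p0), 3 * sqrt(p0 * (1 - p0) / n_b[b]) + 0.01)
  }
})

test_that("a noiseless single quantum yields exactly the quantal size", {
  syn <- quantal_synapse(1, 1, 0.5)
  eps <- gen_photoresponse(syn, spiking_model(jitter_sd = 0,
                                              n_spikes_prob = c(1, 0, 0)),
                           noise_model(baseline_sd = 0, spont_rate = 0),
                           n_sweeps = 1, seed = 1)
  q <- quantify_psp(eps)
  expect_equal(q$amplitude, 0.5, tolerance = 1e-3)
})

test_that("empirical CV follows the binomial closed form", {
  syn <- quantal_synapse(5, 0.5, 0.2)
  eps <- gen_photoresponse(syn, spiking_model(jitter_sd = 0,
                                              n_spikes_prob = c(1, 0, 0)),
                           noise_model(baseline_sd = 0, spont_rate = 0),
                           n_sweeps = 1000, seed = 2)
  gt <- attr(eps, "ground_truth")
  cv_expected <- unname(quantal_moments(syn)["cv"])  # sqrt(0.5/2.5) = 0.447
  # oracle: the recorded per-sweep quantal amplitudes themselves
  amps <- gt$amplitude_per_sweep
  expect_equal(stats::sd(amps) / mean(amps), cv_expected,
               tolerance = 3 / sqrt(2 * 1000) * cv_expected * 3)
  q <- quantify_psp(eps)
  expect_equal(q$cv, stats::sd(amps) / mean(amps), tolerance = 0.02)
  expect_equal(mean(amps), 0.5, tolerance = 3 * 0.447 * 0.5 / sqrt(1000))
})

test_that("absent connections are overwhelmingly classified not-connected", {
  hits <- vapply(1:100, function(s) {
    eps <- gen_photoresponse(NULL, spiking_model(),
                             noise_model(baseline_sd = 0.1, spont_rate = 0),
                             n_sweeps = 20, seed = s)
    length(quantify_psp(eps)$windows$windows) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.01)
})

test_that("generated latency jitter matches the spiking model", {
  sm <- spiking_model(jitter_sd = 0.5, n_spikes_prob = c(1, 0, 0))
  eps <- gen_photoresponse(quantal_synapse(5, 0.9, 0.2), sm, noise_model(),
                           n_sweeps = 100, seed = 8)
  gt <- attr(eps, "ground_truth")
  first <- vapply(gt$spike_times, function(s) s[1], numeric(1))
  # the SD estimator itself has SE ~ sigma/sqrt(2n); stay within 3 SE at
  # n = 100 and within 10% at n = 1000
  expect_lt(abs(stats::sd(first) - 0.5), 3 * 0.5 / sqrt(2 * 100))
  eps2 <- gen_photoresponse(quantal_synapse(5, 0.9, 0.2), sm, noise_model(),
                            n_sweeps = 1000, seed = 9, sample_rate = 5000)
  first2 <- vapply(attr(eps2, "ground_truth")$spike_times, function(s) s[1],
                   numeric(1))
  expect_lt(abs(stats::sd(first2) - 0.5) / 0.5, 0.1)
})

test_that("intrinsic sweeps invert to their generating parameters", {
  pars <- list(v_rest = -70, input_resistance = 100, tau = 15, sag = 0,
               rheobase = 150, ap_fwhm = 1.37,
               upstroke_downstroke_ratio = 4.3, ap_peak = 40,
               ap_trough = -48, avg_firing_rate = 8,
               adaptation_index = 0.09, f_i_slope = 0.12)
  f <- extract_intrinsic(gen_intrinsic_sweeps(pars))
  expect_equal(f[["input_resistance"]], 100, tolerance = 2)
  # -70 pA steady-state deflection is exactly R*I (Ohm's law)
  sw <- gen_intrinsic_sweeps(pars)
  i70 <- which(vapply(sw, `[[`, numeric(1), "current_pA") == -70)
  dfl <- mean(sw[[i70]]$voltage[(sw[[i70]]$step_end_index - 100):
                                  sw[[i70]]$step_end_index]) - (-70)
  expect_equal(dfl, -7, tolerance = 0.05)
  expect_equal(f[["tau"]], 15, tolerance = 0.5)
  expect_equal(f[["capacitance"]], 150, tolerance = 10)
  expect_equal(f[["sag"]], 0, tolerance = 1e-6)
  expect_equal(f[["rheobase"]], 150)
  expect_equal(f[["ap_fwhm"]], 1.37, tolerance = 0.15)
  expect_equal(f[["ap_peak"]], 40, tolerance = 0.5)
  expect_equal(f[["avg_firing_rate"]], 8, tolerance = 0.5)
  expect_equal(f[["adaptation_index"]], 0.09, tolerance = 0.01)
})

test_that("sag cells produce the requested sag ratio", {
  pars <- list(v_rest = -62, input_resistance = 199, tau = 16.8, sag = 0.16,
               rheobase = 130, ap_fwhm = 0.79,
               upstroke_downstroke_ratio = 2.1, ap_peak = 24,
               ap_trough = -52.7, avg_firing_rate = 15.6,
               adaptation_index = 0.081, f_i_slope = 0.29)
  f <- extract_intrinsic(gen_intrinsic_sweeps(pars))
  expect_equal(f[["sag"]], 0.16, tolerance = 0.02)
  expect_equal(f[["ap_trough"]], -52.7, tolerance = 0.2)
})

test_that("experiments are fully reproducible from one seed", {
  cfg <- experiment_config(n_patched = 1, density = 2000, n_sweeps = 3,
                           sample_rate = 10000)
  e1 <- gen_experiment(cfg, seed = 77)
  e2 <- gen_experiment(cfg, seed = 77)
  expect_identical(e1$dataset$pairs, e2$dataset$pairs)
  expect_identical(e1$epochs, e2$epochs)
  # byte-identical serialized connection tables
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_connection_table(e1$dataset, p1)
  write_connection_table(e2$dataset, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an experiment with no patched cells is empty but valid", {
  e <- gen_experiment(experiment_config(n_patched = 0), seed = 1)
  expect_equal(nrow(e$dataset$pairs), 0L)
  expect_s3_class(e$dataset, "connectivity_dataset")
})

test_that("generated datasets satisfy the data-model invariants", {
  cfg <- experiment_config(n_patched = 2, density = 2500, n_sweeps = 3,
                           sample_rate = 10000)
  e <- gen_experiment(cfg, seed = 5)
  p <- e$dataset$pairs
  expect_true(all(p$pre_pia_um >= 0))
  expect_true(all(p$distance_3d_um >= abs(p$horizontal_offset_um) - 1e-9))
  expect_true(all(p$pair_id %in% names(e$epochs)))
  expect_true(all(vapply(e$epochs[[1]], inherits, logical(1), "trace_epoch")))
})
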