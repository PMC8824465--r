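# Seeded generators for every input the pipeline consumes: labeled-cell point
# clouds, ground-truth networks, photostimulus-evoked voltage sweeps,
# loose-seal spike-outcome tables and current-step intrinsic sweeps.
#
# The generators emulate the statistical structure the analysis assumes:
# quantal (binomial) release giving skewed amplitude distributions with an
# inverse CV-amplitude relation, log-normal minimum reliable stimulus powers,
# Gaussian lateral/axial activation falloff, latency/jitter structure of
# photo-evoked spiking, Ornstein-Uhlenbeck membrane noise, Poisson spontaneous
# PSPs, and direct-stimulation artifacts on opsin-positive patched cells.

#' Quantal synapse parameters
#'
#' A binomial release model: `n_sites` independent release sites each
#' releasing with probability `release_prob`, each vesicle contributing
#' `quantal_size` mV at the soma. The mean PSP amplitude is
#' `n_sites * release_prob * quantal_size` and the amplitude CV is
#' `sqrt((1 - release_prob) / (n_sites * release_prob))`, which produces the
#' inverse relation between CV and amplitude seen across strong and weak
#' connections.
#'
#' @param n_sites integer >= 1, number of release sites
#' @param release_prob per-site release probability in (0, 1]
#' @param quantal_size quantal amplitude (mV)
#' @param rise_tau,decay_tau PSP kernel time constants (ms); decay > rise
#' @param synaptic_latency delay from presynaptic spike to PSP onset (ms)
#' @return an object of class `quantal_synapse`
#' @export
quantal_synapse <- function(n_sites, release_prob, quantal_size,
                            rise_tau = 1.5, decay_tau = 18,
                            synaptic_latency = 1.5) {
  stopifnot(n_sites >= 1, release_prob > 0, release_prob <= 1,
            quantal_size > 0)
  if (decay_tau <= rise_tau) stop("decay_tau must exceed rise_tau",
                                  call. = FALSE)
  structure(
    list(n_sites = as.integer(n_sites), release_prob = release_prob,
         quantal_size = quantal_size, rise_tau = rise_tau,
         decay_tau = decay_tau, synaptic_latency = synaptic_latency),
    class = "quantal_synapse")
}

#' Expected mean amplitude and CV of a quantal synapse
#' @param syn a [quantal_synapse()]
#' @return named numeric vector with `mean` (mV) and `cv`
#' @export
quantal_moments <- function(syn) {
  c(mean = syn$n_sites * syn$release_prob * syn$quantal_size,
    cv = sqrt((1 - syn$release_prob) / (syn$n_sites * syn$release_prob)))
}

#' Photo-evoked spiking model
#'
#' Describes how reliably and precisely a cell fires to the photostimulus:
#' the minimum power for reliable (every-trial) spiking, first-spike latency
#' and jitter, the distribution of spikes per stimulus, and Gaussian falloff
#' of spike probability with lateral or axial offset of the stimulus.
#' At zero offset and power at or above `min_reliable_power` the spike
#' probability is exactly `peak_prob` (1 by default).
#'
#' @param min_reliable_power minimum power for 10/10 spiking (mW)
#' @param latency_mean mean first-spike latency (ms)
#' @param jitter_sd SD of first-spike latency (ms)
#' @param n_spikes_prob probabilities of 1, 2 or 3 spikes per stimulus
#' @param lateral_sigma,axial_sigma Gaussian falloff SDs (um)
#' @param peak_prob spike probability at zero offset, reliable power
#' @return an object of class `spiking_model`
#' @export
spiking_model <- function(min_reliable_power = 20, latency_mean = 6,
                          jitter_sd = 0.7,
                          n_spikes_prob = c(0.7, 0.25, 0.05),
                          lateral_sigma = 8, axial_sigma = 20,
                          peak_prob = 1) {
  stopifnot(min_reliable_power > 0, jitter_sd >= 0,
            length(n_spikes_prob) == 3, abs(sum(n_spikes_prob) - 1) < 1e-8,
            lateral_sigma > 0, axial_sigma > 0)
  stop_if_not_scalar_prob(peak_prob, "peak_prob")
  structure(
    list(min_reliable_power = min_reliable_power, latency_mean = latency_mean,
         jitter_sd = jitter_sd, n_spikes_prob = n_spikes_prob,
         lateral_sigma = lateral_sigma, axial_sigma = axial_sigma,
         peak_prob = peak_prob),
    class = "spiking_model")
}

#' Spike probability of a spiking model at a stimulus offset and power
#'
#' Gaussian falloff in each axis; below the minimum reliable power the
#' probability scales as `(power / min_reliable_power)^3`, giving a smooth,
#' monotone power dependence with certainty at and above the minimum.
#'
#' @param model a [spiking_model()]
#' @param lateral,axial stimulus offsets (um)
#' @param power stimulus power (mW)
#' @return spike probability per trial
#' @export
spike_probability <- function(model, lateral = 0, axial = 0,
                              power = model$min_reliable_power) {
  p_pow <- pmin(1, (power / model$min_reliable_power)^3)
  model$peak_prob * p_pow *
    exp(-lateral^2 / (2 * model$lateral_sigma^2)) *
    exp(-axial^2 / (2 * model$axial_sigma^2))
}

#' Membrane noise model
#'
#' Baseline noise is an Ornstein-Uhlenbeck process (default 5 ms correlation
#' time) with the requested stationary SD; spontaneous PSPs arrive as a
#' Poisson process with exponentially distributed amplitudes; opsin-positive
#' patched cells additionally receive a direct-stimulation depolarization
#' whose onset coincides exactly with stimulus onset.
#'
#' @param baseline_sd stationary SD of the baseline noise (mV)
#' @param corr_tau noise correlation time (ms)
#' @param spont_rate spontaneous PSP rate (Hz)
#' @param spont_scale mean spontaneous PSP amplitude (mV)
#' @param artifact_amplitude direct-artifact amplitude for opsin-positive
#'   patched cells (mV); the population median reported for such artifacts
#'   is 0.23 mV
#' @return an object of class `noise_model`
#' @export
noise_model <- function(baseline_sd = 0.1, corr_tau = 5, spont_rate = 0.5,
                        spont_scale = 0.2, artifact_amplitude = 0.23) {
  stopifnot(baseline_sd >= 0, corr_tau > 0, spont_rate >= 0)
  structure(
    list(baseline_sd = baseline_sd, corr_tau = corr_tau,
         spont_rate = spont_rate, spont_scale = spont_scale,
         artifact_amplitude = artifact_amplitude),
    class = "noise_model")
}

# Amplitude-normalized difference-of-exponentials PSP kernel evaluated at
# times t (ms, 0 = onset). Peak value is 1 at t* = log(d/r) * r*d/(d-r).
psp_kernel <- function(t, rise_tau, decay_tau) {
  tstar <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-tstar / decay_tau) - exp(-tstar / rise_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / peak
  out
}

# Stationary OU noise sampled at dt_ms intervals, via its exact AR(1) form.
ou_noise <- function(n, sd, corr_tau, dt_ms) {
  if (sd == 0 || n == 0) return(numeric(n))
  a <- exp(-dt_ms / corr_tau)
  innov_sd <- sd * sqrt(1 - a^2)
  innov <- stats::rnorm(n, 0, innov_sd)
  innov[1] <- stats::rnorm(1, 0, sd)  # stationary start
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Generate a labeled-cell point cloud
#'
#' Cells are placed by a homogeneous Poisson point process within the bounding
#' box, or within per-layer slabs when `density` is a named vector of layer
#' labels (the y axis is the pia axis). Densities are in cells/mm^3 and
#' bounds in um.
#'
#' @param density scalar density, or named vector over layer labels
#' @param bounds list with numeric `x`, `y`, `z` ranges (um); `y` is distance
#'   from the pia
#' @param seed integer seed
#' @return an object of class `cell_map`: positions matrix plus bounds
#' @export
gen_cell_map <- function(density, bounds, seed) {
  if (any(unlist(density) < 0)) stop("densities must be >= 0", call. = FALSE)
  ranges <- lapply(bounds[c("x", "y", "z")], range)
  if (any(vapply(ranges, function(r) diff(r) <= 0, logical(1)))) {
    stop("degenerate bounds", call. = FALSE)
  }
  slabs <- if (is.null(names(density))) {
    list(list(y = ranges$y, density = as.numeric(density)))
  } else {
    b <- layer_boundaries()
    lapply(names(density), function(lab) {
      lo <- b[[lab]]
      hi <- b[which(names(b) == lab) + 1]
      list(y = c(max(lo, ranges$y[1]), min(hi, ranges$y[2])),
           density = density[[lab]])
    })
  }
  pos <- with_substream(seed, "cell_map", {
    do.call(rbind, lapply(slabs, function(s) {
      if (diff(s$y) <= 0) return(NULL)
      vol_mm3 <- diff(ranges$x) * diff(s$y) * diff(ranges$z) * 1e-9
      n <- stats::rpois(1, s$density * vol_mm3)
      if (n == 0) return(NULL)
      cbind(x = stats::runif(n, ranges$x[1], ranges$x[2]),
            y = stats::runif(n, s$y[1], s$y[2]),
            z = stats::runif(n, ranges$z[1], ranges$z[2]))
    }))
  })
  if (is.null(pos)) pos <- matrix(numeric(0), ncol = 3,
                                  dimnames = list(NULL, c("x", "y", "z")))
  structure(list(positions = pos, bounds = ranges), class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells in %.3g mm^3\n", nrow(x$positions),
              cell_map_volume(x)))
  invisible(x)
}

#' Volume of a cell map (mm^3)
#' @param cell_map a [gen_cell_map()] result
#' @export
cell_map_volume <- function(cell_map) {
  prod(vapply(cell_map$bounds, diff, numeric(1))) * 1e-9
}

#' Generate a ground-truth connectivity network
#'
#' Independent Bernoulli draws per ordered (map cell, patched cell) pair with
#' probability given by a distance-dependent kernel.
#'
#' @param cell_map a [gen_cell_map()] result
#' @param patched_cells matrix or data.frame of patched-cell xyz positions
#' @param kernel function of 3D distance (um) returning probability in [0, 1]
#' @param seed integer seed
#' @return logical adjacency matrix, map cells x patched cells, with the
#'   pairwise distances attached as attribute `distance`
#' @export
gen_network <- function(cell_map, patched_cells, kernel, seed) {
  patched <- as.matrix(as.data.frame(patched_cells)[, c("x", "y", "z")])
  pos <- cell_map$positions
  d <- sqrt(outer(rowSums(pos^2), rowSums(patched^2), "+") -
              2 * pos %*% t(patched))
  d[d < 0] <- 0  # numerical noise on coincident points
  p <- kernel(d)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("kernel must return probabilities in [0, 1]", call. = FALSE)
  }
  adj <- with_substream(seed, "network", {
    matrix(stats::runif(length(p)) < p, nrow = nrow(pos))
  })
  attr(adj, "distance") <- d
  adj
}

#' Generate photostimulus-evoked voltage sweeps for one probed pair
#'
#' Each sweep draws a spike count and spike times from the spiking model,
#' drives an amplitude-normalized double-exponential PSP kernel with
#' binomially sampled quantal content per spike, and superposes correlated
#' membrane noise, Poisson spontaneous PSPs and (optionally) a direct
#' stimulation artifact. An absent connection (`connection = NULL`) yields
#' noise-only sweeps. Ground truth (per-sweep first-PSP amplitudes, latency,
#' spike times) is attached as attribute `ground_truth`.
#'
#' @param connection a [quantal_synapse()] or NULL for no connection
#' @param spiking a [spiking_model()]
#' @param noise a [noise_model()]
#' @param n_sweeps number of sweeps (>= 1)
#' @param seed integer seed
#' @param sample_rate sampling rate (Hz)
#' @param pre_ms,post_ms recording length before/after stimulus onset (ms)
#' @param holding_target holding potential (mV)
#' @param polarity +1 for EPSPs, -1 for IPSPs (hyperpolarizing at -55 mV)
#' @param lateral,axial stimulus offsets from the target soma (um)
#' @param power stimulus power (mW)
#' @param opsin_positive_post does the patched cell express opsin
#' @param ppr_scale amplitude scale of PSPs after the first (paired-pulse
#'   ratio of the generating synapse)
#' @return list of [trace_epoch()] with attribute `ground_truth`
#' @export
gen_photoresponse <- function(connection, spiking, noise, n_sweeps, seed,
                              sample_rate = 25000, pre_ms = 100, post_ms = 150,
                              holding_target = -70, polarity = 1,
                              lateral = 0, axial = 0, power = NULL,
                              opsin_positive_post = FALSE, ppr_scale = 1) {
  stopifnot(n_sweeps >= 1)
  if (!is.null(connection) && connection$decay_tau <= connection$rise_tau) {
    stop("decay_tau must exceed rise_tau", call. = FALSE)
  }
  dt <- 1 / sample_rate
  dt_ms <- dt * 1000
  n_pre <- round(pre_ms / dt_ms)
  n_post <- round(post_ms / dt_ms)
  n <- n_pre + n_post
  onset_idx <- n_pre + 1L
  t_ms <- (seq_len(n) - onset_idx) * dt_ms   # 0 at stimulus onset
  power <- power %||% spiking$min_reliable_power
  p_spike <- spike_probability(spiking, lateral, axial, power)

  with_substream(seed, "photoresponse", {
    gt_amp <- rep(NA_real_, n_sweeps)
    gt_lat <- rep(NA_real_, n_sweeps)
    gt_spikes <- vector("list", n_sweeps)
    epochs <- vector("list", n_sweeps)
    clean <- matrix(0, n, n_sweeps)  # signal without noise/spontaneous events
    for (s in seq_len(n_sweeps)) {
      sig <- numeric(n)
      v <- ou_noise(n, noise$baseline_sd, noise$corr_tau, dt_ms)
      # spontaneous PSPs over the whole sweep
      if (noise$spont_rate > 0) {
        n_spont <- stats::rpois(1, noise$spont_rate * (n * dt_ms) / 1000)
        if (n_spont > 0) {
          st <- stats::runif(n_spont, t_ms[1], t_ms[n])
          sa <- stats::rexp(n_spont, 1 / noise$spont_scale)
          for (k in seq_len(n_spont)) {
            v <- v + sa[k] * psp_kernel(t_ms - st[k], 1.5, 18)
          }
        }
      }
      if (opsin_positive_post && noise$artifact_amplitude > 0) {
        sig <- sig + noise$artifact_amplitude * psp_kernel(t_ms, 0.5, 15)
      }
      if (!is.null(connection)) {
        spiked <- stats::runif(1) < p_spike
        if (spiked) {
          n_spk <- sample(1:3, 1, prob = spiking$n_spikes_prob)
          first <- stats::rnorm(1, spiking$latency_mean, spiking$jitter_sd)
          isis <- if (n_spk > 1) stats::runif(n_spk - 1, 5, 10) else numeric(0)
          spk_t <- first + c(0, cumsum(isis))
          gt_spikes[[s]] <- spk_t
          for (k in seq_along(spk_t)) {
            quanta <- stats::rbinom(1, connection$n_sites,
                                    connection$release_prob)
            amp <- quanta * connection$quantal_size *
              if (k > 1) ppr_scale else 1
            if (k == 1) {
              gt_amp[s] <- amp
              gt_lat[s] <- spk_t[1] + connection$synaptic_latency
            }
            if (amp > 0) {
              sig <- sig + polarity * amp *
                psp_kernel(t_ms - spk_t[k] - connection$synaptic_latency,
                           connection$rise_tau, connection$decay_tau)
            }
          }
        } else {
          gt_amp[s] <- 0
        }
      }
      clean[, s] <- sig
      epochs[[s]] <- trace_epoch(holding_target + v + sig, dt, onset_idx,
                                 stim_duration = 10,
                                 holding_target = holding_target,
                                 sweep_index = s)
    }
    attr(epochs, "ground_truth") <- list(
      amplitude_per_sweep = gt_amp,
      mean_amplitude = if (is.null(connection)) 0 else
        mean(gt_amp, na.rm = TRUE),
      expected_amplitude = if (is.null(connection)) 0 else
        unname(quantal_moments(connection)["mean"]),
      latency_per_sweep = gt_lat,
      spike_times = gt_spikes,
      clean_mean = rowMeans(clean),
      onset_index = onset_idx,
      polarity = polarity,
      p_spike = p_spike)
    epochs
  })
}

#' Generate a loose-seal spike-outcome table
#'
#' Reproduces the standard characterization protocol: an ascending power
#' series on target, a radial grid (7 spokes at 10, 20 and 30 um lateral
#' offset) at mapping power, and axial offsets in 10 um steps, each condition
#' with 10 trials. Spike latency grows mildly with offset; outcomes are
#' Bernoulli in the model's spike probability.
#'
#' @param model a [spiking_model()]
#' @param cell_id identifier recorded in the table
#' @param powers ascending test powers (mW) for the on-target series
#' @param map_power power used for offset conditions (mW)
#' @param n_trials trials per condition
#' @param axial_max largest axial offset tested (um)
#' @param seed integer seed
#' @return data.frame of class `spike_outcome_table` with a list column
#'   `spike_times` (ms; empty vector = no spike)
#' @export
gen_spike_outcomes <- function(model, cell_id = "cell1",
                               powers = c(5, 10, 20, 40, 85),
                               map_power = max(powers), n_trials = 10,
                               axial_max = 60, seed = 1) {
  cond <- rbind(
    data.frame(power = powers, lateral = 0, axial = 0, spoke = NA),
    do.call(rbind, lapply(1:7, function(sp) {
      ang <- (sp - 1) * 2 * pi / 7
      data.frame(power = map_power, lateral = c(10, 20, 30), axial = 0,
                 spoke = sp, ang = ang)[, c("power", "lateral", "axial", "spoke")]
    })),
    data.frame(power = map_power, lateral = 0,
               axial = c(-rev(seq(10, axial_max, 10)), seq(10, axial_max, 10)),
               spoke = NA))
  with_substream(seed, paste0("spike_outcomes_", cell_id), {
    rows <- lapply(seq_len(nrow(cond)), function(i) {
      p <- spike_probability(model, cond$lateral[i], abs(cond$axial[i]),
                             cond$power[i])
      lat_mean <- model$latency_mean *
        (1 + 0.02 * (cond$lateral[i] + abs(cond$axial[i])))
      spikes <- lapply(seq_len(n_trials), function(tr) {
        if (stats::runif(1) < p) {
          max(0.1, stats::rnorm(1, lat_mean, model$jitter_sd))
        } else numeric(0)
      })
      data.frame(cell_id = cell_id, power = cond$power[i],
                 lateral_offset = cond$lateral[i], axial_offset = cond$axial[i],
                 trial_index = seq_len(n_trials),
                 spike_times = I(spikes))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("spike_outcome_table", class(out))
    out
  })
}

#' Generate a family of current-step intrinsic-property sweeps
#'
#' Synthesizes 1 s square current injections (default -130 to +250 pA in
#' 20 pA steps) for a cell described by its target intrinsic features.
#' Subthreshold responses follow RC charging with an optional sag component;
#' suprathreshold sweeps carry stereotyped action potentials whose peak,
#' trough, width and upstroke/downstroke ratio match the requested values,
#' with spike trains matching the requested firing rate, adaptation index and
#' f-I slope. Derived features therefore equal the generating parameters
#' within discretization tolerance.
#'
#' @param params named list: `v_rest` (mV), `input_resistance` (MOhm),
#'   `tau` (ms), `sag`, `rheobase` (pA), `ap_fwhm` (ms),
#'   `upstroke_downstroke_ratio`, `ap_peak` (mV), `ap_trough` (mV),
#'   `avg_firing_rate` (Hz at rheobase + 40 pA), `adaptation_index`,
#'   `f_i_slope` (spikes/s/pA)
#' @param current_steps injected currents (pA)
#' @param seed integer seed (noise only; `noise_sd = 0` is fully deterministic)
#' @param sample_rate sampling rate (Hz)
#' @param noise_sd additive voltage noise SD (mV)
#' @return list of class `intrinsic_sweeps`; each element has `current_pA`,
#'   `voltage`, `sample_interval`, `step_start_index`, `step_end_index`
#' @export
gen_intrinsic_sweeps <- function(params,
                                 current_steps = NULL,
                                 seed = 1, sample_rate = 20000,
                                 noise_sd = 0) {
  p <- params
  if (is.null(current_steps)) {
    # standard family; extended in 20 pA steps when rheobase demands more
    current_steps <- seq(-130, max(250, p$rheobase + 60), by = 20)
  }
  dt_ms <- 1000 / sample_rate
  pre_ms <- 250; step_ms <- 1000; post_ms <- 250
  n_pre <- round(pre_ms / dt_ms); n_step <- round(step_ms / dt_ms)
  n_post <- round(post_ms / dt_ms)
  n <- n_pre + n_step + n_post
  t_step <- (seq_len(n_step) - 1) * dt_ms
  sag_tau <- 150  # development time of the sag relaxation (ms)
  sweeps <- with_substream(seed, "intrinsic", {
    lapply(current_steps, function(I) {
      v <- rep(p$v_rest, n)
      d_ss <- p$input_resistance * I * 1e-3  # steady-state deflection, mV
      if (I < 0 && p$sag > 0) {
        curve <- function(d_pk) {
          d_pk * (1 - exp(-t_step / p$tau)) -
            (d_pk - d_ss) * (1 - exp(-t_step / sag_tau))
        }
        realized_sag <- function(d_pk) {
          r <- curve(d_pk)
          pk <- min(r); st <- mean(r[(length(r) - round(100 / dt_ms)):length(r)])
          (pk - st) / pk - p$sag
        }
        d_hi <- d_ss / max(1e-3, (1 - p$sag))
        d_pk <- tryCatch(
          stats::uniroot(realized_sag, c(d_ss * 1.0001, 4 * d_hi))$root,
          error = function(e) d_hi)
        resp <- curve(d_pk)
      } else {
        resp <- d_ss * (1 - exp(-t_step / p$tau))
      }
      # during spiking sweeps the membrane charges toward a plateau just
      # above the AP trough (the inter-spike voltage of a spiking cell)
      if (I >= p$rheobase) {
        plateau <- (p$ap_trough + 8) - p$v_rest
        resp <- plateau * (1 - exp(-t_step / p$tau))
      }
      v[(n_pre + 1):(n_pre + n_step)] <- p$v_rest + resp
      # relaxation back to rest after the step
      tail_t <- (seq_len(n_post) - 1) * dt_ms
      v[(n_pre + n_step + 1):n] <- p$v_rest +
        resp[n_step] * exp(-tail_t / p$tau)
      if (I >= p$rheobase) {
        rate <- max(1, p$avg_firing_rate +
                      p$f_i_slope * (I - (p$rheobase + 40)))
        n_spk <- max(1L, as.integer(round(rate)))
        rho <- (1 + p$adaptation_index) / (1 - p$adaptation_index)
        t0 <- 50
        if (n_spk > 1) {
          w <- rho^(0:(n_spk - 2))
          isi1 <- (step_ms - t0 - 40) / sum(w)
          spk_t <- t0 + c(0, cumsum(isi1 * w))
        } else spk_t <- t0
        v <- add_ap_waveforms(v, spk_t + pre_ms, dt_ms, p)
      }
      if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
      list(current_pA = I, voltage = v, sample_interval = 1 / sample_rate,
           step_start_index = n_pre + 1L, step_end_index = n_pre + n_step)
    })
  })
  structure(sweeps, class = "intrinsic_sweeps", params = params)
}

# Superpose triangular action-potential waveforms whose FWHM, peak, trough and
# upstroke/downstroke ratio are exact by construction. The half-width is the
# time spent above trough + height/2.
add_ap_waveforms <- function(v, spike_times_ms, dt_ms, p) {
  height <- p$ap_peak - p$ap_trough
  r <- p$upstroke_downstroke_ratio
  up <- (height / 2) * (1 + r) / p$ap_fwhm   # mV/ms
  down <- up / r
  n <- length(v)
  for (st in spike_times_ms) {
    i0 <- as.integer(round(st / dt_ms)) + 1L
    if (i0 < 1 || i0 > n) next
    v_pre <- v[i0]
    # quantize segment durations to the sample grid so that the apex and
    # trough fall exactly on samples (keeps peak/trough recovery exact)
    t_up <- max(dt_ms, round(((p$ap_peak - v_pre) / up) / dt_ms) * dt_ms)
    up <- (p$ap_peak - v_pre) / t_up
    t_down <- max(dt_ms, round(((p$ap_peak - p$ap_trough) / down) / dt_ms) *
                    dt_ms)
    down <- (p$ap_peak - p$ap_trough) / t_down
    t_rec <- 5
    t_rel <- seq(0, t_up + t_down + t_rec, by = dt_ms)
    wave <- ifelse(t_rel <= t_up, v_pre + up * t_rel,
            ifelse(t_rel <= t_up + t_down,
                   p$ap_peak - down * (t_rel - t_up),
                   p$ap_trough + (v_pre - p$ap_trough) *
                     (t_rel - t_up - t_down) / t_rec))
    idx <- i0 + seq_along(t_rel) - 1L
    keep <- idx <= n
    v[idx[keep]] <- wave[keep]
  }
  v
}

#' Default configuration for a synthetic mapping experiment
#'
#' The defaults mirror a typical mapping session: a 300 x 600 x 120 um imaged
#' volume, 3 patched L2/3 cells, labeled-cell density 8000 cells/mm^3, at
#' least 20 photostimulus sweeps per probed cell at 25 kHz, an exponentially
#' decaying distance-dependent connection kernel, quantal synapses with
#' skewed amplitude distributions, and 0.1 mV correlated baseline noise.
#'
#' @param ... overrides of the default entries
#' @return named list of class `experiment_config`
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_patched = 3,
    patched_pia = c(150, 330),      # uniform range for patched-cell pia (um)
    density = 8000,                 # labeled cells / mm^3
    bounds = list(x = c(-150, 150), y = c(0, 600), z = c(-60, 60)),
    kernel = function(d) 0.25 * exp(-d / 150),
    n_sweeps = 20,
    sample_rate = 25000,
    pre_ms = 100, post_ms = 150,
    polarity = 1,
    holding_target = -70,
    cre_line = "synthCre",
    expression_method = "AAV",
    stim_power_mw = 85,
    opsin_positive_post_prob = 0,
    noise = noise_model(),
    spiking = spiking_model(),
    synapse_draw = function(n) {
      data.frame(n_sites = 1L + stats::rpois(n, 4),
                 release_prob = stats::runif(n, 0.3, 0.9),
                 quantal_size = stats::rlnorm(n, log(0.15), 0.4))
    })
  ov <- list(...)
  cfg[names(ov)] <- ov
  structure(cfg, class = "experiment_config")
}

#' Generate a complete synthetic mapping experiment
#'
#' Composes the cell-map, network, and photoresponse generators into one
#' seeded experiment: a connection table with ground-truth columns, plus the
#' voltage sweeps for every probed pair.
#'
#' @param config an [experiment_config()]
#' @param seed integer seed; the same seed reproduces the experiment exactly
#' @param experiment_id identifier written into the table
#' @param keep_epochs set FALSE to drop sweeps and return only the table
#' @return list with `dataset` (a [connectivity_dataset()] whose pairs table
#'   carries ground-truth columns `gt_connected`, `gt_amplitude_mv`,
#'   `gt_expected_amplitude_mv`, `gt_latency_ms`), `epochs` (named by
#'   `pair_id`), and `truth` (per-pair generator parameters)
#' @export
gen_experiment <- function(config = experiment_config(), seed = 1,
                           experiment_id = "expt1", keep_epochs = TRUE) {
  cfg <- config
  if (!inherits(cfg, "experiment_config")) stop("config must be an experiment_config",
                                                call. = FALSE)
  if (cfg$n_patched == 0) {
    empty <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(connection_table_columns())),
      connection_table_columns()))
    return(list(dataset = connectivity_dataset(empty), epochs = list(),
                truth = list()))
  }
  cmap <- gen_cell_map(cfg$density, cfg$bounds, substream_seed(seed, "map"))
  patched <- with_substream(seed, "patched", {
    data.frame(x = stats::runif(cfg$n_patched, -30, 30),
               y = stats::runif(cfg$n_patched, cfg$patched_pia[1],
                                cfg$patched_pia[2]),
               z = stats::runif(cfg$n_patched, -20, 20))
  })
  adj <- gen_network(cmap, patched, cfg$kernel, substream_seed(seed, "net"))
  dists <- attr(adj, "distance")
  n_pre <- nrow(cmap$positions)
  syn_par <- with_substream(seed, "synapses", cfg$synapse_draw(n_pre))
  opsin_post <- with_substream(seed, "opsin", {
    stats::runif(cfg$n_patched) < cfg$opsin_positive_post_prob
  })
  rows <- list(); epochs <- list(); truth <- list()
  k <- 0L
  for (j in seq_len(cfg$n_patched)) {
    for (i in seq_len(n_pre)) {
      k <- k + 1L
      pair_id <- sprintf("%s_p%02d_c%04d", experiment_id, j, i)
      connected <- adj[i, j]
      syn <- if (connected) {
        quantal_synapse(syn_par$n_sites[i], syn_par$release_prob[i],
                        syn_par$quantal_size[i],
                        rise_tau = if (cfg$polarity > 0) 1.5 else 2,
                        decay_tau = if (cfg$polarity > 0) 18 else 22)
      } else NULL
      eps <- gen_photoresponse(
        syn, cfg$spiking, cfg$noise, cfg$n_sweeps,
        seed = substream_seed(seed, pair_id),
        sample_rate = cfg$sample_rate, pre_ms = cfg$pre_ms,
        post_ms = cfg$post_ms, holding_target = cfg$holding_target,
        polarity = cfg$polarity, opsin_positive_post = opsin_post[j])
      gt <- attr(eps, "ground_truth")
      horiz <- cmap$positions[i, "x"] - patched$x[j]
      rows[[k]] <- data.frame(
        experiment_id = experiment_id, cre_line = cfg$cre_line,
        expression_method = cfg$expression_method,
        stim_power_mw = cfg$stim_power_mw,
        pre_cell_id = sprintf("c%04d", i), post_cell_id = sprintf("p%02d", j),
        post_subclass = "L2/3 PC",
        pre_pia_um = cmap$positions[i, "y"], post_pia_um = patched$y[j],
        horizontal_offset_um = horiz,
        distance_3d_um = dists[i, j],
        connected = connected, artifact_excluded = FALSE,
        n_sweeps = cfg$n_sweeps,
        psp_amplitude_mv = NA_real_, psp_cv = NA_real_,
        rise_time_ms = NA_real_, latency_ms = NA_real_, ppr = NA_real_,
        pair_id = pair_id,
        gt_connected = connected,
        gt_amplitude_mv = gt$mean_amplitude,
        gt_expected_amplitude_mv = gt$expected_amplitude,
        gt_latency_ms = mean(gt$latency_per_sweep, na.rm = TRUE),
        opsin_positive_post = opsin_post[j])
      if (keep_epochs) epochs[[pair_id]] <- eps
      truth[[pair_id]] <- list(synapse = syn, ground_truth = gt)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(dataset = connectivity_dataset(pairs), epochs = epochs, truth = truth,
       cell_map = cmap, patched = patched)
}
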