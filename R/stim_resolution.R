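# Characterization of the photostimulus from loose-seal spike-outcome
# tables: minimum reliable power, first-spike latency and jitter, and
# Gaussian lateral/axial resolution with FWHM.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Minimum power for reliable spiking
#'
#' The smallest tested power at which the cell spiked on every trial
#' (the 10/10 rule). Only on-target conditions (zero offset) are considered.
#'
#' @param outcomes a spike-outcome table (see [gen_spike_outcomes()]) for one
#'   cell
#' @return power in mW, or NA if no tested power was fully reliable
#' @export
min_reliable_power <- function(outcomes) {
  on_target <- outcomes[outcomes$lateral_offset == 0 &
                          outcomes$axial_offset == 0, ]
  if (!nrow(on_target)) return(NA_real_)
  by_pow <- split(on_target, on_target$power)
  reliable <- vapply(by_pow, function(df) {
    all(vapply(df$spike_times, function(s) length(s) > 0, logical(1)))
  }, logical(1))
  pows <- as.numeric(names(by_pow))
  if (!any(reliable)) return(NA_real_)
  min(pows[reliable])
}

#' First-spike latency and temporal jitter
#'
#' Latencies are the first spike times (relative to stimulus onset) of the
#' spiking trials; jitter is their sample (n-1) standard deviation.
#'
#' @param spike_times list of numeric vectors, one per trial (ms)
#' @return named vector `c(latency, jitter, n_trials)`; jitter is NA with
#'   fewer than two spiking trials
#' @export
latency_jitter <- function(spike_times) {
  first <- vapply(spike_times, function(s) {
    if (length(s)) min(s) else NA_real_
  }, numeric(1))
  first <- first[is.finite(first)]
  c(latency = if (length(first)) mean(first) else NA_real_,
    jitter = if (length(first) >= 2) stats::sd(first) else NA_real_,
    n_trials = length(first))
}

#' Spike probability per offset distance
#'
#' Collapses an outcome table along one offset axis: trials at the same
#' absolute distance (e.g. the 7 spokes of the radial grid) are pooled, and
#' the probability is the fraction of spiking trials.
#'
#' @param outcomes spike-outcome table
#' @param axis "lateral" or "axial"
#' @param power restrict to this power (default: the largest present)
#' @return data.frame with `offset` (um) and `prob`, including offset 0
#' @export
spike_probability_by_offset <- function(outcomes,
                                        axis = c("lateral", "axial"),
                                        power = max(outcomes$power)) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_offset")
  other <- setdiff(c("lateral_offset", "axial_offset"), col)
  sub <- outcomes[outcomes$power == power & outcomes[[other]] == 0, ]
  d <- abs(sub[[col]])
  spiked <- vapply(sub$spike_times, function(s) length(s) > 0, logical(1))
  agg <- stats::aggregate(spiked, by = list(offset = d), FUN = mean)
  names(agg)[2] <- "prob"
  agg[order(agg$offset), ]
}

#' Fit a Gaussian activation-probability profile along one axis
#'
#' Least-squares fit of `p(d) = A * exp(-d^2 / (2 sigma^2))` with the peak
#' constrained to `A` in (0, 1] and the curve centered at zero offset (no
#' baseline term: spike probability vanishes at large offsets). The FWHM is
#' `2 sqrt(2 ln 2) sigma`. Probabilities that do not decrease with offset
#' produce a warning and an infinite-sigma sentinel.
#'
#' @param offsets offsets (um), must include 0 and at least 3 distinct values
#' @param probs spike probabilities at those offsets
#' @return object of class `resolution_fit` with `sigma`, `fwhm`,
#'   `peak_probability`
#' @export
fit_gaussian_resolution <- function(offsets, probs) {
  stopifnot(length(offsets) == length(probs))
  if (length(unique(offsets)) < 3 || !any(offsets == 0)) {
    stop("need probabilities at >= 3 distinct offsets including 0",
         call. = FALSE)
  }
  stop_if_not_scalar_prob(probs, "probs")
  ord <- order(abs(offsets))
  if (probs[ord][length(probs)] >= probs[ord][1]) {
    # no decrease from the nearest to the farthest offset: the width is not
    # identified (e.g. flat p = 1 everywhere)
    warning("spike probability does not decrease with offset; ",
            "returning infinite-width sentinel", call. = FALSE)
    return(structure(list(sigma = Inf, fwhm = Inf,
                          peak_probability = mean(probs), converged = FALSE),
                     class = "resolution_fit"))
  }
  a0 <- min(1, max(probs))
  half <- abs(offsets)[which.min(abs(probs - a0 / 2))]
  s0 <- max(half / FWHM_FACTOR * 2, 1)
  fit <- minpack.lm::nlsLM(
    probs ~ A * exp(-offsets^2 / (2 * sigma^2)),
    start = list(A = a0, sigma = s0),
    lower = c(1e-6, 1e-3), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(sigma = unname(abs(co["sigma"])),
                 fwhm = FWHM_FACTOR * unname(abs(co["sigma"])),
                 peak_probability = unname(co["A"]),
                 converged = TRUE, fit = fit),
            class = "resolution_fit")
}

#' @export
print.resolution_fit <- function(x, ...) {
  cat(sprintf("<resolution_fit> sigma = %.3g um, FWHM = %.3g um, peak p = %.3g\n",
              x$sigma, x$fwhm, x$peak_probability))
  invisible(x)
}

#' Combine lateral and axial fits into a resolution profile
#'
#' @param lateral,axial `resolution_fit` objects for the two axes
#' @return object of class `resolution_profile` with sigma and FWHM per axis
#' @export
resolution_profile <- function(lateral, axial) {
  structure(list(sigma_lateral = lateral$sigma, sigma_axial = axial$sigma,
                 fwhm_lateral = lateral$fwhm, fwhm_axial = axial$fwhm,
                 peak_probability = min(lateral$peak_probability,
                                        axial$peak_probability)),
            class = "resolution_profile")
}

#' @export
print.resolution_profile <- function(x, ...) {
  cat(sprintf("<resolution_profile> lateral FWHM %.3g um, axial FWHM %.3g um\n",
              x$fwhm_lateral, x$fwhm_axial))
  invisible(x)
}

#' Characterize a cell's photostimulus response from its outcome table
#'
#' Convenience wrapper: minimum reliable power, on-target latency/jitter at
#' mapping power, and Gaussian fits along both axes.
#'
#' @param outcomes spike-outcome table for one cell
#' @param map_power power used for the offset protocols
#' @return list with `min_power`, `latency`, `jitter`, `profile`
#' @export
characterize_cell <- function(outcomes, map_power = max(outcomes$power)) {
  on_target <- outcomes[outcomes$lateral_offset == 0 &
                          outcomes$axial_offset == 0 &
                          outcomes$power == map_power, ]
  lj <- latency_jitter(on_target$spike_times)
  lat <- spike_probability_by_offset(outcomes, "lateral", map_power)
  axi <- spike_probability_by_offset(outcomes, "axial", map_power)
  list(min_power = min_reliable_power(outcomes),
       latency = lj[["latency"]], jitter = lj[["jitter"]],
       profile = resolution_profile(
         fit_gaussian_resolution(lat$offset, lat$prob),
         fit_gaussian_resolution(axi$offset, axi$prob)))
}
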