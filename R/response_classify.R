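# Connection classification: the eleven-feature description of each
# photoresponse, the trained SVM pathway, the annotation-independent z-score
# pathway, and exclusion of direct stimulation artifacts.

# The eleven response features, in fixed order.
response_feature_names <- function() {
  c("peak", "time_of_peak", "sd_at_peak_time", "baseline_sd",
    "deconvolved_peak", "time_of_deconvolved_peak", "deconvolved_baseline_sd",
    "n_crossings_3sd", "n_crossings_5sd", "mean_per_sweep_crossings_3sd",
    "sd_per_sweep_crossings")
}

# count upward crossings of a threshold
n_upcrossings <- function(x, thr) {
  above <- x > thr
  sum(above[-1] & !above[-length(above)]) + as.integer(above[1])
}

#' Extract the eleven photoresponse features
#'
#' Features are measured in a 50 ms post-stimulus window beginning at
#' stimulus onset and a 50 ms pre-stimulus window 70-20 ms before onset; the
#' SDs of the average and deconvolved average responses come from a 20 ms
#' baseline window immediately before onset. Four features describe the
#' average response (peak, time of peak, across-sweep SD at the peak time,
#' baseline SD), five the deconvolved average (peak, its time, baseline SD,
#' numbers of 3x- and 5x-SD crossings) and two the individual deconvolved
#' sweeps (mean and SD of per-sweep 3x-SD crossing counts).
#'
#' @param epochs list of QC'd [trace_epoch()]
#' @param polarity +1 for depolarizing, -1 for hyperpolarizing responses
#' @param window c("post", "pre"): measure in the post-stimulus window or in
#'   the pre-stimulus control window
#' @param params a [deconv_params()]
#' @param smooth_ms boxcar width (ms) applied to deconvolved traces before
#'   measuring peaks and crossings (matches the detection smoothing)
#' @return named numeric vector of length 11
#' @export
extract_features <- function(epochs, polarity = 1,
                             window = c("post", "pre"),
                             params = deconv_params(), smooth_ms = 0.5) {
  window <- match.arg(window)
  b <- lapply(epochs, baseline_subtract)
  if (polarity < 0) b <- lapply(b, function(ep) { ep$voltage <- -ep$voltage; ep })
  mat <- do.call(cbind, lapply(b, `[[`, "voltage"))
  avg <- rowMeans(mat)
  ep1 <- b[[1]]
  dt <- ep1$sample_interval
  dt_ms <- dt * 1000
  on <- ep1$stim_onset_index
  n50 <- ms_to_samples(50, dt)
  idx <- if (window == "post") on:(on + n50) else
    (on - ms_to_samples(70, dt)):(on - ms_to_samples(20, dt))
  nb <- ms_to_samples(params$baseline_window_ms, dt)
  base_idx <- (on - nb):(on - 1L)

  base_sd <- stats::sd(avg[base_idx])
  pk_i <- idx[which.max(avg[idx])]
  dec <- deconvolve(avg, params$tau, dt)
  if (smooth_ms > 0) dec <- boxcar_smooth(dec, smooth_ms, dt)
  dsd <- stats::sd(dec[base_idx])
  dpk_i <- idx[which.max(dec[idx])]
  per_sweep_cross <- if (length(b) >= 2) {
    vapply(seq_along(b), function(k) {
      dk <- deconvolve(mat[, k], params$tau, dt)
      if (smooth_ms > 0) dk <- boxcar_smooth(dk, smooth_ms, dt)
      sdk <- stats::sd(dk[base_idx])
      n_upcrossings(dk[idx], 3 * sdk)
    }, numeric(1))
  } else NA_real_
  c(peak = avg[pk_i],
    time_of_peak = (pk_i - on) * dt_ms,
    sd_at_peak_time = if (ncol(mat) >= 2) stats::sd(mat[pk_i, ]) else NA_real_,
    baseline_sd = base_sd,
    deconvolved_peak = dec[dpk_i],
    time_of_deconvolved_peak = (dpk_i - on) * dt_ms,
    deconvolved_baseline_sd = dsd,
    n_crossings_3sd = n_upcrossings(dec[idx], 3 * dsd),
    n_crossings_5sd = n_upcrossings(dec[idx], 5 * dsd),
    mean_per_sweep_crossings_3sd = mean(per_sweep_cross),
    sd_per_sweep_crossings = if (length(b) >= 2) stats::sd(per_sweep_cross)
    else NA_real_)
}

#' Train a support-vector connection classifier
#'
#' Radial-basis SVM on the eleven response features, z-scored on the training
#' split. Excitatory and inhibitory datasets are trained separately (pass
#' them separately). The split is seeded and reported together with the
#' held-out accuracy.
#'
#' @param features matrix or data.frame, one row per probed pair, columns the
#'   eleven features of [extract_features()]
#' @param labels logical or factor: connected / not connected
#' @param split_fraction fraction used for training (default 0.4)
#' @param seed integer seed for the split
#' @param ... passed to [e1071::svm()]
#' @return object of class `psp_svm`: the fitted model, scaling, split
#'   indices and `accuracy` on the held-out set
#' @export
train_classifier <- function(features, labels, split_fraction = 0.4, seed = 1,
                             ...) {
  x <- as.matrix(features)
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(x)
  idx_train <- with_substream(seed, "svm_split", {
    sample.int(n, size = max(2, round(split_fraction * n)))
  })
  ctr <- colMeans(x[idx_train, , drop = FALSE])
  scl <- apply(x[idx_train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  zx <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- e1071::svm(zx[idx_train, , drop = FALSE], y[idx_train],
                    kernel = "radial", ...)
  test <- setdiff(seq_len(n), idx_train)
  pred <- stats::predict(fit, zx[test, , drop = FALSE])
  structure(list(model = fit, center = ctr, scale = scl,
                 train_index = idx_train,
                 accuracy = mean(pred == y[test]),
                 n_train = length(idx_train), n_test = length(test)),
            class = "psp_svm")
}

#' @export
print.psp_svm <- function(x, ...) {
  cat(sprintf("<psp_svm> trained on %d pairs, held-out accuracy %.1f%% (n = %d)\n",
              x$n_train, 100 * x$accuracy, x$n_test))
  invisible(x)
}

#' Predict connection labels with a trained classifier
#'
#' @param object a `psp_svm`
#' @param newdata feature matrix
#' @param ... unused
#' @return logical vector of connected calls
#' @export
predict.psp_svm <- function(object, newdata, ...) {
  zx <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  as.logical(stats::predict(object$model, zx))
}

#' Compute pre- and post-stimulus z-scores for one photoresponse
#'
#' The post z-score is the peak absolute amplitude of the average response in
#' the 50 ms post-stimulus window divided by the SD of the average response
#' in a 20 ms baseline window; the pre z-score is the same statistic measured
#' in the 50 ms control window 70-20 ms before onset.
#'
#' @param epochs list of [trace_epoch()]
#' @param polarity +1 or -1
#' @param params a [deconv_params()]
#' @return named numeric vector `c(pre_z, post_z)`
#' @export
compute_zscores <- function(epochs, polarity = 1, params = deconv_params()) {
  b <- lapply(epochs, baseline_subtract)
  if (polarity < 0) b <- lapply(b, function(ep) { ep$voltage <- -ep$voltage; ep })
  avg <- rowMeans(do.call(cbind, lapply(b, `[[`, "voltage")))
  ep1 <- b[[1]]
  dt <- ep1$sample_interval
  on <- ep1$stim_onset_index
  nb <- ms_to_samples(params$baseline_window_ms, dt)
  base_sd <- stats::sd(avg[(on - nb):(on - 1L)])
  n50 <- ms_to_samples(50, dt)
  post <- max(avg[on:(on + n50)])
  pre <- max(avg[(on - ms_to_samples(70, dt)):(on - ms_to_samples(20, dt))])
  c(pre_z = pre / base_sd, post_z = post / base_sd)
}

#' Annotation-independent z-score classifier
#'
#' The threshold is the empirical 99th percentile of all pre-stimulus
#' z-scores in the dataset (computed per polarity when both are present);
#' a pair is called connected iff its post-stimulus z-score strictly exceeds
#' the threshold. By construction about 1% of unconnected pairs are flagged.
#'
#' @param zscores data.frame with columns `pre_z` and `post_z` (one row per
#'   probed pair), e.g. built from [compute_zscores()]
#' @param percentile threshold percentile of pre-stimulus z-scores
#' @return list of class `zscore_classification`: `connected` logical,
#'   `threshold`
#' @export
zscore_classifier <- function(zscores, percentile = 0.99) {
  zscores <- as.data.frame(zscores)
  if (nrow(zscores) < 100) {
    warning("fewer than 100 pairs: the ", percentile * 100,
            "th percentile threshold is coarse", call. = FALSE)
  }
  thr <- stats::quantile(zscores$pre_z, percentile, names = FALSE,
                         na.rm = TRUE)
  structure(list(connected = zscores$post_z > thr, threshold = thr,
                 percentile = percentile),
            class = "zscore_classification")
}

#' Flag direct stimulation artifacts
#'
#' In opsin-positive patched cells, photostimulation near the soma produces a
#' depolarization whose onset coincides with stimulus onset, unlike synaptic
#' responses which lag by at least a synaptic delay. A response is excluded
#' when its detected onset falls within `margin_ms` of stimulus onset.
#' Opsin-negative cells are never excluded.
#'
#' @param epochs list of [trace_epoch()]
#' @param opsin_positive_post is the patched cell opsin-positive
#' @param margin_ms onset margin (ms)
#' @param params a [deconv_params()]
#' @return logical: TRUE if the pair must be excluded from probability
#'   denominators
#' @export
flag_direct_artifact <- function(epochs, opsin_positive_post,
                                 margin_ms = 1, params = deconv_params()) {
  if (!isTRUE(opsin_positive_post)) return(FALSE)
  avg <- average_response(qc_sweeps(epochs))
  det <- detect_psp_window(avg, params)
  if (!length(det$windows)) return(FALSE)
  onset_ms <- (det$windows[[1]][1] - avg$stim_onset_index) *
    avg$sample_interval * 1000
  onset_ms <= margin_ms
}

#' Classify every pair of a synthetic or measured experiment
#'
#' Runs the z-score pathway (and optionally a trained SVM) over the epochs of
#' an experiment and returns the pairs table with `connected` filled in.
#'
#' @param experiment result of [gen_experiment()] (or a list with `dataset`
#'   and `epochs`)
#' @param method "zscore" or "svm"
#' @param svm_fit optional trained [train_classifier()] model for
#'   `method = "svm"`
#' @param polarity +1 or -1
#' @return the pairs data.frame with columns `connected` (classifier call),
#'   `artifact_excluded`, `pre_z`, `post_z`
#' @export
classify_experiment <- function(experiment, method = c("zscore", "svm"),
                                svm_fit = NULL, polarity = 1) {
  method <- match.arg(method)
  pairs <- experiment$dataset$pairs
  eps <- experiment$epochs
  z <- t(vapply(pairs$pair_id, function(pid) {
    compute_zscores(eps[[pid]], polarity = polarity)
  }, numeric(2)))
  pairs$pre_z <- z[, "pre_z"]; pairs$post_z <- z[, "post_z"]
  if (method == "zscore") {
    cls <- zscore_classifier(pairs[, c("pre_z", "post_z")])
    pairs$connected <- cls$connected
    attr(pairs, "threshold") <- cls$threshold
  } else {
    stopifnot(inherits(svm_fit, "psp_svm"))
    feats <- t(vapply(pairs$pair_id, function(pid) {
      extract_features(eps[[pid]], polarity = polarity)
    }, numeric(11)))
    pairs$connected <- predict(svm_fit, feats)
  }
  if (!is.null(pairs$opsin_positive_post)) {
    pairs$artifact_excluded <- vapply(seq_len(nrow(pairs)), function(i) {
      pairs$connected[i] &&
        flag_direct_artifact(eps[[pairs$pair_id[i]]],
                             pairs$opsin_positive_post[i])
    }, logical(1))
  }
  pairs
}
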