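# Intrinsic electrophysiology: extraction of the 14 standard features from a
# family of 1 s current steps, and unsupervised clustering of interneurons
# into fast-spiking (putative Pvalb), putative VIP and putative Sst classes.

intrinsic_feature_names <- function() {
  c("v_rest", "input_resistance", "tau", "capacitance", "sag", "rheobase",
    "ap_fwhm", "upstroke_downstroke_ratio", "ap_peak", "ap_trough",
    "ap_height", "avg_firing_rate", "adaptation_index", "f_i_slope")
}

#' Reference intrinsic-property statistics per cell class
#'
#' Population means and SDs of the 14 intrinsic features for L2/3 pyramidal
#' cells and the three interneuron classes, used as defaults when simulating
#' feature populations and to map clusters onto class labels.
#'
#' @return data.frame: feature, then mean/sd per class
#' @export
intrinsic_reference_stats <- function() {
  df <- data.frame(
    feature = intrinsic_feature_names(),
    pc_mean  = c(-72.8, 90.3, 14.4, 171, 0.032, 171, 1.37, 4.30, 40.6, -48.4, 89.0, 7.78, 0.090, 0.12),
    pc_sd    = c(6.7, 31.5, 4.3, 58, 0.027, 75, 0.31, 0.68, 8.0, 4.9, 10.1, 2.36, 0.079, 0.06),
    fsi_mean = c(-68.2, 92.4, 6.5, 80, 0.062, 268, 0.62, 1.72, 19.5, -53.0, 72.5, 30.9, 0.008, 0.66),
    fsi_sd   = c(7.3, 33.8, 1.8, 44, 0.042, 119, 0.17, 0.23, 7.9, 5.16, 10.2, 10.8, 0.021, 0.19),
    vip_mean = c(-62.6, 174, 9.9, 56, 0.117, 126, 1.25, 3.36, 27.5, -51.0, 78.5, 15.5, 0.044, 0.20),
    vip_sd   = c(10.5, 64.3, 4.3, 15, 0.068, 77, 0.29, 0.58, 12.7, 2.8, 13.1, 11.3, 0.083, 0.11),
    sst_mean = c(-61.8, 199, 16.8, 87, 0.16, 129, 0.79, 2.10, 24.0, -52.7, 76.7, 15.6, 0.081, 0.29),
    sst_sd   = c(4.6, 57.0, 4.3, 20, 0.096, 52, 0.14, 0.36, 13.4, 5.2, 17.0, 6.6, 0.090, 0.11))
  df
}

#' Extract the 14 intrinsic features from a current-step sweep family
#'
#' Input resistance comes from the steady-state deflection of hyperpolarizing
#' steps (last 100 ms of the step), the membrane time constant from an
#' exponential fit to the charging phase of hyperpolarizing steps excluding
#' the smallest (-10 pA, too contaminated by background synaptic activity),
#' capacitance is tau / R. Sag is (peak - steady) / peak deflection on the
#' -130 pA step. Rheobase is the smallest step evoking a spike; AP shape
#' features (FWHM at half height, upstroke/downstroke ratio, peak, trough,
#' height) come from the first AP at rheobase; firing rate and adaptation
#' index from the step 40 pA above rheobase; the f-I slope from a linear fit
#' of rate against current over suprathreshold steps.
#'
#' @param sweeps an `intrinsic_sweeps` family (see [gen_intrinsic_sweeps()])
#' @return named numeric vector of the 14 features (AP features NA when no
#'   sweep reaches threshold)
#' @export
extract_intrinsic <- function(sweeps) {
  currents <- vapply(sweeps, `[[`, numeric(1), "current_pA")
  dt_ms <- sweeps[[1]]$sample_interval * 1000
  i0 <- sweeps[[1]]$step_start_index; i1 <- sweeps[[1]]$step_end_index
  baseline <- function(sw) mean(sw$voltage[1:(i0 - 1L)])
  steady <- function(sw) {
    n100 <- round(100 / dt_ms)
    mean(sw$voltage[(i1 - n100):i1])
  }
  v_rest <- mean(vapply(sweeps, baseline, numeric(1)))
  hyp <- which(currents < 0)
  defl <- vapply(sweeps[hyp], function(sw) steady(sw) - baseline(sw),
                 numeric(1))
  rin <- stats::coef(stats::lm(defl ~ 0 + currents[hyp]))[[1]] * 1000 # MOhm
  # tau: exponential fit to the charging phase, excluding the smallest step
  fit_steps <- hyp[abs(currents[hyp]) > 10]
  taus <- vapply(sweeps[fit_steps], function(sw) {
    b <- baseline(sw); ss <- steady(sw)
    n_fit <- round(100 / dt_ms)
    y <- sw$voltage[i0:(i0 + n_fit)] - b
    d <- ss - b
    # rough tau from the linearized early charging phase, then a free-
    # asymptote exponential fit over ~2.5 rough time constants (the free
    # asymptote keeps slow components such as sag from biasing tau)
    frac <- y / d
    ok <- which(frac > 0.05 & frac < 0.6)
    if (length(ok) < 5) return(NA_real_)
    t_ms <- (ok - 1) * dt_ms
    tau0 <- -1 / stats::coef(stats::lm(log(1 - frac[ok]) ~ 0 + t_ms))[[1]]
    n_win <- min(length(y), max(10L, round(2.5 * tau0 / dt_ms)))
    tw <- (seq_len(n_win) - 1) * dt_ms
    yw <- y[seq_len(n_win)]
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(yw ~ A * (1 - exp(-tw / tau)),
                   start = list(A = d, tau = tau0),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) tau0 else stats::coef(fit)[["tau"]]
  }, numeric(1))
  tau <- stats::median(taus, na.rm = TRUE)
  # sag on the largest hyperpolarizing step
  big <- which.min(currents)
  swb <- sweeps[[big]]
  b <- baseline(swb)
  peak_defl <- min(swb$voltage[i0:i1]) - b
  steady_defl <- steady(swb) - b
  sag <- if (peak_defl < 0) (peak_defl - steady_defl) / peak_defl else 0
  sag <- max(0, sag)
  # spikes
  spike_idx <- function(sw, thr = -20) {
    v <- sw$voltage[i0:i1]
    above <- v > thr
    which(above & !c(FALSE, above[-length(above)]))
  }
  n_spikes <- vapply(sweeps, function(sw) length(spike_idx(sw)), integer(1))
  supra <- which(n_spikes > 0 & currents > 0)
  if (!length(supra)) {
    ap <- rep(NA_real_, 8)
    names(ap) <- c("rheobase", "ap_fwhm", "upstroke_downstroke_ratio",
                   "ap_peak", "ap_trough", "ap_height", "avg_firing_rate",
                   "adaptation_index")
    fi <- NA_real_
  } else {
    rheo_i <- supra[1]
    rheobase <- currents[rheo_i]
    sw <- sweeps[[rheo_i]]
    v <- sw$voltage
    s1 <- spike_idx(sw)[1] + i0 - 1L
    # first AP: peak, then trough within 10 ms after the peak
    seg_end <- min(length(v), s1 + round(10 / dt_ms))
    pk_i <- (s1:seg_end)[which.max(v[s1:seg_end])]
    tr_i <- (pk_i:seg_end)[which.min(v[pk_i:seg_end])]
    ap_peak <- v[pk_i]; ap_trough <- v[tr_i]
    height <- ap_peak - ap_trough
    half <- ap_trough + height / 2
    above <- which(v > half)
    above <- above[above >= s1 - round(5 / dt_ms) & above <= tr_i]
    fwhm <- length(above) * dt_ms
    dv <- diff(v[(s1 - round(2 / dt_ms)):tr_i]) / dt_ms
    ud <- max(dv) / abs(min(dv))
    # rate and adaptation at rheobase + 40 pA
    tgt <- which.min(abs(currents - (rheobase + 40)))
    spk40 <- spike_idx(sweeps[[tgt]])
    rate <- length(spk40) / ((i1 - i0 + 1) * dt_ms / 1000)
    adi <- if (length(spk40) >= 3) {
      isi <- diff(spk40) * dt_ms
      mean(diff(isi) / (isi[-1] + isi[-length(isi)]))
    } else NA_real_
    ap <- c(rheobase = rheobase, ap_fwhm = fwhm,
            upstroke_downstroke_ratio = ud, ap_peak = ap_peak,
            ap_trough = ap_trough, ap_height = height,
            avg_firing_rate = rate, adaptation_index = adi)
    rates <- n_spikes[supra] / ((i1 - i0 + 1) * dt_ms / 1000)
    fi <- if (length(supra) >= 2) {
      stats::coef(stats::lm(rates ~ currents[supra]))[[2]]
    } else NA_real_
  }
  out <- c(v_rest = v_rest, input_resistance = rin, tau = tau,
           capacitance = tau / rin * 1000, sag = sag, ap, f_i_slope = fi)
  out[intrinsic_feature_names()]
}

#' Simulate interneuron feature populations
#'
#' Draws independent normal feature vectors per class at the reference means
#' and SDs (see [intrinsic_reference_stats()]); `ap_height` is recomputed as
#' `ap_peak - ap_trough` to respect the identity among the drawn features.
#'
#' @param n_per_class cells per class
#' @param classes which classes to draw
#' @param seed integer seed
#' @param stats reference table in the format of
#'   [intrinsic_reference_stats()]
#' @return list with `features` (matrix) and `labels`
#' @export
simulate_interneuron_features <- function(n_per_class = 30,
                                          classes = c("fsi", "vip", "sst"),
                                          seed = 1,
                                          stats = intrinsic_reference_stats()) {
  feats <- intrinsic_feature_names()
  with_substream(seed, "interneuron_features", {
    mats <- lapply(classes, function(cl) {
      mu <- stats[[paste0(cl, "_mean")]]
      sd <- stats[[paste0(cl, "_sd")]]
      m <- vapply(seq_along(feats), function(k) {
        stats::rnorm(n_per_class, mu[k], sd[k])
      }, numeric(n_per_class))
      colnames(m) <- feats
      m[, "ap_height"] <- m[, "ap_peak"] - m[, "ap_trough"]
      m
    })
    list(features = do.call(rbind, mats),
         labels = rep(toupper(classes), each = n_per_class))
  })
}

#' Cluster interneurons into FSI / putative VIP / putative Sst
#'
#' Features are z-scored and clustered into three components with a Gaussian
#' mixture (model selected by BIC among diagonal/spherical covariance
#' families, appropriate for 14 features at typical cell counts) or with
#' Ward agglomerative clustering. Components are mapped to class labels by
#' canonical signatures: the cluster with the narrowest mean AP width is
#' FSI; of the remaining two, the one with the larger mean sag is putative
#' Sst and the other putative VIP.
#'
#' @param features matrix or data.frame of the 14 intrinsic features
#' @param method "gmm" (default) or "ward"
#' @param seed integer seed (GMM initialization)
#' @return factor of labels "FSI", "VIP", "SST" with the model as attribute
#' @import mclust
#' @export
cluster_interneurons <- function(features, method = c("gmm", "ward"),
                                 seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(features)[, intrinsic_feature_names(), drop = FALSE]
  if (nrow(x) < 3) stop("need at least as many cells as clusters",
                        call. = FALSE)
  z <- scale(x)
  z[, apply(z, 2, function(col) any(!is.finite(col)))] <- 0
  cl <- if (method == "gmm") {
    with_substream(seed, "gmm", {
      # EM on a diagonal-covariance Gaussian mixture with multiple restarts
      # (k-means and random initializations), keeping the solution with the
      # highest log-likelihood; single-start EM lands in merged-cluster
      # local optima on a noticeable fraction of draws
      km <- stats::kmeans(z, 3, nstart = 50, iter.max = 50)
      inits <- c(list(km$cluster),
                 lapply(1:10, function(i) sample.int(3, nrow(z),
                                                     replace = TRUE)))
      best <- NULL
      for (ini in inits) {
        if (length(unique(ini)) < 3) next
        em <- tryCatch(
          mclust::me(data = z, modelName = "VVI", z = mclust::unmap(ini)),
          error = function(e) NULL)
        ok <- !is.null(em) && !is.null(em$z) && all(is.finite(em$z)) &&
          is.finite(em$loglik)
        if (ok && (is.null(best) || em$loglik > best$loglik)) best <- em
      }
      if (!is.null(best)) max.col(best$z) else km$cluster
    })
  } else {
    stats::cutree(stats::hclust(stats::dist(z), method = "ward.D2"), k = 3)
  }
  # map clusters to classes by total standardized distance between cluster
  # centroids and the reference class means (best over all assignments);
  # single-feature signatures (e.g. sag for Sst) overlap too much between
  # putative VIP and Sst cells to be reliable on their own
  st <- intrinsic_reference_stats()
  classes <- c("FSI", "VIP", "SST")
  ref_mean <- cbind(FSI = st$fsi_mean, VIP = st$vip_mean, SST = st$sst_mean)
  ref_sd <- cbind(FSI = st$fsi_sd, VIP = st$vip_sd, SST = st$sst_sd)
  cl_ids <- sort(unique(cl))
  cent <- t(vapply(cl_ids, function(k) colMeans(x[cl == k, , drop = FALSE]),
                   numeric(ncol(x))))
  dist_to <- function(ci, cj) {
    sum(((cent[ci, ] - ref_mean[, cj]) / ref_sd[, cj])^2)
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  cost <- vapply(perms, function(pm) {
    sum(vapply(seq_along(cl_ids), function(i) dist_to(i, classes[pm[i]]),
               numeric(1)))
  }, numeric(1))
  pm <- perms[[which.min(cost)]]
  map <- stats::setNames(classes[pm], cl_ids)
  out <- factor(map[as.character(cl)], levels = c("FSI", "VIP", "SST"))
  attr(out, "cluster") <- cl
  out
}
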