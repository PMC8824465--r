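# Convergence/divergence motif counting, completed-motif conditional
# probabilities, the distance- and subclass-conditioned bootstrap null, and
# amplitude correlations with the double-plotting convention.
#
# Throughout, a "pair" is one probed (photostimulated cell, patched cell)
# connection; artifact-excluded pairs are ignored. All motif operations work
# within experiments (cells of different experiments never form motifs).

motif_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs)
  keep <- !as.logical(pairs$artifact_excluded)
  pairs <- pairs[keep, ]
  pairs$connected <- as.logical(pairs$connected)
  pairs
}

#' Count convergence and divergence motifs
#'
#' Convergence: unordered pairs of presynaptic cells both connected to the
#' same patched cell. Divergence: unordered pairs of patched cells both
#' receiving a connection from the same photostimulated cell (plus, as
#' `divergent_cells`, the number of presynaptic cells connected to at least
#' two recorded cells). Denominators are the corresponding eligible pair
#' counts among probed connections.
#'
#' @param pairs connection-table data.frame (columns `experiment_id`,
#'   `pre_cell_id`, `post_cell_id`, `connected`, `artifact_excluded`)
#' @return object of class `motif_counts`
#' @export
count_motifs <- function(pairs) {
  p <- motif_pairs(pairs)
  choose2 <- function(k) k * (k - 1) / 2
  post_key <- interaction(p$experiment_id, p$post_cell_id, drop = TRUE)
  pre_key <- interaction(p$experiment_id, p$pre_cell_id, drop = TRUE)
  conv <- sum(choose2(tapply(p$connected, post_key, sum)))
  conv_elig <- sum(choose2(tapply(p$connected, post_key, length)))
  div_counts <- tapply(p$connected, pre_key, sum)
  div <- sum(choose2(div_counts))
  div_elig <- sum(choose2(tapply(p$connected, pre_key, length)))
  structure(list(convergence = unname(conv),
                 convergence_eligible = unname(conv_elig),
                 divergence = unname(div),
                 divergence_eligible = unname(div_elig),
                 divergent_cells = sum(div_counts >= 2)),
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat(sprintf("<motif_counts> convergence %d/%d, divergence %d/%d (%d divergent cells)\n",
              x$convergence, x$convergence_eligible,
              x$divergence, x$divergence_eligible, x$divergent_cells))
  invisible(x)
}

# internal: per-bin conditional probability with Jeffreys CI
conditional_curve <- function(dist, completed, bin_width) {
  if (!length(dist)) {
    return(structure(data.frame(), class = c("conditional_probability_curve",
                                             "data.frame")))
  }
  edges <- seq(0, max(dist) + bin_width, by = bin_width)
  bin <- findInterval(dist, edges)
  num <- tapply(completed, bin, sum)
  den <- tapply(completed, bin, length)
  ids <- as.integer(names(num))
  ci <- jeffreys_interval(as.integer(num), as.integer(den))
  out <- data.frame(bin_lo = edges[ids], bin_hi = edges[ids + 1L],
                    completed = as.integer(num), eligible = as.integer(den),
                    probability = as.numeric(num / den),
                    jeffreys_lo = ci$lo, jeffreys_hi = ci$hi)
  rownames(out) <- NULL
  structure(out, class = c("conditional_probability_curve", "data.frame"))
}

#' Completed-convergence probability versus distance
#'
#' Enumerates all ordered pairs of photostimulated cells (i, j) probed
#' against a common patched cell in which cell i is connected, and reports
#' the fraction in which cell j is also connected (P(j | i)), binned by
#' distance. Both orders of each pair are counted, so a doubly connected
#' pair contributes to numerator and denominator in both roles.
#'
#' @param pairs connection-table data.frame
#' @param axis distance definition: "between_presyn" (absolute difference of
#'   horizontal offsets of the two photostimulated cells) or
#'   "presyn_to_post" (absolute horizontal offset of cell j)
#' @param bin_width bin width (um)
#' @return `conditional_probability_curve` data.frame
#' @export
completed_convergence <- function(pairs,
                                  axis = c("between_presyn",
                                           "presyn_to_post"),
                                  bin_width = 100) {
  axis <- match.arg(axis)
  p <- motif_pairs(pairs)
  dist <- numeric(0); comp <- logical(0)
  for (key in unique(interaction(p$experiment_id, p$post_cell_id,
                                 drop = TRUE))) {
    g <- p[interaction(p$experiment_id, p$post_cell_id, drop = TRUE) == key, ]
    n <- nrow(g)
    if (n < 2) next
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, ]
    sel <- g$connected[idx$i]
    if (!any(sel)) next
    idx <- idx[sel, ]
    d <- switch(axis,
                between_presyn = abs(g$horizontal_offset_um[idx$i] -
                                       g$horizontal_offset_um[idx$j]),
                presyn_to_post = abs(g$horizontal_offset_um[idx$j]))
    dist <- c(dist, d)
    comp <- c(comp, g$connected[idx$j])
  }
  conditional_curve(dist, comp, bin_width)
}

#' Completed-divergence probability versus distance
#'
#' Enumerates all ordered pairs of patched cells (i, j) sharing a common
#' photostimulated cell where cell i receives a connection, and reports the
#' fraction in which cell j also receives one, binned by the 3D intersomatic
#' distance between the patched cells. Optionally restricts cell j to a
#' postsynaptic subclass (e.g. "L2/3 PC") for comparison against overall
#' connection probabilities.
#'
#' @param pairs connection-table data.frame
#' @param post_positions data.frame with `experiment_id`, `post_cell_id`,
#'   `x`, `y`, `z` (um) giving patched-cell somata
#' @param bin_width bin width (um)
#' @param j_subclass optional subclass filter applied to cell j
#' @return `conditional_probability_curve` data.frame
#' @export
completed_divergence <- function(pairs, post_positions, bin_width = 100,
                                 j_subclass = NULL) {
  p <- motif_pairs(pairs)
  pk <- paste(post_positions$experiment_id, post_positions$post_cell_id)
  pos <- as.matrix(post_positions[, c("x", "y", "z")])
  rownames(pos) <- pk
  dist <- numeric(0); comp <- logical(0)
  for (key in unique(interaction(p$experiment_id, p$pre_cell_id,
                                 drop = TRUE))) {
    g <- p[interaction(p$experiment_id, p$pre_cell_id, drop = TRUE) == key, ]
    n <- nrow(g)
    if (n < 2) next
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$i != idx$j, ]
    sel <- g$connected[idx$i]
    if (!is.null(j_subclass)) sel <- sel & g$post_subclass[idx$j] %in% j_subclass
    if (!any(sel)) next
    idx <- idx[sel, ]
    ki <- paste(g$experiment_id[idx$i], g$post_cell_id[idx$i])
    kj <- paste(g$experiment_id[idx$j], g$post_cell_id[idx$j])
    d <- sqrt(rowSums((pos[ki, , drop = FALSE] - pos[kj, , drop = FALSE])^2))
    dist <- c(dist, d)
    comp <- c(comp, g$connected[idx$j])
  }
  conditional_curve(dist, comp, bin_width)
}

#' Estimate the binned connection-probability table used by the null model
#'
#' Probabilities over (horizontal offset bin x presynaptic pia bin x
#' presynaptic Cre line x postsynaptic subclass), 100 um x 100 um bins by
#' default. Bins with zero found connections contribute probability 0
#' unless `laplace = TRUE`, which adds a (found + 1)/(probed + 2) smoothing.
#'
#' @param pairs connection-table data.frame
#' @param bin_width bin width (um)
#' @param laplace apply add-one smoothing
#' @return data.frame keyed by bin and subclass with `found`, `probed`,
#'   `probability`
#' @export
connection_probability_table <- function(pairs, bin_width = 100,
                                         laplace = FALSE) {
  p <- motif_pairs(pairs)
  key <- paste(floor(abs(p$horizontal_offset_um) / bin_width),
               floor(p$pre_pia_um / bin_width),
               p$cre_line, p$post_subclass, sep = "|")
  found <- tapply(p$connected, key, sum)
  probed <- tapply(p$connected, key, length)
  prob <- if (laplace) (found + 1) / (probed + 2) else found / probed
  data.frame(key = names(found), found = as.integer(found),
             probed = as.integer(probed), probability = as.numeric(prob),
             stringsAsFactors = FALSE)
}

#' Bootstrap test for motif overrepresentation
#'
#' Simulates random connectivity of the dataset `n_sim` times: the geometry
#' and subclass of every probed pair is preserved and only the Bernoulli
#' connection outcome is redrawn at the pair's binned connection probability
#' (estimated from the same dataset over horizontal-offset x presynaptic-pia
#' bins and subclass). Convergence and divergence motif counts are tallied
#' per simulation; the one-sided p-value is the fraction of simulations with
#' a count greater than or equal to the observed count, reported as
#' `< 1/n_sim` when no simulation reaches it.
#'
#' @param pairs connection-table data.frame
#' @param n_sim number of simulations (default 1000)
#' @param seed integer seed
#' @param bin_width probability-table bin width (um)
#' @param laplace smoothing flag passed to [connection_probability_table()]
#' @param prob optional vector of per-pair connection probabilities to use
#'   as the null instead of the table estimated from the dataset (e.g. the
#'   known generative probabilities in calibration studies; plug-in
#'   estimation from the same data makes p-values conservative)
#' @return object of class `motif_bootstrap`: observed counts, simulated
#'   count matrix, p-values and display labels
#' @export
bootstrap_motif_test <- function(pairs, n_sim = 1000, seed = 1,
                                 bin_width = 100, laplace = FALSE,
                                 prob = NULL) {
  p <- motif_pairs(pairs)
  if (is.null(prob)) {
    tab <- connection_probability_table(p, bin_width, laplace)
    key <- paste(floor(abs(p$horizontal_offset_um) / bin_width),
                 floor(p$pre_pia_um / bin_width),
                 p$cre_line, p$post_subclass, sep = "|")
    prob <- tab$probability[match(key, tab$key)]
  } else {
    stopifnot(length(prob) == nrow(p))
  }
  obs <- count_motifs(p)
  post_key <- as.integer(interaction(p$experiment_id, p$post_cell_id,
                                     drop = TRUE))
  pre_key <- as.integer(interaction(p$experiment_id, p$pre_cell_id,
                                    drop = TRUE))
  n_pair <- nrow(p)
  sims <- with_substream(seed, "motif_bootstrap", {
    t(vapply(seq_len(n_sim), function(s) {
      conn <- stats::runif(n_pair) < prob
      kc <- tapply(conn, post_key, sum)
      kd <- tapply(conn, pre_key, sum)
      c(convergence = sum(kc * (kc - 1) / 2),
        divergence = sum(kd * (kd - 1) / 2))
    }, numeric(2)))
  })
  p_of <- function(observed, sim) mean(sim >= observed)
  p_conv <- p_of(obs$convergence, sims[, "convergence"])
  p_div <- p_of(obs$divergence, sims[, "divergence"])
  label <- function(pv) if (pv == 0) sprintf("<%g", 1 / n_sim) else
    sprintf("%g", pv)
  structure(list(observed = obs, simulated = sims, n_sim = n_sim,
                 p_convergence = p_conv, p_divergence = p_div,
                 p_convergence_label = label(p_conv),
                 p_divergence_label = label(p_div)),
            class = "motif_bootstrap")
}

#' @export
print.motif_bootstrap <- function(x, ...) {
  cat(sprintf("<motif_bootstrap> %d simulations\n", x$n_sim))
  cat(sprintf("  convergence: observed %d, null mean %.1f, p %s\n",
              x$observed$convergence, mean(x$simulated[, "convergence"]),
              x$p_convergence_label))
  cat(sprintf("  divergence:  observed %d, null mean %.1f, p %s\n",
              x$observed$divergence, mean(x$simulated[, "divergence"]),
              x$p_divergence_label))
  invisible(x)
}

#' Amplitude correlation across connection pairs with double plotting
#'
#' For pairs of connections sharing a pre- or postsynaptic cell, assignment
#' of the two amplitudes to axes would be arbitrary, so every unordered pair
#' is plotted twice (once as (i, j), once as (j, i)) and Pearson's r is
#' computed on the doubled set. The p-value uses the number of unique
#' unordered pairs (half the plotted points) as the sample size.
#'
#' @param amp_i,amp_j amplitudes of the two connections of each unordered
#'   pair (one entry per unique pair)
#' @param log_space take natural logs of the amplitudes first
#' @return list with `r`, `p_value`, `n_unique`
#' @export
amplitude_correlation <- function(amp_i, amp_j, log_space = FALSE) {
  stopifnot(length(amp_i) == length(amp_j))
  n_unique <- length(amp_i)
  if (n_unique < 3) stop("need at least 3 unique unordered pairs",
                         call. = FALSE)
  if (log_space) { amp_i <- log(amp_i); amp_j <- log(amp_j) }
  x <- c(amp_i, amp_j); y <- c(amp_j, amp_i)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n_unique = n_unique))
  }
  r <- stats::cor(x, y)
  df <- n_unique - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tt), df), n_unique = n_unique)
}
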