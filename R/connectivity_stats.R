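# Connection-probability estimation with distance binning and Jeffreys
# intervals, exact contingency tests, multiple-testing correction, effect
# sizes, rank-based group comparisons, and the cross-method comparison of
# optogenetic mapping against paired recordings.

#' Jeffreys 95% interval for a binomial proportion
#'
#' Equal-tailed quantiles of Beta(found + 1/2, probed - found + 1/2), the
#' Bayesian binomial interval under the Jeffreys prior. Boundary convention:
#' the lower limit is 0 when found = 0 and the upper limit is 1 when
#' found = probed.
#'
#' @param found,probed connection counts (vectorized)
#' @param level interval level (default 0.95)
#' @return data.frame with columns `lo`, `hi`
#' @export
jeffreys_interval <- function(found, probed, level = 0.95) {
  if (any(found < 0) || any(probed < 1) || any(found > probed)) {
    stop("need 0 <= found <= probed with probed >= 1", call. = FALSE)
  }
  a <- (1 - level) / 2
  lo <- stats::qbeta(a, found + 0.5, probed - found + 0.5)
  hi <- stats::qbeta(1 - a, found + 0.5, probed - found + 0.5)
  lo[found == 0] <- 0
  hi[found == probed] <- 1
  data.frame(lo = lo, hi = hi)
}

#' Binned connection probability along a distance axis
#'
#' Artifact-excluded pairs never enter the denominators. Bins are half-open
#' `[lo, hi)`; each bin reports found/probed, the proportion, its Jeffreys
#' 95% interval, and a `drawn` flag that is FALSE when fewer than
#' `min_probed` connections were probed (figure convention; the statistics
#' are always reported).
#'
#' @param pairs data.frame with columns `connected`, `artifact_excluded` and
#'   the distance columns of the connection-table schema
#' @param axis "pia" (presynaptic pia distance), "horizontal" (absolute
#'   horizontal offset) or "distance3d"
#' @param bin_width bin width (um, default 100)
#' @param min_probed drawing threshold (default 20)
#' @return data.frame of class `binned_probability`
#' @export
binned_connection_probability <- function(pairs,
                                          axis = c("pia", "horizontal",
                                                   "distance3d"),
                                          bin_width = 100, min_probed = 20) {
  axis <- match.arg(axis)
  if (!nrow(pairs)) {
    return(structure(data.frame(), class = c("binned_probability",
                                             "data.frame")))
  }
  x <- switch(axis,
              pia = pairs$pre_pia_um,
              horizontal = abs(pairs$horizontal_offset_um),
              distance3d = pairs$distance_3d_um)
  keep <- !as.logical(pairs$artifact_excluded) & is.finite(x)
  x <- x[keep]
  conn <- as.logical(pairs$connected[keep])
  lo <- floor(min(x) / bin_width) * bin_width
  edges <- seq(lo, max(x) + bin_width, by = bin_width)
  bin <- findInterval(x, edges)
  found <- tapply(conn, bin, sum)
  probed <- tapply(conn, bin, length)
  ids <- as.integer(names(found))
  ci <- jeffreys_interval(as.integer(found), as.integer(probed))
  out <- data.frame(
    bin_lo = edges[ids], bin_hi = edges[ids + 1L],
    found = as.integer(found), probed = as.integer(probed),
    probability = as.numeric(found / probed),
    jeffreys_lo = ci$lo, jeffreys_hi = ci$hi,
    drawn = as.integer(probed) >= min_probed)
  rownames(out) <- NULL
  structure(out, class = c("binned_probability", "data.frame"))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Classical minimum-likelihood definition: the p-value sums the
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose point probability does not exceed that of the observed table. The
#' table rows are groups and columns are (found, not found). A zero margin
#' returns p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return two-sided p-value
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Build a found/probed comparison into a 2x2 Fisher table
#'
#' @param found_1,probed_1,found_2,probed_2 counts for the two groups
#' @return 2x2 matrix with columns (found, not found)
#' @export
found_probed_table <- function(found_1, probed_1, found_2, probed_2) {
  matrix(c(found_1, probed_1 - found_1, found_2, probed_2 - found_2),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("group1", "group2"), c("found", "not_found")))
}

#' Chi-squared test across distance bins
#'
#' Pearson chi-squared on the k x 2 (found, not-found) table, df = k - 1.
#'
#' @param found,probed integer vectors over k >= 2 bins
#' @return list with `statistic`, `df`, `p_value`
#' @export
chi_squared_binned <- function(found, probed) {
  stopifnot(length(found) == length(probed), length(found) >= 2)
  tab <- cbind(found = found, not_found = probed - found)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a margin with zero expected count", call. = FALSE)
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`adjusted_i = min over p_j >= p_i of
#' p_j m / rank_j`, capped at 1) plus the rejection set at the requested
#' false discovery rate.
#'
#' @param p raw p-values in [0, 1]
#' @param fdr false discovery rate for the rejection decision
#' @return list with `adjusted` and logical `rejected`
#' @export
benjamini_hochberg <- function(p, fdr = 0.25) {
  stop_if_not_scalar_prob(p, "p")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= fdr)
}

#' Compare connectivity measured by two methods across categories
#'
#' For each connection category (subclass x distance range) with found/probed
#' counts from both methods: a two-sided Fisher exact test, Benjamini-
#' Hochberg adjustment across categories, the Pearson correlation between
#' the two probability vectors, and unweighted OLS of the optogenetic
#' probabilities on the paired-recording probabilities with coefficient
#' standard errors.
#'
#' @param counts data.frame with columns `paired_found`, `paired_probed`,
#'   `opto_found`, `opto_probed` (one row per category)
#' @param fdr false discovery rate for the BH rejection decision
#' @return object of class `method_comparison`
#' @export
compare_methods <- function(counts, fdr = 0.25) {
  stopifnot(nrow(counts) >= 3)
  fisher_p <- vapply(seq_len(nrow(counts)), function(i) {
    fisher_exact_2x2(found_probed_table(
      counts$paired_found[i], counts$paired_probed[i],
      counts$opto_found[i], counts$opto_probed[i]))
  }, numeric(1))
  bh <- benjamini_hochberg(fisher_p, fdr)
  p_paired <- counts$paired_found / counts$paired_probed
  p_opto <- counts$opto_found / counts$opto_probed
  ct <- stats::cor.test(p_paired, p_opto)
  fit <- stats::lm(p_opto ~ p_paired)
  co <- stats::coef(summary(fit))
  structure(list(
    counts = counts, fisher_p = fisher_p, bh_adjusted = bh$adjusted,
    rejected = bh$rejected,
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    slope = co["p_paired", "Estimate"], slope_se = co["p_paired", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = co["(Intercept)", "Std. Error"]),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d categories\n", nrow(x$counts)))
  cat(sprintf("  Pearson r = %.2f (p = %.2g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  OLS: slope = %.2f +/- %.2f, intercept = %.2f +/- %.2f\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  smallest Fisher p = %.2g (BH-adjusted %.2g)\n",
              min(x$fisher_p), x$bh_adjusted[which.min(x$fisher_p)]))
  invisible(x)
}

#' Cohen's d effect size
#'
#' `(mean2 - mean1) / sqrt((SD1^2 + SD2^2) / 2)`.
#'
#' @param group1,group2 numeric vectors (>= 2 values each)
#' @return effect size d, NA when the pooled SD is zero
#' @export
effect_size_cohens_d <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  pooled <- sqrt((stats::sd(group1)^2 + stats::sd(group2)^2) / 2)
  if (pooled == 0) return(NA_real_)
  (mean(group2) - mean(group1)) / pooled
}

#' Dunn's pairwise rank comparisons
#'
#' Post hoc test following Kruskal-Wallis: pairwise z statistics on mean
#' ranks with tie correction, two-sided p-values adjusted for multiplicity.
#'
#' @param values numeric vector
#' @param groups grouping factor
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#' @return data.frame with group pair, z and adjusted p
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  combos <- utils::combn(levels(groups), 2)
  z <- apply(combos, 2, function(gp) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / n_g[[gp[1]]] + 1 / n_g[[gp[2]]]))
    (mean_r[[gp[1]]] - mean_r[[gp[2]]]) / se
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust)
  data.frame(group1 = combos[1, ], group2 = combos[2, ], z = z,
             p_adjusted = p)
}

#' Omnibus and pairwise comparisons of a metric across connection classes
#'
#' Kruskal-Wallis across all groups, then Dunn's pairwise comparisons.
#' Groups with fewer than 2 values are dropped with a warning.
#'
#' @param values numeric vector (e.g. PSP amplitudes)
#' @param groups grouping factor (e.g. presynaptic Cre line x target class)
#' @param p_adjust multiplicity adjustment for the pairwise tests
#' @return list with `kruskal_p`, `kruskal_statistic`, `pairwise`
#'   (a [dunn_test()] table; NULL with fewer than 3 groups retained)
#' @export
group_comparisons <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with fewer than 2 values: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  list(kruskal_p = kw$p.value, kruskal_statistic = unname(kw$statistic),
       pairwise = if (nlevels(groups) >= 2)
         dunn_test(values, groups, p_adjust) else NULL)
}

#' Reference cross-method connection counts
#'
#' The published per-category comparison of connectivity measured by paired
#' recordings and by two-photon optogenetic mapping: found/probed counts for
#' 14 connection categories (presynaptic/postsynaptic subclass x 3D
#' intersomatic distance range), shipped with the package as a plain CSV.
#'
#' @return data.frame with columns `connection_class`, `distance_um`,
#'   `paired_found`, `paired_probed`, `opto_found`, `opto_probed`
#' @export
method_comparison_counts <- function() {
  utils::read.csv(system.file("extdata", "method_comparison_counts.csv",
                              package = "optomap"),
                  stringsAsFactors = FALSE)
}

#' Reference contingency comparisons between connection groups
#'
#' Published found/probed counts for pairwise comparisons of connection
#' probability between presynaptic layers, Cre lines and expression methods,
#' shipped as a plain CSV. Each row defines one two-group comparison.
#'
#' @return data.frame with columns `comparison`, `found_1`, `probed_1`,
#'   `found_2`, `probed_2`
#' @export
contingency_comparison_counts <- function() {
  utils::read.csv(system.file("extdata", "contingency_comparison_counts.csv",
                              package = "optomap"),
                  stringsAsFactors = FALSE)
}
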