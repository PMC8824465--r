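# Off-target activation machinery: labeled-cell density, edge-corrected
# neighbor histograms, min-rule activation-probability maps, expected
# off-target counts, the homogeneous-density analytic variant, and the
# response-probability identity p_response = 1 - (1 - p_connection)^n.

#' Labeled-cell density of a mapped volume
#'
#' Count divided by the imaged volume, converted to cells/mm^3.
#'
#' @param cell_map a [gen_cell_map()] result
#' @return density in cells/mm^3
#' @export
labeled_density <- function(cell_map) {
  vol <- cell_map_volume(cell_map)
  if (vol <= 0) stop("zero or degenerate volume", call. = FALSE)
  nrow(cell_map$positions) / vol
}

#' Labeled-cell density from a reference image
#'
#' Variant for 2D reference images with a known slice thickness:
#' count / (area x thickness).
#'
#' @param count number of counted cells
#' @param area_um2 imaged area (um^2)
#' @param thickness_um slice thickness (um)
#' @return density in cells/mm^3
#' @export
density_from_area <- function(count, area_um2, thickness_um) {
  vol <- area_um2 * thickness_um * 1e-9
  if (vol <= 0) stop("zero or degenerate volume", call. = FALSE)
  count / vol
}

#' Edge-corrected neighbor histogram over lateral x axial offsets
#'
#' For each cell (seed) the lateral and axial offsets to every other cell in
#' the same volume are binned into a 2D histogram. Each bin's count is divided by the number of seed cells
#' whose position keeps the full annulus-times-slab region inside the imaged
#' volume, so bins remain unbiased near the boundaries. The targeted cell is
#' excluded from its own neighbor counts. Bins with no eligible seeds are NA.
#'
#' Axes: the optical (axial) axis is `z`; lateral offset is the radial
#' distance in the (x, y) plane; axial offset is `|dz|`, counted on both
#' sides of the seed.
#'
#' @param cell_map a [gen_cell_map()] result
#' @param lateral_bin,axial_bin bin widths (um)
#' @param max_lateral,max_axial histogram extents (um)
#' @return object of class `neighbor_histogram`: `mean_neighbors` matrix
#'   (lateral bins x axial bins), `eligible` seed counts, bin edges
#' @export
neighbor_histogram <- function(cell_map, lateral_bin = 10, axial_bin = 10,
                               max_lateral = 100, max_axial = 100) {
  pos <- cell_map$positions
  if (nrow(pos) < 1) stop("cell map is empty", call. = FALSE)
  lat_edges <- seq(0, max_lateral, by = lateral_bin)
  ax_edges <- seq(0, max_axial, by = axial_bin)
  nl <- length(lat_edges) - 1L; na <- length(ax_edges) - 1L
  counts <- matrix(0, nl, na)
  eligible <- matrix(0L, nl, na)
  bx <- cell_map$bounds$x; by <- cell_map$bounds$y; bz <- cell_map$bounds$z
  n <- nrow(pos)
  # pairwise offsets
  dx <- outer(pos[, "x"], pos[, "x"], "-")
  dy <- outer(pos[, "y"], pos[, "y"], "-")
  dz <- abs(outer(pos[, "z"], pos[, "z"], "-"))
  dlat <- sqrt(dx^2 + dy^2)
  diag(dlat) <- NA  # a cell is not its own neighbor
  diag(dz) <- NA
  for (li in seq_len(nl)) {
    for (ai in seq_len(na)) {
      l_hi <- lat_edges[li + 1L]; a_hi <- ax_edges[ai + 1L]
      # a seed is eligible if the full annulus x slab (both axial sides)
      # fits inside the volume
      elig <- pos[, "x"] - l_hi >= bx[1] & pos[, "x"] + l_hi <= bx[2] &
        pos[, "y"] - l_hi >= by[1] & pos[, "y"] + l_hi <= by[2] &
        pos[, "z"] - a_hi >= bz[1] & pos[, "z"] + a_hi <= bz[2]
      eligible[li, ai] <- sum(elig)
      if (any(elig)) {
        in_bin <- dlat[elig, , drop = FALSE] >= lat_edges[li] &
          dlat[elig, , drop = FALSE] < l_hi &
          dz[elig, , drop = FALSE] >= ax_edges[ai] &
          dz[elig, , drop = FALSE] < a_hi
        counts[li, ai] <- sum(in_bin, na.rm = TRUE)
      }
    }
  }
  mean_neighbors <- counts / eligible
  mean_neighbors[eligible == 0] <- NA_real_
  structure(list(mean_neighbors = mean_neighbors, eligible = eligible,
                 lateral_edges = lat_edges, axial_edges = ax_edges),
            class = "neighbor_histogram")
}

# axis Gaussians with unit peak, parameterized by sigma
axis_gaussian <- function(d, sigma) exp(-d^2 / (2 * sigma^2))

#' Off-target activation-probability map under the min rule
#'
#' Combined lateral/axial offsets are not directly measured during
#' characterization, so the activation probability at (lateral, axial) is
#' taken as the lower of the two probabilities predicted by the independent
#' axis Gaussians (a conservative estimate). Probabilities are evaluated on
#' a 1 um grid and averaged within each histogram bin; the probability at
#' zero offset is 1 by construction.
#'
#' @param profile a [resolution_profile()]
#' @param lateral_edges,axial_edges bin edges (um), as in
#'   [neighbor_histogram()]
#' @param grid_um evaluation grid resolution (um)
#' @return object of class `activation_prob_map` with `prob` matrix and the
#'   bin edges
#' @export
activation_prob_map <- function(profile, lateral_edges = seq(0, 100, 10),
                                axial_edges = seq(0, 100, 10),
                                grid_um = 1) {
  if (!is.finite(profile$sigma_lateral) || !is.finite(profile$sigma_axial)) {
    stop("both axis fits must be defined", call. = FALSE)
  }
  nl <- length(lateral_edges) - 1L; na <- length(axial_edges) - 1L
  prob <- matrix(NA_real_, nl, na)
  for (li in seq_len(nl)) {
    lat <- seq(lateral_edges[li], lateral_edges[li + 1L] - grid_um,
               by = grid_um) + grid_um / 2
    for (ai in seq_len(na)) {
      ax <- seq(axial_edges[ai], axial_edges[ai + 1L] - grid_um,
                by = grid_um) + grid_um / 2
      g <- outer(axis_gaussian(lat, profile$sigma_lateral),
                 axis_gaussian(ax, profile$sigma_axial), pmin)
      prob[li, ai] <- mean(g)
    }
  }
  structure(list(prob = prob, lateral_edges = lateral_edges,
                 axial_edges = axial_edges),
            class = "activation_prob_map")
}

#' Activation probability at a single combined offset (min rule)
#'
#' @param profile a [resolution_profile()]
#' @param lateral,axial offsets (um)
#' @return min of the two axis-Gaussian probabilities
#' @export
activation_probability <- function(profile, lateral, axial) {
  pmin(axis_gaussian(lateral, profile$sigma_lateral),
       axis_gaussian(abs(axial), profile$sigma_axial))
}

#' Expected off-target activations per stimulus
#'
#' Sum over bins of (mean neighbors per seed) x (activation probability).
#' Bins undefined in the histogram are skipped with a warning.
#'
#' @param hist a [neighbor_histogram()]
#' @param prob_map an [activation_prob_map()] on the same bin grid
#' @return expected number of off-target cells activated per stimulus
#' @export
expected_offtarget <- function(hist, prob_map) {
  if (!identical(hist$lateral_edges, prob_map$lateral_edges) ||
      !identical(hist$axial_edges, prob_map$axial_edges)) {
    stop("histogram and probability map are on different bin grids",
         call. = FALSE)
  }
  h <- hist$mean_neighbors
  und <- is.na(h)
  if (any(und)) warning(sum(und), " undefined histogram bin(s) skipped",
                        call. = FALSE)
  sum(h * prob_map$prob, na.rm = TRUE)
}

#' Expected off-target activation for homogeneously distributed cells
#'
#' Integrates the min-rule activation probability over space for a uniform
#' density: `density * int int min(g_lat(r), g_ax(z)) 2 pi r dr dz`, with
#' the axial integral taken over both sides. The result is linear in
#' density. Quadrature is adaptive with relative tolerance 1e-6.
#'
#' @param density cells/mm^3
#' @param fwhm_lateral,fwhm_axial photostimulus resolution (um)
#' @return expected off-target cells per stimulus (vectorized over density)
#' @export
homogeneous_offtarget <- function(density, fwhm_lateral, fwhm_axial) {
  stopifnot(all(density >= 0), fwhm_lateral > 0, fwhm_axial > 0)
  sl <- fwhm_lateral / FWHM_FACTOR
  sa <- fwhm_axial / FWHM_FACTOR
  f <- function(r, z) {
    pmin(axis_gaussian(r, sl), axis_gaussian(z, sa)) * 2 * pi * r
  }
  vol_um3 <- 2 * pracma::integral2(f, 0, 8 * sl, 0, 8 * sa,
                                   reltol = 1e-6)$Q
  density * vol_um3 * 1e-9
}

#' Monte-Carlo estimate of homogeneous off-target activation
#'
#' Independent oracle for [homogeneous_offtarget()]: place Poisson cells in a
#' cylinder around the stimulus and draw Bernoulli activations with the
#' min-rule probability.
#'
#' @param density cells/mm^3
#' @param fwhm_lateral,fwhm_axial resolution (um)
#' @param n_stimuli number of simulated stimuli
#' @param seed integer seed
#' @return list with `mean` activations/stimulus and its standard error
#' @export
mc_homogeneous_offtarget <- function(density, fwhm_lateral, fwhm_axial,
                                     n_stimuli = 1e4, seed = 1) {
  sl <- fwhm_lateral / FWHM_FACTOR
  sa <- fwhm_axial / FWHM_FACTOR
  R <- 8 * sl; Z <- 8 * sa
  vol_um3 <- pi * R^2 * 2 * Z
  lambda <- density * vol_um3 * 1e-9
  with_substream(seed, "mc_offtarget", {
    counts <- vapply(seq_len(n_stimuli), function(i) {
      n <- stats::rpois(1, lambda)
      if (n == 0) return(0)
      r <- R * sqrt(stats::runif(n))
      z <- stats::runif(n, -Z, Z)
      p <- pmin(axis_gaussian(r, sl), axis_gaussian(abs(z), sa))
      sum(stats::runif(n) < p)
    }, numeric(1))
    list(mean = mean(counts), se = stats::sd(counts) / sqrt(n_stimuli))
  })
}

#' Probability of a photostimulus response given multiple activated cells
#'
#' If a photostimulus activates `n` cells sharing a common connection
#' probability `p`, the probability that at least one is connected is
#' `1 - (1 - p)^n`.
#'
#' @param p_connection per-cell connection probability in [0, 1]
#' @param n number of activated cells (>= 1)
#' @return response probability (vectorized)
#' @export
p_response <- function(p_connection, n) {
  stop_if_not_scalar_prob(p_connection, "p_connection")
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  1 - (1 - p_connection)^n
}
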