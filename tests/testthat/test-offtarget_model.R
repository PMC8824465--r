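# Density, edge-corrected neighbor histograms, min-rule activation maps,
# expected off-target counts, the homogeneous analytic variant, and the
# multi-cell response-probability identity.

# a profile whose axis Gaussians give 0.18 (lateral) and 0.83 (axial) at 10 um
tlx3_like_profile <- function() {
  sl <- sqrt(100 / (2 * log(1 / 0.18)))
  sa <- sqrt(100 / (2 * log(1 / 0.83)))
  resolution_profile(
    structure(list(sigma = sl, fwhm = 2 * sqrt(2 * log(2)) * sl,
                   peak_probability = 1), class = "resolution_fit"),
    structure(list(sigma = sa, fwhm = 2 * sqrt(2 * log(2)) * sa,
                   peak_probability = 1), class = "resolution_fit"))
}

test_that("labeled density is count over volume in mm^3", {
  bounds <- list(x = c(0, 300), y = c(0, 300), z = c(0, 300))
  cm <- gen_cell_map(10000, bounds, 7)
  expect_equal(labeled_density(cm), nrow(cm$positions) / 0.027)
  empty <- gen_cell_map(0, bounds, 1)
  expect_equal(labeled_density(empty), 0)
  # unbiased over 200 seeds
  est <- vapply(1:200, function(s) labeled_density(gen_cell_map(10000, bounds, s)),
                numeric(1))
  expect_lt(abs(mean(est) - 10000), 4 * sqrt(10000 / 0.027) / sqrt(200))
  expect_equal(density_from_area(50, 300 * 300, 50), 50 / (300 * 300 * 50e-9))
})

test_that("neighbor histogram counts a hand-built pair correctly", {
  cm <- structure(list(
    positions = cbind(x = c(150, 165), y = c(150, 150), z = c(60, 60)),
    bounds = list(x = c(0, 300), y = c(0, 300), z = c(0, 120))),
    class = "cell_map")
  nh <- neighbor_histogram(cm, 10, 10, 50, 50)
  expect_equal(nh$mean_neighbors[2, 1], 1)  # 15 um lateral, 0 axial
  expect_equal(sum(nh$mean_neighbors, na.rm = TRUE), 1)
  single <- cm; single$positions <- cm$positions[1, , drop = FALSE]
  nh1 <- neighbor_histogram(single, 10, 10, 50, 50)
  expect_true(all(nh1$mean_neighbors[nh1$eligible > 0] == 0))
})

test_that("edge-corrected histogram is unbiased for homogeneous maps", {
  rho <- 20000
  cm <- gen_cell_map(rho, list(x = c(0, 300), y = c(0, 300), z = c(0, 150)),
                     seed = 9)
  nh <- neighbor_histogram(cm, 10, 10, 50, 50)
  # oracle: expected neighbors = rho x annulus-slab volume (both axial sides)
  for (li in 1:5) for (ai in 1:5) {
    vol_um3 <- pi * (nh$lateral_edges[li + 1]^2 - nh$lateral_edges[li]^2) *
      2 * (nh$axial_edges[ai + 1] - nh$axial_edges[ai])
    expected <- rho * vol_um3 * 1e-9
    n_pairs <- nh$mean_neighbors[li, ai] * nh$eligible[li, ai]
    expect_lt(abs(nh$mean_neighbors[li, ai] - expected),
              4 * sqrt(max(n_pairs, 1)) / nh$eligible[li, ai] + 0.02)
  }
  # an oracle restricted to deep-interior seeds agrees with the correction
  interior <- cm
  keep <- cm$positions[, "x"] > 60 & cm$positions[, "x"] < 240 &
    cm$positions[, "y"] > 60 & cm$positions[, "y"] < 240 &
    cm$positions[, "z"] > 60 & cm$positions[, "z"] < 90
  pos_int <- cm$positions[keep, , drop = FALSE]
  count_int <- 0
  for (i in seq_len(nrow(pos_int))) {
    d <- cm$positions[, c("x", "y")] -
      matrix(pos_int[i, c("x", "y")], nrow(cm$positions), 2, byrow = TRUE)
    dl <- sqrt(rowSums(d^2))
    dz <- abs(cm$positions[, "z"] - pos_int[i, "z"])
    # the seed itself has dl = 0 and never falls in the 10-20 um bin
    count_int <- count_int + sum(dl >= 10 & dl < 20 & dz < 10)
  }
  oracle <- count_int / nrow(pos_int)
  expect_lt(abs(nh$mean_neighbors[2, 1] - oracle),
            4 * sqrt(count_int) / nrow(pos_int))
})

test_that("the min rule reproduces the combined-offset worked example", {
  prof <- tlx3_like_profile()
  expect_equal(activation_probability(prof, 10, 0), 0.18, tolerance = 1e-9)
  expect_equal(activation_probability(prof, 0, 10), 0.83, tolerance = 1e-9)
  expect_equal(activation_probability(prof, 10, 10), 0.18, tolerance = 1e-9)
  expect_equal(activation_probability(prof, 0, 0), 1)
  expect_equal(activation_probability(prof, -10, 10),
               activation_probability(prof, 10, 10))  # lateral symmetry
  pm <- activation_prob_map(prof, seq(0, 50, 10), seq(0, 50, 10))
  expect_true(all(diff(pm$prob[, 1]) <= 0))  # non-increasing along each axis
  expect_true(all(diff(pm$prob[1, ]) <= 0))
  expect_gt(pm$prob[1, 1], 0.5)   # bin average over 0-10 um offsets
  expect_lte(pm$prob[1, 1], 1)
})

test_that("expected off-target matches Monte-Carlo placement", {
  prof <- tlx3_like_profile()
  rho <- 20000
  cm <- gen_cell_map(rho, list(x = c(0, 400), y = c(0, 400), z = c(-80, 80)),
                     seed = 3)
  nh <- neighbor_histogram(cm, 10, 10, 60, 60)
  pm <- activation_prob_map(prof, nh$lateral_edges, nh$axial_edges)
  eo <- expected_offtarget(nh, pm)
  mc <- mc_homogeneous_offtarget(rho, prof$fwhm_lateral, prof$fwhm_axial,
                                 n_stimuli = 5000, seed = 4)
  # histogram estimate carries the map's own sampling error on top of MC SE
  expect_lt(abs(eo - mc$mean), 3 * mc$se + 0.15 * mc$mean)
  expect_error(expected_offtarget(nh, activation_prob_map(prof,
                                                          seq(0, 30, 10),
                                                          seq(0, 30, 10))),
               "grids")
})

test_that("homogeneous off-target integral is linear and matches quadrature", {
  expect_equal(homogeneous_offtarget(0, 12, 35), 0)
  v1 <- homogeneous_offtarget(10000, 12, 35)
  expect_equal(homogeneous_offtarget(20000, 12, 35), 2 * v1, tolerance = 1e-9)
  mc <- mc_homogeneous_offtarget(68000, 12, 35, n_stimuli = 2e4, seed = 8)
  est <- homogeneous_offtarget(68000, 12, 35)
  expect_lt(abs(est - mc$mean) / est, 0.02 + 3 * mc$se / est)
  # monotone in resolution
  expect_gt(homogeneous_offtarget(10000, 24, 66), v1)
})

test_that("multi-cell response probability follows the closed form", {
  expect_equal(p_response(0.37, 1), 0.37)
  expect_equal(p_response(0.5, 5), 0.96875)
  expect_error(p_response(1.2, 2), "\\[0, 1\\]")
  expect_error(p_response(0.5, 0), ">= 1")
  # Monte-Carlo Bernoulli oracle over a (p, n) grid
  set.seed(10)
  for (p in c(0.05, 0.3, 0.7)) for (n in c(1, 2, 5)) {
    draws <- matrix(stats::runif(1e4 * n) < p, ncol = n)
    emp <- mean(rowSums(draws) > 0)
    theo <- p_response(p, n)
    expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / 1e4))
  }
  # monotone in p and n, concave in n
  p_grid <- seq(0.05, 0.95, 0.1)
  expect_true(all(diff(p_response(p_grid, 3)) > 0))
  pn <- p_response(0.2, 1:6)
  expect_true(all(diff(pn) > 0))
  expect_true(all(diff(diff(pn)) < 0))
})
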