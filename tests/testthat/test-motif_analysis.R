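# Motif counting, completed convergence/divergence, bootstrap null,
# amplitude correlations.

test_that("motif counts match the brute-force enumeration oracle", {
  # hand-built: two presyn cells converge on one post
  h <- data.frame(experiment_id = "e", pre_cell_id = c("a", "b"),
                  post_cell_id = "p", connected = TRUE,
                  artifact_excluded = FALSE)
  expect_equal(count_motifs(h)$convergence, 1)
  # one presyn diverging to 3 posts: 3 unordered post pairs completed
  h2 <- data.frame(experiment_id = "e", pre_cell_id = "a",
                   post_cell_id = c("p", "q", "r"), connected = TRUE,
                   artifact_excluded = FALSE)
  expect_equal(count_motifs(h2)$divergence, 3)
  expect_equal(count_motifs(h2)$divergent_cells, 1)
  for (seed in 1:8) {
    pairs <- random_pairs(n_pre = sample(5:15, 1), n_post = sample(2:4, 1),
                          p = stats::runif(1, 0.1, 0.6), seed = seed)
    mc <- count_motifs(pairs)
    bf <- brute_force_motifs(pairs)
    expect_equal(mc$convergence, bf$convergence)
    expect_equal(mc$convergence_eligible, bf$convergence_eligible)
    expect_equal(mc$divergence, bf$divergence)
    expect_equal(mc$divergence_eligible, bf$divergence_eligible)
  }
  # artifact-excluded pairs are invisible to motif counting
  pairs <- random_pairs(seed = 9)
  pairs$artifact_excluded[pairs$connected][1] <- TRUE
  expect_equal(count_motifs(pairs)$convergence,
               brute_force_motifs(pairs)$convergence)
})

test_that("completed convergence matches hand counts and independence", {
  # 3 presyn on one post: a connected, b connected, c not. Ordered pairs
  # with i connected: (a,b),(a,c),(b,a),(b,c) -> completed: (a,b),(b,a)
  h <- data.frame(experiment_id = "e", pre_cell_id = c("a", "b", "c"),
                  post_cell_id = "p", connected = c(TRUE, TRUE, FALSE),
                  artifact_excluded = FALSE,
                  horizontal_offset_um = c(0, 10, 20), pre_pia_um = 100,
                  cre_line = "X", post_subclass = "L2/3 PC")
  cc <- completed_convergence(h, bin_width = 1000)
  expect_equal(cc$eligible, 4)
  expect_equal(cc$completed, 2)
  expect_equal(cc$probability, 0.5)
  # fully connected network: probability 1 in every bin
  full <- random_pairs(10, 3, p = 1, seed = 2)
  full$connected <- TRUE
  ccf <- completed_convergence(full)
  expect_true(all(ccf$probability == 1))
  # independent Bernoulli network: P(j|i) ~= p in every populated bin
  big <- random_pairs(60, 4, p = 0.25, seed = 3)
  ccb <- completed_convergence(big)
  for (i in which(ccb$eligible > 100)) {
    expect_lt(abs(ccb$probability[i] - 0.25),
              3 * sqrt(0.25 * 0.75 / ccb$eligible[i]) + 0.05)
  }
})

test_that("completed divergence uses 3D distance and subclass filters", {
  pairs <- data.frame(
    experiment_id = "e", pre_cell_id = rep(c("a", "b"), each = 3),
    post_cell_id = rep(c("p", "q", "r"), 2),
    connected = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    artifact_excluded = FALSE,
    horizontal_offset_um = 0, pre_pia_um = 100, cre_line = "X",
    post_subclass = rep(c("L2/3 PC", "L2/3 PC", "FSI"), 2))
  posts <- data.frame(experiment_id = "e", post_cell_id = c("p", "q", "r"),
                      x = c(0, 30, 0), y = c(0, 40, 0), z = c(0, 0, 90))
  cd <- completed_divergence(pairs, posts, bin_width = 60)
  # pre a: ordered pairs with i connected: (p,q),(p,r),(q,p),(q,r);
  # pre b: (p,q),(p,r). Completed (j also connected): a's (p,q) and (q,p)
  expect_equal(sum(cd$eligible), 6)
  expect_equal(sum(cd$completed), 2)
  d_pq <- sqrt(30^2 + 40^2)  # both completed pairs lie at 50 um
  expect_true(any(cd$bin_lo <= d_pq & d_pq < cd$bin_hi & cd$completed == 2))
  # restricting cell j to L2/3 PC drops pairs whose j is the FSI (r)
  cd2 <- completed_divergence(pairs, posts, bin_width = 60,
                              j_subclass = "L2/3 PC")
  expect_equal(sum(cd2$eligible), 3)
})

test_that("bootstrap motif p-values behave at the boundaries", {
  pairs <- random_pairs(30, 3, p = 0.15, seed = 5)
  bt <- bootstrap_motif_test(pairs, n_sim = 100, seed = 1)
  bt2 <- bootstrap_motif_test(pairs, n_sim = 100, seed = 1)
  expect_identical(bt$simulated, bt2$simulated)  # seeded reproducibility
  expect_identical(bt$p_convergence, bt2$p_convergence)
  # shuffling pair order leaves the observed counts unchanged
  perm <- sample(nrow(pairs))
  expect_equal(count_motifs(pairs[perm, ])$convergence,
               count_motifs(pairs)$convergence)
  # planted hub beyond every simulation: the < 1/n_sim sentinel label
  hub <- random_pairs(40, 5, p = 0.02, seed = 6)
  hub$connected[hub$pre_cell_id == "c01"] <- TRUE
  bth <- bootstrap_motif_test(hub, n_sim = 100, seed = 2,
                              prob = rep(0.01, nrow(hub)))
  expect_equal(bth$p_divergence, 0)
  expect_equal(bth$p_divergence_label, "<0.01")
})

test_that("bootstrap p-values are calibrated under a known null", {
  set.seed(19)
  ps <- replicate(120, {
    n <- 150
    pairs <- data.frame(
      experiment_id = "e1",
      pre_cell_id = rep(sprintf("c%d", 1:50), 3),
      post_cell_id = rep(sprintf("p%d", 1:3), each = 50),
      connected = stats::runif(n) < 0.12, artifact_excluded = FALSE,
      horizontal_offset_um = stats::runif(n, -250, 250),
      pre_pia_um = stats::runif(n, 80, 480),
      cre_line = "X", post_subclass = "L2/3 PC")
    bt <- bootstrap_motif_test(pairs, n_sim = 199,
                               seed = sample.int(1e6, 1),
                               prob = rep(0.12, n))
    obs <- bt$observed$convergence
    sims <- bt$simulated[, "convergence"]
    # randomized PIT over the simulated null: exactly uniform when the
    # observed count is drawn from the same law
    (sum(sims > obs) + stats::runif(1) * (1 + sum(sims == obs))) /
      (length(sims) + 1)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.05)
})

test_that("planted divergence hubs are detected with high power", {
  set.seed(20)
  hits <- replicate(40, {
    n_post <- 5; n_pre <- 40
    pairs <- data.frame(
      experiment_id = "e1",
      pre_cell_id = rep(sprintf("c%d", 1:n_pre), n_post),
      post_cell_id = rep(sprintf("p%d", 1:n_post), each = n_pre),
      connected = stats::runif(n_post * n_pre) < 0.05,
      artifact_excluded = FALSE,
      horizontal_offset_um = stats::runif(n_post * n_pre, -250, 250),
      pre_pia_um = stats::runif(n_post * n_pre, 80, 480),
      cre_line = "X", post_subclass = "L2/3 PC")
    pairs$connected[pairs$pre_cell_id == "c1"] <- TRUE  # hub to all 5 posts
    bt <- bootstrap_motif_test(pairs, n_sim = 199, seed = sample.int(1e6, 1))
    bt$p_divergence < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("amplitude correlations follow the double-plotting convention", {
  # identical amplitudes within every pair: r = 1
  a <- c(0.2, 0.5, 1.1, 0.7)
  out <- amplitude_correlation(a, a)
  expect_equal(out$r, 1)
  expect_equal(out$n_unique, 4)
  # symmetric input: doubling leaves r unchanged
  set.seed(21)
  x <- stats::rlnorm(30); y <- x + stats::rnorm(30, 0, 0.2)
  r_once <- stats::cor(c(x, y), c(y, x))
  expect_equal(amplitude_correlation(x, y)$r, r_once)
  expect_equal(amplitude_correlation(y, x)$r, r_once)
  # independent amplitudes: r centered on 0, stated-n p-values uniform
  ps <- replicate(200, {
    x <- stats::rlnorm(12); y <- stats::rlnorm(12)
    amplitude_correlation(x, y, log_space = TRUE)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(amplitude_correlation(1:2, 2:1), "at least 3")
  expect_true(is.na(amplitude_correlation(rep(1, 5), rep(1, 5))$r))
})
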