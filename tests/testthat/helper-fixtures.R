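# Shared fixtures, built in code at test time.

DT25 <- 1 / 25000  # 25 kHz sample interval (s)

# a flat trace epoch at the holding target with optional added signal
flat_epoch <- function(n = 6250, onset = 2501, value = -70, dt = DT25,
                       add = 0) {
  trace_epoch(rep(value, n) + add, dt, onset, holding_target = -70)
}

# times (ms, 0 = onset) for a trace of length n with onset index
epoch_times_ms <- function(n = 6250, onset = 2501, dt = DT25) {
  (seq_len(n) - onset) * dt * 1000
}

# double-exponential PSP (peak-normalized amplitude amp) starting t0 ms
# after onset
psp_trace <- function(amp = 1, t0 = 5, rise = 1.5, decay = 18,
                      n = 6250, onset = 2501, dt = DT25) {
  t <- epoch_times_ms(n, onset, dt)
  amp * optomap:::psp_kernel(t - t0, rise, decay)
}

# a small random connection table for motif tests
random_pairs <- function(n_pre = 15, n_post = 3, p = 0.3, seed = 1,
                         experiment_id = "e1") {
  set.seed(seed)
  n <- n_pre * n_post
  data.frame(
    experiment_id = experiment_id,
    pre_cell_id = rep(sprintf("c%02d", seq_len(n_pre)), n_post),
    post_cell_id = rep(sprintf("p%02d", seq_len(n_post)), each = n_pre),
    connected = stats::runif(n) < p,
    artifact_excluded = FALSE,
    horizontal_offset_um = stats::runif(n, -250, 250),
    pre_pia_um = stats::runif(n, 80, 480),
    distance_3d_um = stats::runif(n, 20, 400),
    cre_line = "synthCre", post_subclass = "L2/3 PC",
    stringsAsFactors = FALSE)
}

# brute-force O(n^3)-style motif enumeration oracle
brute_force_motifs <- function(pairs) {
  pairs <- pairs[!as.logical(pairs$artifact_excluded), ]
  conv <- 0; conv_el <- 0; div <- 0; div_el <- 0
  for (ex in unique(pairs$experiment_id)) {
    px <- pairs[pairs$experiment_id == ex, ]
    for (po in unique(px$post_cell_id)) {
      g <- px[px$post_cell_id == po, ]
      pres <- unique(g$pre_cell_id)
      if (length(pres) < 2) next
      cmb <- utils::combn(pres, 2)
      for (k in seq_len(ncol(cmb))) {
        conv_el <- conv_el + 1
        ci <- g$connected[g$pre_cell_id == cmb[1, k]][1]
        cj <- g$connected[g$pre_cell_id == cmb[2, k]][1]
        if (ci && cj) conv <- conv + 1
      }
    }
    for (pr in unique(px$pre_cell_id)) {
      g <- px[px$pre_cell_id == pr, ]
      posts <- unique(g$post_cell_id)
      if (length(posts) < 2) next
      cmb <- utils::combn(posts, 2)
      for (k in seq_len(ncol(cmb))) {
        div_el <- div_el + 1
        ci <- g$connected[g$post_cell_id == cmb[1, k]][1]
        cj <- g$connected[g$post_cell_id == cmb[2, k]][1]
        if (ci && cj) div <- div + 1
      }
    }
  }
  list(convergence = conv, convergence_eligible = conv_el,
       divergence = div, divergence_eligible = div_el)
}

# exhaustive two-sided Fisher oracle by hypergeometric enumeration
fisher_enumeration <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# quadratic-time BH adjusted p-values straight from the definition
bh_definition <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / rk[p >= p[i]]))
  }, numeric(1))
}

# a connection-table data.frame with all mandatory columns
full_schema_pairs <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    experiment_id = "e1", cre_line = "synthCre", expression_method = "AAV",
    stim_power_mw = 85,
    pre_cell_id = sprintf("c%03d", seq_len(n)), post_cell_id = "p01",
    post_subclass = "L2/3 PC",
    pre_pia_um = stats::runif(n, 0, 900),
    post_pia_um = stats::runif(n, 100, 330),
    horizontal_offset_um = stats::runif(n, -300, 300),
    distance_3d_um = stats::runif(n, 10, 500),
    connected = stats::runif(n) < 0.2, artifact_excluded = FALSE,
    n_sweeps = 20L,
    psp_amplitude_mv = round(stats::rlnorm(n, log(0.3), 0.5), 4),
    psp_cv = round(stats::runif(n, 0.2, 1), 4),
    rise_time_ms = round(stats::runif(n, 1, 5), 4),
    latency_ms = round(stats::runif(n, 4, 10), 4),
    ppr = round(stats::runif(n, 0.5, 1.5), 4),
    stringsAsFactors = FALSE)
}
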