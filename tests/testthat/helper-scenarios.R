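# Shared fixture builders. Everything is generated in code; no stored data.

# Small two-network scenario used across estimation tests.
small_scenario <- function(n_subjects = 3, n_regions = 12, n_tasks = 8,
                           blocks_per_task = 8, rest_blocks = 8, seed = 42,
                           within_r = 0.4, between_r = 0.1,
                           task_within_r = 0.3, task_between_r = 0.1) {
  nets <- rep(c("netA", "netB"), each = n_regions / 2)
  scenario_spec(
    n_subjects = n_subjects, n_regions = n_regions, n_tasks = n_tasks,
    blocks_per_task = blocks_per_task, rest_blocks = rest_blocks,
    sigma_rest = build_structured_covariance(nets, within_r, between_r),
    sigma_task = build_structured_covariance(nets, task_within_r, task_between_r),
    seed = seed)
}

two_net_partition <- function(n_regions = 12) {
  network_partition(sprintf("R%03d", seq_len(n_regions)),
                    rep(c("netA", "netB"), each = n_regions / 2))
}

# Group-level signal-noise differential of a synthetic dataset.
group_differential <- function(dataset) {
  scs <- lapply(dataset$betas, compute_sc)
  ncs <- lapply(dataset$betas, compute_nc)
  g_sc <- group_average(scs)
  dnc <- compute_delta_nc(group_average(lapply(ncs, `[[`, "tnc")),
                          group_average(lapply(ncs, `[[`, "rnc")))
  list(sc = g_sc, dnc = dnc, diff = signal_noise_differential(g_sc, dnc))
}

# Brute-force signed modularity oracle: direct double loop over the printed
# formula, independent of the vectorized implementation.
brute_force_q <- function(W, labels, combine = "subtract") {
  diag(W) <- 0
  part <- function(Wp) {
    v <- sum(Wp)
    if (v == 0) return(list(q = 0, v = 0))
    s <- rowSums(Wp)
    q <- 0
    for (i in seq_len(nrow(Wp))) for (j in seq_len(ncol(Wp))) {
      if (labels[i] == labels[j]) q <- q + Wp[i, j] - s[i] * s[j] / v
    }
    list(q = q / v, v = v)
  }
  pos <- part(pmax(W, 0))
  neg <- part(pmax(-W, 0))
  wm <- if (pos$v + neg$v > 0) neg$v / (pos$v + neg$v) else 0
  if (combine == "subtract") pos$q - wm * neg$q else pos$q + wm * neg$q
}

# Brute-force k-clique oracle: test all k-subsets.
brute_force_k_cliques <- function(adjacency, k) {
  n <- nrow(adjacency)
  out <- list()
  for (idx in utils::combn(n, k, simplify = FALSE)) {
    sub <- adjacency[idx, idx]
    if (all(sub[upper.tri(sub)])) out[[length(out) + 1L]] <- idx
  }
  out
}

expect_offdiag_equal <- function(a, b, tol = 1e-12) {
  a <- if (inherits(a, "corr_matrix")) a$values else a
  b <- if (inherits(b, "corr_matrix")) b$values else b
  expect_lt(max(abs((a - b)[row(a) != col(a)]), na.rm = TRUE), tol)
}
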