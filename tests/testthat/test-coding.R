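make_diff <- function(v) {
  v <- v / max(1, max(abs(v), na.rm = TRUE) / 1.9)
  n <- nrow(v)
  dimnames(v) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  diag(v) <- NA
  sc <- matrix(1, n, n, dimnames = dimnames(v))
  signal_noise_differential(corr_matrix(sc, "SC"), corr_matrix(v, "deltaNC"))
}

test_that("thresholding keeps the requested fraction of same-sign pairs", {
  set.seed(12)
  # 10 positive off-diagonal pair values, retain 0.2 -> exactly the 2 largest
  v <- matrix(0, 5, 5)
  vals <- c(0.1, 0.5, 0.3, 0.9, 0.2, 0.4, 0.6, 0.7, 0.05, 0.8)
  v[upper.tri(v)] <- vals
  v <- v + t(v)
  dm <- make_diff(v)
  adj <- threshold_differential(dm, 0.2, "aligned")
  expect_equal(sum(adj[upper.tri(adj)]), 2)
  got <- v[upper.tri(v)][adj[upper.tri(adj)]]
  expect_setequal(got, c(0.9, 0.8))

  # retain_fraction = 1, aligned: every strictly positive entry is an edge
  mixed <- v
  mixed[2, 1] <- mixed[1, 2] <- -0.3
  dmx <- make_diff(mixed)
  adj_all <- threshold_differential(dmx, 1, "aligned")
  expect_equal(sum(adj_all[upper.tri(adj_all)]),
               sum(mixed[upper.tri(mixed)] > 0))

  # all-negative matrix, aligned -> empty graph with a warning
  expect_warning(empty <- threshold_differential(make_diff(-abs(v)), 0.2,
                                                 "aligned"),
                 "empty graph")
  expect_equal(sum(empty), 0)
})

test_that("k-clique enumeration matches brute-force subset search", {
  # complete graph on 6 nodes: choose(6, 5) five-cliques
  full <- matrix(TRUE, 6, 6); diag(full) <- FALSE
  expect_length(find_k_cliques(full, 5), 6)

  # star graph has no triangle
  star <- matrix(FALSE, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- TRUE
  expect_length(find_k_cliques(star, 3), 0)

  set.seed(13)
  for (i in 1:15) {
    n <- sample(8:15, 1)
    k <- sample(3:5, 1)
    adj <- matrix(runif(n * n) < 0.5, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    got <- find_k_cliques(adj, k)
    want <- brute_force_k_cliques(adj, k)
    expect_equal(lapply(got, as.integer), want)
  }

  expect_error(find_k_cliques(full, 7), "exceeds")
  expect_error(find_k_cliques(full, 5, budget = 2), "budget")
})

test_that("the strongest clique maximizes absolute mean differential", {
  # two disjoint 3-cliques with strengths 0.3 and 0.5 -> the 0.5 clique wins
  v <- matrix(0, 6, 6)
  v[1:3, 1:3] <- 0.3
  v[4:6, 4:6] <- 0.5
  dm <- make_diff(v)
  best <- strongest_clique(dm, k = 3, sign = "aligned", retain_fraction = 1)
  expect_equal(best$cliques[[1]], sprintf("R%03d", 4:6))
  expect_equal(best$strength, 0.5)

  # matches exhaustive search on random graphs
  set.seed(14)
  for (i in 1:10) {
    n <- 12
    m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2
    dmr <- make_diff(m)
    got <- strongest_clique(dmr, k = 4, sign = "aligned", retain_fraction = 0.5)
    adj <- threshold_differential(dmr, 0.5, "aligned")
    all4 <- brute_force_k_cliques(adj, 4)
    strengths <- vapply(all4, function(cl) {
      sub <- dmr$values[cl, cl]; mean(sub[upper.tri(sub)])
    }, numeric(1))
    expect_equal(sort(got$members[[1]]), sort(all4[[which.max(abs(strengths))]]))
    expect_equal(abs(got$strength), max(abs(strengths)))
  }

  expect_error(strongest_clique(dm, k = 5, sign = "aligned",
                                retain_fraction = 1),
               "largest clique has")
})

test_that("every returned clique is complete in its thresholded graph", {
  set.seed(15)
  m <- matrix(rnorm(20 * 20), 20, 20); m <- (m + t(m)) / 2
  dm <- make_diff(m)
  for (sgn in c("aligned", "anti_aligned")) {
    adj <- threshold_differential(dm, 0.4, sgn)
    for (cl in find_k_cliques(adj, 3)) {
      sub <- adj[cl, cl]
      expect_true(all(sub[upper.tri(sub)]))
    }
  }
})

test_that("network-matched cliques respect membership and testability rules", {
  # planted aligned block spanning netA/netB; anti-aligned block inside netC/netD
  n <- 16
  v <- matrix(0, n, n)
  v[1:6, 1:6] <- 0.5        # regions 1-3 netA, 4-6 netB
  v[9:14, 9:14] <- -0.5     # regions 9-11 netC, 12-14 netD
  dm <- make_diff(v)
  part <- network_partition(sprintf("R%03d", 1:n),
                            rep(c("A", "B", "C", "D"), each = 4))
  res <- network_matched_cliques(dm, part, k = 5, retain_fraction = 1)
  ab <- res[["A-B"]]
  expect_gt(length(ab$aligned$cliques), 0)
  expect_false(ab$testable) # no anti-aligned clique between A and B
  expect_true(all(unlist(ab$aligned$cliques) %in% sprintf("R%03d", 1:6)))
  # every aligned A-B clique has members from both networks
  for (cl in ab$aligned$members) {
    expect_true(any(cl <= 4) && any(cl > 4))
  }
  cd <- res[["C-D"]]
  expect_gt(length(cd$anti_aligned$cliques), 0)
  expect_true(all(unlist(cd$anti_aligned$cliques) %in% sprintf("R%03d", 9:14)))
  expect_false(cd$testable)
})

test_that("block shuffling preserves task means and destroys correlations", {
  spec <- small_scenario(n_subjects = 1, seed = 16)
  b <- generate_subject_betas(spec, 1)
  shuf <- shuffle_block_structure(b, seed = 5)
  # per-task multisets preserved exactly
  for (tk in unique(b$meta$task)) {
    cols <- b$meta$task == tk
    expect_equal(apply(b$coef[, cols], 1, sort), apply(shuf$coef[, cols], 1, sort))
  }
  expect_identical(compute_sc(shuf)$values, compute_sc(b)$values)

  # two perfectly correlated regions decorrelate on average across seeds
  x <- rnorm(16)
  twin <- beta_series(rbind(x, x), data.frame(
    block_id = sprintf("b%02d", 1:16), task = "taskA",
    block_index = 1:16, state = "task"))
  rs <- vapply(1:500, function(s) {
    sh <- shuffle_block_structure(twin, seed = s)
    stats::cor(sh$coef[1, ], sh$coef[2, ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("decoding is perfect for separable tasks and leakage-free", {
  # widely separated task means, tiny noise
  set.seed(17)
  n_tasks <- 5
  tuning <- matrix(rnorm(6 * n_tasks, sd = 10), 6, n_tasks)
  spec <- scenario_spec(1, 6, n_tasks = n_tasks, blocks_per_task = 6,
                        rest_blocks = 0, tuning = tuning,
                        sigma_rest = 0.01 * diag(6), sigma_task = 0.01 * diag(6),
                        seed = 18)
  b <- generate_subject_betas(spec, 1)
  res <- decode_multitask(b, rownames(b$coef), seed = 1)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_folds, 6)
  expect_equal(res$n_classes, n_tasks)

  # test predictions invariant to reordering of held-out blocks:
  # permute block order within tasks (only metadata order changes)
  perm_b <- b
  for (tk in unique(b$meta$task)) {
    cols <- which(b$meta$task == tk)
    sh <- sample(cols)
    perm_b$coef[, cols] <- b$coef[, sh]
    perm_b$meta$block_index[cols] <- b$meta$block_index[sh]
  }
  res_perm <- decode_multitask(perm_b, rownames(b$coef), seed = 1)
  expect_equal(res_perm$accuracy, res$accuracy)

  expect_error(decode_multitask(b, c("R001", "nope"), seed = 1),
               "not in beta series")
})

test_that("shuffled-training decoding is unbiased when data have no noise correlation", {
  # independent-noise generator: shuffling the training set changes nothing
  # systematically, so paired accuracy differences straddle zero
  spec <- scenario_spec(8, 6, n_tasks = 6, blocks_per_task = 8,
                        rest_blocks = 0, sigma_rest = diag(6),
                        sigma_task = diag(6), seed = 19)
  d <- vapply(1:8, function(s) {
    b <- generate_subject_betas(spec, s)
    a1 <- decode_multitask(b, rownames(b$coef), seed = s)$accuracy
    a2 <- decode_multitask(b, rownames(b$coef), shuffle_training = TRUE,
                           seed = s)$accuracy
    a1 - a2
  }, numeric(1))
  ci <- mean(d) + c(-1, 1) * 2.5 * stats::sd(d) / sqrt(length(d))
  expect_gte(ci[2], 0)
  expect_lte(ci[1], 0)
})

test_that("paired accuracy comparisons use the exact signed-rank tail", {
  a <- seq(0.3, 0.53, by = 0.01)
  expect_message(same <- compare_conditions(a, a), "p = 1 by convention")
  expect_equal(same$p, 1)

  # constant +0.05 shift over 24 subjects: exact all-positive-rank tail
  res <- compare_conditions(a + 0.05, a)
  expect_equal(res$p, 2 * (1 / 2^24), tolerance = 1e-12)

  # Bonferroni arithmetic
  res2 <- compare_conditions(a + 0.05, a, n_tests = 54)
  expect_equal(res2$p_bonferroni, min(1, res$p * 54))
  fake <- list(p = 0.002)
  expect_equal(min(1, fake$p * 54), 0.108)
  expect_false(min(1, fake$p * 54) < 0.05)
})
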