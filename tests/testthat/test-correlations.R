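toy_beta <- function(coef, n_tasks, blocks_per_task, rest_blocks = 0,
                     subject = "sub-01") {
  meta <- data.frame(
    block_id = sprintf("b%03d", seq_len(ncol(coef))),
    task = c(rep(sprintf("task%02d", seq_len(n_tasks)), each = blocks_per_task),
             rep("rest", rest_blocks)),
    block_index = c(rep(seq_len(blocks_per_task), times = n_tasks),
                    seq_len(rest_blocks)),
    state = c(rep("task", n_tasks * blocks_per_task), rep("rest", rest_blocks)),
    stringsAsFactors = FALSE)
  beta_series(coef, meta, subject = subject)
}

test_that("SC is the across-task correlation of mean activations", {
  # two regions with proportional task means -> SC 1; reversed -> SC -1
  means <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  coef <- means[, rep(1:3, each = 4)] # 4 identical blocks per task
  b <- toy_beta(coef, n_tasks = 3, blocks_per_task = 4)
  sc <- compute_sc(b)
  expect_equal(sc$values[1, 2], 1)
  expect_equal(sc$values[1, 3], -1)

  # zero-variance region across task means -> NA with a message
  coef_flat <- rbind(coef, 5)
  expect_message(sc_flat <- compute_sc(toy_beta(coef_flat, 3, 4)),
                 "zero-variance")
  expect_true(all(is.na(sc_flat$values[4, -4])))

  expect_error(compute_sc(toy_beta(means[, rep(1:2, each = 4)], 2, 4)),
               "at least 3 tasks")
})

test_that("NC is the within-task across-block correlation", {
  set.seed(10)
  # identical block series within a task -> NC 1
  x <- rnorm(6)
  b <- toy_beta(rbind(x, x, rnorm(6)), n_tasks = 1, blocks_per_task = 6)
  nc <- compute_nc(b)
  expect_equal(nc$per_task[[1]]$values[1, 2], 1)

  # independent regions: per-task NC centred on zero over many datasets
  vals <- replicate(100, {
    bb <- toy_beta(matrix(rnorm(2 * 16), 2, 16), 1, 16)
    compute_nc(bb)$per_task[[1]]$values[1, 2]
  })
  expect_lt(abs(mean(vals)), 0.05)

  expect_error(compute_nc(toy_beta(matrix(rnorm(4), 2, 2), 1, 2)),
               "at least 3 blocks")
})

test_that("per-task NC estimates are centred on the generating correlation", {
  sigma <- matrix(c(1, 0.3, 0.3, 1), 2)
  spec <- scenario_spec(1, 2, n_tasks = 25, blocks_per_task = 16,
                        rest_blocks = 0, sigma_task = sigma,
                        sigma_rest = sigma, seed = 17)
  # 40 datasets x 25 tasks = 1000 simulated task NCs
  ests <- unlist(lapply(1:40, function(s) {
    spec2 <- spec; spec2$seed <- spec$seed + s; spec2$n_subjects <- 1L
    nc <- compute_nc(generate_subject_betas(spec2, 1))
    vapply(nc$per_task, function(m) m$values[1, 2], numeric(1))
  }))
  expect_length(ests, 1000)
  expect_lt(abs(mean(ests) - 0.3), 0.05)
})

test_that("tNC equals the mean of per-task NC matrices and excludes rest", {
  spec <- small_scenario(n_subjects = 1, seed = 19)
  nc <- compute_nc(generate_subject_betas(spec, 1))
  manual <- Reduce(`+`, lapply(nc$per_task, function(m) m$values)) /
    length(nc$per_task)
  expect_lt(max(abs(nc$tnc$values - manual)), 1e-12)
  expect_length(nc$per_task, spec$n_tasks)
})

test_that("deltaNC is the elementwise tNC - rNC difference", {
  a <- corr_matrix(matrix(c(1, 0.2, 0.2, 1), 2), role = "tNC")
  b <- corr_matrix(matrix(c(1, 0.5, 0.5, 1), 2), role = "rNC")
  d <- compute_delta_nc(a, b)
  expect_equal(d$values[1, 2], -0.3)
  expect_true(is.na(d$values[1, 1]))
  expect_equal(compute_delta_nc(a, a)$values[1, 2], 0)
  # antisymmetry
  expect_offdiag_equal(compute_delta_nc(a, b)$values,
                       -compute_delta_nc(b, a)$values)
  big <- corr_matrix(diag(3), role = "rNC")
  expect_error(compute_delta_nc(a, big), "dimensions")
})

test_that("the signal-noise differential sign algebra is exact", {
  cases <- expand.grid(sc = c(-0.3, 0, 0.5), dnc = c(-0.2, 0, 0.4))
  for (i in seq_len(nrow(cases))) {
    sc <- matrix(c(1, cases$sc[i], cases$sc[i], 1), 2,
                 dimnames = list(c("R1", "R2"), c("R1", "R2")))
    dnc <- matrix(c(NA, cases$dnc[i], cases$dnc[i], NA), 2,
                  dimnames = dimnames(sc))
    dm <- signal_noise_differential(corr_matrix(sc, role = "SC"),
                                    corr_matrix(dnc, role = "deltaNC"))
    prod <- cases$sc[i] * cases$dnc[i]
    expect_equal(dm$values[1, 2], prod)
    expect_equal(dm$alignment[1, 2],
                 if (prod > 0) "aligned" else if (prod < 0) "anti_aligned"
                 else "null")
  }
  # commutativity of the elementwise product
  set.seed(20)
  a <- stats::cor(matrix(rnorm(50), 10, 5))
  b <- stats::cor(matrix(rnorm(50), 10, 5))
  rownames(a) <- colnames(a) <- rownames(b) <- colnames(b) <- paste0("R", 1:5)
  expect_equal(signal_noise_differential(corr_matrix(a, "SC"),
                                         corr_matrix(b, "deltaNC"))$values,
               signal_noise_differential(corr_matrix(b, "SC"),
                                         corr_matrix(a, "deltaNC"))$values)
})

test_that("alignment summaries count unique pairs by sign", {
  v <- matrix(0.1, 4, 4, dimnames = list(paste0("R", 1:4), paste0("R", 1:4)))
  sc <- corr_matrix(diag(4) * 0 + v, role = "SC")
  dnc <- corr_matrix(matrix(1, 4, 4, dimnames = dimnames(v)), role = "deltaNC")
  all_pos <- signal_noise_differential(sc, dnc)
  s <- alignment_summary(all_pos)
  expect_equal(unname(s$overall["aligned"]), 100)
  expect_equal(unname(s$overall["anti_aligned"]), 0)

  # 3 positive / 3 negative pair values -> 50/50
  m <- matrix(0, 4, 4, dimnames = list(paste0("R", 1:4), paste0("R", 1:4)))
  m[upper.tri(m)] <- c(0.1, 0.2, -0.1, 0.3, -0.2, -0.3)
  m <- m + t(m)
  dm <- signal_noise_differential(corr_matrix(sign(m) * 0.5, role = "SC"),
                                  corr_matrix(abs(m), role = "deltaNC"))
  s2 <- alignment_summary(dm, network_partition(paste0("R", 1:4),
                                                c("x", "x", "y", "y")))
  expect_equal(unname(s2$overall["aligned"]), 50)
  expect_equal(unname(s2$overall["anti_aligned"]), 50)
  expect_equal(nrow(s2$per_network), 2)
  # per-region value is the row mean of the differential
  expect_equal(unname(s2$per_region["R1"]), mean(dm$values[1, -1]))

  bad_part <- network_partition(paste0("R", 1:3), c("x", "x", "y"))
  expect_error(alignment_summary(dm, bad_part), "does not cover")
})

test_that("intersubject SC pools tuning across subjects", {
  spec <- small_scenario(n_subjects = 1, seed = 23)
  b <- generate_subject_betas(spec, 1)
  # all subjects identical -> equals within-subject SC
  isc <- intersubject_sc(list(b, b, b))
  expect_offdiag_equal(isc$values, compute_sc(b)$values, tol = 1e-10)
  expect_error(intersubject_sc(list(b)), "at least 2 subjects")

  # shared tuning + independent noise: intersubject SC beats within-subject SC
  spec24 <- small_scenario(n_subjects = 24, blocks_per_task = 4,
                           rest_blocks = 4, seed = 24)
  betas <- lapply(1:24, function(s) generate_subject_betas(spec24, s))
  truth <- population_sc(spec24)$values
  od <- upper.tri(truth)
  err_within <- mean(abs(group_average(lapply(betas, compute_sc))$values - truth)[od])
  err_inter <- mean(abs(intersubject_sc(betas)$values - truth)[od])
  expect_lt(err_inter, err_within)
})

test_that("group averaging supports mean-r and Fisher-z pooling", {
  m1 <- corr_matrix(matrix(c(1, 0.5, 0.5, 1), 2), role = "SC", subject = "a")
  m2 <- corr_matrix(matrix(c(1, -0.5, -0.5, 1), 2), role = "SC", subject = "b")
  expect_equal(group_average(list(m1))$values, m1$values)
  expect_equal(group_average(list(m1, m2))$values[1, 2], 0)

  m3 <- corr_matrix(matrix(c(1, 0.8, 0.8, 1), 2), role = "SC")
  m4 <- corr_matrix(matrix(c(1, 0, 0, 1), 2), role = "SC")
  fz <- group_average(list(m3, m4), method = "fisher_z")
  # tanh(atanh(0.8)/2) = tanh(log(3)/2) = (3 - 1)/(3 + 1) = 0.5 exactly
  expect_equal(fz$values[1, 2], tanh(atanh(0.8) / 2), tolerance = 1e-12)
  expect_equal(fz$values[1, 2], 0.5, tolerance = 1e-12)

  m5 <- corr_matrix(matrix(c(1, 0.1, 0.1, 1), 2), role = "rNC")
  expect_error(group_average(list(m1, m5)), "different roles")
})

test_that("SC is invariant to within-task block shuffling; NC is not", {
  spec <- small_scenario(n_subjects = 1, seed = 29)
  b <- generate_subject_betas(spec, 1)
  shuf <- shuffle_block_structure(b, seed = 99)
  expect_identical(compute_sc(shuf)$values, compute_sc(b)$values)
  expect_false(isTRUE(all.equal(compute_nc(shuf)$tnc$values,
                                compute_nc(b)$tnc$values)))
})
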