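test_that("structured covariance honours the block-correlation design", {
  # independence case
  expect_equal(build_structured_covariance(c("a", "a", "b", "b"), 0, 0),
               diag(4), ignore_attr = TRUE)

  # 2 networks x 2 regions: entries exactly {1, 0.6, 0.2} and PSD
  s <- build_structured_covariance(c("a", "a", "b", "b"), 0.6, 0.2)
  expect_setequal(unique(as.vector(s)), c(1, 0.6, 0.2))
  expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)

  # variances scale the correlation structure
  s2 <- build_structured_covariance(c("a", "a", "b", "b"), 0.6, 0.2,
                                    variances = c(1, 4, 1, 1))
  expect_equal(diag(s2), c(1, 4, 1, 1), ignore_attr = TRUE)
  expect_equal(stats::cov2cor(s2), s, ignore_attr = TRUE)

  expect_error(build_structured_covariance(c("a", "b"), 0.1, 0.9),
               "between_r <= within_r")
  # many equicorrelated negative pairs cannot form a PSD matrix
  expect_error(build_structured_covariance(rep(c("a", "b", "c"), 4), -0.3, -0.3,),
               "non-PSD.*eigenvalue")
})

test_that("subject betas follow the scenario's tuning and block bookkeeping", {
  # degenerate noise: every block equals its task's tuning column
  spec0 <- scenario_spec(1, 5, n_tasks = 4, blocks_per_task = 3, rest_blocks = 2,
                         sigma_rest = matrix(0, 5, 5),
                         sigma_task = matrix(0, 5, 5), seed = 9)
  b0 <- generate_subject_betas(spec0, 1)
  for (tk in spec0$task_labels) {
    cols <- b0$meta$task == tk
    expect_equal(b0$coef[, cols],
                 matrix(spec0$tuning[, tk], 5, sum(cols),
                        dimnames = list(rownames(b0$coef),
                                        b0$meta$block_id[cols])))
  }
  expect_true(all(b0$coef[, b0$meta$state == "rest"] == 0))

  # paper-scale bookkeeping: 26 tasks x 16 blocks = 416 task blocks
  spec <- scenario_spec(2, 4, n_tasks = 26, blocks_per_task = 16, seed = 3)
  b <- generate_subject_betas(spec, 1)
  expect_equal(sum(b$meta$state == "task"), 416)
  expect_equal(ncol(b$coef), 416 + 16)

  # determinism: identical (spec, subject) -> bit-identical data
  expect_identical(generate_subject_betas(spec, 1)$coef, b$coef)
  expect_false(identical(generate_subject_betas(spec, 2)$coef, b$coef))
})

test_that("cross-block correlation converges to the task-noise correlation", {
  nets <- c("a", "a", "b", "b")
  spec <- scenario_spec(1, 4, n_tasks = 2, blocks_per_task = 10000,
                        rest_blocks = 0,
                        sigma_task = build_structured_covariance(nets, 0.5, 0.2),
                        seed = 21)
  b <- generate_subject_betas(spec, 1)
  nc <- compute_nc(b)
  truth <- stats::cov2cor(spec$sigma_task[[1]])
  expect_lt(max(abs(nc$per_task[[1]]$values - truth)), 0.02)
})

test_that("population ground truth matches the generative description exactly", {
  spec <- small_scenario()
  expect_identical(population_sc(spec)$values, stats::cor(t(spec$tuning)),
                   ignore_attr = TRUE)
  expect_equal(population_nc(spec, "rest")$values,
               stats::cov2cor(spec$sigma_rest), ignore_attr = TRUE)
  expect_equal(diag(population_nc(spec, "task")$values), rep(1, spec$n_regions),
               ignore_attr = TRUE)
})

test_that("NC estimates converge to ground truth as blocks increase", {
  mae <- vapply(c(16, 64, 256), function(bpt) {
    spec <- small_scenario(n_subjects = 1, blocks_per_task = bpt,
                           rest_blocks = 4, seed = 5)
    nc <- compute_nc(generate_subject_betas(spec, 1))
    truth <- stats::cov2cor(spec$sigma_task[[1]])
    mean(abs(nc$tnc$values - truth)[upper.tri(truth)])
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("alignment scenarios shift task noise along the SC sign", {
  base <- small_scenario(seed = 8)

  # delta = 0: both scenarios identical
  sc0 <- make_alignment_scenarios(base, 0)
  expect_identical(sc0$aligned$sigma_task, sc0$anti_aligned$sigma_task)

  # two-region definitional case: task correlation = rest +/- delta
  spec2 <- scenario_spec(1, 2, n_tasks = 4, tuning = matrix(c(1, 2, 3, 4,
                                                              2, 4, 6, 8),
                                                            2, 4, byrow = TRUE),
                         sigma_rest = matrix(c(1, 0.3, 0.3, 1), 2),
                         seed = 2)
  pair <- make_alignment_scenarios(spec2, 0.2)
  expect_equal(stats::cov2cor(pair$aligned$sigma_task[[1]])[1, 2], 0.5)
  expect_equal(stats::cov2cor(pair$anti_aligned$sigma_task[[1]])[1, 2], 0.1)

  # marginal variances matched between the two scenarios (high sc_tol keeps
  # the random-tuning shift sparse enough to stay PSD)
  both <- make_alignment_scenarios(base, 0.15, sc_tol = 0.4)
  va <- diag(both$aligned$sigma_task[[1]])
  vx <- diag(both$anti_aligned$sigma_task[[1]])
  expect_lt(max(abs(va - vx) / va), 1e-8)
  expect_lt(max(abs(va - diag(base$sigma_rest)) / va), 1e-8)

  # population differential signs on nonzero-SC pairs
  st <- signal_axis_scenario(n_subjects = 2, seed = 31)
  pair2 <- make_alignment_scenarios(st$spec, 0.2, sc_tol = 0.1)
  for (tag in c("aligned", "anti_aligned")) {
    sp <- pair2[[tag]]
    dnc <- compute_delta_nc(population_nc(sp, "task"), population_nc(sp, "rest"))
    dm <- signal_noise_differential(population_sc(sp), dnc)
    nz <- abs(population_sc(st$spec)$values) > 0.1 & row(dm$values) != col(dm$values)
    if (tag == "aligned") expect_gt(min(dm$values[nz]), 0)
    else expect_lt(max(dm$values[nz]), 0)
  }

  # a PSD-violating shift is rejected with advice, repaired only on request
  wild <- scenario_spec(1, 12, n_tasks = 6, blocks_per_task = 4, seed = 77)
  expect_error(make_alignment_scenarios(wild, 0.6, sc_tol = 0),
               "non-PSD.*reduce delta_magnitude")
  expect_message(make_alignment_scenarios(wild, 0.6, sc_tol = 0, repair = TRUE),
                 "repaired")
})

test_that("synthetic time series recover their generating betas", {
  spec <- scenario_spec(1, 4, n_tasks = 3, blocks_per_task = 3, rest_blocks = 2,
                        sigma_rest = 0.5 * diag(4), sigma_task = 0.5 * diag(4),
                        seed = 12)
  run <- generate_subject_timeseries(spec, 1, tr = 1, noise_sd = 0)
  expect_equal(nrow(run$events), 3 * 3 + 2)
  design <- build_design_matrix(run$events, n_frames = nrow(run$ts$data), tr = 1)
  fit <- fit_beta_series(run$ts, design)
  expect_lt(max(abs(fit$coef - run$betas$coef)), 1e-8)
})

test_that("beta recovery from noisy time series is unbiased", {
  spec <- scenario_spec(200, 2, n_tasks = 2, blocks_per_task = 2,
                        rest_blocks = 0, sigma_rest = diag(2),
                        sigma_task = diag(2), seed = 14)
  errs <- vapply(1:200, function(s) {
    run <- generate_subject_timeseries(spec, s, tr = 2, gap = 4, noise_sd = 1)
    design <- build_design_matrix(run$events, n_frames = nrow(run$ts$data), tr = 2)
    fit <- fit_beta_series(run$ts, design)
    mean(fit$coef - run$betas$coef)
  }, numeric(1))
  se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * se)
})

test_that("scenario JSON round-trips losslessly", {
  spec <- small_scenario(seed = 33)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(spec, path)
  back <- read_scenario_json(path)
  expect_equal(back$tuning, spec$tuning)
  expect_equal(back$sigma_rest, spec$sigma_rest)
  expect_equal(back$sigma_task[[1]], spec$sigma_task[[1]])
  expect_identical(back$blocks_per_task, spec$blocks_per_task)
})
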