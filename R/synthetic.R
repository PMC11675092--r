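# Synthetic multi-subject block-activation data with known population signal
# (tuning) and state-specific noise covariance. The generator is the ground
# truth against which every estimator in the package is validated.

# Deterministic block schedule for one run: tasks interleaved round-robin
# (block round 1 of every task, then round 2, ...), with rest blocks spread
# evenly through the run.
block_schedule <- function(spec) {
  task_rows <- data.frame(
    task = rep(spec$task_labels, times = spec$blocks_per_task),
    block_index = rep(seq_len(spec$blocks_per_task), each = spec$n_tasks),
    state = "task", stringsAsFactors = FALSE)
  n_task_blocks <- nrow(task_rows)
  if (spec$rest_blocks > 0) {
    # insert rest block r after position r * n_task_blocks / (rest_blocks)
    at <- floor(seq_len(spec$rest_blocks) * n_task_blocks / spec$rest_blocks)
    rest_rows <- data.frame(task = "rest",
                            block_index = seq_len(spec$rest_blocks),
                            state = "rest", stringsAsFactors = FALSE)
    order_key <- c(seq_len(n_task_blocks), at + 0.5)
    sched <- rbind(task_rows, rest_rows)[order(order_key), ]
  } else {
    sched <- task_rows
  }
  sched$block_id <- sprintf("b%03d_%s", seq_len(nrow(sched)), sched$task)
  rownames(sched) <- NULL
  sched[, c("block_id", "task", "block_index", "state")]
}

task_sigma <- function(spec, task_idx) {
  if (length(spec$sigma_task) == 1L) spec$sigma_task[[1]] else spec$sigma_task[[task_idx]]
}

#' Generate one subject's synthetic beta series
#'
#' Blocks of task t are independent multivariate-normal draws centred on the
#' subject's tuning column for t (population tuning plus subject jitter) with
#' covariance `sigma_task`; rest blocks are centred on zero with covariance
#' `sigma_rest`. Output is deterministic given `(spec$seed, subject_index)`.
#'
#' @param spec a [scenario_spec()].
#' @param subject_index subject number in `1..spec$n_subjects`.
#' @return a [beta_series()].
#' @export
generate_subject_betas <- function(spec, subject_index) {
  stopifnot(inherits(spec, "scenario_spec"),
            is_count(subject_index), subject_index <= spec$n_subjects)
  sched <- block_schedule(spec)
  p <- spec$n_regions

  tuning_s <- with_seed(
    derive_seed(spec$seed, sprintf("subject:%d:tuning", subject_index)),
    spec$tuning + if (spec$subject_tuning_sd > 0) {
      matrix(stats::rnorm(p * spec$n_tasks, sd = spec$subject_tuning_sd),
             p, spec$n_tasks)
    } else 0)

  factors <- c(lapply(seq_along(spec$task_labels), function(i) {
    cov_factor(task_sigma(spec, i))
  }), list(rest = cov_factor(spec$sigma_rest)))
  names(factors) <- c(spec$task_labels, "rest")

  coef <- with_seed(
    derive_seed(spec$seed, sprintf("subject:%d:blocks", subject_index)), {
      out <- matrix(0, p, nrow(sched))
      for (b in seq_len(nrow(sched))) {
        tk <- sched$task[b]
        mu <- if (tk == "rest") rep(0, p) else tuning_s[, tk]
        out[, b] <- mu + drop(factors[[tk]] %*% stats::rnorm(p))
      }
      out
    })
  rownames(coef) <- spec$region_labels
  beta_series(coef, sched, subject = sprintf("sub-%02d", subject_index))
}

#' Generate a full synthetic dataset with its population ground truth
#'
#' @param spec a [scenario_spec()].
#' @return an object of class `synthetic_dataset`: a list with `betas` (list
#'   of [beta_series()]), `truth` (list with `sc`, `rnc`, `tnc`
#'   `corr_matrix` objects), and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  betas <- lapply(seq_len(spec$n_subjects), function(s) generate_subject_betas(spec, s))
  structure(list(
    betas = betas,
    truth = list(sc = population_sc(spec),
                 rnc = population_nc(spec, "rest"),
                 tnc = population_nc(spec, "task")),
    spec = spec
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d subjects x %d regions (seed %d)\n",
              length(x$betas), x$spec$n_regions, x$spec$seed))
  invisible(x)
}

#' Generate a BOLD-like parcel time series and its events table
#'
#' Builds an end-to-end fixture for the beta-series GLM: block activations are
#' drawn with [generate_subject_betas()], a boxcar-convolved design matrix is
#' built from the corresponding events, and the time series is
#' `design %*% t(betas)` plus white noise. With `noise_sd = 0`,
#' [fit_beta_series()] on the output recovers the generating betas exactly
#' (ordinary least squares on a noiseless full-rank model).
#'
#' @param spec a [scenario_spec()].
#' @param subject_index subject number.
#' @param tr repetition time in seconds (default 1).
#' @param block_duration block length in seconds (default 30).
#' @param gap inter-block interval in seconds (default 10; must leave blocks
#'   non-overlapping, i.e. `gap >= 0`).
#' @param noise_sd standard deviation of additive white measurement noise.
#' @return a list with `ts` (a [parcel_timeseries()]), `events` (an events
#'   data frame with columns onset, duration, trial_type, block_id, state),
#'   and `betas` (the generating [beta_series()]).
#' @export
generate_subject_timeseries <- function(spec, subject_index, tr = 1,
                                        block_duration = 30, gap = 10,
                                        noise_sd = 0) {
  stopifnot(gap >= 0, block_duration > 0, tr > 0, noise_sd >= 0)
  betas <- generate_subject_betas(spec, subject_index)
  sched <- betas$meta
  onsets <- (seq_len(nrow(sched)) - 1) * (block_duration + gap)
  events <- data.frame(onset = onsets, duration = block_duration,
                       trial_type = sched$task, block_id = sched$block_id,
                       state = sched$state, stringsAsFactors = FALSE)
  run_length <- max(onsets) + block_duration + 32 # room for the kernel tail
  n_frames <- ceiling(run_length / tr)
  design <- build_design_matrix(events, n_frames = n_frames, tr = tr)
  y <- design$matrix %*% t(betas$coef)
  if (noise_sd > 0) {
    y <- y + with_seed(
      derive_seed(spec$seed, sprintf("subject:%d:tsnoise", subject_index)),
      matrix(stats::rnorm(length(y), sd = noise_sd), nrow(y), ncol(y)))
  }
  ts <- parcel_timeseries(y, tr = tr, labels = rownames(betas$coef))
  list(ts = ts, events = events, betas = betas)
}
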