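#' Parcellated time series
#'
#' @param data `n_frames x n_regions` numeric matrix (no missing frames).
#' @param tr repetition time in seconds (> 0).
#' @param labels region labels (default taken from column names).
#' @param nuisance optional `n_frames x k` matrix of nuisance signals
#'   (motion/physiological regressors computed upstream).
#' @return an object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(data, tr = 1, labels = NULL, nuisance = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), tr > 0)
  if (anyNA(data)) stop("time series contains missing frames")
  labels <- labels %||% colnames(data) %||% sprintf("R%03d", seq_len(ncol(data)))
  stopifnot(length(labels) == ncol(data))
  colnames(data) <- labels
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == nrow(data))
  }
  structure(list(data = data, tr = tr, labels = labels, nuisance = nuisance),
            class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat(sprintf("parcel_timeseries: %d frames x %d regions (TR %gs%s)\n",
              nrow(x$data), ncol(x$data), x$tr,
              if (is.null(x$nuisance)) "" else
                sprintf(", %d nuisance signals", ncol(x$nuisance))))
  invisible(x)
}

# Validate an events table (onset/duration/trial_type, optional block_id and
# state) and fill in derived columns.
validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    stop("events table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(events) == 0) return(events)
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("event onsets must be strictly increasing")
  }
  if (any(events$duration <= 0)) stop("event durations must be positive")
  ends <- events$onset + events$duration
  if (any(events$onset[-1] < ends[-nrow(events)])) {
    stop("event blocks overlap")
  }
  events$trial_type <- as.character(events$trial_type)
  if (is.null(events$state)) {
    events$state <- ifelse(events$trial_type == "rest", "rest", "task")
  }
  if (is.null(events$block_id)) {
    events$block_id <- sprintf("b%03d_%s", seq_len(nrow(events)), events$trial_type)
  }
  if (anyDuplicated(events$block_id)) stop("duplicate block_id in events")
  bi <- stats::ave(seq_len(nrow(events)), events$trial_type, FUN = seq_along)
  if (is.null(events$block_index)) events$block_index <- bi
  events
}

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical kernel: a gamma density peaking at
#' `peak` seconds minus `1/ratio` times a gamma density peaking at
#' `undershoot` seconds, truncated at `length_s` seconds and scaled to unit
#' peak. Parameters default to the standard values (peak 6 s, undershoot
#' 16 s, undershoot ratio 1:6, 32 s support).
#'
#' @param tr sampling interval in seconds.
#' @param peak time-to-peak of the positive lobe (s).
#' @param undershoot time-to-peak of the undershoot (s).
#' @param ratio peak:undershoot amplitude ratio denominator (default 6).
#' @param length_s kernel support in seconds (default 32).
#' @return numeric vector of kernel samples at `0, tr, 2*tr, ...`.
#' @export
canonical_hrf <- function(tr = 1, peak = 6, undershoot = 16, ratio = 6,
                          length_s = 32) {
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h / max(h)
}

#' Build a beta-series design matrix from an events table
#'
#' One regressor per block: a boxcar spanning the block (1 during the block's
#' frames, 0 elsewhere; a block occupies the half-open frame interval
#' `[floor(onset/tr), floor((onset+duration)/tr))`, 0-based) convolved with
#' the canonical hemodynamic kernel sampled at the TR. Nuisance signals are
#' appended unmodified. Rest blocks listed in the events table get regressors
#' like any other block.
#'
#' @param events events table with columns onset, duration, trial_type
#'   (optionally block_id, state).
#' @param n_frames number of frames in the run.
#' @param tr repetition time in seconds.
#' @param hrf_params list of overrides passed to [canonical_hrf()].
#' @param nuisance optional `n_frames x k` matrix appended as nuisance
#'   columns.
#' @return an object of class `design_matrix`: list with `matrix`
#'   (`n_frames x (n_blocks + k)`), `roles` (data frame describing each
#'   column), `tr`.
#' @export
build_design_matrix <- function(events, n_frames, tr = 1, hrf_params = list(),
                                nuisance = NULL) {
  events <- validate_events(events)
  stopifnot(is_count(n_frames))
  kernel <- do.call(canonical_hrf, c(list(tr = tr), hrf_params))
  n_blocks <- nrow(events)
  X <- matrix(0, n_frames, n_blocks)
  if (n_blocks > 0) {
    start <- floor(events$onset / tr)            # 0-based
    stop_ <- floor((events$onset + events$duration) / tr)
    if (any(stop_ > n_frames)) {
      stop("event block(s) extend beyond the run: ",
           paste(events$block_id[stop_ > n_frames], collapse = ", "))
    }
    nk <- length(kernel)
    for (b in seq_len(n_blocks)) {
      box <- numeric(n_frames)
      box[(start[b] + 1):stop_[b]] <- 1
      # causal convolution; pad the head so early frames are defined
      conv <- stats::filter(c(numeric(nk - 1), box), kernel,
                            method = "convolution", sides = 1)
      X[, b] <- conv[nk:(nk + n_frames - 1)]
    }
    colnames(X) <- events$block_id
  }
  roles <- data.frame(column = events$block_id,
                      type = rep("block", n_blocks),
                      block_id = events$block_id, task = events$trial_type,
                      block_index = events$block_index, state = events$state,
                      stringsAsFactors = FALSE)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_frames)
    nn <- colnames(nuisance) %||% sprintf("nuisance%02d", seq_len(ncol(nuisance)))
    colnames(nuisance) <- nn
    X <- cbind(X, nuisance)
    roles <- rbind(roles, data.frame(column = nn, type = "nuisance",
                                     block_id = NA, task = NA,
                                     block_index = NA, state = NA,
                                     stringsAsFactors = FALSE))
  }
  structure(list(matrix = X, roles = roles, tr = tr), class = "design_matrix")
}

#' Fit a beta-series regression
#'
#' Ordinary least squares of every region's time series on the full design
#' (all block regressors and nuisance regressors simultaneously). Nuisance
#' coefficients are estimated jointly but excluded from the returned beta
#' series; the coefficient of each block regressor is that block's
#' activation.
#'
#' @param ts a [parcel_timeseries()]; its `nuisance` matrix, if present, is
#'   appended to the design.
#' @param design a [design_matrix()] built over the same frames.
#' @param subject subject id recorded in the output.
#' @return a [beta_series()].
#' @export
fit_beta_series <- function(ts, design, subject = "sub-01") {
  stopifnot(inherits(ts, "parcel_timeseries"), inherits(design, "design_matrix"))
  X <- design$matrix
  roles <- design$roles
  if (!is.null(ts$nuisance)) {
    nn <- colnames(ts$nuisance) %||% sprintf("tsnuisance%02d", seq_len(ncol(ts$nuisance)))
    colnames(ts$nuisance) <- nn
    X <- cbind(X, ts$nuisance)
    roles <- rbind(roles, data.frame(column = nn, type = "nuisance",
                                     block_id = NA, task = NA,
                                     block_index = NA, state = NA,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(X) != nrow(ts$data)) {
    stop(sprintf("design has %d frames but time series has %d",
                 nrow(X), nrow(ts$data)))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, ts$data)      # (n_cols x n_regions)
  keep <- roles$type == "block"
  block_roles <- roles[keep, ]
  beta_series(t(coefs[keep, , drop = FALSE]),
              data.frame(block_id = block_roles$block_id,
                         task = block_roles$task,
                         block_index = block_roles$block_index,
                         state = block_roles$state,
                         stringsAsFactors = FALSE),
              subject = subject)
}

#' Remove the mean evoked response with a finite impulse response model
#'
#' For each task, the mean response across that task's blocks is estimated at
#' every peri-block frame offset — from block onset through `post_offset_window`
#' seconds after block offset — and subtracted from every region
#' independently. What remains are the block-to-block "noise" fluctuations
#' with the task-locked (hemodynamically smeared) evoked response removed.
#' Frames claimed by the extended window of more than one block are assigned
#' to the later block's task (a message reports such overlaps). The operation
#' is idempotent.
#'
#' @param ts a [parcel_timeseries()].
#' @param events events table (each `trial_type` needs >= 2 blocks).
#' @param post_offset_window seconds after block offset still attributed to
#'   the block's evoked response (default 20).
#' @return a [parcel_timeseries()] of residuals.
#' @export
fir_residualize <- function(ts, events, post_offset_window = 20) {
  stopifnot(inherits(ts, "parcel_timeseries"), post_offset_window >= 0)
  events <- validate_events(events)
  counts <- table(events$trial_type)
  if (any(counts < 2)) {
    stop("FIR residualization requires >= 2 blocks per task; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  n <- nrow(ts$data)
  tr <- ts$tr
  assigned_event <- rep(NA_integer_, n)
  offset_of <- rep(NA_integer_, n)
  overlap <- FALSE
  for (b in seq_len(nrow(events))) {
    s <- floor(events$onset[b] / tr) + 1
    e <- min(floor((events$onset[b] + events$duration[b] + post_offset_window) / tr), n)
    if (s > n) next
    idx <- s:e
    if (any(!is.na(assigned_event[idx]))) overlap <- TRUE
    assigned_event[idx] <- b
    offset_of[idx] <- seq_along(idx) - 1L
  }
  if (overlap) {
    message("fir_residualize: extended block windows overlap; frames assigned to the later block's task")
  }
  resid <- ts$data
  inwin <- !is.na(assigned_event)
  grp <- paste(events$trial_type[assigned_event[inwin]], offset_of[inwin])
  for (g in unique(grp)) {
    rows <- which(inwin)[grp == g]
    mu <- colMeans(ts$data[rows, , drop = FALSE])
    resid[rows, ] <- sweep(ts$data[rows, , drop = FALSE], 2, mu)
  }
  parcel_timeseries(resid, tr = tr, labels = ts$labels, nuisance = ts$nuisance)
}
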