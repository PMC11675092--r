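#' Region-by-region correlation matrix with a role tag
#'
#' Thin wrapper around a symmetric numeric matrix recording what the matrix
#' is (SC, rNC, tNC, per-task NC, deltaNC, or a signal-noise differential) and
#' whose data produced it. Correlation roles have unit diagonal and entries in
#' \[-1, 1\]; deltaNC entries lie in \[-2, 2\]; the diagonal is excluded from
#' all summaries.
#'
#' @param values symmetric numeric matrix.
#' @param role one of `"SC"`, `"rNC"`, `"tNC"`, `"NC"`, `"deltaNC"`,
#'   `"differential"`.
#' @param subject subject id or `"group"`.
#' @return an object of class `corr_matrix`.
#' @export
corr_matrix <- function(values, role = c("SC", "rNC", "tNC", "NC", "deltaNC",
                                         "differential"),
                        subject = "group") {
  role <- match.arg(role)
  values <- symmetrize(values, tol = 1e-8, what = sprintf("%s matrix", role))
  ok <- !is.na(values)
  if (role %in% c("SC", "rNC", "tNC", "NC")) {
    if (any(abs(values[ok]) > 1 + 1e-10)) stop("correlation entries must lie in [-1, 1]")
  } else if (role == "deltaNC") {
    if (any(abs(values[ok]) > 2 + 1e-10)) stop("deltaNC entries must lie in [-2, 2]")
  }
  if (is.null(rownames(values))) {
    rn <- sprintf("R%03d", seq_len(nrow(values)))
    dimnames(values) <- list(rn, rn)
  }
  structure(list(values = values, role = role, subject = subject,
                 labels = rownames(values)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  v <- offdiag(x$values)
  cat(sprintf("corr_matrix [%s, %s]: %d x %d, off-diagonal range [%.3f, %.3f]\n",
              x$role, x$subject, nrow(x$values), ncol(x$values),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

# accept corr_matrix or plain matrix
unclass_corr <- function(x) {
  if (inherits(x, "corr_matrix")) x$values else x
}

offdiag <- function(m) m[row(m) != col(m)]

check_same_labels <- function(a, b) {
  la <- if (inherits(a, "corr_matrix")) a$labels else rownames(a)
  lb <- if (inherits(b, "corr_matrix")) b$labels else rownames(b)
  if (nrow(unclass_corr(a)) != nrow(unclass_corr(b))) {
    stop("matrices have different dimensions")
  }
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop("matrices have mismatched region labels")
  }
}

#' Signal correlation from a beta series
#'
#' For each region, the mean activation of each task is obtained by averaging
#' blockwise coefficients within the task; the signal correlation between two
#' regions is the Pearson correlation of those task-mean vectors across
#' tasks. It measures task-tuning similarity and uses only the cross-block
#' mean, making it invariant to any permutation of block order within tasks.
#'
#' @param beta a [beta_series()].
#' @return a `corr_matrix` with role `"SC"`. Regions with zero variance
#'   across task means get `NA` rows/columns (reported via a message).
#' @export
compute_sc <- function(beta) {
  m <- task_means(beta)
  if (ncol(m) < 3L) stop("SC requires at least 3 tasks")
  sds <- apply(m, 1L, stats::sd)
  flat <- sds == 0
  sc <- suppressWarnings(stats::cor(t(m)))
  if (any(flat)) {
    message("compute_sc: zero-variance task means for region(s) ",
            paste(rownames(m)[flat], collapse = ", "), "; entries set to NA")
    sc[flat, ] <- NA_real_
    sc[, flat] <- NA_real_
  }
  diag(sc) <- 1
  corr_matrix(sc, role = "SC", subject = beta$subject)
}

#' Noise correlations from a beta series
#'
#' The noise correlation (NC) for a pair of regions within a task is the
#' Pearson correlation of their activation coefficients across that task's
#' blocks. The task-general tNC is the unweighted mean of the per-task NC
#' matrices over task conditions (rest excluded); the rNC is estimated from
#' the rest blocks alone. NC uses only the cross-block fluctuations, the
#' orthogonal complement of the cross-block mean that SC uses.
#'
#' @param beta a [beta_series()].
#' @param tasks optional character vector restricting which task conditions
#'   enter the per-task NCs and the tNC average (default: all tasks).
#' @return a list with components `per_task` (named list of `corr_matrix`,
#'   role `"NC"`), `tnc` and `rnc` (`corr_matrix`; `rnc` is `NULL` when the
#'   series has no rest blocks).
#' @export
compute_nc <- function(beta, tasks = NULL) {
  stopifnot(inherits(beta, "beta_series"))
  meta <- beta$meta
  all_tasks <- sort(unique(meta$task[meta$state == "task"]))
  tasks <- tasks %||% all_tasks
  stopifnot(all(tasks %in% all_tasks))

  nc_of <- function(ids, what) {
    if (length(ids) < 3L) stop("NC requires at least 3 blocks (", what, ")")
    x <- t(beta$coef[, meta$block_id %in% ids, drop = FALSE])
    flat <- apply(x, 2L, stats::sd) == 0
    r <- suppressWarnings(stats::cor(x))
    if (any(flat)) {
      message("compute_nc: constant region(s) within ", what, ": ",
              paste(colnames(x)[flat], collapse = ", "), "; entries set to NA")
      r[flat, ] <- NA_real_
      r[, flat] <- NA_real_
    }
    diag(r) <- 1
    r
  }

  per_task <- lapply(tasks, function(tk) {
    corr_matrix(nc_of(meta$block_id[meta$state == "task" & meta$task == tk], tk),
                role = "NC", subject = beta$subject)
  })
  names(per_task) <- tasks
  tnc_values <- Reduce(`+`, lapply(per_task, unclass_corr)) / length(per_task)
  tnc <- corr_matrix(tnc_values, role = "tNC", subject = beta$subject)
  rnc <- NULL
  if (any(meta$state == "rest")) {
    rnc <- corr_matrix(nc_of(meta$block_id[meta$state == "rest"], "rest blocks"),
                       role = "rNC", subject = beta$subject)
  }
  list(per_task = per_task, tnc = tnc, rnc = rnc)
}

#' State-dependent noise-correlation change (deltaNC = tNC - rNC)
#'
#' @param tnc,rnc `corr_matrix` objects (roles `tNC`/`rNC`, any correlation
#'   role accepted) over the same regions.
#' @return a `corr_matrix` with role `"deltaNC"`; the diagonal is `NA`.
#' @export
compute_delta_nc <- function(tnc, rnc) {
  check_same_labels(tnc, rnc)
  d <- unclass_corr(tnc) - unclass_corr(rnc)
  diag(d) <- NA_real_
  subject <- if (inherits(tnc, "corr_matrix")) tnc$subject else "group"
  corr_matrix(d, role = "deltaNC", subject = subject)
}

#' Signal-noise differential matrix
#'
#' Elementwise (Hadamard) product of the SC matrix with the deltaNC matrix.
#' A positive entry means the state-dependent noise-correlation change is
#' aligned with the pair's signal correlation (putatively information
#' limiting); a negative entry means it is anti-aligned (putatively
#' information enhancing); exact zeros form a third, null category.
#'
#' @param sc,dnc `corr_matrix` objects over the same regions.
#' @return a list of class `differential_matrix` with elements `values`
#'   (symmetric matrix, `NA` diagonal), `alignment` (character matrix with
#'   entries `"aligned"`, `"anti_aligned"`, `"null"`), `labels`, `subject`.
#' @export
signal_noise_differential <- function(sc, dnc) {
  check_same_labels(sc, dnc)
  v <- unclass_corr(sc) * unclass_corr(dnc)
  diag(v) <- NA_real_
  al <- matrix("null", nrow(v), ncol(v), dimnames = dimnames(v))
  al[!is.na(v) & v > 0] <- "aligned"
  al[!is.na(v) & v < 0] <- "anti_aligned"
  diag(al) <- NA_character_
  subject <- if (inherits(sc, "corr_matrix")) sc$subject else "group"
  structure(list(values = v, alignment = al,
                 labels = rownames(v) %||% sprintf("R%03d", seq_len(nrow(v))),
                 subject = subject),
            class = "differential_matrix")
}

#' @export
print.differential_matrix <- function(x, ...) {
  s <- alignment_summary(x)
  cat(sprintf("differential_matrix [%s]: %d regions; %.1f%% aligned, %.1f%% anti-aligned\n",
              x$subject, nrow(x$values), s$overall["aligned"],
              s$overall["anti_aligned"]))
  invisible(x)
}

#' Aligned / anti-aligned fractions of a signal-noise differential
#'
#' Percentages are computed over unique off-diagonal region pairs. Exact-zero
#' (null) differentials are counted in the denominator but in neither
#' category, so aligned + anti-aligned may fall short of 100%. Per-network
#' percentages are computed over pairs with at least one member in the
#' network; the per-region value is the mean of the region's row of the
#' differential matrix.
#'
#' @param diff a `differential_matrix`.
#' @param partition optional [network_partition()] covering all regions; when
#'   supplied, per-network percentages are included.
#' @return a list with `overall` (named percentages: aligned, anti_aligned,
#'   null), `per_region` (named vector of mean differentials), and (with a
#'   partition) `per_network` (data frame of per-network percentages).
#' @export
alignment_summary <- function(diff, partition = NULL) {
  stopifnot(inherits(diff, "differential_matrix"))
  v <- diff$values
  n <- nrow(v)
  ut <- upper.tri(v)
  vals <- v[ut]
  vals <- vals[!is.na(vals)]
  pct <- function(x) 100 * c(aligned = mean(x > 0), anti_aligned = mean(x < 0),
                             null = mean(x == 0))
  out <- list(overall = pct(vals),
              per_region = rowMeans(v, na.rm = TRUE))
  if (!is.null(partition)) {
    labels <- partition_labels(partition, diff$labels)
    nets <- sort(unique(labels))
    per_net <- do.call(rbind, lapply(nets, function(net) {
      inc <- labels == net
      sel <- ut & (inc[row(v)] | inc[col(v)])
      x <- v[sel]
      x <- x[!is.na(x)]
      data.frame(network = net, t(pct(x)))
    }))
    out$per_network <- per_net
  }
  out
}

#' Intersubject signal correlation
#'
#' Correlates region i's task-mean vector in one subject with region j's
#' task-mean vector in other subjects, removing within-subject noise shared
#' across regions. Under `"leave-one-out"` each subject's task means are
#' correlated against the average task means of the remaining subjects and
#' the result is averaged over held-out subjects; `"pairwise"` averages over
#' all ordered subject pairs. The result is symmetrized.
#'
#' @param betas list of [beta_series()] over the same regions and tasks
#'   (at least 2).
#' @param scheme `"leave-one-out"` (default) or `"pairwise"`.
#' @return a `corr_matrix` with role `"SC"` and subject `"group"`.
#' @export
intersubject_sc <- function(betas, scheme = c("leave-one-out", "pairwise")) {
  scheme <- match.arg(scheme)
  if (length(betas) < 2L) stop("intersubject SC requires at least 2 subjects")
  tms <- lapply(betas, task_means)
  tasks <- colnames(tms[[1]])
  for (m in tms) stopifnot(identical(colnames(m), tasks),
                           identical(dim(m), dim(tms[[1]])))
  n_sub <- length(tms)
  acc <- 0
  if (scheme == "leave-one-out") {
    total <- Reduce(`+`, tms)
    for (s in seq_len(n_sub)) {
      others <- (total - tms[[s]]) / (n_sub - 1)
      acc <- acc + stats::cor(t(tms[[s]]), t(others))
    }
    acc <- acc / n_sub
  } else {
    npairs <- 0L
    for (a in seq_len(n_sub)) for (b in seq_len(n_sub)) {
      if (a == b) next
      acc <- acc + stats::cor(t(tms[[a]]), t(tms[[b]]))
      npairs <- npairs + 1L
    }
    acc <- acc / npairs
  }
  acc <- (acc + t(acc)) / 2
  acc <- pmin(pmax(acc, -1), 1)
  corr_matrix(acc, role = "SC", subject = "group")
}

#' Group-average correlation matrices
#'
#' @param matrices list of `corr_matrix` objects with a common role and
#'   region labels.
#' @param method `"mean_r"` (default): elementwise mean of r;
#'   `"fisher_z"`: inverse-transformed mean of atanh(r).
#' @return a `corr_matrix` with subject `"group"`.
#' @export
group_average <- function(matrices, method = c("mean_r", "fisher_z")) {
  method <- match.arg(method)
  stopifnot(length(matrices) >= 1L)
  roles <- vapply(matrices, function(m) m$role, character(1))
  if (length(unique(roles)) > 1L) {
    stop("cannot average matrices with different roles: ",
         paste(unique(roles), collapse = ", "))
  }
  for (m in matrices[-1]) check_same_labels(matrices[[1]], m)
  vals <- lapply(matrices, unclass_corr)
  if (method == "mean_r") {
    avg <- Reduce(`+`, vals) / length(vals)
  } else {
    z <- lapply(vals, function(v) atanh(pmin(pmax(v, -1 + 1e-15), 1 - 1e-15)))
    avg <- tanh(Reduce(`+`, z) / length(z))
    diag(avg) <- diag(Reduce(`+`, vals) / length(vals))
  }
  corr_matrix(avg, role = roles[1], subject = "group")
}
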