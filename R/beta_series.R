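#' Block-wise activation coefficients (beta series)
#'
#' Container for the substrate of all SC/NC estimation: one activation
#' coefficient per region per block, with per-block metadata identifying the
#' task condition, the block's index within its task, and whether the block is
#' a task or rest block.
#'
#' @param coef `n_regions x n_blocks` numeric matrix of activation
#'   coefficients; row names are region labels.
#' @param meta data frame with one row per block and columns `block_id`,
#'   `task` (task label, `"rest"` for rest blocks), `block_index` (1-based
#'   within task), `state` (`"task"` or `"rest"`).
#' @param subject subject identifier.
#' @return an object of class `beta_series`.
#' @export
beta_series <- function(coef, meta, subject = "sub-01") {
  stopifnot(is.matrix(coef), is.data.frame(meta), nrow(meta) == ncol(coef))
  required <- c("block_id", "task", "block_index", "state")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("beta_series metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(meta$state %in% c("task", "rest"))) {
    stop("state must be 'task' or 'rest'")
  }
  if (anyDuplicated(meta$block_id)) stop("block_id values must be unique")
  task_meta <- meta[meta$state == "task", ]
  if (nrow(task_meta)) {
    counts <- table(task_meta$task)
    if (length(unique(counts)) > 1L) {
      stop("every task must have the same number of blocks")
    }
  }
  if (is.null(rownames(coef))) {
    rownames(coef) <- sprintf("R%03d", seq_len(nrow(coef)))
  }
  colnames(coef) <- meta$block_id
  meta$task <- as.character(meta$task)
  meta$state <- as.character(meta$state)
  structure(list(coef = coef, meta = meta, subject = subject),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  nt <- length(unique(x$meta$task[x$meta$state == "task"]))
  cat(sprintf("beta_series [%s]: %d regions x %d blocks (%d tasks, %d rest blocks)\n",
              x$subject, nrow(x$coef), ncol(x$coef), nt,
              sum(x$meta$state == "rest")))
  invisible(x)
}

# region x task matrix of mean activations (task blocks only)
task_means <- function(beta) {
  stopifnot(inherits(beta, "beta_series"))
  tm <- beta$meta[beta$meta$state == "task", ]
  tasks <- sort(unique(tm$task))
  m <- vapply(tasks, function(tk) {
    rowMeans(beta$coef[, beta$meta$block_id %in% tm$block_id[tm$task == tk],
                       drop = FALSE])
  }, numeric(nrow(beta$coef)))
  dimnames(m) <- list(rownames(beta$coef), tasks)
  m
}
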