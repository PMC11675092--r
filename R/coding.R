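# Clique identification on the thresholded signal-noise differential graph
# and shuffle-controlled multitask decoding.

#' Threshold a signal-noise differential into a binary graph
#'
#' For `sign = "aligned"` the `retain_fraction` most-positive off-diagonal
#' entries become edges; for `"anti_aligned"` the most-negative. The fraction
#' is taken of the entries of the requested sign, so every edge of the
#' returned graph is an aligned (resp. anti-aligned) pair.
#'
#' @param diff a `differential_matrix` (or plain symmetric matrix).
#' @param retain_fraction fraction of same-sign entries retained
#'   (default 0.2).
#' @param sign `"aligned"` or `"anti_aligned"`.
#' @return symmetric logical adjacency matrix (no self-loops) with attribute
#'   `"cutoff"`, the differential value at the threshold. If no entries of
#'   the requested sign exist an empty graph is returned with a warning.
#' @export
threshold_differential <- function(diff, retain_fraction = 0.2,
                                   sign = c("aligned", "anti_aligned")) {
  sign <- match.arg(sign)
  v <- if (inherits(diff, "differential_matrix")) diff$values else unclass_corr(diff)
  v <- symmetrize(v, tol = 1e-8, what = "differential matrix")
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  ut <- upper.tri(v)
  key <- if (sign == "aligned") v else -v
  cand <- which(ut & !is.na(key) & key > 0)
  adj <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  if (!length(cand)) {
    warning("no ", sign, " entries in the differential; returning an empty graph")
    attr(adj, "cutoff") <- NA_real_
    return(adj)
  }
  n_keep <- max(1L, ceiling(retain_fraction * length(cand)))
  n_keep <- min(n_keep, length(cand))
  cutoff <- sort(key[cand], decreasing = TRUE)[n_keep]
  keep <- cand[key[cand] >= cutoff]
  adj[keep] <- TRUE
  adj <- adj | t(adj)
  attr(adj, "cutoff") <- if (sign == "aligned") cutoff else -cutoff
  adj
}

#' Enumerate all k-cliques of a binary graph
#'
#' Enumerates k-node fully connected subgraphs by expanding the maximal
#' cliques of the graph (Bron-Kerbosch via igraph) into their k-subsets.
#' Ordering is deterministic: member ids sorted within a clique, cliques
#' sorted lexicographically. A work budget caps the number of k-subsets
#' expanded; graphs exceeding it are an error (raise the threshold or the
#' budget).
#'
#' @param adjacency symmetric logical/0-1 adjacency matrix.
#' @param k clique size (>= 2, <= number of nodes).
#' @param budget maximum number of k-subsets expanded (default 2e5).
#' @return list of integer vectors (sorted node indices); node labels are
#'   carried in the `"labels"` attribute.
#' @export
find_k_cliques <- function(adjacency, k, budget = 2e5) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency),
            is_count(k, 2L))
  n <- nrow(adjacency)
  if (k > n) stop("k exceeds the number of nodes")
  labels <- rownames(adjacency) %||% as.character(seq_len(n))
  mode(adjacency) <- "logical"
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  maximal <- igraph::max_cliques(g, min = k)
  if (!length(maximal)) {
    out <- list()
    attr(out, "labels") <- labels
    return(out)
  }
  total_work <- sum(vapply(maximal, function(m) choose(length(m), k), numeric(1)))
  if (total_work > budget) {
    stop(sprintf("k-clique enumeration needs %.3g subset expansions (budget %.3g); raise the threshold or the budget",
                 total_work, budget))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (m in maximal) {
    m <- sort(as.integer(m))
    combs <- utils::combn(m, k)
    for (j in seq_len(ncol(combs))) {
      key <- paste(combs[, j], collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- combs[, j]
      }
    }
  }
  ord <- order(vapply(out, function(x) paste(sprintf("%06d", x), collapse = ","),
                      character(1)))
  out <- out[ord]
  attr(out, "labels") <- labels
  out
}

clique_strengths <- function(values, cliques) {
  vapply(cliques, function(cl) {
    sub <- values[cl, cl]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

#' A set of same-sign cliques with their differential strengths
#'
#' @param diff a `differential_matrix`.
#' @param cliques list of integer member vectors (as from
#'   [find_k_cliques()]).
#' @param sign `"aligned"` or `"anti_aligned"`.
#' @param retain_fraction threshold fraction used to build the graph.
#' @return object of class `clique_set`: list with `cliques` (member label
#'   lists), `members` (integer indices), `strength` (mean differential over
#'   member pairs), `sign`, `k`, `retain_fraction`.
#' @export
clique_set <- function(diff, cliques, sign, retain_fraction) {
  stopifnot(inherits(diff, "differential_matrix"))
  k <- if (length(cliques)) length(cliques[[1]]) else NA_integer_
  strengths <- clique_strengths(diff$values, cliques)
  structure(list(
    cliques = lapply(cliques, function(cl) diff$labels[cl]),
    members = cliques, strength = strengths, sign = sign, k = k,
    retain_fraction = retain_fraction),
    class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat(sprintf("clique_set: %d %s %d-clique(s), strength range [%.3g, %.3g]\n",
              length(x$cliques), x$sign, x$k,
              if (length(x$strength)) min(x$strength) else NA,
              if (length(x$strength)) max(x$strength) else NA))
  invisible(x)
}

#' Aligned and anti-aligned k-cliques matched to network pairs
#'
#' For every unordered pair of networks (including a network with itself),
#' the thresholded aligned and anti-aligned differential graphs are searched
#' for k-cliques drawn from the union of the two networks' regions with at
#' least one member from each. Network pairs lacking a clique of either sign
#' are flagged untestable and are excluded from aligned-versus-anti-aligned
#' decoding comparisons.
#'
#' @param diff a `differential_matrix`.
#' @param partition a [network_partition()] covering the regions.
#' @param k clique size (default 5).
#' @param retain_fraction threshold fraction (default 0.2).
#' @param budget work budget per pair for [find_k_cliques()].
#' @return data-frame-less list: one element per network pair with
#'   `networks`, `aligned`/`anti_aligned` (`clique_set`s, strongest clique
#'   first), and `testable`.
#' @export
network_matched_cliques <- function(diff, partition, k = 5L,
                                    retain_fraction = 0.2, budget = 2e5) {
  stopifnot(inherits(diff, "differential_matrix"))
  labels <- partition_labels(partition, diff$labels)
  nets <- sort(unique(labels))
  adj <- list(aligned = threshold_differential(diff, retain_fraction, "aligned"),
              anti_aligned = threshold_differential(diff, retain_fraction, "anti_aligned"))
  pairs <- list()
  for (a in seq_along(nets)) for (b in a:length(nets)) {
    in_a <- labels == nets[a]
    in_b <- labels == nets[b]
    idx <- which(in_a | in_b)
    sets <- lapply(names(adj), function(sgn) {
      sub <- adj[[sgn]][idx, idx, drop = FALSE]
      cls <- if (length(idx) >= k) find_k_cliques(sub, k, budget) else list()
      cls <- lapply(cls, function(cl) idx[cl])
      if (a != b) {
        cls <- Filter(function(cl) any(in_a[cl]) && any(in_b[cl]), cls)
      }
      cs <- clique_set(diff, cls, sgn, retain_fraction)
      ord <- order(-abs(cs$strength))
      cs$cliques <- cs$cliques[ord]; cs$members <- cs$members[ord]
      cs$strength <- cs$strength[ord]
      cs
    })
    names(sets) <- names(adj)
    pairs[[paste(nets[a], nets[b], sep = "-")]] <- list(
      networks = c(nets[a], nets[b]),
      aligned = sets$aligned, anti_aligned = sets$anti_aligned,
      testable = length(sets$aligned$cliques) > 0 &&
        length(sets$anti_aligned$cliques) > 0)
  }
  pairs
}

#' Strongest aligned or anti-aligned k-clique
#'
#' Among all k-cliques of the thresholded differential graph, returns the one
#' maximizing the absolute mean differential over member pairs; ties are
#' broken by the lexicographically smallest member set.
#'
#' @param diff a `differential_matrix`.
#' @param k clique size (default 20).
#' @param sign `"aligned"` or `"anti_aligned"`.
#' @param retain_fraction threshold fraction (default 0.2; a looser 0.4 is
#'   conventional for k = 25).
#' @param budget work budget for [find_k_cliques()].
#' @return a `clique_set` holding the single selected clique. If no k-clique
#'   exists, an error reports the size of the largest clique found.
#' @export
strongest_clique <- function(diff, k = 20L, sign = c("aligned", "anti_aligned"),
                             retain_fraction = 0.2, budget = 2e5) {
  sign <- match.arg(sign)
  adj <- threshold_differential(diff, retain_fraction, sign)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  biggest <- igraph::clique_num(g)
  if (biggest < k) {
    stop(sprintf("no %s %d-clique at retain_fraction %.2g; largest clique has %d nodes",
                 sign, k, retain_fraction, biggest))
  }
  cliques <- find_k_cliques(adj, k, budget)
  strengths <- clique_strengths(diff$values, cliques)
  best <- which(abs(strengths) == max(abs(strengths)))
  if (length(best) > 1L) best <- best[1L]  # cliques are in lexicographic order
  clique_set(diff, cliques[best], sign, retain_fraction)
}

#' Destroy noise correlations by shuffling block order
#'
#' Independently permutes the order of blocks within each task for each
#' region. Per-region, per-task multisets of values — and hence all task
#' means and the signal correlation — are exactly preserved, while
#' cross-region block-to-block covariation (the noise correlation) is
#' destroyed.
#'
#' @param beta a [beta_series()] (>= 2 blocks per task).
#' @param seed integer seed.
#' @return a [beta_series()] with shuffled block order per region and task.
#' @export
shuffle_block_structure <- function(beta, seed = 1L) {
  stopifnot(inherits(beta, "beta_series"))
  coef <- beta$coef
  with_seed(seed, {
    for (tk in unique(beta$meta$task)) {
      cols <- which(beta$meta$task == tk)
      if (length(cols) < 2L) next
      for (r in seq_len(nrow(coef))) {
        coef[r, cols] <- coef[r, cols][sample.int(length(cols))]
      }
    }
  })
  beta_series(coef, beta$meta, subject = beta$subject)
}

#' Leave-one-block-out multitask decoding
#'
#' 26-way (or n-task-way) linear decoding of task identity from block
#' activation patterns over a region set, cross-validated across blocks:
#' fold f holds out block f of every task (one test sample per task).
#' Within each training fold the pipeline is: optional within-task block
#' shuffling (destroying noise correlations in the training set only),
#' bootstrap resampling (`n_boot` samples per task, with replacement),
#' feature z-normalization with statistics from the bootstrapped training set
#' (applied to train and test), and a ridge-penalized multinomial logistic
#' classifier. Classifier score ties are broken by lowest class index.
#'
#' @param beta a [beta_series()] (>= 3 blocks per task, >= 2 tasks).
#' @param regions character vector of region labels to decode from (>= 2).
#' @param shuffle_training if `TRUE`, shuffle block order within tasks in
#'   each training fold before bootstrapping.
#' @param seed master seed; per-fold bootstrap and shuffle sub-seeds are
#'   derived from it.
#' @param n_boot bootstrap samples per task per fold (default 20).
#' @param lambda ridge penalty passed to glmnet (default `1 / n_train`,
#'   matching a unit inverse regularization strength).
#' @param permute_labels if `TRUE`, task labels are randomly permuted across
#'   all blocks before decoding (chance-level control).
#' @return object of class `decoding_result`: list with `accuracy`,
#'   `fold_accuracy`, `condition` (`"unshuffled"`/`"shuffled"`), `regions`,
#'   `n_folds`, `n_classes`, `subject`, `seed`.
#' @export
decode_multitask <- function(beta, regions, shuffle_training = FALSE,
                             seed = 1L, n_boot = 20L, lambda = NULL,
                             permute_labels = FALSE) {
  stopifnot(inherits(beta, "beta_series"))
  missing <- setdiff(regions, rownames(beta$coef))
  if (length(missing)) {
    stop("region(s) not in beta series: ", paste(missing, collapse = ", "))
  }
  if (length(regions) < 2L) stop("decoding requires >= 2 regions")
  meta <- beta$meta
  tk_idx <- which(meta$state == "task")
  tasks <- sort(unique(meta$task[tk_idx]))
  if (length(tasks) < 2L) stop("decoding requires >= 2 tasks")
  bpt <- sum(meta$task == tasks[1] & meta$state == "task")
  if (bpt < 3L) stop("decoding requires >= 3 blocks per task")

  x_all <- t(beta$coef[regions, tk_idx, drop = FALSE])
  y_all <- meta$task[tk_idx]
  fold_of <- meta$block_index[tk_idx]
  if (permute_labels) {
    y_all <- with_seed(derive_seed(seed, "decode:permute"), sample(y_all))
    # keep one test sample per class per fold by re-indexing blocks per task
    fold_of <- stats::ave(seq_along(y_all), y_all, FUN = seq_along)
  }

  n_correct <- 0L
  fold_acc <- numeric(bpt)
  for (f in seq_len(bpt)) {
    test <- fold_of == f
    xtr <- x_all[!test, , drop = FALSE]
    ytr <- y_all[!test]
    xte <- x_all[test, , drop = FALSE]
    yte <- y_all[test]
    if (shuffle_training) {
      xtr <- with_seed(derive_seed(seed, sprintf("decode:shuffle:%d", f)), {
        for (tk in tasks) {
          rows <- which(ytr == tk)
          for (j in seq_len(ncol(xtr))) {
            xtr[rows, j] <- xtr[rows, j][sample.int(length(rows))]
          }
        }
        xtr
      })
    }
    boot <- with_seed(derive_seed(seed, sprintf("decode:boot:%d", f)), {
      unlist(lapply(tasks, function(tk) {
        rows <- which(ytr == tk)
        rows[sample.int(length(rows), n_boot, replace = TRUE)]
      }))
    })
    xb <- xtr[boot, , drop = FALSE]
    yb <- ytr[boot]
    mu <- colMeans(xb)
    sd_ <- apply(xb, 2L, stats::sd)
    keep <- sd_ > 0
    if (!all(keep)) {
      message("decode_multitask: dropping zero-variance feature(s): ",
              paste(colnames(xb)[!keep], collapse = ", "))
    }
    if (sum(keep) < 2L) stop("fewer than 2 usable features after normalization")
    xb <- scale(xb[, keep, drop = FALSE], mu[keep], sd_[keep])
    xte_s <- scale(xte[, keep, drop = FALSE], mu[keep], sd_[keep])
    lam <- lambda %||% (1 / nrow(xb))
    fit <- glmnet::glmnet(xb, factor(yb, levels = tasks),
                          family = "multinomial", alpha = 0,
                          lambda = c(lam * 100, lam * 10, lam),
                          standardize = FALSE)
    prob <- drop(stats::predict(fit, newx = xte_s, s = lam, type = "response"))
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
    pred <- tasks[max.col(prob, ties.method = "first")]
    n_correct <- n_correct + sum(pred == yte)
    fold_acc[f] <- mean(pred == yte)
  }
  structure(list(
    accuracy = n_correct / (bpt * length(tasks)),
    fold_accuracy = fold_acc,
    condition = if (shuffle_training) "shuffled" else "unshuffled",
    regions = regions, n_folds = bpt, n_classes = length(tasks),
    chance = 1 / length(tasks), subject = beta$subject, seed = seed),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result [%s, %s]: accuracy %.3f (%d-way, chance %.3f, %d folds)\n",
              x$subject, x$condition, x$accuracy, x$n_classes, x$chance,
              x$n_folds))
  invisible(x)
}

#' Paired comparison of decoding accuracies
#'
#' Wilcoxon signed-rank test on paired per-subject accuracies with
#' Bonferroni correction over `n_tests` comparisons. Zero differences are
#' dropped (all-zero differences give `p = 1` by convention). For up to 100
#' informative pairs the exact signed-rank null distribution is used (ties
#' in the absolute differences receive midranks); beyond that the normal
#' approximation with continuity correction is used.
#'
#' @param acc_a,acc_b paired numeric vectors (length >= 6).
#' @param n_tests number of comparisons in the family (default 1).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   (alternatives refer to `acc_a` relative to `acc_b`).
#' @return list with `statistic` (the signed-rank statistic V), `p`,
#'   `p_bonferroni`, `significant` (Bonferroni-corrected p < 0.05),
#'   `n_tests`.
#' @export
compare_conditions <- function(acc_a, acc_b, n_tests = 1L,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 6L,
            is_count(n_tests))
  d <- acc_a - acc_b
  d <- d[d != 0]
  if (!length(d)) {
    message("compare_conditions: all paired differences are zero; p = 1 by convention")
    return(list(statistic = NA_real_, p = 1, p_bonferroni = 1,
                significant = FALSE, n_tests = n_tests))
  }
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 100L) {
    p_ge <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(v, n)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  pb <- min(1, p * n_tests)
  list(statistic = v, p = p, p_bonferroni = pb,
       significant = pb < 0.05, n_tests = n_tests)
}
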