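#' Region-to-network partition
#'
#' @param region character vector of region ids (each exactly once).
#' @param label network label per region.
#' @return an object of class `network_partition`.
#' @export
network_partition <- function(region, label) {
  region <- as.character(region)
  label <- as.character(label)
  stopifnot(length(region) == length(label))
  if (anyDuplicated(region)) {
    stop("duplicate region(s) in partition: ",
         paste(unique(region[duplicated(region)]), collapse = ", "))
  }
  structure(list(region = region, label = label,
                 modules = sort(unique(label))),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("network_partition: %d regions in %d modules\n",
              length(x$region), length(x$modules)))
  invisible(x)
}

# Resolve a partition against a set of region labels, returning the module
# label vector in that order. Errors on uncovered regions.
partition_labels <- function(partition, regions) {
  if (!inherits(partition, "network_partition")) {
    partition <- network_partition(names(partition) %||% regions, partition)
  }
  idx <- match(regions, partition$region)
  if (anyNA(idx)) {
    stop("partition does not cover region(s): ",
         paste(regions[is.na(idx)], collapse = ", "))
  }
  partition$label[idx]
}

#' Signed modularity with respect to a fixed partition
#'
#' The asymmetric signed variant: positive weights reward within-module
#' concentration, negative weights penalize it.
#' `Q+` and `Q-` are each `(1/v) * sum_ij (w_ij - s_i s_j / v) delta(M_i, M_j)`
#' evaluated on the positive part (entries `max(w, 0)`) and the magnitude of
#' the negative part respectively, with `s_i` a node's total strength and `v`
#' the total weight of that part. The combined statistic is
#' `Q* = Q+ - (v- / (v+ + v-)) Q-` by default; `combine = "add"` flips the
#' sign of the negative contribution. The diagonal is zeroed before all
#' calculations.
#'
#' @param W symmetric weight matrix or `corr_matrix`.
#' @param partition a [network_partition()] (or label vector) covering `W`.
#' @param combine `"subtract"` (default) or `"add"` for the sign of the
#'   `Q-` contribution to `Q*`.
#' @return list with `q_star`, `q_plus`, `q_minus`, `v_plus`, `v_minus`,
#'   `per_module` (data frame of within-module observed and expected weight
#'   per part), and `combine`.
#' @export
signed_modularity <- function(W, partition, combine = c("subtract", "add")) {
  combine <- match.arg(combine)
  W <- symmetrize(unclass_corr(W), tol = 1e-8, what = "weight matrix")
  diag(W) <- 0
  if (anyNA(W)) stop("weight matrix contains NA off-diagonal entries")
  labels <- partition_labels(partition, rownames(W) %||% as.character(seq_len(nrow(W))))
  if (length(unique(labels)) < 2L) stop("modularity requires >= 2 modules")
  same <- outer(labels, labels, "==")

  part_q <- function(Wp, what) {
    v <- sum(Wp)
    if (v == 0) {
      if (what == "plus") stop("positive part of W is all zero; Q+ undefined")
      return(list(q = 0, v = 0, per_module = NULL))
    }
    s <- rowSums(Wp)
    e <- outer(s, s) / v
    q <- sum((Wp - e)[same]) / v
    per_module <- vapply(sort(unique(labels)), function(m) {
      idx <- labels == m
      c(observed = sum(Wp[idx, idx]) / v, expected = sum(e[idx, idx]) / v)
    }, numeric(2))
    list(q = q, v = v, per_module = per_module)
  }

  pos <- part_q(pmax(W, 0), "plus")
  neg <- part_q(pmax(-W, 0), "minus")
  w_minus <- if (pos$v + neg$v > 0) neg$v / (pos$v + neg$v) else 0
  q_star <- if (combine == "subtract") pos$q - w_minus * neg$q
            else pos$q + w_minus * neg$q
  per_module <- data.frame(
    module = sort(unique(labels)),
    within_pos_observed = pos$per_module["observed", ],
    within_pos_expected = pos$per_module["expected", ],
    within_neg_observed = if (is.null(neg$per_module)) 0 else neg$per_module["observed", ],
    within_neg_expected = if (is.null(neg$per_module)) 0 else neg$per_module["expected", ],
    row.names = NULL)
  list(q_star = q_star, q_plus = pos$q, q_minus = neg$q,
       v_plus = pos$v, v_minus = neg$v, per_module = per_module,
       combine = combine)
}

#' Network segregation of a weighted matrix
#'
#' Per region, `s_i = (x_in - x_out) / x_in` where `x_in` is the mean
#' within-module off-diagonal weight of region i and `x_out` the mean
#' between-module weight; the summary is the mean of `s_i` over regions.
#'
#' @param W symmetric weight matrix or `corr_matrix`.
#' @param partition a [network_partition()] (or label vector).
#' @return list with `per_region` (data frame: region, x_in, x_out, s), and
#'   `mean_segregation`. Regions with `x_in == 0` get `NA` (reported via a
#'   message) and are excluded from the mean.
#' @export
segregation <- function(W, partition) {
  W <- symmetrize(unclass_corr(W), tol = 1e-8, what = "weight matrix")
  diag(W) <- NA
  regions <- rownames(W) %||% as.character(seq_len(nrow(W)))
  labels <- partition_labels(partition, regions)
  same <- outer(labels, labels, "==")
  x_in <- vapply(seq_len(nrow(W)), function(i) {
    mean(W[i, same[i, ] & seq_len(ncol(W)) != i], na.rm = TRUE)
  }, numeric(1))
  x_out <- vapply(seq_len(nrow(W)), function(i) {
    mean(W[i, !same[i, ]], na.rm = TRUE)
  }, numeric(1))
  s <- (x_in - x_out) / x_in
  bad <- !is.na(x_in) & x_in == 0
  if (any(bad)) {
    message("segregation: x_in = 0 for region(s) ",
            paste(regions[bad], collapse = ", "), "; s_i set to NA")
    s[bad] <- NA_real_
  }
  list(per_region = data.frame(region = regions, x_in = x_in, x_out = x_out,
                               s = s, stringsAsFactors = FALSE),
       mean_segregation = mean(s, na.rm = TRUE))
}

#' Principal gradients of a thresholded connectivity matrix
#'
#' Off-diagonal entries below the `(1 - retain_fraction)` quantile of
#' off-diagonal values are set to zero (keeping the strongest — i.e. most
#' positive — `retain_fraction` of connections; `mode = "absolute"`
#' thresholds on magnitude instead), region rows are centred, and the
#' principal components of the resulting region-space covariance are
#' returned. Each component ("gradient") assigns one loading per region.
#'
#' @param W symmetric matrix or `corr_matrix`.
#' @param retain_fraction fraction of off-diagonal connections retained
#'   (default 0.2).
#' @param n_components number of gradients to return (default all with
#'   positive variance, capped at 10).
#' @param mode `"signed"` (default; threshold on signed value) or
#'   `"absolute"`.
#' @return list of class `gradient_result`: `loadings`
#'   (regions x components, orthonormal columns), `variance_explained`
#'   (fractions, non-increasing), `threshold` (the cutoff weight used).
#' @export
principal_gradients <- function(W, retain_fraction = 0.2, n_components = NULL,
                                mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  W <- symmetrize(unclass_corr(W), tol = 1e-8, what = "connectivity matrix")
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  off <- offdiag(W)
  off <- off[!is.na(off)]
  key <- if (mode == "signed") off else abs(off)
  thr <- stats::quantile(key, 1 - retain_fraction, names = FALSE, type = 7)
  Wt <- W
  Wt[is.na(Wt)] <- 0
  keepm <- if (mode == "signed") Wt >= thr else abs(Wt) >= thr
  diag(keepm) <- TRUE # threshold applies to connections, not self-weights
  Wt[!keepm] <- 0
  if (stats::sd(Wt) == 0) stop("thresholded matrix is constant; gradients undefined")
  Xc <- Wt - rowMeans(Wt)
  cv <- tcrossprod(Xc) / (ncol(Wt) - 1)
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  pos <- lam > max(lam) * 1e-12
  k <- min(n_components %||% min(sum(pos), 10L), sum(pos))
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(W)
  colnames(loadings) <- sprintf("G%d", seq_len(k))
  structure(list(loadings = loadings,
                 variance_explained = lam[seq_len(k)] / sum(lam),
                 threshold = thr, retain_fraction = retain_fraction,
                 mode = mode),
            class = "gradient_result")
}

#' Rank-correlate two gradients with a permutation test
#'
#' Spearman rank correlation between two region-wise loading vectors with a
#' label-permutation p-value:
#' `p = (1 + #permuted |rho*| >= |rho|) / (n_perm + 1)`. Because the absolute
#' statistic is used, the p-value is invariant to a global sign flip of
#' either gradient (gradient signs are arbitrary). No spatial-autocorrelation
#' correction is applied, which makes the test anti-conservative for smooth
#' cortical maps.
#'
#' @param a,b numeric vectors of equal length (>= 10).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `rho`, `p`, `n_perm`.
#' @export
compare_gradients <- function(a, b, n_perm = 1000L, seed = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 10)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant gradient vector")
  rho <- stats::cor(a, b, method = "spearman")
  ra <- rank(a)
  rb <- rank(b)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(ra, sample(rb))) >= abs(rho)
    }, logical(1)))
  })
  list(rho = rho, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}
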