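# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream key
#'
#' Every stochastic operation in the package draws its randomness from a
#' sub-seed derived from a master seed and a short string naming the stream
#' (e.g. `"subject:3"`, `"decode:fold:7"`). Adding a new stream therefore
#' never perturbs the randomness of existing ones, and all results stay
#' bit-reproducible under a fixed master seed.
#'
#' @param seed integer master seed.
#' @param key character scalar naming the stream.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483629 # prime < 2^31; products below stay exact in doubles
  h <- (abs(seed) %% m)
  for (b in utf8ToInt(paste(key, collapse = ":"))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h + 1)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Symmetric-matrix square root factor L with L %*% t(L) = sigma, via the
# eigendecomposition so that positive semi-definite (singular) covariances are
# handled. Eigenvalues below -tol * max(|eigenvalue|) are an error; small
# negative values from round-off are clipped to zero.
cov_factor <- function(sigma, tol = 1e-8) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  if (max(abs(sigma - t(sigma))) > 1e-10) {
    stop("covariance matrix is not symmetric")
  }
  e <- eigen(sigma, symmetric = TRUE)
  lam <- e$values
  scale <- max(abs(lam), 1)
  if (min(lam) < -tol * scale) {
    stop(sprintf("covariance matrix is not positive semi-definite (smallest eigenvalue %.6g)",
                 min(lam)))
  }
  lam <- pmax(lam, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

# Deterministic multivariate normal draws: n rows, mean 0, covariance sigma
# (or a pre-computed factor). Uses the current RNG stream.
rmvn <- function(n, sigma = NULL, factor = NULL) {
  if (is.null(factor)) factor <- cov_factor(sigma)
  p <- nrow(factor)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% t(factor)
}

# Check symmetry up to tolerance (NA entries must be symmetric too) and
# force exact symmetry.
symmetrize <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, " must be a square matrix")
  if (!identical(is.na(m), is.na(t(m)))) stop(what, " is not symmetric")
  d <- abs(m - t(m))
  if (any(d[!is.na(d)] > tol)) stop(what, " is not symmetric")
  (m + t(m)) / 2
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
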