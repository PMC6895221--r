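#' Non-negative matrix factorization by KL multiplicative updates
#'
#' Factorizes a non-negative catalog matrix `M ~ W %*% H` by minimizing the
#' generalized Kullback-Leibler divergence (the Poisson-consistent objective
#' for count data) with Lee-Seung multiplicative updates, from a random
#' non-negative initialization. After convergence the columns of `W` are
#' normalized to sum 1, with compensating scaling of the rows of `H`, so that
#' `W` columns are probability vectors over channels and `H` carries the
#' mutation counts.
#'
#' @param M Non-negative matrix (channels x samples).
#' @param k Rank (>= 1). A warning is issued when `k` exceeds the number of
#'   samples.
#' @param n_iter Maximum iterations.
#' @param seed Integer seed for the initialization.
#' @param tol Convergence threshold on the relative objective change.
#' @param warn_rank Warn when `k` exceeds the sample count (internal callers
#'   that already warned once disable this).
#' @return List with `W` (96 x k, column-stochastic), `H` (k x samples),
#'   `objective` (per-recorded-iteration KL divergence), `converged`,
#'   `n_iter_used`.
#' @export
nmf_decompose <- function(M, k, n_iter = 2000L, seed = 1L, tol = 1e-8,
                          warn_rank = TRUE) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("M must be non-negative")
  if (sum(M) == 0) stop("M is all zero; nothing to factorize")
  if (k < 1L) stop("rank k must be >= 1")
  if (warn_rank && k > ncol(M)) {
    warning("rank k exceeds the number of samples; solution is not unique")
  }
  eps <- .Machine$double.eps
  res <- with_seed(seed, {
    n <- nrow(M); m <- ncol(M)
    W <- matrix(runif(n * k, 0.1, 1), n, k)
    # deterministic column-wise H start: the multiplicative updates then
    # treat sample columns exchangeably, so permuting the columns of M
    # permutes the solution exactly
    H <- matrix(rep(colSums(M) / k, each = k), k, m)
    obj <- numeric(0)
    prev <- Inf
    converged <- FALSE
    it <- 0L
    kl <- function(V, WH) {
      pos <- V > 0
      sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
    }
    while (it < n_iter) {
      it <- it + 1L
      WH <- W %*% H + eps
      H <- H * (t(W) %*% (M / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((M / WH) %*% t(H)) / matrix(rowSums(H) + eps, nrow(M), k,
                                            byrow = TRUE)
      if (it %% 10L == 0L || it == n_iter) {
        cur <- kl(M, W %*% H + eps)
        obj <- c(obj, cur)
        if (is.finite(prev) && prev - cur < tol * max(1, abs(prev))) {
          converged <- TRUE
          break
        }
        prev <- cur
      }
    }
    list(W = W, H = H, objective = obj, converged = converged,
         n_iter_used = it)
  })
  scl <- colSums(res$W)
  scl[scl == 0] <- 1
  res$W <- sweep(res$W, 2, scl, "/")
  res$H <- sweep(res$H, 1, scl, "*")
  if (!is.null(rownames(M))) rownames(res$W) <- rownames(M)
  if (!is.null(colnames(M))) colnames(res$H) <- colnames(M)
  res
}

# KL divergence of M from W %*% H (used for reporting)
kl_divergence <- function(M, W, H) {
  WH <- W %*% H + .Machine$double.eps
  pos <- M > 0
  sum(M[pos] * log(M[pos] / WH[pos])) - sum(M) + sum(WH)
}

# Relative Frobenius reconstruction error
frobenius_error <- function(M, W, H) {
  norm(M - W %*% H, "F") / norm(M, "F")
}

# Non-negative least-squares refit of exposures against fixed signatures
refit_exposures <- function(M, W) {
  H <- vapply(seq_len(ncol(M)), function(j) {
    pracma::lsqnonneg(W, M[, j])$x
  }, numeric(ncol(W)))
  H <- matrix(H, nrow = ncol(W))
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(M)
  H
}
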