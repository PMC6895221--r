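#' De novo signature extraction by bootstrapped NMF with stability selection
#'
#' For each candidate rank `k`, each bootstrap replicate resamples every
#' sample column multinomially (n = column total, p = normalized column) and
#' factorizes it by [nmf_decompose()] from a fresh seed. The `n_boot * k`
#' candidate signatures are partitioned into `k` clusters by k-medoids on
#' cosine distance; the renormalized medoids are the consensus signatures and
#' the mean silhouette width of the partition is the stability (for `k = 1`,
#' where silhouettes are undefined, stability is the mean cosine similarity
#' of the candidates to their medoid). Exposures are refit against the
#' consensus signatures on the original matrix by non-negative least squares.
#'
#' Rank selection is stability-first with an error guard: among ranks whose
#' relative Frobenius reconstruction error is within `error_tol` (relative)
#' of the minimum across the scanned ranks, the rank with the highest mean
#' stability is selected; ties go to the smaller rank.
#'
#' @param M 96 x n_samples non-negative count matrix (every column total
#'   must be positive).
#' @param k_range Integer vector of ranks to scan.
#' @param n_boot Bootstrap replicates per rank (>= 2).
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @param n_iter Max NMF iterations per replicate.
#' @param resample Disable (FALSE) to factorize identical replicates — then
#'   stability is exactly 1.
#' @param error_tol Relative tolerance on reconstruction error for rank
#'   eligibility.
#' @return A `signature_set` for the selected rank: `W` (96 x k,
#'   column-stochastic), `H` (k x n refit exposures), `k`, `stability`
#'   (per-signature), `mean_stability`, `reconstruction_error` (list:
#'   frobenius, kl), and `scan` (per-rank data frame with mean stability and
#'   errors), plus `per_k` (the full per-rank results).
#' @export
bootstrap_extract <- function(M, k_range = 1:4, n_boot = 25L, seed = 1L,
                              n_iter = 2000L, resample = TRUE,
                              error_tol = 0.10) {
  M <- as.matrix(M)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  if (any(colSums(M) <= 0)) stop("every sample column must have positive total")
  if (any(k_range > ncol(M))) {
    warning("k_range exceeds the number of samples for some ranks")
  }
  totals <- colSums(M)
  probs <- sweep(M, 2, totals, "/")
  per_k <- list()
  for (k in k_range) {
    cands <- matrix(NA_real_, nrow(M), n_boot * k)
    for (b in seq_len(n_boot)) {
      # with resampling disabled the replicates are meant to be identical,
      # so they share one initialization seed
      bseed <- derive_seed(seed, 1000L * k + if (resample) b else 1L)
      Mb <- if (resample) {
        with_seed(derive_seed(seed, 500000L + 1000L * k + b), {
          vapply(seq_len(ncol(M)), function(j) {
            as.numeric(stats::rmultinom(1, totals[j], probs[, j]))
          }, numeric(nrow(M)))
        })
      } else {
        M
      }
      fit <- nmf_decompose(Mb, k, n_iter = n_iter, seed = bseed,
                           warn_rank = FALSE)
      cands[, (b - 1L) * k + seq_len(k)] <- fit$W
    }
    # cosine distance between candidate signatures
    nc <- ncol(cands)
    norms <- sqrt(colSums(cands^2))
    cosm <- crossprod(cands) / tcrossprod(norms)
    cosm[cosm > 1] <- 1
    D <- stats::as.dist(1 - cosm)
    if (k == 1L) {
      med <- which.min(colSums(as.matrix(D)))
      W <- matrix(cands[, med], ncol = 1)
      stab <- mean(cosm[, med])
      per_sig_stab <- stab
      clustering <- rep(1L, nc)
    } else {
      pm <- cluster::pam(D, k, diss = TRUE)
      W <- cands[, pm$id.med, drop = FALSE]
      sil <- cluster::silhouette(pm$clustering, D)
      widths <- sil[, "sil_width"]
      per_sig_stab <- tapply(widths, pm$clustering, mean)
      stab <- mean(widths)
      clustering <- pm$clustering
    }
    W <- sweep(W, 2, colSums(W), "/")
    rownames(W) <- rownames(M)
    colnames(W) <- sprintf("S%d", seq_len(k))
    H <- refit_exposures(M, W)
    per_k[[as.character(k)]] <- list(
      k = k, W = W, H = H, stability = as.numeric(per_sig_stab),
      mean_stability = stab,
      frobenius = frobenius_error(M, W, H),
      kl = kl_divergence(M, W, H),
      clustering = clustering
    )
  }
  scan <- do.call(rbind, lapply(per_k, function(x) {
    data.frame(k = x$k, mean_stability = x$mean_stability,
               frobenius = x$frobenius, kl = x$kl)
  }))
  rownames(scan) <- NULL
  eligible <- scan$frobenius <= min(scan$frobenius) * (1 + error_tol)
  cand <- scan[eligible, , drop = FALSE]
  sel_k <- cand$k[order(-cand$mean_stability, cand$k)][1]
  best <- per_k[[as.character(sel_k)]]
  structure(list(
    W = best$W, H = best$H, k = sel_k, stability = best$stability,
    mean_stability = best$mean_stability,
    reconstruction_error = list(frobenius = best$frobenius, kl = best$kl),
    scan = scan, per_k = per_k
  ), class = "signature_set")
}

#' @method print signature_set
#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: k = %d (mean stability %.3f)\n",
              x$k, x$mean_stability))
  cat(sprintf("reconstruction error: Frobenius %.4g, KL %.4g\n",
              x$reconstruction_error$frobenius, x$reconstruction_error$kl))
  print(x$scan)
  invisible(x)
}

#' Write extracted signatures (96 x k) as TSV
#' @param sigset A `signature_set` or a 96 x k matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signatures_tsv <- function(sigset, path) {
  W <- if (inherits(sigset, "signature_set")) sigset$W else sigset
  write_catalog_tsv(W, path)
}

#' Write exposures (k x n_samples) as TSV
#' @param sigset A `signature_set` or a k x n matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_exposures_tsv <- function(sigset, path) {
  H <- if (inherits(sigset, "signature_set")) sigset$H else sigset
  df <- data.frame(signature = rownames(H) %||% sprintf("S%d", seq_len(nrow(H))),
                   H, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
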