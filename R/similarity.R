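#' Cosine similarity between two spectra
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return `a . b / (|a| |b|)`; in `[0, 1]` for non-negative inputs.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0)) # 1/sqrt(2)
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Pearson correlation between two spectra
#'
#' @param a,b Numeric vectors of equal length, neither constant.
#' @return Centered correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Pearson correlation undefined for a constant vector")
  }
  cor(a, b)
}

#' Match extracted signatures against a reference signature matrix
#'
#' Computes the full cosine and Pearson similarity matrices between extracted
#' and reference signatures, then assigns a best reference match to each
#' extracted signature by greedy descending cosine with one-to-one
#' assignment. Matches below `floor` are flagged.
#'
#' @param extracted 96 x k matrix (columns = extracted signatures) or a
#'   `signature_set` from [bootstrap_extract()].
#' @param reference 96 x r matrix of reference signatures; columns are
#'   renormalized to sum 1 (with a warning) if needed. When both matrices
#'   carry channel rownames they must agree exactly — a mismatch is an error,
#'   never a silent reordering.
#' @param floor Flag matches whose cosine falls below this value.
#' @return A `similarity_report` list: `cosine` (k x r), `pearson` (k x r),
#'   `best_match` data frame (extracted, reference, cosine, pearson,
#'   below_floor).
#' @export
match_to_reference <- function(extracted, reference, floor = 0.80) {
  W <- if (inherits(extracted, "signature_set")) extracted$W else
    as.matrix(extracted)
  R <- as.matrix(reference)
  if (nrow(W) != nrow(R)) stop("extracted and reference row counts differ")
  if (!is.null(rownames(W)) && !is.null(rownames(R)) &&
      !identical(rownames(W), rownames(R))) {
    stop("channel label order differs between extracted and reference; ",
         "refusing to reorder silently")
  }
  cs <- colSums(R)
  if (any(abs(cs - 1) > 1e-6)) {
    warning("reference columns do not sum to 1; renormalizing")
    R <- sweep(R, 2, cs, "/")
  }
  k <- ncol(W)
  r <- ncol(R)
  if (is.null(colnames(W))) colnames(W) <- sprintf("extracted%d", seq_len(k))
  if (is.null(colnames(R))) colnames(R) <- sprintf("ref%d", seq_len(r))
  cosM <- matrix(0, k, r, dimnames = list(colnames(W), colnames(R)))
  peaM <- cosM
  for (i in seq_len(k)) {
    for (j in seq_len(r)) {
      cosM[i, j] <- cosine_similarity(W[, i], R[, j])
      # a constant (flat) signature has no defined correlation; report NA
      peaM[i, j] <- tryCatch(pearson_similarity(W[, i], R[, j]),
                             error = function(e) NA_real_)
    }
  }
  # greedy one-to-one assignment by descending cosine
  avail_i <- rep(TRUE, k)
  avail_j <- rep(TRUE, r)
  pairs <- list()
  for (step in seq_len(min(k, r))) {
    sub <- cosM
    sub[!avail_i, ] <- -Inf
    sub[, !avail_j] <- -Inf
    best <- arrayInd(which.max(sub), dim(sub))
    i <- best[1]; j <- best[2]
    pairs[[step]] <- data.frame(
      extracted = colnames(W)[i], reference = colnames(R)[j],
      cosine = cosM[i, j], pearson = peaM[i, j],
      below_floor = cosM[i, j] < floor, stringsAsFactors = FALSE
    )
    avail_i[i] <- FALSE
    avail_j[j] <- FALSE
  }
  best_match <- do.call(rbind, pairs)
  best_match <- best_match[order(match(best_match$extracted, colnames(W))), ]
  rownames(best_match) <- NULL
  structure(list(cosine = cosM, pearson = peaM, best_match = best_match,
                 floor = floor),
            class = "similarity_report")
}
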