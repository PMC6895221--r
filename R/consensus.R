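#' Consensus vote across caller call sets
#'
#' Implements m-of-n ensemble calling: a variant (exact chrom/pos/ref/alt
#' identity) reported by at least `min_support` callers is retained as a bona
#' fide somatic candidate; all others are recorded with fate
#' `dropped_low_support`. The default, 2 of 3, is the standard consensus rule
#' for small somatic cohorts. The result is independent of the order in which
#' callers are supplied.
#'
#' @param callsets Named list (caller -> data frame chrom/pos/ref/alt).
#' @param min_support Minimum number of supporting callers (default 2).
#' @return Data frame of consensus variants sorted by (chrom, pos, alt):
#'   chrom, pos, ref, alt, support, callers (comma-joined, sorted), fate
#'   (`kept` or `dropped_low_support`).
#' @export
#' @examples
#' a <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G")
#' consensus_vote(list(x = a, y = a, z = a[0, ]))
consensus_vote <- function(callsets, min_support = 2L) {
  if (length(callsets) < 2L) stop("need at least 2 callers")
  if (min_support > length(callsets)) {
    stop("min_support exceeds the number of callers")
  }
  callers <- sort(names(callsets))
  tagged <- lapply(callers, function(cl) {
    df <- callsets[[cl]]
    if (nrow(df) == 0L) return(NULL)
    df <- df[!duplicated(snv_key(df)), c("chrom", "pos", "ref", "alt"),
             drop = FALSE]
    df$caller <- cl
    df
  })
  all <- do.call(rbind, tagged)
  if (is.null(all) || nrow(all) == 0L) {
    out <- empty_snv()
    out$support <- integer(0)
    out$callers <- character(0)
    out$fate <- character(0)
    return(out)
  }
  key <- snv_key(all)
  sup <- tapply(all$caller, key, function(x) paste(sort(x), collapse = ","))
  first <- !duplicated(key)
  out <- all[first, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$callers <- unname(sup[key[first]])
  out$support <- lengths(strsplit(out$callers, ",", fixed = TRUE))
  out$fate <- ifelse(out$support >= min_support, "kept",
                     "dropped_low_support")
  rownames(out) <- NULL
  sort_snvs(out)
}

#' Germline-panel and shared-across-cohort filtering
#'
#' Applies the two somatic post-filters to a cohort of consensus call sets:
#' any consensus-supported variant whose (chrom, pos, ref, alt) appears in the
#' germline panel is marked `dropped_germline_panel`; any variant
#' consensus-supported in *every* sample of the cohort is marked
#' `dropped_shared_cohort` in all samples (residual germline or artifact).
#' Variants already dropped by the vote are untouched. The panel rule is
#' applied first, so a panel variant shared by the whole cohort is attributed
#' to the panel. Filtering is idempotent.
#'
#' @param cohort Named list (sample -> consensus data frame from
#'   [consensus_vote()]).
#' @param panel Data frame of panel variants (chrom/pos/ref/alt), or `NULL`.
#' @param match_alleles If `FALSE`, panel matching is by (chrom, pos) only.
#' @return List with `cohort` (updated fates) and `ledger` (data frame:
#'   sample, chrom, pos, ref, alt, rule).
#' @export
filter_germline <- function(cohort, panel = NULL, match_alleles = TRUE) {
  if (length(cohort) == 0L) stop("cohort must contain at least one sample")
  panel_keys <- if (is.null(panel) || nrow(panel) == 0L) {
    character(0)
  } else if (match_alleles) {
    snv_key(panel)
  } else {
    paste(panel$chrom, panel$pos, sep = ":")
  }
  kept_keys <- lapply(cohort, function(df) {
    snv_key(df[df$fate %in% c("kept", "dropped_germline_panel",
                              "dropped_shared_cohort"), , drop = FALSE])
  })
  shared <- Reduce(intersect, kept_keys)
  ledger <- list()
  for (s in names(cohort)) {
    df <- cohort[[s]]
    if (nrow(df) == 0L) next
    key <- snv_key(df)
    pkey <- if (match_alleles) key else paste(df$chrom, df$pos, sep = ":")
    eligible <- df$fate %in% c("kept", "dropped_germline_panel",
                               "dropped_shared_cohort")
    in_panel <- eligible & pkey %in% panel_keys
    in_shared <- eligible & !in_panel & key %in% shared
    df$fate[in_panel] <- "dropped_germline_panel"
    df$fate[in_shared] <- "dropped_shared_cohort"
    cohort[[s]] <- df
    rem <- df[in_panel | in_shared, c("chrom", "pos", "ref", "alt"),
              drop = FALSE]
    if (nrow(rem) > 0L) {
      rem$sample <- s
      rem$rule <- ifelse(in_panel[in_panel | in_shared],
                         "germline_panel", "shared_cohort")
      ledger[[s]] <- rem[, c("sample", "chrom", "pos", "ref", "alt", "rule")]
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(sample = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), rule = character(0))
  rownames(ledger) <- NULL
  list(cohort = cohort, ledger = ledger)
}

#' Kept variants of a filtered consensus call set
#' @param consensus Data frame from [consensus_vote()] / [filter_germline()].
#' @return Data frame restricted to fate `kept`.
#' @export
kept_variants <- function(consensus) {
  consensus[consensus$fate == "kept", , drop = FALSE]
}

#' Write a consensus call set as a VCF with SUPPORT/CALLERS INFO tags
#' @param consensus Consensus data frame (kept variants are written).
#' @param path Output VCF.
#' @param sample Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path, sample = "sample") {
  kept <- kept_variants(consensus)
  names(kept)[names(kept) == "support"] <- "support"
  write_snv_vcf(kept, path, source = paste0("sigcarcin consensus ", sample),
                info_cols = c(SUPPORT = "support", CALLERS = "callers"))
}
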