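#' Write an SNV table as a minimal VCF 4.2 file
#'
#' @param snvs Data frame with chrom/pos/ref/alt (extra columns ignored
#'   unless named in `info_cols`).
#' @param path Output file.
#' @param source Value for the `##source` header line (e.g. caller name).
#' @param info_cols Optional named character vector mapping INFO keys to
#'   column names of `snvs` (e.g. `c(SUPPORT = "support")`).
#' @param contigs Optional named integer vector of contig lengths for
#'   `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, source = "sigcarcin",
                          info_cols = NULL, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2", paste0("##source=", source))
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(snvs) > 0L) {
    snvs <- sort_snvs(snvs)
    info <- rep(".", nrow(snvs))
    if (!is.null(info_cols)) {
      parts <- vapply(seq_along(info_cols), function(k) {
        paste0(names(info_cols)[k], "=", snvs[[info_cols[k]]])
      }, character(nrow(snvs)))
      parts <- matrix(parts, nrow = nrow(snvs))
      info <- apply(parts, 1, paste, collapse = ";")
    }
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    snvs$chrom, snvs$pos, snvs$ref, snvs$alt, info)
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a caller VCF into an SNV set with a skip report
#'
#' Multiallelic records are split into one candidate per ALT allele. Indels,
#' MNVs, symbolic alleles (`<DEL>` etc.), spanning deletions (`*`) and
#' breakends are skipped and counted by category. Records whose FILTER column
#' is anything other than `PASS` or `.` are skipped (override with
#' `keep_nonpass = TRUE`). Duplicate (chrom, pos, ref, alt) records collapse
#' to one.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param caller Caller name; defaults to the `##source` header when present.
#' @param keep_nonpass Keep records failing the caller's own FILTER.
#' @return List with `snvs` (data frame chrom/pos/ref/alt), `caller`, and
#'   `skips` (named integer counts: nonpass, indel, mnv, symbolic, duplicate).
#' @export
read_caller_vcf <- function(path, caller = NULL, keep_nonpass = FALSE) {
  if (!file.exists(path)) stop(sprintf("VCF file not found: %s", path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  stop(sprintf("failed to parse VCF '%s': %s",
                               path, conditionMessage(e)))
                })
  if (is.null(caller)) {
    src <- grep("^##source=", v@meta, value = TRUE)
    caller <- if (length(src)) sub("^##source=", "", src[1]) else "unknown"
  }
  skips <- c(nonpass = 0L, indel = 0L, mnv = 0L, symbolic = 0L,
             duplicate = 0L)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) {
    # single-record VCFs come back as a bare named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0L) {
    return(list(snvs = empty_snv(), caller = caller, skips = skips))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  filt <- fix$FILTER
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  if (!keep_nonpass) {
    skips["nonpass"] <- sum(!pass)
    fix <- fix[pass, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (alt %in% c("*", ".") || grepl("[<>\\[\\]]", alt)) {
        skips["symbolic"] <- skips["symbolic"] + 1L
        next
      }
      if (nchar(ref) != nchar(alt)) {
        skips["indel"] <- skips["indel"] + 1L
        next
      }
      if (nchar(ref) > 1L) {
        # trim shared leading/trailing context; only true SNVs survive
        norm <- normalize_mnv(ref, alt, as.integer(fix$POS[i]))
        if (is.null(norm)) {
          skips["mnv"] <- skips["mnv"] + 1L
          next
        }
        rows[[length(rows) + 1L]] <- list(chrom = fix$CHROM[i],
                                          pos = norm$pos, ref = norm$ref,
                                          alt = norm$alt)
        next
      }
      if (!ref %in% BASES || !alt %in% BASES) {
        skips["symbolic"] <- skips["symbolic"] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- list(chrom = fix$CHROM[i],
                                        pos = as.integer(fix$POS[i]),
                                        ref = ref, alt = alt)
    }
  }
  if (length(rows) == 0L) {
    return(list(snvs = empty_snv(), caller = caller, skips = skips))
  }
  snvs <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(snv_key(snvs))
  skips["duplicate"] <- sum(dup)
  list(snvs = sort_snvs(snvs[!dup, , drop = FALSE]), caller = caller,
       skips = skips)
}

# Equal-length REF/ALT: strip matching flanks; if exactly one base differs it
# is an SNV in disguise, otherwise a true MNV (skipped by the reader).
normalize_mnv <- function(ref, alt, pos) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  diff <- which(r != a)
  if (length(diff) == 1L && r[diff] %in% BASES && a[diff] %in% BASES) {
    list(pos = pos + diff - 1L, ref = r[diff], alt = a[diff])
  } else {
    NULL
  }
}

#' Read a germline panel VCF
#'
#' @param path Panel VCF; only SNV records are used.
#' @return Data frame with chrom/pos/ref/alt (unique entries).
#' @export
read_panel_vcf <- function(path) {
  res <- read_caller_vcf(path, caller = "panel", keep_nonpass = TRUE)
  res$snvs
}
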