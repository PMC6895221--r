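#' Build an SBS-96 mutation catalog
#'
#' Classifies each SNV by its pyrimidine-normalized trinucleotide context and
#' tallies counts over the 96 channels in the fixed order of
#' [sbs96_channels()]. Variants whose context contains a non-ACGT base (or
#' that sit at a contig edge) are counted as unclassified. A reference
#' mismatch between the variant and the genome is an error — it signals an
#' upstream coordinate bug, not data to be silently dropped.
#'
#' @param snvs Data frame with chrom/pos/ref/alt.
#' @param genome A [Biostrings::DNAStringSet].
#' @param sample Sample name attached to the catalog.
#' @return A `catalog96` list: `sample`, `counts` (named 96-vector),
#'   `n_unclassified`.
#' @export
build_catalog <- function(snvs, genome, sample = "sample") {
  counts <- setNames(integer(96), sbs96_channels())
  if (nrow(snvs) == 0L) {
    return(structure(list(sample = sample, counts = counts,
                          n_unclassified = 0L), class = "catalog96"))
  }
  cls <- classify_snvs(snvs, genome)
  tab <- table(factor(cls$channel, levels = seq_len(96)))
  counts[] <- as.integer(tab)
  structure(list(sample = sample, counts = counts,
                 n_unclassified = sum(is.na(cls$channel))),
            class = "catalog96")
}

#' Pool per-sample catalogs into one (a cohort compilation)
#' @param ... `catalog96` objects (or a single list of them).
#' @param sample Name for the pooled catalog.
#' @return A `catalog96` with summed counts.
#' @export
pool_catalogs <- function(..., sample = "pooled") {
  cats <- list(...)
  if (length(cats) == 1L && !inherits(cats[[1]], "catalog96")) {
    cats <- cats[[1]]
  }
  counts <- Reduce(`+`, lapply(cats, `[[`, "counts"))
  structure(list(sample = sample, counts = counts,
                 n_unclassified = sum(vapply(cats, `[[`, integer(1),
                                             "n_unclassified"))),
            class = "catalog96")
}

#' Assemble per-sample catalogs into a 96 x n matrix
#' @param catalogs List of `catalog96` objects.
#' @return Integer matrix, rownames = channel labels, colnames = samples.
#' @export
catalog_matrix <- function(catalogs) {
  M <- vapply(catalogs, function(x) as.integer(x$counts), integer(96))
  rownames(M) <- sbs96_channels()
  colnames(M) <- vapply(catalogs, `[[`, character(1), "sample")
  M
}

# gene footprint GRanges (full span, introns included) from an annotation
gene_footprint <- function(annotation) {
  if (length(annotation) == 0L) return(annotation)
  annotation[annotation$type == "gene"]
}

#' Assign transcriptional strand labels to SNVs
#'
#' Each variant is located against the full gene footprints (introns
#' included). Outside every gene it is `intergenic`; covered by genes on both
#' strands it is `bidirectional` (ambiguous template, excluded from strand
#' counts). Otherwise the label says where the *pyrimidine* of the mutated
#' pair sits: `U` (untranscribed) when it lies on the gene's coding strand,
#' `T` (transcribed) when it lies on the template strand. Concretely, for a
#' `+` gene an unflipped (pyrimidine-reference) variant is `U` and a flipped
#' one is `T`; mirrored for `-` genes.
#'
#' @param snvs Data frame with chrom/pos/ref/alt.
#' @param annotation GRanges with gene features (strand-aware).
#' @param genome Genome, used for pyrimidine normalization.
#' @return Character vector of labels: `"U"`, `"T"`, `"bidirectional"`,
#'   `"intergenic"`.
#' @export
assign_strand <- function(snvs, annotation, genome) {
  n <- nrow(snvs)
  if (n == 0L) return(character(0))
  genes <- gene_footprint(annotation)
  labels <- rep("intergenic", n)
  if (length(genes) > 0L) {
    gr <- GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos,
                                                              snvs$pos))
    hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    strands <- as.character(GenomicRanges::strand(genes))[
      S4Vectors::subjectHits(hits)]
    gstrand <- tapply(strands, qh, function(x) {
      u <- unique(x)
      if (length(u) == 1L) u else "B"
    })
    flipped <- classify_snvs(snvs, genome)$flipped
    idx <- as.integer(names(gstrand))
    for (k in seq_along(idx)) {
      i <- idx[k]
      gs <- gstrand[[k]]
      if (gs == "B") {
        labels[i] <- "bidirectional"
      } else if (is.na(flipped[i])) {
        labels[i] <- "intergenic"  # unclassifiable context
      } else {
        pyr_strand <- if (flipped[i]) "-" else "+"
        labels[i] <- if (pyr_strand == gs) "U" else "T"
      }
    }
  }
  labels
}

#' Build a transcriptional-strand-resolved SBS-192 catalog
#'
#' Counts each classified SNV in one of 96 x \{T, U\} cells; intergenic and
#' bidirectionally transcribed variants are tallied separately and excluded
#' from the 192 cells. Conservation: the 192-cell sum plus `n_intergenic`
#' plus `n_bidirectional` equals the number of classified SNVs.
#'
#' @inheritParams assign_strand
#' @param sample Sample name.
#' @return A `catalog192` list: `sample`, `counts` (96 x 2 matrix, columns
#'   `T` and `U`), `n_intergenic`, `n_bidirectional`, `n_unclassified`.
#' @export
build_stranded_catalog <- function(snvs, genome, annotation,
                                   sample = "sample") {
  counts <- matrix(0L, nrow = 96, ncol = 2,
                   dimnames = list(sbs96_channels(), c("T", "U")))
  if (nrow(snvs) == 0L) {
    return(structure(list(sample = sample, counts = counts,
                          n_intergenic = 0L, n_bidirectional = 0L,
                          n_unclassified = 0L), class = "catalog192"))
  }
  cls <- classify_snvs(snvs, genome)
  lab <- assign_strand(snvs, annotation, genome)
  ok <- !is.na(cls$channel)
  strand_ok <- ok & lab %in% c("T", "U")
  for (i in which(strand_ok)) {
    counts[cls$channel[i], lab[i]] <- counts[cls$channel[i], lab[i]] + 1L
  }
  structure(list(sample = sample, counts = counts,
                 n_intergenic = sum(ok & lab == "intergenic"),
                 n_bidirectional = sum(ok & lab == "bidirectional"),
                 n_unclassified = sum(!ok)),
            class = "catalog192")
}

#' Fraction of substitutions in translated (CDS) regions
#'
#' "Translated" means overlapping any CDS interval of the annotation;
#' everything else (UTR, intron, intergenic) is untranslated. An alternative
#' exonic reading is available via `mode = "exon"`, which uses `exon`
#' features when present and falls back to CDS otherwise.
#'
#' @param snvs Data frame with chrom/pos.
#' @param annotation GRanges containing CDS (and optionally exon) features.
#' @param sample Sample name.
#' @param mode `"cds"` (default) or `"exon"`.
#' @return A `region_report` list: `sample`, `n_translated`,
#'   `n_untranslated`, `fraction_translated`.
#' @export
region_fractions <- function(snvs, annotation, sample = "sample",
                             mode = c("cds", "exon")) {
  mode <- match.arg(mode)
  feat_type <- if (mode == "exon" &&
                   any(annotation$type == "exon")) "exon" else "CDS"
  feats <- annotation[annotation$type == feat_type]
  n <- nrow(snvs)
  if (n == 0L) {
    return(structure(list(sample = sample, n_translated = 0L,
                          n_untranslated = 0L, fraction_translated = NA_real_),
                     class = "region_report"))
  }
  n_tr <- 0L
  if (length(feats) > 0L) {
    gr <- GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos,
                                                              snvs$pos))
    n_tr <- sum(GenomicRanges::countOverlaps(gr, feats,
                                             ignore.strand = TRUE) > 0L)
  }
  structure(list(sample = sample, n_translated = n_tr,
                 n_untranslated = n - n_tr,
                 fraction_translated = n_tr / n),
            class = "region_report")
}

#' Exact binomial strand-bias test per substitution class
#'
#' For each of the six pyrimidine substitution classes, tests whether
#' untranscribed-strand counts deviate from parity with transcribed-strand
#' counts: a two-sided exact binomial test of `n_untranscribed` successes in
#' `n_untranscribed + n_transcribed` trials at p0 = 0.5. Classes with zero
#' total report p = 1 and an undefined ratio. No trinucleotide-opportunity
#' correction is applied by default; pass per-class `p0` to correct.
#'
#' @param catalog A `catalog192` from [build_stranded_catalog()].
#' @param p0 Null proportion of untranscribed counts (scalar or named
#'   per-class vector), default 0.5.
#' @return Data frame with substitution_class, n_transcribed,
#'   n_untranscribed, ratio (U/T; `NA` when T = 0), p_value.
#' @export
strand_bias_test <- function(catalog, p0 = 0.5) {
  cls <- substr(sbs96_channels(), 3, 5)
  res <- lapply(SUB_CLASSES, function(sc) {
    rows <- cls == sc
    nT <- sum(catalog$counts[rows, "T"])
    nU <- sum(catalog$counts[rows, "U"])
    null_p <- if (length(p0) > 1L) p0[[sc]] else p0
    p <- if (nT + nU == 0L) 1.0 else
      binom.test(nU, nT + nU, p = null_p, alternative = "two.sided")$p.value
    data.frame(substitution_class = sc, n_transcribed = nT,
               n_untranscribed = nU,
               ratio = if (nT > 0L) nU / nT else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a catalog matrix as TSV (channels x samples)
#' @param M Matrix with channel-label rownames (96 or 192 rows).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(M, path) {
  df <- data.frame(channel = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalog (or reference-signature) TSV
#'
#' Expects a `channel` first column with labels in the fixed SBS-96 (or
#' SBS-192) order; a mismatch in labels or order is an error, never a silent
#' reordering.
#'
#' @param path TSV written by [write_catalog_tsv()] or compatible.
#' @return Numeric matrix with channel rownames.
#' @export
read_catalog_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- df[[1]]
  expected <- if (length(labs) == 192L) sbs192_channels() else sbs96_channels()
  if (!identical(labs, expected)) {
    stop("channel labels/order do not match the fixed catalog order")
  }
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- labs
  M
}
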