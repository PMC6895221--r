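#' @importFrom stats runif rbinom setNames binom.test cor
#' @importFrom utils write.table read.delim packageVersion
NULL

BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' SBS-96 channel labels in the fixed catalog order
#'
#' Channels are ordered by substitution class (`C>A`, `C>G`, `C>T`, `T>A`,
#' `T>C`, `T>G`), then by the 5' flanking base (A, C, G, T), then by the 3'
#' flanking base (A, C, G, T), so that channel `i` (1-based) corresponds to
#' `class * 16 + idx5 * 4 + idx3` (0-based). Labels follow the conventional
#' `A[C>A]A` form.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' sbs96_channels()[1:4]
sbs96_channels <- function() {
  labs <- character(96)
  i <- 1L
  for (cls in SUB_CLASSES) {
    ref <- substr(cls, 1, 1)
    for (b5 in BASES) {
      for (b3 in BASES) {
        labs[i] <- paste0(b5, "[", cls, "]", b3)
        i <- i + 1L
      }
    }
  }
  labs
}

#' SBS-192 channel labels (transcribed/untranscribed prefixed)
#'
#' The 96 channels of [sbs96_channels()] each split into a `T:` (transcribed,
#' template strand) and `U:` (untranscribed, coding strand) cell. Order is all
#' `T:` channels followed by all `U:` channels, each block in SBS-96 order.
#'
#' @return Character vector of length 192.
#' @export
sbs192_channels <- function() {
  c(paste0("T:", sbs96_channels()), paste0("U:", sbs96_channels()))
}

revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Classify a substitution into its SBS-96 channel
#'
#' Applies pyrimidine normalization: when the reference base is a purine the
#' trinucleotide context is reverse-complemented and ref/alt complemented, so
#' that every substitution is expressed with a C or T reference. The channel
#' index follows the fixed order documented in [sbs96_channels()].
#'
#' @param context 3-mer reference context centered on the mutated base
#'   (plus strand).
#' @param ref,alt Single reference / alternate bases.
#' @return A list with `channel` (1-based index into the 96 channels, or `NA`
#'   when any base is not A/C/G/T), `label` (e.g. `"A[C>A]A"`), and `flipped`
#'   (`TRUE` when pyrimidine normalization reverse-complemented the context).
#' @export
#' @examples
#' classify_channel("ACA", "C", "A") # channel 1
#' classify_channel("TAC", "A", "G") # purine ref, flipped
classify_channel <- function(context, ref, alt) {
  if (nchar(context) != 3L) stop("context must be a 3-mer")
  if (ref == alt) stop("ref and alt must differ")
  bad <- !all(strsplit(paste0(context, ref, alt), "")[[1]] %in% BASES)
  if (bad) {
    return(list(channel = NA_integer_, label = NA_character_, flipped = NA))
  }
  if (substr(context, 2, 2) != ref) {
    stop(sprintf(
      "context '%s' center does not match ref '%s' (upstream coordinate bug?)",
      context, ref
    ))
  }
  flipped <- ref %in% c("A", "G")
  if (flipped) {
    context <- revcomp(context)
    ref <- unname(COMPLEMENT[ref])
    alt <- unname(COMPLEMENT[alt])
  }
  cls <- match(paste0(ref, ">", alt), SUB_CLASSES) - 1L
  i5 <- match(substr(context, 1, 1), BASES) - 1L
  i3 <- match(substr(context, 3, 3), BASES) - 1L
  ch <- cls * 16L + i5 * 4L + i3 + 1L
  list(channel = ch, label = sbs96_channels()[ch], flipped = flipped)
}

#' Extract the trinucleotide context around a position
#'
#' Returns the plus-strand reference 3-mer centered at `pos` (1-based). At
#' contig edges (no flanking base on one side) the sentinel `"NNN"` is
#' returned; callers count such positions as unclassified.
#'
#' @param genome A [Biostrings::DNAStringSet] (named contigs).
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @return Uppercase 3-mer, or `"NNN"` at an edge.
#' @export
trinuc_context <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("unknown contig '%s'", chrom))
  }
  len <- Biostrings::width(genome[chrom])
  if (pos < 2L || pos > len - 1L) {
    return("NNN")
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], pos - 1L, pos + 1L)))
}

# Vectorized channel classification for a variant table; returns integer
# channel (NA = unclassifiable) and flipped flag. Stops on ref mismatch.
classify_snvs <- function(snvs, genome) {
  n <- nrow(snvs)
  channel <- rep(NA_integer_, n)
  flipped <- rep(NA, n)
  labs <- rep(NA_character_, n)
  seqs <- lapply(setNames(names(genome), names(genome)), function(ct) {
    toupper(as.character(genome[[ct]]))
  })
  lens <- vapply(seqs, nchar, integer(1))
  bad_ct <- setdiff(unique(snvs$chrom), names(genome))
  if (length(bad_ct)) stop("unknown contig(s): ", paste(bad_ct, collapse = ", "))
  chrseq <- unlist(seqs[snvs$chrom], use.names = FALSE)
  interior <- snvs$pos >= 2L & snvs$pos <= lens[snvs$chrom] - 1L
  ctx <- rep("NNN", n)
  ctx[interior] <- substr(chrseq[interior], snvs$pos[interior] - 1L,
                          snvs$pos[interior] + 1L)
  b5 <- substr(ctx, 1, 1); bc <- substr(ctx, 2, 2); b3 <- substr(ctx, 3, 3)
  ok <- interior & b5 %in% BASES & bc %in% BASES & b3 %in% BASES &
    snvs$alt %in% BASES
  mismatch <- ok & bc != snvs$ref
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop(sprintf(
      "reference mismatch at %s:%d — genome has '%s', variant ref is '%s'",
      snvs$chrom[i], snvs$pos[i], bc[i], snvs$ref[i]
    ))
  }
  flp <- snvs$ref %in% c("A", "G")
  p5 <- ifelse(flp, COMPLEMENT[b3], b5)
  p3 <- ifelse(flp, COMPLEMENT[b5], b3)
  pref <- ifelse(flp, COMPLEMENT[snvs$ref], snvs$ref)
  palt <- ifelse(flp, COMPLEMENT[snvs$alt], snvs$alt)
  cls <- match(paste0(pref, ">", palt), SUB_CLASSES) - 1L
  ch <- cls * 16L + (match(p5, BASES) - 1L) * 4L + match(p3, BASES)
  channel[ok] <- ch[ok]
  flipped[ok] <- flp[ok]
  labs[ok] <- sbs96_channels()[ch[ok]]
  data.frame(channel = channel, flipped = flipped, label = labs,
             stringsAsFactors = FALSE)
}
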