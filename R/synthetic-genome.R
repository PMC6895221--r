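#' Generate a random single-contig reference genome
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc_fraction`/2 and
#' P(A) = P(T) = (1 - `gc_fraction`)/2. Deterministic under `seed`.
#'
#' @param length Genome length in bases (>= 1000).
#' @param gc_fraction Target GC proportion, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param contig Contig name.
#' @return A named [Biostrings::DNAStringSet] with one contig.
#' @export
#' @examples
#' g <- gen_genome(10000, 0.5, seed = 1)
#' Biostrings::width(g)
gen_genome <- function(length, gc_fraction, seed, contig = "chrS") {
  if (length < 1000) stop("genome length must be >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must be strictly between 0 and 1")
  }
  seq <- with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- contig
  genome
}

#' Write a genome to FASTA (60-column wrapped)
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Generate non-overlapping gene models with CDS sub-intervals
#'
#' Places `n_genes` mutually disjoint genes on the genome, each assigned a
#' `+`/`-` strand with probability 0.5. Gene lengths are drawn around
#' `gene_length_mean` (uniform on 0.5x--1.5x). Each gene carries one CDS
#' strictly inside its span, so every gene has untranslated flanks; the CDS
#' covers roughly the central half of the gene.
#'
#' @param genome A [Biostrings::DNAStringSet] (first contig is used).
#' @param n_genes Number of genes (>= 0).
#' @param gene_length_mean Mean gene length in bases.
#' @param seed Integer seed.
#' @param max_tries Placement retries before giving up.
#' @return A [GenomicRanges::GRanges] with `type` (`gene`/`CDS`), `gene_id`
#'   and `source` columns; 1-based inclusive coordinates.
#' @export
gen_annotation <- function(genome, n_genes, gene_length_mean = 1000, seed = 1,
                           max_tries = 1000L) {
  contig <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  if (n_genes == 0L) {
    return(GenomicRanges::GRanges(
      seqnames = character(0), ranges = IRanges::IRanges(),
      strand = character(0), type = character(0), gene_id = character(0),
      source = character(0)
    ))
  }
  with_seed(seed, {
    placed <- IRanges::IRanges()
    starts <- integer(0)
    ends <- integer(0)
    strands <- character(0)
    for (i in seq_len(n_genes)) {
      len <- max(30L, round(runif(1, 0.5, 1.5) * gene_length_mean))
      if (len >= glen - 2L) stop("gene longer than genome")
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        st <- sample.int(glen - len, 1L)
        cand <- IRanges::IRanges(st, st + len - 1L)
        if (length(placed) == 0L ||
            sum(IRanges::countOverlaps(cand, placed)) == 0L) {
          placed <- c(placed, cand)
          starts <- c(starts, st)
          ends <- c(ends, st + len - 1L)
          strands <- c(strands, sample(c("+", "-"), 1L))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not place gene %d without overlap after %d tries",
                     i, max_tries))
      }
    }
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    # CDS: central half of the gene, strictly inside the span
    lens <- ends - starts + 1L
    cds_start <- starts + pmax(1L, lens %/% 4L)
    cds_end <- ends - pmax(1L, lens %/% 4L)
    genes <- GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends),
                                    strand = strands, type = "gene",
                                    gene_id = gene_ids, source = "sim")
    cds <- GenomicRanges::GRanges(contig, IRanges::IRanges(cds_start, cds_end),
                                  strand = strands, type = "CDS",
                                  gene_id = gene_ids, source = "sim")
    ann <- c(genes, cds)
    ann[order(GenomicRanges::start(ann), ann$type)]
  })
}

#' Write annotation to GTF
#' @param annotation GRanges as produced by [gen_annotation()].
#' @param path Output GTF file.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  # synthetic CDS carry no phase; rtracklayer warns about the omission
  suppressWarnings(rtracklayer::export(annotation, path, format = "gtf"))
  invisible(path)
}

#' Read a GTF/GFF3 annotation
#' @param path GTF or GFF3 file.
#' @return GRanges with at least `type` and `gene_id` columns.
#' @export
read_annotation <- function(path) {
  rtracklayer::import(path)
}

#' Generate a germline variant panel
#'
#' Draws `n` distinct SNVs at random genomic positions (away from contig
#' edges), avoiding any position listed in `avoid_pos`; used both to inject
#' germline contamination into simulated call sets and to supply decoy panel
#' entries that match nothing.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param n Number of panel variants (>= 0).
#' @param seed Integer seed.
#' @param avoid_pos Integer positions that must not be used (e.g. truth
#'   mutation sites, to keep panel and somatic truth disjoint).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
gen_germline_panel <- function(genome, n, seed, avoid_pos = integer(0)) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0L) return(empty_snv())
  contig <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  with_seed(seed, {
    pool <- setdiff(2:(glen - 1L), avoid_pos)
    if (length(pool) < n) stop("not enough positions for germline panel")
    pos <- sort(sample(pool, n))
    ref <- vapply(pos, function(p) {
      toupper(as.character(Biostrings::subseq(genome[[contig]], p, p)))
    }, character(1))
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    data.frame(chrom = contig, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
  })
}
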