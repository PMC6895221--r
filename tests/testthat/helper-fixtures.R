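# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny deterministic genome whose sequence we can reason about by hand.
tiny_genome <- function(seq = "ACGTACGTACGTACGTACGT", contig = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- contig
  g
}

# Write a VCF from raw lines (header + records supplied as strings).
write_vcf_lines <- function(records, path = tempfile(fileext = ".vcf"),
                            source = "testcaller") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records
  ), path)
  path
}

snv_df <- function(pos, ref, alt, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length.out = length(pos)),
             pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Independent brute-force SBS-96 classifier used as the oracle: builds the
# channel label by direct string construction and looks it up in an
# independently-constructed label table (no calls into classify_channel).
oracle_classify <- function(context, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  if (ref %in% c("A", "G")) {
    context <- rc(context)
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  label <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                  substr(context, 3, 3))
  labels <- unlist(lapply(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
                          function(cl) {
    unlist(lapply(c("A", "C", "G", "T"), function(a) {
      vapply(c("A", "C", "G", "T"),
             function(b) paste0(a, "[", cl, "]", b), character(1))
    }))
  }))
  match(label, labels)
}

# Small but non-trivial cohort used across consensus/filter tests.
small_cohort_config <- function(seed = 7L) {
  simulation_config(
    genome_length = 30000, n_genes = 15, gene_length_mean = 600,
    n_samples = 3, n_mutations_per_sample = 300,
    n_false_positives_per_caller = 30, n_germline = 20, n_panel_decoys = 10,
    seed = seed
  )
}
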