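test_that("catalog of empty input is the zero vector", {
  g <- tiny_genome()
  cat0 <- build_catalog(snv_df(integer(0), character(0), character(0)), g)
  expect_identical(sum(cat0$counts), 0L)
  expect_identical(cat0$n_unclassified, 0L)
})

test_that("catalogs are additive and order-invariant", {
  set.seed(31)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  g <- tiny_genome(seq)
  pos <- sample(2:4999, 200)
  ref <- vapply(pos, function(p) substr(seq, p, p), character(1))
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  snvs <- snv_df(pos, ref, alt)
  A <- snvs[1:120, ]; B <- snvs[121:200, ]
  cA <- build_catalog(A, g); cB <- build_catalog(B, g)
  cAB <- build_catalog(snvs, g)
  expect_identical(cA$counts + cB$counts, cAB$counts)
  shuffled <- build_catalog(snvs[sample(nrow(snvs)), ], g)
  expect_identical(shuffled$counts, cAB$counts)
  pooled <- pool_catalogs(cA, cB)
  expect_identical(pooled$counts, cAB$counts)
})

test_that("catalog equals the truth channel histogram on a synthetic cohort", {
  cfg <- small_cohort_config()
  genome <- gen_genome(cfg$genome_length, cfg$gc_fraction, seed = 1)
  ann <- gen_annotation(genome, cfg$n_genes, cfg$gene_length_mean, seed = 2)
  truth <- sample_mutations(cfg, genome, ann)
  for (s in truth$samples) {
    mut <- truth$mutations[truth$mutations$sample == s, ]
    cat <- build_catalog(mut, genome, sample = s)
    expect_identical(as.integer(cat$counts), tabulate(mut$channel, 96))
    expect_identical(sum(cat$counts) + cat$n_unclassified, nrow(mut))
  }
})

test_that("a reference mismatch raises an integrity error", {
  g <- tiny_genome("AACCCGGTTTAACCGGTTAA")
  expect_error(build_catalog(snv_df(5, "T", "A"), g), "reference mismatch")
})

test_that("strand labels follow the pyrimidine convention", {
  # genome: position 5 is C (pyrimidine on +), position 10 is G (flipped)
  g <- tiny_genome("AAAACAAAAGAAAA")
  plus_gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 13),
                                      strand = "+", type = "gene",
                                      gene_id = "g1", source = "t")
  labs <- assign_strand(snv_df(c(5, 10), c("C", "G"), c("T", "A")),
                        plus_gene, g)
  expect_identical(labs, c("U", "T"))
  minus_gene <- plus_gene
  GenomicRanges::strand(minus_gene) <- "-"
  labs2 <- assign_strand(snv_df(c(5, 10), c("C", "G"), c("T", "A")),
                         minus_gene, g)
  expect_identical(labs2, c("T", "U"))
  # outside any gene, and across opposite-strand overlap
  expect_identical(assign_strand(snv_df(5, "C", "T"),
                                 plus_gene[0], g), "intergenic")
  both <- c(plus_gene, minus_gene)
  expect_identical(assign_strand(snv_df(5, "C", "T"), both, g),
                   "bidirectional")
})

test_that("strand labels equal explicit strand arithmetic on random variants", {
  cfg <- small_cohort_config(seed = 17L)
  genome <- gen_genome(cfg$genome_length, cfg$gc_fraction, seed = 1)
  ann <- gen_annotation(genome, cfg$n_genes, cfg$gene_length_mean, seed = 2)
  truth <- sample_mutations(cfg, genome, ann)
  mut <- truth$mutations[truth$mutations$sample == "sample1", ]
  got <- assign_strand(mut, ann, genome)
  # independent oracle: locate gene by linear scan, compare pyrimidine strand
  genes <- ann[ann$type == "gene"]
  st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
  gs <- as.character(GenomicRanges::strand(genes))
  oracle <- vapply(seq_len(nrow(mut)), function(i) {
    hit <- which(mut$pos[i] >= st & mut$pos[i] <= en)
    if (length(hit) == 0) return("intergenic")
    if (length(unique(gs[hit])) > 1) return("bidirectional")
    pyr <- if (mut$ref[i] %in% c("C", "T")) "+" else "-"
    if (pyr == gs[hit[1]]) "U" else "T"
  }, character(1))
  expect_identical(got, oracle)
  # and both agree with the generator's own labels
  expect_identical(got, mut$strand_label)
})

test_that("stranded catalog conserves counts and empties without genes", {
  cfg <- small_cohort_config(seed = 19L)
  genome <- gen_genome(cfg$genome_length, cfg$gc_fraction, seed = 1)
  ann <- gen_annotation(genome, cfg$n_genes, cfg$gene_length_mean, seed = 2)
  truth <- sample_mutations(cfg, genome, ann)
  mut <- truth$mutations[truth$mutations$sample == "sample1", ]
  sc <- build_stranded_catalog(mut, genome, ann)
  n_classified <- nrow(mut) - sc$n_unclassified
  expect_identical(sum(sc$counts) + sc$n_intergenic + sc$n_bidirectional,
                   n_classified)
  empty_ann <- ann[0]
  sc0 <- build_stranded_catalog(mut, genome, empty_ann)
  expect_identical(sum(sc0$counts), 0L)
  expect_identical(sc0$n_intergenic, n_classified)
})

test_that("reverse-complementing the world swaps T and U exactly", {
  cfg <- small_cohort_config(seed = 23L)
  genome <- gen_genome(cfg$genome_length, cfg$gc_fraction, seed = 1)
  ann <- gen_annotation(genome, cfg$n_genes, cfg$gene_length_mean, seed = 2)
  truth <- sample_mutations(cfg, genome, ann)
  mut <- truth$mutations[truth$mutations$sample == "sample1", ]
  sc <- build_stranded_catalog(mut, genome, ann)
  cat96 <- build_catalog(mut, genome)

  glen <- Biostrings::width(genome)[1]
  rc_genome <- Biostrings::reverseComplement(genome)
  names(rc_genome) <- names(genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_mut <- mut
  rc_mut$pos <- glen - mut$pos + 1L
  rc_mut$ref <- unname(comp[mut$ref])
  rc_mut$alt <- unname(comp[mut$alt])
  rc_ann <- ann
  rng <- IRanges::IRanges(glen - GenomicRanges::end(ann) + 1L,
                          glen - GenomicRanges::start(ann) + 1L)
  rc_ann <- GenomicRanges::GRanges(GenomicRanges::seqnames(ann), rng,
                                   strand = ifelse(
                                     as.character(GenomicRanges::strand(ann))
                                     == "+", "-", "+"),
                                   type = ann$type, gene_id = ann$gene_id,
                                   source = ann$source)
  rc_sc <- build_stranded_catalog(rc_mut, rc_genome, rc_ann)
  rc_cat96 <- build_catalog(rc_mut, rc_genome)
  expect_identical(rc_cat96$counts, cat96$counts)
  expect_identical(rc_sc$counts[, "T"], sc$counts[, "T"])
  expect_identical(rc_sc$counts[, "U"], sc$counts[, "U"])
})

test_that("region fractions match an interval-membership oracle", {
  g <- tiny_genome(paste(rep("ACGT", 500), collapse = ""))
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 400),
                                                         c(199, 499)),
                                strand = "+", type = "CDS",
                                gene_id = c("g1", "g2"), source = "t")
  set.seed(41)
  pos <- sample(2:1999, 300)
  seqstr <- as.character(g[[1]])
  snvs <- snv_df(pos, vapply(pos, function(p) substr(seqstr, p, p),
                             character(1)), "N")
  rep <- region_fractions(snvs, cds)
  oracle <- sum(pos %in% c(100:199, 400:499))
  expect_identical(rep$n_translated, oracle)
  expect_identical(rep$n_untranslated, 300L - oracle)
  expect_equal(rep$fraction_translated, oracle / 300)

  inside <- snv_df(c(105, 150, 420), "N", "N")
  expect_equal(region_fractions(inside, cds)$fraction_translated, 1.0)
  expect_equal(region_fractions(inside, cds[0])$fraction_translated, 0.0)
})

test_that("strand-bias test is the exact two-sided binomial", {
  mk_cat <- function(nT, nU) {
    counts <- matrix(0L, 96, 2, dimnames = list(sbs96_channels(),
                                                c("T", "U")))
    counts[1, "T"] <- nT
    counts[1, "U"] <- nU
    structure(list(sample = "s", counts = counts, n_intergenic = 0L,
                   n_bidirectional = 0L, n_unclassified = 0L),
              class = "catalog192")
  }
  res <- strand_bias_test(mk_cat(50L, 50L))
  ca <- res[res$substitution_class == "C>A", ]
  expect_equal(ca$ratio, 1.0)
  expect_equal(ca$p_value, 1.0)

  res0 <- strand_bias_test(mk_cat(0L, 0L))
  ca0 <- res0[res0$substitution_class == "C>A", ]
  expect_equal(ca0$p_value, 1.0)
  expect_true(is.na(ca0$ratio))

  res2 <- strand_bias_test(mk_cat(25L, 75L))
  ca2 <- res2[res2$substitution_class == "C>A", ]
  expect_equal(ca2$p_value, binom.test(75, 100, 0.5)$p.value,
               tolerance = 1e-12)
})

test_that("catalog TSV round-trips and rejects label mismatch", {
  M <- matrix(sample(0:50, 96 * 3, replace = TRUE), 96, 3,
              dimnames = list(sbs96_channels(), c("a", "b", "c")))
  p <- tempfile(fileext = ".tsv")
  write_catalog_tsv(M, p)
  M2 <- read_catalog_tsv(p)
  expect_equal(unname(M2), unname(M))
  expect_identical(rownames(M2), sbs96_channels())
  lines <- readLines(p)
  lines[2] <- sub("^A\\[C>A\\]A", "X[C>A]A", lines[2])
  writeLines(lines, p)
  expect_error(read_catalog_tsv(p), "do not match")
})
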