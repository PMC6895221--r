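# sigcarcin

Consensus somatic-variant filtering, trinucleotide mutation catalogs, and
mutational-signature extraction for small carcinogen-exposure cohorts, with a
fully synthetic validation harness.

## The scientific problem

Carcinogen-induction experiments — for example, oral tumors induced in mice
by a chemical mutagen — ask whether the induced tumors carry the same
mutational footprint as a human exposure such as tobacco smoking. Answering
that from whole-exome or whole-genome sequencing of a handful of tumor lines
requires four steps, each with known failure modes:

1. **Somatic calls must survive caller disagreement and germline
   contamination.** sigcarcin takes per-caller VCFs, applies an m-of-n
   consensus vote (default 2 of 3 callers), removes variants in a germline
   panel, and removes variants consensus-supported in *every* sample of the
   cohort (in genetically identical animals these are inherited, not
   somatic). With three independent callers at sensitivity *s* = 0.9, the
   expected consensus recall is 3·s²(1−s) + s³ = **0.972**, and a false
   positive private to one caller can never pass.
2. **Mutations are summarized as SBS-96 catalogs** — each single-base
   substitution, pyrimidine-normalized, in its trinucleotide context — and,
   inside gene bodies, as SBS-192 catalogs split by transcriptional strand
   (T = pyrimidine on the template strand, U = on the coding strand).
   Strand asymmetry per substitution class is tested with a two-sided exact
   binomial test, the classical readout of transcription-coupled repair.
3. **Signatures are extracted de novo** by non-negative matrix factorization
   M ≈ WH under the generalized Kullback–Leibler objective (the Poisson
   likelihood for counts), with Lee–Seung multiplicative updates. A
   multinomial bootstrap plus k-medoids consensus clustering on cosine
   distance yields per-signature stability (mean silhouette width); the rank
   is chosen as the most stable rank among those whose reconstruction error
   is within 10% of the scan minimum.
4. **Extracted signatures are matched to references** by cosine similarity
   (the "percent similarity" of the signature literature) and Pearson
   correlation, with one-to-one assignment and a configurable match floor.

Because real inputs of this kind are large and access-restricted, the
package ships a synthetic cohort generator that plants every quantity the
pipeline is supposed to recover — signature mixtures, transcriptional strand
bias, caller sensitivity and private false positives, germline
contamination — so the whole analysis is testable against exact ground
truth.

## Worked example

Simulate the default four-sample cohort (2000 SNVs per sample from an
85/15 tobacco-like/flat mixture, three callers at sensitivity 0.9, 100
private false positives per caller per sample, 50 germline variants), then
run consensus, extraction, matching, and the strand-bias test:

```r
library(sigcarcin)
cfg    <- simulation_config(seed = 42)
cohort <- simulate_cohort(cfg)

voted <- lapply(cohort$callsets, consensus_vote, min_support = 2L)
res   <- filter_germline(voted, panel = cohort$panel)
kept  <- lapply(res$cohort, kept_variants)

cats <- lapply(names(kept), function(s)
  build_catalog(kept[[s]], cohort$genome, sample = s))
M  <- catalog_matrix(cats)
ss <- bootstrap_extract(M, k_range = 1:2, n_boot = 15, seed = 42)

ref <- cbind(tobacco_like = gen_signature("tobacco_like"),
             flat         = gen_signature("flat"))
rownames(ref) <- sbs96_channels()
match_to_reference(ss$W, ref)$best_match

c192 <- build_stranded_catalog(kept[[1]], cohort$genome,
                               cohort$annotation, sample = names(kept)[1])
strand_bias_test(c192)
```

Output of this exact script (seed 42):

```
kept per sample: 1946 1938 1954 1950
consensus recall: 0.9735 (closed form 0.972)
signature_set: k = 1 (mean stability 0.997)
reconstruction error: Frobenius 0.1279, KL 172.2
  k mean_stability frobenius       kl
1 1      0.9966140 0.1279192 172.1979
2 2      0.3669478 0.1216986 176.5138
  extracted    reference    cosine   pearson below_floor
1        S1 tobacco_like 0.9946226 0.9946814       FALSE
  substitution_class n_transcribed n_untranscribed    ratio      p_value
1                C>A           123             306 2.487805 4.399842e-19
```

The dominant planted process is recovered at cosine 0.995 (99.5%
similarity), no private false positive or germline variant survives
filtering, and the planted 2:1 untranscribed:transcribed bias on C>A is
detected (observed ratio 2.49 in one sample, p ≈ 4·10⁻¹⁹).

The same stages are scriptable end to end: `run_pipeline()` consumes a YAML
config pointing at FASTA/GTF/VCF inputs and writes consensus VCFs, catalog
TSVs, strand-bias and rank-selection JSON, signatures, exposures, and a run
report. `run_simulated_pipeline()` materializes a synthetic cohort to disk
and runs that pipeline on the files. `selftest()` runs the whole system
against planted truth and checks recall, precision, fate conservation,
signature recovery, and strand-bias recovery. A command-line front end
lives at `inst/cli/sigcarcin.R` (subcommands: simulate, consensus, catalog,
extract, compare, run, selftest).

See the vignette source (`vignettes/signature-pipeline.Rmd`) for the model,
the numerical choices, and what the generator does and does not emulate.

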