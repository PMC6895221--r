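---
title: "Consensus calling and mutational-signature extraction with sigcarcin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling and mutational-signature extraction with sigcarcin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

sigcarcin characterizes the somatic mutanome of small tumor cohorts — the
motivating case is a handful of carcinogen-induced murine oral squamous-cell
carcinoma lines sequenced against one matched normal — and asks whether the
mutational process that produced them resembles a known mutagen footprint
such as the human tobacco-smoking signature. The pipeline has four analytic
stages, each usable on its own:

1. **Consensus somatic calling.** Per-caller SNV call sets are combined by an
   m-of-n vote (default 2 of 3), then filtered against a germline panel and
   against variants shared by every sample of the cohort.
2. **Catalog construction.** Surviving SNVs are classified into the 96
   pyrimidine-normalized trinucleotide channels (SBS-96), and, inside gene
   footprints, split by transcriptional strand into a 192-channel catalog.
3. **Signature extraction.** Catalogs are factorized by non-negative matrix
   factorization under the generalized Kullback–Leibler objective, wrapped in
   a bootstrap with k-medoids consensus clustering and silhouette-based
   stability selection of the rank.
4. **Reference matching.** Extracted signatures are scored against a
   user-supplied reference matrix by cosine similarity (the headline metric)
   and Pearson correlation.

A synthetic cohort generator produces complete inputs — genome, gene models,
planted signature mixtures with transcriptional strand bias, three imperfect
callers, germline contamination, and a panel — so the full pipeline can be
validated against known ground truth without any external data.

## The consensus model

Callers disagree: each has private false positives and misses true variants.
If caller `c` detects a true somatic SNV independently with sensitivity
`s_c`, the probability that a variant reaches the 2-of-3 threshold is

    P(support >= 2) = s1 s2 (1 - s3) + s1 s3 (1 - s2) + s2 s3 (1 - s1)
                      + s1 s2 s3

— at `s = 0.9` per caller, 0.972. A false positive private to one caller can
never reach support 2, so consensus precision against caller-private noise is
exactly 1. Germline contamination defeats the vote (all callers see it in all
samples), which is why two further filters exist: a panel of known inherited
variants, and removal of variants consensus-supported in *every* sample of
the cohort — in a cohort of genetically identical animals, a variant in all
tumors is almost surely inherited or artifactual.

Design choices a user should know:

* Variant identity is the exact tuple (chrom, pos, ref, alt) after
  multiallelic splitting and padded-allele trimming; callers disagreeing on
  the alternate allele at a site yield distinct variants.
* "Shared across the cohort" means present in **every** sample, not a
  majority — the strictest reading, and a parameter of cohort composition
  rather than of the function.
* Panel matching requires the allele to match by default; position-only
  matching (`match_alleles = FALSE`) is available because published panel
  filters differ on this point, but it discards true somatic hits at
  polymorphic sites.
* Records failing the caller's own FILTER column are excluded before voting
  (`keep_nonpass = TRUE` reverses this); a caller's internal quality flags
  are upstream evidence we have no basis to overrule.

Every variant ever considered carries a fate — `kept`,
`dropped_low_support`, `dropped_germline_panel`, `dropped_shared_cohort` —
and the fates partition the evaluated set exactly, so count conservation is
checkable at any stage. Filtering is idempotent. The panel rule is applied
before the shared-cohort rule, so a panel variant present everywhere is
attributed to the panel.

## Catalogs and strand bias

SBS-96 channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C,
T>G), then 5' flank (A, C, G, T), then 3' flank — the conventional
lexicographic order, written into every output header. Purine-reference
substitutions are reverse-complemented (pyrimidine normalization), so the 192
raw (ref, alt, context) combinations collapse exactly 2-to-1 onto 96
channels. Contexts containing non-ACGT bases, and positions at contig edges,
are counted as unclassified rather than guessed.

Transcriptional strand labels follow where the **pyrimidine** of the mutated
pair sits relative to the gene: on the coding (non-template) strand the
variant is *untranscribed* (U), on the template strand *transcribed* (T).
The gene footprint is the full gene span including introns, because
transcription-coupled repair acts on the transcribed unit, not only exons.
Positions covered by genes on both strands are ambiguous and tallied
separately (never double-counted); intergenic variants likewise.

Strand bias is tested per substitution class with a two-sided exact binomial
test of the U count against p0 = 0.5. No trinucleotide-opportunity
correction is applied by default — the strand-specific opportunity of a
random genome is symmetric in expectation, and the uncorrected test is the
simplest defensible default — but a per-class `p0` argument accepts an
opportunity-corrected null when the user computes one.

"Translated" region fractions count SNVs overlapping any CDS interval;
everything else (UTR, intron, intergenic) is untranslated. An exon-based
alternative (`mode = "exon"`) is provided because the distinction matters
for annotations carrying explicit exon features.

## The factorization model

A catalog matrix `M` (96 x samples) of counts is modeled as `M ~ W H` with
`W >= 0` (96 x k, columns are signatures, each summing to 1) and `H >= 0`
(k x samples, exposures in mutation counts). The objective is the
generalized Kullback–Leibler divergence, the natural likelihood for Poisson
counts, minimized by Lee–Seung multiplicative updates. Numerical choices:

* random non-negative `W` initialization from the seed; `H` starts at the
  deterministic column-wise value `colSums(M) / k`, which makes the update
  dynamics exactly exchangeable in the sample columns — permuting samples
  permutes the solution bit-for-bit;
* convergence when the relative objective decrease over a 10-iteration
  window falls below `tol = 1e-8`, or at `n_iter`;
* a machine-epsilon floor inside divisions; all-zero matrices rejected.

Multiplicative updates guarantee a non-increasing objective; the test suite
asserts it.

### Bootstrap, stability, and rank selection

A single NMF run is sensitive to initialization and to sampling noise. Each
bootstrap replicate resamples every sample column multinomially (n = the
column total, p = the normalized column), preserving per-sample burden, and
factorizes from a fresh seed. The `n_boot * k` candidate signatures are
partitioned into `k` clusters by k-medoids on cosine distance; the
renormalized medoids are the consensus signatures, and the mean silhouette
width of the partition is the stability. For `k = 1`, where the silhouette
is undefined, stability is the mean cosine similarity of the candidates to
their medoid — 1 when every replicate recovers the same direction.

Rank selection is stability-first with an error guard: ranks whose relative
Frobenius reconstruction error (after a non-negative least-squares exposure
refit on the original matrix) is within 10% (relative) of the scan minimum
are eligible, and the eligible rank with the highest mean stability wins;
ties go to the smaller rank. The guard exists because stability alone always
prefers `k = 1` (a single average direction is trivially reproducible), and
error alone always prefers the largest `k`.

Exposures reported to the user are always the NNLS refit against the
consensus signatures on the *original* catalog, not a bootstrap average, so
column sums track the observed mutation burdens.

### Similarity reporting

Cosine similarity of non-negative spectra lies in [0, 1] and is the metric
signature frameworks quote as "percent similarity"; Pearson correlation is
reported alongside because both phrasings circulate in the literature.
Matching to a reference set is greedy on descending cosine with one-to-one
assignment; for well-separated spectra — the regime of real signature
catalogs — this coincides with the assignment maximizing total cosine (the
test suite verifies both this and the greedy rule itself). A floor (default
0.80) flags weak matches. Channel-label mismatches between matrices are an
error, never a silent reordering. Pearson against an exactly flat reference
spectrum is undefined and reported as `NA`.

## What the synthetic cohort emulates

The generator's defaults describe the study system the package targets: a
cohort of **4 samples**, each with **2000 somatic SNVs** drawn from a
mixture of **85% tobacco-like** (>= 60% of mass on C>A channels, graded
context preference) and **15% flat** background; a single **100 kb** contig
at **GC 0.42** (mouse-like); **40 non-overlapping genes** of mean length
1 kb (~40% genic fraction); untranscribed:transcribed odds of **2:1 on C>A**
inside genes (a moderate transcription-coupled-repair footprint; the
acceptance tests also exercise 3:1); **three callers at sensitivity 0.9**
each contributing **100 private false positives** per sample; **50 germline
variants** seen by every caller in every sample, plus 50 panel decoys. The
per-sample burden and the 100 kb genome are desk-scale choices — small
enough that the whole pipeline runs in seconds, large enough that every one
of the 32 pyrimidine contexts occurs thousands of times; they are not claims
about any real cohort's burden.

Mutation placement is by channel: a site with the matching pyrimidine-strand
trinucleotide context is drawn uniformly; if it falls inside a gene the site
is redrawn stratified by strand at the configured odds, so the planted
genic U:T ratio is exact by construction regardless of strand-specific
context availability. Truth labels (signature index, channel, strand) ride
along and must survive re-classification by the catalog builder — a
self-consistency invariant the tests enforce exactly.

What the generator does **not** emulate: multi-contig genomes with
overlapping genes (the classifier handles both; the generator keeps genes
disjoint so placement stays simple), read-level evidence and alignment
artifacts, indels and doublet substitutions, copy-number structure,
caller-correlated error modes (false positives are independent and private
per caller — the worst case for the voting rule, but real callers share
failure modes), and regional mutation-rate variation. Passing the synthetic
recovery tests therefore demonstrates the *computational* correctness of the
pipeline under its stated model, not robustness to every artifact of real
sequencing data.

## Problem sizes used in validation

The packaged tests run the full pipeline on 3–4 sample cohorts of 300–2000
mutations each, the two-signature factorization benchmark on 20 samples x
2000 mutations (planted signatures with mutual cosine 0.13, bootstrap of 25
replicates over ranks 1–4), and the strand-bias recovery on a single sample
of 4000 mutations with 3:1 planted odds. The acceptance script reruns the
default cohort end-to-end plus the two-signature benchmark from a
user-supplied seed.

## Limitations

* Exposure uncertainty is not quantified; only signature stability is.
* Rank selection on very small cohorts (4 samples) can flip between 1 and 2
  for mixtures whose components are individually weak; the per-rank scan is
  always reported so the user can see the margin.
* The exact binomial strand-bias test treats mutations as independent;
  clustered mutational processes would need an overdispersed test.
* The consensus vote assumes caller errors are independent; correlated
  artifacts (alignment, FFPE-like damage) defeat any m-of-n rule and must be
  handled upstream or by the panel.
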