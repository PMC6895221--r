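# Per-position site index for mutation placement: for every interior position
# of the (single-contig) genome, the pyrimidine-strand trinucleotide context,
# whether the pyrimidine lies on the forward strand, and the transcriptional
# category of the site.
build_site_index <- function(genome, annotation) {
  contig <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  bases <- strsplit(toupper(as.character(genome[[contig]])), "")[[1]]
  pos <- 2:(glen - 1L)
  b5 <- bases[pos - 1L]
  bc <- bases[pos]
  b3 <- bases[pos + 1L]
  pyr_fwd <- bc %in% c("C", "T")
  ctx <- ifelse(pyr_fwd,
                paste0(b5, bc, b3),
                paste0(COMPLEMENT[b3], COMPLEMENT[bc], COMPLEMENT[b5]))
  # transcriptional category per position: I intergenic, +/- gene strand,
  # B overlapped by genes on both strands
  cat <- rep("I", glen)
  if (length(annotation)) {
    genes <- annotation[annotation$type == "gene"]
    for (i in seq_along(genes)) {
      rng <- GenomicRanges::start(genes)[i]:GenomicRanges::end(genes)[i]
      st <- as.character(GenomicRanges::strand(genes))[i]
      cur <- cat[rng]
      cat[rng] <- ifelse(cur == "I", st, ifelse(cur == st, cur, "B"))
    }
  }
  gcat <- cat[pos]
  # strand label of the *pyrimidine* relative to the gene: U when the
  # pyrimidine sits on the gene's coding (untranscribed) strand
  pyr_strand <- ifelse(pyr_fwd, "+", "-")
  label <- ifelse(gcat == "I", "intergenic",
           ifelse(gcat == "B", "bidirectional",
           ifelse(pyr_strand == gcat, "U", "T")))
  list(pos = pos, ctx = ctx, pyr_fwd = pyr_fwd, label = label,
       contig = contig, ref = bc)
}

channel_parts <- function() {
  labs <- sbs96_channels()
  data.frame(
    label = labs,
    ctx = paste0(substr(labs, 1, 1), substr(labs, 3, 3), substr(labs, 7, 7)),
    ref = substr(labs, 3, 3),
    alt = substr(labs, 5, 5),
    class = substr(labs, 3, 5),
    stringsAsFactors = FALSE
  )
}

#' Plant somatic mutations from a signature mixture onto a genome
#'
#' For each sample, draws a signature index from the sample's exposure
#' weights and a channel from that signature, independently per mutation,
#' then places the mutation at a genomic site whose pyrimidine-strand
#' trinucleotide context matches the channel. Placement is uniform over
#' matching sites; inside genes the site is re-drawn stratified by strand so
#' that the odds of the pyrimidine lying on the untranscribed (coding) vs
#' transcribed (template) strand equal the configured `strand_bias` ratio for
#' that substitution class. No two mutations share a site within a sample.
#'
#' @param config A [simulation_config()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation GRanges of gene models (may be empty).
#' @return A `truth_set` list: `mutations` (data frame with sample, chrom,
#'   pos, ref, alt, signature, channel, label, strand_label, flipped) and
#'   `samples` (sample names).
#' @export
sample_mutations <- function(config, genome, annotation) {
  idx <- build_site_index(genome, annotation)
  parts <- channel_parts()
  # per-context site pools, split by strand label
  pools <- lapply(split(seq_along(idx$pos), idx$ctx), function(j) {
    list(all = j,
         U = j[idx$label[j] == "U"],
         T = j[idx$label[j] == "T"])
  })
  samples <- sprintf("sample%d", seq_len(config$n_samples))
  exp_w <- config$exposures
  sigs <- config$signatures
  out <- with_seed(derive_seed(config$seed, 11L), {
    res <- vector("list", config$n_samples)
    for (s in seq_len(config$n_samples)) {
      n <- config$n_mutations_per_sample
      sig_idx <- sample.int(length(sigs), n, replace = TRUE, prob = exp_w[s, ])
      channel <- vapply(sig_idx, function(k) {
        sample.int(96L, 1L, prob = sigs[[k]])
      }, integer(1))
      used <- new.env(hash = TRUE)
      rows <- vector("list", n)
      for (m in seq_len(n)) {
        ch <- channel[m]
        ctx <- parts$ctx[ch]
        pool <- pools[[ctx]]
        if (is.null(pool) || length(pool$all) == 0L) {
          stop(sprintf("no genomic site matches context %s (channel %s)",
                       ctx, parts$label[ch]))
        }
        r <- config$strand_bias[[parts$class[ch]]] %||% 1
        placed <- NA_integer_
        for (try in seq_len(200L)) {
          j <- pool$all[sample.int(length(pool$all), 1L)]
          lab <- idx$label[j]
          if (lab %in% c("U", "T") && r != 1 &&
              length(pool$U) > 0L && length(pool$T) > 0L) {
            # re-draw stratified by strand at the configured odds
            take_u <- runif(1) < r / (r + 1)
            j <- if (take_u) {
              pool$U[sample.int(length(pool$U), 1L)]
            } else {
              pool$T[sample.int(length(pool$T), 1L)]
            }
          } else if (lab %in% c("U", "T") && r == 1 &&
                     length(pool$U) > 0L && length(pool$T) > 0L) {
            take_u <- runif(1) < 0.5
            j <- if (take_u) {
              pool$U[sample.int(length(pool$U), 1L)]
            } else {
              pool$T[sample.int(length(pool$T), 1L)]
            }
          }
          key <- as.character(idx$pos[j])
          if (is.null(used[[key]])) {
            used[[key]] <- TRUE
            placed <- j
            break
          }
        }
        if (is.na(placed)) {
          stop(sprintf("could not place mutation for channel %s without %s",
                       parts$label[ch], "site collision"))
        }
        fwd <- idx$pyr_fwd[placed]
        ref <- if (fwd) parts$ref[ch] else unname(COMPLEMENT[parts$ref[ch]])
        alt <- if (fwd) parts$alt[ch] else unname(COMPLEMENT[parts$alt[ch]])
        rows[[m]] <- list(pos = idx$pos[placed], ref = ref, alt = alt,
                          strand_label = idx$label[placed], flipped = !fwd)
      }
      res[[s]] <- data.frame(
        sample = samples[s], chrom = idx$contig,
        pos = vapply(rows, `[[`, integer(1), "pos"),
        ref = vapply(rows, `[[`, character(1), "ref"),
        alt = vapply(rows, `[[`, character(1), "alt"),
        signature = sig_idx, channel = channel,
        label = parts$label[channel],
        strand_label = vapply(rows, `[[`, character(1), "strand_label"),
        flipped = vapply(rows, `[[`, logical(1), "flipped"),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, res)
  })
  structure(list(mutations = sort_by_sample(out), samples = samples),
            class = "truth_set")
}

sort_by_sample <- function(df) {
  df[order(df$sample, df$chrom, df$pos, df$alt), , drop = FALSE]
}

#' Simulate three imperfect caller call sets from a truth set
#'
#' Each caller retains every truth mutation independently with its configured
#' sensitivity, adds caller-private false-positive SNVs at fresh genomic
#' sites, and reports every germline variant (germline contamination is seen
#' by all callers in all samples). Deterministic under the config seed.
#'
#' @param truth A `truth_set` from [sample_mutations()].
#' @param config A [simulation_config()].
#' @param germline Data frame of germline variants to inject (may be empty).
#' @param genome Genome, used to draw reference bases for false positives.
#' @return Nested list: `callsets[[sample]][[caller]]` data frames with
#'   chrom/pos/ref/alt.
#' @export
simulate_callers <- function(truth, config, germline, genome) {
  callers <- names(config$caller_sensitivity)
  contig <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  bases <- strsplit(toupper(as.character(genome[[contig]])), "")[[1]]
  with_seed(derive_seed(config$seed, 23L), {
    out <- list()
    for (s in truth$samples) {
      tm <- truth$mutations[truth$mutations$sample == s,
                            c("chrom", "pos", "ref", "alt")]
      taken <- c(tm$pos, germline$pos)
      out[[s]] <- list()
      for (cl in callers) {
        sens <- config$caller_sensitivity[[cl]]
        keep <- runif(nrow(tm)) < sens
        calls <- tm[keep, , drop = FALSE]
        nfp <- config$n_false_positives_per_caller
        if (nfp > 0L) {
          pool <- setdiff(2:(glen - 1L), taken)
          fp_pos <- sample(pool, nfp)
          taken <- c(taken, fp_pos)  # FPs stay private to this caller
          fp_ref <- bases[fp_pos]
          fp_alt <- vapply(fp_ref, function(r) sample(setdiff(BASES, r), 1L),
                           character(1))
          calls <- rbind(calls, data.frame(chrom = contig, pos = fp_pos,
                                           ref = fp_ref, alt = unname(fp_alt),
                                           stringsAsFactors = FALSE))
        }
        if (nrow(germline) > 0L) {
          calls <- rbind(calls, germline[, c("chrom", "pos", "ref", "alt")])
        }
        out[[s]][[cl]] <- sort_snvs(calls)
      }
    }
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [gen_genome()], [gen_annotation()],
#' [gen_germline_panel()], [sample_mutations()] and [simulate_callers()] from
#' one [simulation_config()]. The germline panel contains the injected
#' contaminants plus `n_panel_decoys` decoy entries; panel and somatic truth
#' never share a site.
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `annotation`, `truth`, `germline` (injected),
#'   `panel` (injected + decoys), `callsets`, and `config`.
#' @export
simulate_cohort <- function(config) {
  genome <- gen_genome(config$genome_length, config$gc_fraction,
                       seed = derive_seed(config$seed, 1L))
  annotation <- gen_annotation(genome, config$n_genes,
                               config$gene_length_mean,
                               seed = derive_seed(config$seed, 2L))
  truth <- sample_mutations(config, genome, annotation)
  panel <- gen_germline_panel(
    genome, config$n_germline + config$n_panel_decoys,
    seed = derive_seed(config$seed, 3L),
    avoid_pos = unique(truth$mutations$pos)
  )
  germline <- panel[seq_len(config$n_germline), , drop = FALSE]
  callsets <- simulate_callers(truth, config, germline, genome)
  list(genome = genome, annotation = annotation, truth = truth,
       germline = germline, panel = panel, callsets = callsets,
       config = config)
}
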