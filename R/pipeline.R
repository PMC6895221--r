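#' Pipeline configuration
#'
#' Bundles every input path and tuning parameter of the consensus -> catalog
#' -> extraction -> comparison pipeline. All referenced input files must
#' exist at validation time; the seed is mandatory because extraction is
#' stochastic.
#'
#' @param genome Path to the reference genome FASTA.
#' @param annotation Path to the gene annotation (GTF/GFF3 with gene and CDS
#'   features).
#' @param vcfs Nested named list: `vcfs[[sample]][[caller]]` -> VCF path.
#' @param panel Optional germline panel VCF path.
#' @param reference Optional reference-signature TSV (96 labeled rows).
#' @param min_support Consensus vote threshold (default 2).
#' @param k_range Ranks scanned by [bootstrap_extract()].
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param outdir Output directory (created if missing).
#' @param keep_nonpass Keep FILTER-failing VCF records before voting.
#' @param match_alleles Panel matching by allele (default) or position only.
#' @param region_mode `"cds"` or `"exon"` for [region_fractions()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genome, annotation, vcfs, panel = NULL,
                            reference = NULL, min_support = 2L,
                            k_range = 1:3, n_boot = 25L, seed = 1L,
                            outdir = "sigcarcin_out", keep_nonpass = FALSE,
                            match_alleles = TRUE,
                            region_mode = c("cds", "exon")) {
  cfg <- list(genome = genome, annotation = annotation, vcfs = vcfs,
              panel = panel, reference = reference,
              min_support = as.integer(min_support), k_range = k_range,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              outdir = outdir, keep_nonpass = keep_nonpass,
              match_alleles = match_alleles,
              region_mode = match.arg(region_mode))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("seed is mandatory")
  for (p in c(cfg$genome, cfg$annotation, cfg$panel, cfg$reference,
              unlist(cfg$vcfs))) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input path does not exist: %s", p))
    }
  }
  if (length(cfg$vcfs) < 1L) stop("at least one sample's VCFs are required")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with keys matching the [pipeline_config()] arguments.
#' @param overrides Named list of values overriding the file's keys.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  for (k in names(overrides)) raw[[k]] <- overrides[[k]]
  do.call(pipeline_config, raw)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full pipeline
#'
#' Executes consensus voting, germline/shared filtering, SBS-96 and SBS-192
#' catalog construction, region classification, strand-bias testing,
#' bootstrapped signature extraction, and (when a reference is supplied)
#' similarity scoring — writing every intermediate to the output directory.
#' Reruns with an identical config and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage_time <- function(name, expr) {
    st <- Sys.time()
    val <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    val
  }

  genome <- stage_time("load_inputs", {
    g <- read_genome_fasta(config$genome)
    log_stage("inputs", "genome: %d contig(s), %d bases", length(g),
              sum(Biostrings::width(g)))
    g
  })
  annotation <- read_annotation(config$annotation)
  panel <- if (!is.null(config$panel)) read_panel_vcf(config$panel) else NULL
  samples <- names(config$vcfs)

  consensus <- stage_time("consensus", {
    res <- list()
    skip_totals <- list()
    for (s in samples) {
      callsets <- list()
      for (cl in names(config$vcfs[[s]])) {
        rd <- read_caller_vcf(config$vcfs[[s]][[cl]], caller = cl,
                              keep_nonpass = config$keep_nonpass)
        callsets[[cl]] <- rd$snvs
        skip_totals[[paste(s, cl)]] <- rd$skips
      }
      res[[s]] <- consensus_vote(callsets, min_support = config$min_support)
      log_stage("consensus", "%s: %d evaluated, %d pass vote", s,
                nrow(res[[s]]), sum(res[[s]]$fate == "kept"))
    }
    attr(res, "skips") <- skip_totals
    res
  })

  filtered <- stage_time("filter", {
    fg <- filter_germline(consensus, panel,
                          match_alleles = config$match_alleles)
    write.table(fg$ledger, file.path(config$outdir, "removal_ledger.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("filter", "%d removals (%d panel, %d shared)",
              nrow(fg$ledger), sum(fg$ledger$rule == "germline_panel"),
              sum(fg$ledger$rule == "shared_cohort"))
    fg
  })
  for (s in samples) {
    write_consensus_vcf(filtered$cohort[[s]],
                        file.path(config$outdir,
                                  sprintf("%s.consensus.vcf", s)),
                        sample = s)
  }

  catalogs <- stage_time("catalog", {
    cats <- lapply(samples, function(s) {
      build_catalog(kept_variants(filtered$cohort[[s]]), genome, sample = s)
    })
    M <- catalog_matrix(cats)
    write_catalog_tsv(M, file.path(config$outdir, "catalog96.tsv"))
    stranded <- lapply(samples, function(s) {
      build_stranded_catalog(kept_variants(filtered$cohort[[s]]), genome,
                             annotation, sample = s)
    })
    names(stranded) <- samples
    S <- vapply(stranded, function(x) c(x$counts[, "T"], x$counts[, "U"]),
                numeric(192))
    rownames(S) <- sbs192_channels()
    write_catalog_tsv(S, file.path(config$outdir, "catalog192.tsv"))
    regions <- lapply(samples, function(s) {
      region_fractions(kept_variants(filtered$cohort[[s]]), annotation,
                       sample = s, mode = config$region_mode)
    })
    pooled192 <- stranded[[1]]
    if (length(stranded) > 1L) {
      for (x in stranded[-1]) {
        pooled192$counts <- pooled192$counts + x$counts
        pooled192$n_intergenic <- pooled192$n_intergenic + x$n_intergenic
        pooled192$n_bidirectional <- pooled192$n_bidirectional +
          x$n_bidirectional
      }
    }
    pooled192$sample <- "pooled"
    bias <- strand_bias_test(pooled192)
    jsonlite::write_json(bias, file.path(config$outdir, "strand_bias.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    log_stage("catalog", "%d SNVs cataloged across %d samples",
              sum(M), length(samples))
    list(M = M, stranded = stranded, regions = regions, bias = bias)
  })

  extraction <- stage_time("extract", {
    sigset <- bootstrap_extract(catalogs$M, k_range = config$k_range,
                                n_boot = config$n_boot, seed = config$seed)
    write_signatures_tsv(sigset, file.path(config$outdir, "signatures.tsv"))
    write_exposures_tsv(sigset, file.path(config$outdir, "exposures.tsv"))
    jsonlite::write_json(
      list(selected_k = sigset$k, mean_stability = sigset$mean_stability,
           scan = sigset$scan),
      file.path(config$outdir, "rank_selection.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    log_stage("extract", "selected k = %d (stability %.3f)", sigset$k,
              sigset$mean_stability)
    sigset
  })

  similarity <- NULL
  if (!is.null(config$reference)) {
    similarity <- stage_time("compare", {
      ref <- read_catalog_tsv(config$reference)
      rep <- match_to_reference(extraction, ref)
      jsonlite::write_json(rep$best_match,
                           file.path(config$outdir, "similarity.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      log_stage("compare", "best cosine %.4f",
                max(rep$best_match$cosine))
      rep
    })
  }

  report <- list(
    version = as.character(packageVersion("sigcarcin")),
    config = config[c("min_support", "k_range", "n_boot", "seed",
                      "keep_nonpass", "match_alleles", "region_mode")],
    samples = samples,
    counts = lapply(filtered$cohort, function(df) {
      list(evaluated = nrow(df),
           kept = sum(df$fate == "kept"),
           dropped_low_support = sum(df$fate == "dropped_low_support"),
           dropped_germline_panel = sum(df$fate == "dropped_germline_panel"),
           dropped_shared_cohort = sum(df$fate == "dropped_shared_cohort"))
    }),
    region = lapply(catalogs$regions, unclass),
    strand_bias = catalogs$bias,
    selected_k = extraction$k,
    mean_stability = extraction$mean_stability,
    similarity = if (!is.null(similarity)) similarity$best_match else NULL,
    timings = timings
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_stage("done", "total %.1fs",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(c(report,
              list(cohort = filtered$cohort, ledger = filtered$ledger,
                   catalog = catalogs$M, stranded = catalogs$stranded,
                   signatures = extraction, similarity_report = similarity)),
            class = "run_report")
}

#' Materialize a synthetic cohort on disk and run the pipeline over it
#'
#' Generates the full synthetic cohort from a [simulation_config()], writes
#' genome FASTA, GTF, per-caller VCFs, panel VCF and a reference-signature
#' TSV (the planted signatures), then runs [run_pipeline()] on those files —
#' an end-to-end exercise through the same file-backed interfaces a real
#' analysis would use.
#'
#' @param sim A [simulation_config()].
#' @param outdir Output directory.
#' @param k_range,n_boot Extraction settings.
#' @return List with `report` (the [run_pipeline()] result), `cohort` (the
#'   generated truth), and `dir`.
#' @export
run_simulated_pipeline <- function(sim = simulation_config(),
                                   outdir = tempfile("sigcarcin_run_"),
                                   k_range = 1:2, n_boot = 15L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(sim)
  inputs <- file.path(outdir, "inputs")
  dir.create(inputs, showWarnings = FALSE)
  gpath <- write_genome_fasta(cohort$genome, file.path(inputs, "genome.fa"))
  apath <- write_annotation_gtf(cohort$annotation,
                                file.path(inputs, "genes.gtf"))
  ppath <- write_snv_vcf(cohort$panel, file.path(inputs, "panel.vcf"),
                         source = "synthetic germline panel")
  vcfs <- list()
  for (s in names(cohort$callsets)) {
    vcfs[[s]] <- list()
    for (cl in names(cohort$callsets[[s]])) {
      p <- file.path(inputs, sprintf("%s.%s.vcf", s, cl))
      write_snv_vcf(cohort$callsets[[s]][[cl]], p, source = cl)
      vcfs[[s]][[cl]] <- p
    }
  }
  W <- do.call(cbind, sim$signatures)
  rownames(W) <- sbs96_channels()
  colnames(W) <- names(sim$signatures) %||%
    sprintf("planted%d", seq_along(sim$signatures))
  rpath <- write_catalog_tsv(W, file.path(inputs, "reference.tsv"))
  cfg <- pipeline_config(genome = gpath, annotation = apath, vcfs = vcfs,
                         panel = ppath, reference = rpath,
                         k_range = k_range, n_boot = n_boot,
                         seed = sim$seed, outdir = file.path(outdir, "out"))
  report <- run_pipeline(cfg)
  list(report = report, cohort = cohort, dir = outdir)
}

#' End-to-end self-test on a synthetic cohort
#'
#' Generates the default synthetic cohort, runs the full pipeline, and
#' asserts the recoveries the design promises: conservation of variant fates,
#' consensus recall near its closed-form expectation with zero retention of
#' caller-private false positives, removal of all injected germline
#' contamination, recovery of the dominant planted signature (cosine >=
#' `min_cosine`), and recovery of the planted transcriptional strand bias.
#'
#' @param seed Integer seed.
#' @param sim Optional [simulation_config()] override (its seed is replaced
#'   by `seed`).
#' @param min_cosine Recovery threshold for the planted signature.
#' @param quiet Suppress the summary printout.
#' @return A `selftest_report` list with `pass` and a `checks` data frame.
#' @export
selftest <- function(seed = 1L, sim = NULL, min_cosine = 0.95,
                     quiet = FALSE) {
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  else sim$seed <- as.integer(seed)
  res <- run_simulated_pipeline(sim, k_range = 1:2, n_boot = 15L)
  rep <- res$report
  cohort <- res$cohort
  checks <- list()
  add <- function(name, value, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = value, pass = pass, stringsAsFactors = FALSE)
  }

  # conservation of fates
  cons_ok <- all(vapply(rep$cohort, function(df) {
    nrow(df) == sum(df$fate %in% c("kept", "dropped_low_support",
                                   "dropped_germline_panel",
                                   "dropped_shared_cohort"))
  }, logical(1)))
  add("fate_conservation", as.numeric(cons_ok), cons_ok)

  # consensus recall vs closed form P(support >= 2 | sens)
  sens <- sim$caller_sensitivity
  p2 <- sum(vapply(seq_along(sens), function(i) {
    prod(sens[-i]) * (1 - sens[i])
  }, numeric(1))) + prod(sens)
  truth_keys <- split(snv_key(cohort$truth$mutations),
                      cohort$truth$mutations$sample)
  recalls <- vapply(names(rep$cohort), function(s) {
    kept <- snv_key(kept_variants(rep$cohort[[s]]))
    mean(truth_keys[[s]] %in% kept)
  }, numeric(1))
  n_truth <- sum(lengths(truth_keys))
  se <- sqrt(p2 * (1 - p2) / n_truth)
  recall <- mean(recalls)
  recall_ok <- abs(recall - p2) <= 3 * se + 1e-12
  add("consensus_recall", recall, recall_ok)
  # absolute floor: a healthy consensus stage recovers >= 90% of truth
  add("consensus_recall_floor", recall, recall >= 0.90)

  # no caller-private false positive can reach support 2
  truth_all <- unique(unlist(truth_keys))
  germ_keys <- snv_key(cohort$germline)
  fp_kept <- sum(vapply(names(rep$cohort), function(s) {
    kept <- snv_key(kept_variants(rep$cohort[[s]]))
    sum(!(kept %in% truth_keys[[s]]) & !(kept %in% germ_keys))
  }, numeric(1)))
  add("false_positives_kept", fp_kept, fp_kept == 0)

  # every injected germline variant removed in every sample
  germ_kept <- sum(vapply(names(rep$cohort), function(s) {
    sum(snv_key(kept_variants(rep$cohort[[s]])) %in% germ_keys)
  }, numeric(1)))
  add("germline_kept", germ_kept, germ_kept == 0)

  # planted-signature recovery (dominant signature, pooled extraction)
  dom <- sim$signatures[[which.max(colMeans(sim$exposures))]]
  rec_cos <- max(apply(rep$signatures$W, 2, cosine_similarity, b = dom))
  add("signature_recovery_cosine", rec_cos, rec_cos >= min_cosine)

  # strand-bias recovery on the biased class
  biased <- names(sim$strand_bias)[sim$strand_bias != 1]
  bias_ok <- TRUE
  bias_val <- NA_real_
  if (length(biased)) {
    sc <- biased[1]
    r <- sim$strand_bias[[sc]]
    row <- rep$strand_bias[rep$strand_bias$substitution_class == sc, ]
    nU <- row$n_untranscribed; nT <- row$n_transcribed
    ci <- stats::binom.test(nU, nU + nT, conf.level = 0.997)$conf.int
    bias_ok <- r / (r + 1) >= ci[1] && r / (r + 1) <= ci[2]
    bias_val <- if (nT > 0) nU / nT else NA_real_
    add(sprintf("strand_bias_ratio_%s", sc), bias_val, bias_ok)
  }

  checks <- do.call(rbind, checks)
  pass <- all(checks$pass)
  if (!quiet) {
    cat("sigcarcin self-test\n")
    cat(sprintf("  cohort: %d samples x %d mutations, genome %d bp\n",
                sim$n_samples, sim$n_mutations_per_sample,
                sim$genome_length))
    for (i in seq_len(nrow(checks))) {
      cat(sprintf("  %-28s %10.4f  %s\n", checks$check[i], checks$value[i],
                  if (checks$pass[i]) "PASS" else "FAIL"))
    }
    cat(if (pass) "ALL CHECKS PASSED\n" else "SELF-TEST FAILED\n")
  }
  structure(list(pass = pass, checks = checks, report = rep,
                 expected_recall = p2),
            class = "selftest_report")
}
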