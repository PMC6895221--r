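#' Generate a 96-channel mutational signature
#'
#' Built-in profiles are synthetic stand-ins for signature shapes commonly
#' used in benchmarking; none is a redistributed reference signature.
#'
#' * `"tobacco_like"`: >= 60% of mass on the 16 C>A channels with a graded
#'   context preference, the remainder spread over the other classes —
#'   mimics the C>A-dominated shape of the human tobacco-smoking signature.
#' * `"flat"`: uniform, 1/96 per channel.
#' * `"uv_like"`: mass concentrated on C>T at dipyrimidine contexts
#'   (5' base C or T).
#'
#' Alternatively pass a named numeric vector of non-negative weights keyed by
#' channel label (as in [sbs96_channels()]) or a bare numeric vector of
#' length 96; weights are normalized to sum 1.
#'
#' @param spec Profile name or weight vector.
#' @return Named numeric 96-vector summing to 1.
#' @export
#' @examples
#' s <- gen_signature("tobacco_like")
#' sum(s[grep("C>A", names(s), fixed = TRUE)]) >= 0.6
gen_signature <- function(spec) {
  labs <- sbs96_channels()
  w <- numeric(96)
  names(w) <- labs
  if (is.character(spec) && length(spec) == 1L) {
    if (spec == "flat") {
      w[] <- 1
    } else if (spec == "tobacco_like") {
      ca <- grep("C>A", labs, fixed = TRUE)
      # graded context preference inside C>A; 3' A/C contexts heavier
      pref <- rep(c(2.0, 1.5, 0.7, 0.8), times = 4)
      w[ca] <- 0.70 * pref / sum(pref)
      w[grep("C>T", labs, fixed = TRUE)] <- 0.12 / 16
      w[grep("C>G", labs, fixed = TRUE)] <- 0.06 / 16
      w[grep("T>A", labs, fixed = TRUE)] <- 0.05 / 16
      w[grep("T>C", labs, fixed = TRUE)] <- 0.04 / 16
      w[grep("T>G", labs, fixed = TRUE)] <- 0.03 / 16
    } else if (spec == "uv_like") {
      ct <- grep("^[CT]\\[C>T\\]", labs)
      w[ct] <- 0.90 / length(ct)
      w[setdiff(seq_len(96), ct)] <- 0.10 / (96 - length(ct))
    } else {
      stop(sprintf("unknown signature profile '%s'", spec))
    }
  } else {
    spec <- unlist(spec)
    if (any(spec < 0)) stop("signature weights must be non-negative")
    if (!is.null(names(spec)) && any(nzchar(names(spec)))) {
      bad <- setdiff(names(spec), labs)
      if (length(bad)) stop("unknown channel label(s): ",
                            paste(bad, collapse = ", "))
      w[names(spec)] <- spec
    } else {
      if (length(spec) != 96L) stop("unnamed weights must have length 96")
      w[] <- spec
    }
  }
  if (sum(w) <= 0) stop("signature weights sum to zero")
  w / sum(w)
}

#' Configuration of the synthetic tumor cohort generator
#'
#' Defaults emulate a small carcinogen-exposure cohort: four tumor samples
#' whose mutations are drawn from a mixture dominated by one tobacco-like
#' (C>A-rich) signature plus a flat background, with transcriptional strand
#' bias on C>A inside genes, observed through three imperfect variant callers
#' with caller-private false positives and germline contamination shared by
#' every caller and every sample.
#'
#' @param genome_length Genome size in bases.
#' @param gc_fraction Genome GC proportion.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_mean Mean gene length (bases).
#' @param n_samples Cohort size.
#' @param signatures List of 96-vectors (each sums to 1).
#' @param exposures `n_samples` x `length(signatures)` matrix of mixture
#'   weights; rows sum to 1.
#' @param strand_bias Named numeric over the six substitution classes: the
#'   odds `r` of placing the pyrimidine on the untranscribed (coding) vs
#'   transcribed (template) strand inside genes; `r = 1` means no bias.
#' @param n_mutations_per_sample Somatic mutations planted per sample.
#' @param caller_sensitivity Named per-caller detection probabilities.
#' @param n_false_positives_per_caller Caller-private false SNVs per sample.
#' @param n_germline Germline variants injected into every caller and sample.
#' @param n_panel_decoys Extra panel entries matching nothing.
#' @param seed Global integer seed; stage seeds are derived by fixed offsets.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(genome_length = 100000,
                              gc_fraction = 0.42,
                              n_genes = 40,
                              gene_length_mean = 1000,
                              n_samples = 4,
                              signatures = list(
                                tobacco_like = gen_signature("tobacco_like"),
                                flat = gen_signature("flat")
                              ),
                              exposures = NULL,
                              strand_bias = c("C>A" = 2, "C>G" = 1, "C>T" = 1,
                                              "T>A" = 1, "T>C" = 1, "T>G" = 1),
                              n_mutations_per_sample = 2000,
                              caller_sensitivity = c(strelka2 = 0.9,
                                                     varscan2 = 0.9,
                                                     mutect2 = 0.9),
                              n_false_positives_per_caller = 100,
                              n_germline = 50,
                              n_panel_decoys = 50,
                              seed = 1L) {
  if (is.null(exposures)) {
    exposures <- matrix(rep(c(0.85, rep(0.15 / max(1, length(signatures) - 1),
                                        length(signatures) - 1)),
                            each = n_samples),
                        nrow = n_samples)
    if (length(signatures) == 1L) exposures <- matrix(1, nrow = n_samples)
  }
  exposures <- as.matrix(exposures)
  cfg <- list(
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes), gene_length_mean = gene_length_mean,
    n_samples = as.integer(n_samples), signatures = signatures,
    exposures = exposures, strand_bias = strand_bias,
    n_mutations_per_sample = as.integer(n_mutations_per_sample),
    caller_sensitivity = caller_sensitivity,
    n_false_positives_per_caller = as.integer(n_false_positives_per_caller),
    n_germline = as.integer(n_germline),
    n_panel_decoys = as.integer(n_panel_decoys),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$genome_length >= 1000,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$n_samples >= 1, cfg$n_mutations_per_sample >= 0,
            cfg$n_false_positives_per_caller >= 0, cfg$n_germline >= 0)
  if (any(cfg$caller_sensitivity < 0) || any(cfg$caller_sensitivity > 1)) {
    stop("caller sensitivities must lie in [0, 1]")
  }
  for (s in cfg$signatures) {
    if (length(s) != 96L || any(s < 0) || abs(sum(s) - 1) > 1e-9) {
      stop("each signature must be a non-negative 96-vector summing to 1")
    }
  }
  if (nrow(cfg$exposures) != cfg$n_samples ||
      ncol(cfg$exposures) != length(cfg$signatures)) {
    stop("exposures must be n_samples x n_signatures")
  }
  if (any(cfg$exposures < 0) ||
      any(abs(rowSums(cfg$exposures) - 1) > 1e-9)) {
    stop("exposure rows must be non-negative and sum to 1")
  }
  if (any(cfg$strand_bias < 0)) stop("strand_bias ratios must be >= 0")
  invisible(cfg)
}

#' Simulate catalog count matrices directly from a signature mixture
#'
#' Draws each sample's channel counts multinomially from its signature
#' mixture — the distributional core of the cohort generator without genomic
#' placement. Useful for factorization benchmarks at scale.
#'
#' @param signatures List (or 96 x k matrix) of signatures.
#' @param exposures n_samples x k mixture weight matrix (rows sum to 1).
#' @param n_mutations Mutations per sample (scalar or per-sample vector).
#' @param seed Integer seed.
#' @param sample_names Optional column names.
#' @return 96 x n_samples integer matrix with channel-label rownames.
#' @export
simulate_catalog_matrix <- function(signatures, exposures, n_mutations, seed,
                                    sample_names = NULL) {
  W <- if (is.list(signatures)) do.call(cbind, signatures) else as.matrix(signatures)
  exposures <- as.matrix(exposures)
  n <- nrow(exposures)
  if (length(n_mutations) == 1L) n_mutations <- rep(n_mutations, n)
  M <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      p <- as.vector(W %*% exposures[i, ])
      as.integer(stats::rmultinom(1, n_mutations[i], p))
    }, integer(96))
  })
  rownames(M) <- sbs96_channels()
  colnames(M) <- sample_names %||% sprintf("sample%d", seq_len(n))
  M
}
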