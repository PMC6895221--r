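# Run `expr` under a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points go through
# this so that the package never perturbs the user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stage-specific seed from a global one by a fixed offset, kept
# inside the 32-bit signed integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical empty SNV table.
empty_snv <- function(sample = character(0)) {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), stringsAsFactors = FALSE)
}

snv_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

sort_snvs <- function(df) {
  df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
}
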