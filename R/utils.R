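# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed from a base seed plus string tags, so random
# streams are split per (generator, platform, replicate): adding a platform
# never perturbs another platform's draws.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483647L
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Columns of a log2ratio tibble that hold values (everything except the
# gene/probe identifier and any stratum annotation).
value_cols <- function(df) {
  setdiff(names(df), c("gene_symbol", "probe_id", "stratum"))
}

# Sample standard error with the single-observation convention se(x) = 0.
se0 <- function(x) {
  n <- length(x)
  if (n <= 1) return(0)
  sd(x) / sqrt(n)
}
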