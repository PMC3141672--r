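# Independent oracles used to check the package implementations. Each is a
# deliberately naive re-derivation (brute force, enumeration, closed form)
# kept separate from the code paths it verifies.

# All probe-transcript alignments with <= max_mm mismatches, via
# Biostrings::vmatchPattern (an implementation entirely separate from the
# package's seeded Hamming scan).
oracle_probe_hits <- function(probes, transcriptome, max_mm = 2L) {
  subj <- Biostrings::DNAStringSet(transcriptome$sequence)
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    pat <- probes$sequence[i]
    m <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mm,
                                   fixed = TRUE)
    for (t in seq_along(m)) {
      st <- Biostrings::startIndex(m)[[t]]
      if (is.null(st) || !length(st)) next
      # vmatchPattern can report out-of-bounds starts with mismatches
      st <- st[st >= 1 & st + nchar(pat) - 1 <= nchar(transcriptome$sequence[t])]
      if (!length(st)) next
      mm <- vapply(st, function(s) {
        ref <- substr(transcriptome$sequence[t], s, s + nchar(pat) - 1)
        sum(utf8ToInt(ref) != utf8ToInt(pat))
      }, numeric(1))
      keep <- mm <= max_mm
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        probe_id = probes$probe_id[i],
        transcript_id = transcriptome$transcript_id[t],
        gene_symbol = transcriptome$gene_symbol[t],
        start = st[keep] - 1L, mismatches = as.integer(mm[keep]))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(probe_id = character(), transcript_id = character(),
                          gene_symbol = character(), start = integer(),
                          mismatches = integer())
  }
  dplyr::arrange(out, probe_id, transcript_id, start)
}

# Direct evaluation of the position-weighted trimming rule.
oracle_trim <- function(read, adapter, max_cost = 1.0, max_tag = 18L,
                        min_overlap = 5L) {
  rlen <- nchar(read)
  alen <- nchar(adapter)
  rch <- strsplit(read, "")[[1]]
  ach <- strsplit(adapter, "")[[1]]
  for (s in 0:(rlen - min_overlap)) {
    l <- min(rlen - s, alen)
    if (l < min_overlap) break
    j <- seq_len(l) - 1L
    cost <- sum(((l - j) / l)[rch[s + j + 1L] != ach[j + 1L]])
    if (cost <= max_cost) return(substr(read, 1, min(s, max_tag)))
  }
  substr(read, 1, min(rlen, max_tag))
}

# Brute-force tag matching over every GATC anchor of every window: each tag
# is compared against the full anchor-substring table in one vectorized
# sweep (a padded character matrix; pad rows always mismatch and their
# excess is subtracted). Returns per-tag status, best mismatch count, and
# the gene for unambiguous tags.
oracle_tag_match <- function(tags, windows, max_mm = 2L, min_len = 10L) {
  anchor_w <- integer(0); anchor_s <- integer(0)
  for (w in seq_len(nrow(windows))) {
    m <- gregexpr("GATC", windows$window_sequence[w], fixed = TRUE)[[1]]
    if (m[1] == -1) next
    anchor_w <- c(anchor_w, rep(w, length(m)))
    anchor_s <- c(anchor_s, as.integer(m) - 1L)
  }
  avail <- nchar(windows$window_sequence[anchor_w]) - anchor_s
  maxlen <- 18L
  refs <- substr(windows$window_sequence[anchor_w], anchor_s + 1,
                 anchor_s + pmin(avail, maxlen))
  pad <- strrep("#", maxlen - nchar(refs))  # '#' mismatches every base
  refmat <- vapply(paste0(refs, pad),
                   function(r) utf8ToInt(r), integer(maxlen),
                   USE.NAMES = FALSE)
  genes <- windows$gene_symbol[anchor_w]
  res_status <- character(length(tags))
  res_mm <- rep(NA_integer_, length(tags))
  res_gene <- rep(NA_character_, length(tags))
  for (i in seq_along(tags)) {
    t <- nchar(tags[i])
    if (t < min_len) { res_status[i] <- "no_match"; next }
    tgv <- utf8ToInt(tags[i])
    mm <- colSums(refmat[seq_len(t), , drop = FALSE] != tgv) -
      pmax(t - avail, 0L)
    mm[pmin(t, avail) < min_len] <- max_mm + 1L
    best <- min(mm)
    if (best > max_mm) { res_status[i] <- "no_match"; next }
    g <- unique(genes[mm == best])
    res_mm[i] <- best
    if (length(g) > 1) {
      res_status[i] <- "ambiguous"
    } else {
      res_status[i] <- "unambiguous"
      res_gene[i] <- g
    }
  }
  tibble::tibble(tag = tags, status = res_status, mismatches = res_mm,
                 gene_symbol = res_gene)
}

# All permutations of a vector (recursive; for small n only).
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Full (G!)^k enumeration of rank-product null: returns for each observed
# rank-product value the expected count E of null RPs at or below it per
# permutation round.
oracle_rankprod_E <- function(ranks, rp_obs) {
  G <- nrow(ranks); k <- ncol(ranks)
  col_perms <- lapply(seq_len(k), function(j) all_perms(ranks[, j]))
  combos <- expand.grid(lapply(col_perms, seq_along))
  B <- nrow(combos)
  null_rp <- numeric(B * G)
  for (b in seq_len(B)) {
    m <- vapply(seq_len(k), function(j) col_perms[[j]][[combos[b, j]]],
                numeric(G))
    null_rp[((b - 1) * G + 1):(b * G)] <- exp(rowMeans(log(m)))
  }
  vapply(rp_obs, function(v) sum(null_rp <= v + 1e-9) / B, numeric(1))
}

# Direct O(N) running-sum GSEA enrichment score.
oracle_gsea_es <- function(metric, hit, weight_p = 1) {
  N <- length(metric)
  w <- abs(metric)^weight_p
  S <- sum(hit)
  tot <- sum(w[hit])
  step <- rep(-1 / (N - S), N)
  step[hit] <- if (tot == 0) 1 / S else w[hit] / tot
  prof <- cumsum(step)
  prof[which.max(abs(prof))]
}

# F statistic by literal RSS sums (loops, no shortcuts).
oracle_ga_f <- function(y) {
  rss0 <- 0; rss1 <- 0; df <- 0
  for (g in seq_len(nrow(y))) {
    obs <- y[g, !is.na(y[g, ])]
    rss0 <- rss0 + sum(obs^2)
    rss1 <- rss1 + sum((obs - mean(obs))^2)
    df <- df + length(obs) - 1
  }
  if (rss0 == 0) return(0)
  if (rss1 == 0) return(Inf)
  ((rss0 - rss1) / nrow(y)) / (rss1 / df)
}

# Exhaustive sign-flip p for the gene-set F, recomputing F per flip.
oracle_ga_p <- function(y) {
  n <- ncol(y)
  flips <- expand.grid(rep(list(c(-1, 1)), n))
  f_obs <- oracle_ga_f(y)
  f_null <- apply(flips, 1, function(e) {
    oracle_ga_f(sweep(y, 2, as.numeric(e), `*`))
  })
  mean(f_null >= f_obs - 1e-12)
}

# Small deterministic transcriptome for hand-built cases.
tiny_transcriptome <- function(seqs, genes = NULL) {
  n <- length(seqs)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(n))
  out <- tibble::tibble(
    transcript_id = sprintf("%s.t1", genes),
    gene_symbol = genes, sequence = seqs, has_polya = TRUE)
  class(out) <- c("transcriptome", class(out))
  out
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
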