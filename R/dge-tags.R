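#' Trim the 3' adapter from DGE reads with position-weighted costs
#'
#' Finds, for each read, the leftmost start `s` at which a prefix of the
#' adapter aligns with total mismatch cost at most `max_cost`, where a
#' mismatch at offset `j` of an aligned region of length `l` costs
#' `(l - j)/l` — errors near the read's 3' end are penalized less,
#' following the error distribution of sequencing-by-synthesis reads. The
#' read prefix before `s` is the tag. When no acceptable alignment exists
#' the read is truncated to the maximum tag length (18 nt). Alignments
#' shorter than 5 nt are not considered, and returned tags are capped at
#' 18 nt.
#'
#' @param reads Character vector of reads (each >= 10 nt).
#' @param adapter Adapter sequence (>= 5 nt).
#' @param max_cost Cost budget per alignment (default 1.0).
#' @return Character vector of trimmed tags.
#' @examples
#' trim_adapter("ACGTACGTACGTACGTAGGGGGAAAAACCCCC", "GGGGGAAAAACCCCC")
#' @export
trim_adapter <- function(reads, adapter, max_cost = 1.0) {
  if (nchar(adapter) < 5) stop("adapter must be at least 5 nt", call. = FALSE)
  if (any(nchar(reads) < 10)) stop("reads must be at least 10 nt",
                                   call. = FALSE)
  cpp_trim_adapter(reads, adapter, max_cost, 18L, 5L)
}

#' Build the DpnII reduced-complexity reference
#'
#' One tag window per GATC occurrence per transcript: the site plus up to
#' `flank` nt on either side, truncated at the transcript ends. The last
#' site of each transcript is flagged `is_3prime_most` — the site the
#' oligo-dT-anchored library actually samples.
#'
#' @param transcriptome A `transcriptome` tibble.
#' @param flank Flank length on each side of the site (default 36).
#' @return Tibble of class `tag_windows`: `window_id`, `transcript_id`,
#'   `gene_symbol`, `site_start` (0-based offset of GATC in the
#'   transcript), `window_start` (0-based), `window_sequence`,
#'   `site_offset` (0-based offset of GATC within the window),
#'   `is_3prime_most`.
#' @export
build_reduced_reference <- function(transcriptome, flank = 36L) {
  if (flank < 0) stop("flank must be non-negative", call. = FALSE)
  hits <- gregexpr("GATC", transcriptome$sequence, fixed = TRUE)
  sites <- lapply(hits, function(m) if (m[1] == -1) integer(0)
                  else as.integer(m) - 1L)  # 0-based
  n_sites <- lengths(sites)
  idx <- rep.int(seq_len(nrow(transcriptome)), n_sites)
  site0 <- unlist(sites)
  out <- if (length(site0)) {
    seqs <- transcriptome$sequence[idx]
    win_start <- pmax(site0 - flank, 0L)
    win_end <- pmin(site0 + 3L + flank, nchar(seqs) - 1L)
    is3p <- unlist(lapply(n_sites[n_sites > 0],
                          function(k) seq_len(k) == k))
    tibble::tibble(
      window_id = sprintf("%s|%d", transcriptome$transcript_id[idx], site0),
      transcript_id = transcriptome$transcript_id[idx],
      gene_symbol = transcriptome$gene_symbol[idx],
      site_start = site0,
      window_start = win_start,
      window_sequence = substring(seqs, win_start + 1L, win_end + 1L),
      site_offset = site0 - win_start,
      is_3prime_most = is3p)
  } else tibble::tibble()
  if (!nrow(out)) {
    out <- tibble::tibble(window_id = character(), transcript_id = character(),
                          gene_symbol = character(), site_start = integer(),
                          window_start = integer(),
                          window_sequence = character(),
                          site_offset = integer(), is_3prime_most = logical())
  }
  class(out) <- c("tag_windows", class(out))
  out
}

#' Canonical expected tag of a transcript
#'
#' The tag released by MmeI cleavage: the substring starting at the
#' 3'-most GATC, of length 17 or 18 (the site plus 13 or 14 nt). `NA` when
#' the transcript has no GATC or too few bases remain downstream.
#'
#' @param sequence A transcript sequence (character scalar).
#' @param tag_length 17 or 18.
#' @return The tag, or `NA_character_`.
#' @export
extract_expected_tag <- function(sequence, tag_length = 17L) {
  if (!tag_length %in% c(17L, 18L)) {
    stop("tag_length must be 17 or 18", call. = FALSE)
  }
  m <- gregexpr("GATC", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1) return(NA_character_)
  start <- max(as.integer(m))
  if (nchar(sequence) - start + 1L < tag_length) return(NA_character_)
  substr(sequence, start, start + tag_length - 1L)
}

#' Count trimmed tags against the reduced reference
#'
#' Each tag is matched ungapped at every GATC anchor inside every window,
#' over `min(tag length, bases available)` bases, keeping the minimal
#' achievable mismatch count up to `max_mismatches` (ties prefer the
#' longer alignment, then the 3'-most site). Tags whose best matches span
#' two or more gene symbols are ambiguous: they are tallied in the mapping
#' statistics but excluded from the count matrix. Unambiguous tags count
#' toward the matched window of their gene.
#'
#' @param tag_lists Named list of character vectors of trimmed tags, one
#'   per sample.
#' @param windows A `tag_windows` tibble from [build_reduced_reference()].
#' @param max_mismatches Maximum Hamming distance (default 2).
#' @return A list with `counts` — a tibble of class `tag_count_matrix`
#'   (`window_id`, `transcript_id`, `gene_symbol`, `is_3prime_most`, one
#'   column per sample; attribute `stage = "raw"`) — and `stats`, a
#'   [MappingStats] tibble (`sample`, `total`, `unambiguous`, `mm0`,
#'   `mm1`, `mm2`, `ambiguous`, `no_match`) satisfying
#'   `total = unambiguous + ambiguous + no_match` and
#'   `unambiguous = mm0 + mm1 + mm2`.
#' @export
count_tags <- function(tag_lists, windows, max_mismatches = 2L) {
  if (!nrow(windows)) stop("empty window set", call. = FALSE)
  anchors <- lapply(windows$window_sequence, function(w) {
    m <- gregexpr("GATC", w, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  })
  gene_idx <- as.integer(factor(windows$gene_symbol))
  samples <- names(tag_lists)
  if (is.null(samples)) samples <- sprintf("s%d", seq_along(tag_lists))
  counts <- matrix(0L, nrow = nrow(windows), ncol = length(tag_lists),
                   dimnames = list(windows$window_id, samples))
  stats <- vector("list", length(tag_lists))
  for (s in seq_along(tag_lists)) {
    tags <- tag_lists[[s]]
    utags <- unique(tags)
    n_per <- tabulate(match(tags, utags), nbins = length(utags))
    res <- cpp_match_tags(utags, windows$window_sequence, anchors,
                          gene_idx, windows$site_start,
                          windows$is_3prime_most,
                          as.integer(max_mismatches), 10L)
    unamb <- res$status == 0L
    amb <- res$status == 1L
    if (any(unamb)) {
      add <- tapply(n_per[unamb], res$window_idx[unamb], sum)
      counts[as.integer(names(add)), s] <-
        counts[as.integer(names(add)), s] + as.integer(add)
    }
    mm <- res$mismatches
    stats[[s]] <- tibble::tibble(
      sample = samples[s],
      total = length(tags),
      unambiguous = sum(n_per[unamb]),
      mm0 = sum(n_per[unamb & mm == 0L]),
      mm1 = sum(n_per[unamb & mm == 1L]),
      mm2 = sum(n_per[unamb & mm == 2L]),
      ambiguous = sum(n_per[amb]),
      no_match = sum(n_per[res$status == 2L]))
  }
  stats <- dplyr::bind_rows(stats)
  stopifnot(all(stats$total == stats$unambiguous + stats$ambiguous +
                  stats$no_match),
            all(stats$unambiguous == stats$mm0 + stats$mm1 + stats$mm2))
  out <- windows |>
    dplyr::select("window_id", "transcript_id", "gene_symbol",
                  "is_3prime_most") |>
    dplyr::bind_cols(tibble::as_tibble(counts))
  out <- set_stage(out, "raw")
  list(counts = out, stats = stats)
}

set_stage <- function(x, stage) {
  attr(x, "stage") <- stage
  if (!inherits(x, "tag_count_matrix")) {
    class(x) <- c("tag_count_matrix", class(x))
  }
  x
}

#' Processing stage of a tag count matrix
#' @param x A `tag_count_matrix`.
#' @return One of `"raw"`, `"filtered"`, `"normalized"`, `"gene-summed"`.
#' @export
count_stage <- function(x) attr(x, "stage")

count_cols <- function(x) {
  setdiff(names(x), c("window_id", "transcript_id", "gene_symbol",
                      "is_3prime_most"))
}

require_stage <- function(x, want) {
  if (!identical(count_stage(x), want)) {
    stop(sprintf("expected a '%s'-stage count matrix, got '%s'",
                 want, count_stage(x)), call. = FALSE)
  }
}

#' Filter windows below the per-gene mean-minus-standard-error level
#'
#' For every sample and gene the mean and standard error of the gene's
#' window counts are computed; a window row is removed when its count
#' falls below `mean - SE` in at least `ceil(fraction * n_samples)`
#' samples. Genes with a single window have SE defined as 0 and are never
#' removed; for two-window genes `mean - SE = min(count1, count2)`, so no
#' removal is possible there either.
#'
#' @param raw A raw-stage `tag_count_matrix`.
#' @param fraction Required fraction of samples (default 0.90).
#' @return The filtered matrix (stage `"filtered"`).
#' @export
filter_low_probes <- function(raw, fraction = 0.90) {
  require_stage(raw, "raw")
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  cols <- count_cols(raw)
  need <- ceiling(fraction * length(cols))
  below <- matrix(FALSE, nrow(raw), length(cols))
  for (j in seq_along(cols)) {
    x <- raw[[cols[j]]]
    grp <- split(seq_len(nrow(raw)), raw$gene_symbol)
    for (idx in grp) {
      mu <- mean(x[idx])
      se <- se0(x[idx])
      # tolerance guards the two-window identity mean - SE = min(x): a
      # window is only removed when strictly below the cutoff
      below[idx, j] <- x[idx] < mu - se - 1e-9 * (1 + abs(mu))
    }
  }
  keep <- rowSums(below) < need
  set_stage(raw[keep, , drop = FALSE], "filtered")
}

#' Normalize samples to the median library total
#'
#' Each sample's counts are scaled by `median(all totals) / (its total)`,
#' so every post-normalization total equals the median total.
#'
#' @param filtered A filtered-stage `tag_count_matrix`.
#' @return The normalized matrix (stage `"normalized"`).
#' @export
normalize_totals <- function(filtered) {
  require_stage(filtered, "filtered")
  cols <- count_cols(filtered)
  totals <- vapply(cols, function(cn) sum(filtered[[cn]]), numeric(1))
  if (any(totals == 0)) {
    stop(sprintf("sample '%s' has zero total counts",
                 cols[which(totals == 0)[1]]), call. = FALSE)
  }
  med <- median(totals)
  out <- filtered
  for (cn in cols) out[[cn]] <- out[[cn]] * (med / sum(out[[cn]]))
  set_stage(out, "normalized")
}

#' Sum window counts to gene level
#'
#' One row per gene symbol; per-sample column totals are conserved.
#'
#' @param normalized A normalized-stage `tag_count_matrix`.
#' @return Gene-summed matrix (stage `"gene-summed"`): `gene_symbol` plus
#'   sample columns.
#' @export
sum_by_gene <- function(normalized) {
  require_stage(normalized, "normalized")
  cols <- count_cols(normalized)
  out <- normalized |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), sum)) |>
    dplyr::arrange(.data$gene_symbol)
  set_stage(out, "gene-summed")
}

#' Paired log2ratios from gene-summed tag counts
#'
#' `log2((treated + pseudocount) / (control + pseudocount))` per pair; a
#' cell is missing when both counts are zero (the gene was simply not
#' observed in that pair).
#'
#' @param gene_counts A gene-summed `tag_count_matrix`.
#' @param pairs Tibble or data frame with columns `control`, `treated`
#'   (sample labels) and optionally `label` for the output column names.
#' @param pseudocount Added to both counts (default 0.5).
#' @param platform_id Prefix for output column labels (default `"DGE"`).
#' @return Gene-level log2ratio tibble: `gene_symbol` plus one column per
#'   pair.
#' @export
dge_log2ratio <- function(gene_counts, pairs, pseudocount = 0.5,
                          platform_id = "DGE") {
  require_stage(gene_counts, "gene-summed")
  labs <- if ("label" %in% names(pairs)) pairs$label else
    sprintf("%s:r%d", platform_id, seq_len(nrow(pairs)))
  out <- tibble::tibble(gene_symbol = gene_counts$gene_symbol)
  for (i in seq_len(nrow(pairs))) {
    ctrl <- pairs$control[i]; trt <- pairs$treated[i]
    if (!ctrl %in% names(gene_counts) || !trt %in% names(gene_counts)) {
      stop(sprintf("unknown sample label in pair %d (%s, %s)", i, ctrl, trt),
           call. = FALSE)
    }
    c0 <- gene_counts[[ctrl]]; c1 <- gene_counts[[trt]]
    v <- log2((c1 + pseudocount) / (c0 + pseudocount))
    v[c0 == 0 & c1 == 0] <- NA_real_
    out[[labs[i]]] <- v
  }
  out
}

#' Write mapping statistics as TSV
#'
#' Row labels mirror a sequencing-run summary: total reads, unambiguous
#' (by 0/1/2 mismatches), ambiguous, no matches.
#'
#' @param stats MappingStats tibble from [count_tags()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_stats <- function(stats, path) {
  long <- tibble::tibble(
    statistic = c("total reads", "unambiguous", "0 mismatches",
                  "1 mismatch", "2 mismatches", "ambiguous", "no matches"))
  for (i in seq_len(nrow(stats))) {
    long[[stats$sample[i]]] <- c(stats$total[i], stats$unambiguous[i],
                                 stats$mm0[i], stats$mm1[i], stats$mm2[i],
                                 stats$ambiguous[i], stats$no_match[i])
  }
  readr::write_tsv(long, path)
  invisible(path)
}

#' Write tag windows as FASTA with structured headers
#'
#' Headers are `transcript_id|gene|site|site_offset`.
#'
#' @param windows A `tag_windows` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  seqs <- Biostrings::DNAStringSet(windows$window_sequence)
  names(seqs) <- sprintf("%s|%s|%d|%d", windows$transcript_id,
                         windows$gene_symbol, windows$site_start,
                         windows$site_offset)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
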