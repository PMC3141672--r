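#' Generate a synthetic gene-symbol-annotated transcriptome
#'
#' Builds a reference transcriptome of random transcripts, one per gene (or
#' more with `isoforms_per_gene`), each annotated with a HUGO-like gene
#' symbol. DpnII recognition sites (`GATC`) are planted explicitly: a
#' transcript carries at least one site with probability `dpn_site_prob` and
#' is otherwise guaranteed GATC-free, so the "gene undetectable by tag
#' sequencing because it lacks DpnII sites" case is represented at a known
#' rate.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Integer pair, inclusive range of transcript lengths
#'   (minimum 60 nt).
#' @param dpn_site_prob Probability that a transcript carries at least one
#'   GATC site.
#' @param isoforms_per_gene Transcripts per gene (default 1).
#' @param seed Integer seed; the same seed reproduces the transcriptome
#'   byte for byte.
#' @return A tibble of class `transcriptome` with columns `transcript_id`,
#'   `gene_symbol`, `sequence`, `has_polya`.
#' @examples
#' tx <- generate_transcriptome(5, seed = 1)
#' tx$gene_symbol
#' @export
generate_transcriptome <- function(n_genes, length_range = c(200L, 800L),
                                   dpn_site_prob = 0.95,
                                   isoforms_per_gene = 1L, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] < 60 ||
      length_range[2] < length_range[1]) {
    stop("length_range must be an increasing pair with minimum >= 60",
         call. = FALSE)
  }
  if (dpn_site_prob < 0 || dpn_site_prob > 1) {
    stop("dpn_site_prob must be a probability", call. = FALSE)
  }
  width <- max(4L, nchar(as.character(n_genes)))
  symbols <- sprintf(paste0("SYNG%0", width, "d"), seq_len(n_genes))
  with_seed(derive_seed(seed, "transcriptome"), {
    n_tx <- n_genes * isoforms_per_gene
    ids <- character(n_tx)
    gsym <- character(n_tx)
    seqs <- character(n_tx)
    k <- 0L
    for (g in seq_len(n_genes)) {
      for (iso in seq_len(isoforms_per_gene)) {
        k <- k + 1L
        len <- sample(length_range[1]:length_range[2], 1L)
        seqc <- random_gatc_free(len)
        if (runif(1) < dpn_site_prob) {
          n_sites <- 1L + rpois(1L, 1.2)
          seqc <- plant_gatc(seqc, n_sites)
        }
        ids[k] <- sprintf("%s.t%d", symbols[g], iso)
        gsym[k] <- symbols[g]
        seqs[k] <- seqc
      }
    }
    out <- tibble::tibble(transcript_id = ids, gene_symbol = gsym,
                          sequence = seqs, has_polya = TRUE)
    class(out) <- c("transcriptome", class(out))
    out
  })
}

# Random DNA with every GATC occurrence scrubbed (G -> C until none remain).
random_gatc_free <- function(len) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  while (grepl("GATC", s, fixed = TRUE)) {
    s <- sub("GATC", "CATC", s, fixed = TRUE)
  }
  s
}

# Overwrite n_sites non-overlapping GATC sites at random positions, keeping
# the 3'-most site at least 14 nt from the transcript end so a full 18-mer
# tag exists. Planting never creates accidental extra sites: positions are
# kept >= 4 apart and the backbone is GATC-free, but a plant boundary can in
# principle form a new GATC with flanking bases; those are scrubbed too.
plant_gatc <- function(s, n_sites) {
  len <- nchar(s)
  lo <- 1L
  hi <- len - 17L
  if (hi < lo) hi <- lo
  pos <- sort(sample(lo:hi, min(n_sites, hi - lo + 1L)))
  keep <- c(TRUE, diff(pos) >= 4L)
  pos <- pos[keep]
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p:(p + 3L)] <- c("G", "A", "T", "C")
  out <- paste(ch, collapse = "")
  # scrub accidental sites formed at plant boundaries, never the planted ones
  planted <- pos
  m <- gregexpr("GATC", out, fixed = TRUE)[[1]]
  if (m[1] != -1) {
    stray <- setdiff(as.integer(m), planted)
    if (length(stray)) {
      ch <- strsplit(out, "", fixed = TRUE)[[1]]
      for (p in stray) ch[p] <- "C"
      out <- paste(ch, collapse = "")
    }
  }
  out
}

#' Write a transcriptome (or any sequence tibble) to FASTA
#'
#' Headers carry the transcript id and `gene=<symbol>` so the file round
#' trips through [read_transcriptome_fasta()].
#'
#' @param transcriptome A `transcriptome` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  seqs <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(seqs) <- sprintf("%s gene=%s", transcriptome$transcript_id,
                         transcriptome$gene_symbol)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a transcriptome FASTA written by [write_transcriptome_fasta()]
#'
#' @param path FASTA path.
#' @return A `transcriptome` tibble.
#' @export
read_transcriptome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  out <- tibble::tibble(
    transcript_id = sub("\\s.*$", "", hdr),
    gene_symbol = stringr::str_match(hdr, "gene=(\\S+)")[, 2],
    sequence = as.character(seqs),
    has_polya = TRUE
  )
  class(out) <- c("transcriptome", class(out))
  out
}
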