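#' Simulate DGE tag-sequencing read libraries
#'
#' Emulates the DpnII/MmeI library protocol: each read is the canonical tag
#' of a transcript — the 17- or 18-mer starting at the transcript's 3'-most
#' GATC — followed by the 3' adapter, truncated to the read length.
#' Transcript sampling per library is multinomial with weights proportional
#' to `truth$base_abundance`, multiplied by `2^effect` in treated samples;
#' transcripts without a GATC site have weight zero and never produce
#' reads. Per-base substitution errors are applied at
#' `noise$seq_error_rate`.
#'
#' @param truth A `synthetic_truth`.
#' @param transcriptome A `transcriptome` tibble.
#' @param noise A [noise_model()]; `library_sizes` must have one entry per
#'   sample.
#' @param adapter 3' adapter sequence (>= 5 nt).
#' @param n_samples Number of libraries; samples alternate control/treated,
#'   giving `n_samples/2` pairs.
#' @param read_length Read length in nt (default 36).
#' @param seed Integer seed; streams are split per sample.
#' @return A list of class `dge_reads`: `samples` (tibble: `sample_id`,
#'   `condition`, `pair_id`, `library_size`), `reads` (named list of
#'   character vectors), and `tag_tally` (named list of per-transcript
#'   sampled counts, the generator's ground truth).
#' @export
generate_dge_reads <- function(truth, transcriptome, noise = noise_model(),
                               adapter = "TCGTATGCCGTCTTCTGCTTG",
                               n_samples = 6L, read_length = 36L, seed = 1L) {
  if (nchar(adapter) < 5) stop("adapter must be at least 5 nt", call. = FALSE)
  assert_dna(adapter, "adapter")
  if (length(noise$library_sizes) != n_samples) {
    stop("library_sizes must have one entry per sample", call. = FALSE)
  }
  if (n_samples %% 2 != 0) stop("n_samples must be even (paired design)",
                                call. = FALSE)
  eff <- setNames(truth$gene_effects$effect, truth$gene_effects$gene_symbol)
  tags17 <- vapply(transcriptome$sequence, extract_expected_tag, "",
                   tag_length = 17L, USE.NAMES = FALSE)
  tags18 <- vapply(transcriptome$sequence, extract_expected_tag, "",
                   tag_length = 18L, USE.NAMES = FALSE)
  usable <- !is.na(tags17)  # an 18-mer site always allows the 17-mer too
  w_base <- truth$base_abundance[transcriptome$gene_symbol]
  w_base[!usable] <- 0
  tx_eff <- eff[transcriptome$gene_symbol]
  pair_id <- rep(seq_len(n_samples / 2L), each = 2L)
  condition <- rep(c("control", "treated"), n_samples / 2L)
  sample_id <- sprintf("%s%d", ifelse(condition == "control", "C", "E"),
                       pair_id)
  reads <- vector("list", n_samples)
  tally <- vector("list", n_samples)
  names(reads) <- names(tally) <- sample_id
  for (s in seq_len(n_samples)) {
    w <- w_base
    if (condition[s] == "treated") w <- w * 2^tx_eff
    if (sum(w) == 0) stop("no transcript is sequenceable", call. = FALSE)
    w <- w / sum(w)
    with_seed(derive_seed(seed, "dge", sample_id[s]), {
      counts <- as.integer(rmultinom(1L, noise$library_sizes[s], w))
      idx <- rep.int(seq_along(counts), counts)
      use18 <- runif(length(idx)) < 0.5 & !is.na(tags18[idx])
      tag <- ifelse(use18, tags18[idx], tags17[idx])
      rd <- substr(paste0(tag, adapter), 1L, read_length)
      rd <- apply_seq_errors(rd, noise$seq_error_rate)
      reads[[s]] <- rd
      tally[[s]] <- setNames(counts, transcriptome$transcript_id)
    })
  }
  structure(list(
    samples = tibble::tibble(sample_id = sample_id, condition = condition,
                             pair_id = pair_id,
                             library_size = noise$library_sizes),
    reads = reads, tag_tally = tally), class = "dge_reads")
}

#' @export
print.dge_reads <- function(x, ...) {
  cat(sprintf("<dge_reads> %d samples (%s), %s reads total\n",
              nrow(x$samples), paste(x$samples$sample_id, collapse = " "),
              format(sum(lengths(x$reads)), big.mark = ",")))
  invisible(x)
}

# Independent per-base substitution errors at rate `rate`. Error positions
# and substitutions are drawn in R (deterministic under the caller's seed);
# the string surgery happens in C++.
apply_seq_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(reads)
  pos <- unlist(lapply(hit, function(i) sample.int(lens[i], n_err[i])))
  idx <- rep.int(hit, n_err[hit])
  pick <- sample.int(3L, length(idx), replace = TRUE)
  cpp_apply_errors(reads, idx, pos, pick)
}

#' Write DGE reads as FASTQ (Phred+33, constant quality)
#'
#' One `<sample_id>.fastq` file per sample under `dir`.
#'
#' @param dge A `dge_reads` object.
#' @param dir Output directory (created if missing).
#' @return Tibble of `sample_id`, `path`, invisibly.
#' @export
write_dge_fastq <- function(dge, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(dge$samples))
  for (s in seq_len(nrow(dge$samples))) {
    id <- dge$samples$sample_id[s]
    rd <- dge$reads[[id]]
    seqs <- Biostrings::DNAStringSet(rd)
    names(seqs) <- sprintf("%s_read%d", id, seq_along(rd))
    paths[s] <- file.path(dir, paste0(id, ".fastq"))
    Biostrings::writeXStringSet(
      seqs, paths[s], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(rd))))
  }
  invisible(tibble::tibble(sample_id = dge$samples$sample_id, path = paths))
}

#' Read a FASTQ file into a character vector of reads
#'
#' @param path FASTQ path (Phred+33).
#' @return Character vector of read sequences.
#' @export
read_fastq_reads <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}
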