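#' Noise model for the synthetic generators
#'
#' @param probe_sd Per-probe log2 noise standard deviation (>= 0).
#' @param replicate_sd Per-replicate biological noise standard deviation
#'   (>= 0), shared by all probes of a gene within one replicate.
#' @param seq_error_rate Per-base substitution error probability for DGE
#'   reads, in \[0, 0.1\].
#' @param library_sizes Positive integer read counts, one per DGE sample
#'   (control and treated alternating).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(probe_sd = 0.3, replicate_sd = 0.3,
                        seq_error_rate = 0.01,
                        library_sizes = rep(100000L, 6L)) {
  if (probe_sd < 0 || replicate_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (seq_error_rate < 0 || seq_error_rate > 0.1) {
    stop("seq_error_rate must lie in [0, 0.1]", call. = FALSE)
  }
  if (any(library_sizes < 1)) {
    stop("library_sizes must be positive integers", call. = FALSE)
  }
  structure(list(probe_sd = probe_sd, replicate_sd = replicate_sd,
                 seq_error_rate = seq_error_rate,
                 library_sizes = as.integer(library_sizes)),
            class = "noise_model")
}

#' Define the ground truth of a synthetic experiment
#'
#' Chooses the differentially expressed genes and their log2 effects, the
#' per-platform gene coverage, and the baseline transcript abundances. The
#' default design mirrors a three-microarray + tag-sequencing study: three
#' array platforms each covering a random ~90% of genes (so every coverage
#' stratum from the full intersection down to singletons is populated), and
#' a `DGE` pseudo-platform covering exactly the genes whose transcripts
#' contain a DpnII site.
#'
#' @param transcriptome A `transcriptome` tibble.
#' @param n_de Number of differentially expressed genes (half up, half
#'   down).
#' @param effect_min,effect_max Absolute log2 fold-change range for DE
#'   genes; treated/control abundance ratio is `2^effect`.
#' @param platforms Character vector of array platform ids.
#' @param coverage Fraction of genes covered by each array platform.
#' @param include_dge Add the `DGE` platform (coverage = genes with a GATC
#'   site)?
#' @param abundance_sd Log-scale standard deviation of baseline abundances.
#' @param seed Integer seed.
#' @return A list of class `synthetic_truth` with elements `gene_effects`
#'   (tibble: `gene_symbol`, `effect`, `direction`), `de_up`, `de_down`,
#'   `platform_coverage` (named list of gene-symbol vectors),
#'   `base_abundance` (named proportions summing to 1), `seed`.
#' @export
make_truth <- function(transcriptome, n_de = 200L,
                       effect_min = 1, effect_max = 1,
                       platforms = c("AGI", "OPE", "ILM"),
                       coverage = 0.9, include_dge = TRUE,
                       abundance_sd = 1.2, seed = 1L) {
  genes <- unique(transcriptome$gene_symbol)
  n <- length(genes)
  if (n_de > n) stop("n_de exceeds the number of genes", call. = FALSE)
  if (effect_min <= 0 || effect_max < effect_min) {
    stop("effect range must satisfy 0 < effect_min <= effect_max",
         call. = FALSE)
  }
  with_seed(derive_seed(seed, "truth"), {
    de <- sample(genes, n_de)
    n_up <- ceiling(n_de / 2)
    de_up <- de[seq_len(n_up)]
    de_down <- setdiff(de, de_up)
    eff <- setNames(numeric(n), genes)
    eff[de_up] <- runif(length(de_up), effect_min, effect_max)
    eff[de_down] <- -runif(length(de_down), effect_min, effect_max)
    cov <- list()
    for (p in platforms) {
      cov[[p]] <- sort(sample(genes, round(coverage * n)))
    }
    if (include_dge) {
      has_site <- transcriptome |>
        dplyr::group_by(.data$gene_symbol) |>
        dplyr::summarise(site = any(grepl("GATC", .data$sequence, fixed = TRUE)))
      cov[["DGE"]] <- sort(has_site$gene_symbol[has_site$site])
    }
    ab <- exp(rnorm(n, 0, abundance_sd))
    ab <- setNames(ab / sum(ab), genes)
    structure(list(
      gene_effects = tibble::tibble(
        gene_symbol = genes, effect = unname(eff),
        direction = dplyr::case_when(eff > 0 ~ "up", eff < 0 ~ "down",
                                     TRUE ~ "none")),
      de_up = de_up, de_down = de_down,
      platform_coverage = cov, base_abundance = ab, seed = seed),
      class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes, %d up / %d down, platforms: %s\n",
              nrow(x$gene_effects), length(x$de_up), length(x$de_down),
              paste(names(x$platform_coverage), collapse = ", ")))
  invisible(x)
}

#' Truth table as a tibble
#'
#' One row per gene: true effect and per-platform coverage flags, suitable
#' for writing as TSV next to generated data.
#'
#' @param truth A `synthetic_truth` object.
#' @return A tibble.
#' @export
truth_table <- function(truth) {
  out <- truth$gene_effects
  for (p in names(truth$platform_coverage)) {
    out[[paste0("on_", p)]] <- out$gene_symbol %in% truth$platform_coverage[[p]]
  }
  out
}

#' Simulate probe-level microarray data for one platform
#'
#' Emits a probe set (60-mers drawn from covered genes' transcripts) and a
#' probe-level log2ratio matrix over paired control/treated replicates. The
#' generating model is
#' `log2ratio(probe, rep) = effect(gene) + a(gene, rep) + b(probe, rep)`
#' with `a ~ N(0, replicate_sd^2)` shared across a gene's probes within a
#' replicate and `b ~ N(0, probe_sd^2)` independent per probe. A fraction
#' `bad_probe_fraction` of probes are cross-gene chimeras (half the probe
#' from another gene's transcript): they map to no single gene and exercise
#' the ambiguity/discard path downstream; their signal is pure noise.
#'
#' @param truth A `synthetic_truth`.
#' @param transcriptome A `transcriptome` tibble.
#' @param platform_id One of `names(truth$platform_coverage)`.
#' @param n_probes_per_gene Probes per covered gene.
#' @param n_replicates Paired biological replicates.
#' @param noise A [noise_model()].
#' @param probe_length Probe length in nt (default 60).
#' @param bad_probe_fraction Fraction of chimeric probes.
#' @param seed Integer seed; streams are split per platform.
#' @return A list with `probes` (tibble: `probe_id`, `platform_id`,
#'   `gene_symbol` as annotated, `origin_gene`, `sequence`, `is_bad`) and
#'   `ratios` (probe-level log2ratio tibble: `probe_id` plus one
#'   `<platform>:r<i>` column per replicate).
#' @export
generate_platform_data <- function(truth, transcriptome, platform_id,
                                   n_probes_per_gene = 2L, n_replicates = 3L,
                                   noise = noise_model(), probe_length = 60L,
                                   bad_probe_fraction = 0.05, seed = 1L) {
  if (!platform_id %in% names(truth$platform_coverage)) {
    stop(sprintf("unknown platform '%s'", platform_id), call. = FALSE)
  }
  covered <- truth$platform_coverage[[platform_id]]
  if (!length(covered)) stop("platform coverage set is empty", call. = FALSE)
  tx_by_gene <- split(transcriptome$sequence, transcriptome$gene_symbol)
  eff <- setNames(truth$gene_effects$effect, truth$gene_effects$gene_symbol)
  with_seed(derive_seed(seed, "platform", platform_id), {
    m <- n_probes_per_gene
    gene <- rep(covered, each = m)
    n_probe <- length(gene)
    # pick one isoform per probe, then a random substring of it
    src <- vapply(gene, function(g) {
      seqs <- tx_by_gene[[g]]
      seqs[[sample.int(length(seqs), 1L)]]
    }, character(1), USE.NAMES = FALSE)
    src_len <- nchar(src)
    if (any(src_len < probe_length)) {
      stop("transcript shorter than probe length", call. = FALSE)
    }
    start <- 1L + floor(runif(n_probe) * (src_len - probe_length + 1L))
    probe <- substr(src, start, start + probe_length - 1L)
    bad <- runif(n_probe) < bad_probe_fraction
    origin <- gene
    if (any(bad)) {
      all_genes <- names(tx_by_gene)
      half <- probe_length %/% 2L
      for (i in which(bad)) {
        other_g <- sample(setdiff(all_genes, gene[i]), 1L)
        other <- tx_by_gene[[other_g]][[1L]]
        probe[i] <- paste0(substr(probe[i], 1L, half),
                           random_substring(other, probe_length - half))
        origin[i] <- NA_character_
      }
    }
    probes <- tibble::tibble(
      probe_id = sprintf("%s_%s_p%d", platform_id, gene,
                         rep(seq_len(m), times = length(covered))),
      platform_id = platform_id, gene_symbol = gene, origin_gene = origin,
      sequence = probe, is_bad = bad)
    n_probe <- nrow(probes)
    rep_noise <- matrix(rnorm(length(covered) * n_replicates,
                              0, noise$replicate_sd),
                        nrow = length(covered),
                        dimnames = list(covered, NULL))
    vals <- matrix(0, nrow = n_probe, ncol = n_replicates)
    gene_effect <- ifelse(probes$is_bad, 0, eff[probes$gene_symbol])
    for (r in seq_len(n_replicates)) {
      vals[, r] <- gene_effect + rep_noise[probes$gene_symbol, r] +
        rnorm(n_probe, 0, noise$probe_sd)
    }
    colnames(vals) <- sprintf("%s:r%d", platform_id, seq_len(n_replicates))
    ratios <- tibble::tibble(probe_id = probes$probe_id) |>
      dplyr::bind_cols(tibble::as_tibble(vals))
    list(probes = probes, ratios = ratios)
  })
}

random_substring <- function(s, len) {
  n <- nchar(s)
  if (n < len) stop("transcript shorter than probe length", call. = FALSE)
  start <- sample.int(n - len + 1L, 1L)
  substr(s, start, start + len - 1L)
}

#' Write a probe set to FASTA
#'
#' Headers are `platform|probe_id gene=<annotated symbol>`.
#'
#' @param probes Probe tibble from [generate_platform_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  seqs <- Biostrings::DNAStringSet(probes$sequence)
  names(seqs) <- sprintf("%s|%s gene=%s", probes$platform_id,
                         probes$probe_id, probes$gene_symbol)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a probe FASTA written by [write_probe_fasta()]
#'
#' @param path FASTA path.
#' @return A tibble with `probe_id`, `platform_id`, `gene_symbol`,
#'   `sequence`.
#' @export
read_probe_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  lead <- sub("\\s.*$", "", hdr)
  tibble::tibble(
    probe_id = sub("^[^|]*\\|", "", lead),
    platform_id = sub("\\|.*$", "", lead),
    gene_symbol = stringr::str_match(hdr, "gene=(\\S+)")[, 2],
    sequence = as.character(seqs))
}
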