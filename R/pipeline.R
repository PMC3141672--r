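#' Simulate a complete multi-platform study
#'
#' Convenience wrapper chaining the generators: a transcriptome, a ground
#' truth, probe-level data for each array platform and DGE read libraries,
#' all from one seed. The defaults mirror the reference design: three
#' array platforms plus tag sequencing, three paired replicates each.
#'
#' @param n_genes Genes in the reference transcriptome.
#' @param n_de Differentially expressed genes (half up, half down).
#' @param effect_min,effect_max Absolute log2 effect range.
#' @param platforms Array platform ids.
#' @param coverage Array coverage fraction.
#' @param include_dge Simulate DGE libraries too?
#' @param n_replicates Paired replicates per platform.
#' @param noise A [noise_model()].
#' @param n_probes_per_gene Probes per covered gene on each array.
#' @param bad_probe_fraction Chimeric probe fraction.
#' @param adapter DGE 3' adapter.
#' @param dpn_site_prob Probability a transcript carries a GATC site.
#' @param seed Integer seed.
#' @return List of class `sim_study`: `transcriptome`, `truth`,
#'   `platform_data` (named list of [generate_platform_data()] outputs),
#'   `dge` (a `dge_reads` or `NULL`), `adapter`, `seed`.
#' @export
simulate_study <- function(n_genes = 2000L, n_de = 200L, effect_min = 1,
                           effect_max = 1,
                           platforms = c("AGI", "OPE", "ILM"),
                           coverage = 0.9, include_dge = TRUE,
                           n_replicates = 3L, noise = noise_model(),
                           n_probes_per_gene = 2L, bad_probe_fraction = 0.05,
                           adapter = "TCGTATGCCGTCTTCTGCTTG",
                           dpn_site_prob = 0.95, seed = 1L) {
  tx <- generate_transcriptome(n_genes, dpn_site_prob = dpn_site_prob,
                               seed = seed)
  truth <- make_truth(tx, n_de = n_de, effect_min = effect_min,
                      effect_max = effect_max, platforms = platforms,
                      coverage = coverage, include_dge = include_dge,
                      seed = seed)
  pdata <- lapply(setNames(platforms, platforms), function(p) {
    generate_platform_data(truth, tx, p,
                           n_probes_per_gene = n_probes_per_gene,
                           n_replicates = n_replicates, noise = noise,
                           bad_probe_fraction = bad_probe_fraction,
                           seed = seed)
  })
  dge <- if (include_dge) {
    generate_dge_reads(truth, tx, noise = noise, adapter = adapter,
                       n_samples = 2L * n_replicates, seed = seed)
  } else NULL
  structure(list(transcriptome = tx, truth = truth, platform_data = pdata,
                 dge = dge, adapter = adapter, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d genes, platforms: %s%s, seed %d\n",
              nrow(x$transcriptome),
              paste(names(x$platform_data), collapse = ", "),
              if (!is.null(x$dge)) " + DGE" else "", x$seed))
  invisible(x)
}

#' Run the cross-platform processing pipeline on a simulated study
#'
#' Per array platform: map probes to the transcriptome, discard ambiguous
#' probes, aggregate probe log2ratios to gene level by the median. For the
#' DGE libraries: trim adapters, build the DpnII reduced reference, count
#' tags, filter low windows, normalize to the median total, sum to gene
#' level and form paired log2ratios. Finally all gene-level matrices are
#' merged into the coverage-stratified matrix.
#'
#' @param sim A `sim_study`.
#' @param config An [analysis_config()].
#' @return List of class `study_matrices`: `gene_matrices` (named list,
#'   one gene-level log2ratio tibble per platform incl. `DGE`), `merged`
#'   (the `merged_matrix`), `dge_counts` (gene-summed counts or `NULL`),
#'   `mapping_stats`, `windows`.
#' @export
process_study <- function(sim, config = analysis_config()) {
  gene_matrices <- list()
  for (p in names(sim$platform_data)) {
    pd <- sim$platform_data[[p]]
    hits <- map_probes(pd$probes, sim$transcriptome)
    assignment <- assign_genes(hits)
    gene_matrices[[p]] <- summarize_gene(pd$ratios, assignment)
  }
  dge_counts <- NULL
  stats <- NULL
  windows <- NULL
  if (!is.null(sim$dge)) {
    trimmed <- lapply(sim$dge$reads, trim_adapter, adapter = sim$adapter)
    windows <- build_reduced_reference(sim$transcriptome,
                                       flank = config$flank)
    counted <- count_tags(trimmed, windows)
    stats <- counted$stats
    norm <- counted$counts |>
      filter_low_probes(fraction = config$filter_fraction) |>
      normalize_totals()
    dge_counts <- sum_by_gene(norm)
    pairs <- sim$dge$samples |>
      tidyr::pivot_wider(id_cols = "pair_id", names_from = "condition",
                         values_from = "sample_id") |>
      dplyr::mutate(label = sprintf("DGE:r%d", .data$pair_id))
    gene_matrices[["DGE"]] <- dge_log2ratio(dge_counts, pairs)
  }
  merged <- build_merged_matrix(gene_matrices)
  structure(list(gene_matrices = gene_matrices, merged = merged,
                 dge_counts = dge_counts, mapping_stats = stats,
                 windows = windows),
            class = "study_matrices")
}

#' @export
print.study_matrices <- function(x, ...) {
  cat(sprintf("<study_matrices> platforms: %s; merged: %d genes in %d strata\n",
              paste(names(x$gene_matrices), collapse = ", "),
              nrow(x$merged), length(unique(x$merged$stratum))))
  invisible(x)
}
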