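#' Map probe sequences to a reference transcriptome
#'
#' Every ungapped sense-strand alignment of each probe against each
#' transcript with Hamming distance at most `max_mismatches` is reported
#' (up to 2 mismatches, accommodating probe-design-era sequence divergence
#' from the reference). Matching is exhaustive over all start positions; a
#' probe longer than every transcript simply yields no hits.
#'
#' @param probes Tibble with at least `probe_id` and `sequence` columns
#'   (plus anything else, carried along by id).
#' @param transcriptome A `transcriptome` tibble.
#' @param max_mismatches Maximum Hamming distance (0-2).
#' @return Tibble of hits: `probe_id`, `transcript_id`, `gene_symbol`,
#'   `start` (0-based), `mismatches`.
#' @examples
#' tx <- generate_transcriptome(10, seed = 3)
#' probes <- tibble::tibble(probe_id = "p1",
#'                          sequence = substr(tx$sequence[1], 11, 70))
#' map_probes(probes, tx)
#' @export
map_probes <- function(probes, transcriptome, max_mismatches = 2L) {
  if (max_mismatches < 0 || max_mismatches > 2) {
    stop("max_mismatches must be between 0 and 2", call. = FALSE)
  }
  assert_dna(probes$sequence, "probe sequence")
  assert_dna(transcriptome$sequence, "transcript sequence")
  hits <- cpp_probe_hits(probes$sequence, transcriptome$sequence,
                         as.integer(max_mismatches))
  tibble::tibble(
    probe_id = probes$probe_id[hits$probe_idx],
    transcript_id = transcriptome$transcript_id[hits$tx_idx],
    gene_symbol = transcriptome$gene_symbol[hits$tx_idx],
    start = hits$start,
    mismatches = hits$mismatches)
}

#' Assign probes to genes, discarding ambiguous probes
#'
#' A probe is assigned if and only if all of its hits share a single gene
#' symbol; multiple hits within one gene (isoforms, repeated sequence) are
#' fine. Probes hitting two or more gene symbols, or nothing at all, are
#' dropped.
#'
#' @param hits Hit tibble from [map_probes()].
#' @return Tibble `probe_id`, `gene_symbol` — the unambiguous assignments.
#' @export
assign_genes <- function(hits) {
  hits |>
    dplyr::distinct(.data$probe_id, .data$gene_symbol) |>
    dplyr::add_count(.data$probe_id, name = "n_genes") |>
    dplyr::filter(.data$n_genes == 1L) |>
    dplyr::select("probe_id", "gene_symbol")
}

#' Aggregate a probe-level log2ratio matrix to gene level
#'
#' Each gene/column cell is the median of the gene's probes' values in that
#' column, ignoring missing values; the cell is missing only when every
#' contributing probe is missing. Even probe counts take the arithmetic
#' mean of the two central values. Probes absent from `assignment` are
#' dropped.
#'
#' @param ratios Probe-level tibble: `probe_id` plus value columns.
#' @param assignment Tibble `probe_id`, `gene_symbol` from
#'   [assign_genes()].
#' @return Gene-level tibble: `gene_symbol` plus the same value columns.
#' @export
summarize_gene <- function(ratios, assignment) {
  cols <- value_cols(ratios)
  joined <- dplyr::inner_join(assignment, ratios, by = "probe_id")
  if (!nrow(joined)) {
    return(tibble::tibble(gene_symbol = character(0)) |>
             dplyr::bind_cols(ratios[0, cols, drop = FALSE]))
  }
  joined |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(cols),
      ~ if (all(is.na(.x))) NA_real_ else median(.x, na.rm = TRUE))) |>
    dplyr::arrange(.data$gene_symbol)
}

#' Build the coverage-stratified merged matrix across platforms
#'
#' Genes are partitioned by their exact platform-coverage signature — the
#' set of platforms whose gene-level matrix contains them — ordered from
#' the full intersection down to singletons. Within a stratum only the
#' covering platforms' columns carry values; the other platforms' columns
#' are missing by construction, never imputed. The partition is verified on
#' every build: strata are disjoint and cover the union of all platforms'
#' genes.
#'
#' @param gene_matrices Named list of gene-level log2ratio tibbles, one per
#'   platform (names are the platform ids; column names must be
#'   `<platform>:<replicate>`).
#' @return Tibble of class `merged_matrix`: `stratum` (signature string,
#'   platforms joined by `|`), `gene_symbol`, then all platforms' value
#'   columns.
#' @export
build_merged_matrix <- function(gene_matrices) {
  if (!length(gene_matrices)) stop("need at least one platform matrix",
                                   call. = FALSE)
  if (is.null(names(gene_matrices)) || any(names(gene_matrices) == "")) {
    stop("gene_matrices must be a named list (platform ids)", call. = FALSE)
  }
  platforms <- names(gene_matrices)
  for (p in platforms) {
    g <- gene_matrices[[p]]$gene_symbol
    if (anyDuplicated(g)) {
      stop(sprintf("duplicate gene within platform '%s'", p), call. = FALSE)
    }
  }
  union_genes <- sort(unique(unlist(lapply(gene_matrices,
                                           function(m) m$gene_symbol))))
  sig_mat <- vapply(platforms,
                    function(p) union_genes %in% gene_matrices[[p]]$gene_symbol,
                    logical(length(union_genes)))
  if (length(union_genes) == 1L) sig_mat <- matrix(sig_mat, nrow = 1L)
  signature <- apply(sig_mat, 1L, function(z) paste(platforms[z],
                                                    collapse = "|"))
  n_platforms <- rowSums(sig_mat)
  base <- tibble::tibble(gene_symbol = union_genes, stratum = signature,
                         .n_plat = n_platforms)
  wide <- base
  for (p in platforms) {
    wide <- dplyr::left_join(wide, gene_matrices[[p]],
                             by = "gene_symbol")
  }
  out <- wide |>
    dplyr::arrange(dplyr::desc(.n_plat), .data$stratum, .data$gene_symbol) |>
    dplyr::select(-".n_plat") |>
    dplyr::relocate("stratum", "gene_symbol")
  # partition invariant: disjoint strata covering the union
  stopifnot(!anyDuplicated(out$gene_symbol),
            setequal(out$gene_symbol, union_genes))
  attr(out, "platforms") <- platforms
  class(out) <- c("merged_matrix", class(out))
  out
}

#' Platform ids covering each stratum of a merged matrix
#'
#' @param merged A `merged_matrix`.
#' @return Named list: stratum signature -> character vector of platforms.
#' @export
strata_platforms <- function(merged) {
  sigs <- unique(merged$stratum)
  setNames(strsplit(sigs, "|", fixed = TRUE), sigs)
}

#' Write / read log2ratio and merged matrices as TSV
#'
#' @param x A tibble (gene- or probe-level matrix, or `merged_matrix`).
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
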