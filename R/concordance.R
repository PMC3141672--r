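#' Build a deterministic ranked gene list
#'
#' Sorted by metric descending; ties broken lexicographically by gene
#' symbol so construction is reproducible.
#'
#' @param genes Character vector of gene symbols.
#' @param metric Numeric sorting key (e.g. mean log2ratio), same length.
#' @return Tibble of class `ranked_list`: `gene_symbol`, `metric`, in rank
#'   order.
#' @export
ranked_list <- function(genes, metric) {
  stopifnot(length(genes) == length(metric), !anyDuplicated(genes))
  ord <- order(-metric, genes)
  out <- tibble::tibble(gene_symbol = genes[ord], metric = metric[ord])
  class(out) <- c("ranked_list", class(out))
  out
}

#' Ranked list from a log2ratio matrix by mean value
#'
#' @param mat Gene-level log2ratio tibble.
#' @return A [ranked_list()] keyed by the per-gene mean of the value
#'   columns (missing values ignored).
#' @export
rank_by_mean <- function(mat) {
  m <- rowMeans(as.matrix(mat[, value_cols(mat)]), na.rm = TRUE)
  ranked_list(mat$gene_symbol, m)
}

# ES from sorted hit positions: O(|S|). wvec = |metric|^p over the ranked
# universe, miss decrement = 1/(N - |S|). Candidate extrema sit right after
# each hit and right before each hit; the profile ends at exactly 0.
es_from_positions <- function(pos, wvec, N) {
  S <- length(pos)
  w <- wvec[pos]
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / S else w <- w / tot
  miss <- 1 / (N - S)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(S)) * miss
  before <- c(0, cw[-S]) - (pos - seq_len(S)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Gene set enrichment analysis (weighted running-sum statistic)
#'
#' Walks the ranked list: genes in the set add `|metric|^p`, normalized to
#' sum to one over the set; genes outside subtract `1/(N - |S|)`. The
#' enrichment score ES is the signed extremum of this running sum. The
#' null distribution relabels the gene set — random sets of equal size —
#' because with three paired replicates per platform phenotype permutation
#' is degenerate. NES is ES divided by the mean absolute null ES of
#' matching sign; the nominal p is the matching-sign exceedance fraction
#' (and, for a single-set call, doubles as the FDR estimate).
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of gene symbols (a strict, non-empty
#'   subset of the ranked universe after intersection).
#' @param weight_p Weighting exponent (default 1).
#' @param n_permutations Null set count.
#' @param seed Integer seed.
#' @return List of class `gsea_result`: `ES`, `NES`, `nominal_p`, `fdr_q`,
#'   `running_profile`, `hit_positions`, `n_hits`, `n_permutations`.
#' @export
gsea <- function(ranked, gene_set, weight_p = 1, n_permutations = 1000L,
                 seed = 1L) {
  N <- nrow(ranked)
  hit <- ranked$gene_symbol %in% gene_set
  S <- sum(hit)
  if (S == 0) stop("gene_set does not intersect the ranked list",
                   call. = FALSE)
  if (S >= N) stop("gene_set must be a strict subset of the universe",
                   call. = FALSE)
  wvec <- abs(ranked$metric)^weight_p
  pos <- which(hit)
  w <- wvec[pos]
  tot <- sum(w)
  inc <- if (tot == 0) rep(1 / S, S) else w / tot
  step <- rep(-1 / (N - S), N)
  step[pos] <- inc
  profile <- cumsum(step)
  ES <- profile[which.max(abs(profile))]
  null_es <- with_seed(derive_seed(seed, "gsea"), {
    vapply(seq_len(n_permutations), function(b) {
      es_from_positions(sort(sample.int(N, S)), wvec, N)
    }, numeric(1))
  })
  if (ES >= 0) {
    same <- null_es[null_es >= 0]
    p <- if (length(same)) mean(same >= ES) else 0
    NES <- if (length(same) && mean(same) > 0) ES / mean(same) else NA_real_
  } else {
    same <- null_es[null_es < 0]
    p <- if (length(same)) mean(same <= ES) else 0
    NES <- if (length(same)) ES / mean(abs(same)) else NA_real_
  }
  structure(list(ES = ES, NES = NES, nominal_p = p, fdr_q = p,
                 running_profile = profile, hit_positions = pos,
                 n_hits = S, n_permutations = n_permutations),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.4f, NES = %.3f, p = %.4g (%d hits / %d genes)\n",
              x$ES, x$NES, x$nominal_p, x$n_hits,
              length(x$running_profile)))
  invisible(x)
}

#' @export
tidy.gsea_result <- function(x, ...) {
  tibble::tibble(position = seq_along(x$running_profile),
                 running_es = x$running_profile,
                 is_hit = seq_along(x$running_profile) %in% x$hit_positions)
}

#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(ES = x$ES, NES = x$NES, nominal_p = x$nominal_p,
                 fdr_q = x$fdr_q, n_hits = x$n_hits,
                 n_permutations = x$n_permutations)
}

#' Concordance-at-the-top curve
#'
#' For each list size n, the proportion of genes shared between the two
#' rankings' top-n lists.
#'
#' @param list_a,list_b [ranked_list()]s over a shared gene universe.
#' @param max_n Largest n (clipped to the smaller universe with a
#'   warning).
#' @return Tibble of class `cat_curve`: `n`, `concordance`.
#' @export
cat_curve <- function(list_a, list_b, max_n) {
  limit <- min(nrow(list_a), nrow(list_b))
  if (max_n > limit) {
    warning(sprintf("max_n clipped from %d to the universe size %d",
                    max_n, limit))
    max_n <- limit
  }
  a <- list_a$gene_symbol
  b <- list_b$gene_symbol
  # incremental top-set intersection: O(max_n) set updates
  in_a <- new.env(hash = TRUE, parent = emptyenv())
  in_b <- new.env(hash = TRUE, parent = emptyenv())
  shared <- 0L
  out <- numeric(max_n)
  for (n in seq_len(max_n)) {
    ga <- a[n]; gb <- b[n]
    if (identical(ga, gb)) {
      shared <- shared + 1L
    } else {
      if (exists(ga, envir = in_b, inherits = FALSE)) shared <- shared + 1L
      if (exists(gb, envir = in_a, inherits = FALSE)) shared <- shared + 1L
    }
    assign(ga, TRUE, envir = in_a)
    assign(gb, TRUE, envir = in_b)
    out[n] <- shared / n
  }
  res <- tibble::tibble(n = seq_len(max_n), concordance = out)
  class(res) <- c("cat_curve", class(res))
  res
}

#' Venn region counts for 2-4 gene lists
#'
#' Counts every non-empty membership pattern; zero-count regions are
#' reported too, and the counts always sum to the union size.
#'
#' @param lists Named list of 2-4 character vectors.
#' @return Tibble: one logical column per input list, `region` (pattern
#'   label) and `count`.
#' @export
overlap_summary <- function(lists) {
  k <- length(lists)
  if (k < 2 || k > 4) stop("need 2-4 lists", call. = FALSE)
  if (is.null(names(lists))) names(lists) <- sprintf("list%d", seq_len(k))
  universe <- unique(unlist(lists))
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-2^k, , drop = FALSE]
  names(patterns) <- names(lists)
  pat_key <- apply(patterns, 1, paste, collapse = "")
  obs_key <- apply(member, 1, paste, collapse = "")
  counts <- vapply(pat_key, function(kk) sum(obs_key == kk), integer(1))
  out <- tibble::as_tibble(patterns)
  out$region <- apply(patterns, 1, function(z)
    paste(names(lists)[unlist(z)], collapse = "&"))
  out$count <- unname(counts)
  stopifnot(sum(out$count) == length(universe))
  out
}

#' Detection-level-stratified correlation of tag and array log2ratios
#'
#' Pearson correlation between per-gene DGE log2ratio (mean over pairs)
#' and the mean microarray log2ratio, over all genes with any tag counts,
#' and again over genes reaching `threshold` counts in at least one
#' sample. Strata with fewer than 3 shared genes yield `NA` rather than an
#' error.
#'
#' @param dge Gene-level DGE log2ratio tibble.
#' @param array_mean Gene-level log2ratio tibble whose value columns are
#'   averaged (unweighted) per gene.
#' @param gene_counts Gene-summed `tag_count_matrix`.
#' @param threshold Detection level in counts (default 32).
#' @return Tibble: `r_all`, `r_above`, `n_all`, `n_above`.
#' @export
stratified_correlation <- function(dge, array_mean, gene_counts,
                                   threshold = 32L) {
  dge_m <- rowMeans(as.matrix(dge[, value_cols(dge)]), na.rm = TRUE)
  arr_m <- rowMeans(as.matrix(array_mean[, value_cols(array_mean)]),
                    na.rm = TRUE)
  cnt <- as.matrix(gene_counts[, count_cols(gene_counts)])
  any_count <- gene_counts$gene_symbol[rowSums(cnt) > 0]
  above <- gene_counts$gene_symbol[apply(cnt >= threshold, 1, any)]
  shared_all <- Reduce(intersect, list(dge$gene_symbol,
                                       array_mean$gene_symbol, any_count))
  shared_above <- intersect(shared_all, above)
  cor_or_na <- function(genes) {
    if (length(genes) < 3) return(NA_real_)
    x <- dge_m[match(genes, dge$gene_symbol)]
    y <- arr_m[match(genes, array_mean$gene_symbol)]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    cor(x[ok], y[ok])
  }
  tibble::tibble(r_all = cor_or_na(shared_all),
                 r_above = cor_or_na(shared_above),
                 n_all = length(shared_all),
                 n_above = length(shared_above))
}
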