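#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline: the linear fold-change
#' gate (1.2), the adjusted-p gate (0.05), permutation counts, the SAM
#' fudge factor, the tag detection level (32 counts), the pathway
#' significance gate (Holm-adjusted 0.01) and the network edge threshold
#' (2 shared regulated genes).
#'
#' @param fc_threshold Linear fold-change threshold (> 1).
#' @param p_threshold Adjusted-p threshold for DE calls.
#' @param n_permutations Monte-Carlo permutation count.
#' @param seed Integer seed for all stochastic operations.
#' @param s0 SAM fudge factor, a number or `"auto"` (median of the
#'   per-gene standard errors).
#' @param detection_count Tag-count detection level for stratified
#'   correlation.
#' @param pathway_alpha Holm-adjusted significance gate for pathways.
#' @param min_shared Minimum shared regulated genes for a network edge.
#' @param flank DpnII window flank length.
#' @param filter_fraction Sample fraction for the low-count window filter.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fc_threshold = 1.2, p_threshold = 0.05,
                            n_permutations = 1000L, seed = 1L, s0 = "auto",
                            detection_count = 32L, pathway_alpha = 0.01,
                            min_shared = 2L, flank = 36L,
                            filter_fraction = 0.90) {
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1", call. = FALSE)
  if (p_threshold <= 0 || pathway_alpha <= 0) {
    stop("significance thresholds must be positive", call. = FALSE)
  }
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), s0 = s0,
                 detection_count = as.integer(detection_count),
                 pathway_alpha = pathway_alpha,
                 min_shared = as.integer(min_shared),
                 flank = as.integer(flank),
                 filter_fraction = filter_fraction),
            class = "analysis_config")
}

#' Benjamini-Hochberg and Holm adjustment
#'
#' Thin wrappers over [stats::p.adjust()]: BH is the step-up
#' false-discovery-rate procedure with monotonicity enforcement, Holm the
#' step-down family-wise procedure; both restore the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))
#' holm_adjust(c(0.001, 0.02))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  p.adjust(p, method = "BH")
}

#' @rdname bh_adjust
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  p.adjust(p, method = "holm")
}

#' One-sample SAM-style permutation test per gene
#'
#' For paired log2ratios the hypothesis is a zero mean per gene. The
#' statistic is `d = mean(y) / (se(y) + s0)` with the fudge factor `s0`
#' stabilizing small standard errors (`"auto"` = median of all genes'
#' standard errors). The null is the sign-flip distribution: full
#' enumeration of the `2^n` flip assignments when `n <= 12`, Monte-Carlo
#' otherwise; p is two-sided against each gene's own null, q is BH across
#' genes. Genes with fewer than two observed values are excluded (their
#' number is reported via a warning).
#'
#' @param mat Gene-level log2ratio tibble (`gene_symbol` + value columns)
#'   for one platform.
#' @param config An [analysis_config()].
#' @return Tibble of class `sam_result`: `gene_symbol`, `n`, `mean`, `se`,
#'   `d`, `p`, `q`.
#' @export
sam_test <- function(mat, config = analysis_config()) {
  cols <- value_cols(mat)
  y <- as.matrix(mat[, cols])
  nobs <- rowSums(!is.na(y))
  drop <- nobs < 2
  if (any(drop)) {
    warning(sprintf("%d gene(s) with fewer than 2 values excluded",
                    sum(drop)))
  }
  y <- y[!drop, , drop = FALSE]
  genes <- mat$gene_symbol[!drop]
  nobs <- nobs[!drop]
  mu <- rowMeans(y, na.rm = TRUE)
  ss <- rowSums(y^2, na.rm = TRUE)
  v <- (ss - nobs * mu^2) / (nobs - 1)
  v[v < 0] <- 0  # numerical guard
  se <- sqrt(v) / sqrt(nobs)
  s0 <- if (identical(config$s0, "auto")) median(se) else config$s0
  d <- mu / (se + s0)
  p <- numeric(length(genes))
  for (n in unique(nobs)) {
    sel <- which(nobs == n)
    yn <- y[sel, , drop = FALSE]
    # columns observed can differ between genes with equal n; handle via NA->0
    y0 <- yn; y0[is.na(y0)] <- 0
    flips <- if (n <= 12) {
      sign_matrix(ncol(y))
    } else {
      with_seed(derive_seed(config$seed, "sam", "mc", n),
                matrix(sample(c(-1, 1), ncol(y) * config$n_permutations,
                              replace = TRUE), nrow = ncol(y)))
    }
    mu_star <- (y0 %*% flips) / n
    v_star <- (ss[sel] - n * mu_star^2) / (n - 1)
    v_star[v_star < 0] <- 0
    d_star <- mu_star / (sqrt(v_star) / sqrt(n) + s0)
    p[sel] <- rowMeans(abs(d_star) >= abs(d[sel]) - 1e-12)
  }
  out <- tibble::tibble(gene_symbol = genes, n = nobs, mean = mu, se = se,
                        d = d, p = p, q = bh_adjust(p))
  class(out) <- c("sam_result", class(out))
  attr(out, "s0") <- s0
  out
}

# All 2^n sign vectors as an n x 2^n matrix.
sign_matrix <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t(unname(g))
}

rank_one_column <- function(x, direction) {
  if (direction == "up") {
    x <- ifelse(is.na(x), -Inf, x)
    rank(-x, ties.method = "average")
  } else {
    x <- ifelse(is.na(x), Inf, x)
    rank(x, ties.method = "average")
  }
}

#' Rank product of genes across paired comparisons
#'
#' Genes are ranked 1..G per column — by decreasing value for direction
#' `"up"`, increasing for `"down"` — with average ranks for ties and
#' missing values ranked last (worst in the tested direction). The rank
#' product is the geometric mean of a gene's ranks; it depends only on the
#' within-column orderings, so it is invariant under any strictly monotone
#' per-column transform.
#'
#' @param mat Log2ratio tibble (`gene_symbol` + value columns).
#' @param direction `"up"` or `"down"`.
#' @return Tibble `gene_symbol`, `rank_product`.
#' @export
rank_product <- function(mat, direction = c("up", "down")) {
  direction <- match.arg(direction)
  cols <- value_cols(mat)
  y <- as.matrix(mat[, cols])
  if (nrow(y) < 2) stop("need at least 2 genes", call. = FALSE)
  all_missing <- vapply(seq_len(ncol(y)), function(j) all(is.na(y[, j])),
                        logical(1))
  if (any(all_missing)) {
    stop(sprintf("column '%s' is entirely missing", cols[which(all_missing)[1]]),
         call. = FALSE)
  }
  ranks <- vapply(seq_len(ncol(y)),
                  function(j) rank_one_column(y[, j], direction),
                  numeric(nrow(y)))
  tibble::tibble(gene_symbol = mat$gene_symbol,
                 rank_product = exp(rowMeans(log(ranks))))
}

#' Permutation significance of rank products
#'
#' The null is generated by independent uniform permutations of the
#' observed ranks within each column. `E` is the expected number of null
#' rank products at or below a gene's observed value per permutation
#' round, `pfp = E / rank position of the gene` (the proportion of false
#' prediction, an FDR-like quantity), and the nominal p is `min(1, E/G)`.
#' For G <= 5 genes and at most 3 columns the null is computed exactly
#' (equivalent to full enumeration of all rank-matrix permutations);
#' otherwise `config$n_permutations` Monte-Carlo rounds are used.
#'
#' @param mat Log2ratio tibble (`gene_symbol` + value columns).
#' @param direction `"up"` or `"down"`.
#' @param config An [analysis_config()]; `n_permutations >= 100` in
#'   Monte-Carlo mode.
#' @param stream Extra tag mixed into the random stream (used by
#'   [meta_rankprod()] to decorrelate strata).
#' @param mode `"auto"` (exhaustive for G <= 5 genes and <= 3 columns,
#'   Monte-Carlo otherwise), or force `"exhaustive"` (G <= 8, k <= 4) or
#'   `"montecarlo"`.
#' @return Tibble `gene_symbol`, `rank_product`, `E`, `pfp`, `nominal_p`.
#' @export
rankprod_significance <- function(mat, direction = c("up", "down"),
                                  config = analysis_config(), stream = "",
                                  mode = c("auto", "exhaustive",
                                           "montecarlo")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  rp <- rank_product(mat, direction)
  cols <- value_cols(mat)
  y <- as.matrix(mat[, cols])
  G <- nrow(y); k <- ncol(y)
  ranks <- vapply(seq_len(k), function(j) rank_one_column(y[, j], direction),
                  numeric(G))
  if (G == 1 || k == 0) stop("degenerate matrix", call. = FALSE)
  log_rp <- log(rp$rank_product)
  if (mode == "auto") {
    mode <- if (G <= 5 && k <= 3) "exhaustive" else "montecarlo"
  }
  if (mode == "exhaustive" && (G > 8 || k > 4)) {
    stop("exhaustive mode supports at most 8 genes and 4 columns",
         call. = FALSE)
  }
  if (mode == "exhaustive") {
    # exact: over all column permutations a gene's rank is uniform over the
    # observed ranks, independently per column; enumerate the G^k grid
    grid <- as.matrix(expand.grid(lapply(seq_len(k),
                                         function(j) log(ranks[, j]))))
    null_log <- rowMeans(grid)
    E <- vapply(log_rp, function(v) G * mean(null_log <= v + 1e-9),
                numeric(1))
  } else {
    B <- config$n_permutations
    if (B < 100) stop("n_permutations must be >= 100 in Monte-Carlo mode",
                      call. = FALSE)
    log_ranks <- log(ranks)
    null_log <- numeric(B * G)
    with_seed(derive_seed(config$seed, "rankprod", direction, stream), {
      for (b in seq_len(B)) {
        acc <- numeric(G)
        for (j in seq_len(k)) acc <- acc + log_ranks[sample.int(G), j]
        null_log[((b - 1) * G + 1):(b * G)] <- acc / k
      }
    })
    null_sorted <- sort(null_log)
    E <- findInterval(log_rp + 1e-9, null_sorted) / B
  }
  pos <- rank(rp$rank_product, ties.method = "average")
  tibble::tibble(gene_symbol = rp$gene_symbol,
                 rank_product = rp$rank_product,
                 E = E, pfp = E / pos, nominal_p = pmin(1, E / G))
}

#' RankProd meta-analysis over platform-coverage strata
#'
#' Runs the rank-product permutation test independently within each
#' coverage stratum of the merged matrix (using only the covering
#' platforms' columns), in both directions; pools the nominal p-values
#' over the union of all genes (both directions jointly) and BH-adjusts
#' them; and calls a gene regulated when its adjusted p is below
#' `config$p_threshold` **and** its median linear fold change — `2^(median
#' log2ratio across all its measurements)` — exceeds `fc_threshold` (up)
#' or falls below `1/fc_threshold` (down). Strata with fewer than two
#' genes are skipped with a warning.
#'
#' @param merged A `merged_matrix` from [build_merged_matrix()].
#' @param config An [analysis_config()].
#' @return Object of class `meta_rankprod`: a list with `results` (tibble:
#'   `gene_symbol`, `direction`, `rank_product`, `E`, `pfp`, `nominal_p`,
#'   `adjusted_p`, `median_fc`, `stratum`, `n_columns`, `called`) and
#'   `config`. Use [tidy()] / [glance()] / [called_genes()].
#' @export
meta_rankprod <- function(merged, config = analysis_config()) {
  if (!nrow(merged)) stop("empty merged matrix", call. = FALSE)
  platforms <- attr(merged, "platforms")
  all_cols <- value_cols(merged)
  col_platform <- sub(":.*$", "", all_cols)
  res <- list()
  for (sig in unique(merged$stratum)) {
    block <- merged[merged$stratum == sig, , drop = FALSE]
    cover <- strsplit(sig, "|", fixed = TRUE)[[1]]
    cols <- all_cols[col_platform %in% cover]
    if (nrow(block) < 2) {
      warning(sprintf("stratum '%s' has fewer than 2 genes; skipped", sig))
      next
    }
    sub <- block[, c("gene_symbol", cols)]
    med_l2 <- apply(as.matrix(sub[, cols]), 1, median, na.rm = TRUE)
    for (dir in c("up", "down")) {
      r <- rankprod_significance(sub, dir, config, stream = sig)
      r$direction <- dir
      r$stratum <- sig
      r$n_columns <- length(cols)
      r$median_fc <- 2^med_l2
      res[[paste(sig, dir)]] <- r
    }
  }
  results <- dplyr::bind_rows(res)
  results$adjusted_p <- bh_adjust(results$nominal_p)
  fc <- config$fc_threshold
  results$called <- results$adjusted_p < config$p_threshold &
    ((results$direction == "up" & results$median_fc > fc) |
       (results$direction == "down" & results$median_fc < 1 / fc))
  results <- results |>
    dplyr::relocate("gene_symbol", "direction", "rank_product", "E", "pfp",
                    "nominal_p", "adjusted_p", "median_fc", "stratum",
                    "n_columns", "called")
  structure(list(results = results, config = config),
            class = "meta_rankprod")
}

#' Regulated genes called by the meta-analysis
#'
#' @param x A `meta_rankprod` object.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return Character vector of gene symbols.
#' @export
called_genes <- function(x, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  r <- x$results[x$results$called, ]
  if (direction != "both") r <- r[r$direction == direction, ]
  sort(unique(r$gene_symbol))
}

#' @export
print.meta_rankprod <- function(x, ...) {
  up <- length(called_genes(x, "up"))
  dn <- length(called_genes(x, "down"))
  cat(sprintf(
    "<meta_rankprod> %d genes in %d strata; %d up / %d down called (adjusted p < %g, |FC| > %g)\n",
    length(unique(x$results$gene_symbol)),
    length(unique(x$results$stratum)), up, dn,
    x$config$p_threshold, x$config$fc_threshold))
  invisible(x)
}

#' @export
tidy.meta_rankprod <- function(x, ...) x$results

#' @export
glance.meta_rankprod <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$results$gene_symbol)),
    n_strata = length(unique(x$results$stratum)),
    n_up = length(called_genes(x, "up")),
    n_down = length(called_genes(x, "down")),
    p_threshold = x$config$p_threshold,
    fc_threshold = x$config$fc_threshold)
}

#' @export
tidy.sam_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), s0 = attr(x, "s0"),
                 n_q05 = sum(x$q < 0.05))
}

#' Write a DE result table as TSV
#'
#' @param x A `meta_rankprod` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
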