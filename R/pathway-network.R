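#' One-group GlobalAncova F statistic for a gene-set block
#'
#' Paired log2ratios reduce the two-group gene-set model to a one-group
#' hypothesis: all gene means are zero. The statistic compares the
#' residual sums of squares of the null model (`RSS0 = sum y^2`) and the
#' gene-means model (`RSS1 = sum (y - gene mean)^2`):
#' `F = ((RSS0 - RSS1)/|S|) / (RSS1 / sum(n_g - 1))`. Rows with missing
#' cells use their available columns (per-gene `n_g`). `RSS1 = 0` with
#' `RSS0 > 0` yields `Inf`; an all-zero block yields 0.
#'
#' @param y Numeric matrix, genes in rows, paired comparisons in columns
#'   (missing allowed, no fully-missing row), at least 2 columns.
#' @return The F statistic (non-negative, possibly `Inf`).
#' @examples
#' globalancova_f(rbind(c(1, 2, 3), c(0, 0, 0)))  # 12
#' @export
globalancova_f <- function(y) {
  y <- as.matrix(y)
  if (ncol(y) < 2) stop("need at least 2 columns", call. = FALSE)
  n_g <- rowSums(!is.na(y))
  if (any(n_g == 0)) stop("fully-missing gene row", call. = FALSE)
  rss0 <- sum(y^2, na.rm = TRUE)
  mu <- rowMeans(y, na.rm = TRUE)
  rss1 <- sum((y - mu)^2, na.rm = TRUE)
  if (rss0 == 0) return(0)
  if (rss1 == 0) return(Inf)
  ((rss0 - rss1) / nrow(y)) / (rss1 / sum(n_g - 1))
}

#' Sign-flip permutation p-value for the gene-set F statistic
#'
#' The null flips the sign of whole columns — the same flip vector applied
#' to every gene — preserving the gene-gene correlation the test's theory
#' requires. Exhaustive mode enumerates all `2^n` flip vectors and reports
#' the exact exceedance fraction; Monte-Carlo mode draws `B` flips and
#' reports `(1 + #{F* >= F}) / (1 + B)`.
#'
#' @param y Numeric matrix (genes x columns).
#' @param mode `"exhaustive"` (n <= 16) or `"montecarlo"`.
#' @param B Monte-Carlo flip count (>= 100).
#' @param seed Integer seed (Monte-Carlo mode).
#' @return Nominal p-value.
#' @export
globalancova_p <- function(y, mode = c("exhaustive", "montecarlo"),
                           B = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  y <- as.matrix(y)
  n <- ncol(y)
  f_obs <- globalancova_f(y)
  if (mode == "exhaustive") {
    if (n > 16) stop("exhaustive mode supports at most 16 columns",
                     call. = FALSE)
    flips <- sign_matrix(n)
    f_null <- flip_f(y, flips)
    mean(f_null >= f_obs - 1e-12)
  } else {
    if (B < 100) stop("B must be >= 100 in Monte-Carlo mode", call. = FALSE)
    flips <- with_seed(derive_seed(seed, "ga"), {
      matrix(sample(c(-1, 1), n * B, replace = TRUE), nrow = n)
    })
    f_null <- flip_f(y, flips)
    (1 + sum(f_null >= f_obs - 1e-12)) / (1 + B)
  }
}

# F statistics for all sign-flip vectors at once. RSS0 and per-gene sums of
# squares are flip-invariant; only the gene means move:
# mean*_g = (1/n_g) sum_j eps_j y_gj over observed cells.
flip_f <- function(y, flips) {
  y0 <- y
  y0[is.na(y0)] <- 0
  n_g <- rowSums(!is.na(y))
  rss0 <- sum(y^2, na.rm = TRUE)
  if (rss0 == 0) return(rep(0, ncol(flips)))
  mu_star <- (y0 %*% flips) / n_g
  rss1 <- rss0 - colSums(mu_star^2 * n_g)
  rss1[rss1 < 0] <- 0
  num <- (rss0 - rss1) / nrow(y)
  den <- rss1 / sum(n_g - 1)
  out <- num / den
  out[rss1 == 0] <- Inf
  out
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: id, description/name, then member gene symbols.
#'
#' @param path GMT file path.
#' @return `read_gmt`: tibble `pathway_id`, `name`, `genes` (list-column).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  ids <- vapply(lines, `[`, "", 1L)
  names_ <- vapply(lines, function(x) if (length(x) >= 2) x[2] else "", "")
  tibble::tibble(pathway_id = ids, name = names_,
                 genes = unname(sets[ids]))
}

#' @rdname read_gmt
#' @param pathways Tibble as returned by `read_gmt` (or with `genes` as a
#'   named list).
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$name[i],
            pathways$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' GlobalAncova-style testing of a pathway collection
#'
#' Tests each pathway with at least one gene in the supplied matrix —
#' conventionally the all-platform intersection stratum of the merged
#' matrix, where every gene is measured on every column — computing the
#' one-group F and its sign-flip p (exhaustive when the column count
#' allows, Monte-Carlo otherwise), then Holm-adjusts across tested
#' pathways (a deliberately conservative family-wise correction, since
#' the test is sensitive). Each result carries the pathway's regulated
#' genes: the intersection with the meta-analysis called set.
#'
#' @param mat Gene-level log2ratio tibble (`gene_symbol` + value
#'   columns); typically `intersection_stratum(merged)`.
#' @param pathways Tibble from [read_gmt()] (`pathway_id`, `name`,
#'   `genes` list-column).
#' @param de A `meta_rankprod` object (or a character vector of regulated
#'   genes).
#' @param config An [analysis_config()].
#' @return Tibble of class `pathway_results`: `pathway_id`, `name`,
#'   `n_genes_in_data`, `F`, `nominal_p`, `holm_p`, `significant`,
#'   `regulated_genes` (list-column), `n_regulated`.
#' @export
test_pathways <- function(mat, pathways, de, config = analysis_config()) {
  if (!nrow(pathways)) stop("empty pathway collection", call. = FALSE)
  called <- if (inherits(de, "meta_rankprod")) called_genes(de) else de
  cols <- value_cols(mat)
  y_all <- as.matrix(mat[, cols])
  rownames(y_all) <- mat$gene_symbol
  n <- length(cols)
  rows <- vector("list", nrow(pathways))
  n_skipped <- 0L
  for (i in seq_len(nrow(pathways))) {
    genes <- intersect(pathways$genes[[i]], mat$gene_symbol)
    if (!length(genes)) { n_skipped <- n_skipped + 1L; next }
    y <- y_all[genes, , drop = FALSE]
    f <- globalancova_f(y)
    p <- if (n <= 12) {
      globalancova_p(y, "exhaustive")
    } else {
      globalancova_p(y, "montecarlo", B = config$n_permutations,
                     seed = derive_seed(config$seed, "pathway",
                                        pathways$pathway_id[i]))
    }
    reg <- intersect(pathways$genes[[i]], called)
    rows[[i]] <- tibble::tibble(
      pathway_id = pathways$pathway_id[i], name = pathways$name[i],
      n_genes_in_data = length(genes), F = f, nominal_p = p,
      regulated_genes = list(sort(reg)), n_regulated = length(reg))
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("no pathway overlaps the matrix", call. = FALSE)
  out$holm_p <- holm_adjust(out$nominal_p)
  out$significant <- out$holm_p < config$pathway_alpha
  out <- dplyr::relocate(out, "pathway_id", "name", "n_genes_in_data", "F",
                         "nominal_p", "holm_p", "significant")
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("pathway_results", class(out))
  out
}

#' All-platform intersection stratum of a merged matrix
#'
#' @param merged A `merged_matrix`.
#' @return Gene-level tibble restricted to genes measured on every
#'   platform.
#' @export
intersection_stratum <- function(merged) {
  platforms <- attr(merged, "platforms")
  full <- paste(platforms, collapse = "|")
  out <- merged[merged$stratum == full, setdiff(names(merged), "stratum")]
  tibble::as_tibble(out)
}

#' Build the pathway-interconnectivity network
#'
#' Nodes are the significant pathways; two nodes are joined when they
#' share at least `min_shared` regulated genes, with the shared count as
#' edge weight. Isolated significant pathways remain as degree-0 nodes.
#' `connections` is the sum of a node's incident edge weights (its
#' weighted degree); `degree` the number of incident edges.
#'
#' @param results A `pathway_results` tibble.
#' @param min_shared Minimum shared regulated genes for an edge.
#' @return List of class `pathway_network`: `nodes` (tibble:
#'   `pathway_id`, `name`, `F`, `holm_p`, `n_regulated`, `degree`,
#'   `connections`) and `edges` (tibble: `from`, `to`, `shared`).
#' @export
build_network <- function(results, min_shared = 2L) {
  sig <- results[results$significant, , drop = FALSE]
  ids <- sig$pathway_id
  edges <- tibble::tibble(from = character(), to = character(),
                          shared = integer())
  if (nrow(sig) >= 2) {
    pair_idx <- combn(nrow(sig), 2)
    shared <- apply(pair_idx, 2, function(ij) {
      length(intersect(sig$regulated_genes[[ij[1]]],
                       sig$regulated_genes[[ij[2]]]))
    })
    keep <- shared >= min_shared
    edges <- tibble::tibble(from = ids[pair_idx[1, keep]],
                            to = ids[pair_idx[2, keep]],
                            shared = as.integer(shared[keep]))
  }
  degree <- setNames(integer(length(ids)), ids)
  connections <- setNames(integer(length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    degree[edges$from[i]] <- degree[edges$from[i]] + 1L
    degree[edges$to[i]] <- degree[edges$to[i]] + 1L
    connections[edges$from[i]] <- connections[edges$from[i]] + edges$shared[i]
    connections[edges$to[i]] <- connections[edges$to[i]] + edges$shared[i]
  }
  nodes <- tibble::tibble(pathway_id = ids, name = sig$name, F = sig$F,
                          holm_p = sig$holm_p,
                          n_regulated = sig$n_regulated,
                          degree = unname(degree),
                          connections = unname(connections))
  structure(list(nodes = nodes, edges = edges), class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %d significant pathways, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.pathway_network <- function(x, ...) x$nodes

#' @export
glance.pathway_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 total_edge_weight = sum(x$edges$shared),
                 n_isolated = sum(x$nodes$degree == 0))
}

#' Convert a pathway network to an igraph object
#'
#' Node attributes F, holm_p and n_regulated and the `shared` edge weight
#' are carried over.
#'
#' @param network A `pathway_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes))
}

#' Write a pathway network as TSV edge list plus node table, or GraphML
#'
#' @param network A `pathway_network`.
#' @param edge_path Path for the edge list TSV.
#' @param node_path Path for the node attribute TSV.
#' @return Invisibly, the paths.
#' @export
write_network_tsv <- function(network, edge_path, node_path) {
  readr::write_tsv(network$edges, edge_path)
  readr::write_tsv(network$nodes, node_path)
  invisible(c(edge_path, node_path))
}

#' @rdname write_network_tsv
#' @param path GraphML output path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
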