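#' Cluster detected novel cells
#'
#' Builds a k-nearest-neighbour graph on the top principal components of
#' the normalized expression of the novel cells and partitions it with
#' the Leiden algorithm (modularity objective). Cluster labels are
#' contiguous integers from 0, ordered by decreasing cluster size.
#'
#' @param m [expression_matrix()] restricted to the detected novel cells
#'   (raw layer is normalized first).
#' @param k Number of neighbours for the kNN graph (default 15).
#' @param resolution Leiden resolution parameter (default 1).
#' @param n_pcs Number of principal components (default 50, capped at
#'   `n_cells - 1` and `n_genes`).
#' @param seed Integer seed for the Leiden refinement.
#' @return A tibble of class `novel_cluster_result` with columns
#'   `cell_id`, `cluster`; attributes `k`, `resolution`, `sizes`.
#' @export
cluster_novel <- function(m, k = 15, resolution = 1, n_pcs = 50, seed = 0) {
  stopifnot(is_expression_matrix(m), k >= 1)
  n <- nrow(m$values)
  if (n < k + 1) {
    stop("need at least k + 1 = ", k + 1, " novel cells (got ", n,
         "); lower `k`")
  }
  if (m$layer == "raw") m <- normalize_expression(m)
  X <- m$values
  if (all(apply(X, 2, stats::var) == 0)) {
    # degenerate input: all cells identical
    out <- tibble::tibble(cell_id = m$cell_ids, cluster = 0L)
  } else {
    npc <- min(n_pcs, n - 1, ncol(X))
    pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                         rank. = npc)$x
    d <- as.matrix(stats::dist(pcs))
    diag(d) <- Inf
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[seq_len(k)]
      cbind(i, nb)
    }))
    # undirected union of directed kNN edges, deduplicated
    edges <- unique(t(apply(edges, 1, sort)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    set.seed(as.integer(seed))
    comm <- igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 10)
    memb <- igraph::membership(comm)
    # relabel contiguously from 0, largest cluster first
    sizes <- sort(table(memb), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
    out <- tibble::tibble(cell_id = m$cell_ids,
                          cluster = unname(relab[as.character(memb)]))
  }
  attr(out, "k") <- k
  attr(out, "resolution") <- resolution
  attr(out, "sizes") <- as.integer(table(out$cluster))
  class(out) <- c("novel_cluster_result", class(out))
  out
}

wilcox_p <- function(x, y) {
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

#' Rank marker genes per cluster
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene and cluster on
#' the normalized expression. Genes are ranked by the signed score
#' `-log10(p) * sign(log2FC)` (descending), so up-regulated genes lead.
#' Log2 fold-changes use a pseudocount of 1 on the group means; p-values
#' are Benjamini-Hochberg adjusted within each cluster.
#'
#' @param m [expression_matrix()] of the clustered cells (raw layer is
#'   normalized first).
#' @param clusters Integer cluster assignment per cell (or a
#'   `novel_cluster_result` tibble).
#' @param top_n Markers to report per cluster (default 10; capped at the
#'   number of genes).
#' @return Tibble with columns `cluster`, `rank`, `gene_id`, `log2fc`,
#'   `p_value`, `p_adj`, `mean_in`, `mean_out`.
#' @export
rank_marker_genes <- function(m, clusters, top_n = 10) {
  stopifnot(is_expression_matrix(m))
  if (inherits(clusters, "novel_cluster_result") ||
      is.data.frame(clusters)) {
    cl_df <- clusters
    stopifnot(all(m$cell_ids %in% cl_df$cell_id))
    clusters <- cl_df$cluster[match(m$cell_ids, cl_df$cell_id)]
  }
  stopifnot(length(clusters) == nrow(m$values))
  if (length(unique(clusters)) < 2) {
    stop("marker ranking needs at least 2 clusters")
  }
  # fold-changes on the linear library-size-normalized scale; the
  # rank-sum test is invariant to the (monotone) log transform anyway
  if (m$layer == "raw") m <- normalize_expression(m, log1p = FALSE)
  X <- m$values
  top_n <- min(top_n, ncol(X))
  purrr::map_dfr(sort(unique(clusters)), function(cl) {
    inside <- clusters == cl
    stats_gene <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
      xi <- X[inside, j]
      xo <- X[!inside, j]
      tibble::tibble(
        gene_id = m$gene_ids[j],
        mean_in = mean(xi), mean_out = mean(xo),
        log2fc = log2((mean(xi) + 1) / (mean(xo) + 1)),
        p_value = wilcox_p(xi, xo))
    })
    stats_gene$p_adj <- stats::p.adjust(stats_gene$p_value, "BH")
    score <- -log10(pmax(stats_gene$p_value, 1e-300)) *
      sign(stats_gene$log2fc)
    ord <- order(-score, -stats_gene$log2fc)
    top <- stats_gene[ord[seq_len(top_n)], ]
    tibble::tibble(cluster = cl, rank = seq_len(top_n)) |>
      dplyr::bind_cols(top)
  })
}

#' Two-group differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two condition
#' groups (e.g. disease vs healthy within selected novel clusters), with
#' Benjamini-Hochberg adjustment and log2 fold-change of the
#' pseudocounted group means, computed on the linear library-size
#' normalized scale. The output is volcano-ready; the default
#' significance cut is `|log2FC| >= 1` and adjusted p < 0.05.
#'
#' @param m [expression_matrix()] (raw layer is normalized first).
#' @param groups Two-level factor (or character) vector, one entry per
#'   cell of `m`. The first factor level (first-appearance order for
#'   characters) is the numerator of the fold-change; relevel to flip
#'   the comparison, which negates `log2fc` and preserves p-values.
#' @param cells Optional cell-id subset (e.g. cells of selected
#'   clusters) applied to both `m` and `groups`.
#' @param lfc_cut,alpha Significance thresholds for the `significant`
#'   column.
#' @return Tibble of class `de_result` with columns `gene_id`, `log2fc`,
#'   `p_value`, `p_adj`, `mean_group1`, `mean_group2`, `significant`;
#'   attribute `groups` holds the two level names.
#' @export
group_de <- function(m, groups, cells = NULL, lfc_cut = 1, alpha = 0.05) {
  stopifnot(is_expression_matrix(m))
  if (!is.factor(groups)) {
    groups <- factor(groups, levels = unique(as.character(groups)))
  }
  groups <- droplevels(groups)
  stopifnot(length(groups) == nrow(m$values))
  if (!is.null(cells)) {
    keep <- m$cell_ids %in% cells
    m <- subset_matrix(m, which(keep))
    groups <- droplevels(groups[keep])
  }
  levels <- levels(groups)
  if (length(levels) != 2) {
    stop("`groups` must have exactly 2 levels (got ",
         length(levels), ")")
  }
  g1 <- groups == levels[1]
  if (!any(g1) || all(g1)) stop("both groups must be non-empty")
  if (m$layer == "raw") m <- normalize_expression(m, log1p = FALSE)
  X <- m$values
  out <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    x1 <- X[g1, j]
    x2 <- X[!g1, j]
    tibble::tibble(
      gene_id = m$gene_ids[j],
      mean_group1 = mean(x1), mean_group2 = mean(x2),
      log2fc = log2((mean(x1) + 1) / (mean(x2) + 1)),
      p_value = wilcox_p(x1, x2))
  })
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$significant <- abs(out$log2fc) >= lfc_cut & out$p_adj < alpha
  out <- out[, c("gene_id", "log2fc", "p_value", "p_adj", "mean_group1",
                 "mean_group2", "significant")]
  attr(out, "groups") <- levels
  class(out) <- c("de_result", class(out))
  out
}
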