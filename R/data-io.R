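#' Read an expression matrix from disk
#'
#' Supports 10x-style MatrixMarket triplet directories (`matrix.mtx` +
#' `barcodes.tsv` + `features.tsv`/`genes.tsv`) and dense CSV/TSV with a
#' header row of gene names and cell ids in the first column. MTX
#' orientation (cells x genes vs genes x cells) is auto-detected from the
#' barcodes/features lengths; the returned matrix is always cells x genes.
#'
#' @param path File (csv/tsv) or directory (mtx_dir) to read.
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`. `"h5ad"` is
#'   recognised but not supported in this build and errors with a pointer
#'   to the supported formats.
#' @return A raw-layer [expression_matrix()].
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv", "tsv", "h5ad")) {
  format <- match.arg(format)
  if (format == "h5ad") {
    stop("h5ad containers are not supported by this build; ",
         "export to an MTX triplet or dense CSV/TSV instead")
  }
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "mtx_dir") {
    read_mtx_dir(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = 1,
                            stringsAsFactors = FALSE)
    expression_matrix(as.matrix(df), cell_ids = rownames(df),
                      gene_ids = colnames(df), layer = "raw")
  }
}

read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  barcodes <- file.path(dir, "barcodes.tsv")
  features <- file.path(dir, "features.tsv")
  if (!file.exists(features)) features <- file.path(dir, "genes.tsv")
  for (f in c(mtx, barcodes, features)) {
    if (!file.exists(f)) stop("missing MTX triplet member: ", basename(f))
  }
  m <- as.matrix(Matrix::readMM(mtx))
  cells <- utils::read.table(barcodes, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  feats <- utils::read.table(features, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  # orientation: rows must match one id list, columns the other
  if (nrow(m) == length(cells) && ncol(m) == length(feats)) {
    # cells x genes already
  } else if (nrow(m) == length(feats) && ncol(m) == length(cells)) {
    m <- t(m)
  } else {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither barcodes (", length(cells),
         ") nor features (", length(feats), ") orientation")
  }
  expression_matrix(m, cell_ids = cells, gene_ids = feats, layer = "raw")
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()] for the same formats.
#'
#' @param m An [expression_matrix()].
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(is_expression_matrix(m))
  if (format == "mtx_dir") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    writeLines(m$gene_ids, file.path(path, "features.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(m$values)
    utils::write.table(cbind(cell_id = m$cell_ids, df), path, sep = sep,
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell type labels
#'
#' Two-column CSV `cell_id,cell_type`, returned in the order of `cell_ids`
#' when given.
#'
#' @param path CSV file path.
#' @param cell_ids Optional cell ids to order/subset by; every id must be
#'   present in the file.
#' @return Character vector of labels (named by cell id).
#' @export
read_labels <- function(path, cell_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label file needs columns cell_id, cell_type")
  labs <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, names(labs))
    if (length(missing) > 0) {
      stop("labels missing for cells: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    labs <- labs[cell_ids]
  }
  labs
}

#' Write per-cell labels as CSV
#' @param labels Named (by cell id) or plain character vector.
#' @param path Output CSV path.
#' @param cell_ids Cell ids; defaults to `names(labels)`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, cell_ids = names(labels)) {
  utils::write.csv(data.frame(cell_id = cell_ids,
                              cell_type = as.character(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Library-size normalization
#'
#' Scales each cell to a common total (counts-per-`target_sum`) and
#' optionally applies log1p — the de-facto scRNA-seq preprocessing.
#' Cells with zero total counts are left all-zero and reported via a
#' warning and the `zero_cells` attribute.
#'
#' @param m Raw-layer [expression_matrix()].
#' @param target_sum Positive per-cell total after scaling (default 1e4).
#' @param log1p Apply `log(1 + v)` after scaling (default `TRUE`).
#' @return A normalized-layer [expression_matrix()] with attribute
#'   `zero_cells` listing all-zero cell ids.
#' @export
normalize_expression <- function(m, target_sum = 1e4, log1p = TRUE) {
  stopifnot(is_expression_matrix(m), target_sum > 0)
  if (m$layer != "raw") stop("`m` must be a raw-layer matrix")
  totals <- rowSums(m$values)
  zero <- totals == 0
  scale <- ifelse(zero, 0, target_sum / totals)
  v <- m$values * scale
  if (log1p) v <- log1p(v)
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts left all-zero: ",
            paste(utils::head(m$cell_ids[zero], 5), collapse = ", "))
  }
  out <- expression_matrix(v, m$cell_ids, m$gene_ids, layer = "normalized")
  attr(out, "zero_cells") <- m$cell_ids[zero]
  out
}

#' Align reference and query to a shared gene space
#'
#' Restricts both matrices to the intersection of their gene ids, ordered
#' by the reference's gene order. No imputation of missing genes is done.
#'
#' @param ref,query [expression_matrix()] objects.
#' @return List with elements `ref`, `query` (aligned matrices) and
#'   `report`, a tibble of dropped genes per side.
#' @export
align_genes <- function(ref, query) {
  stopifnot(is_expression_matrix(ref), is_expression_matrix(query))
  shared <- ref$gene_ids[ref$gene_ids %in% query$gene_ids]
  if (length(shared) == 0) stop("no shared genes between reference and query")
  dropped_ref <- setdiff(ref$gene_ids, shared)
  dropped_query <- setdiff(query$gene_ids, shared)
  report <- tibble::tibble(
    side = c(rep("ref", length(dropped_ref)),
             rep("query", length(dropped_query))),
    gene_id = c(dropped_ref, dropped_query)
  )
  list(
    ref = expression_matrix(ref$values[, shared, drop = FALSE],
                            ref$cell_ids, shared, layer = ref$layer),
    query = expression_matrix(query$values[, shared, drop = FALSE],
                              query$cell_ids, shared, layer = query$layer),
    report = report
  )
}

#' Highly-variable-gene selection (optional)
#'
#' Ranks genes by dispersion (variance / mean on the raw scale) and keeps
#' the top `n`. Off by default throughout the package; provided for users
#' who want a reduced feature space.
#'
#' @param m [expression_matrix()].
#' @param n Number of genes to keep.
#' @return [expression_matrix()] restricted to the selected genes, in
#'   original gene order.
#' @export
select_hvg <- function(m, n = 2000) {
  stopifnot(is_expression_matrix(m))
  mu <- colMeans(m$values)
  v <- apply(m$values, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- rank(-disp, ties.method = "first") <= min(n, length(disp))
  expression_matrix(m$values[, keep, drop = FALSE], m$cell_ids,
                    m$gene_ids[keep], layer = m$layer)
}
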