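#' Expression matrix container
#'
#' A light wrapper around a dense cells x genes numeric matrix carrying
#' cell identifiers, gene identifiers and a layer tag distinguishing raw
#' counts from normalized expression. All package functions orient data
#' cells-as-rows.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers,
#'   length `nrow(values)`.
#' @param gene_ids Character vector of unique gene identifiers,
#'   length `ncol(values)`.
#' @param layer Either `"raw"` (non-negative finite counts) or
#'   `"normalized"` (finite reals).
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell_", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("gene_", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("`cell_ids` length (", length(cell_ids),
         ") does not match the number of rows (", nrow(values), ")")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("`gene_ids` length (", length(gene_ids),
         ") does not match the number of columns (", ncol(values), ")")
  }
  dup_cells <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_cells) > 0) {
    stop("duplicate cell ids: ", paste(utils::head(dup_cells, 5), collapse = ", "))
  }
  dup_genes <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_genes) > 0) {
    stop("duplicate gene ids: ", paste(utils::head(dup_genes, 5), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite")
  }
  if (layer == "raw" && any(values < 0)) {
    stop("raw-layer counts must be non-negative")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         layer = layer),
    class = "expression_matrix"
  )
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes [%s layer]\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

is_expression_matrix <- function(x) inherits(x, "expression_matrix")

#' Labeled reference dataset
#'
#' Bundles an expression matrix with one cell-type label per cell. The
#' ordered set of distinct classes fixes the classifier output dimension.
#'
#' @param matrix An [expression_matrix()].
#' @param labels Character vector of per-cell class labels, one per cell.
#' @param class_names Optional ordered character vector of the distinct
#'   classes; defaults to the sorted unique labels. Every label must be a
#'   member and every class must appear at least once.
#'
#' @return An object of class `labeled_reference`.
#' @export
labeled_reference <- function(matrix, labels, class_names = NULL) {
  stopifnot(is_expression_matrix(matrix))
  labels <- as.character(labels)
  if (length(labels) != nrow(matrix$values)) {
    stop("`labels` must have one entry per cell (",
         nrow(matrix$values), " cells, ", length(labels), " labels)")
  }
  if (is.null(class_names)) {
    class_names <- sort(unique(labels))
  }
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) stop("`class_names` must be unique")
  missing_lab <- setdiff(labels, class_names)
  if (length(missing_lab) > 0) {
    stop("labels not in `class_names`: ", paste(missing_lab, collapse = ", "))
  }
  absent <- setdiff(class_names, labels)
  if (length(absent) > 0) {
    stop("classes with zero cells: ", paste(absent, collapse = ", "))
  }
  if (length(class_names) < 2) {
    stop("a reference needs at least 2 cell-type classes")
  }
  structure(
    list(matrix = matrix, labels = labels, class_names = class_names),
    class = "labeled_reference"
  )
}

#' @exportS3Method base::print
print.labeled_reference <- function(x, ...) {
  cat(sprintf("<labeled_reference> %d cells x %d genes, %d classes\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              length(x$class_names)))
  counts <- table(factor(x$labels, levels = x$class_names))
  cat(paste(sprintf("  %s: %d", names(counts), as.integer(counts)),
            collapse = "\n"), "\n")
  invisible(x)
}
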