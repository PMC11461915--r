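#' Multi-batch expression container
#'
#' A `BatchCollection` holds an ordered set of gene x cell expression
#' matrices that share one gene axis, together with batch labels, per-cell
#' identifiers and optional cell-type labels. It is the input container for
#' every stage of the package: reading, normalization, highly-variable-gene
#' selection, centering and the JIVE decomposition itself.
#'
#' @param matrices list of numeric gene x cell matrices (dense or
#'   `Matrix` sparse), all with the same number of rows in the same gene
#'   order. Batch `i` contributes `n_i` cells (columns).
#' @param gene_ids character vector of gene identifiers, one per row.
#' @param batch_labels character vector, one distinct label per matrix.
#' @param cell_ids list of character vectors of per-batch cell identifiers;
#'   defaults to `<batch>_cell<j>`.
#' @param cell_types optional list of per-batch cell-type label vectors
#'   (same lengths as `cell_ids`).
#' @param value_space one of `"counts"`, `"lognorm"`, `"centered"`,
#'   recording which transformations have been applied.
#'
#' @return An object of class `BatchCollection`.
#' @export
batch_collection <- function(matrices, gene_ids, batch_labels,
                             cell_ids = NULL, cell_types = NULL,
                             value_space = c("counts", "lognorm", "centered")) {
  value_space <- match.arg(value_space)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (length(batch_labels) != length(matrices))
    stop("need one batch label per matrix")
  if (anyDuplicated(batch_labels))
    stop("batch labels must be unique")
  p <- length(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids are not allowed")
  for (i in seq_along(matrices)) {
    if (nrow(matrices[[i]]) != p)
      stop(sprintf("matrix %d has %d rows; expected %d genes", i,
                   nrow(matrices[[i]]), p))
  }
  if (is.null(cell_ids)) {
    cell_ids <- lapply(seq_along(matrices), function(i)
      paste0(batch_labels[i], "_cell", seq_len(ncol(matrices[[i]]))))
  }
  for (i in seq_along(matrices)) {
    if (length(cell_ids[[i]]) != ncol(matrices[[i]]))
      stop("cell_ids lengths must match matrix column counts")
  }
  if (!is.null(cell_types)) {
    for (i in seq_along(matrices)) {
      if (length(cell_types[[i]]) != ncol(matrices[[i]]))
        stop("cell_types must cover every cell")
    }
  }
  structure(list(matrices = matrices,
                 gene_ids = as.character(gene_ids),
                 batch_labels = as.character(batch_labels),
                 cell_ids = cell_ids,
                 cell_types = cell_types,
                 value_space = value_space),
            class = "BatchCollection")
}

#' @export
print.BatchCollection <- function(x, ...) {
  n_i <- vapply(x$matrices, ncol, integer(1))
  cat(sprintf("BatchCollection: %d genes, %d batches, %d cells (%s space)\n",
              length(x$gene_ids), length(x$matrices), sum(n_i), x$value_space))
  for (i in seq_along(x$matrices))
    cat(sprintf("  %s: %d cells\n", x$batch_labels[i], n_i[i]))
  if (!is.null(x$cell_types))
    cat("  cell types:", paste(sort(unique(unlist(x$cell_types))),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Number of batches / cells / genes in a collection
#' @param collection a [batch_collection()].
#' @return integer.
#' @export
n_batches <- function(collection) length(collection$matrices)

#' @rdname n_batches
#' @export
n_cells <- function(collection)
  sum(vapply(collection$matrices, ncol, integer(1)))

#' @rdname n_batches
#' @export
n_genes <- function(collection) length(collection$gene_ids)

# per-batch cell counts
batch_sizes <- function(collection)
  vapply(collection$matrices, ncol, integer(1))

# concatenated per-cell labels in batch order
batch_factor <- function(collection) {
  n_i <- batch_sizes(collection)
  factor(rep(collection$batch_labels, n_i), levels = collection$batch_labels)
}

cell_type_factor <- function(collection) {
  if (is.null(collection$cell_types)) return(NULL)
  factor(unlist(collection$cell_types, use.names = FALSE))
}

check_collection_space <- function(collection, space, what) {
  if (!identical(collection$value_space, space))
    stop(sprintf("%s expects a collection in '%s' space, got '%s'",
                 what, space, collection$value_space))
  invisible(TRUE)
}
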