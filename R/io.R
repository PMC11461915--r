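#' Read per-batch expression matrices and cell labels
#'
#' Reads one or more gene x cell matrices (Matrix Market `.mtx` with
#' plain-text row/column-name sidecars, or dense CSV with gene ids in the
#' first column and cell ids in the header) together with a labels TSV
#' mapping `cell_id` to `batch` and, optionally, `cell_type`. Cells from all
#' files are pooled and re-partitioned by batch, in the order batches first
#' appear in the labels file.
#'
#' All files must carry the same gene list in the same order; if gene sets
#' differ, read the matrices yourself and call [align_genes()] first.
#'
#' @param matrix_paths character vector of `.mtx` or `.csv` file paths.
#'   For `path.mtx`, sidecars `path.mtx.rownames` and `path.mtx.colnames`
#'   hold one gene / cell id per line.
#' @param labels_path TSV file with header columns `cell_id`, `batch` and
#'   optionally `cell_type`.
#' @return A [batch_collection()] in counts space.
#' @seealso [write_batches()], [align_genes()]
#' @export
read_batches <- function(matrix_paths, labels_path) {
  missing <- c(matrix_paths, labels_path)[!file.exists(c(matrix_paths,
                                                         labels_path))]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  req <- c("cell_id", "batch")
  if (!all(req %in% names(labels)))
    stop("labels file must have columns 'cell_id' and 'batch'")
  if (anyDuplicated(labels$cell_id))
    stop("duplicate cell ids in labels file")

  parts <- lapply(matrix_paths, read_one_matrix)
  genes <- parts[[1]]$genes
  for (pt in parts[-1]) {
    if (!identical(pt$genes, genes))
      stop("gene lists differ between matrix files; align them with align_genes() first")
  }
  mat <- do.call(cbind, lapply(parts, `[[`, "mat"))
  cells <- unlist(lapply(parts, `[[`, "cells"), use.names = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell ids across matrix files")
  colnames(mat) <- cells

  unknown <- setdiff(cells, labels$cell_id)
  if (length(unknown))
    stop(sprintf("cell ids missing from labels file: %s%s",
                 paste(utils::head(unknown, 3), collapse = ", "),
                 if (length(unknown) > 3) ", ..." else ""))
  labels <- labels[labels$cell_id %in% cells, , drop = FALSE]
  batches <- unique(labels$batch)
  lab_of <- stats::setNames(labels$batch, labels$cell_id)
  type_of <- if ("cell_type" %in% names(labels))
    stats::setNames(labels$cell_type, labels$cell_id) else NULL

  mats <- list(); ids <- list(); types <- if (is.null(type_of)) NULL else list()
  for (b in batches) {
    keep <- cells[lab_of[cells] == b]
    mats[[b]] <- mat[, keep, drop = FALSE]
    ids[[b]] <- keep
    if (!is.null(type_of)) types[[b]] <- unname(type_of[keep])
  }
  batch_collection(unname(mats), gene_ids = genes, batch_labels = batches,
                   cell_ids = unname(ids),
                   cell_types = if (is.null(types)) NULL else unname(types),
                   value_space = "counts")
}

read_one_matrix <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop(sprintf("sidecar name files do not match dimensions of %s", path))
    if (anyDuplicated(rn)) stop("duplicate gene ids in ", path)
    m <- methods::as(m, "CsparseMatrix")
    list(mat = m, genes = rn, cells = cn)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    list(mat = m, genes = genes, cells = colnames(df)[-1])
  }
}

#' Write a collection back to disk
#'
#' Inverse of [read_batches()]: one matrix file per batch plus a labels TSV.
#'
#' @param collection a [batch_collection()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"mtx"`.
#' @return Invisibly, the paths written.
#' @export
write_batches <- function(collection, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(collection$matrices)) {
    b <- collection$batch_labels[i]
    m <- collection$matrices[[i]]
    if (format == "csv") {
      f <- file.path(dir, paste0(b, ".csv"))
      df <- data.frame(gene_id = collection$gene_ids,
                       as.matrix(m), check.names = FALSE)
      colnames(df) <- c("gene_id", collection$cell_ids[[i]])
      utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    } else {
      f <- file.path(dir, paste0(b, ".mtx"))
      Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"),
                                  "generalMatrix"), f)
      writeLines(collection$gene_ids, paste0(f, ".rownames"))
      writeLines(collection$cell_ids[[i]], paste0(f, ".colnames"))
    }
    paths <- c(paths, f)
  }
  lab <- data.frame(cell_id = unlist(collection$cell_ids, use.names = FALSE),
                    batch = rep(collection$batch_labels,
                                batch_sizes(collection)))
  if (!is.null(collection$cell_types))
    lab$cell_type <- unlist(collection$cell_types, use.names = FALSE)
  lf <- file.path(dir, "labels.tsv")
  utils::write.table(lab, lf, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(paths, lf))
}

#' Restrict batches to their shared genes
#'
#' Takes per-batch matrices whose gene lists differ and restricts every
#' matrix to the intersection of the gene sets, in a single shared order
#' (the order genes appear in the first matrix). The number of genes
#' dropped from each input is reported via `message()` and attached as the
#' `"dropped"` attribute.
#'
#' @param matrices list of gene x cell matrices with gene ids as rownames,
#'   or a `BatchCollection` (already aligned; returned unchanged).
#' @param batch_labels labels for the matrices (defaults to list names or
#'   `batch1..k`).
#' @param ... passed on to [batch_collection()] (e.g. `cell_ids`,
#'   `value_space`).
#' @return A [batch_collection()] on the shared gene set.
#' @export
align_genes <- function(matrices, batch_labels = NULL, ...) {
  if (inherits(matrices, "BatchCollection")) return(matrices)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  gene_lists <- lapply(matrices, rownames)
  if (any(vapply(gene_lists, is.null, logical(1))))
    stop("every matrix needs gene ids as rownames")
  shared <- Reduce(intersect, gene_lists)
  if (length(shared) == 0) stop("gene sets have an empty intersection")
  # keep the first matrix's ordering of the shared genes
  shared <- gene_lists[[1]][gene_lists[[1]] %in% shared]
  dropped <- vapply(gene_lists, function(g) length(g) - length(shared),
                    integer(1))
  message(sprintf("align_genes: kept %d shared genes; dropped %s per batch",
                  length(shared), paste(dropped, collapse = "/")))
  if (is.null(batch_labels))
    batch_labels <- names(matrices) %||% paste0("batch", seq_along(matrices))
  out <- lapply(matrices, function(m) m[shared, , drop = FALSE])
  bc <- batch_collection(out, gene_ids = shared, batch_labels = batch_labels,
                         ...)
  attr(bc, "dropped") <- dropped
  bc
}
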