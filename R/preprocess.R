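#' Library-size log-normalization
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' `x -> log(1 + scale_factor * x / L_c)` with `L_c` the cell's total
#' counts. This is the standard "log-normalize" step of single-cell
#' workflows (counts per ten thousand by default).
#'
#' Cells with zero library size are dropped with a warning; the transform
#' is undefined for them.
#'
#' @param collection a [batch_collection()] in counts space.
#' @param scale_factor positive scalar, default `1e4`.
#' @return The collection in `lognorm` space.
#' @export
log_normalize <- function(collection, scale_factor = 1e4) {
  check_collection_space(collection, "counts", "log_normalize")
  stopifnot(is.numeric(scale_factor), scale_factor > 0)
  mats <- collection$matrices
  ids <- collection$cell_ids
  types <- collection$cell_types
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    if (min(if (is_sparse(m)) m@x else m, 0) < 0)
      stop("log_normalize: negative entries in counts matrix")
    L <- col_sums(m)
    if (any(L == 0)) {
      warning(sprintf("dropping %d zero-library cell(s) from batch %s",
                      sum(L == 0), collection$batch_labels[i]))
      keep <- L > 0
      m <- m[, keep, drop = FALSE]
      ids[[i]] <- ids[[i]][keep]
      if (!is.null(types)) types[[i]] <- types[[i]][keep]
      L <- L[keep]
    }
    if (is_sparse(m)) {
      m <- m %*% Matrix::Diagonal(x = scale_factor / L)
      m@x <- log1p(m@x)
    } else {
      m <- log1p(sweep(m, 2, L / scale_factor, "/"))
    }
    mats[[i]] <- m
  }
  batch_collection(mats, collection$gene_ids, collection$batch_labels,
                   cell_ids = ids, cell_types = types,
                   value_space = "lognorm")
}

#' Highly variable gene selection
#'
#' Keeps the `n_genes` genes with the largest variance of log-normalized
#' expression, pooled across all cells of all batches. The relative order
#' of the kept genes is preserved.
#'
#' @param collection a [batch_collection()] in lognorm space.
#' @param n_genes number of genes to keep (default 2000).
#' @return The restricted collection, still in lognorm space.
#' @export
select_hvg <- function(collection, n_genes = 2000) {
  check_collection_space(collection, "lognorm", "select_hvg")
  p <- n_genes(collection)
  if (n_genes > p) stop(sprintf("n_genes (%d) exceeds gene count (%d)",
                                n_genes, p))
  v <- pooled_row_vars(collection$matrices)
  keep <- sort(utils::head(order(v, decreasing = TRUE), n_genes))
  batch_collection(lapply(collection$matrices,
                          function(m) m[keep, , drop = FALSE]),
                   collection$gene_ids[keep], collection$batch_labels,
                   cell_ids = collection$cell_ids,
                   cell_types = collection$cell_types,
                   value_space = "lognorm")
}

#' Center genes on their pooled mean
#'
#' Subtracts from each gene its mean across all cells of all batches
#' pooled. Pooled (rather than per-batch) centering is deliberate:
#' per-batch centering would itself remove batch location effects and
#' confound the decomposition's attribution of variation. Matrices are
#' densified here; downstream decomposition is dense.
#'
#' @param collection a [batch_collection()] in lognorm space.
#' @return list with `collection` (centered space) and `gene_means`
#'   (length-p numeric, for back-transformation).
#' @export
center_batches <- function(collection) {
  check_collection_space(collection, "lognorm", "center_batches")
  n <- n_cells(collection)
  mu <- as.numeric(Reduce(`+`, lapply(collection$matrices, row_sums))) / n
  mats <- lapply(collection$matrices, function(m) as_dense(m) - mu)
  if (n_genes(collection) * n > 5e7)
    message("center_batches: densified a large collection (",
            n_genes(collection), " x ", n, "); expect high memory use")
  list(collection = batch_collection(mats, collection$gene_ids,
                                     collection$batch_labels,
                                     cell_ids = collection$cell_ids,
                                     cell_types = collection$cell_types,
                                     value_space = "centered"),
       gene_means = mu)
}
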