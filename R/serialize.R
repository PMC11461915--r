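#' Serialize a fitted model to a plain-text archive
#'
#' Writes `U`, `S`, the per-batch `W_i` and `S_i`, ranks, gene means and
#' the objective trace into a directory of CSV files plus a JSON manifest.
#' Residual matrices are not stored (they are reproducible from the data
#' and the model); a model read back with [read_jive_model()] therefore
#' supports [correct_batches()] and [joint_embedding()] but needs the
#' original collection for [variance_explained()].
#'
#' @param model a fitted `JIVEModel`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_jive_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) utils::write.table(
    m, file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE)
  wm(model$U, "U.csv")
  wm(model$S, "S.csv")
  for (i in seq_along(model$W)) {
    wm(model$W[[i]], sprintf("W_%d.csv", i))
    wm(model$S_ind[[i]], sprintf("S_ind_%d.csv", i))
  }
  manifest <- list(ranks = model$ranks,
                   gene_means = model$gene_means,
                   gene_ids = model$gene_ids,
                   batch_labels = model$batch_labels,
                   n_per_batch = model$n_per_batch,
                   cell_ids = model$cell_ids,
                   cell_types = model$cell_types,
                   scale_batches = model$scale_batches,
                   batch_norms = model$batch_norms,
                   objective_trace = model$objective_trace,
                   converged = model$converged,
                   n_iter = model$n_iter)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_jive_model
#' @return For `read_jive_model`, a `JIVEModel` (without residuals).
#' @export
read_jive_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  # equal-length per-batch vectors get simplified to a matrix (one row per
  # batch); restore the list-of-vectors shape
  as_batch_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (is.list(x) || is.null(x)) x
    else list(x)
  }
  man$cell_ids <- as_batch_list(man$cell_ids)
  man$cell_types <- as_batch_list(man$cell_types)
  rm_ <- function(f, ncol_hint = NULL) {
    path <- file.path(dir, f)
    if (file.size(path) == 0)
      return(matrix(0, 0, ncol_hint %||% 0))
    as.matrix(utils::read.table(path, sep = ","))
  }
  k <- length(man$batch_labels)
  p <- length(man$gene_ids)
  n <- sum(man$n_per_batch)
  U <- rm_("U.csv"); S <- rm_("S.csv", p)
  if (man$ranks$joint == 0) { U <- matrix(0, n, 0); S <- matrix(0, 0, p) }
  W <- vector("list", k); S_ind <- vector("list", k)
  for (i in seq_len(k)) {
    if (man$ranks$individual[i] == 0) {
      W[[i]] <- matrix(0, man$n_per_batch[i], 0)
      S_ind[[i]] <- matrix(0, 0, p)
    } else {
      W[[i]] <- rm_(sprintf("W_%d.csv", i))
      S_ind[[i]] <- rm_(sprintf("S_ind_%d.csv", i))
    }
  }
  dimnames(U) <- dimnames(S) <- NULL
  structure(list(U = U, S = S, W = lapply(W, unname),
                 S_ind = lapply(S_ind, unname), R = NULL,
                 ranks = list(joint = as.integer(man$ranks$joint),
                              individual = as.integer(man$ranks$individual)),
                 gene_means = man$gene_means,
                 gene_ids = man$gene_ids,
                 batch_labels = man$batch_labels,
                 n_per_batch = as.integer(man$n_per_batch),
                 cell_ids = man$cell_ids,
                 cell_types = man$cell_types,
                 scale_batches = isTRUE(man$scale_batches),
                 batch_norms = man$batch_norms,
                 objective_trace = man$objective_trace,
                 converged = isTRUE(man$converged),
                 n_iter = man$n_iter), class = "JIVEModel")
}
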