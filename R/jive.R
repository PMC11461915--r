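#' Fit the JIVE decomposition to a multi-batch collection
#'
#' Decomposes `k >= 2` centered batches into a joint structure shared
#' across batches, per-batch individual structures and residual noise.
#' Working in the transposed (horizontal-integration) orientation, each
#' batch's cells x genes matrix `Y_i = t(X_i)` is modeled as
#'
#' \deqn{Y_i = U_i S + W_i S_i + R_i}
#'
#' where the rows of the joint loading matrix `S` (r x p) span one subspace
#' of gene space common to all batches, `U_i` are the per-batch joint
#' scores, and the individual loadings `S_i` (r_i x p) are constrained
#' orthogonal to `S` (`S %*% t(S_i) = 0`). The orthogonality is what lets
#' joint structure be read as cross-batch (biological) signal and
#' individual structure as within-batch (technical) signal without the two
#' trading variance back and forth.
#'
#' Estimation alternates two exact least-squares steps until the structures
#' stop moving:
#' * J-step: rank-`r` truncated SVD of the stacked `Y - A` gives the new
#'   joint structure `J = U S` and its right basis `V` (p x r);
#' * I-step: for each batch, rank-`r_i` truncated SVD of
#'   `(Y_i - J_i) (I - V V')` gives the new individual structure, orthogonal
#'   to the joint basis by construction.
#'
#' The individual structures are estimated *first* (the initial joint
#' estimate is zero, so `A_i` starts as the plain rank-`r_i` approximation
#' of `Y_i`). This ordering is load-bearing for batch correction: it lets
#' each batch's own expression offset be captured by its individual
#' structure before the joint step runs; initializing with `A = 0` instead
#' would hand those directions to the joint structure permanently, and the
#' "corrected" joint scores would still separate the batches.
#'
#' Each step minimizes the total residual sum of squares given the other
#' block, so the objective is non-increasing; the trace is stored and
#' checked.
#'
#' @param collection a [batch_collection()] in centered space (see
#'   [center_batches()]), with at least 2 batches.
#' @param joint_rank joint rank `r >= 0`.
#' @param individual_ranks integer vector of per-batch ranks `r_i >= 0`
#'   (recycled if length 1).
#' @param tol convergence threshold on the maximum relative Frobenius
#'   change of `J` and each `A_i` between iterations. Default `1e-6`.
#' @param max_iter iteration cap, default 1000.
#' @param scale_batches if `TRUE`, divide each `Y_i` by its Frobenius norm
#'   before fitting (useful for heterogeneous assays; off by default since
#'   all batches here share one assay).
#' @param gene_means optional length-p vector of gene means removed by
#'   centering, stored for back-transformation.
#' @return A `JIVEModel`: joint scores `U` (n x r, rows grouped by batch),
#'   joint loadings `S` (r x p), per-batch `W[[i]]` (n_i x r_i) and
#'   `S_ind[[i]]` (r_i x p), residuals `R[[i]]`, ranks, `objective_trace`
#'   (per-iteration SSE), `converged`, `n_iter`.
#' @references Lock, E.F., Hoadley, K.A., Marron, J.S. and Nobel, A.B.
#'   (2013) Joint and individual variation explained (JIVE) for integrated
#'   analysis of multiple data types. Ann. Appl. Stat. 7(1).
#' @export
fit_jive <- function(collection, joint_rank, individual_ranks,
                     tol = 1e-6, max_iter = 1000, scale_batches = FALSE,
                     gene_means = NULL) {
  check_collection_space(collection, "centered", "fit_jive")
  k <- n_batches(collection)
  if (k < 2) stop("fit_jive needs at least 2 batches")
  if (length(individual_ranks) == 1)
    individual_ranks <- rep(individual_ranks, k)
  stopifnot(length(individual_ranks) == k,
            joint_rank >= 0, all(individual_ranks >= 0))
  r <- as.integer(joint_rank)
  ri <- as.integer(individual_ranks)

  p <- n_genes(collection)
  n_i <- batch_sizes(collection)
  n <- sum(n_i)
  if (r > min(n, p)) stop("joint rank exceeds matrix dimensions")
  for (i in seq_len(k)) {
    if (r + ri[i] > min(n_i[i], p))
      stop(sprintf("joint rank + individual rank (%d) exceeds min(n_%d, p) = %d",
                   r + ri[i], i, min(n_i[i], p)))
  }

  # transposed orientation: cells x genes
  Y <- lapply(collection$matrices, function(m) t(as_dense(m)))
  batch_norms <- vapply(Y, frob, numeric(1))
  if (scale_batches) Y <- Map(function(m, s) m / s, Y, batch_norms)

  idx <- split(seq_len(n), rep(seq_len(k), n_i))
  Ys <- do.call(rbind, Y)
  total_norm <- frob(Ys)

  # Individual-first initialization: with the initial joint estimate at
  # zero, the first individual step is an unconstrained rank-r_i fit to
  # each batch alone. This matters: it lets per-batch structure (e.g. a
  # batch's expression offset) be claimed by the individual component
  # before the joint step ever sees it. Starting instead from A = 0 makes
  # the first joint step absorb the strongest batch-specific directions
  # and the alternation cannot move them out afterwards.
  A <- lapply(seq_len(k), function(i) truncated_approx(Y[[i]], ri[i])$approx)
  J <- matrix(0, n, p)
  V <- matrix(0, p, 0)
  U <- matrix(0, n, 0); S <- matrix(0, 0, p)
  W <- lapply(seq_len(k), function(i) matrix(0, n_i[i], 0))
  S_ind <- lapply(seq_len(k), function(i) matrix(0, 0, p))

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    J_old <- J; A_old <- A

    js <- truncated_approx(Ys - do.call(rbind, A), r)
    J <- js$approx
    V <- if (r > 0) js$v else matrix(0, p, 0)
    U <- js$scores
    S <- js$loadings

    for (i in seq_len(k)) {
      Zi <- Y[[i]] - J[idx[[i]], , drop = FALSE]
      if (r > 0) Zi <- Zi - (Zi %*% V) %*% t(V)
      as_i <- truncated_approx(Zi, ri[i])
      A[[i]] <- as_i$approx
      W[[i]] <- as_i$scores
      S_ind[[i]] <- as_i$loadings
    }

    As <- do.call(rbind, A)
    trace <- c(trace, sum((Ys - J - As)^2))

    delta <- rel_change(J_old, J, total_norm)
    for (i in seq_len(k))
      delta <- max(delta, rel_change(A_old[[i]], A[[i]], total_norm))
    if (delta < tol) { converged <- TRUE; break }
  }

  R <- lapply(seq_len(k),
              function(i) Y[[i]] - J[idx[[i]], , drop = FALSE] - A[[i]])

  structure(list(
    U = U, S = S, W = W, S_ind = S_ind, R = R,
    ranks = list(joint = r, individual = ri),
    gene_means = gene_means,
    gene_ids = collection$gene_ids,
    batch_labels = collection$batch_labels,
    n_per_batch = n_i,
    cell_ids = collection$cell_ids,
    cell_types = collection$cell_types,
    scale_batches = scale_batches,
    batch_norms = batch_norms,
    objective_trace = trace,
    converged = converged,
    n_iter = iter), class = "JIVEModel")
}

rel_change <- function(old, new, total_norm) {
  fo <- frob(old)
  fd <- frob(new - old)
  if (fo > 0) fd / fo
  else if (fd == 0) 0
  else fd / total_norm
}

#' @export
print.JIVEModel <- function(x, ...) {
  cat(sprintf("JIVEModel: %d batches, %d cells x %d genes\n",
              length(x$n_per_batch), sum(x$n_per_batch), ncol(x$S)))
  cat(sprintf("  joint rank %d; individual ranks %s\n", x$ranks$joint,
              paste(x$ranks$individual, collapse = ", ")))
  cat(sprintf("  %d iterations, converged: %s, final SSE %.6g\n",
              x$n_iter, x$converged, utils::tail(x$objective_trace, 1)))
  invisible(x)
}

# joint/individual blocks for batch i, in cells x genes orientation
joint_block <- function(model, i) {
  offs <- cumsum(c(0, model$n_per_batch))
  rows <- (offs[i] + 1):offs[i + 1]
  model$U[rows, , drop = FALSE] %*% model$S
}
individual_block <- function(model, i) model$W[[i]] %*% model$S_ind[[i]]

#' Per-batch variance attribution of a fitted model
#'
#' For each batch, the fractions of total squared Frobenius norm captured
#' by the joint structure, the individual structure and the residual.
#' Rows sum to 1 at convergence (the three parts are mutually orthogonal).
#'
#' @param model a fitted `JIVEModel`.
#' @param collection the centered collection the model was fitted on.
#' @return data.frame with columns `batch`, `joint`, `individual`,
#'   `residual`.
#' @export
variance_explained <- function(model, collection) {
  check_collection_space(collection, "centered", "variance_explained")
  k <- length(model$n_per_batch)
  if (n_batches(collection) != k ||
      !identical(batch_sizes(collection), model$n_per_batch) ||
      n_genes(collection) != ncol(model$S))
    stop("collection does not match the fitted model's dimensions")
  out <- data.frame(batch = model$batch_labels, joint = NA_real_,
                    individual = NA_real_, residual = NA_real_)
  for (i in seq_len(k)) {
    Yi <- t(as_dense(collection$matrices[[i]]))
    if (model$scale_batches) Yi <- Yi / model$batch_norms[i]
    tot <- sum(Yi^2)
    out$joint[i] <- sum(joint_block(model, i)^2) / tot
    out$individual[i] <- sum(individual_block(model, i)^2) / tot
    out$residual[i] <- sum(model$R[[i]]^2) / tot
  }
  out
}

#' Batch-corrected matrix and joint embedding
#'
#' The corrected expression block for batch `i` is the transposed joint
#' structure `t(U_i S)` (genes x cells); blocks are concatenated in batch
#' order. The joint scores `U` double as the low-dimensional embedding used
#' for the integration metrics.
#'
#' @param model a fitted `JIVEModel`.
#' @param add_back_means add the stored gene means back onto every cell
#'   (requires `gene_means` recorded at fit time). Default `FALSE`: output
#'   stays in centered log-normalized space.
#' @return list with `corrected` (p x n matrix, cells in batch order) and
#'   `joint_scores` (n x r matrix `U`).
#' @export
correct_batches <- function(model, add_back_means = FALSE) {
  r <- model$ranks$joint
  if (r == 0 && !add_back_means)
    warning("joint rank is 0: corrected matrix is identically zero")
  k <- length(model$n_per_batch)
  blocks <- lapply(seq_len(k), function(i) {
    b <- t(joint_block(model, i))
    if (model$scale_batches) b <- b * model$batch_norms[i]
    b
  })
  corrected <- do.call(cbind, blocks)
  if (add_back_means) {
    if (is.null(model$gene_means))
      stop("model carries no gene_means; refit with gene_means= or use center_batches()")
    corrected <- corrected + model$gene_means
  }
  rownames(corrected) <- model$gene_ids
  colnames(corrected) <- unlist(model$cell_ids, use.names = FALSE)
  list(corrected = corrected, joint_scores = model$U)
}
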