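# Small internal helpers shared across modules.

is_sparse <- function(x) inherits(x, "Matrix")

col_sums <- function(x) if (is_sparse(x)) Matrix::colSums(x) else colSums(x)
row_sums <- function(x) if (is_sparse(x)) Matrix::rowSums(x) else rowSums(x)
row_means <- function(x) if (is_sparse(x)) Matrix::rowMeans(x) else rowMeans(x)

as_dense <- function(x) if (is_sparse(x)) as.matrix(x) else x

#' @noRd
frob <- function(x) sqrt(sum(x^2))

# Pooled per-gene variance across a list of gene x cell matrices.
pooled_row_vars <- function(mats) {
  n <- sum(vapply(mats, ncol, integer(1)))
  sx <- Reduce(`+`, lapply(mats, row_sums))
  sx2 <- Reduce(`+`, lapply(mats, function(m) row_sums(m * m)))
  (sx2 - sx^2 / n) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
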