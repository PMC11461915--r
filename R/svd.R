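#' Leading singular triplets of a matrix
#'
#' Returns the `k` largest singular values and the corresponding singular
#' vectors of `M`, equal (up to paired sign) to the first `k` columns of a
#' full SVD. Small problems go through LAPACK directly; for large matrices
#' with `k` far below `min(dim(M))` the triplets are obtained from a
#' symmetric eigendecomposition of the smaller Gram matrix, which is the
#' work-saving step that makes the alternating JIVE fit affordable at
#' single-cell scale (only `r` or `r_i` components are ever needed).
#'
#' Sign convention: the entry of largest magnitude in each left singular
#' vector is made positive, so results are reproducible across BLAS
#' backends.
#'
#' @param M numeric matrix (m x p).
#' @param k number of triplets, `1 <= k <= min(m, p)`.
#' @return list with `u` (m x k), `d` (length k, non-increasing), `v`
#'   (p x k), class `"svd_triplet"`.
#' @export
partial_svd <- function(M, k) {
  M <- as_dense(M)
  m <- nrow(M); p <- ncol(M)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > min(m, p))
    stop(sprintf("k must lie in [1, %d]", min(m, p)))
  k <- as.integer(k)
  if (min(m, p) <= 256L || k > min(m, p) %/% 4L) {
    s <- svd(M, nu = k, nv = k)
    out <- list(u = s$u, d = s$d[seq_len(k)], v = s$v)
  } else if (m <= p) {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    u <- e$vectors[, seq_len(k), drop = FALSE]
    v <- crossprod(M, u)
    v <- scale_singular(v, d)
    out <- list(u = u, d = d, v = v)
  } else {
    e <- eigen(crossprod(M), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    v <- e$vectors[, seq_len(k), drop = FALSE]
    u <- M %*% v
    u <- scale_singular(u, d)
    out <- list(u = u, d = d, v = v)
  }
  out <- fix_svd_signs(out)
  class(out) <- "svd_triplet"
  out
}

# divide columns by their singular values, guarding numerically-zero ones
scale_singular <- function(x, d) {
  tiny <- d <= max(d[1], .Machine$double.eps) * 1e-12
  for (j in seq_along(d)) {
    x[, j] <- if (tiny[j]) {
      nrm <- frob(x[, j])
      if (nrm > 0) x[, j] / nrm else x[, j]
    } else x[, j] / d[j]
  }
  x
}

fix_svd_signs <- function(s) {
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  s
}

#' @export
print.svd_triplet <- function(x, ...) {
  cat(sprintf("svd_triplet: %d x %d, k = %d\n", nrow(x$u), nrow(x$v),
              length(x$d)))
  cat("singular values:", format(x$d, digits = 4), "\n")
  invisible(x)
}

# Rank-k approximation M ~ u diag(d) v'; k = 0 gives an all-zero matrix.
# Returns scores (u diag(d)), loadings (t(v)) and the product.
truncated_approx <- function(M, k) {
  m <- nrow(M); p <- ncol(M)
  if (k == 0) {
    return(list(scores = matrix(0, m, 0), loadings = matrix(0, 0, p),
                approx = matrix(0, m, p)))
  }
  s <- partial_svd(M, k)
  scores <- s$u * rep(s$d, each = m)
  loadings <- t(s$v)
  list(scores = scores, loadings = loadings, approx = scores %*% loadings,
       v = s$v, d = s$d, u = s$u)
}

# top singular values only (no vectors); cheap path for permutation nulls
singular_values <- function(M, k = min(dim(M))) {
  m <- nrow(M); p <- ncol(M)
  if (min(m, p) <= 256L || k > min(m, p) %/% 4L) {
    d <- svd(M, nu = 0, nv = 0)$d
  } else if (m <= p) {
    d <- sqrt(pmax(eigen(tcrossprod(M), symmetric = TRUE,
                         only.values = TRUE)$values, 0))
  } else {
    d <- sqrt(pmax(eigen(crossprod(M), symmetric = TRUE,
                         only.values = TRUE)$values, 0))
  }
  d[seq_len(min(k, length(d)))]
}
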