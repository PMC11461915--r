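#' Principal variance component analysis
#'
#' Attributes the total variability of an expression matrix to batch,
#' cell type and residual error. The leading principal components of the
#' cell-by-cell covariance are computed; for each PC score vector a mixed
#' linear model with batch and cell type as random effects is fitted
#' (REML via lme4; negative components cannot occur), giving per-PC
#' variance-component proportions which are then averaged with each PC's
#' eigenvalue share as weight.
#'
#' @param matrix p x n numeric matrix (genes x cells); gene means are
#'   removed internally.
#' @param batch_labels,cell_labels per-cell factors. A factor with a
#'   single level contributes a fixed 0 component.
#' @param n_pcs number of leading PCs, default 10.
#' @return named numeric vector `c(batch, cell, residual)` summing to 1.
#' @export
pvca <- function(matrix, batch_labels, cell_labels, n_pcs = 10) {
  m <- as_dense(matrix)
  n <- ncol(m)
  if (length(batch_labels) != n || length(cell_labels) != n)
    stop("labels must have one entry per cell")
  if (n_pcs > min(dim(m))) stop("n_pcs exceeds matrix dimensions")
  batch <- factor(batch_labels)
  cell <- factor(cell_labels)
  m <- m - rowMeans(m)
  s <- partial_svd(m, n_pcs)
  scores <- s$v * rep(s$d, each = n) # n x n_pcs cell scores
  evals <- s$d^2
  wts <- evals / sum(evals)

  use_batch <- nlevels(batch) > 1
  use_cell <- nlevels(cell) > 1
  props <- matrix(0, n_pcs, 3,
                  dimnames = list(NULL, c("batch", "cell", "residual")))
  df <- data.frame(batch = batch, cell = cell)
  for (j in seq_len(n_pcs)) {
    df$y <- scores[, j]
    vc <- pc_variance_components(df, use_batch, use_cell)
    props[j, ] <- vc / sum(vc)
  }
  out <- colSums(props * wts)
  out / sum(out)
}

pc_variance_components <- function(df, use_batch, use_cell) {
  terms <- c(if (use_batch) "(1 | batch)", if (use_cell) "(1 | cell)")
  if (length(terms) == 0 || stats::var(df$y) == 0)
    return(c(batch = 0, cell = 0, residual = max(stats::var(df$y),
                                                 .Machine$double.eps)))
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) { # degenerate fit: fall back to one-way moment estimates
    return(c(batch = if (use_batch) mom_one_way(df$y, df$batch) else 0,
             cell = if (use_cell) mom_one_way(df$y, df$cell) else 0,
             residual = stats::var(df$y)))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) max(v, 0) else 0
  }
  c(batch = get("batch"), cell = get("cell"), residual = get("Residual"))
}

# one-way ANOVA method-of-moments variance component, truncated at 0
mom_one_way <- function(y, g) {
  g <- droplevels(factor(g))
  a <- nlevels(g)
  if (a < 2) return(0)
  n <- length(y)
  ni <- as.integer(table(g))
  means <- tapply(y, g, mean)
  ssb <- sum(ni * (means - mean(y))^2)
  ssw <- sum((y - means[as.integer(g)])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  n0 <- (n - sum(ni^2) / n) / (a - 1)
  max((msb - msw) / n0, 0)
}
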