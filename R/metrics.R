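#' Per-cell embedding with labels attached
#'
#' Light container used by all integration metrics: an n x d coordinate
#' matrix plus the batch (and optionally cell-type) label of every cell.
#'
#' @param coords n x d numeric matrix of per-cell coordinates.
#' @param batch length-n batch labels.
#' @param cell_type optional length-n cell-type labels.
#' @param provenance one of `"pca-of-matrix"`, `"joint-scores"`,
#'   `"external"`.
#' @return An object of class `Embedding`.
#' @export
make_embedding <- function(coords, batch, cell_type = NULL,
                           provenance = c("external", "pca-of-matrix",
                                          "joint-scores")) {
  provenance <- match.arg(provenance)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("embedding coordinates must be finite")
  if (length(batch) != nrow(coords))
    stop("one batch label per embedding row required")
  if (!is.null(cell_type) && length(cell_type) != nrow(coords))
    stop("one cell-type label per embedding row required")
  structure(list(coords = coords, batch = factor(batch),
                 cell_type = if (is.null(cell_type)) NULL
                             else factor(cell_type),
                 provenance = provenance),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d dims (%s), %d batches%s\n",
              nrow(x$coords), ncol(x$coords), x$provenance,
              nlevels(x$batch),
              if (is.null(x$cell_type)) ""
              else sprintf(", %d cell types", nlevels(x$cell_type))))
  invisible(x)
}

#' Principal-component embedding of an expression matrix
#'
#' Scores of each cell on the `d` leading principal components of a
#' genes x cells matrix (gene means are removed first). This is the
#' standard input representation for the integration metrics: 30 PCs by
#' default.
#'
#' @param matrix p x n numeric matrix (genes x cells).
#' @param d number of components, default 30.
#' @param batch,cell_type per-cell labels forwarded to [make_embedding()].
#' @return An `Embedding` with provenance `"pca-of-matrix"`.
#' @export
pca_embed <- function(matrix, d = 30, batch = NULL, cell_type = NULL) {
  m <- as_dense(matrix)
  if (d < 1 || d > min(dim(m)))
    stop(sprintf("d must lie in [1, %d]", min(dim(m))))
  m <- m - rowMeans(m)
  s <- partial_svd(m, d)
  scores <- s$v * rep(s$d, each = ncol(m))
  if (is.null(batch)) batch <- rep("all", ncol(m))
  make_embedding(scores, batch, cell_type, provenance = "pca-of-matrix")
}

#' Embedding from a fitted model's joint scores
#'
#' @param model a fitted `JIVEModel`.
#' @return An `Embedding` with provenance `"joint-scores"`.
#' @export
joint_embedding <- function(model) {
  n_i <- model$n_per_batch
  make_embedding(model$U, rep(model$batch_labels, n_i),
                 cell_type = if (is.null(model$cell_types)) NULL
                             else unlist(model$cell_types, use.names = FALSE),
                 provenance = "joint-scores")
}

# squared Euclidean distances from the rows `q` of E to all rows of E
dist2_to_all <- function(E, q) {
  n2 <- rowSums(E^2)
  d2 <- outer(n2[q], n2, "+") - 2 * (E[q, , drop = FALSE] %*% t(E))
  pmax(d2, 0)
}

#' kBET acceptance rate
#'
#' k-nearest-neighbor batch-effect test: for randomly chosen cells, a
#' Pearson chi-squared test compares the batch composition of the cell's
#' `k0`-nearest neighborhood (Euclidean, the query cell included) against
#' the global batch proportions, with `#batches - 1` degrees of freedom. A
#' well-mixed embedding should fail to reject most tests; the acceptance
#' rate is `1 - rejection rate`, so larger is better.
#'
#' @param embedding an `Embedding` with >= 2 batches.
#' @param fraction neighborhood size as a fraction of `n`
#'   (`k0 = round(fraction * n)`); the standard sweep uses
#'   0.05, 0.10, 0.15, 0.20, 0.25.
#' @param alpha test level, default 0.05.
#' @param n_tests number of sampled neighborhoods (without replacement),
#'   default 100.
#' @param seed optional seed.
#' @return acceptance rate in `[0, 1]`.
#' @export
kbet_acceptance <- function(embedding, fraction, alpha = 0.05,
                            n_tests = 100, seed = NULL) {
  stopifnot(inherits(embedding, "Embedding"),
            fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  E <- embedding$coords
  b <- embedding$batch
  n <- nrow(E)
  if (nlevels(b) < 2) stop("kBET needs at least 2 batches")
  props <- table(b) / n
  if (any(props == 0)) stop("a batch level is absent from the data")
  k0 <- round(fraction * n)
  if (k0 < nlevels(b))
    stop("neighborhood size smaller than the number of batches")
  q <- sample.int(n, min(n_tests, n))
  d2 <- dist2_to_all(E, q)
  expd <- k0 * as.numeric(props)
  rejected <- vapply(seq_along(q), function(j) {
    nb <- order(d2[j, ])[seq_len(k0)]
    obs <- tabulate(b[nb], nbins = nlevels(b))
    stat <- sum((obs - expd)^2 / expd)
    pval <- stats::pchisq(stat, df = nlevels(b) - 1, lower.tail = FALSE)
    pval < alpha
  }, logical(1))
  1 - mean(rejected)
}

# mean silhouette width of labeled points (Euclidean); singleton clusters
# get silhouette 0
mean_silhouette <- function(coords, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("silhouette needs at least 2 clusters")
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  counts <- as.integer(table(labels))
  # G[i, l]: mean distance of point i to cluster l (own cluster: excl. self)
  G <- t(rowsum(D, labels)) # n x L of distance sums
  own <- cbind(seq_len(n), as.integer(labels))
  a <- G[own] / pmax(counts[as.integer(labels)] - 1L, 1L)
  G_mean <- sweep(G, 2, counts, "/")
  G_mean[own] <- Inf
  bmin <- apply(G_mean, 1, min)
  s <- (bmin - a) / pmax(a, bmin)
  s[counts[as.integer(labels)] == 1L] <- 0
  mean(s)
}

#' Average silhouette width under repeated subsampling
#'
#' Subsamples the embedding (80% by default), computes the mean silhouette
#' width with batch labels as clusters (mixing: lower is better, reported
#' downstream as `1 - ASW batch`) and with cell-type labels as clusters
#' (purity: higher is better), and repeats; the medians over repeats are
#' returned. Silhouettes use Euclidean distance and lie in `[-1, 1]`;
#' singleton-cluster points score 0.
#'
#' @param embedding an `Embedding`; cell-type labels required for
#'   `asw_cell`.
#' @param subsample_fraction fraction of cells per repeat, default 0.8.
#' @param repeats number of subsamples, default 20.
#' @param seed optional seed.
#' @return list with `asw_batch` and `asw_cell` (NA when no cell-type
#'   labels), each the median over repeats, plus the per-repeat values.
#' @export
asw_report <- function(embedding, subsample_fraction = 0.8, repeats = 20,
                       seed = NULL) {
  stopifnot(inherits(embedding, "Embedding"))
  if (!is.null(seed)) set.seed(seed)
  E <- embedding$coords
  n <- nrow(E)
  m <- max(2L, floor(subsample_fraction * n))
  has_batch <- nlevels(embedding$batch) >= 2
  has_cell <- !is.null(embedding$cell_type) &&
    nlevels(embedding$cell_type) >= 2
  if (!has_batch && !has_cell)
    stop("asw_report needs at least one label set with 2+ clusters")
  vb <- vc <- rep(NA_real_, repeats)
  for (r in seq_len(repeats)) {
    idx <- subsample_with_clusters(
      n, m,
      if (has_batch) embedding$batch else NULL,
      if (has_cell) embedding$cell_type else NULL)
    if (has_batch)
      vb[r] <- mean_silhouette(E[idx, , drop = FALSE], embedding$batch[idx])
    if (has_cell)
      vc[r] <- mean_silhouette(E[idx, , drop = FALSE],
                               embedding$cell_type[idx])
  }
  list(asw_batch = if (has_batch) stats::median(vb) else NA_real_,
       asw_cell = if (has_cell) stats::median(vc) else NA_real_,
       per_repeat = data.frame(batch = vb, cell = vc))
}

# draw a subsample keeping >= 2 members in every cluster of every label set
subsample_with_clusters <- function(n, m, ...) {
  labels <- Filter(Negate(is.null), list(...))
  for (try in 1:100) {
    idx <- sample.int(n, m)
    ok <- all(vapply(labels, function(l)
      all(table(droplevels(l[idx])) >= 2) &&
        nlevels(droplevels(l[idx])) == nlevels(droplevels(l)), logical(1)))
    if (ok) return(idx)
  }
  warning("could not draw a subsample with >= 2 members per cluster; using the last draw")
  idx
}

#' Local inverse Simpson's index
#'
#' For every cell, Gaussian kernel weights over its `K = 3 * perplexity`
#' nearest neighbors are tuned by bisection so the weight entropy equals
#' `log(perplexity)`; label probabilities are the summed weights per label
#' and the score is the inverse Simpson's index `1 / sum(q_l^2)` — the
#' effective number of labels in the cell's neighborhood. Scores lie in
#' `[1, #labels]`. With batch labels (iLISI) higher means better mixing;
#' with cell-type labels (cLISI) lower means better purity (reported
#' downstream as `1 - cLISI` after scaling).
#'
#' @param embedding an `Embedding`, or a bare coordinate matrix.
#' @param labels per-cell labels; or the string `"batch"` / `"cell_type"`
#'   to take them from the embedding.
#' @param perplexity kernel perplexity, default 30; lowered with a warning
#'   when `n <= 3 * perplexity`.
#' @return numeric vector of per-cell scores.
#' @export
lisi_scores <- function(embedding, labels = "batch", perplexity = 30) {
  if (inherits(embedding, "Embedding")) {
    E <- embedding$coords
    if (is.character(labels) && length(labels) == 1)
      labels <- switch(labels, batch = embedding$batch,
                       cell_type = embedding$cell_type,
                       stop("unknown label name: ", labels))
  } else E <- as.matrix(embedding)
  labels <- factor(labels)
  n <- nrow(E)
  if (length(labels) != n) stop("one label per cell required")
  if (nlevels(labels) == 1) return(rep(1, n))
  if (n <= 3 * perplexity) {
    perplexity <- max(1, floor((n - 1) / 3))
    warning("perplexity lowered to ", perplexity, " for n = ", n)
  }
  K <- min(3 * perplexity, n - 1)
  target <- log(perplexity)
  lab <- as.integer(labels)
  L <- nlevels(labels)
  scores <- numeric(n)
  d2all <- dist2_to_all(E, seq_len(n))
  for (i in seq_len(n)) {
    d2 <- d2all[i, ]
    nb <- order(d2)
    nb <- nb[nb != i][seq_len(K)]
    w <- gaussian_kernel_weights(d2[nb], target)
    q <- vapply(seq_len(L), function(l) sum(w[lab[nb] == l]), numeric(1))
    scores[i] <- 1 / sum(q^2)
  }
  scores
}

# bisection on precision beta so that entropy(w) = target; 50 steps, 1e-5
gaussian_kernel_weights <- function(d2, target, iters = 50, tol = 1e-5) {
  if (all(d2 == 0)) return(rep(1 / length(d2), length(d2)))
  beta <- 1 / stats::median(d2[d2 > 0])
  lo <- 0; hi <- Inf
  for (it in seq_len(iters)) {
    w <- exp(-beta * (d2 - min(d2)))
    w <- w / sum(w)
    H <- -sum(ifelse(w > 0, w * log(w), 0))
    if (abs(H - target) < tol) break
    if (H > target) { # too flat: increase precision
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- (lo + beta) / 2
    }
  }
  w
}

#' Min-max scaling of a metric across methods
#'
#' Rescales one metric's values over a set of compared methods to
#' `[0, 1]`; optionally inverts (`1 - x`) afterwards, the convention used
#' for ASW batch and cLISI so that larger is always better.
#'
#' @param values named numeric vector (one value per method).
#' @param invert apply `1 - scaled` after scaling.
#' @return named numeric vector in `[0, 1]`.
#' @export
scale_across_methods <- function(values, invert = FALSE) {
  v <- unlist(values)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("all methods have equal values; scaled values are all 0")
    out <- stats::setNames(rep(0, length(v)), names(v))
  } else {
    out <- (v - rng[1]) / diff(rng)
  }
  if (invert) out <- 1 - out
  out
}

#' Full metric report for one embedding
#'
#' Convenience wrapper running kBET over a neighborhood-fraction sweep,
#' ASW (batch and cell type) and LISI (iLISI batch, cLISI cell type) with
#' one seed. Cross-method min-max scaling is a separate step
#' ([scale_across_methods()]) since it needs several methods' values.
#'
#' @param embedding an `Embedding`.
#' @param kbet_fractions neighborhood fractions, default
#'   `c(0.05, 0.1, 0.15, 0.2, 0.25)`.
#' @param seed seed for all stochastic steps.
#' @param ... forwarded to [kbet_acceptance()] and [asw_report()].
#' @return list of class `MetricReport`.
#' @export
metric_report <- function(embedding,
                          kbet_fractions = c(0.05, 0.1, 0.15, 0.2, 0.25),
                          seed = 1, ...) {
  kb <- vapply(kbet_fractions, function(f)
    kbet_acceptance(embedding, f, seed = seed, ...), numeric(1))
  names(kb) <- paste0("f", kbet_fractions)
  asw <- asw_report(embedding, seed = seed)
  il <- stats::median(lisi_scores(embedding, "batch"))
  cl <- if (!is.null(embedding$cell_type))
    stats::median(lisi_scores(embedding, "cell_type")) else NA_real_
  structure(list(kbet_acceptance = kb,
                 asw_batch = asw$asw_batch, asw_cell = asw$asw_cell,
                 ilisi_batch = il, clisi_cell = cl, seed = seed),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("MetricReport\n  kBET acceptance:",
      paste(sprintf("%s=%.3f", names(x$kbet_acceptance), x$kbet_acceptance),
            collapse = " "), "\n")
  cat(sprintf("  ASW batch %.4f | ASW cell %.4f\n", x$asw_batch, x$asw_cell))
  cat(sprintf("  iLISI batch %.4f | cLISI cell %.4f\n", x$ilisi_batch,
              x$clisi_cell))
  invisible(x)
}
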