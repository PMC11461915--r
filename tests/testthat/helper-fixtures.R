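# Shared fixtures and independent oracle implementations.
# Oracles are deliberately written with plain base-R (full svd(), explicit
# loops) so they never share code paths with the package internals.

# small two-batch counts collection with known labels
tiny_counts <- function(seed = 1, p = 5, n = c(3, 4)) {
  set.seed(seed)
  mats <- lapply(n, function(ni) matrix(rpois(p * ni, 5), p, ni))
  batch_collection(mats, gene_ids = paste0("g", seq_len(p)),
                   batch_labels = paste0("b", seq_along(n)),
                   cell_types = lapply(n, function(ni)
                     sample(c("t1", "t2"), ni, replace = TRUE)),
                   value_space = "counts")
}

# centered gaussian collection (no structure unless stated)
gaussian_collection <- function(n = c(10, 10), p = 8, seed = 1, sd = 1) {
  set.seed(seed)
  mats <- lapply(n, function(ni) {
    m <- matrix(rnorm(p * ni, sd = sd), p, ni)
    m
  })
  batch_collection(mats, gene_ids = paste0("g", seq_len(p)),
                   batch_labels = paste0("b", seq_along(n)),
                   value_space = "centered")
}

frobnorm <- function(x) sqrt(sum(x^2))

# independent brute-force alternating JIVE minimizer (full SVD, random or
# given initialization), returning the final SSE
brute_jive_sse <- function(Ylist, r, ri, init = NULL, tol = 1e-12,
                           maxit = 20000) {
  k <- length(Ylist)
  n_i <- sapply(Ylist, nrow)
  p <- ncol(Ylist[[1]])
  idx <- split(seq_len(sum(n_i)), rep(seq_len(k), n_i))
  if (is.null(init))
    init <- lapply(Ylist, function(Y) matrix(0, nrow(Y), ncol(Y)))
  A <- init
  Ys <- do.call(rbind, Ylist)
  sse_old <- Inf
  for (it in seq_len(maxit)) {
    s <- svd(Ys - do.call(rbind, A))
    J <- if (r > 0)
      s$u[, seq_len(r), drop = FALSE] %*%
        (s$d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
    else matrix(0, sum(n_i), p)
    V <- s$v[, seq_len(r), drop = FALSE]
    for (i in seq_len(k)) {
      Zi <- Ylist[[i]] - J[idx[[i]], , drop = FALSE]
      if (r > 0) Zi <- Zi - (Zi %*% V) %*% t(V)
      if (ri[i] > 0) {
        si <- svd(Zi)
        A[[i]] <- si$u[, seq_len(ri[i]), drop = FALSE] %*%
          (si$d[seq_len(ri[i])] * t(si$v[, seq_len(ri[i]), drop = FALSE]))
      } else A[[i]] <- matrix(0, n_i[i], p)
    }
    sse <- sum((Ys - J - do.call(rbind, A))^2)
    if (abs(sse_old - sse) < tol * max(sse, 1)) break
    sse_old <- sse
  }
  sse
}

# random rank-ri starting individual structures for multi-start runs
random_init <- function(Ylist, ri, seed) {
  set.seed(seed)
  lapply(seq_along(Ylist), function(i) {
    Y <- Ylist[[i]]
    if (ri[i] == 0) return(matrix(0, nrow(Y), ncol(Y)))
    R <- matrix(rnorm(nrow(Y) * ncol(Y)), nrow(Y))
    sv <- svd(R)
    sv$u[, seq_len(ri[i]), drop = FALSE] %*%
      (sv$d[seq_len(ri[i])] * t(sv$v[, seq_len(ri[i]), drop = FALSE])) *
      stats::sd(Y)
  })
}

# brute-force silhouette: literal per-point a/b computation
brute_silhouette_mean <- function(coords, labels) {
  labels <- as.character(labels)
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force LISI with explicit kernel weights (independent bisection)
brute_lisi <- function(coords, labels, perplexity = 30) {
  labels <- factor(labels)
  n <- nrow(coords)
  K <- min(3 * perplexity, n - 1)
  D2 <- as.matrix(dist(coords))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- ord[ord != i][seq_len(K)]
    d2 <- D2[i, nb]
    if (all(d2 == 0)) {
      w <- rep(1 / K, K)
    } else {
      lo <- 0; hi <- Inf; beta <- 1 / median(d2[d2 > 0])
      for (it in 1:50) {
        w <- exp(-beta * (d2 - min(d2))); w <- w / sum(w)
        H <- -sum(w[w > 0] * log(w[w > 0]))
        if (abs(H - log(perplexity)) < 1e-5) break
        if (H > log(perplexity)) {
          lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else 2 * beta
        } else { hi <- beta; beta <- (lo + beta) / 2 }
      }
    }
    q <- tapply(w, labels[nb], sum, default = 0)
    out[i] <- 1 / sum(q^2)
  }
  out
}

# cached medium-scale correction experiment shared by acceptance tests 6/7
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_correction_run <- function(cells, seed = 2024) {
  key <- paste0("run_", paste(cells, collapse = "_"))
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  # scaled-down world: 2000-gene panel; library size e^8 ~ 3000 counts per
  # cell keeps per-gene depth realistic for a droplet-era HVG panel (the
  # full-transcriptome default e^11 would put ~30 counts on every gene)
  cfg <- simulation_config(n_genes = 2000, cells_per_batch = cells,
                           de_location = 0.75, batch_location = 0.75,
                           libsize_location = 8, seed = seed)
  sim <- simulate_counts(cfg)
  cen <- center_batches(log_normalize(sim$collection))
  batch <- rep(cen$collection$batch_labels, cells)
  ct <- unlist(cen$collection$cell_types, use.names = FALSE)
  raw <- do.call(cbind, cen$collection$matrices)
  model <- fit_jive(cen$collection, 10, 20, tol = 1e-5, max_iter = 60)
  emb_raw <- pca_embed(raw, 30, batch = batch, cell_type = ct)
  emb_jive <- joint_embedding(model)
  res <- list(
    kbet_raw = kbet_acceptance(emb_raw, 0.05, seed = 1),
    kbet_jive = kbet_acceptance(emb_jive, 0.05, seed = 1),
    asw_raw = asw_report(emb_raw, seed = 1),
    asw_jive = asw_report(emb_jive, seed = 1),
    model = model, raw = raw, batch = batch, cell_type = ct)
  .acceptance_cache[[key]] <- res
  res
}
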