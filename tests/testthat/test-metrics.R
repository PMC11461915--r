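test_that("pca_embed reproduces low-rank geometry and matches full SVD", {
  set.seed(41)
  # exact rank-2 data: pairwise distances preserved with d = 2
  p <- 20; n <- 15
  X <- matrix(rnorm(p * 2), p, 2) %*% matrix(rnorm(2 * n), 2, n)
  X <- X - rowMeans(X)
  emb <- pca_embed(X, 2)
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(t(X))),
               tolerance = 1e-8)
  # random matrix: scores match full-SVD-derived scores up to sign
  M <- matrix(rnorm(50 * 40), 50, 40)
  Mc <- M - rowMeans(M)
  e <- pca_embed(M, 5)
  fs <- svd(Mc)
  sc <- fs$v[, 1:5] * rep(fs$d[1:5], each = 40)
  for (j in 1:5)
    expect_equal(abs(e$coords[, j]), abs(sc[, j]), tolerance = 1e-8)
  # 1-D data: component aligned with the varying direction
  v <- rnorm(10); v <- v / sqrt(sum(v^2))
  X1 <- v %*% t(seq(-2, 2, length.out = 9))
  e1 <- pca_embed(X1, 1)
  expect_equal(abs(cor(e1$coords[, 1], seq(-2, 2, length.out = 9))), 1,
               tolerance = 1e-10)
  expect_error(pca_embed(M, 60), "d must lie")
})

test_that("kbet chi-squared math matches the hand computation", {
  # neighborhood counts (4, 0) against global (1/2, 1/2):
  # chi2 = (4-2)^2/2 + (0-2)^2/2 = 4, df 1, p ~ 0.0455 -> rejected at 0.05
  expect_equal(pchisq(4, df = 1, lower.tail = FALSE), 0.04550026,
               tolerance = 1e-6)
  # engineered embedding where every 4-neighborhood is single-batch
  coords <- cbind(c(0, 0.1, 0.2, 0.3, 100, 100.1, 100.2, 100.3), 0)
  emb <- make_embedding(coords, rep(c("a", "b"), each = 4))
  expect_equal(kbet_acceptance(emb, fraction = 0.5, n_tests = 8, seed = 1),
               0)
  # the same points with alternating labels are perfectly mixed
  emb2 <- make_embedding(coords, rep(c("a", "b"), 4))
  expect_equal(kbet_acceptance(emb2, fraction = 0.5, n_tests = 8, seed = 1),
               1)
})

test_that("kbet acceptance is high for identically distributed batches", {
  accs <- sapply(1:5, function(s) {
    set.seed(s)
    emb <- make_embedding(matrix(rnorm(400 * 5), 400),
                          sample(rep(c("a", "b"), 200)))
    kbet_acceptance(emb, 0.1, seed = s)
  })
  expect_true(all(accs >= 0.8))
  # separated clouds -> acceptance ~ 0
  set.seed(6)
  emb <- make_embedding(rbind(matrix(rnorm(200 * 3), 200),
                              matrix(rnorm(200 * 3, mean = 50), 200)),
                        rep(c("a", "b"), each = 200))
  expect_lt(kbet_acceptance(emb, 0.1, seed = 2), 0.05)
  expect_error(kbet_acceptance(
    make_embedding(matrix(rnorm(20), 10), factor(rep("a", 10),
                                                 levels = c("a", "b"))),
    0.5), "absent|2 batches")
})

test_that("silhouettes match the worked 1-D example and a brute-force oracle", {
  # points {0, 1} in cluster A, {10, 11} in cluster B
  coords <- matrix(c(0, 1, 10, 11), 4, 1)
  labels <- c("A", "A", "B", "B")
  emb <- make_embedding(coords, rep("x", 4), cell_type = labels)
  # hand values: s = (b - a)/max(a, b)
  expect_equal(brute_silhouette_mean(coords, labels),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))
  rep <- asw_report(emb, subsample_fraction = 1, repeats = 1, seed = 1)
  expect_equal(rep$asw_cell, 0.8997, tolerance = 1e-4)
  # brute-force equivalence on random labeled data
  set.seed(42)
  for (i in 1:5) {
    co <- matrix(rnorm(60), 30, 2)
    la <- sample(c("u", "v", "w"), 30, replace = TRUE)
    e <- make_embedding(co, la)
    r <- asw_report(e, subsample_fraction = 1, repeats = 1, seed = 1)
    expect_equal(r$asw_batch, brute_silhouette_mean(co, la),
                 tolerance = 1e-12)
  }
})

test_that("asw_report behaves at the exchangeable and adversarial limits", {
  set.seed(43)
  # random labels on one distribution -> ASW ~ 0
  co <- matrix(rnorm(300 * 2), 300)
  e <- make_embedding(co, sample(rep(c("a", "b"), 150)))
  r <- asw_report(e, seed = 3)
  expect_lt(abs(r$asw_batch), 0.05)
  # duplicated points with swapped labels -> negative ASW
  co2 <- rbind(matrix(rnorm(40), 20, 2))
  dup <- rbind(co2, co2)
  lab <- c(rep("a", 20), rep("b", 20))
  expect_lt(brute_silhouette_mean(dup, lab), 0)
  e2 <- make_embedding(dup, lab)
  r2 <- asw_report(e2, subsample_fraction = 1, repeats = 1, seed = 1)
  expect_lt(r2$asw_batch, 0)
  expect_error(asw_report(make_embedding(co2, rep("a", 20))),
               "2\\+ clusters")
})

test_that("inverse Simpson arithmetic and degenerate label sets", {
  # probabilities (0.5, 0.25, 0.25) -> 1/0.375 = 2.6667
  expect_equal(1 / sum(c(0.5, 0.25, 0.25)^2), 2.666667, tolerance = 1e-6)
  # one label -> exactly 1 for every cell
  set.seed(44)
  co <- matrix(rnorm(120 * 2), 120)
  expect_equal(lisi_scores(co, rep("a", 120)), rep(1, 120))
  # perfectly interleaved grid of two labels -> scores near 2
  g <- expand.grid(x = 1:12, y = 1:12)
  lab <- rep(c("a", "b"), length.out = 144)
  sc <- suppressWarnings(lisi_scores(as.matrix(g), lab, perplexity = 20))
  expect_gt(median(sc), 1.9)
  expect_true(all(sc >= 1 & sc <= 2 + 1e-8))
})

test_that("lisi_scores equals the brute-force kernel computation", {
  set.seed(45)
  for (i in 1:3) {
    n <- sample(80:150, 1)
    co <- matrix(rnorm(n * 4), n)
    lab <- sample(c("a", "b", "c"), n, replace = TRUE)
    got <- suppressWarnings(lisi_scores(co, lab, perplexity = 15))
    want <- brute_lisi(co, lab, perplexity = 15)
    expect_equal(got, want, tolerance = 1e-6)
    expect_true(all(got >= 1 - 1e-9 & got <= 3 + 1e-9))
  }
  # perplexity lowered with warning when n is small
  expect_warning(lisi_scores(matrix(rnorm(40), 20), rep(c("a", "b"), 10),
                             perplexity = 30), "perplexity lowered")
})

test_that("scale_across_methods implements min-max with inversion", {
  expect_equal(scale_across_methods(c(A = 2, B = 4, C = 3)),
               c(A = 0, B = 1, C = 0.5))
  expect_equal(scale_across_methods(c(A = 0, B = 1), invert = TRUE),
               c(A = 1, B = 0))
  expect_warning(out <- scale_across_methods(c(A = 2, B = 2)), "equal")
  expect_equal(out, c(A = 0, B = 0))
})

test_that("pvca attributes variance sensibly", {
  set.seed(46)
  n <- 120; p <- 60
  batch <- rep(c("b1", "b2"), each = n / 2)
  cell <- sample(c("t1", "t2"), n, replace = TRUE)
  # large constant batch shift, no cell structure
  X <- matrix(rnorm(p * n, sd = 0.5), p, n)
  X[, batch == "b2"] <- X[, batch == "b2"] + 3
  pv <- pvca(X, batch, cell)
  expect_gt(pv["batch"], 0.8)
  expect_lt(pv["cell"], 0.05)
  expect_equal(sum(pv), 1, tolerance = 1e-9)
  # closed-form one-way check on the dominant PC's scores
  s <- svd(X - rowMeans(X))
  y <- s$v[, 1] * s$d[1]
  a <- 2; ni <- table(batch); ntot <- n
  means <- tapply(y, batch, mean)
  msb <- sum(ni * (means - mean(y))^2) / (a - 1)
  msw <- sum((y - means[batch])^2) / (ntot - a)
  n0 <- (ntot - sum(ni^2) / ntot) / (a - 1)
  sigma_b <- max((msb - msw) / n0, 0)
  expect_gt(sigma_b / (sigma_b + msw), 0.9) # PC1 is essentially batch
  # random labels on pure noise -> residual ~ 1
  pv2 <- pvca(matrix(rnorm(p * n), p, n), sample(batch), cell)
  expect_gt(pv2["residual"], 0.9)
  # invariance to relabeling factor levels
  pv3 <- pvca(X, ifelse(batch == "b1", "z9", "z1"),
              ifelse(cell == "t1", "k2", "k1"))
  expect_equal(unname(pv3), unname(pv), tolerance = 1e-6)
  # single-level factor contributes zero
  pv4 <- pvca(X, batch, rep("only", n))
  expect_equal(unname(pv4["cell"]), 0)
})

test_that("metric_report aggregates and respects value ranges", {
  set.seed(47)
  co <- rbind(matrix(rnorm(80 * 3), 80), matrix(rnorm(80 * 3, 2), 80))
  emb <- make_embedding(co, rep(c("a", "b"), each = 80),
                        cell_type = sample(c("t1", "t2"), 160, TRUE))
  rep <- suppressWarnings(metric_report(emb, kbet_fractions = c(0.1, 0.2),
                                        seed = 1))
  expect_s3_class(rep, "MetricReport")
  expect_true(all(rep$kbet_acceptance >= 0 & rep$kbet_acceptance <= 1))
  expect_true(rep$asw_batch >= -1 && rep$asw_batch <= 1)
  expect_true(rep$ilisi_batch >= 1 && rep$ilisi_batch <= 2)
  expect_true(rep$clisi_cell >= 1 && rep$clisi_cell <= 2)
})
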