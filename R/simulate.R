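#' Low-rank Gaussian multi-batch benchmark data
#'
#' Generates per-batch cells x genes matrices `Y_i = U_i S + W_i S_i + E_i`
#' with a joint loading matrix `S` shared by all batches, individual
#' loadings `S_i` exactly orthogonal to `S` (and to each other), and
#' i.i.d. Gaussian noise. Defaults mirror the classic two-batch benchmark:
#' two 200 x 1000 matrices, rank-1 joint plus rank-1 individual structure
#' plus standard-normal noise.
#'
#' Scales are per-entry root-mean-square amplitudes of the corresponding
#' structure, so `joint_scale = individual_scale = noise_sd = 1` gives the
#' three parts comparable per-entry energy.
#'
#' @param n_rows cells per batch, default `c(200, 200)`.
#' @param p genes, default 1000.
#' @param joint_rank,individual_ranks structure ranks (defaults 1 and
#'   `c(1, 1)`).
#' @param joint_scale,individual_scale,noise_sd amplitudes (defaults 1).
#' @param seed optional integer seed.
#' @return list with `collection` (a [batch_collection()] in centered
#'   space, genes x cells) and `truth` (exact `joint`, `individual`,
#'   `noise` matrices per batch in cells x genes orientation, plus `S` and
#'   `S_individual`).
#' @export
simulate_lowrank <- function(n_rows = c(200, 200), p = 1000,
                             joint_rank = 1,
                             individual_ranks = rep(1, length(n_rows)),
                             joint_scale = 1, individual_scale = 1,
                             noise_sd = 1, seed = NULL) {
  k <- length(n_rows)
  stopifnot(k >= 1, joint_rank >= 0, all(individual_ranks >= 0),
            joint_scale >= 0, individual_scale >= 0, noise_sd >= 0,
            length(individual_ranks) == k)
  r <- joint_rank; ri <- individual_ranks
  if (r + max(ri) > min(min(n_rows), p))
    stop("total rank exceeds matrix dimensions")
  if (!is.null(seed)) set.seed(seed)

  # one orthonormal gene-space basis carved into joint + individual blocks,
  # so S %*% t(S_i) = 0 holds exactly
  q_tot <- r + sum(ri)
  Q <- qr.Q(qr(matrix(stats::rnorm(p * max(q_tot, 1)), p)))
  S <- t(Q[, seq_len(r), drop = FALSE])            # r x p, orthonormal rows
  offs <- r + cumsum(c(0, ri))
  S_i <- lapply(seq_len(k), function(i)
    t(Q[, offs[i] + seq_len(ri[i]), drop = FALSE])) # r_i x p

  joint <- vector("list", k); indiv <- vector("list", k)
  noise <- vector("list", k); mats <- vector("list", k)
  for (i in seq_len(k)) {
    ni <- n_rows[i]
    Ui <- matrix(stats::rnorm(ni * r), ni, r)
    Wi <- matrix(stats::rnorm(ni * ri[i]), ni, ri[i])
    # sqrt(p/r) makes per-entry RMS of the structure equal its scale
    joint[[i]] <- if (r > 0)
      joint_scale * sqrt(p / r) * (Ui %*% S) else matrix(0, ni, p)
    indiv[[i]] <- if (ri[i] > 0)
      individual_scale * sqrt(p / ri[i]) * (Wi %*% S_i[[i]])
      else matrix(0, ni, p)
    noise[[i]] <- matrix(stats::rnorm(ni * p, sd = noise_sd), ni, p)
    mats[[i]] <- t(joint[[i]] + indiv[[i]] + noise[[i]]) # genes x cells
  }
  collection <- batch_collection(mats,
                                 gene_ids = paste0("g", seq_len(p)),
                                 batch_labels = paste0("batch", seq_len(k)),
                                 value_space = "centered")
  list(collection = collection,
       truth = list(joint = joint, individual = indiv, noise = noise,
                    S = S, S_individual = S_i))
}

#' Simulation configuration for multi-batch scRNA-seq counts
#'
#' Parameters of the Gamma-Poisson count generator ([simulate_counts()]).
#' Location parameters follow the convention that 0 means "effect absent"
#' (the multiplicative factor is exactly 1); nonzero locations are the
#' log-scale means of log-normal fold changes.
#'
#' @param n_genes genes, default 5000.
#' @param cells_per_batch cells per batch, default `c(500, 500)`
#'   (unbalanced preset: `c(800, 200)`).
#' @param n_cell_types number of cell types, default 3.
#' @param cell_type_proportions per-type proportions, default balanced;
#'   unbalanced preset `c(0.5, 0.3, 0.2)`.
#' @param de_location,de_scale log-normal location/scale of cell-type
#'   differential-expression factors (defaults 0.5 and 0.4).
#' @param batch_location,batch_scale log-normal location/scale of batch
#'   factors (defaults 0.5 and 0.1).
#' @param de_prob probability a gene is differentially expressed in a
#'   given cell type, default 0.1.
#' @param mean_shape,mean_rate Gamma parameters of gene base means,
#'   defaults 0.6 and 0.3.
#' @param libsize_location,libsize_scale log-normal library-size
#'   parameters, defaults 11 and 0.2.
#' @param bcv common biological coefficient of variation: counts are
#'   Gamma-Poisson (negative binomial) with this extra per-gene-per-cell
#'   dispersion. Default 0.4, the effective Splat-like BCV at these
#'   expression levels (common BCV plus the `1/sqrt(mean)` trend); 0
#'   gives pure Poisson counts.
#' @param dropout logical, add logistic dropout (default `FALSE`).
#' @param dropout_midpoint,dropout_shape logistic dropout parameters on
#'   the log-mean scale (defaults 0 and -1).
#' @param seed integer seed.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 5000,
                              cells_per_batch = c(500, 500),
                              n_cell_types = 3,
                              cell_type_proportions =
                                rep(1 / n_cell_types, n_cell_types),
                              de_location = 0.5, de_scale = 0.4,
                              batch_location = 0.5, batch_scale = 0.1,
                              de_prob = 0.1,
                              mean_shape = 0.6, mean_rate = 0.3,
                              libsize_location = 11, libsize_scale = 0.2,
                              bcv = 0.4,
                              dropout = FALSE, dropout_midpoint = 0,
                              dropout_shape = -1, seed = 1L) {
  cfg <- list(n_genes = n_genes, cells_per_batch = cells_per_batch,
              n_cell_types = n_cell_types,
              cell_type_proportions = cell_type_proportions,
              de_location = de_location, de_scale = de_scale,
              batch_location = batch_location, batch_scale = batch_scale,
              de_prob = de_prob, mean_shape = mean_shape,
              mean_rate = mean_rate, libsize_location = libsize_location,
              libsize_scale = libsize_scale, bcv = bcv, dropout = dropout,
              dropout_midpoint = dropout_midpoint,
              dropout_shape = dropout_shape, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  if (abs(sum(cfg$cell_type_proportions) - 1) > 1e-8)
    stop("cell_type_proportions must sum to 1")
  if (length(cfg$cell_type_proportions) != cfg$n_cell_types)
    stop("need one proportion per cell type")
  if (any(cfg$cells_per_batch <= 0)) stop("cells_per_batch must be positive")
  with(cfg, stopifnot(de_scale >= 0, batch_scale >= 0, de_location >= 0,
                      batch_location >= 0, de_prob >= 0, de_prob <= 1,
                      mean_shape > 0, mean_rate > 0, libsize_scale >= 0,
                      bcv >= 0))
  invisible(cfg)
}

#' Simulate multi-batch scRNA-seq counts
#'
#' Gamma-Poisson generative model in the style of the Splat simulator:
#' gene base means are Gamma distributed; each cell type applies
#' log-normal differential-expression factors to a random `de_prob` subset
#' of genes (factor direction uniform up/down); each batch applies
#' log-normal factors to every gene; a cell's expected counts are its
#' gene proportions rescaled to a log-normal library size; counts are
#' Poisson. A location parameter of 0 means the corresponding factors are
#' identically 1 (effect absent). Optional logistic dropout zeroes counts
#' with probability decreasing in the log expected mean.
#'
#' @param config a [simulation_config()].
#' @return list with `collection` (counts-space [batch_collection()] with
#'   cell-type labels) and `truth` (per-cell labels, gene base means,
#'   genes x types DE factors, genes x batches batch factors, library
#'   sizes).
#' @export
simulate_counts <- function(config) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  p <- cfg$n_genes
  k <- length(cfg$cells_per_batch)
  Tn <- cfg$n_cell_types

  lambda <- stats::rgamma(p, shape = cfg$mean_shape, rate = cfg$mean_rate)

  de <- matrix(1, p, Tn)
  if (cfg$de_location > 0) {
    for (t in seq_len(Tn)) {
      sel <- stats::runif(p) < cfg$de_prob
      sgn <- sample(c(-1, 1), sum(sel), replace = TRUE)
      de[sel, t] <- exp(sgn * stats::rnorm(sum(sel), cfg$de_location,
                                           cfg$de_scale))
    }
  }
  bf <- matrix(1, p, k)
  if (cfg$batch_location > 0) {
    for (b in seq_len(k)) {
      sgn <- sample(c(-1, 1), p, replace = TRUE)
      bf[, b] <- exp(sgn * stats::rnorm(p, cfg$batch_location,
                                        cfg$batch_scale))
    }
  }

  mats <- vector("list", k); types <- vector("list", k)
  libs <- vector("list", k)
  for (b in seq_len(k)) {
    ni <- cfg$cells_per_batch[b]
    tt <- sample(quota_types(ni, cfg$cell_type_proportions))
    L <- stats::rlnorm(ni, cfg$libsize_location, cfg$libsize_scale)
    m <- matrix(0L, p, ni)
    base <- lambda * bf[, b]
    for (c in seq_len(ni)) {
      mu <- base * de[, tt[c]]
      mu <- mu / sum(mu) * L[c]
      if (cfg$bcv > 0)
        mu <- mu * stats::rgamma(p, shape = 1 / cfg$bcv^2,
                                 rate = 1 / cfg$bcv^2)
      cnt <- stats::rpois(p, mu)
      if (cfg$dropout) {
        pdrop <- stats::plogis(cfg$dropout_shape *
                                 (log(mu + 1e-8) - cfg$dropout_midpoint))
        cnt[stats::runif(p) < pdrop] <- 0L
      }
      m[, c] <- cnt
    }
    mats[[b]] <- m
    types[[b]] <- paste0("type", tt)
    libs[[b]] <- L
  }
  collection <- batch_collection(mats,
                                 gene_ids = paste0("g", seq_len(p)),
                                 batch_labels = paste0("batch", seq_len(k)),
                                 cell_types = types,
                                 value_space = "counts")
  list(collection = collection,
       truth = list(batch = rep(paste0("batch", seq_len(k)),
                                cfg$cells_per_batch),
                    cell_type = unlist(types, use.names = FALSE),
                    gene_means = lambda, de_factors = de,
                    batch_factors = bf,
                    library_sizes = unlist(libs, use.names = FALSE),
                    config = cfg))
}

# deterministic type composition: floor quotas, remainder to largest shares
quota_types <- function(n, props) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(props * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(props), base)
}

#' The full simulation grid
#'
#' The Cartesian product of 5 differential-expression locations x 5 batch
#' locations x balanced/unbalanced batches x balanced/unbalanced cell-type
#' proportions: 100 configurations with deterministic per-condition seeds.
#' Unbalanced batches are `c(800, 200)` cells; unbalanced cell types use
#' proportions `c(0.5, 0.3, 0.2)`.
#'
#' @param n_genes genes per condition, default 5000.
#' @param base_seed offset for the per-condition seeds, default 20000.
#' @return list of 100 [simulation_config()] objects with attributes
#'   `grid` (a data.frame describing each condition).
#' @export
simulation_grid <- function(n_genes = 5000, base_seed = 20000L) {
  locs <- c(0, 0.25, 0.5, 0.75, 1)
  grid <- expand.grid(de_location = locs, batch_location = locs,
                      batch_balance = c("balanced", "unbalanced"),
                      type_balance = c("balanced", "unbalanced"),
                      stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    simulation_config(
      n_genes = n_genes,
      cells_per_batch = if (g$batch_balance == "balanced") c(500, 500)
                        else c(800, 200),
      cell_type_proportions = if (g$type_balance == "balanced")
        rep(1 / 3, 3) else c(0.5, 0.3, 0.2),
      de_location = g$de_location,
      batch_location = g$batch_location,
      seed = base_seed + i)
  })
  attr(configs, "grid") <- grid
  configs
}
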