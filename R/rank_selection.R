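#' Permutation-test selection of joint and individual ranks
#'
#' Chooses the joint rank and the per-batch individual ranks by comparing
#' observed singular values against permutation nulls, iterating with
#' refits until the ranks stabilize.
#'
#' In this horizontal-integration setting the shared axis is genes, so the
#' null for the *joint* rank is built by independently permuting the gene
#' (column) order of each transposed batch: this destroys cross-batch
#' alignment while preserving each batch's internal structure, so any
#' singular value of the stacked matrix that beats the null reflects
#' genuinely shared structure. The null for each *individual* rank
#' permutes the entries within each column of that batch's joint-removed
#' residual, destroying all low-rank structure while preserving per-gene
#' marginals.
#'
#' One cycle is: (a) test singular values of the stacked matrix with the
#' current individual estimates removed, yielding `r`; (b) form the rank-r
#' joint estimate, test each batch's residual, yielding `r_i`; (c) if the
#' ranks changed, refit JIVE at the new ranks and repeat. Testing is
#' sequential: the rank is the number of leading singular values exceeding
#' the `1 - alpha` null quantile, stopping at the first failure.
#'
#' Significance uses the standard permutation p-value convention
#' `p = (1 + m) / (n_perm + 1)` with `m` the number of null values at or
#' above the observed one, which keeps the test at level alpha exactly (an
#' interpolated empirical quantile can be anti-conservative at these
#' permutation counts).
#'
#' @param collection a [batch_collection()] in centered space, `k >= 2`.
#' @param n_perm permutations per test (default 100; must be >= 19 for
#'   alpha = 0.05 to be attainable).
#' @param alpha per-component significance level, default 0.05.
#' @param max_cycles cap on test/refit cycles, default 10.
#' @param seed optional integer seed; all permutations draw from one
#'   generator.
#' @param r_max upper bound on any tested rank (default 50) to bound cost.
#' @return A `RankSelectionResult`: `joint_rank`, `individual_ranks`,
#'   observed singular values, per-permutation null values and null
#'   quantiles of the final cycle, `n_cycles`, `converged`, plus the call
#'   parameters.
#' @export
select_ranks_permutation <- function(collection, n_perm = 100, alpha = 0.05,
                                     max_cycles = 10, seed = NULL,
                                     r_max = 50) {
  check_collection_space(collection, "centered", "select_ranks_permutation")
  k <- n_batches(collection)
  if (k < 2) stop("need at least 2 batches")
  if (n_perm < ceiling(1 / alpha) - 1)
    stop(sprintf("n_perm = %d cannot resolve alpha = %g", n_perm, alpha))
  if (!is.null(seed)) set.seed(seed)

  Y <- lapply(collection$matrices, function(m) t(as_dense(m)))
  n_i <- vapply(Y, nrow, integer(1))
  p <- ncol(Y[[1]])
  n <- sum(n_i)

  if (frob(do.call(rbind, Y)) == 0) {
    warning("all-constant input; selecting ranks (0, [0...])")
    return(structure(list(joint_rank = 0L,
                          individual_ranks = rep(0L, k),
                          n_permutations = n_perm, alpha = alpha,
                          joint_observed = numeric(0),
                          joint_null_quantiles = numeric(0),
                          individual_observed = vector("list", k),
                          individual_null_quantiles = vector("list", k),
                          n_cycles = 0L, converged = TRUE),
                     class = "RankSelectionResult"))
  }

  cap_joint <- min(r_max, n, p)
  cap_ind <- pmin(r_max, n_i, p)

  r <- 0L; ri <- rep(0L, k)
  A <- lapply(n_i, function(ni) matrix(0, ni, p))
  J_blocks <- lapply(n_i, function(ni) matrix(0, ni, p))
  converged <- FALSE
  cyc <- 0L
  diag_joint <- NULL; diag_ind <- vector("list", k)

  # one permutation stream reused in every cycle (common random numbers):
  # cycle-to-cycle changes then reflect only the updated structure
  # estimates, not fresh Monte-Carlo noise, so borderline components do
  # not get repeated independent chances to cross the threshold
  perm_seed <- sample.int(.Machine$integer.max, 1)

  while (cyc < max_cycles) {
    cyc <- cyc + 1L
    set.seed(perm_seed)

    # (a) joint rank: stacked matrix, individual structure removed
    Z <- Map(`-`, Y, A)
    obs_j <- singular_values(do.call(rbind, Z), cap_joint)
    null_j <- matrix(0, n_perm, length(obs_j))
    for (b in seq_len(n_perm)) {
      perm <- lapply(Z, function(z) z[, sample.int(p), drop = FALSE])
      null_j[b, ] <- singular_values(do.call(rbind, perm), length(obs_j))
    }
    q_j <- apply(null_j, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
    r_new <- leading_significant(obs_j, null_j, alpha)
    diag_joint <- list(observed = obs_j, quantiles = q_j, null = null_j)

    # joint estimate at the candidate rank (individual estimates removed)
    js <- truncated_approx(do.call(rbind, Z), r_new)
    offs <- cumsum(c(0, n_i))
    J_blocks <- lapply(seq_len(k), function(i)
      js$approx[(offs[i] + 1):offs[i + 1], , drop = FALSE])

    # (b) individual ranks: per-batch joint-removed residual
    ri_new <- integer(k)
    for (i in seq_len(k)) {
      Zi <- Y[[i]] - J_blocks[[i]]
      obs_i <- singular_values(Zi, cap_ind[i])
      null_i <- matrix(0, n_perm, length(obs_i))
      for (b in seq_len(n_perm)) {
        shuf <- apply(Zi, 2, sample)
        null_i[b, ] <- singular_values(shuf, length(obs_i))
      }
      q_i <- apply(null_i, 2, stats::quantile, probs = 1 - alpha,
                   names = FALSE)
      ri_new[i] <- leading_significant(obs_i, null_i, alpha)
      diag_ind[[i]] <- list(observed = obs_i, quantiles = q_i, null = null_i)
    }

    if (r_new == r && all(ri_new == ri)) { converged <- TRUE; break }
    r <- r_new; ri <- ri_new

    # (c) refit at the new ranks to update the structure estimates
    fit <- fit_jive(collection, r, ri, tol = 1e-4, max_iter = 200)
    A <- lapply(seq_len(k), function(i) individual_block(fit, i))
  }

  structure(list(joint_rank = r, individual_ranks = ri,
                 n_permutations = n_perm, alpha = alpha,
                 joint_observed = diag_joint$observed,
                 joint_null_quantiles = diag_joint$quantiles,
                 joint_null = diag_joint$null,
                 individual_observed = lapply(diag_ind, `[[`, "observed"),
                 individual_null_quantiles = lapply(diag_ind, `[[`,
                                                    "quantiles"),
                 individual_null = lapply(diag_ind, `[[`, "null"),
                 n_cycles = cyc, converged = converged),
            class = "RankSelectionResult")
}

# number of leading observed values whose permutation p-value
# (1 + #{null >= obs}) / (B + 1) is <= alpha; stops at the first failure
leading_significant <- function(obs, null, alpha) {
  B <- nrow(null)
  pvals <- vapply(seq_along(obs), function(j)
    (1 + sum(null[, j] >= obs[j])) / (B + 1), numeric(1))
  ok <- pvals <= alpha
  if (!length(ok) || !ok[1]) return(0L)
  if (all(ok)) return(length(ok))
  as.integer(which(!ok)[1] - 1L)
}

#' @export
print.RankSelectionResult <- function(x, ...) {
  cat(sprintf("RankSelectionResult: joint %d, individual %s (%d perms, alpha %g, %d cycle(s), converged %s)\n",
              x$joint_rank, paste(x$individual_ranks, collapse = "/"),
              x$n_permutations, x$alpha, x$n_cycles, x$converged))
  invisible(x)
}
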