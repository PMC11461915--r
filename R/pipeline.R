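#' End-to-end batch-correction pipeline
#'
#' Runs the configured stages in order — obtain input (simulate counts or
#' read files), preprocess (log-normalize, optional HVG selection),
#' center, choose ranks (given or permutation test), fit, correct,
#' evaluate — and writes every artifact into a run directory with a
#' manifest recording the seed and configuration. Deterministic stages
#' reproduce bit-for-bit under the same configuration and seed.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{input}{either `list(simulate = <args for simulation_config>)`
#'       or `list(matrix_paths = ..., labels_path = ...)` — exactly one.}
#'     \item{log_normalize}{logical, default `TRUE`; `scale_factor`
#'       optional (default 1e4).}
#'     \item{hvg}{number of highly variable genes to keep, or `NULL` to
#'       skip.}
#'     \item{ranks}{`list(joint = , individual = )` for given ranks
#'       (defaults joint 10, individual 20), or `"permutation"` with
#'       optional `rank_args` (n_perm, alpha, r_max).}
#'     \item{metrics}{character subset of `c("kbet", "asw", "lisi",
#'       "pvca")`; default all.}
#'     \item{kbet_fractions}{default `c(0.05, 0.1, 0.15, 0.2, 0.25)`.}
#'     \item{out_dir}{run directory.}
#'     \item{seed}{integer, default 1.}
#'   }
#' @return Invisibly, a list with the fitted model, the corrected matrix,
#'   the embeddings and the metric report; all also written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg)
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  stage <- "config"
  result <- list()
  tryCatch({
    set.seed(cfg$seed)

    stage <- "input"
    truth <- NULL
    if (!is.null(cfg$input$simulate)) {
      sim_args <- cfg$input$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim <- simulate_counts(do.call(simulation_config, sim_args))
      collection <- sim$collection
      truth <- sim$truth
    } else {
      collection <- read_batches(cfg$input$matrix_paths,
                                 cfg$input$labels_path)
    }
    log_line(stage, sprintf("%d genes x %d cells, %d batches",
                            n_genes(collection), n_cells(collection),
                            n_batches(collection)))

    stage <- "preprocess"
    if (isTRUE(cfg$log_normalize)) {
      collection <- log_normalize(collection,
                                  cfg$scale_factor %||% 1e4)
    } else if (identical(collection$value_space, "counts")) {
      # caller vouches the values are already normalized
      collection$value_space <- "lognorm"
    }
    if (!is.null(cfg$hvg))
      collection <- select_hvg(collection, cfg$hvg)
    cen <- center_batches(collection)
    centered <- cen$collection
    log_line(stage, sprintf("%d genes retained", n_genes(centered)))

    stage <- "ranks"
    if (identical(cfg$ranks, "permutation")) {
      ra <- cfg$rank_args %||% list()
      rs <- do.call(select_ranks_permutation,
                    c(list(collection = centered, seed = cfg$seed), ra))
      joint_rank <- rs$joint_rank
      individual_ranks <- rs$individual_ranks
      jsonlite::write_json(
        list(joint_rank = rs$joint_rank,
             individual_ranks = rs$individual_ranks,
             alpha = rs$alpha, n_permutations = rs$n_permutations,
             n_cycles = rs$n_cycles, converged = rs$converged),
        file.path(cfg$out_dir, "rank_selection.json"),
        auto_unbox = TRUE, digits = NA)
      result$rank_selection <- rs
    } else {
      joint_rank <- cfg$ranks$joint %||% 10
      individual_ranks <- cfg$ranks$individual %||% 20
    }
    log_line(stage, sprintf("joint %d, individual %s", joint_rank,
                            paste(individual_ranks, collapse = "/")))
    if (joint_rank == 0)
      warning("selected joint rank is 0: the corrected matrix will be zero")

    stage <- "fit"
    model <- fit_jive(centered, joint_rank, individual_ranks,
                      tol = cfg$tol %||% 1e-6,
                      max_iter = cfg$max_iter %||% 1000,
                      gene_means = cen$gene_means)
    write_jive_model(model, file.path(cfg$out_dir, "model"))
    log_line(stage, sprintf("%d iterations, converged %s", model$n_iter,
                            model$converged))

    stage <- "correct"
    corr <- suppressWarnings(correct_batches(model))
    utils::write.csv(
      data.frame(cell_id = unlist(model$cell_ids, use.names = FALSE),
                 batch = rep(model$batch_labels, model$n_per_batch),
                 corr$joint_scores, check.names = FALSE),
      file.path(cfg$out_dir, "joint_scores.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(gene_id = model$gene_ids, corr$corrected,
                 check.names = FALSE),
      file.path(cfg$out_dir, "corrected.csv"), row.names = FALSE)

    stage <- "evaluate"
    metrics <- cfg$metrics %||% c("kbet", "asw", "lisi", "pvca")
    batch <- rep(model$batch_labels, model$n_per_batch)
    ctypes <- if (!is.null(centered$cell_types))
      unlist(centered$cell_types, use.names = FALSE) else NULL
    raw_mat <- do.call(cbind, lapply(centered$matrices, as_dense))
    d_embed <- min(30, dim(raw_mat), sum(model$n_per_batch) - 1)
    emb_raw <- pca_embed(raw_mat, d = d_embed, batch = batch,
                         cell_type = ctypes)
    emb_jive <- if (joint_rank > 0) joint_embedding(model) else NULL
    report <- list(seed = cfg$seed)
    for (nm in c(raw = "raw", jive = "jive")) {
      emb <- if (nm == "raw") emb_raw else emb_jive
      if (is.null(emb)) next
      rep_i <- list()
      if ("kbet" %in% metrics)
        rep_i$kbet_acceptance <- sapply(
          cfg$kbet_fractions %||% c(0.05, 0.1, 0.15, 0.2, 0.25),
          function(f) kbet_acceptance(emb, f, seed = cfg$seed))
      if ("asw" %in% metrics) {
        asw <- asw_report(emb, seed = cfg$seed)
        rep_i$asw_batch <- asw$asw_batch
        rep_i$asw_cell <- asw$asw_cell
      }
      if ("lisi" %in% metrics) {
        rep_i$ilisi_batch <- stats::median(lisi_scores(emb, "batch"))
        rep_i$clisi_cell <- if (!is.null(emb$cell_type))
          stats::median(lisi_scores(emb, "cell_type")) else NA
      }
      report[[nm]] <- rep_i
    }
    if ("pvca" %in% metrics && !is.null(ctypes)) {
      report$pvca_raw <- as.list(pvca(raw_mat, batch, ctypes))
      if (joint_rank > 0)
        report$pvca_corrected <- as.list(pvca(corr$corrected, batch, ctypes))
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log_line(stage, "metrics written")

    stage <- "manifest"
    jsonlite::write_json(
      list(package = "jivebatch",
           version = as.character(utils::packageVersion("jivebatch")),
           seed = cfg$seed, config = cfg),
      file.path(cfg$out_dir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null")

    result$model <- model
    result$corrected <- corr$corrected
    result$joint_scores <- corr$joint_scores
    result$metrics <- report
    result$truth <- truth
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  inp <- config$input
  has_sim <- !is.null(inp$simulate)
  has_files <- !is.null(inp$matrix_paths)
  if (has_sim == has_files)
    stop("config$input needs exactly one of 'simulate' or 'matrix_paths'+'labels_path'")
  if (has_files && is.null(inp$labels_path))
    stop("config$input$labels_path is required with matrix_paths")
  config$seed <- as.integer(config$seed %||% 1L)
  config$log_normalize <- config$log_normalize %||% TRUE
  config$ranks <- config$ranks %||% list(joint = 10, individual = 20)
  config
}
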