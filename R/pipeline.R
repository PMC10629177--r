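#' Run the full cell-type detection pipeline
#'
#' Orchestrates: kernel embedding of the expression matrix, then (for the
#' `sclstm` variant) pseudo-label derivation, pair sampling, twin-LSTM
#' training and all-pair scoring, and finally clustering of the resulting
#' similarity. Variants:
#' \describe{
#'   \item{`sclstm`}{full pipeline; clustering runs on the learned
#'     similarity.}
#'   \item{`siglstm`}{single-branch ablation: the same training, but cells
#'     are represented by one branch's final hidden state and clustered in
#'     that embedding space (Euclidean distances for AG/KM).}
#'   \item{`raw_kernel`}{no network; the kernel similarity is clustered
#'     directly (the "direct agglomerative clustering" control).}
#' }
#' With `n_repeats > 1` the network is retrained under seeds
#' `seed..seed+n_repeats-1` and the run with the best unsupervised mean
#' silhouette of its clustered similarity is kept — never a label-dependent
#' score, so repeats do not leak ground truth.
#'
#' @param x an [expression_matrix()] or a path readable by
#'   [read_expression_matrix()].
#' @param labels optional true labels; used for pair supervision when
#'   `supervise_pairs = TRUE` and always for the metrics report.
#' @param k number of clusters; when `NULL` it is estimated from the kernel
#'   similarity with [estimate_num_clusters()].
#' @param variant `"sclstm"`, `"siglstm"` or `"raw_kernel"`.
#' @param method final partitioner: `"AG"`, `"KM"` or `"SC"`.
#' @param config a [siamese_config()].
#' @param seed master seed; overrides `config$seed`.
#' @param supervise_pairs build training pairs from `labels` instead of
#'   pseudo-labels (reproduces a semi-supervised protocol).
#' @param min_cells when not `NULL`, genes expressed in fewer than
#'   `min_cells` cells are dropped first (the 10x preprocessing rule,
#'   `min_cells = 3`).
#' @param out_dir when not `NULL`, writes `labels.tsv`, `M.csv`,
#'   `metrics.json` (if labels given), `config.echo.json` and `run.log`.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return A `pipeline_run` list: `result` (a `clustering_result`), `S`,
#'   `M` (NULL for `raw_kernel`), `model`, `metrics`, `k`, `k_source`,
#'   `variant`, `method`, `seed`, `elapsed`.
#' @examples
#' \donttest{
#' sim <- simulate_counts(synthetic_spec(n_cells = 60, n_genes = 500, k = 2,
#'                                       seed = 1))
#' run <- run_pipeline(sim$expr, labels = sim$labels, k = 2,
#'                     config = siamese_config(epochs = 5))
#' run$metrics$ari
#' }
#' @export
run_pipeline <- function(x, labels = NULL, k = NULL,
                         variant = c("sclstm", "siglstm", "raw_kernel"),
                         method = c("AG", "KM", "SC"),
                         config = siamese_config(), seed = config$seed,
                         supervise_pairs = FALSE, min_cells = NULL,
                         out_dir = NULL, force = FALSE) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  config$seed <- as.integer(seed)

  if (is.character(x)) x <- read_expression_matrix(x)
  x <- validate_expression_matrix(x)
  if (!is.null(min_cells)) x <- filter_low_prevalence_genes(x, min_cells)
  if (!is.null(labels)) {
    check_that(length(labels) == nrow(x), "labels/matrix length mismatch")
  }
  note("input: %d cells x %d genes, variant=%s, method=%s, seed=%d",
       nrow(x), ncol(x), variant, method, config$seed)

  s <- kernel_embedding(x)
  note("kernel embedding done")

  k_source <- "given"
  if (is.null(k)) {
    k <- estimate_num_clusters(s)
    k_source <- "estimated"
    note("estimated k = %d by silhouette sweep", k)
  }

  model <- NULL; m <- NULL
  if (variant == "raw_kernel") {
    result <- cluster_similarity(s, k, method, config$seed)
  } else {
    pair_labels <- if (supervise_pairs && !is.null(labels)) labels
                   else derive_pseudo_labels(s, k)
    best <- NULL
    for (r in seq_len(config$n_repeats)) {
      cfg_r <- config
      cfg_r$seed <- config$seed + r - 1L
      pairs <- generate_pairs(pair_labels, cfg_r)
      fit <- train_siamese(s, pairs, cfg_r)
      m_r <- score_all_pairs(fit, s)
      sil <- mean_silhouette(1 - unclass(m_r),
                             agglomerative_from_similarity(m_r, k)$labels)
      note("repeat %d: loss %.4f -> %.4f, silhouette %.4f", r,
           fit$epoch_losses[1], fit$epoch_losses[length(fit$epoch_losses)], sil)
      if (is.null(best) || sil > best$sil) {
        best <- list(model = fit, m = m_r, sil = sil)
      }
    }
    model <- best$model; m <- best$m
    if (variant == "sclstm") {
      result <- cluster_similarity(m, k, method, config$seed)
    } else {
      e <- embed_single_branch(model, s)
      result <- cluster_embedding(e, k, method, config$seed)
    }
  }
  result$k_source <- k_source
  result$seed <- config$seed
  note("clustering done: %d clusters", result$k)

  metrics <- if (!is.null(labels)) evaluate_clustering(labels, result$labels)
  if (!is.null(metrics)) {
    note("metrics: ARI %.4f NMI %.4f ACC %.4f BAS %.4f",
         metrics$ari, metrics$nmi, metrics$acc, metrics$bas)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  run <- structure(list(result = result, S = s, M = m, model = model,
                        metrics = metrics, k = result$k, k_source = k_source,
                        variant = variant, method = method,
                        seed = config$seed, config = config,
                        elapsed = elapsed, log = log_lines),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir, force)
  run
}

# final partitioner on a similarity matrix, by method
cluster_similarity <- function(m, k, method, seed) {
  switch(method,
         AG = agglomerative_from_similarity(m, k),
         KM = cluster_variants(as_unit_similarity(m), k, "KM", seed),
         SC = cluster_variants(m, k, "SC", seed))
}

# final partitioner on a per-cell embedding (single-branch variant)
cluster_embedding <- function(e, k, method, seed) {
  if (method == "AG") {
    hc <- hclust(dist(e), method = "average")
    labels <- cutree(hc, k) - 1L
    names(labels) <- rownames(e)
    clustering_result(labels, k, "AG", "given", seed, tree = hc)
  } else if (method == "KM") {
    cluster_variants(e, k, "KM", seed)
  } else {
    aff <- exp(-as.matrix(dist(e))^2 / stats::median(dist(e))^2)
    cluster_variants(aff, k, "SC", seed)
  }
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> variant=%s method=%s k=%d (%s) seed=%d [%.1fs]\n",
              x$variant, x$method, x$k, x$k_source, x$seed, x$elapsed))
  if (!is.null(x$metrics)) {
    cat(sprintf("  ARI %.4f  NMI %.4f  ACC %.4f  BAS %.4f\n",
                x$metrics$ari, x$metrics$nmi, x$metrics$acc, x$metrics$bas))
  }
  invisible(x)
}

write_run <- function(run, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop(sprintf("output directory %s is not empty; use force = TRUE", out_dir),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_result(run$result, file.path(out_dir, "labels.tsv"))
  if (!is.null(run$M)) write_matrix(run$M, file.path(out_dir, "M.csv"))
  if (!is.null(run$metrics)) {
    jsonlite::write_json(run$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cfg <- unclass(run$config)
  cfg$variant <- run$variant; cfg$method <- run$method
  jsonlite::write_json(cfg, file.path(out_dir, "config.echo.json"),
                       auto_unbox = TRUE)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
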