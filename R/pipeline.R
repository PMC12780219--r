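#' Pipeline configuration
#'
#' Flat, dotted-key configuration for [run_full()]. Any key may be
#' overridden through `...`; unknown keys are an error. The single `seed`
#' fans out to per-stage seeds as `seed + stage index`, so stages are
#' isolated but reproducible.
#'
#' @param ... Key-value overrides, e.g. `gain.gain = 5`,
#'   `cluster.resolution = 1`.
#' @param sim A [sim_config()] to simulate input data, or `NULL` when
#'   ingesting external data via the `io.*` keys.
#' @param seed Master seed.
#' @return A list of class `"scgain_config"` with a stable `hash`.
#' @export
pipeline_config <- function(..., sim = sim_config(), seed = 1L) {
  cfg <- list(
    qc.min_genes = 200, qc.max_mito = 0.05,
    norm.scale_factor = 1e4,
    hvg.n_top = 2000, hvg.n_bins = 20,
    scale.clip = 10,
    gain.markers = NULL,        # NULL -> the dataset's flagged markers
    gain.gain = 5, gain.force_hvg = TRUE, gain.rescale_markers = FALSE,
    cnv.window = 101, cnv.clamp = 3, cnv.threshold = 1.009,
    cnv.min_mean = 0.1,
    cnv.level = "cell", cnv.reference = NULL,  # NULL -> truth label
    cluster.n_pcs = 30, cluster.k_neighbors = 20,
    cluster.resolution = 1.0, cluster.prune = 1 / 15,
    marker.min_fraction = 0.5, marker.refine = TRUE,
    dge.method = "wilcoxon", dge.alpha = 0.05, dge.max_comparator = 2000,
    gsea.gmt = NULL, gsea.n_perm = 1000, gsea.weight_p = 1,
    gsea.n_random_sets = 5, gsea.random_set_size = 50,
    umap.enabled = FALSE,
    io.matrix = NULL, io.barcodes = NULL, io.genes = NULL,
    io.annotations = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg$sim <- sim
  cfg$seed <- as.integer(seed)
  cfg$hash <- rlang::hash(cfg[order(names(cfg))])
  class(cfg) <- "scgain_config"
  cfg
}

stage_seed <- function(config, index) config$seed + as.integer(index)

#' Run the full rare-cell detection pipeline
#'
#' Executes simulate/ingest -> QC -> log-normalization -> CNV scoring and
#' positivity gating -> input-gain clustering of CNV-positive cancer cells
#' -> marker-cluster identification and recovery metrics -> differential
#' expression (marker cluster vs double-negative comparator cells) ->
#' preranked GSEA and gene-set overlap. Fully seeded; rerunning with an
#' identical configuration reproduces every result (manifest wall-times
#' aside).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, labels, metrics, the DGE
#'   and enrichment tables and a JSON manifest are written there.
#' @return An object of class `"scgain_run"`; see [glance.scgain_run()]
#'   for the one-row summary and [tidy.scgain_run()] for the per-cell
#'   table.
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "scgain_config"))
  t0 <- Sys.time()
  manifest <- list()
  note <- function(stage, n_in, n_out, params = "") {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out, params = params,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  # 1: input data
  if (!is.null(config$io.matrix)) {
    dataset <- ingest_external(config$io.matrix, config$io.barcodes,
                               config$io.genes, config$io.annotations)
  } else {
    simc <- config$sim
    simc$seed <- stage_seed(config, 1)
    dataset <- simulate_dataset(simc)
  }
  n0 <- nrow(dataset$counts)
  note("input", n0, n0)

  # 2: QC
  qc <- filter_cells(dataset, config$qc.min_genes, config$qc.max_mito)
  note("qc", n0, nrow(qc$counts),
       sprintf("min_genes=%d max_mito=%g", config$qc.min_genes,
               config$qc.max_mito))

  # 3: normalization
  norm <- lognormalize(qc, config$norm.scale_factor)
  note("lognormalize", nrow(qc$counts), nrow(norm$values))

  # 4: CNV gate
  ref_cells <- config$cnv.reference %||%
    norm$cells$cell_id[norm$cells$truth_label %in% "reference"]
  cnv_scores <- NULL
  if (length(ref_cells) > 0 && !anyNA(norm$genes$chromosome)) {
    cnv_scores <- cnv_score_cells(norm, ref_cells,
                                  window = config$cnv.window,
                                  clamp = config$cnv.clamp,
                                  min_mean = config$cnv.min_mean)
    cnv_pos <- select_cnv_positive(cnv_scores, config$cnv.threshold,
                                   level = config$cnv.level)
    test_cells <- setdiff(cnv_pos, ref_cells)
  } else {
    warn("no reference cells or gene positions; CNV gate skipped.")
    test_cells <- setdiff(norm$cells$cell_id, ref_cells)
  }
  note("cnv_gate", nrow(norm$values), length(test_cells),
       sprintf("threshold=%g level=%s", config$cnv.threshold,
               config$cnv.level))

  # 5: input-gain clustering of gated cells
  markers <- config$gain.markers %||% dataset$genes$gene_id[dataset$genes$marker]
  if (length(markers) == 0) abort("no marker genes configured or flagged.")
  sub <- subset_cells(norm, test_cells)
  spec <- gain_spec(markers, gain = config$gain.gain,
                    force_hvg = config$gain.force_hvg,
                    rescale_markers = config$gain.rescale_markers)
  sub <- apply_input_gain(sub, spec)
  sub <- select_hvg(sub, n_top = min(config$hvg.n_top, ncol(sub$values)),
                    n_bins = config$hvg.n_bins)
  sub <- scale_features(sub, clip = config$scale.clip)
  emb <- pca_embed(sub, n_pcs = config$cluster.n_pcs,
                   seed = stage_seed(config, 5))
  labels <- cluster_cells(emb, k_neighbors = config$cluster.k_neighbors,
                          resolution = config$cluster.resolution,
                          seed = stage_seed(config, 6),
                          prune = config$cluster.prune)
  umap <- if (isTRUE(config$umap.enabled))
    umap_embed(emb, seed = stage_seed(config, 6)) else NULL
  note("gain_cluster", length(test_cells), max(labels),
       sprintf("gain=%g n_pcs=%d resolution=%g", config$gain.gain,
               config$cluster.n_pcs, config$cluster.resolution))

  # 6: marker cluster + recovery metrics (subcluster refinement when the
  # rare cluster is absorbed at the chosen resolution)
  if (isTRUE(config$marker.refine)) {
    found <- find_marker_cluster(labels, sub, markers, emb,
                                 min_fraction = config$marker.min_fraction,
                                 k_neighbors = config$cluster.k_neighbors,
                                 resolution = config$cluster.resolution,
                                 seed = stage_seed(config, 6),
                                 prune = config$cluster.prune)
    marker_cluster <- found$cluster
    labels <- found$labels
  } else {
    marker_cluster <- identify_marker_cluster(labels, sub, markers,
                                              config$marker.min_fraction)
  }
  threshold_cells <- marker_threshold_select(sub, markers)
  cluster_cells_ids <- if (!is.na(marker_cluster))
    names(labels)[labels == marker_cluster] else character(0)
  metrics <- recovery_metrics(cluster_cells_ids, threshold_cells,
                              length(test_cells))
  truth <- dataset$cells$truth_label
  truth_metrics <- NULL
  if (!all(is.na(truth))) {
    planted <- dataset$cells$cell_id[truth %in% "SRCC"]
    truth_metrics <- tibble(
      n_planted = length(planted),
      recall = if (length(planted)) length(intersect(cluster_cells_ids,
                                                     planted)) /
        length(planted) else NA_real_,
      precision = if (length(cluster_cells_ids))
        length(intersect(cluster_cells_ids, planted)) /
        length(cluster_cells_ids) else NA_real_)
  }
  note("marker_cluster", max(labels),
       ifelse(is.na(marker_cluster), 0L, length(cluster_cells_ids)),
       sprintf("cluster=%s recovery=%.3f",
               ifelse(is.na(marker_cluster), "none", marker_cluster),
               metrics$recovery_fraction %||% NA))

  # 7: differential expression, marker cluster vs double-negative cells
  dge <- NULL; gsea <- NULL; overlap <- NULL
  if (!is.na(marker_cluster) && length(cluster_cells_ids) >= 3) {
    double_neg <- setdiff(test_cells, threshold_cells)
    double_neg <- setdiff(double_neg, cluster_cells_ids)
    if (length(double_neg) > config$dge.max_comparator) {
      double_neg <- withr::with_seed(stage_seed(config, 7),
        sample(double_neg, config$dge.max_comparator))
    }
    if (length(double_neg) >= 3) {
      dge <- differential_expression(sub, cluster_cells_ids, double_neg,
                                     method = config$dge.method)
      note("dge", ncol(sub$values), sum(dge$adj_p < config$dge.alpha,
                                        na.rm = TRUE),
           sprintf("method=%s A=%d B=%d", config$dge.method,
                   length(cluster_cells_ids), length(double_neg)))

      # 8: GSEA on the signed -log10 p ranking
      sets <- if (!is.null(config$gsea.gmt)) read_gmt(config$gsea.gmt)
      else default_gene_sets(dataset, config)
      sets <- Filter(function(s) length(intersect(s, dge$gene_id)) >= 2, sets)
      if (length(sets) > 0) {
        gsea <- preranked_gsea(gsea_ranking(dge), sets,
                               weight_p = config$gsea.weight_p,
                               n_perm = config$gsea.n_perm,
                               seed = stage_seed(config, 8))
        note("gsea", length(sets), sum(gsea$adj_p < 0.05, na.rm = TRUE))
      }

      # 9: overlap of significant DEG with the first reference set
      if (length(sets) > 0) {
        deg <- dge$gene_id[!is.na(dge$adj_p) & dge$adj_p < config$dge.alpha]
        overlap <- geneset_overlap(deg, intersect(sets[[1]], dge$gene_id),
                                   dge$gene_id)
        note("overlap", length(deg), overlap$n_overlap,
             sprintf("set=%s", names(sets)[1]))
      }
    }
  }

  run <- structure(list(
    config = config, manifest = dplyr::bind_rows(manifest),
    dataset = dataset, qc = attr(qc, "qc"), norm = sub,
    cnv_scores = cnv_scores, test_cells = test_cells,
    embedding = emb, umap = umap, labels = labels,
    marker_cluster = marker_cluster, markers = markers,
    threshold_cells = threshold_cells, metrics = metrics,
    truth_metrics = truth_metrics, dge = dge, gsea = gsea,
    overlap = overlap), class = "scgain_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# gene sets used when no GMT is supplied: the simulated dormancy signature
# plus seeded random sets as negative controls
default_gene_sets <- function(dataset, config) {
  sets <- list()
  if (!is.null(dataset$params$dormancy_genes))
    sets$dormancy_signature <- dataset$params$dormancy_genes
  pool <- setdiff(dataset$genes$gene_id,
                  dataset$genes$gene_id[dataset$genes$marker])
  rnd <- withr::with_seed(stage_seed(config, 8) + 100L,
    lapply(seq_len(config$gsea.n_random_sets), function(i)
      sample(pool, min(config$gsea.random_set_size, length(pool)))))
  names(rnd) <- sprintf("random_set_%02d", seq_along(rnd))
  c(sets, rnd)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lab <- tibble(barcode = names(run$labels), cluster = as.integer(run$labels),
                is_marker_cluster = as.integer(
                  !is.na(run$marker_cluster) &
                    run$labels == run$marker_cluster))
  write.table(lab, file.path(out_dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  metrics <- c(as.list(run$metrics),
               if (!is.null(run$truth_metrics)) as.list(run$truth_metrics))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  emb <- data.frame(barcode = rownames(run$embedding), run$embedding)
  write.table(emb, file.path(out_dir, "embedding.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(run$dge))
    write.table(run$dge, file.path(out_dir, "dge.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(run$gsea)) {
    g <- run$gsea
    g$leading_edge <- vapply(g$leading_edge, paste, character(1),
                             collapse = ";")
    write.table(g, file.path(out_dir, "gsea.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = run$config$hash, seed = run$config$seed,
         stages = run$manifest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.scgain_run <- function(x, ...) {
  cat("<scgain_run>\n")
  print(x$manifest[, c("stage", "n_in", "n_out", "params")])
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `scgain_run`.
#' @param ... Unused.
#' @return A one-row tibble with cell counts per stage, the marker-cluster
#'   size and recovery metrics, truth-based recall/precision when truth
#'   labels exist, and the number of significant DEG.
#' @export
glance.scgain_run <- function(x, ...) {
  tibble(
    n_cells = nrow(x$dataset$counts),
    n_cells_qc = sum(x$qc$keep),
    n_cnv_positive = length(x$test_cells),
    marker_cluster = as.integer(x$marker_cluster),
    cluster_size = x$metrics$cluster_size,
    recovery_fraction = x$metrics$recovery_fraction,
    precision_vs_threshold = x$metrics$precision,
    population_fraction = x$metrics$population_fraction,
    recall_truth = if (!is.null(x$truth_metrics)) x$truth_metrics$recall
      else NA_real_,
    precision_truth = if (!is.null(x$truth_metrics)) x$truth_metrics$precision
      else NA_real_,
    n_deg = if (!is.null(x$dge))
      sum(x$dge$adj_p < x$config$dge.alpha, na.rm = TRUE) else NA_integer_)
}

#' Per-cell tidy table of a pipeline run
#'
#' @param x A `scgain_run`.
#' @param ... Unused.
#' @return Tibble over the clustered cells: `cell_id`, `truth_label`,
#'   `cnv_score`, `cluster`, `in_marker_cluster`, `threshold_positive`,
#'   and the first two embedding coordinates.
#' @export
tidy.scgain_run <- function(x, ...) {
  ids <- names(x$labels)
  tibble(
    cell_id = ids,
    truth_label = x$dataset$cells$truth_label[
      match(ids, x$dataset$cells$cell_id)],
    cnv_score = if (!is.null(x$cnv_scores)) x$cnv_scores[ids] else NA_real_,
    cluster = as.integer(x$labels),
    in_marker_cluster = !is.na(x$marker_cluster) &
      x$labels == x$marker_cluster,
    threshold_positive = ids %in% x$threshold_cells,
    dim1 = x$embedding[, 1], dim2 = x$embedding[, 2])
}
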