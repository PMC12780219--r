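#' Input-gain specification for marker genes
#'
#' Defines the multiplicative pre-amplification ("input gain") applied to
#' marker genes upstream of PCA clustering, the device that makes a rare
#' marker-defined population separable where an unmodified embedding
#' fails.
#'
#' @param marker_genes Non-empty character vector of marker gene ids.
#' @param gain Multiplicative gain, finite and >= 1 (default 5).
#' @param force_hvg Force the markers into the highly variable gene set so
#'   the amplification survives feature selection.
#' @param rescale_markers If `TRUE`, marker columns are re-standardized
#'   after the gain like any other gene (which annuls a pure rescaling);
#'   the default `FALSE` scales them by their pre-gain SD so the
#'   amplification persists into PCA (see [scale_features()]).
#' @return A list of class `"scgain_gain_spec"`.
#' @export
gain_spec <- function(marker_genes, gain = 5, force_hvg = TRUE,
                      rescale_markers = FALSE) {
  if (length(marker_genes) < 1) abort("`marker_genes` must be non-empty.")
  if (!is.finite(gain) || gain < 1) abort("`gain` must be finite and >= 1.")
  structure(list(marker_genes = as.character(marker_genes), gain = gain,
                 force_hvg = force_hvg, rescale_markers = rescale_markers),
            class = "scgain_gain_spec")
}

#' Apply a marker input gain to a log-normalized matrix
#'
#' Multiplies the marker columns of the log-normalized expression by
#' `spec$gain`, leaving all other columns untouched, and records the gain
#' in the object's metadata. Must run after [lognormalize()] and before
#' [select_hvg()] / [scale_features()].
#'
#' @param norm A `scgain_norm`.
#' @param spec A [gain_spec()].
#' @return The `scgain_norm` with gained marker columns.
#' @export
apply_input_gain <- function(norm, spec) {
  stopifnot(inherits(norm, "scgain_norm"), inherits(spec, "scgain_gain_spec"))
  if (any(c("hvg", "scale") %in% norm$stages))
    abort("apply_input_gain() must run before select_hvg()/scale_features().")
  missing <- setdiff(spec$marker_genes, norm$genes$gene_id)
  if (length(missing))
    abort(sprintf("marker gene(s) not in the matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "scgain_missing_marker")
  midx <- match(spec$marker_genes, norm$genes$gene_id)
  if (spec$gain != 1)   # gain 1 is the exact identity
    norm$values[, midx] <- norm$values[, midx, drop = FALSE] * spec$gain
  norm$gain <- spec
  norm$stages <- c(norm$stages, "gain")
  norm
}

#' Principal-component embedding
#'
#' Computes the top principal-component scores of the scaled HVG matrix
#' (columns centered). Exact SVD is used for small problems and seeded
#' truncated SVD (irlba) otherwise; the sign of each component is fixed so
#' that its largest-magnitude loading is positive, making scores
#' deterministic.
#'
#' @param x A `scgain_norm` with `scaled` set, or a numeric matrix
#'   (cells x features).
#' @param n_pcs Number of components (must not exceed `min(dim)`).
#' @param seed Seed for the truncated SVD initialization.
#' @param exact Force exact SVD regardless of size.
#' @return Scores matrix (cells x `n_pcs`) with attributes `"loadings"`
#'   and `"sdev"`.
#' @export
pca_embed <- function(x, n_pcs = 30, seed = 0, exact = FALSE) {
  X <- if (inherits(x, "scgain_norm")) {
    if (is.null(x$scaled)) abort("run scale_features() before pca_embed().")
    x$scaled
  } else as.matrix(x)
  if (!all(is.finite(X))) abort("embedding input must be finite.")
  if (n_pcs > min(dim(X)))
    abort("`n_pcs` exceeds min(cells, features).")
  Xc <- sweep(X, 2, colMeans(X))
  if (exact || min(dim(Xc)) <= 300 || n_pcs > min(dim(Xc)) / 3) {
    sv <- svd(Xc, nu = n_pcs, nv = n_pcs)
    d <- sv$d[seq_len(n_pcs)]
    u <- sv$u; v <- sv$v
  } else {
    sv <- withr::with_seed(as.integer(seed),
                           irlba::irlba(Xc, nv = n_pcs, tol = 1e-10,
                                        maxit = 1000))
    d <- sv$d; u <- sv$u; v <- sv$v
  }
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- u %*% diag(d, n_pcs)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  attr(scores, "loadings") <- v
  attr(scores, "sdev") <- d / sqrt(max(1, nrow(X) - 1))
  scores
}

#' Shared-nearest-neighbour graph of an embedding
#'
#' Builds the Euclidean kNN graph (neighbor sets include the cell itself,
#' the standard SNN convention), weights edges by Jaccard overlap of the
#' neighbor sets, and drops edges below `prune`.
#'
#' @param embedding Cells x PCs matrix.
#' @param k Neighbourhood size.
#' @param prune Jaccard pruning threshold.
#' @return An undirected weighted `igraph` graph.
#' @export
snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  n <- nrow(embedding)
  if (n <= k) {
    warn(sprintf("fewer cells (%d) than k_neighbors (%d); lowering k.", n, k))
    k <- n - 1L
  }
  nn <- RANN::nn2(embedding, k = k + 1L)$nn.idx  # first neighbor is self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  snn <- shared
  snn@x <- snn@x / (2 * (k + 1L) - snn@x)   # Jaccard: s / (|A|+|B|-s)
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  igraph::graph_from_adjacency_matrix(snn, mode = "max", weighted = TRUE)
}

#' Cluster cells on a kNN/SNN graph with Leiden community detection
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance in PC space),
#' weights edges by shared-nearest-neighbour Jaccard overlap (pruned below
#' `prune`), and partitions it with the Leiden algorithm under the
#' modularity objective at the given resolution. Labels are contiguous
#' integers ordered by decreasing cluster size (ties by first occurrence).
#'
#' @param embedding Cells x PCs matrix.
#' @param k_neighbors Neighbourhood size (lowered with a warning when
#'   there are fewer cells).
#' @param resolution Modularity resolution; as it approaches 0 a connected
#'   graph collapses to one cluster.
#' @param seed RNG seed for Leiden.
#' @param prune SNN Jaccard pruning threshold.
#' @param n_iterations Leiden refinement iterations.
#' @param graph Optional pre-built SNN graph from [snn_graph()]; the kNN
#'   construction is skipped (useful when varying only the community
#'   detection seed).
#' @return Integer cluster labels named by cell id.
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 1.0,
                          seed = 0, prune = 1 / 15, n_iterations = 5,
                          graph = NULL) {
  if (!all(is.finite(embedding))) abort("embedding must be finite.")
  g <- graph %||% snn_graph(embedding, k = k_neighbors, prune = prune)
  memb <- withr::with_seed(as.integer(seed),
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = n_iterations)$membership)
  # relabel by decreasing size, ties by first appearance
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relabel[memb]
  names(labels) <- rownames(embedding)
  labels
}

#' Split one cluster by re-running community detection on its cells
#'
#' Builds a fresh SNN graph on the embedding rows of the chosen cluster
#' and partitions it at the given resolution; the new sub-clusters replace
#' the original cluster and all labels are re-numbered by decreasing size.
#'
#' @param labels Integer cluster labels named by cell id.
#' @param embedding The embedding the labels were derived from.
#' @param cluster Cluster id to split.
#' @inheritParams cluster_cells
#' @return Re-numbered integer labels with the cluster split.
#' @export
subcluster_labels <- function(labels, embedding, cluster, k_neighbors = 20,
                              resolution = 1.0, seed = 0, prune = 1 / 15) {
  cells <- names(labels)[labels == cluster]
  if (length(cells) < 3) return(labels)
  sub_lab <- cluster_cells(embedding[cells, , drop = FALSE],
                           k_neighbors = min(k_neighbors,
                                             length(cells) - 1),
                           resolution = resolution, seed = seed,
                           prune = prune)
  new <- labels
  new[cells] <- max(labels) + sub_lab
  sizes <- table(new)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(max(new))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- relabel[new]
  names(out) <- names(labels)
  out
}

#' Identify the marker cluster, refining by subclustering when needed
#'
#' Applies [identify_marker_cluster()]; if no cluster reaches the
#' double-positive qualification floor, the cluster holding the most
#' double-positive cells is split with [subcluster_labels()] and the
#' identification is repeated. This mirrors standard practice when a rare
#' population is absorbed into a larger community at the chosen
#' resolution.
#'
#' @inheritParams identify_marker_cluster
#' @param embedding The embedding the labels were derived from.
#' @param k_neighbors,resolution,seed,prune Passed to the subclustering.
#' @param max_rounds Maximum refinement rounds.
#' @return A list with `cluster` (id or `NA`), `labels` (possibly
#'   refined), and `refined` (number of rounds applied).
#' @export
find_marker_cluster <- function(labels, norm, markers, embedding,
                                min_fraction = 0.5, k_neighbors = 20,
                                resolution = 1.0, seed = 0, prune = 1 / 15,
                                max_rounds = 2) {
  id <- identify_marker_cluster(labels, norm, markers, min_fraction)
  rounds <- 0
  while (is.na(id) && rounds < max_rounds) {
    fr <- attr(id, "fractions")
    cand <- fr$cluster[which.max(fr$n_positive)]
    if (fr$n_positive[match(cand, fr$cluster)] < 2) break
    new_labels <- subcluster_labels(labels, embedding, cand,
                                    k_neighbors = k_neighbors,
                                    resolution = resolution,
                                    seed = seed + rounds, prune = prune)
    if (identical(new_labels, labels)) break
    labels <- new_labels
    id <- identify_marker_cluster(labels, norm, markers, min_fraction)
    rounds <- rounds + 1
  }
  list(cluster = id, labels = labels, refined = rounds)
}

#' Identify the marker-positive cluster
#'
#' Returns the cluster maximizing the fraction of cells with strictly
#' positive normalized expression of ALL markers; `NA` when the best
#' fraction falls below `min_fraction`. Ties go to the larger cluster,
#' then to the lower cluster id.
#'
#' @param labels Integer cluster labels named by cell id.
#' @param norm A `scgain_norm` covering the labelled cells.
#' @param markers Marker gene ids.
#' @param min_fraction Qualification floor for the double-positive
#'   fraction (default 0.5).
#' @return Integer cluster id (or `NA_integer_`), with attribute
#'   `"fractions"`: a tibble of per-cluster double-positive fractions.
#' @export
identify_marker_cluster <- function(labels, norm, markers,
                                    min_fraction = 0.5) {
  stopifnot(inherits(norm, "scgain_norm"))
  pos_cells <- marker_threshold_select(norm, markers)
  pos <- names(labels) %in% pos_cells
  tab <- tibble(cluster = as.integer(names(table(labels))),
                size = as.integer(table(labels)))
  tab$n_positive <- vapply(tab$cluster,
                           function(cl) sum(pos[labels == cl]), integer(1))
  tab$fraction <- tab$n_positive / tab$size
  ord <- order(-tab$fraction, -tab$size, tab$cluster)
  best <- tab[ord[1], ]
  id <- if (best$fraction < min_fraction) NA_integer_ else best$cluster
  attr(id, "fractions") <- tab
  id
}

#' Threshold-based marker-positive cell selection
#'
#' Selects the cells with strictly positive normalized expression for
#' every marker (i.e. at least one raw count in each).
#'
#' @param norm A `scgain_norm`.
#' @param markers Marker gene ids.
#' @return Character vector of cell ids.
#' @export
marker_threshold_select <- function(norm, markers) {
  stopifnot(inherits(norm, "scgain_norm"))
  missing <- setdiff(markers, norm$genes$gene_id)
  if (length(missing))
    abort(sprintf("marker gene(s) not in the matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "scgain_missing_marker")
  midx <- match(markers, norm$genes$gene_id)
  sub <- norm$values[, midx, drop = FALSE]
  all_pos <- Matrix::rowSums(sub > 0) == length(midx)
  rownames(norm$values)[all_pos]
}

#' Recovery metrics of a cluster against a threshold-selected cell set
#'
#' @param cluster_cells Cell ids in the identified cluster.
#' @param threshold_cells Cell ids selected by the marker threshold.
#' @param total_cells Total number of cells in the analysed universe.
#' @return One-row tibble: `recovery_fraction` (share of threshold cells
#'   captured by the cluster; `NA` if the threshold set is empty),
#'   `precision` (share of the cluster in the threshold set; `NA` for an
#'   empty cluster), `cluster_size` and `population_fraction`.
#' @export
recovery_metrics <- function(cluster_cells, threshold_cells, total_cells) {
  inter <- length(intersect(cluster_cells, threshold_cells))
  tibble(
    recovery_fraction = if (length(threshold_cells) == 0) NA_real_
      else inter / length(threshold_cells),
    precision = if (length(cluster_cells) == 0) NA_real_
      else inter / length(cluster_cells),
    cluster_size = length(cluster_cells),
    population_fraction = length(cluster_cells) / total_cells)
}

#' UMAP layout of an embedding (visualization only)
#'
#' Thin deterministic wrapper around uwot; carries no quantitative
#' contract and is excluded from all pipeline metrics.
#'
#' @param embedding Cells x PCs matrix.
#' @param seed RNG seed.
#' @param n_neighbors UMAP neighbourhood size.
#' @return Cells x 2 coordinate matrix.
#' @export
umap_embed <- function(embedding, seed = 0, n_neighbors = 30) {
  if (!requireNamespace("uwot", quietly = TRUE))
    abort("uwot is required for umap_embed().")
  coords <- withr::with_seed(as.integer(seed),
    uwot::umap(embedding, n_neighbors = min(n_neighbors, nrow(embedding) - 1),
               n_threads = 1, n_sgd_threads = 1))
  rownames(coords) <- rownames(embedding)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}
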