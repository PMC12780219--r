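#' Per-cell QC metrics
#'
#' @param dataset A `scgain_dataset`.
#' @return Tibble with `cell_id`, `n_detected` (genes with nonzero count),
#'   `total_counts`, and `mito_fraction` (0 for zero-total cells).
#' @export
qc_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "scgain_dataset"))
  counts <- dataset$counts
  if (nrow(dataset$genes) != ncol(counts))
    abort("gene table is misaligned with the count matrix.")
  detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito_total <- if (any(dataset$genes$mito))
    Matrix::rowSums(counts[, dataset$genes$mito, drop = FALSE])
  else rep(0, nrow(counts))
  mito_fraction <- unname(ifelse(total > 0, mito_total / total, 0))
  tibble(cell_id = rownames(counts), n_detected = as.integer(unname(detected)),
         total_counts = as.numeric(unname(total)),
         mito_fraction = mito_fraction)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Retains exactly the cells with at least `min_genes` detected genes
#' (nonzero counts) AND a mitochondrial count fraction of at most
#' `max_mito`; both boundaries are inclusive (the exclusion rule "fewer
#' than 200 features and more than 5% mitochondrial" is read strictly).
#' Zero-total cells have mito fraction 0 and fall to the gene filter.
#' Cell order is preserved; the operation is idempotent.
#'
#' @param dataset A `scgain_dataset`.
#' @param min_genes Minimum detected genes to keep a cell.
#' @param max_mito Maximum mitochondrial count fraction to keep a cell.
#' @return The filtered `scgain_dataset`, with an attribute `"qc"` holding
#'   the per-cell metrics and the keep mask.
#' @export
filter_cells <- function(dataset, min_genes = 200, max_mito = 0.05) {
  qc <- qc_metrics(dataset)
  keep <- qc$n_detected >= min_genes & qc$mito_fraction <= max_mito
  out <- subset_dataset(dataset, which(keep))
  attr(out, "qc") <- list(metrics = qc, keep = keep,
                          min_genes = min_genes, max_mito = max_mito)
  out
}

subset_dataset <- function(dataset, cell_idx) {
  dataset$counts <- dataset$counts[cell_idx, , drop = FALSE]
  dataset$cells <- dataset$cells[cell_idx, , drop = FALSE]
  dataset
}

#' Log-normalize counts
#'
#' Depth-normalizes each cell to `scale_factor` total counts and applies
#' `log(1 + x)`: `value(c, g) = ln(1 + scale_factor * count(c, g) /
#' total(c))`. The sparsity pattern is preserved and the result is
#' invariant to per-cell count rescaling.
#'
#' @param dataset A `scgain_dataset` (run [filter_cells()] first; cells
#'   with zero total counts are an error).
#' @param scale_factor Depth-normalization scale (default 10,000).
#' @return An object of class `"scgain_norm"`: list with sparse `values`
#'   (cells x genes, log-normalized), `genes`, `cells`, `totals`,
#'   `scale_factor`, and a `stages` record used to enforce the pipeline
#'   order (normalize -> gain -> HVG -> scale).
#' @export
lognormalize <- function(dataset, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "scgain_dataset"))
  counts <- as(dataset$counts, "CsparseMatrix")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    abort("cells with zero total counts present; run filter_cells() first.")
  values <- counts
  values@x <- log1p(scale_factor * counts@x / totals[counts@i + 1L])
  structure(list(values = values, genes = dataset$genes,
                 cells = dataset$cells, totals = totals,
                 scale_factor = scale_factor,
                 gain = NULL, hvg = NULL, scaled = NULL,
                 stages = "lognormalize"),
            class = "scgain_norm")
}

#' @export
print.scgain_norm <- function(x, ...) {
  cat(sprintf("<scgain_norm> %d cells x %d genes | stages: %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$stages, collapse = " -> ")))
  invisible(x)
}

#' Subset a normalized matrix to a set of cells
#'
#' @param norm A `scgain_norm`.
#' @param cell_ids Character cell ids (or integer indices) to keep.
#' @return The subset `scgain_norm`.
#' @export
subset_cells <- function(norm, cell_ids) {
  idx <- if (is.character(cell_ids)) match(cell_ids, rownames(norm$values))
  else cell_ids
  if (anyNA(idx)) abort("unknown cell ids in subset.")
  norm$values <- norm$values[idx, , drop = FALSE]
  norm$cells <- norm$cells[idx, , drop = FALSE]
  norm$totals <- norm$totals[idx]
  if (!is.null(norm$scaled)) norm$scaled <- norm$scaled[idx, , drop = FALSE]
  norm
}

# per-gene mean and variance of a sparse cells x genes matrix (sample var)
sparse_col_moments <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  sumsq <- Matrix::colSums(m^2)
  v <- (sumsq - n * mu^2) / max(1, n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic: the variance of the
#' log-normalized values, z-scored within `n_bins` equal-width bins of the
#' gene mean. The top `n_top` genes are flagged; ties are broken by
#' lexicographic `gene_id`. If an input gain with `force_hvg = TRUE` has
#' been applied, the marker genes are forced into the selection.
#'
#' @param norm A `scgain_norm`.
#' @param n_top Number of genes to flag (must not exceed the gene count).
#' @param n_bins Number of gene-mean bins for dispersion standardization.
#' @return The `scgain_norm` with `hvg` (logical per gene) and a
#'   `"dispersion"` attribute on `hvg` holding the ranking statistic.
#' @export
select_hvg <- function(norm, n_top = 2000, n_bins = 20) {
  stopifnot(inherits(norm, "scgain_norm"))
  if ("scale" %in% norm$stages)
    abort("select_hvg() must run before scale_features().")
  G <- ncol(norm$values)
  if (n_top > G) abort("`n_top` exceeds the number of genes.")
  mom <- sparse_col_moments(norm$values)
  disp <- numeric(G)
  rng <- range(mom$mean)
  bins <- if (diff(rng) == 0) rep(1L, G)
  else as.integer(cut(mom$mean, breaks = seq(rng[1], rng[2],
                                             length.out = n_bins + 1),
                      include.lowest = TRUE))
  global_sd <- sd(mom$var)
  for (b in unique(bins)) {
    idx <- bins == b
    mu_b <- mean(mom$var[idx])
    sd_b <- sd(mom$var[idx])
    if (!is.na(sd_b) && sd_b > 0) {
      disp[idx] <- (mom$var[idx] - mu_b) / sd_b
    } else if (!is.na(global_sd) && global_sd > 0) {
      # degenerate bin (single gene or no spread): standardize against the
      # global variance distribution so lone high-variance genes still rank
      disp[idx] <- (mom$var[idx] - mean(mom$var)) / global_sd
    } else disp[idx] <- 0
  }
  ord <- order(-disp, norm$genes$gene_id)
  sel <- logical(G)
  sel[ord[seq_len(n_top)]] <- TRUE
  if (!is.null(norm$gain) && isTRUE(norm$gain$force_hvg)) {
    midx <- match(norm$gain$marker_genes, norm$genes$gene_id)
    if (any(!sel[midx])) {
      # markers displace the lowest-ranked selected genes
      n_add <- sum(!sel[midx])
      drop_idx <- setdiff(ord[seq_len(n_top)], midx)
      sel[utils::tail(drop_idx, n_add)] <- FALSE
      sel[midx] <- TRUE
    }
  }
  attr(sel, "dispersion") <- disp
  norm$hvg <- sel
  norm$stages <- c(norm$stages, "hvg")
  norm
}

#' Z-score and clip the highly variable genes
#'
#' Each HVG column is centered and scaled by its sample standard deviation
#' (denominator n - 1) across cells and clipped to `[-clip, clip]`;
#' zero-variance genes map to all-zero columns. When an input gain is
#' active and `rescale_markers = FALSE` (the default recorded by
#' [gain_spec()]), marker columns are standardized and clipped on their
#' pre-gain scale and then multiplied by the gain, so the amplified column
#' is exactly `gain` times the column the unmodified pipeline would
#' produce (range `[-clip * gain, clip * gain]`). This preserves the
#' multiplicative marker contrast into PCA; a plain post-gain z-score
#' would annul the amplification.
#'
#' @param norm A `scgain_norm` with `hvg` set.
#' @param clip Clipping bound in SD units.
#' @return The `scgain_norm` with a dense `scaled` matrix (cells x HVGs).
#' @export
scale_features <- function(norm, clip = 10) {
  stopifnot(inherits(norm, "scgain_norm"))
  if (is.null(norm$hvg)) abort("run select_hvg() before scale_features().")
  hv_idx <- which(norm$hvg)
  Z <- as.matrix(norm$values[, hv_idx, drop = FALSE])
  n <- nrow(Z)
  mu <- colMeans(Z)
  s <- sqrt(colSums(Z^2) / (n - 1) - n / (n - 1) * mu^2)
  s[is.na(s) | s < 1e-12] <- Inf   # zero-variance genes -> all-zero column
  # column-wise, in place, to avoid whole-matrix temporaries
  for (j in seq_len(ncol(Z)))
    Z[, j] <- pmin(pmax((Z[, j] - mu[j]) / s[j], -clip), clip)
  if (!is.null(norm$gain) && norm$gain$gain != 1 &&
      !isTRUE(norm$gain$rescale_markers)) {
    midx <- which(colnames(Z) %in% norm$gain$marker_genes)
    # z-scores are invariant to the (linear) gain, so Z already holds the
    # pre-gain z; re-apply the gain after clipping
    Z[, midx] <- Z[, midx, drop = FALSE] * norm$gain$gain
  }
  norm$scaled <- Z
  norm$clip <- clip
  norm$stages <- c(norm$stages, "scale")
  norm
}
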