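# core smoother on a dense cell-block: residual vs reference mean, clamp,
# per-chromosome moving average with edge-shrunk windows, subtraction of
# the smoothed reference profile (when given), per-cell median
# re-centering, baseline offset to 1. `gene_order` gives genomic order.
smooth_block <- function(E, ref_mean, ref_sd, gene_order, chr_ordered,
                         window, clamp, warn_small = TRUE,
                         ref_smoothed = NULL, recenter = TRUE) {
  band <- clamp * ref_sd
  # clamp column-wise to avoid large temporaries
  for (j in seq_len(ncol(E))) {
    r <- E[, j] - ref_mean[j]
    b <- band[j]
    E[, j] <- pmin(pmax(r, -b), b)
  }
  Ro <- E[, gene_order, drop = FALSE]
  S <- Ro
  h <- (window - 1L) / 2L
  for (cc in unique(chr_ordered)) {
    idx <- which(chr_ordered == cc)
    g <- length(idx)
    if (g < 3) {
      if (warn_small)
        warn(sprintf("chromosome %s has %d genes; passed through unsmoothed.",
                     cc, g))
      next
    }
    if (h == 0) next
    B <- Ro[, idx, drop = FALSE]
    CS <- B
    for (j in seq_len(g)[-1]) CS[, j] <- CS[, j - 1L] + B[, j]
    lo <- pmax(seq_len(g) - h, 1L)
    hi <- pmin(seq_len(g) + h, g)
    W <- CS[, hi, drop = FALSE] - cbind(0, CS)[, lo, drop = FALSE]
    S[, idx] <- sweep(W, 2, hi - lo + 1L, "/")
  }
  if (!is.null(ref_smoothed)) S <- sweep(S, 2, ref_smoothed)
  if (recenter) S <- S - apply(S, 1, median)
  M <- 1 + S
  M[, order(gene_order), drop = FALSE]   # back to original column order
}

# per-gene mean of the smoothed residuals over the reference cells (in
# genomic order), computed with the same smoothing but without per-cell
# re-centering; subtracting it removes systematic bias (e.g. window edge
# effects) shared by all cells
smooth_ref_profile <- function(vals, ref_idx, ref_mean, ref_sd, gene_order,
                               chr_ordered, window, clamp) {
  Mref <- smooth_block(as.matrix(vals[ref_idx, , drop = FALSE]),
                       ref_mean, ref_sd, gene_order, chr_ordered,
                       window, clamp, warn_small = FALSE, recenter = FALSE)
  colMeans(Mref[, gene_order, drop = FALSE]) - 1
}

cnv_gene_order <- function(genes) {
  if (anyNA(genes$chromosome) || anyNA(genes$start))
    abort("gene table lacks chromosome/start positions; cannot smooth.")
  chr_levels <- unique(genes$chromosome[chrom_order(genes$chromosome)])
  order(match(genes$chromosome, chr_levels), genes$start)
}

# resolve a reference-cell specification (ids, logical mask, or indices)
ref_cell_index <- function(reference_cells, norm) {
  idx <- if (is.character(reference_cells))
    match(reference_cells, rownames(norm$values))
  else if (is.logical(reference_cells)) which(reference_cells)
  else as.integer(reference_cells)
  if (length(idx) == 0 || anyNA(idx))
    abort("reference cell set is empty or contains unknown ids.")
  idx
}

# genes retained for CNV analysis: mean depth-normalized expression at or
# above `min_mean` (the cited tool's documented low-expression cutoff for
# droplet data); weakly expressed genes carry no copy-number information
# and only dilute the windowed signal
cnv_gene_filter <- function(norm, min_mean) {
  if (min_mean <= 0) return(rep(TRUE, ncol(norm$values)))
  e <- norm$values
  e@x <- expm1(e@x)
  Matrix::colMeans(e) >= min_mean
}

#' Position-smoothed relative expression (simplified CNV signal)
#'
#' A lightweight expression-based copy-number signal in the spirit of
#' inferCNV's public description, without HMMs or subclustering: per gene,
#' the residual of log-normalized expression against the reference-cell
#' mean is clamped to `clamp` reference SDs, averaged over a moving window
#' of `window` genes along each chromosome (windows shrink at chromosome
#' edges; chromosomes with fewer than 3 genes pass through unsmoothed with
#' a warning), re-centered per cell by subtracting the cell's median
#' smoothed value, and offset to a diploid baseline of 1.
#'
#' @param norm A `scgain_norm`.
#' @param reference_cells Character ids (or logical/integer index) of the
#'   diploid reference cells; must be non-empty.
#' @param window Odd window width in genes (1 = no smoothing: the output
#'   is the clamped centered residual + 1).
#' @param clamp Residual clamp in units of the per-gene reference SD.
#' @param min_mean Low-expression cutoff: genes with mean depth-normalized
#'   expression below this are excluded from smoothing and scoring (0
#'   keeps all genes).
#' @param subtract_reference Subtract the smoothed reference-cell mean
#'   profile (computed with the same smoothing, without per-cell
#'   re-centering) before re-centering; removes systematic bias shared by
#'   all cells, such as window edge effects.
#' @return Dense matrix (cells x retained genes, original column order) of
#'   modified expression centered at 1.
#' @export
smooth_relative_expression <- function(norm, reference_cells, window = 101,
                                       clamp = 3, min_mean = 0.1,
                                       subtract_reference = TRUE) {
  stopifnot(inherits(norm, "scgain_norm"))
  if (window %% 2 != 1 || window < 1) abort("`window` must be odd and >= 1.")
  ref_idx <- ref_cell_index(reference_cells, norm)
  keep <- cnv_gene_filter(norm, min_mean)
  if (sum(keep) < 3) abort("fewer than 3 genes pass the expression cutoff.")
  genes <- norm$genes[keep, , drop = FALSE]
  vals <- norm$values[, keep, drop = FALSE]
  n_ref <- length(ref_idx)
  ref <- vals[ref_idx, , drop = FALSE]
  ref_mean <- as.numeric(Matrix::colMeans(ref))
  ref_sd <- sqrt(pmax(as.numeric(Matrix::colSums(ref^2)) / max(1, n_ref - 1) -
                        n_ref / max(1, n_ref - 1) * ref_mean^2, 0))
  ord <- cnv_gene_order(genes)
  prof <- if (subtract_reference)
    smooth_ref_profile(vals, ref_idx, ref_mean, ref_sd, ord,
                       genes$chromosome[ord], window, clamp) else NULL
  M <- smooth_block(as.matrix(vals), ref_mean, ref_sd, ord,
                    genes$chromosome[ord], window, clamp,
                    ref_smoothed = prof)
  dimnames(M) <- list(rownames(norm$values), genes$gene_id)
  M
}

#' Per-cell CNV score
#'
#' The mean over genes of the squared baseline-1 modified expression,
#' \eqn{S_c = \frac{1}{G}\sum_g m_{cg}^2}; exactly 1 for a perfectly
#' diploid cell and > 1 in the presence of smoothed deviations.
#'
#' @param modified_expression Matrix from [smooth_relative_expression()].
#' @return Named numeric vector of per-cell scores.
#' @export
cnv_score <- function(modified_expression) {
  rowMeans(modified_expression^2)
}

#' Memory-bounded per-cell CNV scores
#'
#' Equivalent to `cnv_score(smooth_relative_expression(...))` but streams
#' over blocks of cells so the dense smoothed matrix is never held in full;
#' used by [run_full()] on large datasets.
#'
#' @inheritParams smooth_relative_expression
#' @param block_size Number of cells smoothed per block.
#' @return Named numeric vector of per-cell scores.
#' @export
cnv_score_cells <- function(norm, reference_cells, window = 101, clamp = 3,
                            min_mean = 0.1, subtract_reference = TRUE,
                            block_size = 4000) {
  stopifnot(inherits(norm, "scgain_norm"))
  if (window %% 2 != 1 || window < 1) abort("`window` must be odd and >= 1.")
  ref_idx <- ref_cell_index(reference_cells, norm)
  keep <- cnv_gene_filter(norm, min_mean)
  if (sum(keep) < 3) abort("fewer than 3 genes pass the expression cutoff.")
  genes <- norm$genes[keep, , drop = FALSE]
  vals <- norm$values[, keep, drop = FALSE]
  ref <- vals[ref_idx, , drop = FALSE]
  n_ref <- length(ref_idx)
  ref_mean <- as.numeric(Matrix::colMeans(ref))
  ref_sd <- sqrt(pmax(as.numeric(Matrix::colSums(ref^2)) / max(1, n_ref - 1) -
                        n_ref / max(1, n_ref - 1) * ref_mean^2, 0))
  ord <- cnv_gene_order(genes)
  chr_o <- genes$chromosome[ord]
  prof <- if (subtract_reference)
    smooth_ref_profile(vals, ref_idx, ref_mean, ref_sd, ord, chr_o,
                       window, clamp) else NULL
  n <- nrow(vals)
  scores <- numeric(n)
  first <- TRUE
  for (b in seq_len(ceiling(n / block_size))) {
    rows <- ((b - 1L) * block_size + 1L):min(b * block_size, n)
    M <- smooth_block(as.matrix(vals[rows, , drop = FALSE]),
                      ref_mean, ref_sd, ord, chr_o, window, clamp,
                      warn_small = first, ref_smoothed = prof)
    scores[rows] <- rowMeans(M^2)
    first <- FALSE
  }
  names(scores) <- rownames(norm$values)
  scores
}

#' Select CNV-positive cells
#'
#' Cells (default) or whole clusters with CNV score strictly greater than
#' the threshold. In cluster mode a cluster qualifies when its mean score
#' exceeds the threshold, and all its cells are returned.
#'
#' @param cell_score Named per-cell scores from [cnv_score()].
#' @param threshold Strict lower bound (default 1.009).
#' @param level `"cell"` or `"cluster"`.
#' @param labels Cluster labels named by cell id (required for
#'   `level = "cluster"`).
#' @return Character vector of selected cell ids.
#' @export
select_cnv_positive <- function(cell_score, threshold = 1.009,
                                level = c("cell", "cluster"), labels = NULL) {
  level <- match.arg(level)
  if (level == "cell") return(names(cell_score)[cell_score > threshold])
  if (is.null(labels))
    abort("cluster-level gating requires cluster labels.")
  labels <- labels[names(cell_score)]
  means <- tapply(cell_score, labels, mean)
  keep <- names(means)[means > threshold]
  names(cell_score)[as.character(labels) %in% keep]
}
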