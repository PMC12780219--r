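#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via `stats::p.adjust(method = "BH")`. `NA`
#' p-values propagate as `NA` and are excluded from the number of tests;
#' the result is invariant to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    abort("p-values must lie in [0, 1].")
  p.adjust(p_values, method = "BH")
}

# Vectorized two-sided rank-sum p under the normal approximation with tie
# and continuity correction; agrees with wilcox.test(exact = FALSE,
# correct = TRUE) per gene (asserted in the test suite).
wilcoxon_approx_p <- function(A, B) {
  na <- nrow(A); nb <- nrow(B); N <- na + nb
  vapply(seq_len(ncol(A)), function(j) {
    y <- c(A[, j], B[, j])
    if (all(y == y[1])) return(1)
    r <- rank(y)
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(y)
    sigma2 <- na * nb / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- u - na * nb / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))
}

#' Differential expression between two cell groups
#'
#' Two tests are provided. `"wilcoxon"` (default): a two-sided rank-sum
#' test per gene on the log-normalized values (exact for small tie-free
#' groups, normal approximation with tie correction otherwise, as
#' implemented by `stats::wilcox.test`). `"nb_wald"`: a per-gene
#' negative-binomial regression on the raw counts with a log library-size
#' offset (`MASS::glm.nb`), with a Wald z-test on the group coefficient.
#'
#' The fold change is `log2((mean_a + eps) / (mean_b + eps))` on
#' depth-normalized means with `eps = 1e-9`. Genes whose values are
#' identical across both groups report `p = 1` and fold change 0.
#'
#' @param x A `scgain_norm` (required for `"wilcoxon"`); for `"nb_wald"` a
#'   `scgain_dataset` (raw counts) is required.
#' @param cells_a,cells_b Disjoint character cell-id groups, each with at
#'   least 3 cells. Group A is the population of interest (e.g. the rare
#'   marker cluster), group B the comparator.
#' @param method `"wilcoxon"` or `"nb_wald"`.
#' @param genes Optional subset of gene ids to test (default all).
#' @param scale_factor Depth scale for group means.
#' @return A tibble (one row per gene): `gene_id`, `log2_fc`, `mean_a`,
#'   `mean_b`, `p_value`, `adj_p` (BH), `direction`; `nb_wald` adds the
#'   natural-log coefficient `beta` and its standard error.
#' @export
differential_expression <- function(x, cells_a, cells_b,
                                    method = c("wilcoxon", "nb_wald"),
                                    genes = NULL, scale_factor = 1e4) {
  method <- match.arg(method)
  if (length(intersect(cells_a, cells_b)) > 0)
    abort("cell groups must be disjoint.")
  if (length(cells_a) < 3 || length(cells_b) < 3)
    abort("each group needs at least 3 cells.")
  eps <- 1e-9

  if (method == "wilcoxon") {
    stopifnot(inherits(x, "scgain_norm"))
    mat <- x$values
    totals <- x$totals
  } else {
    stopifnot(inherits(x, "scgain_dataset"))
    mat <- x$counts
    totals <- Matrix::rowSums(x$counts)
  }
  all_genes <- colnames(mat)
  genes <- genes %||% all_genes
  gidx <- match(genes, all_genes)
  if (anyNA(gidx)) abort("unknown gene ids requested.")
  ia <- match(cells_a, rownames(mat))
  ib <- match(cells_b, rownames(mat))
  if (anyNA(ia) || anyNA(ib)) abort("unknown cell ids in groups.")

  if (method == "wilcoxon") {
    # depth-normalized means from lognorm values: expm1 inverts log1p
    A <- mat[ia, gidx, drop = FALSE]; B <- mat[ib, gidx, drop = FALSE]
    mean_a <- Matrix::colMeans(expm1(as.matrix(A)))
    mean_b <- Matrix::colMeans(expm1(as.matrix(B)))
    Ad <- as.matrix(A); Bd <- as.matrix(B)
    na <- length(ia); nb <- length(ib)
    if (na < 50 && nb < 50) {
      # small groups: wilcox.test (exact when tie-free)
      p <- vapply(seq_along(gidx), function(j) {
        a <- Ad[, j]; b <- Bd[, j]
        if (all(a == a[1]) && all(b == a[1])) return(1)
        suppressWarnings(wilcox.test(a, b)$p.value)
      }, numeric(1))
    } else {
      p <- wilcoxon_approx_p(Ad, Bd)
    }
  } else {
    suba <- mat[ia, gidx, drop = FALSE]; subb <- mat[ib, gidx, drop = FALSE]
    mean_a <- Matrix::colMeans(suba / totals[ia] * scale_factor)
    mean_b <- Matrix::colMeans(subb / totals[ib] * scale_factor)
    grp <- factor(c(rep("a", length(ia)), rep("b", length(ib))),
                  levels = c("b", "a"))
    off <- log(c(totals[ia], totals[ib]))
    Ya <- as.matrix(suba); Yb <- as.matrix(subb)
    beta <- se <- p <- rep(NA_real_, length(gidx))
    for (j in seq_along(gidx)) {
      y <- c(Ya[, j], Yb[, j])
      if (all(y == y[1])) { p[j] <- 1; beta[j] <- 0; next }
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(y ~ grp + offset(off))),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
      if (is.null(cf) || !"grpa" %in% rownames(cf)) next
      beta[j] <- cf["grpa", "Estimate"]
      se[j] <- cf["grpa", "Std. Error"]
      p[j] <- cf["grpa", "Pr(>|z|)"]
    }
  }

  lfc <- log2((mean_a + eps) / (mean_b + eps))
  # identical-in-both-groups convention: fold change 0
  zerovar <- vapply(seq_along(gidx), function(j) {
    va <- mat[ia, gidx[j]]; vb <- mat[ib, gidx[j]]
    all(va == va[1]) && all(vb == va[1])
  }, logical(1))
  lfc[zerovar] <- 0
  out <- tibble(gene_id = genes, log2_fc = lfc,
                mean_a = as.numeric(mean_a), mean_b = as.numeric(mean_b),
                p_value = p, adj_p = bh_adjust(p),
                direction = dplyr::case_when(lfc > 0 ~ "up",
                                             lfc < 0 ~ "down",
                                             TRUE ~ "none"))
  if (method == "nb_wald") { out$beta <- beta; out$se <- se }
  out
}

#' Hypergeometric overlap of a gene list with a reference set
#'
#' One-sided upper-tail hypergeometric test of the overlap between a
#' differentially expressed gene list and a reference signature within a
#' stated universe.
#'
#' @param deg_genes Character gene list (e.g. significant DEG).
#' @param reference_set Character reference signature.
#' @param universe Character universe; both sets must be subsets of it.
#' @return One-row tibble: `n_deg`, `n_set`, `n_overlap`, `n_universe`,
#'   `p_hyper`.
#' @export
geneset_overlap <- function(deg_genes, reference_set, universe) {
  if (length(universe) == 0) abort("empty universe.")
  if (!all(deg_genes %in% universe) || !all(reference_set %in% universe))
    abort("both gene sets must be subsets of the universe.")
  deg_genes <- unique(deg_genes); reference_set <- unique(reference_set)
  k <- length(intersect(deg_genes, reference_set))
  tibble(n_deg = length(deg_genes), n_set = length(reference_set),
         n_overlap = k, n_universe = length(unique(universe)),
         p_hyper = phyper(k - 1, length(reference_set),
                          length(unique(universe)) - length(reference_set),
                          length(deg_genes), lower.tail = FALSE))
}

#' Fraction of cells positive for a gene
#'
#' Fraction of the given cells with strictly positive normalized
#' expression of the gene (`NA` for an empty cell set).
#'
#' @param norm A `scgain_norm`.
#' @param cells Character cell ids.
#' @param gene A single gene id.
#' @return Numeric fraction in `[0, 1]`, or `NA`.
#' @export
marker_positive_fraction <- function(norm, cells, gene) {
  stopifnot(inherits(norm, "scgain_norm"), length(gene) == 1)
  if (!gene %in% norm$genes$gene_id) abort("gene not present.")
  if (length(cells) == 0) return(NA_real_)
  idx <- match(cells, rownames(norm$values))
  if (anyNA(idx)) abort("unknown cell ids.")
  mean(norm$values[idx, match(gene, norm$genes$gene_id)] > 0)
}
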