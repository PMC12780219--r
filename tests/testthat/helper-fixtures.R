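# Small simulation configs and independent oracles shared across tests.

small_config <- function(n_cells = 600, n_genes = 300, rare_fraction = 0.01,
                         n_reference = round(n_cells / 5), seed = 42,
                         n_chromosomes = 4, ...) {
  seg_len <- max(2L, floor(n_genes * 0.9 / n_chromosomes / 2))
  sim_config(n_cells = n_cells, n_genes = n_genes,
             rare_fraction = rare_fraction, n_reference = n_reference,
             n_chromosomes = n_chromosomes,
             cnv_segments = list(
               list(chromosome = "chr1", start_gene_index = 1,
                    end_gene_index = seg_len, multiplier = 2)),
             n_dormancy = min(20L, max(2L, round(n_genes / 15))),
             seed = seed, ...)
}

# dataset with hand-built counts for exact QC enumeration
toy_dataset <- function(counts, chromosome = NULL, mito = NULL,
                        truth = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  n <- nrow(counts); g <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("c%03d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%03d", seq_len(g))
  genes <- tibble::tibble(
    gene_id = colnames(counts),
    chromosome = chromosome %||% rep("chr1", g),
    start = seq_len(g) * 1000L,
    mito = mito %||% rep(FALSE, g),
    marker = rep(FALSE, g))
  structure(list(
    counts = methods::as(counts, "CsparseMatrix"),
    cells = tibble::tibble(cell_id = rownames(counts),
                           truth_label = truth %||% rep(NA_character_, n)),
    genes = genes, params = NULL, config = NULL),
    class = "scgain_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force GSEA running sum: literal step-by-step loop;
# tie between symmetric extremes resolved toward the positive one, as in
# the definition under test
brute_es <- function(stats_sorted, gene_set, p = 1) {
  nm <- names(stats_sorted)
  N <- length(nm)
  hit <- nm %in% gene_set
  nr <- sum(abs(stats_sorted[hit])^p)
  run <- 0; mx <- -Inf; mn <- Inf
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (nr > 0) abs(stats_sorted[[i]])^p / nr else 1 / sum(hit)
    } else -1 / (N - sum(hit))
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  as.numeric(if (mx + mn >= -1e-12) mx else mn)
}

# exact two-sided rank-sum p by enumeration of all group-A assignments
enum_wilcox_p <- function(a, b) {
  y <- c(a, b); na <- length(a)
  r <- rank(y)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(y), na)
  stat <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- na * (length(y) + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

# NB counts for two groups with the first n_de genes at e^beta fold
nb_sim_dataset <- function(n_per_group, n_de, n_null, beta = 1, theta = 2,
                           seed) {
  withr::with_seed(seed, {
    mu0 <- exp(runif(n_de + n_null, log(2), log(20)))
    beta_true <- c(rep(beta, n_de), rep(0, n_null))
    counts <- sapply(seq_len(n_de + n_null), function(g) {
      c(rnbinom(n_per_group, mu = mu0[g] * exp(beta_true[g]), size = theta),
        rnbinom(n_per_group, mu = mu0[g], size = theta))
    })
    rownames(counts) <- c(sprintf("a%03d", seq_len(n_per_group)),
                          sprintf("b%03d", seq_len(n_per_group)))
    colnames(counts) <- sprintf("g%04d", seq_len(ncol(counts)))
    toy_dataset(counts)
  })
}

# Mann-Whitney AUC
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}
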