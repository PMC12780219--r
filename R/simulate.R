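#' Simulation configuration for a planted rare-population scRNA-seq dataset
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults describe the study conditions used throughout the package: a
#' 20,000-cell tumor dataset carrying a rare (0.1%) double-marker-positive
#' dormant subpopulation ("SRCC") inside a copy-number-altered cancer
#' compartment, alongside diploid reference cells. Counts are negative
#' binomial with cell-specific log-normal library sizes.
#'
#' The expected count for cell \eqn{c} and gene \eqn{g} is
#' \deqn{\mu_{cg} = L_c \, p_g \, m_{cg},}
#' where \eqn{L_c} is the cell's library size, \eqn{p_g} the baseline gene
#' proportion (proportions sum to 1), and \eqn{m_{cg}} the product of the
#' multipliers that apply to that cell/gene: the CNV segment multiplier for
#' cancer cells, the marker fold for rare-population cells on marker genes
#' (a Bernoulli on/off background for all other cells), the dormancy fold
#' for rare-population cells on dormancy genes, and the mitochondrial
#' stress multiplier for stressed cells on chrM genes. Counts are drawn as
#' \eqn{NB(\mu, \theta)} with variance \eqn{\mu + \mu^2/\theta}.
#'
#' @param n_cells Total number of cells (includes reference cells).
#' @param n_genes Total number of genes (autosomal + mitochondrial).
#' @param rare_fraction Fraction of cells planted as the rare double-marker
#'   population, in `[0, 1)`. The planted count is `round(rare_fraction *
#'   n_cells)` (half away from zero) with a floor of 1 whenever
#'   `rare_fraction > 0`.
#' @param n_reference Number of diploid reference cells (no CNV).
#' @param n_chromosomes Number of autosomes genes are spread over; all
#'   mitochondrial genes sit on `"chrM"`.
#' @param marker_genes Character ids of the marker genes defining the rare
#'   population (default two, standing for the SLC52A2/NOTCH1 pair).
#' @param marker_mean_fold Fold elevation of marker mean expression in the
#'   rare population relative to a background-positive cell; must be > 1
#'   when `rare_fraction > 0`.
#' @param marker_background_rate Probability that a cell outside the rare
#'   population expresses a marker at all (per marker, independent).
#' @param marker_base_mean Expected marker count in a background-positive
#'   cell at the typical library size.
#' @param dispersion Negative-binomial inverse-dispersion \eqn{\theta}
#'   (scalar, or vector of length `n_genes`).
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size
#'   parameters (natural log).
#' @param mito_fraction_genes Fraction of genes flagged mitochondrial.
#' @param mito_budget Share of baseline expression mass carried by
#'   mitochondrial genes.
#' @param stress_fraction Fraction of cells with elevated mitochondrial
#'   content (exercises the QC mito rule).
#' @param stress_multiplier Mitochondrial multiplier for stressed cells.
#' @param low_quality_fraction Fraction of cells with collapsed library
#'   size (exercises the QC detected-genes rule).
#' @param low_quality_scale Library-size multiplier for low-quality cells.
#' @param cnv_segments List of segments applied to cancer cells; each a
#'   list with `chromosome`, `start_gene_index`, `end_gene_index` (1-based
#'   indices within that chromosome's genes, genomic order) and
#'   `multiplier` (> 0). Reference cells never carry these.
#' @param dormancy_genes Character ids of genes down-regulated in the rare
#'   population, or `NULL` to sample `n_dormancy` genes at simulation time.
#' @param n_dormancy Number of dormancy genes sampled when
#'   `dormancy_genes` is `NULL`.
#' @param dormancy_fold Fold factor in `(0, 1)` applied to dormancy genes
#'   in the rare population.
#' @param reference_program_fraction Fraction of ordinary genes carrying a
#'   cell-type program that distinguishes the reference compartment
#'   (fibroblast/B-cell-like) from the epithelial compartment; half the
#'   program genes are elevated and half suppressed in reference cells.
#' @param reference_program_fold Fold factor (> 1) of the reference
#'   program.
#' @param seed Integer RNG seed; fully determines the dataset.
#'
#' @return A validated list of class `"scgain_sim_config"`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_cells = 20000,
                       n_genes = 3000,
                       rare_fraction = 0.001,
                       n_reference = 4000,
                       n_chromosomes = 10,
                       marker_genes = c("SLC52A2", "NOTCH1"),
                       marker_mean_fold = 8,
                       marker_background_rate = 0.01,
                       marker_base_mean = 2,
                       dispersion = 2,
                       libsize_log_mean = log(1e4),
                       libsize_log_sd = 0.3,
                       mito_fraction_genes = 0.02,
                       mito_budget = 0.035,
                       stress_fraction = 0.02,
                       stress_multiplier = 3,
                       low_quality_fraction = 0.01,
                       low_quality_scale = 0.02,
                       cnv_segments = list(
                         list(chromosome = "chr1", start_gene_index = 1,
                              end_gene_index = 150, multiplier = 1.5),
                         list(chromosome = "chr5", start_gene_index = 1,
                              end_gene_index = 150, multiplier = 1.4),
                         list(chromosome = "chr7", start_gene_index = 1,
                              end_gene_index = 150, multiplier = 1.6)),
                       dormancy_genes = NULL,
                       n_dormancy = 50,
                       dormancy_fold = 0.5,
                       reference_program_fraction = 0.1,
                       reference_program_fold = 3,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    rare_fraction = rare_fraction, n_reference = as.integer(n_reference),
    n_chromosomes = as.integer(n_chromosomes),
    marker_genes = as.character(marker_genes),
    marker_mean_fold = marker_mean_fold,
    marker_background_rate = marker_background_rate,
    marker_base_mean = marker_base_mean,
    dispersion = dispersion,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    mito_fraction_genes = mito_fraction_genes, mito_budget = mito_budget,
    stress_fraction = stress_fraction, stress_multiplier = stress_multiplier,
    low_quality_fraction = low_quality_fraction,
    low_quality_scale = low_quality_scale,
    cnv_segments = cnv_segments,
    dormancy_genes = dormancy_genes, n_dormancy = as.integer(n_dormancy),
    dormancy_fold = dormancy_fold,
    reference_program_fraction = reference_program_fraction,
    reference_program_fold = reference_program_fold,
    seed = as.integer(seed))
  class(cfg) <- "scgain_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 1, cfg$n_genes >= 10, cfg$n_chromosomes >= 1)
  if (cfg$rare_fraction < 0 || cfg$rare_fraction >= 1)
    abort("`rare_fraction` must lie in [0, 1).", class = "scgain_invalid_config")
  if (cfg$rare_fraction > 0 && cfg$rare_fraction * cfg$n_cells < 1 &&
      round_half_up(cfg$rare_fraction * cfg$n_cells) < 1) {
    # floor-1 rule still plants one cell; nothing to reject
  }
  if (cfg$rare_fraction > 0 && cfg$marker_mean_fold <= 1)
    abort(paste("`marker_mean_fold` must exceed 1 when a rare population is",
                "planted; the population would be undetectable by construction."),
          class = "scgain_invalid_config")
  if (cfg$n_reference < 0 || cfg$n_reference >= cfg$n_cells)
    abort("`n_reference` must be in [0, n_cells).", class = "scgain_invalid_config")
  if (length(cfg$marker_genes) < 1 || anyDuplicated(cfg$marker_genes))
    abort("`marker_genes` must be a non-empty set of unique ids.",
          class = "scgain_invalid_config")
  for (seg in cfg$cnv_segments) {
    if (!all(c("chromosome", "start_gene_index", "end_gene_index", "multiplier")
             %in% names(seg)))
      abort("each CNV segment needs chromosome, start/end gene index, multiplier.",
            class = "scgain_invalid_config")
    if (seg$multiplier <= 0)
      abort("CNV multipliers must be > 0.", class = "scgain_invalid_config")
    if (seg$start_gene_index < 1 || seg$end_gene_index < seg$start_gene_index)
      abort("CNV segment gene indices must satisfy 1 <= start <= end.",
            class = "scgain_invalid_config")
  }
  if (cfg$dormancy_fold <= 0 || cfg$dormancy_fold >= 1)
    abort("`dormancy_fold` must lie in (0, 1).", class = "scgain_invalid_config")
  if (cfg$reference_program_fraction < 0 || cfg$reference_program_fraction >= 1)
    abort("`reference_program_fraction` must lie in [0, 1).",
          class = "scgain_invalid_config")
  if (cfg$reference_program_fold <= 1)
    abort("`reference_program_fold` must exceed 1.",
          class = "scgain_invalid_config")
  if (any(cfg$dispersion <= 0))
    abort("`dispersion` must be positive.", class = "scgain_invalid_config")
  cfg
}

#' Number of planted rare cells implied by a configuration
#'
#' Deterministic rounding rule: `round(rare_fraction * n_cells)` half away
#' from zero, with a floor of 1 whenever `rare_fraction > 0`.
#'
#' @param config A [sim_config()] object.
#' @return Integer count of planted cells.
#' @export
n_planted_cells <- function(config) {
  if (config$rare_fraction == 0) return(0L)
  max(1L, as.integer(round_half_up(config$rare_fraction * config$n_cells)))
}

# Build the gene table (ids, chromosome, 1-based start, mito/marker flags)
# and the per-gene baseline proportions. Deterministic given the RNG state.
build_gene_universe <- function(cfg) {
  n_mito <- as.integer(round_half_up(cfg$mito_fraction_genes * cfg$n_genes))
  n_auto <- cfg$n_genes - n_mito
  chr <- paste0("chr", rep(seq_len(cfg$n_chromosomes), length.out = n_auto)[
    order(rep(seq_len(cfg$n_chromosomes), length.out = n_auto))])
  # per-chromosome gene order and start coordinates
  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  chromosome <- c(chr, rep("chrM", n_mito))
  start <- unlist(lapply(split(seq_along(chromosome), chromosome), seq_along))
  start <- integer(length(chromosome))
  for (cc in unique(chromosome)) {
    idx <- which(chromosome == cc)
    start[idx] <- seq_along(idx) * 100000L
  }
  mito <- chromosome == "chrM"

  # genes covered by CNV segments (kept marker-free)
  in_segment <- logical(cfg$n_genes)
  for (seg in cfg$cnv_segments) {
    idx <- which(chromosome == seg$chromosome)
    if (length(idx) < seg$end_gene_index)
      abort(sprintf("CNV segment on %s exceeds its %d genes.",
                    seg$chromosome, length(idx)),
            class = "scgain_invalid_config")
    in_segment[idx[seg$start_gene_index:seg$end_gene_index]] <- TRUE
  }

  # markers replace ordinary autosomal genes outside CNV segments, placed on
  # the last autosome so the marker signal is independent of the CNV signal
  candidates <- which(!mito & !in_segment)
  if (length(candidates) < length(cfg$marker_genes))
    abort("not enough non-mito, non-CNV genes to host the markers.",
          class = "scgain_invalid_config")
  marker_idx <- utils::tail(candidates, length(cfg$marker_genes))
  gene_id[marker_idx] <- cfg$marker_genes
  marker <- seq_len(cfg$n_genes) %in% marker_idx

  # baseline proportions: heavy-tailed log-normal abundances; markers pinned
  # to marker_base_mean at the typical library size; mito genes share a
  # fixed budget so the QC mito fraction is controlled
  draw <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.5)
  p <- numeric(cfg$n_genes)
  p_marker <- cfg$marker_base_mean / exp(cfg$libsize_log_mean)
  p[marker] <- p_marker
  p[mito] <- cfg$mito_budget * draw[mito] / sum(draw[mito])
  rest <- !marker & !mito
  p[rest] <- (1 - cfg$mito_budget - sum(p[marker])) * draw[rest] / sum(draw[rest])

  list(genes = tibble(gene_id = gene_id, chromosome = chromosome,
                      start = as.integer(start), mito = mito, marker = marker),
       proportions = p, in_segment = in_segment, marker_idx = marker_idx)
}

#' Simulate a scRNA-seq count dataset with a planted rare population
#'
#' Draws negative-binomial counts under the generative model described in
#' [sim_config()] and returns the counts together with per-cell truth
#' labels and a gene table (chromosome, start, mitochondrial and marker
#' flags). Identical configurations (including the seed) give
#' byte-identical datasets.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"scgain_dataset"`: a list with
#'   * `counts`: sparse `dgCMatrix`, cells x genes, non-negative integers;
#'   * `cells`: tibble with `cell_id` and `truth_label` in
#'     `{"SRCC", "cancer_nonSRCC", "reference"}`;
#'   * `genes`: gene table tibble;
#'   * `params`: generative quantities (baseline proportions, library
#'     sizes, resolved dormancy genes, per-gene multiplier summaries) used
#'     by tests to assert on expected means rather than samples;
#'   * `config`: the configuration.
#' @examples
#' ds <- simulate_dataset(sim_config(n_cells = 300, n_genes = 120,
#'                                   rare_fraction = 0.01, n_reference = 60,
#'                                   cnv_segments = list(), seed = 7))
#' table(ds$cells$truth_label)
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    uni <- build_gene_universe(config)
    genes <- uni$genes
    p <- uni$proportions
    n <- config$n_cells
    G <- config$n_genes

    n_srcc <- n_planted_cells(config)
    n_ref <- config$n_reference
    n_cancer <- n - n_ref - n_srcc
    if (n_cancer < 0)
      abort("n_reference + planted cells exceed n_cells.",
            class = "scgain_invalid_config")
    truth <- sample(c(rep("reference", n_ref),
                      rep("cancer_nonSRCC", n_cancer),
                      rep("SRCC", n_srcc)))
    cell_id <- sprintf("cell%05d", seq_len(n))
    is_cancer <- truth != "reference"
    is_srcc <- truth == "SRCC"

    # library sizes, low-quality and mito-stressed cells (never planted cells
    # are exempted: degraded cells are drawn from the whole population)
    L <- rlnorm(n, config$libsize_log_mean, config$libsize_log_sd)
    lowq <- runif(n) < config$low_quality_fraction
    L[lowq] <- L[lowq] * config$low_quality_scale
    stressed <- runif(n) < config$stress_fraction

    # dormancy genes: sampled among ordinary autosomal genes if not given
    if (is.null(config$dormancy_genes)) {
      pool <- genes$gene_id[!genes$mito & !genes$marker & !uni$in_segment]
      dormancy <- sample(pool, min(config$n_dormancy, length(pool)))
    } else {
      dormancy <- config$dormancy_genes
      if (!all(dormancy %in% genes$gene_id))
        abort("dormancy_genes must exist in the gene universe.",
              class = "scgain_invalid_config")
    }
    dorm_idx <- match(dormancy, genes$gene_id)

    # reference cell-type program: distinguishes the diploid compartment
    # (fibroblast/B-cell-like) from the epithelial compartments, as in real
    # tumor scRNA-seq; half up, half down in reference cells
    prog_pool <- setdiff(which(!genes$mito & !genes$marker & !uni$in_segment),
                         dorm_idx)
    n_prog <- min(length(prog_pool),
                  as.integer(round_half_up(config$reference_program_fraction *
                                             config$n_genes)))
    prog_idx <- sample(prog_pool, n_prog)
    prog_fold <- rep(c(config$reference_program_fold,
                       1 / config$reference_program_fold),
                     length.out = n_prog)
    ref_mult <- rep(1, G)
    ref_mult[prog_idx] <- prog_fold

    # per-gene CNV multiplier (cancer cells only)
    cnv_mult <- rep(1, G)
    for (seg in config$cnv_segments) {
      idx <- which(genes$chromosome == seg$chromosome)
      cnv_mult[idx[seg$start_gene_index:seg$end_gene_index]] <- seg$multiplier
    }

    # marker background on/off indicators for non-rare cells
    marker_on <- matrix(runif(n * length(uni$marker_idx)) <
                          config$marker_background_rate,
                        nrow = n)

    theta <- rep(config$dispersion, length.out = G)

    # draw counts gene-blockwise to bound memory
    block <- 500L
    parts <- list()
    for (b in seq_len(ceiling(G / block))) {
      cols <- ((b - 1L) * block + 1L):min(b * block, G)
      mu <- outer(L, p[cols])
      seg_cols <- cnv_mult[cols] != 1
      if (any(seg_cols))
        mu[is_cancer, seg_cols] <- mu[is_cancer, seg_cols, drop = FALSE] *
          rep(cnv_mult[cols][seg_cols], each = sum(is_cancer))
      mito_cols <- genes$mito[cols]
      if (any(mito_cols) && any(stressed))
        mu[stressed, mito_cols] <- mu[stressed, mito_cols, drop = FALSE] *
          config$stress_multiplier
      pcols <- which(ref_mult[cols] != 1)
      if (length(pcols) && any(!is_cancer))
        mu[!is_cancer, pcols] <- mu[!is_cancer, pcols, drop = FALSE] *
          rep(ref_mult[cols][pcols], each = sum(!is_cancer))
      dcols <- which(cols %in% dorm_idx)
      if (length(dcols) && any(is_srcc))
        mu[is_srcc, dcols] <- mu[is_srcc, dcols, drop = FALSE] *
          config$dormancy_fold
      mcols <- which(cols %in% uni$marker_idx)
      for (j in mcols) {
        which_marker <- match(cols[j], uni$marker_idx)
        mult <- ifelse(is_srcc, config$marker_mean_fold,
                       as.numeric(marker_on[, which_marker]))
        mu[, j] <- mu[, j] * mult
      }
      cnt <- rnbinom(length(mu), mu = mu,
                     size = rep(theta[cols], each = n))
      parts[[b]] <- Matrix(matrix(cnt, nrow = n), sparse = TRUE)
    }
    counts <- do.call(cbind, parts)
    counts <- as(counts, "CsparseMatrix")
    dimnames(counts) <- list(cell_id, genes$gene_id)

    structure(list(
      counts = counts,
      cells = tibble(cell_id = cell_id, truth_label = truth),
      genes = genes,
      params = list(proportions = p, libsize = L, cnv_multiplier = cnv_mult,
                    dormancy_genes = dormancy, marker_idx = uni$marker_idx,
                    reference_multiplier = ref_mult,
                    stressed = stressed, low_quality = lowq),
      config = config),
      class = "scgain_dataset")
  })
}

#' @export
print.scgain_dataset <- function(x, ...) {
  cat(sprintf("<scgain_dataset> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$cells$truth_label))
  invisible(x)
}

#' Expected normalized marker expression by truth label
#'
#' Generative (not sampled) mean expression of each marker gene per truth
#' label, on the depth-normalized scale `scale_factor * p_g * m_g`. Used to
#' assert the planted-signal property on expected values.
#'
#' @param config A [sim_config()] object.
#' @param scale_factor Depth-normalization scale.
#' @return Tibble with `gene_id`, `label`, `expected_mean`.
#' @export
expected_marker_means <- function(config, scale_factor = 1e4) {
  config <- validate_sim_config(config)
  uni <- withr::with_seed(config$seed, build_gene_universe(config))
  p <- uni$proportions[uni$marker_idx]
  out <- list()
  for (i in seq_along(uni$marker_idx)) {
    out[[i]] <- tibble(
      gene_id = config$marker_genes[i],
      label = c("SRCC", "cancer_nonSRCC", "reference"),
      expected_mean = scale_factor * p[i] *
        c(config$marker_mean_fold, config$marker_background_rate,
          config$marker_background_rate))
  }
  dplyr::bind_rows(out)
}
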