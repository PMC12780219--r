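# a dataset with well-expressed genes so the CNV expression cutoff is moot
cnv_fixture <- function(n_cells = 300, n_genes = 120, multiplier = 2,
                        seg_len = 40, seed = 71, n_chromosomes = 2) {
  sim_config(n_cells = n_cells, n_genes = n_genes, rare_fraction = 0,
             n_reference = round(n_cells / 2),
             n_chromosomes = n_chromosomes,
             cnv_segments = if (is.null(multiplier)) list() else
               list(list(chromosome = "chr1", start_gene_index = 1,
                         end_gene_index = seg_len, multiplier = multiplier)),
             low_quality_fraction = 0, stress_fraction = 0,
             mito_fraction_genes = 0, mito_budget = 0,
             reference_program_fraction = 0,   # null premise: identical profiles
             n_dormancy = 2, seed = seed)
}

test_that("null case: cells distributed like the reference give m close to 1", {
  ds <- simulate_dataset(cnv_fixture(n_genes = 600, multiplier = NULL))
  nm <- lognormalize(filter_cells(ds, 20))
  ref <- nm$cells$cell_id[nm$cells$truth_label == "reference"]
  M <- smooth_relative_expression(nm, ref, window = 101)
  test_cells <- setdiff(rownames(M), ref)
  # no systematic deviation: per-gene means across test cells hug the
  # diploid baseline, per-cell deviations stay at the smoothing noise floor
  expect_lt(max(abs(colMeans(M[test_cells, ]) - 1)), 0.05)
  expect_gt(mean(abs(rowMeans(M[test_cells, , drop = FALSE]) - 1) < 0.05),
            0.95)
  # per-entry deviations sit at the smoothing noise floor (sigma/sqrt(w))
  expect_lt(mean(abs(M - 1)), 0.08)
})

test_that("window of 1 degenerates to the clamped centered residual plus 1", {
  ds <- simulate_dataset(cnv_fixture(n_cells = 80, n_genes = 40,
                                     multiplier = NULL))
  nm <- lognormalize(filter_cells(ds, 5))
  ref <- nm$cells$cell_id[nm$cells$truth_label == "reference"]
  M <- smooth_relative_expression(nm, ref, window = 1, min_mean = 0,
                                  subtract_reference = FALSE)
  E <- as.matrix(nm$values)
  ridx <- match(ref, rownames(E))
  mu <- colMeans(E[ridx, ])
  s <- apply(E[ridx, ], 2, sd)
  R <- sweep(E, 2, mu)
  R <- pmin(pmax(R, rep(-3 * s, each = nrow(R))), rep(3 * s, each = nrow(R)))
  expected <- 1 + (R - apply(R, 1, median))
  expect_equal(M, expected[, colnames(M)], tolerance = 1e-12)
})

test_that("a planted segment elevates smoothed expression for nearly all carriers", {
  ds <- simulate_dataset(cnv_fixture(n_cells = 400, n_genes = 160,
                                     multiplier = 2, seg_len = 60))
  nm <- lognormalize(filter_cells(ds, 20))
  ref <- nm$cells$cell_id[nm$cells$truth_label == "reference"]
  M <- smooth_relative_expression(nm, ref, window = 41)
  seg_genes <- intersect(ds$genes$gene_id[ds$params$cnv_multiplier == 2],
                         colnames(M))
  out_genes <- setdiff(colnames(M), seg_genes)
  carriers <- setdiff(rownames(M), ref)
  inside <- rowMeans(M[carriers, seg_genes])
  outside <- rowMeans(M[carriers, out_genes])
  expect_gt(mean(inside > outside), 0.95)
})

test_that("cnv_score matches closed forms", {
  M1 <- matrix(1, 5, 10)
  expect_equal(unname(cnv_score(M1)), rep(1, 5))
  # 10% of genes at 1.1, rest at 1: S = 0.9 + 0.1 * 1.21 = 1.021
  M2 <- matrix(1, 1, 100); M2[1, 1:10] <- 1.1
  expect_equal(unname(cnv_score(M2)), 1.021)
  M3 <- matrix(0, 3, 4)
  expect_equal(unname(cnv_score(M3)), rep(0, 3))
  expect_true(all(cnv_score(matrix(rnorm(50), 5)) >= 0))
})

test_that("CNV positivity is strict at the threshold and supports cluster gating", {
  s <- c(a = 1.009, b = 1.0090001, c = 0.5, d = 2)
  expect_setequal(select_cnv_positive(s, 1.009), c("b", "d"))
  expect_setequal(select_cnv_positive(s, 0), names(s))
  # cluster level: gate whole clusters by mean score; cluster {a, b} has
  # mean 1.004 and is dropped even though b alone passes
  s2 <- c(a = 1.000, b = 1.008, c = 0.9, d = 1.5)
  lab <- setNames(c(1, 1, 2, 2), names(s2))
  expect_setequal(select_cnv_positive(s2, 1.009, level = "cluster",
                                      labels = lab), c("c", "d"))
  expect_error(select_cnv_positive(s, 1.009, level = "cluster"), "labels")
})

test_that("streamed block scoring equals the in-memory path", {
  ds <- simulate_dataset(cnv_fixture(n_cells = 250, n_genes = 100))
  nm <- lognormalize(filter_cells(ds, 20))
  ref <- nm$cells$cell_id[nm$cells$truth_label == "reference"]
  s1 <- cnv_score(smooth_relative_expression(nm, ref, window = 21))
  s2 <- cnv_score_cells(nm, ref, window = 21, block_size = 64)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("tiny chromosomes pass through unsmoothed with a warning", {
  set.seed(72)
  counts <- matrix(rpois(40 * 10, 20), 40, 10)
  ds <- toy_dataset(counts, chromosome = c(rep("chr1", 8), "chr2", "chr2"))
  nm <- lognormalize(ds)
  expect_warning(
    smooth_relative_expression(nm, ds$cells$cell_id[1:20], window = 5,
                               min_mean = 0),
    "unsmoothed")
})

test_that("smoothing is equivariant to swapping identically laid-out chromosomes", {
  set.seed(73)
  n <- 60; g_per <- 30
  block <- matrix(rpois(n * g_per, 15), n, g_per)
  counts <- cbind(block, matrix(rpois(n * g_per, 15), n, g_per))
  ds <- toy_dataset(counts,
                    chromosome = rep(c("chr1", "chr2"), each = g_per))
  ds$genes$start <- rep(seq_len(g_per) * 1000L, 2)
  # swap the two chromosomes' count blocks
  ds_swap <- ds
  ds_swap$counts <- ds$counts[, c((g_per + 1):(2 * g_per), 1:g_per)]
  colnames(ds_swap$counts) <- colnames(ds$counts)
  ref <- ds$cells$cell_id[1:30]
  m1 <- smooth_relative_expression(lognormalize(ds), ref, window = 11,
                                   min_mean = 0)
  m2 <- smooth_relative_expression(lognormalize(ds_swap), ref, window = 11,
                                   min_mean = 0)
  expect_equal(unname(m1[, 1:g_per]), unname(m2[, (g_per + 1):(2 * g_per)]),
               tolerance = 1e-12)
  expect_equal(unname(m1[, (g_per + 1):(2 * g_per)]), unname(m2[, 1:g_per]),
               tolerance = 1e-12)
})

test_that("reference self-score stays in the diploid band on default-style data", {
  ds <- simulate_dataset(small_config(n_cells = 800, n_genes = 400,
                                      seed = 77))
  nm <- lognormalize(filter_cells(ds, 50))
  ref <- nm$cells$cell_id[nm$cells$truth_label == "reference"]
  s <- cnv_score_cells(nm, ref)
  expect_gt(mean(s[ref]), 0.98)
  expect_lt(mean(s[ref]), 1.02)
})
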