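dge_fixture <- function(seed = 91) {
  ds <- simulate_dataset(small_config(n_cells = 200, n_genes = 120,
                                      rare_fraction = 0.05, seed = seed))
  list(ds = ds, norm = lognormalize(filter_cells(ds, 10)))
}

test_that("BH adjustment matches the hand-computed step-up and its contracts", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.2), 0.2)
  # order invariance: sort-and-restore exactness
  p <- c(0.04, 0.001, 0.9, 0.2, 0.012)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # NA p-values propagate and are excluded from the number of tests
  out <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_adjust(c(0.01, 0.02)))
  # adjusted values never fall below raw ones
  set.seed(92)
  q <- runif(50)
  expect_true(all(bh_adjust(q) >= q))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("wilcoxon p matches exact enumeration for small groups", {
  # clean separation A = {7,8,9} vs B = {1,2,3}: exact p = 2/20 = 0.1
  fx <- dge_fixture()
  expect_equal(enum_wilcox_p(c(7, 8, 9), c(1, 2, 3)), 0.1)
  expect_equal(wilcox.test(c(7, 8, 9), c(1, 2, 3))$p.value, 0.1)
  # random tie-free instances, groups of size <= 6
  set.seed(93)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    vals <- sample(1000, na + nb) / 7
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(wilcox.test(a, b)$p.value, enum_wilcox_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the vectorized rank-sum path equals wilcox.test's normal approximation", {
  set.seed(94)
  A <- matrix(rpois(60 * 25, 1.2), 60)
  B <- matrix(rpois(80 * 25, 1.6), 80)
  mine <- scgain:::wilcoxon_approx_p(A, B)
  ref <- vapply(1:25, function(j)
    suppressWarnings(wilcox.test(A[, j], B[, j], exact = FALSE,
                                 correct = TRUE)$p.value), numeric(1))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("identical groups yield p = 1 for every gene under wilcoxon", {
  fx <- dge_fixture()
  cells <- fx$norm$cells$cell_id
  # same distribution on both sides: copy the matrix rows into two aliases
  ds <- fx$ds
  dup <- ds
  dup$counts <- rbind(ds$counts, ds$counts)
  rownames(dup$counts) <- c(paste0(ds$cells$cell_id, "_a"),
                            paste0(ds$cells$cell_id, "_b"))
  dup$cells <- tibble::tibble(cell_id = rownames(dup$counts),
                              truth_label = rep(ds$cells$truth_label, 2))
  nm <- lognormalize(dup)
  res <- differential_expression(nm, paste0(ds$cells$cell_id, "_a"),
                                 paste0(ds$cells$cell_id, "_b"))
  expect_true(all(res$p_value > 0.999))
  expect_true(all(res$log2_fc == 0))
})

test_that("group preconditions are enforced", {
  fx <- dge_fixture()
  ids <- fx$norm$cells$cell_id
  expect_error(differential_expression(fx$norm, ids[1:5], ids[3:10]),
               "disjoint")
  expect_error(differential_expression(fx$norm, ids[1:2], ids[3:10]),
               "at least 3")
})

test_that("wilcoxon flags planted marker elevation with sensible fold changes", {
  fx <- dge_fixture()
  lab <- fx$norm$cells$truth_label
  srcc <- fx$norm$cells$cell_id[lab == "SRCC"]
  rest <- fx$norm$cells$cell_id[lab == "cancer_nonSRCC"]
  res <- differential_expression(fx$norm, srcc, rest)
  mk <- res[res$gene_id %in% c("SLC52A2", "NOTCH1"), ]
  expect_true(all(mk$adj_p < 0.05))
  expect_true(all(mk$log2_fc > 1))
  expect_true(all(res$adj_p >= res$p_value, na.rm = TRUE))
})

test_that("NB Wald recovers a true log fold change of 1 at n = 200 per group", {
  # DE genes kept a small share of the library so the size-factor offset is
  # not distorted by composition
  ds <- nb_sim_dataset(200, n_de = 30, n_null = 570, seed = 95)
  ids <- rownames(ds$counts)
  res <- differential_expression(ds, ids[1:200], ids[201:400],
                                 method = "nb_wald")
  expect_lt(abs(mean(res$beta[1:30]) - 1), 0.15)
  # null genes stay near zero, up to the small composition shift that a
  # total-count offset inherits from asymmetric DE
  expect_lt(abs(mean(res$beta[31:600])), 0.1)
})

test_that("NB Wald type-I error is calibrated on an all-null simulation", {
  ds <- nb_sim_dataset(100, n_de = 0, n_null = 500, seed = 96)
  ids <- rownames(ds$counts)
  res <- differential_expression(ds, ids[1:100], ids[101:200],
                                 method = "nb_wald")
  t1 <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gte(t1, 0.02)
  expect_lte(t1, 0.08)
})

test_that("zero-variance genes report p = 1 and fold change 0", {
  # equal cell totals so depth normalization keeps the constant gene constant
  counts <- cbind(rep(3L, 8),
                  c(rep(0L, 4), rep(6L, 4)),
                  c(rep(6L, 4), rep(0L, 4)))
  ds <- toy_dataset(counts)
  nm <- lognormalize(ds)
  ids <- ds$cells$cell_id
  res <- differential_expression(nm, ids[1:4], ids[5:8])
  expect_equal(res$p_value[1], 1)
  expect_equal(unname(res$log2_fc[1]), 0)
  expect_equal(res$direction[1], "none")
  expect_equal(res$direction[2:3], c("down", "up"))
})

test_that("hypergeometric overlap matches the closed form and direct PMF sums", {
  # universe 20, draw 5, set 4, overlap 3 -> 496/15504
  u <- sprintf("g%02d", 1:20)
  deg <- u[1:5]
  set <- c(u[1:3], u[20])
  res <- geneset_overlap(deg, set, u)
  expect_equal(res$n_overlap, 3)
  expect_equal(res$p_hyper, 496 / 15504, tolerance = 1e-12)
  expect_equal(round(res$p_hyper, 4), 0.032)
  # identical sets: overlap = |set|, minimal p
  res2 <- geneset_overlap(deg, deg, u)
  expect_equal(res2$n_overlap, 5)
  expect_equal(res2$p_hyper, 1 / choose(20, 5), tolerance = 1e-12)
  # disjoint sets: upper tail at k >= 0 is 1
  expect_equal(geneset_overlap(u[1:5], u[6:9], u)$p_hyper, 1)
  expect_error(geneset_overlap(deg, set, character(0)), "empty")
  expect_error(geneset_overlap(c(deg, "nope"), set, u), "subsets")
})

test_that("hypergeometric p equals direct PMF summation on random small instances", {
  set.seed(96)
  for (i in 1:25) {
    N <- sample(10:50, 1)
    u <- sprintf("u%03d", seq_len(N))
    k_set <- sample(2:(N - 2), 1)
    k_deg <- sample(2:(N - 2), 1)
    set <- sample(u, k_set); deg <- sample(u, k_deg)
    ov <- length(intersect(set, deg))
    direct <- sum(vapply(ov:min(k_set, k_deg), function(k)
      choose(k_set, k) * choose(N - k_set, k_deg - k) / choose(N, k_deg),
      numeric(1)))
    expect_equal(geneset_overlap(deg, set, u)$p_hyper, direct,
                 tolerance = 1e-10)
  }
})

test_that("marker positive fractions follow the counting rule", {
  counts <- matrix(0L, nrow = 15, ncol = 2,
                   dimnames = list(sprintf("c%02d", 1:15), c("CD82", "G")))
  counts[, "G"] <- 4L
  counts[1:8, "CD82"] <- 1L
  nm <- lognormalize(toy_dataset(counts))
  ids <- rownames(counts)
  expect_equal(marker_positive_fraction(nm, ids, "CD82"), 8 / 15)
  expect_equal(round(100 * marker_positive_fraction(nm, ids, "CD82"), 1),
               53.3)
  expect_equal(marker_positive_fraction(nm, ids, "G"), 1)
  expect_true(is.na(marker_positive_fraction(nm, character(0), "CD82")))
  # whole-dataset fraction equals the size-weighted mean of cluster fractions
  f1 <- marker_positive_fraction(nm, ids[1:5], "CD82")
  f2 <- marker_positive_fraction(nm, ids[6:15], "CD82")
  expect_equal((5 * f1 + 10 * f2) / 15,
               marker_positive_fraction(nm, ids, "CD82"))
  # an all-zero gene has fraction 0
  counts0 <- counts; counts0[, "CD82"] <- 0L
  nm0 <- lognormalize(toy_dataset(counts0))
  expect_equal(marker_positive_fraction(nm0, ids, "CD82"), 0)
})
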