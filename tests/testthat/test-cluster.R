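norm_fixture <- function(seed = 51, n_cells = 300, n_genes = 150) {
  ds <- simulate_dataset(small_config(n_cells = n_cells, n_genes = n_genes,
                                      seed = seed))
  lognormalize(filter_cells(ds, min_genes = 20))
}

test_that("input gain multiplies marker columns only and records metadata", {
  nm <- norm_fixture()
  before <- nm$values
  spec <- gain_spec(c("SLC52A2", "NOTCH1"), gain = 5)
  out <- apply_input_gain(nm, spec)
  midx <- match(c("SLC52A2", "NOTCH1"), nm$genes$gene_id)
  expect_equal(as.numeric(out$values[, midx]),
               5 * as.numeric(before[, midx]))
  expect_equal(out$values[, -midx], before[, -midx])
  expect_equal(out$gain$gain, 5)
  expect_true("gain" %in% out$stages)
  # worked example: {0, 1.2} -> {0, 6.0}
  v <- c(0, 1.2)
  expect_equal(v * 5, c(0, 6.0))
})

test_that("gain of 1 is the identity and gains compose to their product", {
  nm <- norm_fixture()
  out1 <- apply_input_gain(nm, gain_spec("SLC52A2", gain = 1))
  expect_equal(out1$values, nm$values)
  g <- 3.7
  once <- apply_input_gain(nm, gain_spec("SLC52A2", gain = g))
  # dividing the gained column by g restores the original to 1e-12
  midx <- match("SLC52A2", nm$genes$gene_id)
  expect_equal(as.numeric(once$values[, midx]) / g,
               as.numeric(nm$values[, midx]), tolerance = 1e-12)
})

test_that("a missing marker gene is reported by name", {
  nm <- norm_fixture()
  expect_error(apply_input_gain(nm, gain_spec(c("SLC52A2", "NOPE1"))),
               "NOPE1", class = "scgain_missing_marker")
  expect_error(marker_threshold_select(nm, "NOPE2"),
               class = "scgain_missing_marker")
})

test_that("gain_spec validates its arguments", {
  expect_error(gain_spec(character(0)), "non-empty")
  expect_error(gain_spec("g", gain = 0.5), ">= 1")
  expect_error(gain_spec("g", gain = Inf), "finite")
})

test_that("PCA scores match a dense SVD oracle after sign fixing", {
  set.seed(60)
  X <- matrix(rnorm(100 * 40), 100, 40)
  emb <- pca_embed(X, n_pcs = 5, seed = 1)
  sv <- svd(scale(X, scale = FALSE))
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  for (j in 1:5) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) oracle[, j] <- -oracle[, j]
  }
  expect_equal(unname(emb[, 1:5]), oracle, tolerance = 1e-6)
})

test_that("PCA on a rank-1 matrix concentrates variance in PC1 and is centered", {
  u <- rnorm(80); v <- rnorm(30)
  X <- outer(u, v)
  emb <- pca_embed(X, n_pcs = 3, seed = 2)
  sdev <- attr(emb, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.99999)
  expect_lt(max(abs(colMeans(emb))), 1e-8)
  expect_error(pca_embed(X, n_pcs = 31), "exceeds")
})

test_that("truncated and exact SVD agree on the same embedding", {
  set.seed(61)
  # low-rank structure plus noise, big enough to trigger the irlba path
  X <- matrix(rnorm(400 * 310), 400, 310) +
    outer(rnorm(400, sd = 4), rnorm(310))
  e1 <- pca_embed(X, n_pcs = 4, seed = 3)
  e2 <- pca_embed(X, n_pcs = 4, seed = 3, exact = TRUE)
  expect_equal(unname(e1[, 1]), unname(e2[, 1]), tolerance = 1e-8)
  # trailing PCs sit in a near-degenerate noise spectrum; compare loosely
  expect_equal(abs(unname(e1)), abs(unname(e2)), tolerance = 1e-3)
})

test_that("well-separated blobs are recovered exactly and deterministically", {
  set.seed(62)
  n <- 150
  emb <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2, mean = 30), n, 2))
  rownames(emb) <- sprintf("c%03d", seq_len(2 * n))
  truth <- rep(1:2, each = n)
  # modest resolution: modularity at 1.0 legitimately shatters diffuse
  # Gaussians into parts; blob recovery is a low-resolution regime
  lab <- cluster_cells(emb, k_neighbors = 15, resolution = 0.2, seed = 4)
  expect_equal(max(lab), 2)
  # ARI = 1 <=> label sets coincide up to renaming
  expect_true(all(table(lab, truth) %in% c(0L, n)))
  lab2 <- cluster_cells(emb, k_neighbors = 15, resolution = 0.2, seed = 4)
  expect_identical(lab, lab2)
})

test_that("vanishing resolution merges a connected graph into one cluster", {
  set.seed(63)
  emb <- matrix(rnorm(200 * 3), 200, 3)
  rownames(emb) <- sprintf("c%03d", 1:200)
  lab <- cluster_cells(emb, k_neighbors = 20, resolution = 1e-6, seed = 5)
  expect_equal(max(lab), 1)
})

test_that("labels partition the cells and k is lowered with a warning", {
  emb <- matrix(rnorm(10 * 2), 10, 2)
  rownames(emb) <- sprintf("c%02d", 1:10)
  expect_warning(lab <- cluster_cells(emb, k_neighbors = 20, seed = 6),
                 "lowering k")
  expect_length(lab, 10)
  expect_false(anyNA(lab))
})

test_that("marker threshold selection applies the all-markers rule", {
  counts <- matrix(0L, nrow = 10, ncol = 4,
                   dimnames = list(sprintf("c%02d", 1:10), NULL))
  colnames(counts) <- c("M1", "M2", "G1", "G2")
  counts[, "G1"] <- 5L               # keeps totals positive
  counts[1:3, "M1"] <- 1L; counts[1:3, "M2"] <- 1L   # double positive
  counts[4, "M1"] <- 5L              # M1 only
  counts[5, "M2"] <- 2L              # M2 only
  ds <- toy_dataset(counts)
  nm <- lognormalize(ds)
  sel <- marker_threshold_select(nm, c("M1", "M2"))
  expect_setequal(sel, sprintf("c%02d", 1:3))
})

test_that("marker cluster identification maximizes the double-positive fraction", {
  counts <- matrix(0L, nrow = 9, ncol = 3,
                   dimnames = list(sprintf("c%02d", 1:9),
                                   c("M1", "M2", "G1")))
  counts[, "G1"] <- 5L
  counts[1:3, c("M1", "M2")] <- 2L
  ds <- toy_dataset(counts)
  nm <- lognormalize(ds)
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
                     rownames(counts))
  id <- identify_marker_cluster(labels, nm, c("M1", "M2"))
  expect_equal(as.integer(id), 1L)
  # all clusters below the qualification floor -> NA
  counts0 <- counts; counts0[, c("M1", "M2")] <- 0L; counts0[, "G1"] <- 5L
  nm0 <- lognormalize(toy_dataset(counts0))
  expect_true(is.na(identify_marker_cluster(labels, nm0, c("M1", "M2"))))
})

test_that("marker cluster ties break by size then lower id", {
  counts <- matrix(0L, nrow = 10, ncol = 3,
                   dimnames = list(sprintf("c%02d", 1:10),
                                   c("M1", "M2", "G1")))
  counts[, "G1"] <- 5L
  counts[1:5, c("M1", "M2")] <- 2L   # cells 1:5 double-positive
  nm <- lognormalize(toy_dataset(counts))
  # cluster 1 = {1,2}, cluster 2 = {3,4,5} both at fraction 1 -> larger wins
  labels <- setNames(c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L),
                     rownames(counts))
  expect_equal(as.integer(identify_marker_cluster(labels, nm,
                                                  c("M1", "M2"))), 2L)
  # equal sizes at equal fraction -> lower id
  labels3 <- setNames(c(7L, 7L, 4L, 4L, 5L, 2L, 2L, 2L, 3L, 3L),
                      rownames(counts))
  # clusters 7 = {1,2} and 4 = {3,4} both size 2, fraction 1 -> id 4 wins
  expect_equal(as.integer(identify_marker_cluster(labels3, nm,
                                                  c("M1", "M2"))), 4L)
})

test_that("recovery metrics follow their definitions exactly", {
  m <- recovery_metrics(paste0("c", 1:10), paste0("c", 6:20), 100)
  expect_equal(m$recovery_fraction, 5 / 15)
  expect_equal(m$precision, 5 / 10)
  expect_equal(m$cluster_size, 10)
  expect_equal(m$population_fraction, 0.1)
  # identical sets
  m2 <- recovery_metrics(paste0("c", 1:7), paste0("c", 1:7), 50)
  expect_equal(m2$recovery_fraction, 1)
  expect_equal(m2$precision, 1)
  # disjoint sets; empty threshold set gives NA recovery
  expect_equal(recovery_metrics("a", "b", 10)$recovery_fraction, 0)
  expect_true(is.na(recovery_metrics("a", character(0), 10)$recovery_fraction))
})

test_that("a 285-cell cluster capturing 285 of 437 threshold cells recovers 65.2%", {
  threshold <- sprintf("cell%03d", 1:437)
  cluster <- threshold[1:285]
  m <- recovery_metrics(cluster, threshold, 208506)
  expect_equal(m$recovery_fraction, 285 / 437)
  expect_equal(round(100 * m$recovery_fraction, 1), 65.2)
})

test_that("UMAP layout is deterministic and two-dimensional", {
  skip_if_not_installed("uwot")
  set.seed(64)
  emb <- matrix(rnorm(120 * 5), 120, 5)
  rownames(emb) <- sprintf("c%03d", 1:120)
  u1 <- umap_embed(emb, seed = 7)
  u2 <- umap_embed(emb, seed = 7)
  expect_identical(u1, u2)
  expect_equal(dim(u1), c(120L, 2L))
})
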