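make_nm <- function(values, classes = NULL) {
  # wrap a plain matrix as a norm_matrix for unit tests
  classes <- classes %||% rep("t", ncol(values))
  structure(list(values = values,
                 norm_factors = setNames(rep(1, ncol(values)),
                                         colnames(values)),
                 lib_sizes = setNames(rep(1e6, ncol(values)),
                                      colnames(values)),
                 prior = 1,
                 sample_meta = tibble::tibble(sample_id = colnames(values),
                                              tissue_class = classes,
                                              replicate = "1")),
            class = "norm_matrix")
}

rand_nm <- function(n_genes, n_samples, seed, classes = NULL) {
  withr::with_seed(seed, {
    v <- matrix(abs(rnorm(n_genes * n_samples, 5, 2)), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    make_nm(v, classes)
  })
}

test_that("cv_filter matches direct sd/mean recomputation in both modes", {
  nm <- rand_nm(50, 8, seed = 21)
  cv_direct <- apply(nm$values, 1, sd) / rowMeans(nm$values)
  kept <- cv_filter(nm, "threshold", 0.3)
  expect_setequal(kept$gene_id, rownames(nm$values)[cv_direct > 0.3])
  kept_q <- cv_filter(nm, "quantile", 0.5)
  expect_setequal(kept_q$gene_id,
                  rownames(nm$values)[cv_direct > median(cv_direct)])
  # 10 strictly distinct CVs -> median split keeps exactly 5
  nm10 <- rand_nm(10, 6, seed = 22)
  expect_identical(nrow(cv_filter(nm10, "quantile", 0.5)), 5L)
})

test_that("cv_filter excludes flat genes, rejects bad quantiles, ignores global rescaling", {
  nm <- rand_nm(30, 6, seed = 23)
  nm$values["g001", ] <- 4  # CV = 0
  expect_false("g001" %in% cv_filter(nm, "threshold", 0.85)$gene_id)
  expect_error(cv_filter(nm, "quantile", 1.5), "\\[0, 1\\]")
  nm_scaled <- nm
  nm_scaled$values <- nm$values * 7
  expect_identical(cv_filter(nm, "threshold", 0.3)$gene_id,
                   cv_filter(nm_scaled, "threshold", 0.3)$gene_id)
})

test_that("scale_genes z-scores rows and collapses replicates correctly", {
  v <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  sm <- scale_genes(make_nm(v), by = "sample")
  expect_equal(unname(sm$values[1, ]), c(-1, 0, 1))

  # equal replicates: tissue_mean path equals scaling the collapsed matrix
  v2 <- withr::with_seed(4, matrix(rnorm(40, 5), 10, 4,
                                   dimnames = list(sprintf("g%02d", 1:10),
                                                   c("a1", "a2", "b1", "b2"))))
  v2[, "a2"] <- v2[, "a1"]
  v2[, "b2"] <- v2[, "b1"]
  nm2 <- make_nm(v2, classes = c("A", "A", "B", "B"))
  sm_t <- scale_genes(nm2, by = "tissue_mean")
  collapsed <- v2[, c("a1", "b1")]
  colnames(collapsed) <- c("A", "B")
  sm_direct <- scale_genes(make_nm(collapsed, classes = c("A", "B")),
                           by = "sample")
  expect_equal(sm_t$values, sm_direct$values)
})

test_that("scale_genes drops zero-variance genes and output rows are z-scores", {
  nm <- rand_nm(20, 5, seed = 25)
  nm$values["g020", ] <- 2
  expect_message(sm <- scale_genes(nm, by = "sample"), "zero-variance")
  expect_false("g020" %in% rownames(sm$values))
  expect_true(all(abs(rowMeans(sm$values)) < 1e-9))
  expect_true(all(abs(apply(sm$values, 1, sd) - 1) < 1e-9))
})

test_that("pca_genes agrees with an SVD of the centered matrix up to sign", {
  sm <- suppressMessages(scale_genes(rand_nm(30, 5, seed = 26), by = "sample"))
  p <- pca_genes(sm)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  centered <- scale(sm$values, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  for (j in seq_len(ncol(p$scores))) {
    ours <- p$scores[, j]
    svd_scores <- sv$u[, j] * sv$d[j]
    expect_true(max(abs(ours - svd_scores)) < 1e-8 ||
                  max(abs(ours + svd_scores)) < 1e-8)
  }
  # reconstruction: scores %*% t(loadings) recovers the centered data
  expect_equal(p$scores %*% t(p$loadings), unclass(centered),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("pca_genes handles rank-1 input and rejects degenerate input", {
  v <- withr::with_seed(8, {
    base <- rnorm(20)
    matrix(c(base, 2 * base), 20, 2,
           dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  })
  p <- pca_genes(structure(list(values = v, columns = c("a", "b"),
                                by = "sample"), class = "scaled_matrix"))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-9)
  flat <- matrix(3, 5, 3, dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_error(
    pca_genes(structure(list(values = flat, columns = colnames(flat),
                             by = "sample"), class = "scaled_matrix")),
    "degenerate")
})

test_that("classical_mds preserves Euclidean geometry", {
  # equilateral triangle, side 1
  d <- matrix(1, 3, 3) - diag(3)
  xy <- classical_mds(d, k = 2)
  rec <- as.matrix(dist(xy[, c("MDS1", "MDS2")]))
  expect_equal(unname(rec[upper.tri(rec)]), rep(1, 3), tolerance = 1e-6)

  pts <- withr::with_seed(12, matrix(rnorm(24), 8, 3))
  rownames(pts) <- paste0("p", 1:8)
  out <- classical_mds(pts, k = 3)
  expect_equal(unname(as.matrix(dist(out[, -1]))),
               unname(as.matrix(dist(pts))), tolerance = 1e-6)

  # identical points land on identical coordinates
  two <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 7))
  xy2 <- classical_mds(two, k = 1)
  expect_equal(xy2$MDS1[1], xy2$MDS1[2], tolerance = 1e-9)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(asym), "symmetric")
})

test_that("classical MDS on centered data reproduces PCA scores up to sign", {
  sm <- suppressMessages(scale_genes(rand_nm(25, 4, seed = 30), by = "sample"))
  p <- pca_genes(sm)
  centered <- scale(sm$values, center = TRUE, scale = FALSE)
  xy <- classical_mds(centered, k = 3)
  for (j in 1:3) {
    a <- p$scores[, j]
    b <- xy[[paste0("MDS", j)]]
    expect_true(max(abs(a - b)) < 1e-6 || max(abs(a + b)) < 1e-6)
  }
})
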