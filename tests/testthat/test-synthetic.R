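test_that("simulate_tissue_counts is seed-deterministic with valid structure", {
  s1 <- simulate_tissue_counts(n_genes = 100, reps = 2, seed = 5)
  s2 <- simulate_tissue_counts(n_genes = 100, reps = 2, seed = 5)
  expect_identical(s1$counts$counts, s2$counts$counts)
  s3 <- simulate_tissue_counts(n_genes = 100, reps = 2, seed = 6)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
  expect_identical(dim(s1$counts$counts), c(100L, 12L))
  expect_identical(sum(!is.na(s1$truth$cluster)), 100L)
  expect_error(simulate_tissue_counts(dispersion = 0), "positive")
  expect_error(simulate_tissue_counts(n_genes = 10,
                                      clusters = list(list(size = 20,
                                                           up_tissues = "stem",
                                                           fold = 2))),
               "exceed")
})

test_that("planted fold changes appear in per-tissue means (NB moment check)", {
  sim <- simulate_tissue_counts(
    n_genes = 60, reps = 50,
    clusters = list(list(size = 30,
                         up_tissues = c("prehaustoria", "haustoria"),
                         fold = 6)),
    dispersion = 0.05, depth_sdlog = 0, seed = 42)
  cm <- sim$counts
  planted <- sim$truth$gene_id[!is.na(sim$truth$cluster)]
  up <- cm$sample_meta$sample_id[cm$sample_meta$tissue_class %in%
                                   c("prehaustoria", "haustoria")]
  down <- setdiff(cm$sample_meta$sample_id, up)
  ratio <- rowMeans(cm$counts[planted, up]) /
    rowMeans(cm$counts[planted, down])
  # mean fold ratio concentrates near 6 over 30 genes x 100/200 samples
  expect_equal(mean(ratio), 6, tolerance = 0.15)
  bg <- sim$truth$gene_id[is.na(sim$truth$cluster)]
  ratio_bg <- rowMeans(cm$counts[bg, up]) / rowMeans(cm$counts[bg, down])
  expect_equal(mean(ratio_bg), 1, tolerance = 0.1)
  # fold = 1 removes all planted structure in expectation
  null_sim <- simulate_tissue_counts(
    n_genes = 60, reps = 50,
    clusters = list(list(size = 30, up_tissues = "stem", fold = 1)),
    dispersion = 0.05, depth_sdlog = 0, seed = 43)
  s <- null_sim$counts$sample_meta$sample_id[
    null_sim$counts$sample_meta$tissue_class == "stem"]
  o <- setdiff(colnames(null_sim$counts$counts), s)
  r0 <- rowMeans(null_sim$counts$counts[, s]) /
    rowMeans(null_sim$counts$counts[, o])
  expect_equal(mean(r0), 1, tolerance = 0.1)
})

test_that("module expression has the factor-model correlation structure", {
  # noise_sd = 0: within-module |r| = 1 exactly
  pure <- simulate_module_expression(n_genes = 20,
                                     modules = list(list(size = 10)),
                                     n_samples = 12, noise_sd = 0, seed = 9)
  rr <- cor(t(pure$values[1:10, ]))
  expect_equal(unname(abs(rr)), matrix(1, 10, 10), tolerance = 1e-12)

  sim <- simulate_module_expression(
    n_genes = 120,
    modules = list(list(size = 40, hub_loading = 1, member_loading = 0.6),
                   list(size = 40, hub_loading = 1, member_loading = 0.6)),
    n_samples = 200, noise_sd = 0.5, seed = 10)
  r <- cor(t(sim$values))
  m1 <- sim$truth$gene_id[which(sim$truth$module == 1)]
  m2 <- sim$truth$gene_id[which(sim$truth$module == 2)]
  cross <- r[m1, m2]
  expect_lt(mean(abs(cross)), 0.15)
  # hub-member correlation matches the closed form of the factor model
  hub <- sim$truth$gene_id[sim$truth$is_hub & sim$truth$module == 1]
  members <- setdiff(m1, hub)
  expected_r <- (1 * 0.6) / sqrt((1 + 0.25) * (0.36 + 0.25))
  expect_lt(abs(mean(r[hub, members]) - expected_r), 0.05)
  expect_error(simulate_module_expression(n_genes = 5,
                                          modules = list(list(size = 10))),
               "exceed")
  expect_error(simulate_module_expression(
    modules = list(list(size = 10, member_loading = 1.7))), "loadings")
})

test_that("planted_partition_graph has the expected block structure", {
  g <- planted_partition_graph(3, 5, p_in = 1, p_out = 0, seed = 1)
  expect_equal(nrow(g$net$edges), 3 * choose(5, 2))
  part <- fast_greedy_partition(g$net)
  expect_equal(adjusted_rand_index(part$membership[names(g$labels)],
                                   g$labels), 1)
  # expected edge counts within binomial noise over seeds
  counts <- vapply(1:20, function(s) {
    nrow(planted_partition_graph(3, 10, 0.4, 0.05, seed = s)$net$edges)
  }, numeric(1))
  n_in <- 3 * choose(10, 2); n_out <- choose(3, 2) * 100
  expected <- n_in * 0.4 + n_out * 0.05
  sd_edges <- sqrt(n_in * 0.4 * 0.6 + n_out * 0.05 * 0.95)
  expect_lt(abs(mean(counts) - expected), 3 * sd_edges / sqrt(20))
  expect_identical(planted_partition_graph(2, 4, 0.5, 0.1, seed = 3)$net$edges,
                   planted_partition_graph(2, 4, 0.5, 0.1, seed = 3)$net$edges)
  expect_error(planted_partition_graph(2, 4, 0.5, 0.6, seed = 1), "p_out")
})

test_that("adjusted_rand_index agrees with mclust and has its fixed points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    lab <- withr::with_seed(s, list(a = sample(1:3, 30, TRUE),
                                    b = sample(1:4, 30, TRUE)))
    expect_equal(adjusted_rand_index(lab$a, lab$b),
                 mclust::adjustedRandIndex(lab$a, lab$b), tolerance = 1e-12)
  }
})
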