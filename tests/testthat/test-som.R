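as_sm <- function(values) {
  structure(list(values = values, columns = colnames(values), by = "sample"),
            class = "scaled_matrix")
}

test_that("a 1x1 SOM tracks the data mean", {
  pts <- matrix(c(0, 0, 3, 0, 0, 3), 3, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  fit <- som_train(as_sm(pts), rows = 1, cols = 1, epochs = 500,
                   alpha = c(0.05, 0.0001), seed = 1)
  expect_true(all(fit$assignment == 1L))
  expect_equal(unname(fit$codebook[1, ]), unname(colMeans(pts)),
               tolerance = 1e-2)
  # quantization error does not increase over training
  expect_lte(fit$trace[length(fit$trace)], fit$trace[1])
})

test_that("SOM recovers two well-separated clusters exactly (ARI = 1)", {
  sep <- withr::with_seed(2, {
    a <- matrix(rnorm(40 * 4, 0, 1), 40, 4)
    b <- matrix(rnorm(40 * 4, 10, 1), 40, 4)
    x <- rbind(a, b)
    dimnames(x) <- list(sprintf("g%02d", 1:80), paste0("s", 1:4))
    x
  })
  truth <- rep(1:2, each = 40)
  fit <- som_train(as_sm(sep), rows = 2, cols = 1, epochs = 50, seed = 7)
  expect_equal(adjusted_rand_index(fit$assignment, truth), 1)
})

test_that("every gene is assigned to its nearest codebook vector", {
  sm <- as_sm(withr::with_seed(3, matrix(rnorm(200), 50, 4,
                                         dimnames = list(sprintf("g%02d", 1:50),
                                                         paste0("s", 1:4)))))
  fit <- som_train(sm, rows = 2, cols = 3, epochs = 20, seed = 5)
  d <- as.matrix(dist(rbind(sm$values, fit$codebook)))
  d <- d[seq_len(50), 50 + seq_len(6), drop = FALSE]
  expect_identical(unname(fit$assignment), unname(apply(d, 1, which.min)))
  expect_equal(unname(fit$distance_to_bmu),
               unname(d[cbind(1:50, fit$assignment)]), tolerance = 1e-9)
})

test_that("same seed gives bit-identical fits; unit count and errors behave", {
  sm <- as_sm(withr::with_seed(4, matrix(rnorm(120), 30, 4,
                                         dimnames = list(sprintf("g%02d", 1:30),
                                                         paste0("s", 1:4)))))
  f1 <- som_train(sm, rows = 2, cols = 3, epochs = 15, seed = 9)
  f2 <- som_train(sm, rows = 2, cols = 3, epochs = 15, seed = 9)
  expect_identical(f1, f2)
  f3 <- som_train(sm, rows = 2, cols = 3, epochs = 15, seed = 10)
  expect_false(identical(f1$codebook, f3$codebook))
  expect_error(som_train(sm, rows = 10, cols = 10, epochs = 5, seed = 1),
               "smaller grid")
})

test_that("som_summarize equals brute-force group-by and conserves gene counts", {
  sm <- as_sm(withr::with_seed(6, matrix(rnorm(80), 20, 4,
                                         dimnames = list(sprintf("g%02d", 1:20),
                                                         c("t1", "t2", "t3", "t4")))))
  fit <- som_train(sm, rows = 2, cols = 2, epochs = 20, seed = 2)
  summ <- som_summarize(fit, sm)
  expect_identical(sum(summ$n_genes[!duplicated(summ$unit)]), 20L)
  for (u in unique(fit$assignment)) {
    members <- names(fit$assignment)[fit$assignment == u]
    for (cl in colnames(sm$values)) {
      expect_equal(
        summ$mean_scaled[summ$unit == u & summ$column == cl],
        mean(sm$values[members, cl]), tolerance = 1e-12)
    }
  }
  # a unit with exactly one gene reports that gene's profile
  singles <- names(which(table(fit$assignment) == 1))
  if (length(singles) > 0) {
    u <- as.integer(singles[1])
    g <- names(fit$assignment)[fit$assignment == u]
    expect_equal(summ$mean_scaled[summ$unit == u],
                 unname(sm$values[g, ]), tolerance = 1e-12)
  }
})

test_that("select_som_clusters is a direct assignment lookup", {
  sm <- as_sm(withr::with_seed(8, matrix(rnorm(80), 20, 4,
                                         dimnames = list(sprintf("g%02d", 1:20),
                                                         paste0("s", 1:4)))))
  fit <- som_train(sm, rows = 2, cols = 2, epochs = 10, seed = 3)
  expect_identical(select_som_clusters(fit, 1:4), names(fit$assignment))
  expect_identical(select_som_clusters(fit, integer(0)), character(0))
  u <- fit$assignment[["g05"]]
  expect_true("g05" %in% select_som_clusters(fit, u))
  expect_identical(select_som_clusters(fit, u),
                   names(fit$assignment)[fit$assignment == u])
  expect_error(select_som_clusters(fit, 9), "unknown unit")
})

test_that("planted tissue clusters concentrate in single SOM units over seeds", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_tissue_counts(
      n_genes = 300, reps = 3,
      clusters = list(list(size = 60,
                           up_tissues = c("prehaustoria", "haustoria"),
                           fold = 6)),
      dispersion = 0.1, seed = 400 + s)
    nm <- suppressMessages(tmm_normalize(sim$counts))
    sm <- suppressMessages(scale_genes(nm, by = "tissue_mean"))
    fit <- som_train(sm, rows = 2, cols = 6, epochs = 40, seed = s)
    planted <- sim$truth$gene_id[!is.na(sim$truth$cluster)]
    planted <- intersect(planted, names(fit$assignment))
    max(table(fit$assignment[planted])) / length(planted)
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})
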