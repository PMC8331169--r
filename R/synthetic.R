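#' Simulate multi-tissue RNA-seq counts with planted expression clusters
#'
#' Generates a negative-binomial count matrix emulating a multi-tissue bulk
#' RNA-seq design: six tissue classes by default (seed, seedling, stem,
#' prehaustoria, haustoria, flower) with replicates. Each gene draws a base
#' mean from a log-normal (meanlog 5, sdlog 1, so a median around 150
#' counts); genes belonging to a planted cluster have their mean multiplied
#' by `fold` in that cluster's up-regulated tissues — e.g. a cluster up in
#' both prehaustoria and haustoria mimics the invasive-tissue expression
#' pattern that the SOM9 unit captures. Counts are drawn NB with variance
#' mu + dispersion * mu^2, and each sample gets a log-normal(0, 0.2) depth
#' factor so the TMM stage has library-size signal to estimate.
#'
#' @param n_genes total genes.
#' @param tissue_classes character vector of tissue labels.
#' @param reps replicates per tissue class.
#' @param clusters list of planted clusters, each
#'   `list(size =, up_tissues =, fold =)` with `fold >= 1`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); must
#'   be positive.
#' @param base_meanlog,base_sdlog log-normal parameters of gene base means.
#' @param depth_sdlog sd of the per-sample log-normal depth factor.
#' @param seed integer seed; same seed and parameters give identical output.
#' @return list with `counts` (a [count_matrix()]) and `truth` (a tibble
#'   `gene_id`, `cluster` with `NA` for background genes) plus `params`.
#' @export
simulate_tissue_counts <- function(n_genes = 2000,
                                   tissue_classes = c("seed", "seedling",
                                                      "stem", "prehaustoria",
                                                      "haustoria", "flower"),
                                   reps = 3,
                                   clusters = list(list(size = 100,
                                                        up_tissues = c("prehaustoria",
                                                                       "haustoria"),
                                                        fold = 6)),
                                   dispersion = 0.1,
                                   base_meanlog = 5, base_sdlog = 1,
                                   depth_sdlog = 0.2,
                                   seed = 1) {
  if (dispersion <= 0) abort("dispersion must be positive")
  sizes <- vapply(clusters, function(cl) cl$size, numeric(1))
  if (sum(sizes) > n_genes) abort("cluster sizes exceed n_genes")
  for (cl in clusters) {
    if (cl$fold < 1) abort("cluster fold must be >= 1")
    if (!all(cl$up_tissues %in% tissue_classes)) {
      abort("cluster up_tissues must be tissue classes")
    }
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_meta <- tibble(
    sample_id = paste0(rep(tissue_classes, each = reps), "_r",
                       rep(seq_len(reps), length(tissue_classes))),
    tissue_class = rep(tissue_classes, each = reps),
    replicate = as.character(rep(seq_len(reps), length(tissue_classes)))
  )
  cluster_lab <- rep(NA_integer_, n_genes)
  at <- 1
  for (ci in seq_along(clusters)) {
    cluster_lab[at:(at + clusters[[ci]]$size - 1)] <- ci
    at <- at + clusters[[ci]]$size
  }
  counts <- with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, meanlog = base_meanlog,
                             sdlog = base_sdlog)
    depth <- stats::rlnorm(nrow(sample_meta), meanlog = 0,
                           sdlog = depth_sdlog)
    mu <- matrix(base_mu, n_genes, nrow(sample_meta))
    for (ci in seq_along(clusters)) {
      g <- which(cluster_lab == ci)
      s <- which(sample_meta$tissue_class %in% clusters[[ci]]$up_tissues)
      mu[g, s] <- mu[g, s] * clusters[[ci]]$fold
    }
    mu <- sweep(mu, 2, depth, "*")
    mat <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                  n_genes, nrow(sample_meta))
    dimnames(mat) <- list(gene_ids, sample_meta$sample_id)
    mat
  })
  list(
    counts = count_matrix(counts, sample_meta),
    truth = tibble(gene_id = gene_ids, cluster = cluster_lab),
    params = list(n_genes = n_genes, tissue_classes = tissue_classes,
                  reps = reps, clusters = clusters, dispersion = dispersion,
                  base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                  depth_sdlog = depth_sdlog, seed = seed)
  )
}

#' Simulate latent-factor coexpression modules with designated hubs
#'
#' Emulates hub-centered coexpression structure: each module has one latent
#' sample profile drawn standard normal; a member gene's value is
#' `loading * latent + noise_sd * N(0, 1)`, with the module's designated hub
#' carrying `hub_loading` (default 1.0) and ordinary members
#' `member_loading` (default 0.6), so hub-member correlations exceed
#' member-member correlations and the hub emerges as the most connected node
#' after thresholding. The hub is the first gene of each module and is
#' flagged as a transcription factor in the truth table. Background genes are
#' independent standard normal noise.
#'
#' @param n_genes total genes.
#' @param modules list of `list(size =, hub_loading = 1.0,
#'   member_loading = 0.6)`.
#' @param n_samples number of expression columns.
#' @param noise_sd sd of the additive gene-specific noise.
#' @param seed integer seed.
#' @return list with `values` (genes x samples matrix), `truth` (tibble
#'   `gene_id`, `module`, `is_hub`), `params`.
#' @export
simulate_module_expression <- function(n_genes = 300,
                                       modules = list(
                                         list(size = 30, hub_loading = 1.0,
                                              member_loading = 0.6),
                                         list(size = 30, hub_loading = 1.0,
                                              member_loading = 0.6),
                                         list(size = 30, hub_loading = 1.0,
                                              member_loading = 0.6)),
                                       n_samples = 18, noise_sd = 0.5,
                                       seed = 1) {
  sizes <- vapply(modules, function(m) m$size, numeric(1))
  if (sum(sizes) > n_genes) abort("module sizes exceed n_genes")
  for (m in modules) {
    hl <- m$hub_loading %||% 1.0
    ml <- m$member_loading %||% 0.6
    if (hl <= 0 || hl > 1 || ml <= 0 || ml > 1) {
      abort("loadings must be in (0, 1]")
    }
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  module_lab <- rep(NA_integer_, n_genes)
  is_hub <- rep(FALSE, n_genes)
  at <- 1
  for (mi in seq_along(modules)) {
    module_lab[at:(at + modules[[mi]]$size - 1)] <- mi
    is_hub[at] <- TRUE
    at <- at + modules[[mi]]$size
  }
  values <- with_seed(seed, {
    mat <- matrix(0, n_genes, n_samples)
    latent <- matrix(stats::rnorm(length(modules) * n_samples),
                     length(modules), n_samples)
    for (g in seq_len(n_genes)) {
      if (is.na(module_lab[g])) {
        mat[g, ] <- stats::rnorm(n_samples)
      } else {
        m <- modules[[module_lab[g]]]
        loading <- if (is_hub[g]) m$hub_loading %||% 1.0 else
          m$member_loading %||% 0.6
        mat[g, ] <- loading * latent[module_lab[g], ] +
          noise_sd * stats::rnorm(n_samples)
      }
    }
    dimnames(mat) <- list(gene_ids, sprintf("s%02d", seq_len(n_samples)))
    mat
  })
  list(
    values = values,
    truth = tibble(gene_id = gene_ids, module = module_lab, is_hub = is_hub),
    params = list(n_genes = n_genes, modules = modules,
                  n_samples = n_samples, noise_sd = noise_sd, seed = seed)
  )
}

#' Planted-partition benchmark graph
#'
#' k blocks of equal size with independent Bernoulli edges: probability
#' `p_in` within a block, `p_out` between blocks. The standard benchmark for
#' community-detection recovery.
#'
#' @param k number of blocks.
#' @param size nodes per block.
#' @param p_in,p_out within/between edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return list with `net` (a `gcn`) and `labels` (named integer vector).
#' @export
planted_partition_graph <- function(k, size, p_in, p_out, seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1")
  }
  n <- k * size
  nodes <- sprintf("v%03d", seq_len(n))
  labels <- stats::setNames(rep(seq_len(k), each = size), nodes)
  edges <- with_seed(seed, {
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- labels[pair[, 1]] == labels[pair[, 2]]
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(nrow(pair)) < p
    tibble(from = nodes[pair[keep, 1]], to = nodes[pair[keep, 2]], weight = 1)
  })
  list(net = gcn_graph(nodes, edges), labels = labels)
}
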