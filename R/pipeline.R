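#' Assemble a pipeline configuration
#'
#' Collects every knob of the analysis in one validated list. Paths may be
#' `NULL` when the corresponding stage is skipped (no annotation, no
#' enrichment) or when a count matrix is passed to [run_pipeline()] directly.
#'
#' @param counts_path,meta_path input TSVs for [read_counts()].
#' @param cv_mode,cv_value coefficient-of-variation filter settings
#'   (see [cv_filter()]).
#' @param scale_by column collapsing before scaling (see [scale_genes()]).
#' @param som_rows,som_cols,som_epochs,som_alpha,som_seed SOM settings.
#' @param selected_units SOM units whose genes enter the network; `NULL`
#'   means all units.
#' @param gcn_method,gcn_q network threshold settings (see [build_gcn()]).
#' @param focal_gene optional focal gene for the neighborhood report.
#' @param blast_path,tf_ids,evalue_max annotation settings; optional.
#' @param gene2term_path GMT-style term mapping for enrichment; optional.
#' @param outdir output directory (created if absent).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, meta_path = NULL,
                            cv_mode = "threshold", cv_value = 0.85,
                            scale_by = "tissue_mean",
                            som_rows = 2, som_cols = 6, som_epochs = 100,
                            som_alpha = c(0.05, 0.01), som_seed = 1,
                            selected_units = NULL,
                            gcn_method = "normal", gcn_q = 0.93,
                            focal_gene = NULL,
                            blast_path = NULL, tf_ids = character(),
                            evalue_max = 1e-5,
                            gene2term_path = NULL,
                            outdir = tempfile("somgcn_run_")) {
  for (p in c(counts_path, meta_path, blast_path, gene2term_path)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("path not found: %s", p))
  }
  structure(list(counts_path = counts_path, meta_path = meta_path,
                 cv_mode = cv_mode, cv_value = cv_value, scale_by = scale_by,
                 som_rows = som_rows, som_cols = som_cols,
                 som_epochs = som_epochs, som_alpha = som_alpha,
                 som_seed = som_seed, selected_units = selected_units,
                 gcn_method = gcn_method, gcn_q = gcn_q,
                 focal_gene = focal_gene, blast_path = blast_path,
                 tf_ids = tf_ids, evalue_max = evalue_max,
                 gene2term_path = gene2term_path, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full hub-discovery pipeline
#'
#' Executes every stage in order — TMM normalization, CV filtering, PCA and
#' MDS, SOM clustering with per-unit summary, unit selection, coexpression
#' network construction, fast-greedy module partition, centrality, hub
#' ranking, the focal gene's neighborhood layers, and per-module term
#' enrichment when a mapping is supplied — writing each result as a TSV under
#' `cfg$outdir` and returning a manifest of file hashes and parameters.
#' Reruns with identical inputs and seeds produce byte-identical artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param cm optional [count_matrix()] to use instead of reading
#'   `cfg$counts_path`.
#' @return (invisibly) a list with the fitted objects and `manifest`, a
#'   tibble of artifact paths and MD5 hashes.
#' @export
run_pipeline <- function(cfg, cm = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$outdir, name)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  if (is.null(cm)) {
    if (is.null(cfg$counts_path)) abort("no counts: give counts_path or cm")
    cm <- stage("read_counts", read_counts(cfg$counts_path, cfg$meta_path))
  }
  nm <- stage("normalize", tmm_normalize(cm))
  norm_tab <- as_tibble(nm$values, rownames = "gene_id")
  readr::write_tsv(norm_tab, out("normalized_log_cpm.tsv"), progress = FALSE)

  cvk <- stage("cv_filter", cv_filter(nm, mode = cfg$cv_mode,
                                      value = cfg$cv_value))
  readr::write_tsv(cvk, out("cv_filtered_genes.tsv"), progress = FALSE)

  sm <- stage("scale", scale_genes(nm, by = cfg$scale_by,
                                   genes = cvk$gene_id))
  pca <- stage("pca", pca_genes(sm))
  readr::write_tsv(tidy(pca, "scores"), out("pca_scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(pca, "loadings"), out("pca_loadings.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(pca, "eigenvalues"), out("pca_variance.tsv"),
                   progress = FALSE)
  mds <- stage("mds", classical_mds(t(nm$values), k = 2))
  readr::write_tsv(mds, out("mds_samples.tsv"), progress = FALSE)

  fit <- stage("som", som_train(sm, rows = cfg$som_rows, cols = cfg$som_cols,
                                epochs = cfg$som_epochs,
                                alpha = cfg$som_alpha, seed = cfg$som_seed))
  readr::write_tsv(tidy(fit), out("som_assignment.tsv"), progress = FALSE)
  readr::write_tsv(som_summarize(fit, sm), out("som_summary.tsv"),
                   progress = FALSE)

  units <- cfg$selected_units %||% seq_len(cfg$som_rows * cfg$som_cols)
  genes <- stage("select_units", select_som_clusters(fit, units))
  corr <- stage("correlate", pearson_matrix(sm, genes = genes))
  net <- stage("network", build_gcn(corr, q = cfg$gcn_q,
                                    method = cfg$gcn_method))
  write_edge_table(net, out("gcn_edges.tsv"))

  part <- stage("modules", fast_greedy_partition(net))
  readr::write_tsv(tidy(part), out("modules.tsv"), progress = FALSE)
  ct <- stage("centrality", centrality_scores(net))
  readr::write_tsv(ct, out("centrality.tsv"), progress = FALSE)

  ann <- NULL
  if (!is.null(cfg$blast_path)) {
    ann <- stage("annotation",
                 merge_annotation(cfg$blast_path, genes = cm |>
                                    (\(x) rownames(x$counts))(),
                                  evalue_max = cfg$evalue_max,
                                  tf_ids = cfg$tf_ids))
  } else if (length(cfg$tf_ids) > 0) {
    ann <- tibble(gene_id = rownames(cm$counts),
                  is_tf = rownames(cm$counts) %in% cfg$tf_ids)
  }
  hubs <- stage("hubs", hub_ranking(ct, ann = ann, tf_only = FALSE))
  readr::write_tsv(hubs, out("hub_ranking.tsv"), progress = FALSE)

  node_attrs <- tidy(part) |>
    left_join(ct, by = "gene_id") |>
    left_join(tidy(fit)[, c("gene_id", "unit")], by = "gene_id")
  if (!is.null(ann)) {
    node_attrs <- left_join(node_attrs,
                            ann[, intersect(c("gene_id", "is_tf",
                                              "description"), names(ann))],
                            by = "gene_id")
  }
  write_node_table(net, out("gcn_nodes.tsv"), node_attrs = node_attrs)

  layers <- NULL
  if (!is.null(cfg$focal_gene)) {
    layers <- stage("ego", ego_layers(net, cfg$focal_gene))
    readr::write_tsv(tidy(layers), out("focal_layers.tsv"), progress = FALSE)
    readr::write_tsv(
      tibble(focal = layers$focal,
             n_first_layer = length(layers$first_layer),
             n_second_layer = length(layers$second_layer),
             n_outside = length(layers$outside)),
      out("focal_layer_counts.tsv"), progress = FALSE)
  }

  enr <- NULL
  if (!is.null(cfg$gene2term_path)) {
    g2t <- read_gmt(cfg$gene2term_path)
    universe <- net$nodes
    enr <- stage("enrichment", {
      tidy(part) |>
        group_by(.data$module) |>
        dplyr::group_modify(function(d, key) {
          enrich_terms(intersect(d$gene_id, universe), universe, g2t)
        }) |>
        ungroup()
    })
    readr::write_tsv(enr, out("module_enrichment.tsv"), progress = FALSE)
  }

  files <- list.files(cfg$outdir, full.names = TRUE)
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    som_seed = cfg$som_seed, gcn_q = cfg$gcn_q, gcn_method = cfg$gcn_method
  )
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)
  invisible(list(counts = cm, normalized = nm, cv = cvk, scaled = sm,
                 pca = pca, mds = mds, som = fit, network = net,
                 partition = part, centrality = ct, hubs = hubs,
                 layers = layers, enrichment = enr, manifest = manifest))
}
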