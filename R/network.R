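#' Pairwise gene correlation matrix
#'
#' Correlations between gene expression profiles across the columns of a
#' scaled (or any numeric) matrix. Pearson on log-CPM z-scores is the default
#' metric for network construction; Spearman is available.
#'
#' @param sm a `scaled_matrix`, or a numeric genes-x-columns matrix with
#'   rownames.
#' @param genes optional gene ids to restrict to.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(sm, genes = NULL,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- if (inherits(sm, "scaled_matrix")) sm$values else as.matrix(sm)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing) > 0) {
      abort(sprintf("genes not in matrix: %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    x <- x[genes, , drop = FALSE]
  }
  if (ncol(x) < 3) abort("need at least 3 columns to correlate profiles")
  r <- stats::cor(t(x), method = method)
  diag(r) <- 1
  r
}

#' Build a correlation-thresholded gene coexpression network
#'
#' Converts a gene correlation matrix into an undirected network keeping only
#' the most-correlated pairs. With `method = "normal"` (the quantile-cutoff
#' rule used for all networks here, e.g. q = 0.93 for the SOM9 network and
#' q = 0.94 for the SOM2+3+9 and microdissection networks), the off-diagonal
#' upper-triangle correlations are Fisher-transformed (z = atanh r), a normal
#' is fit by their mean and standard deviation, and pairs with
#' z > mean + qnorm(q) * sd become edges. With `method = "empirical"` the
#' top `1 - q` fraction of pairs by correlation is retained (the realized
#' cutoff reported is the smallest kept correlation).
#' Edge weight is the raw correlation; every node of the input matrix is
#' retained even if isolated. Pairs with r = 1 (infinite z) are excluded from
#' the normal fit but always exceed a finite cutoff and so are kept as edges.
#'
#' @param corr symmetric correlation matrix from [pearson_matrix()].
#' @param q quantile in (0, 1).
#' @param method `"normal"` (default) or `"empirical"`.
#' @return an object of class `gcn`: `nodes`, `edges` (tibble `from`, `to`,
#'   `weight` with `from < to`), `threshold` record (method, q, realized
#'   cutoff on the r scale, candidate-pair and edge counts).
#' @export
build_gcn <- function(corr, q, method = c("normal", "empirical")) {
  method <- match.arg(method)
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)")
  corr <- as.matrix(corr)
  nodes <- rownames(corr)
  n <- nrow(corr)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  if (method == "normal") {
    z <- atanh(pmin(pmax(r, -1), 1))
    zf <- z[is.finite(z)]
    if (length(zf) < 2 || stats::sd(zf) == 0) {
      abort("correlations are all identical; normal fit undefined")
    }
    z_cut <- mean(zf) + stats::qnorm(q) * stats::sd(zf)
    keep <- z > z_cut
    cutoff <- tanh(z_cut)
  } else {
    # empirical rule: retain the top (1 - q) fraction of pairs by r.
    # keep count = n - floor(q * n), so q -> 0 keeps every pair and q = 0.5
    # on distinct values keeps exactly the top half; ties broken by pair
    # index so the edge set is deterministic and nested in q.
    n_keep <- length(r) - floor(q * length(r))
    ord <- order(-r)
    keep <- logical(length(r))
    if (n_keep > 0) keep[ord[seq_len(n_keep)]] <- TRUE
    cutoff <- if (n_keep > 0) min(r[keep]) else Inf
  }
  edges <- tibble(
    from = nodes[pmin(ut[keep, 1], ut[keep, 2])],
    to = nodes[pmax(ut[keep, 1], ut[keep, 2])],
    weight = r[keep]
  ) |> arrange(.data$from, .data$to)
  structure(list(
    nodes = nodes,
    edges = edges,
    threshold = list(method = method, q = q, cutoff = cutoff,
                     n_candidate_pairs = length(r), n_edges = nrow(edges))
  ), class = "gcn")
}

#' Construct a network directly from node and edge lists
#'
#' Lower-level companion to [build_gcn()] for benchmark graphs and tests.
#'
#' @param nodes character vector of node ids.
#' @param edges data frame with columns `from`, `to` and optionally `weight`.
#' @param threshold optional threshold provenance record.
#' @return a `gcn` object.
#' @export
gcn_graph <- function(nodes, edges, threshold = NULL) {
  assert_unique(nodes, "node ids")
  edges <- as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes))
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) abort("duplicate edges are not allowed")
  edges <- tibble(from = pmin(edges$from, edges$to),
                  to = pmax(edges$from, edges$to),
                  weight = edges$weight) |> arrange(.data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "gcn")
}

#' @export
print.gcn <- function(x, ...) {
  thr <- if (is.null(x$threshold)) "" else
    sprintf(" (%s q = %g, cutoff r = %.3f)", x$threshold$method,
            x$threshold$q, x$threshold$cutoff)
  cat(sprintf("<gcn> %d nodes, %d edges%s\n", length(x$nodes),
              nrow(x$edges), thr))
  invisible(x)
}

#' Tidy a network into its edge table
#'
#' @param x a `gcn`.
#' @param ... unused.
#' @return tibble with `from`, `to`, `weight`.
#' @export
tidy.gcn <- function(x, ...) x$edges

#' One-row summary of a network
#'
#' @param x a `gcn`.
#' @param ... unused.
#' @return tibble with node/edge counts, density, and threshold provenance.
#' @export
glance.gcn <- function(x, ...) {
  n <- length(x$nodes)
  tibble(n_nodes = n, n_edges = nrow(x$edges),
         density = if (n > 1) nrow(x$edges) / (n * (n - 1) / 2) else NA_real_,
         threshold_method = x$threshold$method %||% NA_character_,
         q = x$threshold$q %||% NA_real_,
         cutoff = x$threshold$cutoff %||% NA_real_)
}

# adjacency list: integer neighbor indices per node
gcn_adjacency <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  adj <- vector("list", length(net$nodes))
  for (k in seq_len(nrow(net$edges))) {
    i <- idx[[net$edges$from[k]]]
    j <- idx[[net$edges$to[k]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

#' Convert a network to an igraph object
#'
#' @param net a `gcn`.
#' @return an undirected [igraph::graph] with edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gcn"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Export network tables for external visualization
#'
#' Writes a Cytoscape-importable edge list (`source`, `target`, `weight`) and
#' an optional node attribute table; `export_graphml()` writes GraphML with
#' the node attributes attached.
#'
#' @param net a `gcn`.
#' @param path output TSV path.
#' @param node_attrs optional tibble keyed by `gene_id` with per-node columns
#'   (SOM unit, module, centrality, annotation, ...).
#' @return the path, invisibly.
#' @export
write_edge_table <- function(net, path) {
  stopifnot(inherits(net, "gcn"))
  readr::write_tsv(
    tibble(source = net$edges$from, target = net$edges$to,
           weight = net$edges$weight),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
write_node_table <- function(net, path, node_attrs = NULL) {
  stopifnot(inherits(net, "gcn"))
  out <- tibble(gene_id = net$nodes)
  if (!is.null(node_attrs)) out <- left_join(out, node_attrs, by = "gene_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
export_graphml <- function(net, path, node_attrs = NULL) {
  g <- as_igraph(net)
  if (!is.null(node_attrs)) {
    ord <- match(igraph::V(g)$name, node_attrs$gene_id)
    for (col in setdiff(names(node_attrs), "gene_id")) {
      val <- node_attrs[[col]][ord]
      if (is.logical(val)) val <- as.integer(val)
      g <- igraph::set_vertex_attr(g, col, value = val)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
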