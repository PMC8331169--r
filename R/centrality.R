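#' Degree and betweenness centrality of every gene in a network
#'
#' Degree is the incident edge count. Betweenness is computed with Brandes'
#' dependency-accumulation algorithm over unweighted shortest paths: for each
#' source, a BFS counts shortest paths and dependencies are accumulated back
#' down the BFS tree; endpoint pairs are excluded and totals are halved for
#' undirectedness. Scores are unnormalized — they are used for ranking, where
#' normalization cancels.
#'
#' @param net a `gcn`.
#' @return tibble with `gene_id`, `degree`, `betweenness`, in node order.
#' @export
centrality_scores <- function(net) {
  stopifnot(inherits(net, "gcn"))
  n <- length(net$nodes)
  adj <- gcn_adjacency(net)
  degree <- vapply(adj, length, integer(1))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # Brandes single-source phase
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s)
    head <- 1
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  tibble(gene_id = net$nodes, degree = as.integer(degree),
         betweenness = bc / 2)
}

#' First- and second-layer neighborhoods of a focal gene
#'
#' Partitions the network around a focal node by unweighted shortest-path
#' distance: the first layer is the direct neighbors, the second layer the
#' nodes at distance exactly 2, and everything else (further away or
#' disconnected) is outside — the structure used to read off how many genes a
#' focal regulator such as CcLBD25 touches directly and indirectly.
#'
#' @param net a `gcn`.
#' @param focal a node id present in the network.
#' @return an object of class `neighbor_layers`: `focal`, `first_layer`,
#'   `second_layer`, `outside` (character vectors).
#' @export
ego_layers <- function(net, focal) {
  stopifnot(inherits(net, "gcn"))
  if (!focal %in% net$nodes) {
    near <- net$nodes[order(utils::adist(focal, net$nodes))]
    abort(sprintf("focal gene '%s' not in network; nearest ids: %s", focal,
                  paste(utils::head(near, 3), collapse = ", ")))
  }
  adj <- gcn_adjacency(net)
  idx <- match(focal, net$nodes)
  dist <- rep(-1L, length(net$nodes)); dist[idx] <- 0L
  queue <- c(idx); head <- 1
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1
    for (w in adj[[v]]) {
      if (dist[w] < 0) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  structure(list(
    focal = focal,
    first_layer = net$nodes[dist == 1L],
    second_layer = net$nodes[dist == 2L],
    outside = net$nodes[dist > 2L | dist < 0L]
  ), class = "neighbor_layers")
}

#' @export
print.neighbor_layers <- function(x, ...) {
  cat(sprintf("<neighbor_layers> focal %s: %d first-layer, %d second-layer, %d outside\n",
              x$focal, length(x$first_layer), length(x$second_layer),
              length(x$outside)))
  invisible(x)
}

#' Tidy neighborhood layers
#'
#' @param x a `neighbor_layers`.
#' @param ... unused.
#' @return tibble with `gene_id`, `layer` (focal/first/second/outside).
#' @export
tidy.neighbor_layers <- function(x, ...) {
  bind_rows(
    tibble(gene_id = x$focal, layer = "focal"),
    tibble(gene_id = x$first_layer, layer = "first"),
    tibble(gene_id = x$second_layer, layer = "second"),
    tibble(gene_id = x$outside, layer = "outside")
  )
}

#' Rank hub genes by centrality
#'
#' Sorts genes by degree (descending), then betweenness (descending), then
#' gene id — the ordering used to call hub regulators within a module.
#' Optionally restricts to a node subset (e.g. one module) and/or to
#' annotated transcription factors.
#'
#' @param ct centrality tibble from [centrality_scores()].
#' @param ann optional annotation tibble with `gene_id`, `is_tf` columns
#'   (from [merge_annotation()]).
#' @param tf_only if `TRUE`, keep only genes with `is_tf = TRUE`.
#' @param nodes optional gene ids to restrict to before ranking.
#' @return the ranked tibble with a `rank` column (and `is_tf` if `ann` was
#'   given).
#' @export
hub_ranking <- function(ct, ann = NULL, tf_only = FALSE, nodes = NULL) {
  out <- ct
  if (!is.null(nodes)) out <- filter(out, .data$gene_id %in% nodes)
  if (!is.null(ann)) {
    out <- left_join(out, select(ann, "gene_id", "is_tf"), by = "gene_id") |>
      mutate(is_tf = !is.na(.data$is_tf) & .data$is_tf)
  }
  if (tf_only) {
    if (is.null(ann)) abort("tf_only requires an annotation table")
    out <- filter(out, .data$is_tf)
  }
  out |>
    arrange(desc(.data$degree), desc(.data$betweenness), .data$gene_id) |>
    mutate(rank = dplyr::row_number())
}
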