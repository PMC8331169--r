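# value of named numeric vector at key, 0 when absent
nv_get <- function(v, k) if (k %in% names(v)) v[[k]] else 0

#' Fast-greedy modularity community detection
#'
#' Clauset–Newman–Moore agglomerative optimization of Newman modularity
#' Q = sum_c (m_c / m - (d_c / 2m)^2) on the unweighted thresholded graph.
#' Starting from singletons, the connected pair of communities with the
#' largest modularity gain is merged at each step (ties broken by the
#' lexicographically smallest pair of smallest member ids, so the result is
#' deterministic); the returned partition is the state along the merge
#' history with maximal Q. Modules are relabeled 1, 2, ... by decreasing
#' size, then by smallest member id. Isolated nodes have no incident edges,
#' are never merged, and remain singleton modules.
#'
#' @param net a `gcn`.
#' @return an object of class `module_partition`: `membership` (named integer
#'   vector over nodes), `modularity`, `merge_history` (tibble with the merged
#'   pair, the gain `delta_q`, and `q_after` at each step).
#' @export
fast_greedy_partition <- function(net) {
  stopifnot(inherits(net, "gcn"))
  nodes <- net$nodes
  n <- length(nodes)
  if (n == 0) {
    return(structure(list(membership = stats::setNames(integer(0), character(0)),
                          modularity = 0,
                          merge_history = tibble(a = character(), b = character(),
                                                 delta_q = numeric(),
                                                 q_after = numeric())),
                     class = "module_partition"))
  }
  m <- nrow(net$edges)
  comm <- seq_len(n)                    # community id per node
  members <- lapply(seq_len(n), identity)
  idx <- stats::setNames(seq_len(n), nodes)
  deg <- numeric(n)
  # between-community edge counts as a list of named numeric vectors
  between <- lapply(seq_len(n), function(i) numeric(0))
  for (k in seq_len(nrow(net$edges))) {
    i <- idx[[net$edges$from[k]]]
    j <- idx[[net$edges$to[k]]]
    deg[i] <- deg[i] + 1
    deg[j] <- deg[j] + 1
    between[[i]][as.character(j)] <- nv_get(between[[i]], as.character(j)) + 1
    between[[j]][as.character(i)] <- nv_get(between[[j]], as.character(i)) + 1
  }
  if (m == 0) {
    membership <- relabel_modules(stats::setNames(seq_len(n), nodes), nodes)
    return(structure(list(membership = membership, modularity = 0,
                          merge_history = tibble(a = character(), b = character(),
                                                 delta_q = numeric(),
                                                 q_after = numeric())),
                     class = "module_partition"))
  }
  d_sum <- deg                           # community degree sums
  m_within <- numeric(n)                 # within-community edges
  alive <- rep(TRUE, n)
  q_now <- sum(m_within[alive] / m - (d_sum[alive] / (2 * m))^2)
  best_q <- q_now
  best_state <- comm
  hist_a <- character(0); hist_b <- character(0)
  hist_dq <- numeric(0); hist_q <- numeric(0)

  # smallest member node id of each community, for deterministic tie-breaks
  min_id <- nodes

  repeat {
    best <- NULL
    best_dq <- -Inf
    for (i in which(alive)) {
      nb <- between[[i]]
      if (length(nb) == 0) next
      for (js in names(nb)) {
        j <- as.integer(js)
        if (j <= i) next
        dq <- nb[[js]] / m - 2 * (d_sum[i] / (2 * m)) * (d_sum[j] / (2 * m))
        pair_key <- sort(c(min_id[i], min_id[j]))
        if (dq > best_dq + 1e-12 ||
            (abs(dq - best_dq) <= 1e-12 && !is.null(best) &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best_dq <- dq
          best <- list(i = i, j = j, key = pair_key)
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    # merge j into i
    m_within[i] <- m_within[i] + m_within[j] + between[[i]][[as.character(j)]]
    d_sum[i] <- d_sum[i] + d_sum[j]
    members[[i]] <- c(members[[i]], members[[j]])
    min_id[i] <- min(min_id[i], min_id[j])
    alive[j] <- FALSE
    # fold j's between-edges into i's
    bi <- between[[i]]
    bi <- bi[names(bi) != as.character(j)]
    for (ks in names(between[[j]])) {
      if (ks == as.character(i)) next
      k <- as.integer(ks)
      bi[ks] <- nv_get(bi, ks) + between[[j]][[ks]]
      bk <- between[[k]]
      add <- between[[j]][[ks]]
      bk <- bk[names(bk) != as.character(j)]
      bk[as.character(i)] <- nv_get(bk, as.character(i)) + add
      between[[k]] <- bk
    }
    # drop stale references to j from i's old neighbors
    for (ks in names(between[[i]])) {
      k <- as.integer(ks)
      if (!alive[k]) next
      between[[k]] <- between[[k]][names(between[[k]]) != as.character(j)]
    }
    between[[i]] <- bi
    between[[j]] <- numeric(0)
    comm[members[[i]]] <- i
    q_now <- q_now + best_dq
    hist_a <- c(hist_a, best$key[1]); hist_b <- c(hist_b, best$key[2])
    hist_dq <- c(hist_dq, best_dq); hist_q <- c(hist_q, q_now)
    if (q_now > best_q + 1e-12) {
      best_q <- q_now
      best_state <- comm
    }
  }
  membership <- relabel_modules(stats::setNames(best_state, nodes), nodes)
  structure(list(membership = membership, modularity = best_q,
                 merge_history = tibble(a = hist_a, b = hist_b,
                                        delta_q = hist_dq, q_after = hist_q)),
            class = "module_partition")
}

# 1-based labels ordered by decreasing module size, ties by smallest member id
relabel_modules <- function(membership, nodes) {
  groups <- split(nodes, membership[nodes])
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, min, character(1)))
  out <- integer(length(nodes))
  names(out) <- nodes
  for (new_lab in seq_along(ord)) {
    out[groups[[ord[new_lab]]]] <- new_lab
  }
  out
}

#' Newman modularity of a node partition
#'
#' Q = sum_c (m_c / m - (d_c / 2m)^2) over communities c, on the unweighted
#' graph; 0 for graphs without edges.
#'
#' @param net a `gcn`.
#' @param membership named vector of community labels over `net$nodes`.
#' @return a single numeric value in \[-1, 1\].
#' @export
modularity_q <- function(net, membership) {
  stopifnot(inherits(net, "gcn"))
  m <- nrow(net$edges)
  if (m == 0) return(0)
  lab <- membership[net$nodes]
  deg <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  within <- 0
  for (k in seq_len(m)) {
    f <- net$edges$from[k]; t <- net$edges$to[k]
    deg[f] <- deg[f] + 1
    deg[t] <- deg[t] + 1
    if (lab[f] == lab[t]) within <- within + 1
  }
  d_sum <- tapply(deg, lab, sum)
  within / m - sum((d_sum / (2 * m))^2)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes, %d modules, Q = %.4f\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity))
  invisible(x)
}

#' Tidy a module partition
#'
#' @param x a `module_partition`.
#' @param ... unused.
#' @return tibble with `gene_id`, `module`.
#' @export
tidy.module_partition <- function(x, ...) {
  tibble(gene_id = names(x$membership), module = unname(x$membership))
}

#' One-row summary of a module partition
#'
#' @param x a `module_partition`.
#' @param ... unused.
#' @return tibble with module count, modularity, and largest-module size.
#' @export
glance.module_partition <- function(x, ...) {
  sizes <- table(x$membership)
  tibble(n_modules = length(sizes), modularity = x$modularity,
         largest_module = if (length(sizes)) max(sizes) else 0L)
}
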