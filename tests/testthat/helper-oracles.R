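# Independent oracle implementations used to verify the package's own
# algorithms. Each is written directly from the defining formula, on a
# different code path from the implementation it checks.

# --- second from-scratch TMM: order-statistic trimming, explicit loops ------
oracle_tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(k) {
    x <- counts[, k]; r <- counts[, ref]
    pos <- x > 0 & r > 0
    m <- log2((x[pos] / lib[k]) / (r[pos] / lib[ref]))
    a <- 0.5 * log2((x[pos] / lib[k]) * (r[pos] / lib[ref]))
    w <- (lib[k] - x[pos]) / (lib[k] * x[pos]) +
      (lib[ref] - r[pos]) / (lib[ref] * r[pos])
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    # mid-rank computed by explicit counting (ties get the average rank)
    midrank <- function(v) sapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2)
    rm_ <- midrank(m); ra_ <- midrank(a)
    lo <- floor(n * m_trim) + 1
    lo_a <- floor(n * a_trim) + 1
    keep <- rm_ >= lo & rm_ <= n + 1 - lo & ra_ >= lo_a & ra_ <= n + 1 - lo_a
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  })
  f / exp(mean(log(f)))
}

# --- exhaustive betweenness: enumerate every shortest path ------------------
oracle_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  idx <- setNames(seq_len(n), nodes)
  for (k in seq_len(nrow(edges))) {
    i <- idx[[edges$from[k]]]; j <- idx[[edges$to[k]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  bfs_dist <- function(s) {
    d <- rep(NA_integer_, n); d[s] <- 0L
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    d
  }
  all_paths <- function(s, t, d) {
    # all shortest s->t paths by backward recursion on the BFS layering
    recurse <- function(v) {
      if (v == s) return(list(s))
      out <- list()
      for (u in adj[[v]]) {
        if (!is.na(d[u]) && d[u] == d[v] - 1L) {
          for (p in recurse(u)) out <- c(out, list(c(p, v)))
        }
      }
      out
    }
    recurse(t)
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in seq(s + 1, n)) {
      if (is.na(d[t])) next
      paths <- all_paths(s, t, d)
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tab <- table(interior)
        ii <- as.integer(names(tab))
        bc[ii] <- bc[ii] + as.numeric(tab) / length(paths)
      }
    }
  }
  setNames(bc, nodes)
}

# --- exhaustive maximum-modularity search over all partitions ---------------
oracle_q <- function(nodes, edges, labels) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- setNames(numeric(length(nodes)), nodes)
  within <- 0
  for (k in seq_len(m)) {
    deg[edges$from[k]] <- deg[edges$from[k]] + 1
    deg[edges$to[k]] <- deg[edges$to[k]] + 1
    if (labels[edges$from[k]] == labels[edges$to[k]]) within <- within + 1
  }
  within / m - sum(tapply(deg, labels[nodes], sum)^2) / (4 * m^2)
}

oracle_max_modularity <- function(nodes, edges) {
  n <- length(nodes)
  best <- -Inf
  best_labels <- NULL
  # enumerate set partitions via restricted growth strings
  rgs <- rep(1L, n)
  repeat {
    labels <- setNames(rgs, nodes)
    q <- oracle_q(nodes, edges, labels)
    if (q > best) { best <- q; best_labels <- labels }
    # next restricted growth string: rightmost position that can grow
    i <- n
    advanced <- FALSE
    while (i >= 2) {
      if (rgs[i] <= max(rgs[seq_len(i - 1)])) {
        rgs[i] <- rgs[i] + 1L
        if (i < n) rgs[seq(i + 1, n)] <- 1L
        advanced <- TRUE
        break
      }
      i <- i - 1
    }
    if (!advanced) break
  }
  list(q = best, labels = best_labels)
}

# --- misc fixtures ----------------------------------------------------------
clique_edges <- function(ids) {
  p <- t(combn(ids, 2))
  data.frame(from = p[, 1], to = p[, 2])
}

random_count_matrix <- function(n_genes, n_samples, seed, mu = 150,
                                size = 10) {
  withr::with_seed(seed, {
    cts <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
                  n_genes, n_samples,
                  dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                  sprintf("s%02d", seq_len(n_samples))))
    count_matrix(cts, data.frame(sample_id = colnames(cts),
                                 tissue_class = rep(c("a", "b"),
                                                    length.out = n_samples),
                                 replicate = seq_len(n_samples)))
  })
}
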