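#' TMM normalization and log2-CPM transform
#'
#' Computes trimmed-mean-of-M-values scaling factors between samples and
#' returns log2 counts-per-million on the effective (factor-adjusted) library
#' sizes. The reference sample is the one whose upper-quartile of
#' library-size-scaled counts is closest to the mean upper-quartile. For each
#' sample, per-gene log-ratios M and log-abundances A are computed against the
#' reference over genes positive in both; M is trimmed two-sided by `m_trim`
#' and A by `a_trim`; the factor is 2 raised to the precision-weighted mean of
#' the surviving M values, and factors are recentered to geometric mean 1.
#'
#' Genes with zero counts in every sample are dropped (with a message) before
#' normalization, since they carry no variation for any downstream stage.
#'
#' @param cm a [count_matrix()].
#' @param m_trim two-sided trim fraction on M (log-ratio), default 0.30.
#' @param a_trim two-sided trim fraction on A (log-abundance), default 0.05.
#' @param prior pseudocount added to CPM before log2, default 1 so that a zero
#'   count maps to exactly `log2(prior)` = 0.
#' @return an object of class `norm_matrix`: `values` (genes x samples log2
#'   CPM), `norm_factors`, `lib_sizes`, `sample_meta`.
#' @export
tmm_normalize <- function(cm, m_trim = 0.30, a_trim = 0.05, prior = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (ncol(counts) < 2) abort("TMM needs at least 2 samples")
  all_zero <- rowSums(counts) == 0
  if (any(all_zero)) {
    inform(sprintf("dropping %d genes with zero counts in all samples",
                   sum(all_zero)))
    counts <- counts[!all_zero, , drop = FALSE]
  }
  lib_sizes <- colSums(counts)
  if (any(lib_sizes == 0)) {
    abort(sprintf("sample '%s' has all-zero counts",
                  colnames(counts)[which(lib_sizes == 0)[1]]))
  }
  uq <- apply(sweep(counts, 2, lib_sizes, "/"), 2, stats::quantile,
              probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  factors <- vapply(seq_len(ncol(counts)), function(k) {
    tmm_pair_factor(counts[, k], counts[, ref], lib_sizes[k], lib_sizes[ref],
                    m_trim, a_trim)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  eff_lib <- lib_sizes * factors
  values <- log2(sweep(counts, 2, eff_lib, "/") * 1e6 + prior)
  structure(list(values = values,
                 norm_factors = stats::setNames(factors, colnames(counts)),
                 lib_sizes = stats::setNames(lib_sizes, colnames(counts)),
                 prior = prior,
                 sample_meta = cm$sample_meta),
            class = "norm_matrix")
}

# one pairwise TMM factor: sample obs against sample ref
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, m_trim, a_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) abort("no gene positive in both samples of a TMM pair")
  p_obs <- obs[pos] / n_obs
  p_ref <- ref[pos] / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  # asymptotic (delta-method) variance of M, used as inverse weight
  w <- (n_obs - obs[pos]) / (n_obs * obs[pos]) +
    (n_ref - ref[pos]) / (n_ref * ref[pos])
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * m_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * a_trim) + 1
  hi_a <- n + 1 - lo_a
  if (lo_m > hi_m || lo_a > hi_a) {
    warn("too few genes to trim; using untrimmed weighted mean of M")
    keep <- rep(TRUE, n)
  } else {
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    if (!any(keep)) {
      warn("trimming removed all genes; using untrimmed weighted mean of M")
      keep <- rep(TRUE, n)
    }
  }
  f <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
  2^f
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d genes x %d samples, log2(CPM + %g), TMM factors in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$prior,
              min(x$norm_factors), max(x$norm_factors)))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' Tidy a normalized matrix into a long tibble
#'
#' @param x a `norm_matrix` from [tmm_normalize()].
#' @param ... unused.
#' @return tibble with `gene_id`, `sample_id`, `log_cpm`, `tissue_class`.
#' @export
tidy.norm_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id", names_to = "sample_id",
                              values_to = "log_cpm")
  left_join(long, x$sample_meta, by = "sample_id")
}

#' One-row summary of a normalization
#'
#' @param x a `norm_matrix`.
#' @param ... unused.
#' @return tibble with gene/sample counts and the spread of TMM factors.
#' @export
glance.norm_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$values), n_samples = ncol(x$values),
         min_factor = min(x$norm_factors), max_factor = max(x$norm_factors),
         median_lib_size = stats::median(x$lib_sizes))
}
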