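#' Filter genes by coefficient of variation
#'
#' Per gene, CV = sample (n-1) standard deviation / mean of the normalized
#' values; genes with nonpositive mean are excluded from consideration. In
#' `threshold` mode the genes with CV strictly above `value` are kept (the
#' tissue analysis uses CV > 0.85); in `quantile` mode the genes strictly
#' above the `value`-quantile of all computed CVs (the microdissection
#' analysis keeps the upper half, `value = 0.5`).
#'
#' @param nm a `norm_matrix` from [tmm_normalize()].
#' @param mode `"threshold"` or `"quantile"`.
#' @param value CV cutoff, or quantile in \[0, 1\].
#' @return tibble with columns `gene_id`, `cv` for the retained genes, in
#'   input gene order.
#' @export
cv_filter <- function(nm, mode = c("threshold", "quantile"), value = 0.85) {
  stopifnot(inherits(nm, "norm_matrix"))
  mode <- match.arg(mode)
  mu <- rowMeans(nm$values)
  sdv <- apply(nm$values, 1, stats::sd)
  ok <- mu > 0
  cv <- ifelse(ok, sdv / mu, NA_real_)
  if (mode == "quantile") {
    if (value < 0 || value > 1) abort("quantile value must be in [0, 1]")
    cut <- stats::quantile(cv[ok], probs = value, na.rm = TRUE)
  } else {
    cut <- value
  }
  keep <- ok & cv > cut
  tibble(gene_id = rownames(nm$values)[keep], cv = cv[keep])
}

#' Z-score gene expression profiles
#'
#' Scales each gene to mean 0, sd 1 across columns. With `by = "tissue_mean"`
#' replicates are first averaged within tissue class (columns become tissue
#' classes, in first-appearance order), then z-scored; with `by = "sample"`
#' the per-sample values are scaled directly. Zero-variance genes cannot be
#' scaled and are dropped with a message.
#'
#' @param nm a `norm_matrix`.
#' @param by `"tissue_mean"` (default) or `"sample"`.
#' @param genes optional gene ids to restrict to (e.g. a CV-filtered set).
#' @return an object of class `scaled_matrix`: `values` (genes x columns
#'   z-scores), `columns`, `by`.
#' @export
scale_genes <- function(nm, by = c("tissue_mean", "sample"), genes = NULL) {
  stopifnot(inherits(nm, "norm_matrix"))
  by <- match.arg(by)
  vals <- nm$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vals))
    if (length(missing) > 0) {
      abort(sprintf("genes not in matrix: %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
    vals <- vals[genes, , drop = FALSE]
  }
  if (by == "tissue_mean") {
    classes <- unique(nm$sample_meta$tissue_class)
    vals <- vapply(classes, function(cl) {
      cols <- nm$sample_meta$sample_id[nm$sample_meta$tissue_class == cl]
      rowMeans(vals[, cols, drop = FALSE])
    }, numeric(nrow(vals)))
    colnames(vals) <- classes
  }
  sdv <- apply(vals, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    inform(sprintf("dropping %d zero-variance genes before scaling",
                   sum(flat)))
    vals <- vals[!flat, , drop = FALSE]
    sdv <- sdv[!flat]
  }
  z <- (vals - rowMeans(vals)) / sdv
  structure(list(values = z, columns = colnames(z), by = by),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %d genes x %d columns (by %s)\n",
              nrow(x$values), ncol(x$values), x$by))
  invisible(x)
}

#' @export
dim.scaled_matrix <- function(x) dim(x$values)

#' Principal component analysis of gene profiles
#'
#' PCA with genes as observations and expression columns as variables (each
#' dot in a score plot is a gene), on centered data via [stats::prcomp()].
#' A deterministic sign convention is applied: within each loading vector the
#' largest-magnitude entry is made positive.
#'
#' @param sm a `scaled_matrix` from [scale_genes()].
#' @return an object of class `gene_pca`: `scores` (genes x components),
#'   `loadings` (columns x components), `variance_fraction`.
#' @export
pca_genes <- function(sm) {
  stopifnot(inherits(sm, "scaled_matrix"))
  x <- sm$values
  if (nrow(x) < 2 || ncol(x) < 2) abort("PCA needs at least 2 genes and 2 columns")
  if (all(abs(scale(x, scale = FALSE)) < 1e-12)) abort("degenerate rank-0 input")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf, center = p$center),
            class = "gene_pca")
}

#' @export
print.gene_pca <- function(x, ...) {
  cat(sprintf("<gene_pca> %d genes, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$variance_fraction[1],
              if (length(x$variance_fraction) > 1)
                100 * x$variance_fraction[2] else NA))
  invisible(x)
}

#' Tidy PCA scores
#'
#' @param x a `gene_pca`.
#' @param matrix `"scores"` (default), `"loadings"` or `"eigenvalues"`.
#' @param ... unused.
#' @return a tibble of the requested component.
#' @export
tidy.gene_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = as_tibble(x$scores, rownames = "gene_id"),
    loadings = as_tibble(x$loadings, rownames = "column"),
    eigenvalues = tibble(component = seq_along(x$variance_fraction),
                         variance_fraction = x$variance_fraction)
  )
}

#' Classical multidimensional scaling
#'
#' Double-centered eigendecomposition of squared distances via
#' [stats::cmdscale()]. Accepts either a symmetric distance matrix (zero
#' diagonal) or a numeric data matrix, in which case Euclidean distances
#' between rows are used.
#'
#' @param x distance matrix, `dist` object, or data matrix.
#' @param k number of output dimensions (default 2).
#' @return tibble with an `id` column and `MDS1..MDSk` coordinates.
#' @export
classical_mds <- function(x, k = 2) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (nrow(x) == ncol(x) && all(abs(diag(x)) < 1e-12)) {
      if (max(abs(x - t(x))) > 1e-8) abort("distance matrix is not symmetric")
      if (any(x < 0)) abort("distance matrix has negative entries")
      d <- stats::as.dist(x)
    } else {
      d <- stats::dist(x)
    }
  }
  coords <- stats::cmdscale(d, k = k)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  as_tibble(coords, rownames = "id")
}
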