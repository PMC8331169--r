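#' Construct a count matrix container
#'
#' Bundles a genes-by-samples matrix of raw nonnegative integer counts with
#' per-sample metadata (tissue class and replicate labels). This is the entry
#' point of the pipeline; all downstream stages consume it or objects derived
#' from it.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param sample_meta data frame with columns `sample_id`, `tissue_class` and
#'   optionally `replicate`, one row per sample.
#' @return an object of class `count_matrix` with elements `counts` and
#'   `sample_meta` (a tibble ordered as the matrix columns).
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene ids as rownames and sample ids as colnames")
  }
  assert_unique(rownames(counts), "gene ids")
  assert_unique(colnames(counts), "sample ids")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "double"
  meta <- as_tibble(sample_meta)
  if (!all(c("sample_id", "tissue_class") %in% names(meta))) {
    abort("sample_meta needs columns sample_id and tissue_class")
  }
  assert_unique(meta$sample_id, "metadata sample ids")
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("samples missing from metadata: %s",
                  paste(missing, collapse = ", ")))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, sample_meta = meta), class = "count_matrix")
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The count file is tab-delimited with a header row of sample ids and gene
#' ids in the first column. The metadata file has columns `sample_id`,
#' `tissue_class`, `replicate`. Duplicated ids, negative or non-integer cells,
#' and samples absent from the metadata are hard errors.
#'
#' @param path TSV file of raw counts.
#' @param meta_path TSV file of sample metadata.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  gene_ids <- as.character(tab[[1]])
  assert_unique(gene_ids, "gene ids")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- gene_ids
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(),
                          progress = FALSE)
  count_matrix(counts, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param cm a [count_matrix()].
#' @param path output TSV path for counts.
#' @param meta_path optional output TSV path for the sample metadata.
#' @return `cm`, invisibly.
#' @export
write_counts <- function(cm, path, meta_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- tibble(gene_id = rownames(cm$counts))
  out <- dplyr::bind_cols(out, as_tibble(cm$counts))
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(meta_path)) {
    readr::write_tsv(cm$sample_meta, meta_path, progress = FALSE)
  }
  invisible(cm)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d tissue classes)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_meta$tissue_class))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into a long tibble
#'
#' @param x a [count_matrix()].
#' @param ... unused.
#' @return tibble with columns `gene_id`, `sample_id`, `count`, `tissue_class`.
#' @export
tidy.count_matrix <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id", names_to = "sample_id",
                              values_to = "count")
  left_join(long, x$sample_meta, by = "sample_id")
}
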