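#' Hypergeometric term over-representation with Benjamini-Hochberg control
#'
#' For every term with at least one member in the universe, tests whether the
#' target gene set contains more term members than expected by chance. With a
#' universe of N genes of which K carry the term, and a target of n genes of
#' which k carry it, the upper-tail p-value is
#' `P(X >= k)` for X hypergeometric(N, K, n), computed with
#' [stats::phyper()]. P-values are adjusted across all tested terms by the
#' Benjamini-Hochberg step-up procedure. Offline equivalent of the web-based
#' GO over-representation test applied to network modules and clusters; the
#' default universe is the gene set entering the network stage, not a whole
#' genome.
#'
#' @param target character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe character vector of background genes.
#' @param gene2term tibble with columns `term_id`, `term_name`, `gene_id`
#'   (see [read_gmt()]), or a named list of gene vectors.
#' @return tibble with `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fdr`, sorted by p-value (ties by term id).
#' @export
enrich_terms <- function(target, universe, gene2term) {
  target <- unique(target)
  universe <- unique(universe)
  stray <- setdiff(target, universe)
  if (length(stray) > 0) {
    abort(sprintf("target gene(s) not in universe: %s",
                  paste(utils::head(stray, 5), collapse = ", ")))
  }
  if (is.list(gene2term) && !is.data.frame(gene2term)) {
    gene2term <- purrr::imap_dfr(gene2term, function(genes, term) {
      tibble(term_id = term, term_name = term, gene_id = genes)
    })
  }
  gene2term <- as_tibble(gene2term)
  if (!"term_name" %in% names(gene2term)) {
    gene2term$term_name <- gene2term$term_id
  }
  gene2term <- filter(gene2term, .data$gene_id %in% universe)
  N <- length(universe)
  n <- length(target)
  res <- gene2term |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% target),
              .groups = "drop") |>
    mutate(n = n, N = N,
           p_value = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                                   lower.tail = FALSE))
  res |>
    mutate(fdr = stats::p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$term_id) |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_value", "fdr")
}

#' Read a GMT-style gene set file
#'
#' One term per line: term id, term name, then tab-separated member genes.
#' Two-column TSV files (`term_id`, `gene_id`, with an optional header) are
#' also accepted.
#'
#' @param path input file.
#' @return tibble with columns `term_id`, `term_name`, `gene_id`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (all(widths == 2)) {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                           col_names = c("term_id", "gene_id"))
    if (identical(unlist(tab[1, ], use.names = FALSE),
                  c("term_id", "gene_id"))) tab <- tab[-1, ]
    return(mutate(tab, term_name = .data$term_id)[
      , c("term_id", "term_name", "gene_id")])
  }
  purrr::map_dfr(fields, function(f) {
    if (length(f) < 3) abort("malformed GMT line: fewer than 3 fields")
    tibble(term_id = f[1], term_name = f[2], gene_id = f[-(1:2)])
  })
}
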