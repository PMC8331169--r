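#' Merge best BLAST hits into a per-gene annotation table
#'
#' Reads a standard 12-column tabular BLAST hit file (query, subject,
#' identity, length, mismatches, gaps, qstart, qend, sstart, send, evalue,
#' bitscore), keeps per query gene the highest-bitscore hit among hits passing
#' the e-value threshold, and returns one row per requested gene. Ties on
#' bitscore are broken by smaller e-value, then lexicographic subject id, so
#' the output is independent of input row order. Genes without a qualifying
#' hit get an empty-annotation row.
#'
#' @param blast_path tabular hit file (outfmt-6 dialect).
#' @param genes character vector of gene ids to annotate; hits for unknown
#'   genes are skipped with a message.
#' @param evalue_max e-value threshold for a hit to qualify (default 1e-5).
#' @param tf_ids optional character vector of subject or gene ids to flag as
#'   transcription factors.
#' @param descriptions optional named character vector (names = subject ids)
#'   of free-text descriptions to carry along.
#' @return tibble with columns `gene_id`, `best_hit_id`, `bitscore`, `evalue`,
#'   `tair_id`, `description`, `is_tf`.
#' @export
merge_annotation <- function(blast_path, genes, evalue_max = 1e-5,
                             tf_ids = character(), descriptions = NULL) {
  assert_unique(genes, "gene ids")
  lines <- readr::read_lines(blast_path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  hits <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 12) {
      abort(sprintf("malformed BLAST line %d: expected 12 fields, got %d",
                    i, length(f)))
    }
    ev <- suppressWarnings(as.numeric(f[11]))
    bs <- suppressWarnings(as.numeric(f[12]))
    if (is.na(ev) || is.na(bs)) {
      abort(sprintf("malformed BLAST line %d: non-numeric evalue/bitscore", i))
    }
    tibble(gene_id = f[1], best_hit_id = f[2], evalue = ev, bitscore = bs)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(hits$gene_id), genes)
    if (length(unknown) > 0) {
      inform(sprintf("skipping hits for %d genes absent from the gene list",
                     length(unknown)))
      hits <- filter(hits, .data$gene_id %in% genes)
    }
    hits <- filter(hits, .data$evalue <= evalue_max)
  }
  best <- hits |>
    arrange(.data$gene_id, desc(.data$bitscore), .data$evalue,
            .data$best_hit_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  out <- tibble(gene_id = genes) |>
    left_join(best, by = "gene_id") |>
    mutate(
      tair_id = NA_character_,
      description = if (is.null(descriptions)) NA_character_ else
        unname(descriptions[.data$best_hit_id]),
      is_tf = .data$gene_id %in% tf_ids |
        (!is.na(.data$best_hit_id) & .data$best_hit_id %in% tf_ids)
    )
  out[, c("gene_id", "best_hit_id", "bitscore", "evalue", "tair_id",
          "description", "is_tf")]
}
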