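#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   desc left_join bind_rows n
NULL

# single place for seeded RNG so callers' RNG state is never clobbered
with_seed <- function(seed, code) {
  if (requireNamespace("withr", quietly = TRUE)) {
    return(withr::with_seed(seed, code))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used throughout the recovery tests to compare inferred cluster or module
#' assignments with planted ground truth. 1 means identical partitions up to
#' relabeling; 0 is the expected value under independent random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

assert_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s: %s", what,
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(x)
}
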