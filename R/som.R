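#' Train a hexagonal self-organizing map on gene profiles
#'
#' Online Kohonen algorithm on a `grid_rows` x `grid_cols` hexagonal grid.
#' Units live at hexagonal coordinates (odd rows offset by 0.5 column units,
#' rows spaced sqrt(3)/2 apart) and are numbered 1-based in row-major order,
#' so "SOM9" addresses unit 9 of a 12-unit grid. The codebook is initialized
#' by sampling `rows * cols` distinct gene profiles; each epoch presents all
#' genes in a reshuffled order and pulls every unit within the current
#' neighborhood radius of the best-matching unit (BMU) toward the presented
#' profile: `w <- w + alpha(t) * h * (x - w)`. The learning rate decays
#' linearly from `alpha[1]` to `alpha[2]` and the radius linearly from 2/3 of
#' the grid diagonal to 0 over the epochs. The default neighborhood `h` is a
#' hard bubble (1 within the radius, 0 outside); a Gaussian mode
#' (`exp(-d^2 / (2 r^2))`) is available. After training, assignments are
#' recomputed as exact nearest-codebook matches, ties going to the lowest
#' unit index, so the fit always satisfies the BMU definition.
#'
#' @param sm a `scaled_matrix` from [scale_genes()] (genes x columns).
#' @param rows,cols grid dimensions.
#' @param epochs training epochs (default 100).
#' @param alpha length-2 numeric, start and end learning rate
#'   (default `c(0.05, 0.01)`).
#' @param neighborhood `"bubble"` (default) or `"gaussian"`.
#' @param seed integer seed controlling initialization and presentation order.
#' @return an object of class `som_fit`: `grid_rows`, `grid_cols`, `codebook`
#'   (units x columns), `assignment` (named integer, gene -> unit),
#'   `distance_to_bmu`, `params`, `trace` (per-epoch mean quantization error).
#' @export
som_train <- function(sm, rows, cols, epochs = 100, alpha = c(0.05, 0.01),
                      neighborhood = c("bubble", "gaussian"), seed = 1) {
  stopifnot(inherits(sm, "scaled_matrix"))
  neighborhood <- match.arg(neighborhood)
  x <- sm$values
  n_units <- rows * cols
  if (n_units < 1) abort("grid must have at least one unit")
  if (n_units > nrow(x)) {
    abort(sprintf(
      "more units (%d) than genes (%d); use a smaller grid", n_units, nrow(x)))
  }
  grid <- som_grid_coords(rows, cols)
  diag_len <- sqrt(sum((grid[n_units, ] - grid[1, ])^2))
  radius_start <- 2 / 3 * diag_len
  unit_dist <- as.matrix(stats::dist(grid))

  trace <- numeric(epochs)
  codebook <- NULL
  with_seed(seed, {
    init <- sample.int(nrow(x), n_units)
    codebook <- x[init, , drop = FALSE]
    rownames(codebook) <- NULL
    for (e in seq_len(epochs)) {
      frac <- if (epochs == 1) 0 else (e - 1) / (epochs - 1)
      a <- alpha[1] + frac * (alpha[2] - alpha[1])
      r <- radius_start * (1 - frac)
      ord <- sample.int(nrow(x))
      qe <- 0
      for (i in ord) {
        xi <- x[i, ]
        d2 <- rowSums((codebook - matrix(xi, n_units, ncol(x),
                                         byrow = TRUE))^2)
        bmu <- which.min(d2)
        qe <- qe + sqrt(d2[bmu])
        h <- if (neighborhood == "bubble") {
          as.numeric(unit_dist[, bmu] <= r)
        } else {
          if (r > 0) exp(-unit_dist[, bmu]^2 / (2 * r^2)) else
            as.numeric(seq_len(n_units) == bmu)
        }
        upd <- h > 0
        codebook[upd, ] <- codebook[upd, , drop = FALSE] +
          a * h[upd] * (matrix(xi, sum(upd), ncol(x), byrow = TRUE) -
                          codebook[upd, , drop = FALSE])
      }
      trace[e] <- qe / nrow(x)
    }
  })
  d <- outer(rowSums(x^2), rowSums(codebook^2), "+") -
    2 * x %*% t(codebook)
  d[d < 0] <- 0
  assignment <- apply(d, 1, which.min)  # which.min breaks ties at lowest index
  structure(list(
    grid_rows = rows, grid_cols = cols, topology = "hexagonal",
    codebook = codebook,
    assignment = stats::setNames(as.integer(assignment), rownames(x)),
    distance_to_bmu = stats::setNames(
      sqrt(d[cbind(seq_len(nrow(x)), assignment)]), rownames(x)),
    params = list(epochs = epochs, alpha_start = alpha[1],
                  alpha_end = alpha[2], radius_start = radius_start,
                  radius_end = 0, neighborhood = neighborhood, seed = seed),
    trace = trace,
    columns = colnames(x)
  ), class = "som_fit")
}

# hexagonal unit coordinates, row-major: odd rows (0-based index odd) shifted
# +0.5 in x, rows sqrt(3)/2 apart in y
som_grid_coords <- function(rows, cols) {
  coords <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  coords <- coords[order(coords$row, coords$col), ]
  cbind(x = coords$col - 1 + 0.5 * ((coords$row - 1) %% 2),
        y = (coords$row - 1) * sqrt(3) / 2)
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %dx%d hexagonal grid, %d genes, %d epochs (seed %d)\n",
              x$grid_rows, x$grid_cols, length(x$assignment),
              x$params$epochs, x$params$seed))
  invisible(x)
}

#' Tidy a SOM fit into a per-gene assignment table
#'
#' @param x a `som_fit`.
#' @param ... unused.
#' @return tibble with `gene_id`, `unit`, `distance_to_bmu`.
#' @export
tidy.som_fit <- function(x, ...) {
  tibble(gene_id = names(x$assignment), unit = unname(x$assignment),
         distance_to_bmu = unname(x$distance_to_bmu))
}

#' One-row summary of a SOM fit
#'
#' @param x a `som_fit`.
#' @param ... unused.
#' @return tibble with grid size, gene count, occupied units, and final mean
#'   quantization error.
#' @export
glance.som_fit <- function(x, ...) {
  tibble(grid_rows = x$grid_rows, grid_cols = x$grid_cols,
         n_genes = length(x$assignment),
         n_occupied_units = length(unique(x$assignment)),
         quantization_error = x$trace[length(x$trace)])
}

#' Per-unit, per-tissue-class expression summary of a SOM fit
#'
#' For every map unit, the mean scaled expression of its member genes in each
#' column of the scaled matrix (tissue classes or developmental stages),
#' together with the member count — the numbers behind a code/sector plot of
#' the map. Empty units are reported with count 0 and `NA` means.
#'
#' @param fit a `som_fit`.
#' @param sm the `scaled_matrix` the fit was trained on.
#' @return tibble with `unit`, `n_genes`, `column`, `mean_scaled`.
#' @export
som_summarize <- function(fit, sm) {
  stopifnot(inherits(fit, "som_fit"), inherits(sm, "scaled_matrix"))
  if (!identical(names(fit$assignment), rownames(sm$values))) {
    abort("fit and scaled matrix do not share gene ids")
  }
  units <- seq_len(fit$grid_rows * fit$grid_cols)
  purrr::map_dfr(units, function(u) {
    members <- names(fit$assignment)[fit$assignment == u]
    if (length(members) == 0) {
      tibble(unit = u, n_genes = 0L, column = colnames(sm$values),
             mean_scaled = NA_real_)
    } else {
      tibble(unit = u, n_genes = length(members),
             column = colnames(sm$values),
             mean_scaled = unname(colMeans(sm$values[members, , drop = FALSE])))
    }
  })
}

#' Genes belonging to a set of SOM units
#'
#' Union of the member genes of the requested units, in the fit's gene order —
#' e.g. the SOM9 cluster of genes highly expressed in both prehaustoria and
#' haustoria, or SOM2+3+9 for the comprehensive network.
#'
#' @param fit a `som_fit`.
#' @param units integer vector of unit ids (1-based, row-major).
#' @return character vector of gene ids.
#' @export
select_som_clusters <- function(fit, units) {
  stopifnot(inherits(fit, "som_fit"))
  valid <- seq_len(fit$grid_rows * fit$grid_cols)
  bad <- setdiff(units, valid)
  if (length(bad) > 0) {
    abort(sprintf("unknown unit id(s): %s", paste(bad, collapse = ", ")))
  }
  names(fit$assignment)[fit$assignment %in% units]
}
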