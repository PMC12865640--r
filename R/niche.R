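#' Per-cell neighborhood cell-type composition
#'
#' For each cell, the cell-type frequency vector of its `k_neighbors`
#' nearest neighbors in the same field of view (Euclidean distance, self
#' excluded). This is the standard local-microenvironment descriptor on
#' which niches are defined: cells sharing similar neighbor composition
#' belong to the same tissue neighborhood. Distance ties are broken by
#' `cell_id` order for determinism; in FOVs with `<= k_neighbors` cells, k
#' is truncated to the FOV size minus one (with a warning) and the
#' composition uses all available neighbors.
#'
#' @inheritParams directional_proximity
#' @param k_neighbors Number of nearest neighbors (default 30).
#' @return A `niche_composition` tibble: `cell_id`, `fov_id`, then one
#'   proportion column per cell type; proportion columns sum to 1 per row.
#' @export
neighborhood_composition <- function(cells, k_neighbors = 30) {
  cells <- validate_cells(cells)
  stopifnot("k_neighbors must be a positive integer" = is_count(k_neighbors))
  types <- sort(unique(cells$cell_type))
  comp <- matrix(0, nrow(cells), length(types),
                 dimnames = list(cells$cell_id, types))
  for (f in unique(cells$fov_id)) {
    idx <- which(cells$fov_id == f)
    k <- min(k_neighbors, length(idx) - 1)
    if (k < 1) {
      warning("FOV ", f, " has a single cell; its composition is NA")
      comp[idx, ] <- NA_real_
      next
    }
    if (k < k_neighbors)
      warning("FOV ", f, " has only ", length(idx),
              " cells; k truncated to ", k)
    d <- cross_dist(cells$x_um[idx], cells$y_um[idx],
                    cells$x_um[idx], cells$y_um[idx])
    ids <- cells$cell_id[idx]
    for (a in seq_along(idx)) {
      ord <- order(d[a, ], ids)            # ties by cell_id
      nn <- setdiff(ord, a)[seq_len(k)]    # self excluded
      tab <- table(factor(cells$cell_type[idx[nn]], levels = types))
      comp[idx[a], ] <- as.numeric(tab) / k
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(cell_id = cells$cell_id, fov_id = cells$fov_id),
    tibble::as_tibble(comp)
  )
  structure(out, class = c("niche_composition", class(tibble::tibble())),
            k_neighbors = as.integer(k_neighbors), types = types)
}

#' Cluster neighborhood compositions into niches
#'
#' Partitions the per-cell composition vectors of
#' [neighborhood_composition()] into at most `n_niches` clusters with
#' k-means started from a deterministic, row-order-invariant
#' initialization (evenly spaced rows of the lexicographically sorted
#' distinct compositions), so the partition is reproducible and does not
#' depend on the order cells arrive in; `seed` is recorded in the model
#' for provenance.
#' Clusters are relabeled by descending size as `niche_1`, `niche_2`, ...;
#' empty clusters (fewer distinct compositions than requested niches) are
#' dropped rather than re-seeded.
#'
#' @param composition A `niche_composition` (or plain data frame with
#'   `cell_id` plus proportion columns).
#' @param n_niches Maximum number of niches (>= 2; default 6).
#' @param seed Integer seed for the k-means initialization.
#' @return A `niche_model`: list with `niche_of` (tibble `cell_id`,
#'   `niche`), `centers`, `sizes`, `n_niches`, `k_neighbors`, `seed`.
#'   Methods: [tidy()], [glance()], [ggplot2::autoplot()].
#' @export
assign_niches <- function(composition, n_niches = 6, seed = 1L) {
  stopifnot("n_niches must be >= 2" = is_count(n_niches) && n_niches >= 2)
  comp_cols <- setdiff(names(composition), c("cell_id", "fov_id"))
  mat <- as.matrix(tibble::as_tibble(composition)[, comp_cols, drop = FALSE])
  if (anyNA(mat))
    stop("composition contains NA rows; remove single-cell FOVs first",
         call. = FALSE)
  if (n_niches > nrow(mat))
    stop("n_niches (", n_niches, ") exceeds the number of cells (",
         nrow(mat), ")", call. = FALSE)

  n_distinct_rows <- nrow(unique(mat))
  centers <- min(n_niches, n_distinct_rows)
  if (centers < n_niches)
    message("only ", n_distinct_rows, " distinct composition(s); ",
            "fitting ", centers, " niche(s)")
  if (centers == 1) {
    cluster <- rep(1L, nrow(mat))
    fit <- list(centers = matrix(colMeans(mat), 1,
                                 dimnames = list(NULL, comp_cols)),
                tot.withinss = 0)
  } else {
    # deterministic, row-order-invariant initialization: evenly spaced
    # rows of the lexicographically sorted distinct compositions
    sorted <- unique(mat[do.call(order, as.data.frame(mat)), , drop = FALSE])
    init <- sorted[round(seq(1, nrow(sorted), length.out = centers)), ,
                   drop = FALSE]
    fit <- tryCatch(
      stats::kmeans(mat, centers = init, iter.max = 100),
      error = function(e) suppressWarnings(
        stats::kmeans(mat, centers = init, iter.max = 100,
                      algorithm = "Lloyd")))
    cluster <- fit$cluster
  }
  sizes <- tabulate(cluster, nbins = centers)
  keep <- which(sizes > 0)
  relabel <- integer(centers)
  relabel[keep[order(-sizes[keep], keep)]] <- seq_along(keep)
  niche <- paste0("niche_", relabel[cluster])

  structure(list(
    niche_of = tibble::tibble(cell_id = composition$cell_id, niche = niche),
    centers = fit$centers[keep[order(-sizes[keep], keep)], , drop = FALSE],
    sizes = sort(sizes[keep], decreasing = TRUE),
    n_niches = as.integer(n_niches),
    k_neighbors = attr(composition, "k_neighbors"),
    tot_withinss = fit$tot.withinss,
    seed = as.integer(seed)
  ), class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat("<niche_model> ", length(x$sizes), " niche(s) over ",
      nrow(x$niche_of), " cells (k_neighbors = ",
      x$k_neighbors %||% NA, ")\n", sep = "")
  print(stats::setNames(x$sizes, paste0("niche_", seq_along(x$sizes))))
  invisible(x)
}

#' @rdname assign_niches
#' @param x A `niche_model`.
#' @param ... Unused.
#' @method tidy niche_model
#' @export
tidy.niche_model <- function(x, ...) {
  centers <- tibble::as_tibble(x$centers)
  centers$niche <- paste0("niche_", seq_along(x$sizes))
  centers$size <- x$sizes
  tidyr::pivot_longer(centers, cols = -c("niche", "size"),
                      names_to = "cell_type", values_to = "center_proportion")
}

#' @rdname assign_niches
#' @method glance niche_model
#' @export
glance.niche_model <- function(x, ...) {
  tibble::tibble(n_niches = length(x$sizes), n_cells = nrow(x$niche_of),
                 k_neighbors = x$k_neighbors %||% NA_integer_,
                 tot_withinss = x$tot_withinss, seed = x$seed)
}

#' Per-niche composition, landmark distance and gene-expression summaries
#'
#' For each niche: (a) the cell-type proportions of its member cells,
#' (b) the mean distance from member cells to the nearest landmark-type
#' cell (self excluded, per FOV), and (c) the mean expression of each
#' panel gene — by default the inflammation/fibrosis transcripts CCL2,
#' CXCL10, ITGAM, CCR2, COL1A1 plus the IL1B/IL1R1 axis.
#'
#' @param model A `niche_model` from [assign_niches()].
#' @param cells Validated cell table covering the model's cells.
#' @param expr cells x genes matrix aligned to `cells` (normally
#'   normalized).
#' @param landmark_type Landmark cell type for the distance summary.
#' @param gene_panel Genes to summarize; an unknown gene is an error.
#' @return A list of tibbles: `proportions` (`niche`, `cell_type`,
#'   `proportion`, rows per niche summing to 1), `landmark_distance`
#'   (`niche`, `mean_distance_um`, `n`), `expression` (`niche`, `gene`,
#'   `mean_expression`).
#' @export
niche_summaries <- function(model, cells, expr, landmark_type,
                            gene_panel = c("CCL2", "CXCL10", "ITGAM",
                                           "CCR2", "COL1A1", "IL1B",
                                           "IL1R1")) {
  stopifnot(inherits(model, "niche_model"))
  cells <- validate_cells(cells)
  assert_known_type(cells, landmark_type, "landmark_type")
  missing_genes <- setdiff(gene_panel, colnames(expr))
  if (length(missing_genes) > 0)
    stop("unknown panel gene(s): ", paste(missing_genes, collapse = ", "),
         call. = FALSE)

  df <- dplyr::inner_join(cells, model$niche_of, by = "cell_id")
  props <- df |>
    dplyr::count(.data$niche, .data$cell_type) |>
    dplyr::group_by(.data$niche) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("niche", "cell_type", "proportion")

  df$landmark_dist <- landmark_dist_all_cells(df, landmark_type)
  dist_tbl <- df |>
    dplyr::filter(!is.na(.data$landmark_dist)) |>
    dplyr::group_by(.data$niche) |>
    dplyr::summarise(mean_distance_um = mean(.data$landmark_dist),
                     n = dplyr::n(), .groups = "drop")

  x <- as.matrix(expr[df$cell_id, gene_panel, drop = FALSE])
  expr_tbl <- tibble::as_tibble(x) |>
    dplyr::mutate(niche = df$niche) |>
    tidyr::pivot_longer(-"niche", names_to = "gene",
                        values_to = "expression") |>
    dplyr::group_by(.data$niche, .data$gene) |>
    dplyr::summarise(mean_expression = mean(.data$expression),
                     .groups = "drop")

  list(proportions = props, landmark_distance = dist_tbl,
       expression = expr_tbl)
}
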