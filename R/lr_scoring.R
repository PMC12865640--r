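#' Library-size normalize an expression matrix
#'
#' Divides each cell's values by its total and multiplies by `scale`
#' (counts-per-10k by default). Cells with a zero total cannot be
#' normalized; they are left all-zero, recorded in the `"zero_cells"`
#' attribute, and excluded from downstream scoring.
#'
#' @param expr cells x genes matrix (sparse or dense), non-negative.
#' @param scale Target per-cell total (default `1e4`).
#' @return A sparse `dgCMatrix` of the same shape; attribute
#'   `"zero_cells"` holds the ids of flagged cells.
#' @export
normalize_expression <- function(expr, scale = 1e4) {
  stopifnot(scale > 0)
  if (min(expr) < 0) stop("expression values must be non-negative", call. = FALSE)
  m <- methods::as(Matrix::Matrix(expr, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::rowSums(m)
  zero <- totals == 0
  if (any(zero))
    message(sum(zero), " cell(s) with zero total counts flagged; ",
            "they are excluded from scoring")
  out <- Matrix::Diagonal(x = ifelse(zero, 0, scale / totals)) %*% m
  out <- methods::as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(m)
  attr(out, "zero_cells") <- rownames(m)[zero]
  out
}

# drop flagged (all-zero) cells before scoring; keeps expr/cells aligned
drop_zero_cells <- function(expr, cells) {
  keep <- Matrix::rowSums(expr) > 0
  list(expr = expr[keep, , drop = FALSE],
       cells = cells[keep, , drop = FALSE])
}

assert_gene <- function(expr, gene) {
  if (!gene %in% colnames(expr))
    stop("gene '", gene, "' is not in the expression matrix", call. = FALSE)
}

#' Spatially weighted ligand-receptor score for one pair and direction
#'
#' Integrates ligand expression in source-type cells, receptor expression
#' in target-type cells, and their spatial proximity into a single
#' directional interaction score:
#' \deqn{score = \frac{\sum_i \sum_j x_{iL}\, x_{jR}\, w_{ij}}
#'                    {\sum_i \sum_j w_{ij}}}
#' with i over source cells, j over target cells in the same field of
#' view, and `w_ij` the Gaussian kernel weight of
#' [directional_proximity()]. The score is the kernel-weighted mean of the
#' ligand x receptor expression product, so it is comparable across
#' directions with different cell abundances. Self-self cell-type
#' requests are rejected: the statistic targets intercellular, not
#' autocrine, signaling.
#'
#' @param expr cells x genes matrix aligned to `cells`; normally the
#'   output of [normalize_expression()]. All-zero cells are excluded.
#' @param cells Validated cell table.
#' @param ligand,receptor Gene names of the pair.
#' @param source_type,target_type Cell types; must differ.
#' @param bandwidth_um Kernel bandwidth, micrometers.
#' @return The score (non-negative scalar), or `NA` (with a message) when
#'   no source-target weight exists.
#' @examples
#' cells <- tibble::tibble(cell_id = c("s", "t"), x_um = c(0, 12),
#'                         y_um = 0, fov_id = "f1", cell_type = c("S", "T"))
#' expr <- matrix(c(2, 0, 0, 3), 2, dimnames = list(c("s", "t"),
#'                                                  c("L", "R")))
#' spatial_lr_score(expr, cells, "L", "R", "S", "T")  # 2 * 3 = 6
#' @export
spatial_lr_score <- function(expr, cells, ligand, receptor,
                             source_type, target_type, bandwidth_um = 20) {
  cells <- validate_cells(cells)
  if (source_type == target_type)
    stop("self-self cell-type interactions are excluded ",
         "(source_type == target_type)", call. = FALSE)
  assert_gene(expr, ligand)
  assert_gene(expr, receptor)
  assert_known_type(cells, source_type, "source_type")
  assert_known_type(cells, target_type, "target_type")

  dz <- drop_zero_cells(expr, cells)
  expr <- dz$expr; cells <- dz$cells
  num <- 0; den <- 0
  for (f in unique(cells$fov_id)) {
    si <- which(cells$fov_id == f & cells$cell_type == source_type)
    ti <- which(cells$fov_id == f & cells$cell_type == target_type)
    if (length(si) == 0 || length(ti) == 0) next
    w <- exp(-cross_dist(cells$x_um[si], cells$y_um[si],
                         cells$x_um[ti], cells$y_um[ti])^2 /
               (2 * bandwidth_um^2))
    xl <- as.numeric(expr[si, ligand])
    xr <- as.numeric(expr[ti, receptor])
    num <- num + drop(crossprod(xl, w %*% xr))
    den <- den + sum(w)
  }
  if (den == 0) {
    message("no source-target kernel weight for ", source_type, " -> ",
            target_type, "; score is NA")
    return(NA_real_)
  }
  num / den
}

#' Score every ligand-receptor pair over every directed cell-type pair
#'
#' Computes the [spatial_lr_score()] for each row of `pairs` and each
#' ordered (source type, target type) combination with source != target.
#' Self-self cell-type combinations never appear in the result.
#'
#' @inheritParams spatial_lr_score
#' @param pairs Tibble with `ligand`, `receptor`, `pair_id` columns (see
#'   [read_lr_pairs()] / [filter_lr_pairs()]).
#' @return An `lr_score_result` tibble with columns `source_type`,
#'   `target_type`, `pair_id`, `ligand`, `receptor`, `score`, `n_source`,
#'   `n_target`. Deterministic given the inputs.
#' @seealso [rank_lr_pairs()], [lr_permutation_test()]
#' @export
spatial_lr_scores <- function(expr, cells, pairs, bandwidth_um = 20) {
  cells <- validate_cells(cells)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("ligand", "receptor", "pair_id") %in% names(pairs)))
  for (g in unique(c(pairs$ligand, pairs$receptor))) assert_gene(expr, g)

  dz <- drop_zero_cells(expr, cells)
  expr <- dz$expr; cells <- dz$cells
  types <- sort(unique(cells$cell_type))
  n_by_type <- c(table(factor(cells$cell_type, levels = types)))
  genes_used <- unique(c(pairs$ligand, pairs$receptor))
  x <- as.matrix(expr[, genes_used, drop = FALSE])

  dir_key <- function(s, t) paste(s, t, sep = "\r")
  cross <- list(); den <- list()
  for (f in unique(cells$fov_id)) {
    idx_f <- which(cells$fov_id == f)
    w_full <- kernel_matrix(cells$x_um[idx_f], cells$y_um[idx_f], bandwidth_um)
    by_type <- split(seq_along(idx_f), cells$cell_type[idx_f])
    for (s in names(by_type)) for (t in names(by_type)) {
      if (s == t) next
      w <- w_full[by_type[[s]], by_type[[t]], drop = FALSE]
      key <- dir_key(s, t)
      cp <- crossprod(x[idx_f[by_type[[s]]], , drop = FALSE],
                      w %*% x[idx_f[by_type[[t]]], , drop = FALSE])
      cross[[key]] <- if (is.null(cross[[key]])) cp else cross[[key]] + cp
      den[[key]] <- (den[[key]] %||% 0) + sum(w)
    }
  }

  grid <- tidyr::expand_grid(source_type = types, target_type = types) |>
    dplyr::filter(.data$source_type != .data$target_type)
  out <- purrr::pmap_dfr(grid, function(source_type, target_type) {
    key <- dir_key(source_type, target_type)
    d <- den[[key]] %||% 0
    sc <- if (d > 0) cross[[key]][cbind(pairs$ligand, pairs$receptor)] / d
          else rep(NA_real_, nrow(pairs))
    tibble::tibble(source_type = source_type, target_type = target_type,
                   pair_id = pairs$pair_id, ligand = pairs$ligand,
                   receptor = pairs$receptor, score = sc,
                   n_source = as.integer(n_by_type[source_type]),
                   n_target = as.integer(n_by_type[target_type]))
  })
  if (anyNA(out$score))
    message(sum(is.na(out$score)), " score(s) NA: directions with no ",
            "source-target kernel weight")
  new_lr_score_result(out, bandwidth_um)
}

new_lr_score_result <- function(tbl, bandwidth_um) {
  structure(tbl, class = c("lr_score_result", class(tibble::tibble())),
            bandwidth_um = bandwidth_um)
}

#' Top ligand-receptor pairs for one signaling direction
#'
#' Orders the scores of a single source -> target direction descending;
#' ties are broken by `pair_id` lexicographic order so rankings are
#' deterministic.
#'
#' @param result An `lr_score_result` from [spatial_lr_scores()].
#' @param source_type,target_type The direction to rank.
#' @param top_n Number of pairs to keep (default 20, the usual figure
#'   depth); truncated to the number available.
#' @return A tibble of the top pairs with a `rank` column.
#' @export
rank_lr_pairs <- function(result, source_type, target_type, top_n = 20) {
  hit <- dplyr::filter(tibble::as_tibble(result),
                       .data$source_type == !!source_type,
                       .data$target_type == !!target_type)
  if (nrow(hit) == 0)
    stop("direction ", source_type, " -> ", target_type,
         " is not present in the result", call. = FALSE)
  hit |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pair_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = top_n)
}

#' Summary of an `lr_score_result` (directions, pairs, bandwidth)
#' @param x An `lr_score_result`.
#' @param ... Unused.
#' @method glance lr_score_result
#' @export
glance.lr_score_result <- function(x, ...) {
  tibble::tibble(n_directions = dplyr::n_distinct(paste(x$source_type,
                                                        x$target_type)),
                 n_pairs = dplyr::n_distinct(x$pair_id),
                 bandwidth_um = attr(x, "bandwidth_um"))
}

#' Permutation significance for a spatial ligand-receptor score
#'
#' Builds an empirical null for [spatial_lr_score()] by shuffling
#' cell-type labels within each field of view (coordinates and expression
#' stay fixed, so the null preserves spatial structure and per-FOV type
#' composition) and recomputing the score `n_perm` times.
#'
#' The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, so it is never 0. The
#' z-score is `(observed - null mean) / null sd`; a degenerate null
#' (sd = 0) yields `NA` for the z-score while the p-value remains valid.
#'
#' @inheritParams spatial_lr_score
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed; results are deterministic given it.
#' @return A one-row tibble: `observed`, `perm_z`, `perm_p`, `n_perm`.
#' @export
lr_permutation_test <- function(expr, cells, ligand, receptor,
                                source_type, target_type,
                                bandwidth_um = 20, n_perm = 199, seed = 1L) {
  cells <- validate_cells(cells)
  if (n_perm < 19) stop("n_perm must be at least 19", call. = FALSE)
  if (source_type == target_type)
    stop("self-self cell-type interactions are excluded", call. = FALSE)
  assert_gene(expr, ligand)
  assert_gene(expr, receptor)
  assert_known_type(cells, source_type, "source_type")
  assert_known_type(cells, target_type, "target_type")

  dz <- drop_zero_cells(expr, cells)
  expr <- dz$expr; cells <- dz$cells
  fovs <- unique(cells$fov_id)
  pre <- lapply(fovs, function(f) {
    idx <- which(cells$fov_id == f)
    list(w = kernel_matrix(cells$x_um[idx], cells$y_um[idx], bandwidth_um),
         xl = as.numeric(expr[idx, ligand]),
         xr = as.numeric(expr[idx, receptor]),
         labels = cells$cell_type[idx])
  })
  score_with <- function(label_list) {
    num <- 0; den <- 0
    for (k in seq_along(pre)) {
      si <- which(label_list[[k]] == source_type)
      ti <- which(label_list[[k]] == target_type)
      if (length(si) == 0 || length(ti) == 0) next
      w <- pre[[k]]$w[si, ti, drop = FALSE]
      # elementwise form so a constant-expression null is exactly degenerate
      num <- num + sum(w * outer(pre[[k]]$xl[si], pre[[k]]$xr[ti]))
      den <- den + sum(w)
    }
    if (den == 0) NA_real_ else num / den
  }

  observed <- score_with(lapply(pre, `[[`, "labels"))
  null_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      score_with(lapply(pre, function(p) sample(p$labels)))
    }, numeric(1))
  })
  ok <- !is.na(null_scores)
  perm_p <- (1 + sum(null_scores[ok] >= observed)) / (sum(ok) + 1)
  null_sd <- stats::sd(null_scores[ok])
  perm_z <- if (is.na(null_sd) || null_sd == 0) NA_real_
            else (observed - mean(null_scores[ok])) / null_sd
  tibble::tibble(observed = observed, perm_z = perm_z, perm_p = perm_p,
                 n_perm = n_perm)
}
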