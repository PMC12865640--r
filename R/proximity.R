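#' Directional spatial proximity scores between cell types
#'
#' Quantifies how likely cells of a source type are to sit next to cells
#' of each target type. For every source cell i, each other cell j in the
#' same field of view receives a Gaussian kernel weight
#' `w_ij = exp(-d_ij^2 / (2 * bandwidth_um^2))`; the self weight is
#' excluded and cells in different FOVs get weight 0 (imaging tiles are
#' non-contiguous, so cross-FOV distances are not physical). With
#' `normalize = TRUE` the weights of each source cell are divided by their
#' sum, making them a composition over that cell's neighborhood. The score
#' for a source type S and target type T is the mean over cells of type S
#' of the total (normalized) weight landing on cells of type T. Because
#' the average runs over source cells, `score(S, T) != score(T, S)` in
#' general — the matrix is directional.
#'
#' Under normalization, source cells with zero total kernel weight
#' (isolated within floating point) cannot be normalized; they are
#' excluded from the average and counted in `n_excluded`. A source type
#' whose cells are all isolated yields a row of `NA`.
#'
#' @param cells Validated cell table (see [read_cells()]).
#' @param bandwidth_um Gaussian kernel bandwidth in micrometers. The
#'   default 20 matches the neighborhood radius used for direct
#'   cell-contact analyses.
#' @param normalize Normalize kernel weights per source cell (default);
#'   normalized rows of the score matrix sum to 1 over target types.
#' @return A `proximity_matrix` object: list with `score` (source x
#'   target matrix), `bandwidth_um`, `normalized`, `n_cells` (cells per
#'   type), `n_excluded`. Use [tidy()] for a long tibble and
#'   [ggplot2::autoplot()] for a heatmap.
#' @examples
#' cells <- tibble::tibble(cell_id = c("a", "b", "c"),
#'                         x_um = c(0, 10, 0), y_um = c(0, 0, 10),
#'                         fov_id = "f1", cell_type = c("S", "T1", "T2"))
#' directional_proximity(cells, bandwidth_um = 20)$score
#' @export
directional_proximity <- function(cells, bandwidth_um = 20, normalize = TRUE) {
  cells <- validate_cells(cells)
  if (!is.numeric(bandwidth_um) || length(bandwidth_um) != 1 ||
      bandwidth_um <= 0)
    stop("bandwidth_um must be a positive number", call. = FALSE)
  if (nrow(cells) < 2)
    stop("at least 2 cells are required", call. = FALSE)

  types <- sort(unique(cells$cell_type))
  k <- length(types)
  # per-cell total weight landing on each target type, stacked over FOVs
  rows <- matrix(0, nrow(cells), k, dimnames = list(NULL, types))
  included <- rep(TRUE, nrow(cells))
  for (f in unique(cells$fov_id)) {
    idx <- which(cells$fov_id == f)
    w <- kernel_matrix(cells$x_um[idx], cells$y_um[idx], bandwidth_um)
    rs <- rowSums(w)
    if (normalize) {
      iso <- rs == 0
      included[idx[iso]] <- FALSE
      w <- w / ifelse(rs == 0, 1, rs)
    }
    tind <- stats::model.matrix(~ 0 + factor(cells$cell_type[idx],
                                             levels = types))
    rows[idx, ] <- w %*% tind
  }

  score <- matrix(NA_real_, k, k, dimnames = list(types, types))
  for (s in types) {
    use <- cells$cell_type == s & included
    if (!any(use)) {
      message("source type '", s, "' has no non-isolated cells; row is NA")
      next
    }
    score[s, ] <- colMeans(rows[use, , drop = FALSE])
  }
  structure(list(score = score, bandwidth_um = bandwidth_um,
                 normalized = normalize,
                 n_cells = table(cells$cell_type),
                 n_excluded = sum(!included)),
            class = "proximity_matrix")
}

# dense Gaussian kernel within one FOV, self weight zeroed
kernel_matrix <- function(x, y, bandwidth_um) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  w <- exp(-d2 / (2 * bandwidth_um^2))
  diag(w) <- 0
  w
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat("<proximity_matrix> ", nrow(x$score), " cell types, bandwidth ",
      x$bandwidth_um, " um, ",
      if (x$normalized) "per-cell normalized" else "unnormalized", "\n",
      sep = "")
  print(round(x$score, 4))
  invisible(x)
}

#' @rdname directional_proximity
#' @param x A `proximity_matrix`.
#' @param ... Unused.
#' @method tidy proximity_matrix
#' @export
tidy.proximity_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$score, responseName = "score",
                                        stringsAsFactors = FALSE)) |>
    dplyr::rename(source_type = "Var1", target_type = "Var2")
}

#' @rdname directional_proximity
#' @method glance proximity_matrix
#' @export
glance.proximity_matrix <- function(x, ...) {
  tibble::tibble(n_types = nrow(x$score), bandwidth_um = x$bandwidth_um,
                 normalized = x$normalized, n_excluded = x$n_excluded)
}

assert_known_type <- function(cells, type, arg) {
  if (!type %in% cells$cell_type)
    stop("unknown cell type for ", arg, ": '", type, "'", call. = FALSE)
}

#' Distance from each cell of one type to the nearest landmark cell
#'
#' For every cell of `query_type`, the Euclidean distance (micrometers) to
#' the nearest cell of `landmark_type` in the same field of view — e.g.
#' the shortest distance from each endothelial cell to the nearest
#' cholangiocyte, a proxy for distance to the portal tract. Query cells in
#' FOVs that contain no landmark cell get `NA` and are excluded from
#' summaries.
#'
#' @inheritParams directional_proximity
#' @param query_type Cell type whose per-cell distances are reported.
#' @param landmark_type Cell type serving as the spatial landmark; must
#'   differ from `query_type`.
#' @return A `spax_distances` tibble (`cell_id`, `fov_id`, `value`) with
#'   the measure recorded in attributes; summarize with [glance()].
#' @examples
#' cells <- tibble::tibble(cell_id = c("q", "l1", "l2"),
#'                         x_um = c(0, 3, 10), y_um = c(0, 4, 0),
#'                         fov_id = "f1",
#'                         cell_type = c("EC", "Chol", "Chol"))
#' nearest_landmark_distance(cells, "EC", "Chol")$value  # 5
#' @export
nearest_landmark_distance <- function(cells, query_type, landmark_type) {
  cells <- validate_cells(cells)
  assert_known_type(cells, query_type, "query_type")
  assert_known_type(cells, landmark_type, "landmark_type")
  if (query_type == landmark_type)
    stop("query_type and landmark_type must differ ",
         "(the nearest-landmark distance of a landmark to itself is 0 ",
         "everywhere)", call. = FALSE)

  q <- dplyr::filter(cells, .data$cell_type == query_type)
  value <- rep(NA_real_, nrow(q))
  for (f in unique(q$fov_id)) {
    qi <- which(q$fov_id == f)
    lm <- dplyr::filter(cells, .data$fov_id == f,
                        .data$cell_type == landmark_type)
    if (nrow(lm) == 0) {
      message("FOV ", f, " has no '", landmark_type,
              "' cells; its query cells are NA")
      next
    }
    d <- cross_dist(q$x_um[qi], q$y_um[qi], lm$x_um, lm$y_um)
    value[qi] <- apply(d, 1, min)
  }
  new_spax_distances(q, value, measure = "nearest_landmark_um",
                     query_type = query_type, landmark_type = landmark_type)
}

#' Count neighbors of one type within a radius of each cell of another
#'
#' For every cell of `center_type`, the number of `neighbor_type` cells at
#' Euclidean distance at most `radius_um` in the same field of view, the
#' center cell itself excluded — e.g. the number of macrophages within
#' 20 micrometers of each endothelial cell.
#'
#' @inheritParams directional_proximity
#' @param center_type Cell type at the center of each neighborhood.
#' @param neighbor_type Cell type being counted (may equal `center_type`).
#' @param radius_um Neighborhood radius in micrometers (default 20).
#' @return A `spax_distances` tibble of per-cell counts; [glance()] gives
#'   the mean count.
#' @export
neighbors_within_radius <- function(cells, center_type, neighbor_type,
                                    radius_um = 20) {
  cells <- validate_cells(cells)
  assert_known_type(cells, center_type, "center_type")
  assert_known_type(cells, neighbor_type, "neighbor_type")
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("radius_um must be positive", call. = FALSE)

  ctr <- dplyr::filter(cells, .data$cell_type == center_type)
  value <- rep(0, nrow(ctr))
  for (f in unique(ctr$fov_id)) {
    ci <- which(ctr$fov_id == f)
    nb <- dplyr::filter(cells, .data$fov_id == f,
                        .data$cell_type == neighbor_type)
    if (nrow(nb) == 0) next
    d <- cross_dist(ctr$x_um[ci], ctr$y_um[ci], nb$x_um, nb$y_um)
    self <- outer(ctr$cell_id[ci], nb$cell_id, "==")
    value[ci] <- rowSums(d <= radius_um & !self)
  }
  new_spax_distances(ctr, value, measure = "neighbor_count",
                     center_type = center_type, neighbor_type = neighbor_type,
                     radius_um = radius_um)
}

new_spax_distances <- function(cells, value, measure, ...) {
  out <- tibble::tibble(cell_id = cells$cell_id, fov_id = cells$fov_id,
                        value = value)
  structure(out, class = c("spax_distances", class(out)),
            measure = measure, params = list(...))
}

#' Summary statistics (mean, median, n) for per-cell distances/counts
#' @param x A `spax_distances` tibble.
#' @param ... Unused.
#' @method glance spax_distances
#' @export
glance.spax_distances <- function(x, ...) {
  v <- x$value[!is.na(x$value)]
  tibble::tibble(measure = attr(x, "measure"),
                 mean = mean(v), median = stats::median(v), n = length(v))
}

# distance from every cell to the nearest landmark-type cell (self
# excluded), for per-niche summaries where landmark cells are members too
landmark_dist_all_cells <- function(cells, landmark_type) {
  value <- rep(NA_real_, nrow(cells))
  for (f in unique(cells$fov_id)) {
    idx <- which(cells$fov_id == f)
    lm <- which(cells$fov_id == f & cells$cell_type == landmark_type)
    if (length(lm) == 0) next
    d <- cross_dist(cells$x_um[idx], cells$y_um[idx],
                    cells$x_um[lm], cells$y_um[lm])
    d[outer(cells$cell_id[idx], cells$cell_id[lm], "==")] <- Inf
    mins <- apply(d, 1, min)
    mins[!is.finite(mins)] <- NA_real_   # a lone landmark has no neighbor
    value[idx] <- mins
  }
  value
}
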