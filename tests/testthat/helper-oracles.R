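# Independent brute-force reference implementations (plain double loops,
# no shared code with the package internals) used as oracles.

euclid <- function(ax, ay, bx, by) sqrt((ax - bx)^2 + (ay - by)^2)

bf_nearest_landmark <- function(cells, query_type, landmark_type) {
  q <- cells[cells$cell_type == query_type, ]
  out <- rep(NA_real_, nrow(q))
  for (i in seq_len(nrow(q))) {
    best <- Inf
    for (j in seq_len(nrow(cells))) {
      if (cells$cell_type[j] != landmark_type) next
      if (cells$fov_id[j] != q$fov_id[i]) next
      d <- euclid(q$x_um[i], q$y_um[i], cells$x_um[j], cells$y_um[j])
      if (d < best) best <- d
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

bf_radius_count <- function(cells, center_type, neighbor_type, radius_um) {
  ctr <- cells[cells$cell_type == center_type, ]
  out <- integer(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    for (j in seq_len(nrow(cells))) {
      if (cells$cell_type[j] != neighbor_type) next
      if (cells$fov_id[j] != ctr$fov_id[i]) next
      if (cells$cell_id[j] == ctr$cell_id[i]) next
      d <- euclid(ctr$x_um[i], ctr$y_um[i], cells$x_um[j], cells$y_um[j])
      if (d <= radius_um) out[i] <- out[i] + 1L
    }
  }
  out
}

bf_proximity <- function(cells, bandwidth_um, normalize) {
  types <- sort(unique(cells$cell_type))
  n <- nrow(cells)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || cells$fov_id[i] != cells$fov_id[j]) next
    d <- euclid(cells$x_um[i], cells$y_um[i], cells$x_um[j], cells$y_um[j])
    w[i, j] <- exp(-d^2 / (2 * bandwidth_um^2))
  }
  included <- rep(TRUE, n)
  if (normalize) {
    for (i in seq_len(n)) {
      s <- sum(w[i, ])
      if (s == 0) included[i] <- FALSE else w[i, ] <- w[i, ] / s
    }
  }
  score <- matrix(NA_real_, length(types), length(types),
                  dimnames = list(types, types))
  for (s in types) {
    rows <- which(cells$cell_type == s & included)
    if (length(rows) == 0) next
    for (t in types) {
      cols <- which(cells$cell_type == t)
      score[s, t] <- mean(vapply(rows, function(i) sum(w[i, cols]),
                                 numeric(1)))
    }
  }
  score
}

bf_lr_score <- function(expr, cells, ligand, receptor,
                        source_type, target_type, bandwidth_um) {
  expr <- as.matrix(expr)
  keep <- rowSums(expr) > 0
  expr <- expr[keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  num <- 0; den <- 0
  for (i in seq_len(nrow(cells))) {
    if (cells$cell_type[i] != source_type) next
    for (j in seq_len(nrow(cells))) {
      if (cells$cell_type[j] != target_type) next
      if (cells$fov_id[j] != cells$fov_id[i]) next
      d <- euclid(cells$x_um[i], cells$y_um[i], cells$x_um[j], cells$y_um[j])
      w <- exp(-d^2 / (2 * bandwidth_um^2))
      num <- num + expr[i, ligand] * expr[j, receptor] * w
      den <- den + w
    }
  }
  if (den == 0) NA_real_ else num / den
}

bf_knn_composition <- function(cells, k_neighbors) {
  types <- sort(unique(cells$cell_type))
  comp <- matrix(0, nrow(cells), length(types),
                 dimnames = list(cells$cell_id, types))
  for (i in seq_len(nrow(cells))) {
    same <- which(cells$fov_id == cells$fov_id[i] &
                    cells$cell_id != cells$cell_id[i])
    d <- euclid(cells$x_um[i], cells$y_um[i],
                cells$x_um[same], cells$y_um[same])
    k <- min(k_neighbors, length(same))
    nn <- same[order(d, cells$cell_id[same])][seq_len(k)]
    for (t in cells$cell_type[nn])
      comp[i, t] <- comp[i, t] + 1 / k
  }
  comp
}

# random scattered cells across FOVs for property tests
random_cells <- function(n, n_types = 4, n_fovs = 2, fov_um = 200,
                         seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    fov_id = sample(sprintf("fov%d", seq_len(n_fovs)), n, replace = TRUE),
    x_um = stats::runif(n, 0, fov_um),
    y_um = stats::runif(n, 0, fov_um),
    cell_type = sample(LETTERS[seq_len(n_types)], n, replace = TRUE)
  ))
}

random_expr <- function(cells, genes, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(nrow(cells) * length(genes), 3),
                nrow(cells), length(genes),
                dimnames = list(cells$cell_id, genes))
    m
  })
}

# rigid transform: rotate all coordinates by theta about a point, then
# translate; preserves every within-FOV distance
rigid_transform <- function(cells, theta, dx, dy) {
  x <- cells$x_um; y <- cells$y_um
  cells$x_um <- cos(theta) * x - sin(theta) * y + dx
  cells$y_um <- sin(theta) * x + cos(theta) * y + dy
  cells
}
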