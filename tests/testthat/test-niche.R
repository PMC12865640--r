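test_that("composition closed forms: pure neighborhood and k = 1 one-hot", {
  # 1 center with 5 nearest all of type T, plus a far cell of type U
  cells <- tibble::tibble(
    cell_id = sprintf("c%d", 1:7),
    x_um = c(0, 1, 2, -1, -2, 1.5, 100), y_um = 0,
    fov_id = "f1",
    cell_type = c("C", "T", "T", "T", "T", "T", "U"))
  comp <- neighborhood_composition(cells, k_neighbors = 5)
  row1 <- comp[comp$cell_id == "c1", c("C", "T", "U")]
  expect_equal(as.numeric(row1), c(0, 1, 0))

  k1 <- neighborhood_composition(cells, k_neighbors = 1)
  expect_equal(as.numeric(k1[k1$cell_id == "c7", c("C", "T", "U")]),
               c(0, 1, 0))  # nearest neighbor of the far cell is type T
})

test_that("composition equals the brute-force k-NN oracle", {
  cells <- random_cells(300, n_types = 4, n_fovs = 2, seed = 73)
  comp <- neighborhood_composition(cells, k_neighbors = 12)
  mat <- as.matrix(comp[, LETTERS[1:4]])
  rownames(mat) <- comp$cell_id
  expect_equal(mat, bf_knn_composition(cells, 12), tolerance = 1e-12)
  expect_equal(unname(rowSums(mat)), rep(1, 300), tolerance = 1e-9)
})

test_that("k is truncated in small FOVs with a warning", {
  cells <- random_cells(8, n_types = 2, n_fovs = 1, seed = 79)
  expect_warning(comp <- neighborhood_composition(cells, k_neighbors = 30),
                 "truncated")
  expect_equal(unname(rowSums(as.matrix(comp[, c("A", "B")]))), rep(1, 8))
})

test_that("perfectly separated composition blocks are recovered exactly", {
  comp <- tibble::tibble(
    cell_id = sprintf("c%d", 1:40),
    T1 = c(rep(0.9, 20), rep(0.1, 20)),
    T2 = c(rep(0.1, 20), rep(0.9, 20)))
  model <- assign_niches(comp, n_niches = 2, seed = 3)
  lab <- model$niche_of$niche
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)
  expect_false(lab[1] == lab[40])
})

test_that("identical compositions collapse to a single niche", {
  comp <- tibble::tibble(cell_id = sprintf("c%d", 1:15), T1 = 0.5, T2 = 0.5)
  model <- suppressMessages(assign_niches(comp, n_niches = 4, seed = 1))
  expect_equal(length(model$sizes), 1)
  expect_true(all(model$niche_of$niche == "niche_1"))
})

test_that("niche labels are ordered by descending cluster size", {
  comp <- tibble::tibble(
    cell_id = sprintf("c%d", 1:30),
    T1 = c(rep(0.9, 5), rep(0.1, 25)),
    T2 = c(rep(0.1, 5), rep(0.9, 25)))
  model <- assign_niches(comp, n_niches = 2, seed = 7)
  expect_equal(unname(model$sizes), c(25, 5))
  expect_equal(unique(model$niche_of$niche[6:30]), "niche_1")
})

test_that("assignment is invariant to cell-row permutation and rigid motion", {
  cells <- random_cells(200, n_types = 3, n_fovs = 2, seed = 83)
  comp <- neighborhood_composition(cells, 10)
  m1 <- assign_niches(comp, 3, seed = 11)

  perm <- withr::with_seed(5, sample(nrow(cells)))
  comp_p <- neighborhood_composition(cells[perm, ], 10)
  m2 <- assign_niches(comp_p, 3, seed = 11)
  j <- dplyr::inner_join(m1$niche_of, m2$niche_of, by = "cell_id")
  expect_gt(mclust::adjustedRandIndex(j$niche.x, j$niche.y), 0.999)

  comp_r <- neighborhood_composition(rigid_transform(cells, 1.1, 50, -20), 10)
  m3 <- assign_niches(comp_r, 3, seed = 11)
  j2 <- dplyr::inner_join(m1$niche_of, m3$niche_of, by = "cell_id")
  expect_gt(mclust::adjustedRandIndex(j2$niche.x, j2$niche.y), 0.999)
})

test_that("n_niches larger than the cell count is an error", {
  comp <- tibble::tibble(cell_id = c("a", "b"), T1 = c(0, 1), T2 = c(1, 0))
  expect_error(assign_niches(comp, n_niches = 5, seed = 1), "exceeds")
})

test_that("niche summaries match an independent group-by recomputation", {
  sim <- generate_dataset(sim_config(n_fovs = 2, cells_per_fov = 150,
                                     genes = default_panel_genes(30),
                                     decoy_pairs = 5, seed = 19))
  norm <- suppressMessages(normalize_expression(sim$expr))
  # random niche assignment: summaries are pure group-bys
  model <- assign_niches(neighborhood_composition(sim$cells, 10), 3, seed = 2)
  withr::with_seed(4, {
    model$niche_of$niche <- sample(c("niche_1", "niche_2"),
                                   nrow(sim$cells), replace = TRUE)
  })
  out <- niche_summaries(model, sim$cells, norm, "Cholangiocytes",
                         gene_panel = c("IL1B", "CCL2"))

  joined <- dplyr::inner_join(sim$cells, model$niche_of, by = "cell_id")
  for (nn in unique(joined$niche)) {
    members <- joined[joined$niche == nn, ]
    # (a) proportions
    got_p <- out$proportions[out$proportions$niche == nn, ]
    for (tt in got_p$cell_type)
      expect_equal(got_p$proportion[got_p$cell_type == tt],
                   mean(members$cell_type == tt))
    expect_equal(sum(got_p$proportion), 1, tolerance = 1e-9)
    # (c) mean expression
    got_e <- out$expression[out$expression$niche == nn, ]
    expect_equal(got_e$mean_expression[got_e$gene == "IL1B"],
                 mean(norm[members$cell_id, "IL1B"]))
  }
})

test_that("single-niche proportions equal global type frequencies", {
  cells <- random_cells(100, n_types = 3, seed = 89)
  expr <- random_expr(cells, c("IL1B", "CCL2"), seed = 1)
  comp <- tibble::tibble(cell_id = cells$cell_id, T1 = 0.5, T2 = 0.5)
  model <- suppressMessages(assign_niches(comp, 2, seed = 1))
  out <- niche_summaries(model, cells, expr, "B", gene_panel = "IL1B")
  for (tt in LETTERS[1:3])
    expect_equal(
      out$proportions$proportion[out$proportions$cell_type == tt],
      mean(cells$cell_type == tt))
})

test_that("members all 10 um from a landmark average exactly 10", {
  cells <- tibble::tibble(
    cell_id = c("m1", "m2", "lm"),
    x_um = c(10, -10, 0), y_um = 0, fov_id = "f1",
    cell_type = c("T", "T", "Chol"))
  expr <- matrix(1, 3, 1, dimnames = list(cells$cell_id, "IL1B"))
  comp <- tibble::tibble(cell_id = cells$cell_id, a = 1)
  model <- suppressMessages(assign_niches(comp, 2, seed = 1))
  out <- niche_summaries(model, cells, expr, "Chol", gene_panel = "IL1B")
  # the two T cells are each 10 um from the landmark; the landmark itself
  # has no other landmark and is excluded
  expect_equal(out$landmark_distance$mean_distance_um, 10)
  expect_equal(out$landmark_distance$n, 2)
})

test_that("unknown panel genes are named in the error", {
  cells <- random_cells(30, n_types = 2, seed = 97)
  expr <- random_expr(cells, "IL1B")
  comp <- tibble::tibble(cell_id = cells$cell_id, a = 1)
  model <- suppressMessages(assign_niches(comp, 2, seed = 1))
  expect_error(niche_summaries(model, cells, expr, "B",
                               gene_panel = c("IL1B", "FAKE1")), "FAKE1")
})
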