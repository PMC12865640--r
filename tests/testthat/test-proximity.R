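test_that("nearest landmark distance matches closed forms", {
  cells <- tibble::tibble(
    cell_id = c("q", "l1", "l2"), x_um = c(0, 3, 10), y_um = c(0, 4, 0),
    fov_id = "f1", cell_type = c("EC", "Chol", "Chol"))
  expect_equal(nearest_landmark_distance(cells, "EC", "Chol")$value, 5)

  coincident <- tibble::tibble(cell_id = c("q", "l"), x_um = 7, y_um = 7,
                               fov_id = "f1", cell_type = c("EC", "Chol"))
  expect_equal(nearest_landmark_distance(coincident, "EC", "Chol")$value, 0)
})

test_that("landmark distance rejects ill-posed or unknown queries", {
  cells <- random_cells(20, n_types = 2)
  expect_error(nearest_landmark_distance(cells, "A", "A"), "differ")
  expect_error(nearest_landmark_distance(cells, "A", "Nope"), "Nope")
  expect_error(nearest_landmark_distance(cells, "Nope", "A"), "Nope")
})

test_that("landmark distances equal the double-loop oracle exactly", {
  cells <- random_cells(200, n_types = 2, n_fovs = 2, seed = 13)
  got <- nearest_landmark_distance(cells, "A", "B")
  expect_equal(got$value, bf_nearest_landmark(cells, "A", "B"),
               tolerance = 0)
})

test_that("radius counts match closed forms and exclude self", {
  cells <- tibble::tibble(
    cell_id = c("ctr", "n1", "n2", "n3"),
    x_um = c(0, 5, 19.9, 25), y_um = 0, fov_id = "f1",
    cell_type = c("EC", "Mac", "Mac", "Mac"))
  expect_equal(neighbors_within_radius(cells, "EC", "Mac", 20)$value, 2)

  lone <- tibble::tibble(cell_id = "only", x_um = 0, y_um = 0,
                         fov_id = "f1", cell_type = "Mac")
  expect_equal(neighbors_within_radius(lone, "Mac", "Mac", 20)$value, 0)
})

test_that("radius counts equal the double-loop oracle on a random instance", {
  cells <- random_cells(500, n_types = 3, n_fovs = 3, seed = 17)
  got <- neighbors_within_radius(cells, "A", "B", 25)
  expect_identical(as.integer(got$value), bf_radius_count(cells, "A", "B", 25))
  same <- neighbors_within_radius(cells, "B", "B", 25)
  expect_identical(as.integer(same$value), bf_radius_count(cells, "B", "B", 25))
})

test_that("proximity score closed forms: lone neighbor and equidistant split", {
  two <- tibble::tibble(cell_id = c("s", "t"), x_um = c(0, 30), y_um = 0,
                        fov_id = "f1", cell_type = c("S", "T"))
  p <- directional_proximity(two, bandwidth_um = 20, normalize = TRUE)
  expect_equal(p$score["S", "T"], 1)

  tri <- tibble::tibble(cell_id = c("s", "t1", "t2"),
                        x_um = c(0, 15, -15), y_um = 0, fov_id = "f1",
                        cell_type = c("S", "T1", "T2"))
  p2 <- directional_proximity(tri, bandwidth_um = 20, normalize = TRUE)
  expect_equal(p2$score["S", "T1"], 0.5)
  expect_equal(p2$score["S", "T2"], 0.5)
})

test_that("proximity matrix equals the brute-force oracle to 1e-12", {
  for (norm in c(TRUE, FALSE)) {
    cells <- random_cells(300, n_types = 4, n_fovs = 2, seed = 23)
    got <- directional_proximity(cells, bandwidth_um = 20, normalize = norm)
    expect_equal(got$score, bf_proximity(cells, 20, norm),
                 tolerance = 1e-12)
  }
})

test_that("normalized rows sum to 1 and the matrix is directional", {
  cells <- random_cells(250, n_types = 5, n_fovs = 2, seed = 29)
  p <- directional_proximity(cells, bandwidth_um = 15, normalize = TRUE)
  expect_equal(unname(rowSums(p$score)), rep(1, 5), tolerance = 1e-9)
  expect_false(isSymmetric(p$score))
})

test_that("cross-FOV weights are zero", {
  cells <- tibble::tibble(
    cell_id = c("s", "t_far", "t_other_fov"),
    x_um = c(0, 50, 1), y_um = 0,
    fov_id = c("f1", "f1", "f2"),
    cell_type = c("S", "T", "T"))
  # t_other_fov is 1 um away in coordinates but in another FOV: only the
  # 50-um same-FOV cell can receive weight
  p <- directional_proximity(cells, bandwidth_um = 20, normalize = TRUE)
  expect_equal(p$score["S", "T"], 1)
  un <- directional_proximity(cells, bandwidth_um = 20, normalize = FALSE)
  expect_equal(un$score["S", "T"], exp(-50^2 / (2 * 20^2)))
})

test_that("distance outputs are invariant under rigid transforms", {
  cells <- random_cells(200, n_types = 3, n_fovs = 2, seed = 31)
  moved <- rigid_transform(cells, theta = 0.83, dx = -120, dy = 450)
  expect_equal(nearest_landmark_distance(moved, "A", "B")$value,
               nearest_landmark_distance(cells, "A", "B")$value,
               tolerance = 1e-9)
  expect_equal(neighbors_within_radius(moved, "A", "C", 22)$value,
               neighbors_within_radius(cells, "A", "C", 22)$value)
  expect_equal(directional_proximity(moved, 20)$score,
               directional_proximity(cells, 20)$score, tolerance = 1e-9)
})

test_that("scaling all distances up never increases unnormalized scores", {
  cells <- random_cells(150, n_types = 3, seed = 37)
  base <- directional_proximity(cells, 20, normalize = FALSE)$score
  bigger <- cells
  bigger$x_um <- bigger$x_um * 1.7
  bigger$y_um <- bigger$y_um * 1.7
  scaled <- directional_proximity(bigger, 20, normalize = FALSE)$score
  expect_true(all(scaled <= base + 1e-12))
})

test_that("bad bandwidth and too-few cells are rejected", {
  cells <- random_cells(10)
  expect_error(directional_proximity(cells, bandwidth_um = 0), "bandwidth")
  expect_error(directional_proximity(cells[1, ], 20), "2 cells")
})

test_that("periportal cells sit closer to landmarks than distal cells", {
  pvals <- vapply(1:10, function(s) {
    sim <- generate_dataset(sim_config(n_fovs = 1, cells_per_fov = 250,
                                       genes = default_panel_genes(20),
                                       decoy_pairs = 4, seed = 100 + s))
    pp <- nearest_landmark_distance(sim$cells, "ECs_and_LSECs_1",
                                    "Cholangiocytes")$value
    di <- nearest_landmark_distance(sim$cells, "ECs_and_LSECs_3",
                                    "Cholangiocytes")$value
    stats::wilcox.test(pp, di, alternative = "less")$p.value
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})
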