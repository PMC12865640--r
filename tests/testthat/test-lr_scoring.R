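test_that("normalization gives rows summing to scale; zero cells flagged", {
  m <- matrix(c(2, 8,
                0, 0,
                1, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
  norm <- suppressMessages(normalize_expression(m, scale = 10))
  expect_equal(as.numeric(norm["c1", ]), c(2, 8))   # total already 10
  expect_equal(attr(norm, "zero_cells"), "c2")
  expect_equal(sum(norm["c2", ]), 0)

  r <- random_expr(random_cells(80), sprintf("g%02d", 1:15), seed = 6)
  rn <- suppressMessages(normalize_expression(r))
  sums <- Matrix::rowSums(rn)
  expect_true(all(abs(sums[Matrix::rowSums(r) > 0] - 1e4) < 1e-9))
})

test_that("single source-target pair cancels the kernel: score = xL * xR", {
  cells <- tibble::tibble(cell_id = c("s", "t"), x_um = c(0, 137.5),
                          y_um = 0, fov_id = "f1", cell_type = c("S", "T"))
  expr <- matrix(c(2, 0, 0, 3), 2,
                 dimnames = list(c("s", "t"), c("L", "R")))
  expect_equal(spatial_lr_score(expr, cells, "L", "R", "S", "T"), 6)
})

test_that("all-zero ligand in source cells gives score 0", {
  cells <- random_cells(60, n_types = 2, seed = 41)
  expr <- random_expr(cells, c("L", "R", "other"), seed = 2)
  expr[cells$cell_type == "A", "L"] <- 0
  expr[, "other"] <- 5   # keep totals positive
  expect_equal(spatial_lr_score(expr, cells, "L", "R", "A", "B"), 0)
})

test_that("self-self requests and missing genes error out explicitly", {
  cells <- random_cells(20, n_types = 2)
  expr <- random_expr(cells, c("L", "R"))
  expect_error(spatial_lr_score(expr, cells, "L", "R", "A", "A"),
               "self-self")
  expect_error(spatial_lr_score(expr, cells, "NOPE", "R", "A", "B"), "NOPE")
})

test_that("spatial LR score equals the double-loop oracle to 1e-10", {
  cells <- random_cells(200, n_types = 3, n_fovs = 2, seed = 43)
  expr <- random_expr(cells, c("L", "R", sprintf("g%d", 1:6)), seed = 3)
  norm <- suppressMessages(normalize_expression(expr))
  got <- spatial_lr_score(norm, cells, "L", "R", "A", "B", 20)
  ref <- bf_lr_score(norm, cells, "L", "R", "A", "B", 20)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("the score is bilinear in ligand expression", {
  cells <- random_cells(100, n_types = 2, seed = 47)
  expr <- random_expr(cells, c("L", "R", "pad"), seed = 4)
  expr[, "pad"] <- 1
  s1 <- spatial_lr_score(expr, cells, "L", "R", "A", "B")
  doubled <- expr
  doubled[cells$cell_type == "A", "L"] <- 2 * doubled[cells$cell_type == "A", "L"]
  expect_equal(spatial_lr_score(doubled, cells, "L", "R", "A", "B"), 2 * s1)
})

test_that("cells of uninvolved types do not change the score", {
  cells <- random_cells(120, n_types = 2, seed = 53)
  expr <- random_expr(cells, c("L", "R", "pad"), seed = 5)
  expr[, "pad"] <- 1
  base <- spatial_lr_score(expr, cells, "L", "R", "A", "B")
  extra_cells <- random_cells(40, n_types = 1, seed = 59)
  extra_cells$cell_id <- paste0("x", extra_cells$cell_id)
  extra_cells$cell_type <- "Z"
  aug <- dplyr::bind_rows(cells, extra_cells)
  aug_expr <- rbind(expr, random_expr(extra_cells, colnames(expr), seed = 7))
  rownames(aug_expr) <- aug$cell_id
  expect_equal(spatial_lr_score(aug_expr, aug, "L", "R", "A", "B"), base)
})

test_that("score_all covers every ordered direction exactly once", {
  cells <- random_cells(90, n_types = 3, seed = 61)
  pairs <- tibble::tibble(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                          pair_id = c("p1", "p2"))
  expr <- random_expr(cells, c("L1", "L2", "R1", "R2"), seed = 8)
  res <- spatial_lr_scores(expr, cells, pairs)
  expect_equal(nrow(res), 3 * 2 * 2)                 # 3 types, 2 pairs
  expect_false(any(res$source_type == res$target_type))

  # row-order invariance of the inputs
  shuffle <- withr::with_seed(10, sample(nrow(cells)))
  res2 <- spatial_lr_scores(expr[shuffle, ], cells[shuffle, ], pairs)
  key <- function(d) dplyr::arrange(tibble::as_tibble(d), source_type,
                                    target_type, pair_id)
  expect_equal(key(res2), key(res), tolerance = 1e-12)

  # per-direction scores agree with the single-pair entry point
  for (i in seq_len(nrow(res))) {
    expect_equal(res$score[i],
                 spatial_lr_score(expr, cells, res$ligand[i], res$receptor[i],
                                  res$source_type[i], res$target_type[i]),
                 tolerance = 1e-12)
  }
})

test_that("ranking sorts by score with lexicographic tie-breaks", {
  res <- structure(tibble::tibble(
    source_type = "S", target_type = "T",
    pair_id = c("A", "B", "C"), ligand = "l", receptor = "r",
    score = c(3, 1, 3), n_source = 5L, n_target = 5L),
    class = c("lr_score_result", class(tibble::tibble())))
  expect_identical(rank_lr_pairs(res, "S", "T")$pair_id, c("A", "C", "B"))
  expect_equal(nrow(rank_lr_pairs(res, "S", "T", top_n = 50)), 3)
  expect_error(rank_lr_pairs(res, "T", "S"), "not present")

  withr::with_seed(12, {
    res$score <- runif(3)
    expect_identical(rank_lr_pairs(res, "S", "T")$pair_id,
                     res$pair_id[order(-res$score, res$pair_id)])
  })
})

test_that("permutation p is 1 when the observed score matches every null", {
  # all cells identical expression: any relabeling gives the same score
  cells <- random_cells(40, n_types = 2, seed = 67)
  expr <- matrix(1, nrow(cells), 2,
                 dimnames = list(cells$cell_id, c("L", "R")))
  out <- lr_permutation_test(expr, cells, "L", "R", "A", "B",
                             n_perm = 49, seed = 2)
  expect_equal(out$perm_p, 1)
  expect_true(is.na(out$perm_z))   # degenerate null SD
})

test_that("permutation testing is deterministic given the seed", {
  cells <- random_cells(80, n_types = 2, seed = 71)
  expr <- random_expr(cells, c("L", "R"), seed = 9)
  a <- lr_permutation_test(expr, cells, "L", "R", "A", "B", n_perm = 49,
                           seed = 5)
  b <- lr_permutation_test(expr, cells, "L", "R", "A", "B", n_perm = 49,
                           seed = 5)
  expect_identical(a, b)
  expect_error(lr_permutation_test(expr, cells, "L", "R", "A", "B",
                                   n_perm = 5), "19")
})
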