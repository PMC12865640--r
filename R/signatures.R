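#' Gene-set signature score per cell
#'
#' The per-cell total expression over a gene set: the plain sum of
#' (normally library-normalized) expression values across the set's genes.
#' Genes absent from the matrix are skipped with a warning; a set with no
#' measurable gene is an error. The score is additive over disjoint sets
#' by construction.
#'
#' @param expr cells x genes matrix, normally from
#'   [normalize_expression()].
#' @param gene_set Character vector of gene names.
#' @param cells Optional cell table; when given, `group` can name one of
#'   its columns to attach a grouping label per cell.
#' @param group Optional column of `cells` used as the group label.
#' @param set_name Label stored in the result (default derived from the
#'   call).
#' @return A `geneset_score` tibble: `cell_id`, `score`, optional
#'   `group`; attributes record the set name and `n_genes_used`.
#' @export
geneset_score <- function(expr, gene_set, cells = NULL, group = NULL,
                          set_name = "gene_set") {
  present <- intersect(gene_set, colnames(expr))
  missing_genes <- setdiff(gene_set, present)
  if (length(present) == 0)
    stop("none of the ", length(gene_set),
         " set genes are in the expression matrix", call. = FALSE)
  if (length(missing_genes) > 0)
    warning(length(missing_genes), " set gene(s) not on the panel, skipped: ",
            paste(utils::head(missing_genes, 5), collapse = ", "))
  score <- Matrix::rowSums(expr[, present, drop = FALSE])
  out <- tibble::tibble(cell_id = rownames(expr), score = as.numeric(score))
  if (!is.null(cells) && !is.null(group)) {
    if (!group %in% names(cells))
      stop("grouping column '", group, "' not found in cells", call. = FALSE)
    out$group <- cells[[group]][match(out$cell_id, cells$cell_id)]
  }
  structure(out, class = c("geneset_score", class(tibble::tibble())),
            set_name = set_name, n_genes_used = length(present))
}

#' Compare signature scores between two groups
#'
#' Two-sided Mann-Whitney rank-sum comparison of per-cell scores between
#' two groups, with the difference of group means for direction.
#'
#' @param scores A `geneset_score` tibble with a `group` column (or any
#'   data frame with `score` and `group`).
#' @param group_a,group_b The two group labels to compare.
#' @return A one-row tibble: `diff_means` (mean A - mean B), `statistic`
#'   (Mann-Whitney U for group A), `p_value`, `n_a`, `n_b`.
#' @export
compare_scores <- function(scores, group_a, group_b) {
  if (!all(c("score", "group") %in% names(scores)))
    stop("scores must have 'score' and 'group' columns", call. = FALSE)
  a <- scores$score[scores$group == group_a]
  b <- scores$score[scores$group == group_b]
  if (length(a) == 0) stop("group '", group_a, "' is empty", call. = FALSE)
  if (length(b) == 0) stop("group '", group_b, "' is empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(diff_means = mean(a) - mean(b),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n_a = length(a), n_b = length(b))
}

#' Absolute monocyte-derived macrophage count from flow-cytometry yields
#'
#' Converts a total live non-parenchymal cell (NPC) yield and two gating
#' frequencies into an absolute MoMF count:
#' total live NPCs x (fraction CD45+ of live) x (fraction MoMF of CD45+),
#' rounded to the nearest whole cell.
#'
#' @param total_live_npcs Non-negative total live NPC count(s).
#' @param pct_cd45_of_live Fraction of live cells that are CD45+, in
#'   `[0, 1]`.
#' @param pct_momf_of_cd45 Fraction of CD45+ cells that are MoMFs, in
#'   `[0, 1]`.
#' @return Integer count(s).
#' @examples
#' momf_count(1e6, 0.5, 0.2)  # 100000
#' @export
momf_count <- function(total_live_npcs, pct_cd45_of_live, pct_momf_of_cd45) {
  if (any(total_live_npcs < 0))
    stop("total_live_npcs must be non-negative", call. = FALSE)
  for (frac in list(pct_cd45_of_live, pct_momf_of_cd45))
    if (any(frac < 0 | frac > 1))
      stop("gating fractions must lie in [0, 1]", call. = FALSE)
  as.integer(round(total_live_npcs * pct_cd45_of_live * pct_momf_of_cd45))
}
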