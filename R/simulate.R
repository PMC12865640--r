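#' Configuration for the synthetic CosMx-like dataset generator
#'
#' Builds a validated configuration object for [generate_dataset()]. The
#' generator emulates the gross statistical structure of an imaging-based
#' spatial transcriptomics run on liver tissue: a mosaic of rectangular
#' fields of view (FOVs), a landmark cell type (cholangiocyte-like, marking
#' portal tracts) clustered around one anchor point per FOV, an optional
#' periportal cell type whose density decays away from that anchor, counts
#' with log-normal library-size variation, and "planted" ligand-receptor
#' interactions: multiplicative up-regulation of a ligand in source-type
#' cells and of its receptor in target-type cells whenever the cell lies
#' within a stated range of a cell of the partner type.
#'
#' @param n_fovs Number of fields of view. FOVs tile a global grid of
#'   `fov_size_um`-sized squares, so global coordinates are well defined.
#' @param fov_size_um Side length of each square FOV, micrometers.
#' @param cells_per_fov Number of cells placed in each FOV.
#' @param cell_types Named numeric vector of cell-type abundance weights
#'   (need not sum to 1).
#' @param landmark_type Cell type clustered around the per-FOV anchor
#'   (emulates cholangiocytes at portal tracts). Must appear in
#'   `cell_types`.
#' @param periportal_type Cell type whose placement density decays with
#'   distance from the anchor under `zone_layout = "radial_gradient"`, and
#'   which shares the landmark's block under `"two_block"`.
#' @param zone_layout `"radial_gradient"` (periportal cells concentrate
#'   around the anchor) or `"two_block"` (two lateral blocks per FOV with
#'   distinct type composition; see Details).
#' @param genes Character vector of gene names in the panel.
#' @param baseline_rate Mean count per gene per unit library factor; a
#'   scalar (recycled) or a vector named by gene.
#' @param library_size_dispersion Standard deviation (log scale) of the
#'   per-cell log-normal library-size factor. 0 disables library variation.
#' @param planted_interactions Data frame with columns `ligand`,
#'   `receptor`, `source_type`, `target_type`, `effect_size` (>= 1) and
#'   `interaction_range_um` (> 0). Use `effect_size = 1` for a null.
#' @param decoy_pairs Number of additional non-planted ligand-receptor
#'   pairs added to the returned pair table, drawn from genes not used by
#'   any planted interaction.
#' @param periportal_radius_um Distance from the anchor that delimits the
#'   ground-truth "periportal" zone under `radial_gradient`; also sets the
#'   decay scale (half this value) of the periportal type's placement.
#' @param zone_bias Probability, under `two_block`, that a portal-associated
#'   cell (landmark or periportal type) is placed in block A and any other
#'   cell in block B.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @details Under `two_block`, block A spans x in `[0, 0.45] * fov_size_um`
#' and block B spans `[0.55, 1] * fov_size_um` of each FOV, with an
#' unpopulated margin between them; the anchor sits inside block A. The
#' ground-truth zone of every cell is the block it falls in.
#'
#' @return An object of class `spax_sim_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
sim_config <- function(n_fovs = 2,
                       fov_size_um = 500,
                       cells_per_fov = 300,
                       cell_types = c(Hepatocytes = 0.30, Macrophages = 0.20,
                                      ECs_and_LSECs_1 = 0.15, ECs_and_LSECs_3 = 0.15,
                                      HSCs = 0.08, T_cells = 0.07,
                                      Cholangiocytes = 0.05),
                       landmark_type = "Cholangiocytes",
                       periportal_type = "ECs_and_LSECs_1",
                       zone_layout = c("radial_gradient", "two_block"),
                       genes = default_panel_genes(),
                       baseline_rate = 2.5,
                       library_size_dispersion = 0.3,
                       planted_interactions = default_planted_interactions(),
                       decoy_pairs = 50,
                       periportal_radius_um = 100,
                       zone_bias = 0.9,
                       seed = 1L) {
  zone_layout <- match.arg(zone_layout)
  planted_interactions <- tibble::as_tibble(planted_interactions)

  stopifnot(
    "n_fovs must be a positive integer" = is_count(n_fovs),
    "cells_per_fov must be a positive integer" = is_count(cells_per_fov),
    "fov_size_um must be positive" = is.numeric(fov_size_um) && fov_size_um > 0,
    "cell_types must be a named vector of weights" =
      length(cell_types) > 0 && !is.null(names(cell_types)),
    "decoy_pairs must be a non-negative integer" =
      is_count(decoy_pairs) || decoy_pairs == 0,
    "zone_bias must lie in [0, 1]" = zone_bias >= 0 && zone_bias <= 1,
    "periportal_radius_um must be positive" = periportal_radius_um > 0
  )
  if (any(!is.finite(cell_types)) || any(cell_types < 0) || sum(cell_types) <= 0)
    stop("cell_types weights must be non-negative with a positive finite sum",
         call. = FALSE)
  if (!landmark_type %in% names(cell_types))
    stop("landmark_type '", landmark_type, "' is not in cell_types", call. = FALSE)
  if (!periportal_type %in% names(cell_types))
    stop("periportal_type '", periportal_type, "' is not in cell_types", call. = FALSE)
  if (anyDuplicated(genes))
    stop("gene names must be unique", call. = FALSE)

  need <- c("ligand", "receptor", "source_type", "target_type",
            "effect_size", "interaction_range_um")
  if (nrow(planted_interactions) > 0) {
    missing_cols <- setdiff(need, names(planted_interactions))
    if (length(missing_cols) > 0)
      stop("planted_interactions lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    bad_genes <- setdiff(c(planted_interactions$ligand,
                           planted_interactions$receptor), genes)
    if (length(bad_genes) > 0)
      stop("planted ligand/receptor gene(s) not in panel: ",
           paste(bad_genes, collapse = ", "), call. = FALSE)
    bad_types <- setdiff(c(planted_interactions$source_type,
                           planted_interactions$target_type), names(cell_types))
    if (length(bad_types) > 0)
      stop("planted source/target type(s) not in cell_types: ",
           paste(bad_types, collapse = ", "), call. = FALSE)
    if (any(planted_interactions$effect_size < 1))
      stop("effect_size must be >= 1", call. = FALSE)
    if (any(planted_interactions$interaction_range_um <= 0))
      stop("interaction_range_um must be > 0", call. = FALSE)
  }
  planted_genes <- unique(c(planted_interactions$ligand,
                            planted_interactions$receptor))
  if (length(setdiff(genes, planted_genes)) < 2 * decoy_pairs)
    stop("not enough non-planted genes to draw ", decoy_pairs,
         " decoy pairs", call. = FALSE)
  if (!is.numeric(baseline_rate) || any(baseline_rate <= 0))
    stop("baseline_rate must be positive", call. = FALSE)
  if (length(baseline_rate) > 1 && length(baseline_rate) != length(genes))
    stop("baseline_rate must be scalar or one value per gene", call. = FALSE)
  if (library_size_dispersion < 0)
    stop("library_size_dispersion must be non-negative", call. = FALSE)

  structure(list(
    n_fovs = as.integer(n_fovs), fov_size_um = fov_size_um,
    cells_per_fov = as.integer(cells_per_fov), cell_types = cell_types,
    landmark_type = landmark_type, periportal_type = periportal_type,
    zone_layout = zone_layout, genes = genes, baseline_rate = baseline_rate,
    library_size_dispersion = library_size_dispersion,
    planted_interactions = planted_interactions,
    decoy_pairs = as.integer(decoy_pairs),
    periportal_radius_um = periportal_radius_um, zone_bias = zone_bias,
    seed = as.integer(seed)
  ), class = "spax_sim_config")
}

#' Default gene panel for simulations
#'
#' A small stand-in for a 1000-plex panel: named liver
#' inflammation/fibrosis genes plus anonymous filler genes.
#'
#' @param n Total panel size (>= 12).
#' @return Character vector of gene names.
#' @export
default_panel_genes <- function(n = 120) {
  named <- c("IL1B", "IL1R1", "CCL2", "CCR2", "CXCL10", "CXCR3",
             "ITGAM", "COL1A1", "PECAM1", "LYVE1", "KRT19", "ALB")
  stopifnot(n >= length(named))
  c(named, sprintf("GENE%03d", seq_len(n - length(named))))
}

#' Default planted interaction: macrophage-derived IL1B to IL1R1 on a
#' periportal endothelial subset, effect 5 within 30 micrometers.
#' @return A one-row tibble in the `planted_interactions` layout.
#' @export
default_planted_interactions <- function() {
  tibble::tibble(ligand = "IL1B", receptor = "IL1R1",
                 source_type = "Macrophages",
                 target_type = "ECs_and_LSECs_1",
                 effect_size = 5, interaction_range_um = 30)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

#' Generate a synthetic spatial transcriptomics dataset
#'
#' Draws a complete dataset from a [sim_config()]: a per-cell metadata
#' table, a sparse cells-by-genes count matrix, a ligand-receptor pair
#' table (planted pairs plus decoys), and the ground truth used to plant
#' it. Fully deterministic given `config$seed`.
#'
#' The count model is Poisson with rate (per-cell library factor) x
#' (per-gene baseline); the library factor is log-normal with log-sd
#' `library_size_dispersion`, giving negative-binomial-like overdispersion
#' at the gene level. Planted interactions act multiplicatively on the
#' rate, never by editing counts, so normalization interacts with effects
#' the way it would in real data.
#'
#' @param config A `spax_sim_config` from [sim_config()].
#' @return An object of class `spax_sim`: a list with elements
#'   \describe{
#'     \item{cells}{tibble: `cell_id`, `x_um`, `y_um` (global frame),
#'       `fov_id`, `cell_type`, `region` (all `"non_tumor"`).}
#'     \item{expr}{sparse `dgCMatrix`, cells x genes, raw counts, rows in
#'       `cells` order.}
#'     \item{lr_pairs}{tibble: `ligand`, `receptor`, `pair_id`; planted
#'       pairs first, then decoys.}
#'     \item{truth}{list: `zones` (per-cell zone label and distance to the
#'       FOV anchor), `pairs` (per-pair planted flag), `anchors` (per-FOV
#'       anchor coordinates, global frame).}
#'   }
#' @examples
#' sim <- generate_dataset(sim_config(n_fovs = 1, cells_per_fov = 100,
#'                                    decoy_pairs = 5, seed = 42))
#' dplyr::count(sim$cells, cell_type)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "spax_sim_config"))
    config <- do.call(sim_config, config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  fov <- cfg$fov_size_um
  n_grid <- ceiling(sqrt(cfg$n_fovs))
  type_names <- names(cfg$cell_types)
  portal_types <- unique(c(cfg$landmark_type, cfg$periportal_type))

  per_fov <- vector("list", cfg$n_fovs)
  anchors <- vector("list", cfg$n_fovs)
  for (f in seq_len(cfg$n_fovs)) {
    off_x <- ((f - 1) %% n_grid) * fov
    off_y <- ((f - 1) %/% n_grid) * fov
    n <- cfg$cells_per_fov
    ct <- sample(type_names, n, replace = TRUE, prob = cfg$cell_types)

    if (cfg$zone_layout == "radial_gradient") {
      anchor <- stats::runif(2, 0.25 * fov, 0.75 * fov)
      x <- stats::runif(n, 0, fov)
      y <- stats::runif(n, 0, fov)
      lm <- ct == cfg$landmark_type
      if (any(lm)) {
        x[lm] <- stats::rnorm(sum(lm), anchor[1], 25)
        y[lm] <- stats::rnorm(sum(lm), anchor[2], 25)
      }
      pp <- ct == cfg$periportal_type
      if (any(pp)) {
        r <- stats::rexp(sum(pp), rate = 2 / cfg$periportal_radius_um)
        th <- stats::runif(sum(pp), 0, 2 * pi)
        x[pp] <- anchor[1] + r * cos(th)
        y[pp] <- anchor[2] + r * sin(th)
      }
      x <- pmin(pmax(x, 0), fov)
      y <- pmin(pmax(y, 0), fov)
      d_anchor <- sqrt((x - anchor[1])^2 + (y - anchor[2])^2)
      zone <- ifelse(d_anchor <= cfg$periportal_radius_um,
                     "periportal", "distal")
    } else { # two_block
      is_portal <- ct %in% portal_types
      in_a <- ifelse(is_portal,
                     stats::runif(n) < cfg$zone_bias,
                     stats::runif(n) >= cfg$zone_bias)
      x <- ifelse(in_a, stats::runif(n, 0, 0.45 * fov),
                  stats::runif(n, 0.55 * fov, fov))
      y <- stats::runif(n, 0, fov)
      anchor <- c(stats::runif(1, 0.1 * fov, 0.35 * fov),
                  stats::runif(1, 0.25 * fov, 0.75 * fov))
      lm <- ct == cfg$landmark_type & in_a
      if (any(lm)) {
        x[lm] <- pmin(pmax(stats::rnorm(sum(lm), anchor[1], 25), 0), 0.45 * fov)
        y[lm] <- pmin(pmax(stats::rnorm(sum(lm), anchor[2], 25), 0), fov)
      }
      d_anchor <- sqrt((x - anchor[1])^2 + (y - anchor[2])^2)
      zone <- ifelse(x < 0.5 * fov, "block_A", "block_B")
    }

    per_fov[[f]] <- tibble::tibble(
      cell_id = sprintf("f%02d_c%04d", f, seq_len(n)),
      x_um = x + off_x, y_um = y + off_y,
      fov_id = sprintf("fov_%02d", f),
      cell_type = ct, region = "non_tumor",
      .zone = zone, .d_anchor = d_anchor
    )
    anchors[[f]] <- tibble::tibble(fov_id = sprintf("fov_%02d", f),
                                   x_um = anchor[1] + off_x,
                                   y_um = anchor[2] + off_y)
  }
  cells_full <- dplyr::bind_rows(per_fov)
  zones <- tibble::tibble(cell_id = cells_full$cell_id,
                          zone = cells_full$.zone,
                          dist_to_anchor_um = cells_full$.d_anchor)
  cells <- dplyr::select(cells_full, -".zone", -".d_anchor")

  # expression: rate = library factor x per-gene baseline, planted effects
  # multiply the rate for cells within range of a partner-type cell
  n_cells <- nrow(cells)
  n_genes <- length(cfg$genes)
  lib <- if (cfg$library_size_dispersion > 0)
    exp(stats::rnorm(n_cells, 0, cfg$library_size_dispersion)) else rep(1, n_cells)
  base <- rep_len(cfg$baseline_rate, n_genes)
  rate <- outer(lib, base)
  dimnames(rate) <- list(cells$cell_id, cfg$genes)

  pl <- cfg$planted_interactions
  for (k in seq_len(nrow(pl))) {
    boost <- planted_boost_mask(cells, pl$source_type[k], pl$target_type[k],
                                pl$interaction_range_um[k])
    rate[boost$source, pl$ligand[k]] <-
      rate[boost$source, pl$ligand[k]] * pl$effect_size[k]
    rate[boost$target, pl$receptor[k]] <-
      rate[boost$target, pl$receptor[k]] * pl$effect_size[k]
  }

  counts <- matrix(stats::rpois(n_cells * n_genes, lambda = rate),
                   nrow = n_cells, dimnames = dimnames(rate))
  expr <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  # LR pair table: planted pairs first, then decoys on untouched genes
  planted_genes <- unique(c(pl$ligand, pl$receptor))
  planted_tbl <- if (nrow(pl) > 0) {
    tibble::tibble(ligand = pl$ligand, receptor = pl$receptor,
                   pair_id = paste(pl$ligand, pl$receptor, sep = "_"))
  } else tibble::tibble(ligand = character(), receptor = character(),
                        pair_id = character())
  decoy_tbl <- if (cfg$decoy_pairs > 0) {
    pool <- sample(setdiff(cfg$genes, planted_genes), 2 * cfg$decoy_pairs)
    lig <- pool[seq(1, length(pool), by = 2)]
    rec <- pool[seq(2, length(pool), by = 2)]
    tibble::tibble(ligand = lig, receptor = rec,
                   pair_id = paste(lig, rec, sep = "_"))
  } else planted_tbl[0, ]
  lr_pairs <- dplyr::distinct(dplyr::bind_rows(planted_tbl, decoy_tbl),
                              .data$pair_id, .keep_all = TRUE)

  truth <- list(
    zones = zones,
    pairs = tibble::tibble(pair_id = lr_pairs$pair_id,
                           planted = lr_pairs$pair_id %in% planted_tbl$pair_id),
    anchors = dplyr::bind_rows(anchors)
  )
  structure(list(cells = cells, expr = expr, lr_pairs = lr_pairs,
                 truth = truth, config = cfg),
            class = "spax_sim")
}

# cells of source_type within range of any target_type cell and vice
# versa, per FOV; used to decide which rates a planted interaction boosts
planted_boost_mask <- function(cells, source_type, target_type, range_um) {
  src_hit <- logical(nrow(cells))
  tgt_hit <- logical(nrow(cells))
  for (f in unique(cells$fov_id)) {
    in_f <- cells$fov_id == f
    si <- which(in_f & cells$cell_type == source_type)
    ti <- which(in_f & cells$cell_type == target_type)
    if (length(si) == 0 || length(ti) == 0) next
    d <- cross_dist(cells$x_um[si], cells$y_um[si],
                    cells$x_um[ti], cells$y_um[ti])
    near_t <- apply(d, 1, min) <= range_um
    near_s <- apply(d, 2, min) <= range_um
    src_hit[si[near_t]] <- TRUE
    tgt_hit[ti[near_s]] <- TRUE
  }
  list(source = src_hit, target = tgt_hit)
}

cross_dist <- function(x1, y1, x2, y2) {
  sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
}

#' @export
print.spax_sim <- function(x, ...) {
  cat("<spax_sim> ", nrow(x$cells), " cells, ",
      ncol(x$expr), " genes, ", length(unique(x$cells$fov_id)), " FOV(s), ",
      nrow(x$lr_pairs), " LR pairs (",
      sum(x$truth$pairs$planted), " planted)\n", sep = "")
  invisible(x)
}
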