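#' Configuration for an end-to-end analysis run
#'
#' Bundles every parameter of the pipeline — input source (a simulation
#' config or file paths), kernel bandwidth, neighborhood radius, niche
#' parameters, permutation depth and the master seed — into a validated
#' object for [run_pipeline()]. A seed is mandatory: no stage of the
#' pipeline is allowed an unseeded source of randomness.
#'
#' @param sim Optional [sim_config()] — when given, the run starts by
#'   generating a synthetic dataset.
#' @param cells_path,expr_path,pairs_path Input files (used when `sim` is
#'   `NULL`): cell CSV, expression MTX/CSV, LR pair TSV.
#' @param bandwidth_um Kernel bandwidth for proximity and LR scoring.
#' @param radius_um Radius for neighbor counts (default 20).
#' @param k_neighbors,n_niches Niche analysis parameters.
#' @param top_n Ranking depth for the focal direction.
#' @param n_perm Permutations for the focal direction's top pairs (0
#'   disables the permutation stage).
#' @param seed Master seed (required).
#' @param drop_tumor Drop `region == "tumor"` cells on input.
#' @param landmark_type Landmark cell type for distance summaries; taken
#'   from `sim` when omitted.
#' @param focal_source,focal_target The signaling direction highlighted in
#'   rankings, distance and radius summaries; defaults to the first
#'   planted interaction when `sim` is given.
#' @param gene_panel Genes summarized per niche.
#' @return A `spax_run_config` list.
#' @export
run_config <- function(sim = NULL, cells_path = NULL, expr_path = NULL,
                       pairs_path = NULL, bandwidth_um = 20, radius_um = 20,
                       k_neighbors = 30, n_niches = 6, top_n = 20,
                       n_perm = 0, seed = NULL, drop_tumor = TRUE,
                       landmark_type = NULL, focal_source = NULL,
                       focal_target = NULL,
                       gene_panel = c("CCL2", "CXCL10", "ITGAM", "CCR2",
                                      "COL1A1", "IL1B", "IL1R1")) {
  if (is.null(seed) || !is_count(abs(seed) + 1))
    stop("run_config requires an integer seed; unseeded runs are not allowed",
         call. = FALSE)
  for (p in list(bandwidth_um = bandwidth_um, radius_um = radius_um,
                 k_neighbors = k_neighbors, n_niches = n_niches,
                 top_n = top_n))
    if (!is.numeric(p) || p <= 0)
      stop("all numeric pipeline parameters must be positive", call. = FALSE)
  if (n_perm < 0) stop("n_perm must be >= 0", call. = FALSE)
  if (is.null(sim) && (is.null(cells_path) || is.null(expr_path) ||
                       is.null(pairs_path)))
    stop("either 'sim' or all three input paths must be given", call. = FALSE)
  if (!is.null(sim)) {
    landmark_type <- landmark_type %||% sim$landmark_type
    if (nrow(sim$planted_interactions) > 0) {
      focal_source <- focal_source %||% sim$planted_interactions$source_type[1]
      focal_target <- focal_target %||% sim$planted_interactions$target_type[1]
    }
  }
  structure(list(sim = sim, cells_path = cells_path, expr_path = expr_path,
                 pairs_path = pairs_path, bandwidth_um = bandwidth_um,
                 radius_um = radius_um, k_neighbors = as.integer(k_neighbors),
                 n_niches = as.integer(n_niches), top_n = as.integer(top_n),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 drop_tumor = drop_tumor, landmark_type = landmark_type,
                 focal_source = focal_source, focal_target = focal_target,
                 gene_panel = gene_panel),
            class = "spax_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; an optional
#' `sim:` block mirrors [sim_config()] (its `planted_interactions` as a
#' list of records).
#'
#' @param path YAML file.
#' @return A `spax_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$planted_interactions))
      y$sim$planted_interactions <-
        dplyr::bind_rows(lapply(y$sim$planted_interactions, tibble::as_tibble))
    if (!is.null(y$sim$cell_types))
      y$sim$cell_types <- unlist(y$sim$cell_types)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(run_config, y)
}

#' Run the full spatial crosstalk pipeline
#'
#' Executes simulate/read, validation, expression normalization,
#' directional proximity, spatial LR scoring (with optional permutation
#' significance on the focal direction's top pairs), landmark-distance
#' and radius-neighbor summaries, niche analysis and signature scoring,
#' writing every stage's table plus a machine-readable run manifest to
#' `out_dir`. Re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config A `spax_run_config` from [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "spax_run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stale_flag <- file.path(out_dir, "INCOMPLETE")
  file.create(stale_flag)
  counts <- list()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  data <- stage("input", {
    if (!is.null(config$sim)) {
      sim <- generate_dataset(config$sim)
      write_dataset(sim, file.path(out_dir, "data"))
      list(cells = validate_cells(sim$cells, drop_tumor = config$drop_tumor),
           expr = sim$expr, pairs = sim$lr_pairs)
    } else {
      cells <- read_cells(config$cells_path, drop_tumor = config$drop_tumor)
      list(cells = cells,
           expr = read_expression(config$expr_path, cells),
           pairs = read_lr_pairs(config$pairs_path))
    }
  })
  cells <- data$cells
  pairs <- filter_lr_pairs(data$pairs, colnames(data$expr))
  norm <- stage("normalize", normalize_expression(data$expr))
  counts$cells <- nrow(cells); counts$lr_pairs <- nrow(pairs)

  prox <- stage("proximity",
                directional_proximity(cells, config$bandwidth_um))
  readr::write_tsv(tidy(prox), file.path(out_dir, "proximity.tsv"))
  counts$proximity <- nrow(tidy(prox))

  scores <- stage("lr_score",
                  spatial_lr_scores(norm, cells, pairs, config$bandwidth_um))
  out_scores <- tibble::as_tibble(scores)
  out_scores$perm_z <- NA_real_
  out_scores$perm_p <- NA_real_

  if (config$n_perm > 0 && !is.null(config$focal_source)) {
    top <- rank_lr_pairs(scores, config$focal_source, config$focal_target,
                         config$top_n)
    perms <- stage("permutation", purrr::map_dfr(seq_len(nrow(top)), function(i) {
      lr_permutation_test(norm, cells, top$ligand[i], top$receptor[i],
                          config$focal_source, config$focal_target,
                          config$bandwidth_um, config$n_perm,
                          seed = config$seed + i)
    }))
    hit <- match(paste(config$focal_source, config$focal_target, top$pair_id),
                 paste(out_scores$source_type, out_scores$target_type,
                       out_scores$pair_id))
    out_scores$perm_z[hit] <- perms$perm_z
    out_scores$perm_p[hit] <- perms$perm_p
  }
  readr::write_tsv(out_scores[, c("source_type", "target_type", "pair_id",
                                  "ligand", "receptor", "score", "n_source",
                                  "n_target", "perm_z", "perm_p")],
                   file.path(out_dir, "lr_scores.tsv"))
  counts$lr_scores <- nrow(out_scores)

  summaries <- list()
  if (!is.null(config$landmark_type) && !is.null(config$focal_target)) {
    ld <- stage("landmark_distance",
                nearest_landmark_distance(cells, config$focal_target,
                                          config$landmark_type))
    readr::write_tsv(ld, file.path(out_dir, "landmark_distance.tsv"))
    rc <- stage("radius_count",
                neighbors_within_radius(cells, config$focal_target,
                                        config$focal_source,
                                        config$radius_um))
    readr::write_tsv(rc, file.path(out_dir, "radius_counts.tsv"))
    summaries <- list(landmark_distance = ld, radius_counts = rc)
    counts$landmark_distance <- nrow(ld)
    counts$radius_counts <- nrow(rc)
  }

  comp <- stage("niche_composition",
                neighborhood_composition(cells, config$k_neighbors))
  model <- stage("niche_assign",
                 assign_niches(comp, config$n_niches, seed = config$seed))
  readr::write_csv(model$niche_of, file.path(out_dir, "niches.csv"))
  counts$niches <- length(model$sizes)
  niche_tabs <- NULL
  if (!is.null(config$landmark_type)) {
    panel <- intersect(config$gene_panel, colnames(norm))
    if (length(panel) > 0) {
      niche_tabs <- stage("niche_summaries",
                          niche_summaries(model, cells, norm,
                                          config$landmark_type, panel))
      readr::write_tsv(niche_tabs$proportions,
                       file.path(out_dir, "niche_proportions.tsv"))
      readr::write_tsv(niche_tabs$landmark_distance,
                       file.path(out_dir, "niche_landmark_distance.tsv"))
      readr::write_tsv(niche_tabs$expression,
                       file.path(out_dir, "niche_expression.tsv"))
    }
  }

  manifest <- list(
    package = "spaxtalk",
    version = as.character(utils::packageVersion("spaxtalk")),
    parameters = config[setdiff(names(config), "sim")],
    sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    input_checksums = {
      files <- sort(list.files(file.path(out_dir, "data"), full.names = TRUE))
      cs <- tools::md5sum(files)
      names(cs) <- basename(files)
      as.list(cs)
    },
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  file.remove(stale_flag)
  invisible(list(cells = cells, expr = norm, pairs = pairs, proximity = prox,
                 lr_scores = scores, summaries = summaries,
                 niche_model = model, niche_summaries = niche_tabs,
                 manifest = manifest))
}
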