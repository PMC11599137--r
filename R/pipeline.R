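# Reproducible end-to-end runs tying the stages together: simulate a
# synthetic dataset to disk, run the morphometric pipeline over label
# TIFFs, and run the gene-prioritization pipeline over tables.  Each run
# writes a manifest (inputs, config, seeds, file hashes, package version)
# sufficient to reproduce deterministic outputs bit-for-bit.

write_manifest <- function(dir, kind, config, files) {
  manifest <- list(
    kind = kind,
    package = "gscmorph",
    version = as.character(utils::packageVersion("gscmorph")),
    config = config,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Simulate a synthetic dataset to disk
#'
#' Writes single-cell masks (16-bit TIFF + ground-truth JSON sidecars), a
#' time-lapse track table and omics tables (CSV), and a manifest with the
#' seeds and file hashes.  Fixed seeds give byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_cells Number of synthetic cell masks.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param track_spec A [track_sim_spec()] (default conditions when `NULL`).
#' @param omics_spec An [omics_sim_spec()] (defaults when `NULL`).
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(out_dir, n_cells = 20L, seed = 1L,
                         track_spec = NULL, omics_spec = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  files <- character(0)
  for (i in seq_len(n_cells)) {
    cell_seed <- seed * 10000L + i
    g <- generate_cell_mask(random_cell_spec(seed = cell_seed),
                            seed = cell_seed)
    tf <- sprintf("cell_%03d.tif", i)
    write_label_tiff(label_image(matrix(as.integer(g$mask), nrow(g$mask))),
                     file.path(out_dir, tf))
    gt <- g$ground_truth
    gt$tips <- NULL  # data.frame; keep sidecar flat
    gt$centerlines <- NULL
    gt$soma_boundary <- NULL
    jsonlite::write_json(gt, file.path(out_dir, sprintf("cell_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, tf, sprintf("cell_%03d.json", i),
               paste0(tf, ".meta.json"))
  }
  if (is.null(track_spec)) track_spec <- track_sim_spec(seed = seed)
  tracks <- generate_tracks(track_spec)
  utils::write.csv(tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  if (is.null(omics_spec)) omics_spec <- omics_sim_spec(seed = seed)
  om <- generate_omics_tables(omics_spec)
  utils::write.csv(data.frame(gene = rownames(om$expression), om$expression),
                   file.path(out_dir, "expression.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = rownames(om$dependency), om$dependency),
                   file.path(out_dir, "dependency.csv"), row.names = FALSE)
  writeLines(om$core_fitness, file.path(out_dir, "core_fitness.txt"))
  writeLines(om$anchors$essential, file.path(out_dir, "anchors_essential.txt"))
  writeLines(om$anchors$nonessential,
             file.path(out_dir, "anchors_nonessential.txt"))
  files <- c(files, "tracks.csv", "expression.csv", "dependency.csv",
             "core_fitness.txt", "anchors_essential.txt",
             "anchors_nonessential.txt")
  invisible(write_manifest(out_dir, "simulate",
                           list(n_cells = n_cells, seed = seed), files))
}

#' Run the morphometric pipeline over label TIFFs
#'
#' Reads every `*.tif` label mask in `in_dir`, extracts centered cell
#' crops, computes shape features, protrusion metrics, Sholl profiles and
#' morphoclass labels, and writes one joined per-cell table plus a
#' long-format Sholl table.
#'
#' @param in_dir Directory of label TIFFs.
#' @param out_dir Output directory.
#' @param pixel_size_um Pixel size fallback when a mask has no metadata.
#' @param prune_um,min_protrusion_um,sholl_step_um Skeleton settings (see
#'   [build_skeleton()], [sholl_profile()]).
#' @param cfg A [classifier_config()].
#' @param min_area_px Crop area filter.
#' @return Invisibly, the manifest path.  Per-stage kept/flagged counts are
#'   reported via `message()`.
#' @export
run_morpho <- function(in_dir, out_dir, pixel_size_um = NULL, prune_um = 4,
                       min_protrusion_um = 5, sholl_step_um = 5,
                       cfg = classifier_config(), min_area_px = 50L) {
  tifs <- sort(list.files(in_dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(tifs) == 0L) stopf("no TIFF files in %s", in_dir)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  per_cell <- NULL; sholl_long <- NULL
  n_flagged <- 0L
  for (tf in tifs) {
    img <- read_label_tiff(tf)
    if (!is.null(pixel_size_um)) img$pixel_size_um <- pixel_size_um
    crops <- extract_cell_crops(img, min_area_px = min_area_px)
    for (cr in crops) {
      if (cr$border || cr$multi_component) { n_flagged <- n_flagged + 1L; next }
      shape <- compute_shape_features(cr)
      res <- analyze_protrusions(cr, prune_um = prune_um,
                                 min_protrusion_um = min_protrusion_um,
                                 sholl_step_um = sholl_step_um)
      cls <- classify_morphoclass(shape, res$metrics, res$soma, cfg,
                                  pixel_size_um = cr$pixel_size_um)
      cell <- sprintf("%s#%d", basename(tf), cr$source_label)
      per_cell <- rbind(per_cell, data.frame(
        cell = cell, file = basename(tf), label = cr$source_label,
        area_um2 = shape$area_um2, perimeter_um = shape$perimeter_um,
        major_axis_um = shape$major_axis_um,
        minor_axis_um = shape$minor_axis_um,
        eccentricity = shape$eccentricity, axis_ratio = shape$axis_ratio,
        n_primary = res$metrics$n_primary, n_total = res$metrics$n_total,
        avg_length_um = res$metrics$avg_length_um,
        max_length_um = res$metrics$max_length_um,
        branching_index = res$metrics$branching_index,
        morphoclass = cls))
      sholl_long <- rbind(sholl_long, data.frame(
        cell = cell, radius_um = res$sholl$radii_um,
        intersections = res$sholl$intersections))
    }
  }
  message(sprintf("analyzed %d cell(s); %d flagged (border/multi-component) skipped",
                  if (is.null(per_cell)) 0L else nrow(per_cell), n_flagged))
  utils::write.csv(per_cell, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(sholl_long, file.path(out_dir, "sholl.csv"), row.names = FALSE)
  invisible(write_manifest(out_dir, "morpho",
                           list(prune_um = prune_um,
                                min_protrusion_um = min_protrusion_um,
                                sholl_step_um = sholl_step_um,
                                min_area_px = min_area_px,
                                classifier = unclass(cfg)),
                           c("cells.csv", "sholl.csv")))
}

#' Run the gene-prioritization pipeline over tables on disk
#'
#' @param expression_csv,dependency_csv CSV tables, first column `gene`,
#'   remaining columns cell lines.
#' @param shared_genes One-symbol-per-line text file of candidate genes.
#' @param core_fitness,anchors_essential,anchors_nonessential Gene-list
#'   files.
#' @param out_dir Output directory.
#' @param seed Seed for the mixture gate.
#' @param enrichment Optional `c(N =, n =, k =, x =)` for a hypergeometric
#'   enrichment summary.
#' @return Invisibly, the `prioritization` object; writes `report.csv` and
#'   `summary.json`.
#' @export
run_prioritize <- function(expression_csv, dependency_csv, shared_genes,
                           core_fitness, anchors_essential,
                           anchors_nonessential, out_dir, seed = 1L,
                           enrichment = NULL) {
  read_mat <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1L] != "gene")
      stopf("%s: first column must be `gene` (line 1)", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stopf("%s: non-numeric values in matrix body", path)
    rownames(m) <- df$gene
    m
  }
  expr <- read_mat(expression_csv)
  dep <- read_mat(dependency_csv)
  shared <- gene_set(readLines(shared_genes))
  core <- gene_set(readLines(core_fitness))
  anch <- list(essential = gene_set(readLines(anchors_essential)),
               nonessential = gene_set(readLines(anchors_nonessential)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  pr <- prioritize_genes(shared, expr, dep, core, anch, seed = seed)
  utils::write.csv(pr$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  summary <- list(
    n_shared = length(shared), n_missing = length(pr$missing_genes),
    n_gated_high = length(pr$gated_high),
    n_core_excluded = length(pr$excluded_core),
    n_ranked = nrow(pr$report),
    top_gene = if (nrow(pr$report)) pr$report$gene[1L] else NA,
    seed = seed)
  if (!is.null(enrichment)) {
    p <- hypergeom_upper_tail(enrichment[["N"]], enrichment[["n"]],
                              enrichment[["k"]], enrichment[["x"]])
    summary$enrichment <- c(as.list(enrichment), list(p_value = p))
    message(sprintf("hypergeometric enrichment: p = %.3g", p))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "prioritize", list(seed = seed),
                 c("report.csv", "summary.json"))
  invisible(pr)
}
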