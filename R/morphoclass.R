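# The four-morphoclass taxonomy (nonpolar, flat polar, circular multipolar,
# elongated), its rule-based assignment from quantitative features, and the
# time-lapse statistics: interphase transition and mitotic inheritance
# matrices, mitotic somal translocation, tumor-tumor-connection density and
# the neurosphere invasion index.

#' Classifier configuration
#'
#' Thresholds for the rule-based morphoclass assignment.  The class
#' definitions in the source taxonomy are qualitative ("long and thin",
#' "many short protrusions", "big and flat cell body"); these defaults
#' operationalize them and are freely configurable.
#'
#' @param ecc_threshold Eccentricity at or above which a cell counts as
#'   elongated (default 0.85).
#' @param long_protrusion_factor A protrusion longer than this multiple of
#'   the soma equivalent diameter also makes the cell elongated (default 2).
#' @param multipolar_min_primary Minimum primary protrusions for circular
#'   multipolar (default 3).
#' @param flat_area_um2_threshold Cell area at or above which a
#'   non-elongated cell is flat polar rather than circular multipolar
#'   (default 1000 um^2).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(ecc_threshold = 0.85, long_protrusion_factor = 2,
                              multipolar_min_primary = 3L,
                              flat_area_um2_threshold = 1000) {
  if (ecc_threshold <= 0 || ecc_threshold >= 1)
    stopf("`ecc_threshold` must be in (0, 1)")
  check_number(long_protrusion_factor, "long_protrusion_factor", 0, TRUE)
  check_number(multipolar_min_primary, "multipolar_min_primary", 0, TRUE)
  check_number(flat_area_um2_threshold, "flat_area_um2_threshold", 0, TRUE)
  structure(list(ecc_threshold = ecc_threshold,
                 long_protrusion_factor = long_protrusion_factor,
                 multipolar_min_primary = as.integer(multipolar_min_primary),
                 flat_area_um2_threshold = flat_area_um2_threshold),
            class = "classifier_config")
}

#' Assign a morphoclass from quantitative features
#'
#' Rule cascade, first match wins:
#' 1. nonpolar: no primary protrusion;
#' 2. elongated: eccentricity >= `ecc_threshold` OR longest protrusion >=
#'    `long_protrusion_factor` x soma equivalent diameter;
#' 3. circular multipolar: >= `multipolar_min_primary` primaries, below the
#'    eccentricity threshold, and area < `flat_area_um2_threshold`;
#' 4. otherwise flat polar.
#'
#' @param shape A `shape_features` object.
#' @param prot A `protrusion_metrics` object for the same cell.
#' @param soma The cell's `soma_model`.
#' @param cfg A [classifier_config()].
#' @param pixel_size_um Pixel size used for the soma equivalent diameter.
#' @return One of [morphoclass_levels()].
#' @export
classify_morphoclass <- function(shape, prot, soma,
                                 cfg = classifier_config(),
                                 pixel_size_um = 1) {
  stopifnot(inherits(shape, "shape_features"),
            inherits(prot, "protrusion_metrics"),
            inherits(soma, "soma_model"))
  if (prot$n_primary == 0L) return("nonpolar")
  if (is.na(prot$max_length_um))
    stopf("max protrusion length undefined with %d primary protrusion(s)",
          prot$n_primary)
  soma_equiv_diam_um <- 2 * sqrt(sum(soma$soma_mask) / pi) * pixel_size_um
  if (shape$eccentricity >= cfg$ecc_threshold ||
      prot$max_length_um >= cfg$long_protrusion_factor * soma_equiv_diam_um)
    return("elongated")
  if (prot$n_primary >= cfg$multipolar_min_primary &&
      shape$area_um2 < cfg$flat_area_um2_threshold)
    return("circular_multipolar")
  "flat_polar"
}

#' Morphoclass distribution with replicate-level SEM
#'
#' @param labels_by_replicate List (one element per replicate) of character
#'   vectors of morphoclass labels; or, for several groups, a named list of
#'   such lists.
#' @return data.frame with one row per (group x) class: proportion mean
#'   over replicates and SEM.  Empty replicates are flagged and excluded.
#' @export
morphoclass_distribution <- function(labels_by_replicate) {
  lv <- morphoclass_levels()
  grouped <- is.list(labels_by_replicate[[1L]])
  groups <- if (grouped) labels_by_replicate else list(all = labels_by_replicate)
  out <- NULL
  for (gname in names(groups)) {
    reps <- groups[[gname]]
    props <- lapply(reps, function(r) {
      if (length(r) == 0L) return(NULL)  # empty replicate: excluded
      bad <- setdiff(unique(r), lv)
      if (length(bad)) stopf("unknown morphoclass label(s): %s",
                             paste(bad, collapse = ", "))
      as.vector(table(factor(r, levels = lv))) / length(r)
    })
    dropped <- sum(vapply(props, is.null, logical(1)))
    if (dropped > 0L)
      warning(sprintf("group '%s': %d empty replicate(s) excluded", gname,
                      dropped), call. = FALSE)
    props <- do.call(rbind, props)
    if (is.null(props)) next
    m <- colMeans(props)
    sem <- if (nrow(props) > 1L)
      apply(props, 2L, stats::sd) / sqrt(nrow(props)) else rep(NA_real_, 4L)
    out <- rbind(out, data.frame(group = gname, class = lv, proportion = m,
                                 sem = sem, n_replicates = nrow(props)))
  }
  rownames(out) <- NULL
  out
}

validate_tracks <- function(tracks) {
  need <- c("cell_id", "frame", "class", "mitosis")
  if (!all(need %in% names(tracks)))
    stopf("track table must have columns %s", paste(need, collapse = ", "))
  ord <- order(tracks$cell_id, tracks$frame)
  tracks <- tracks[ord, ]
  if (any(unlist(tapply(tracks$frame, tracks$cell_id, function(f) diff(f) <= 0))))
    stopf("frames must be strictly increasing within each cell_id")
  tracks
}

new_transition_matrix <- function(counts) {
  lv <- morphoclass_levels()
  dimnames(counts) <- list(from = lv, to = lv)
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, proportions = props, row_totals = rs),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("<transition_matrix> counts:\n"); print(x$counts)
  cat("proportions (rows sum to 1; empty rows NA):\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Interphase morphoclass transition matrix
#'
#' Counts frame-to-frame class steps within each track, excluding the step
#' into a mitosis-flagged frame; proportions are row-normalized.  Also
#' reports, per starting class, the fraction of cells that acquire at least
#' one new morphology during their interphase lifetime (any frame-to-frame
#' class change counts).
#'
#' @param tracks Track table (see [generate_tracks()] for the column
#'   contract).
#' @return A `transition_matrix` with an extra field `fraction_changing`
#'   (per-class named vector) and `n_cells_per_class`.
#' @export
interphase_transitions <- function(tracks) {
  tracks <- validate_tracks(tracks)
  lv <- morphoclass_levels()
  counts <- matrix(0L, 4L, 4L)
  changed <- stats::setNames(numeric(4L), lv)
  totals <- stats::setNames(numeric(4L), lv)
  for (df in split(tracks, tracks$cell_id)) {
    n <- nrow(df)
    first_class <- df$class[1L]
    totals[first_class] <- totals[first_class] + 1
    any_change <- FALSE
    if (n >= 2L) for (i in seq_len(n - 1L)) {
      if (df$mitosis[i + 1L]) next  # step into mitosis excluded
      a <- match(df$class[i], lv); b <- match(df$class[i + 1L], lv)
      counts[a, b] <- counts[a, b] + 1L
      if (a != b) any_change <- TRUE
    }
    if (any_change) changed[first_class] <- changed[first_class] + 1
  }
  out <- new_transition_matrix(counts)
  out$fraction_changing <- ifelse(totals == 0, NA_real_, changed / totals)
  out$n_cells_per_class <- totals
  out
}

#' Mitotic inheritance matrix
#'
#' `counts[i, j]` = daughters of class `j` (at their first post-mitosis
#' frame) born to mothers of class `i` (at the mitosis-flagged frame, the
#' mother's last).  Denominators (mothers and daughters per class) are
#' reported.
#'
#' @param tracks Track table with `parent_id` linking daughters to mothers.
#' @return A `transition_matrix` with extra fields `n_mothers_per_class`
#'   and `n_daughters_per_class`.
#' @export
mitotic_inheritance <- function(tracks) {
  tracks <- validate_tracks(tracks)
  lv <- morphoclass_levels()
  moms <- tracks[tracks$mitosis, ]
  if (any(duplicated(moms$cell_id)))
    stopf("cell(s) with more than one mitosis-flagged row: %s",
          paste(unique(moms$cell_id[duplicated(moms$cell_id)]), collapse = ", "))
  kids_first <- do.call(rbind, lapply(
    split(tracks[!is.na(tracks$parent_id), ], tracks$cell_id[!is.na(tracks$parent_id)]),
    function(df) df[1L, ]))
  if (!is.null(kids_first)) {
    orphan <- setdiff(kids_first$parent_id, moms$cell_id)
    if (length(orphan))
      stopf("daughter track(s) whose parent has no mitosis row: parent id(s) %s",
            paste(orphan, collapse = ", "))
  }
  counts <- matrix(0L, 4L, 4L)
  n_mothers <- stats::setNames(integer(4L), lv)
  for (i in seq_len(nrow(moms))) {
    mc <- match(moms$class[i], lv)
    n_mothers[mc] <- n_mothers[mc] + 1L
    kids <- kids_first[kids_first$parent_id == moms$cell_id[i], , drop = FALSE]
    if (nrow(kids) == 0L)
      stopf("mitosis-flagged cell %s has no daughter tracks", moms$cell_id[i])
    for (k in seq_len(nrow(kids)))
      counts[mc, match(kids$class[k], lv)] <- counts[mc, match(kids$class[k], lv)] + 1L
  }
  out <- new_transition_matrix(counts)
  out$n_mothers_per_class <- n_mothers
  out$n_daughters_per_class <- rowSums(counts)
  out
}

#' Mitotic somal translocation (MST) length
#'
#' The distance the nucleus travels during the time step immediately
#' preceding mitosis, in micrometres.
#'
#' @param track Track rows for one mother cell (must contain one
#'   mitosis-flagged frame).
#' @param pixel_size_um Pixel size.
#' @return MST length in um, or `NA` (with a warning) when the mitosis is
#'   at the track's first frame.
#' @export
mst_length <- function(track, pixel_size_um = 1) {
  track <- track[order(track$frame), ]
  i <- which(track$mitosis)
  if (length(i) != 1L) stopf("track must contain exactly one mitosis-flagged frame")
  if (i == 1L) {
    warning("mitosis at the first tracked frame: MST undefined", call. = FALSE)
    return(NA_real_)
  }
  sqrt((track$x_px[i] - track$x_px[i - 1L])^2 +
       (track$y_px[i] - track$y_px[i - 1L])^2) * pixel_size_um
}

#' Tumor-tumor connection (microtube) density
#'
#' Number of microtubes per 100 um of cell perimeter, expressed per cell.
#'
#' @param n_connections Integer count of connections (>= 0).
#' @param perimeter_um Cell perimeter in micrometres (> 0).
#' @return Density (connections per 100 um perimeter).
#' @export
ttc_density <- function(n_connections, perimeter_um) {
  if (any(n_connections < 0)) stopf("`n_connections` must be >= 0")
  if (any(perimeter_um <= 0)) stopf("`perimeter_um` must be > 0")
  n_connections / perimeter_um * 100
}

#' Neurosphere invasion index
#'
#' Ratio between the total area of the neurosphere (core plus outgrowths)
#' and the area of its core; >= 1 and increasing with invasion.  Set
#' `reciprocal = TRUE` for the core/total orientation.
#'
#' @param core_area,total_area Areas in consistent units,
#'   `0 < core_area <= total_area`.
#' @param reciprocal Return core/total instead of total/core.
#' @return Invasion index.
#' @export
invasion_index <- function(core_area, total_area, reciprocal = FALSE) {
  if (any(core_area <= 0)) stopf("`core_area` must be > 0")
  if (any(core_area > total_area))
    stopf("`core_area` cannot exceed `total_area`")
  if (reciprocal) core_area / total_area else total_area / core_area
}
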