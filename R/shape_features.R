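# Whole-cell shape descriptors from a binary mask: area, traced-boundary
# perimeter, moment-equivalent-ellipse axes, eccentricity and axis ratio.

# Clockwise Moore neighbourhood (image rows increase downward).
MOORE <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
               dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# Boundary length by Moore-neighbour contour tracing (clockwise radial
# sweep); orthogonal steps count 1, diagonal steps sqrt(2).  `mask` must
# hold one 8-connected component; 1-px-wide arms are traced out and back,
# so both sides of a thin process contribute, as a boundary should.
trace_perimeter <- function(mask) {
  n <- sum(mask)
  if (n == 1L) return(4)
  idx <- which(mask)[1L]  # column-major: first pixel of first occupied column
  p0 <- c(((idx - 1L) %% nrow(mask)) + 1L, ((idx - 1L) %/% nrow(mask)) + 1L)
  dir_index <- function(d) which(MOORE[, 1L] == d[1L] & MOORE[, 2L] == d[2L])
  at <- function(p) {
    if (p[1L] < 1L || p[1L] > nrow(mask) || p[2L] < 1L || p[2L] > ncol(mask))
      FALSE else mask[p[1L], p[2L]]
  }
  next_on_contour <- function(cur, prev) {
    back <- dir_index(prev - cur)
    for (k in 0:7) {  # sweep clockwise from just past the backtrack direction
      i <- ((back + k) %% 8L) + 1L
      nxt <- cur + MOORE[i, ]
      if (at(nxt)) return(nxt)
    }
    NULL
  }
  first <- next_on_contour(p0, p0 + c(0L, -1L))  # entered from the west
  if (is.null(first)) return(4)
  step_len <- function(a, b) if (all(abs(a - b) == 1L)) sqrt(2) else 1
  per <- step_len(p0, first)
  prev <- p0; cur <- first
  steps <- 0L
  repeat {
    nxt <- next_on_contour(cur, prev)
    if (all(cur == p0) && all(nxt == first)) break  # initial move re-reached
    per <- per + step_len(cur, nxt)
    prev <- cur; cur <- nxt
    steps <- steps + 1L
    if (steps > 8L * n + 8L) break  # safety
  }
  per
}

#' Whole-cell shape descriptors
#'
#' Area, perimeter, moment-equivalent ellipse axes, eccentricity and axis
#' ratio of a single-cell binary mask.  Axis lengths follow the
#' `4 * sqrt(eigenvalue)` convention on the central second-moment matrix of
#' pixel centers (the convention of scikit-image's `regionprops`), so a disk
#' of radius r yields major = minor = 2r.  The perimeter is the traced
#' 8-connected boundary with sqrt(2) weighting of diagonal steps.  All
#' lengths are in micrometres, areas in square micrometres.
#'
#' @param mask A `cell_crop` (see [extract_cell_crops()], [as_cell_crop()])
#'   or a logical matrix.
#' @param pixel_size_um Pixel size; defaults to the crop's.
#' @return Object of class `shape_features`: `area_um2`, `perimeter_um`,
#'   `major_axis_um`, `minor_axis_um`, `eccentricity` (0 = circle),
#'   `axis_ratio` (minor/major), `centroid` (row, col, px).
#' @export
compute_shape_features <- function(mask, pixel_size_um = NULL) {
  if (inherits(mask, "cell_crop")) {
    if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
    mask <- mask$mask
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1
  mask <- mask != 0
  n <- sum(mask)
  if (n == 0L) stopf("empty mask")
  if (n < 5L) stopf("mask has %d px; at least 5 required for stable moments", n)
  if (n_components8(mask) != 1L) stopf("mask must contain exactly one connected component")

  w <- which_px(mask)
  mu <- colMeans(w)
  dr <- w[, 1L] - mu[1L]; dc <- w[, 2L] - mu[2L]
  C <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2L)
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1L]) * pixel_size_um
  minor <- 4 * sqrt(ev[2L]) * pixel_size_um
  ratio <- if (major > 0) minor / major else 1
  ratio <- max(ratio, 1e-12)  # degenerate 1-D masks
  ecc <- min(sqrt(max(0, 1 - ratio^2)), 1 - 1e-12)
  structure(list(area_um2 = n * pixel_size_um^2,
                 perimeter_um = trace_perimeter(mask) * pixel_size_um,
                 major_axis_um = major, minor_axis_um = minor,
                 eccentricity = ecc, axis_ratio = ratio,
                 centroid = mu),
            class = "shape_features")
}

#' @export
print.shape_features <- function(x, ...) {
  cat(sprintf(paste0("<shape_features> area %.1f um^2, perimeter %.1f um, ",
                     "axes %.1f x %.1f um, eccentricity %.3f\n"),
              x$area_um2, x$perimeter_um, x$major_axis_um, x$minor_axis_um,
              x$eccentricity))
  invisible(x)
}

#' Tabulate shape features for a list of crops
#'
#' @param crops List of `cell_crop` objects.
#' @return data.frame with one row per cell (label, area_um2, perimeter_um,
#'   major_axis_um, minor_axis_um, eccentricity, axis_ratio).
#' @export
shape_features_table <- function(crops) {
  rows <- lapply(crops, function(cr) {
    f <- compute_shape_features(cr)
    data.frame(label = cr$source_label, area_um2 = f$area_um2,
               perimeter_um = f$perimeter_um, major_axis_um = f$major_axis_um,
               minor_axis_um = f$minor_axis_um, eccentricity = f$eccentricity,
               axis_ratio = f$axis_ratio)
  })
  do.call(rbind, rows)
}
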