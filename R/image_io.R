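# Reading/writing label masks and stacks, maximum-intensity projection, and
# extraction of centered single-cell crops from a labelled segmentation.

#' Construct a label image
#'
#' @param pixels Integer matrix; 0 = background, positive integers = cell ids.
#' @param pixel_size_um Physical pixel size (micrometres per pixel).
#' @return An object of class `label_image`.
#' @export
label_image <- function(pixels, pixel_size_um = 1) {
  if (!is.matrix(pixels) || any(pixels < 0) || any(pixels != round(pixels)))
    stopf("`pixels` must be a matrix of non-negative integers")
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 pixel_size_um = pixel_size_um),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  labs <- setdiff(unique(as.vector(x$pixels)), 0L)
  cat(sprintf("<label_image> %d x %d px, %.4g um/px, %d label(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, length(labs)))
  invisible(x)
}

#' Construct a fluorescence z-stack
#'
#' @param planes 3-D numeric array `(plane, row, col)` with at least one plane.
#' @param pixel_size_um,z_step_um Physical calibration.
#' @return An object of class `zstack`.
#' @export
zstack <- function(planes, pixel_size_um = 1, z_step_um = 1) {
  if (!is.array(planes) || length(dim(planes)) != 3L || dim(planes)[1L] < 1L)
    stopf("`planes` must be a (plane, row, col) array with >= 1 plane")
  structure(list(planes = planes, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "zstack")
}

#' Write / read a label image as an unsigned-integer TIFF
#'
#' Masks are stored as single-page 16-bit unsigned TIFF.  The TIFF writer
#' available here does not persist resolution tags, so the pixel size
#' round-trips through a small JSON sidecar (`<path>.meta.json`); when the
#' sidecar is absent, 1 um/px is assumed with a warning.
#'
#' @param img A [label_image()].
#' @param path Output TIFF path.
#' @return `write_label_tiff` returns `path` invisibly; `read_label_tiff`
#'   returns a [label_image()].
#' @export
write_label_tiff <- function(img, path) {
  stopifnot(inherits(img, "label_image"))
  if (max(img$pixels) > 65535L) stopf("labels exceed 16-bit range")
  tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = img$pixel_size_um),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(x)) == 3L)
    stopf("%s is a multi-channel (RGB) TIFF; expected a single-channel integer label mask", path)
  bps <- attr(x, "bits.per.sample")
  if (!is.null(bps) && bps >= 32L)
    stopf("%s is a %d-bit (float-typed) TIFF; expected an unsigned-integer label mask", path, bps)
  meta <- paste0(path, ".meta.json")
  px <- if (file.exists(meta)) {
    jsonlite::read_json(meta)$pixel_size_um
  } else {
    warning(sprintf("no pixel-size metadata for %s; assuming 1 um/px", path),
            call. = FALSE)
    1
  }
  label_image(matrix(as.integer(x), nrow(x)), pixel_size_um = px)
}

#' Maximum-intensity projection of a z-stack
#'
#' `out[r, c] = max over planes p of stack[p, r, c]`.
#'
#' @param stack A [zstack()] or a 3-D `(plane, row, col)` array.
#' @return 2-D numeric matrix.
#' @export
max_intensity_projection <- function(stack) {
  planes <- if (inherits(stack, "zstack")) stack$planes else stack
  if (!is.array(planes) || length(dim(planes)) != 3L || dim(planes)[1L] < 1L)
    stopf("empty or invalid stack")
  out <- planes[1L, , ]
  for (p in seq_len(dim(planes)[1L])[-1L]) out <- pmax(out, planes[p, , ])
  out
}

#' Extract centered single-cell crops from a label image
#'
#' One crop per label with area >= `min_area_px`.  All crops share one
#' square side, the largest bounding-box side over all kept cells (plus
#' `pad`), and each cell's centroid sits at the crop center within 1 px.
#' Labels touching the image border are kept but flagged.
#'
#' @param label A [label_image()].
#' @param min_area_px Minimum label area in pixels (default 50, suppressing
#'   segmentation fragments).
#' @param pad Extra pixels added to the shared side.
#' @return List of crops, each of class `cell_crop` with fields `mask`
#'   (logical matrix), `source_label`, `offset` (row, col of crop origin in
#'   the source, 1-based), `pixel_size_um`, `border` flag and
#'   `multi_component` flag.  The crop manifest (one row per crop) is
#'   attached as attribute `manifest`.
#' @export
extract_cell_crops <- function(label, min_area_px = 50L, pad = 2L) {
  stopifnot(inherits(label, "label_image"))
  px <- label$pixels
  ids <- setdiff(sort(unique(as.vector(px))), 0L)
  keep <- ids[vapply(ids, function(i) sum(px == i) >= min_area_px, logical(1))]
  if (length(keep) == 0L) return(structure(list(), manifest = NULL))

  boxes <- lapply(keep, function(i) {
    w <- which_px(px == i)
    list(id = i, px = w,
         side = max(diff(range(w[, 1L])), diff(range(w[, 2L]))) + 1L)
  })
  side <- max(vapply(boxes, `[[`, integer(1), "side")) + as.integer(pad)
  if (side %% 2L == 0L) side <- side + 1L  # odd side => exact center pixel

  crops <- lapply(boxes, function(bx) {
    w <- bx$px
    centroid <- colMeans(w)
    ctr <- (side + 1L) %/% 2L
    off <- round(centroid) - ctr  # crop origin minus 1
    m <- matrix(FALSE, side, side)
    rr <- w[, 1L] - off[1L]; cc <- w[, 2L] - off[2L]
    ok <- rr >= 1L & rr <= side & cc >= 1L & cc <= side
    m[cbind(rr[ok], cc[ok])] <- TRUE
    border <- any(w[, 1L] == 1L | w[, 1L] == nrow(px) |
                  w[, 2L] == 1L | w[, 2L] == ncol(px))
    structure(list(mask = m, source_label = bx$id,
                   offset = as.integer(off + 1L),
                   pixel_size_um = label$pixel_size_um,
                   border = border,
                   multi_component = n_components8(m) > 1L),
              class = "cell_crop")
  })
  manifest <- data.frame(
    label = vapply(crops, `[[`, integer(1), "source_label"),
    offset_row = vapply(crops, function(cr) cr$offset[1L], integer(1)),
    offset_col = vapply(crops, function(cr) cr$offset[2L], integer(1)),
    area_px = vapply(crops, function(cr) sum(cr$mask), integer(1)),
    border_flag = vapply(crops, `[[`, logical(1), "border"))
  structure(crops, manifest = manifest)
}

#' Wrap a logical mask as a cell crop
#'
#' Convenience for analysing a mask that is already a single centered cell
#' (e.g. straight from [generate_cell_mask()]).
#'
#' @param mask Logical matrix with one foreground component.
#' @param pixel_size_um Physical pixel size.
#' @param source_label Label id to record.
#' @return A `cell_crop`.
#' @export
as_cell_crop <- function(mask, pixel_size_um = 1, source_label = 1L) {
  structure(list(mask = mask != 0, source_label = as.integer(source_label),
                 offset = c(1L, 1L), pixel_size_um = pixel_size_um,
                 border = FALSE,
                 multi_component = n_components8(mask != 0) > 1L),
            class = "cell_crop")
}
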