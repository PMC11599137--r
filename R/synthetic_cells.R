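# Synthetic single-cell phantoms: an elliptical soma with branched, stroked
# protrusions whose centerline geometry is recorded exactly, so that
# skeleton-based protrusion metrics can be validated against known truth.

#' Specify one (possibly branched) protrusion
#'
#' A protrusion is a polyline starting on the soma boundary at
#' `origin_angle` and growing outward segment by segment; each segment turns
#' by its `turn_angle` relative to the previous heading (the first segment's
#' heading is `origin_angle + turn_angles[1]`, i.e. radial when 0).  Branches
#' attach at a fractional offset along a parent segment; a branch's
#' `origin_angle` is then interpreted as the turn relative to the parent
#' segment's heading at the attachment point.
#'
#' @param origin_angle Angle (radians) on the soma boundary (or turn relative
#'   to the parent segment, for branches).
#' @param lengths Numeric vector of segment lengths in pixels (> 0).
#' @param turn_angles Turn per segment in radians (recycled to `lengths`).
#' @param branches List of branches, each `list(segment =, offset =, spec =)`
#'   with `offset` in `[0, 1]` and `spec` a `protrusion_spec`.
#' @param width_px Stroke half-width in pixels (> 0).
#' @return An object of class `protrusion_spec`.
#' @export
protrusion_spec <- function(origin_angle, lengths, turn_angles = 0,
                            branches = list(), width_px = 1.8) {
  check_number(origin_angle, "origin_angle")
  if (!is.numeric(lengths) || length(lengths) < 1L || any(lengths <= 0))
    stopf("`lengths` must be positive segment lengths")
  turn_angles <- rep_len(turn_angles, length(lengths))
  check_number(width_px, "width_px", min = 0, strict = TRUE)
  for (b in branches) {
    if (!all(c("segment", "offset", "spec") %in% names(b)))
      stopf("each branch needs `segment`, `offset`, `spec`")
    if (b$segment < 1L || b$segment > length(lengths))
      stopf("branch segment index out of range")
    if (b$offset < 0 || b$offset > 1)
      stopf("branch offset must be in [0, 1]")
    if (!inherits(b$spec, "protrusion_spec"))
      stopf("branch `spec` must be a protrusion_spec")
  }
  structure(list(origin_angle = origin_angle, lengths = as.numeric(lengths),
                 turn_angles = as.numeric(turn_angles), branches = branches,
                 width_px = width_px),
            class = "protrusion_spec")
}

#' Specify a synthetic cell
#'
#' @param soma_radius_px Minor semi-axis of the elliptical soma (>= 2 px).
#' @param soma_aspect Soma elongation (major/minor semi-axis, >= 1); the
#'   major axis lies along image columns.
#' @param protrusions List of [protrusion_spec()] objects.
#' @param boundary_jitter_px SD of per-vertex Gaussian displacement of the
#'   soma boundary polygon (protrusion centerlines are never jittered, so
#'   length ground truth stays exact).
#' @param pixel_size_um Physical pixel size, micrometres per pixel.
#' @param image_shape Integer `(rows, cols)` of the rendered mask.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(soma_radius_px, soma_aspect = 1, protrusions = list(),
                      boundary_jitter_px = 0, pixel_size_um = 1,
                      image_shape = c(161L, 161L)) {
  check_number(soma_radius_px, "soma_radius_px", min = 2)
  check_number(soma_aspect, "soma_aspect", min = 1)
  check_number(boundary_jitter_px, "boundary_jitter_px", min = 0)
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  if (length(image_shape) != 2L || any(image_shape < 8))
    stopf("`image_shape` must be (rows, cols), each >= 8")
  for (p in protrusions)
    if (!inherits(p, "protrusion_spec")) stopf("protrusions must be protrusion_spec objects")
  structure(list(soma_radius_px = soma_radius_px, soma_aspect = soma_aspect,
                 protrusions = protrusions,
                 boundary_jitter_px = boundary_jitter_px,
                 pixel_size_um = pixel_size_um,
                 image_shape = as.integer(image_shape)),
            class = "cell_spec")
}

# Unjittered soma boundary radius at angle theta (a along cols, b along rows).
soma_radius_at <- function(theta, b, aspect) {
  a <- b * aspect
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# Trace one protrusion tree. Returns unique centerline edges (r1,c1,r2,c2),
# tip positions and exact root-to-tip centerline lengths.
trace_protrusion <- function(spec, start, heading0, base_len) {
  edges <- NULL
  pos <- start; heading <- heading0; cum <- base_len
  seg_start_pos <- vector("list", length(spec$lengths))
  seg_heading <- numeric(length(spec$lengths))
  seg_base <- numeric(length(spec$lengths))
  for (i in seq_along(spec$lengths)) {
    heading <- heading + spec$turn_angles[i]
    seg_start_pos[[i]] <- pos; seg_heading[i] <- heading; seg_base[i] <- cum
    nxt <- pos + spec$lengths[i] * c(sin(heading), cos(heading))
    edges <- rbind(edges, c(pos, nxt, spec$width_px))
    pos <- nxt; cum <- cum + spec$lengths[i]
  }
  tips <- data.frame(row = pos[1L], col = pos[2L], length_px = cum)
  for (b in spec$branches) {
    i <- b$segment
    bstart <- seg_start_pos[[i]] +
      b$offset * spec$lengths[i] * c(sin(seg_heading[i]), cos(seg_heading[i]))
    sub <- trace_protrusion(b$spec, bstart,
                            seg_heading[i] + b$spec$origin_angle - b$spec$turn_angles[1L],
                            seg_base[i] + b$offset * spec$lengths[i])
    edges <- rbind(edges, sub$edges)
    tips <- rbind(tips, sub$tips)
  }
  list(edges = edges, tips = tips)
}

# Pixels (centers) within `width` of segment (p1, p2); returns logical matrix.
stroke_segment <- function(shape, p1, p2, width) {
  r0 <- max(1L, floor(min(p1[1L], p2[1L]) - width - 1))
  r1 <- min(shape[1L], ceiling(max(p1[1L], p2[1L]) + width + 1))
  c0 <- max(1L, floor(min(p1[2L], p2[2L]) - width - 1))
  c1 <- min(shape[2L], ceiling(max(p1[2L], p2[2L]) + width + 1))
  out <- matrix(FALSE, shape[1L], shape[2L])
  if (r0 > r1 || c0 > c1) return(out)
  rr <- r0:r1; cc <- c0:c1
  pr <- rep(rr, times = length(cc)); pc <- rep(cc, each = length(rr))
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- if (L2 == 0) rep(0, length(pr)) else
    pmin(1, pmax(0, ((pr - p1[1L]) * v[1L] + (pc - p1[2L]) * v[2L]) / L2))
  d2 <- (pr - (p1[1L] + t * v[1L]))^2 + (pc - (p1[2L] + t * v[2L]))^2
  sel <- d2 <= width^2
  out[cbind(pr[sel], pc[sel])] <- TRUE
  out
}

#' Render a synthetic cell mask with exact ground truth
#'
#' Rasterizes the soma (pixel-center-in-shape test against the jittered
#' boundary polygon) and strokes each protrusion centerline with a disk of
#' radius `width_px`, so the recorded centerline length is the exact geodesic
#' ground truth.  Identical `(spec, seed)` give bit-identical output.
#'
#' @param spec A [cell_spec()].
#' @param seed Integer seed driving the boundary jitter.
#' @return A list with `mask` (logical matrix, a single 8-connected
#'   component) and `ground_truth`: `n_primary`, `n_total_tips`,
#'   `tip_lengths_px` (root-to-tip centerline lengths, from the soma
#'   boundary), `centerlines` (matrix: segment endpoints `r1,c1,r2,c2` plus
#'   stroke half-width), `soma_center`,
#'   `soma_radius_px`, `soma_boundary` (jittered polygon in polar form),
#'   `intended_morphoclass`.
#' @export
generate_cell_mask <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_spec"))
  shape <- spec$image_shape
  center <- c(floor((shape[1L] + 1L) / 2), floor((shape[2L] + 1L) / 2))
  b <- spec$soma_radius_px; aspect <- spec$soma_aspect

  nv <- 120L
  theta <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  base_r <- soma_radius_at(theta, b, aspect)
  jit <- local_seed(seed, stats::rnorm(nv, 0, spec$boundary_jitter_px))
  rad <- pmax(2, base_r + jit)

  if (max(rad) + 1 > min(center[1L] - 1, center[2L] - 1,
                         shape[1L] - center[1L], shape[2L] - center[2L]))
    stopf("soma does not fit inside image_shape")

  # soma: star-convex polygon, linear interpolation of the jittered radius
  pr <- rep(seq_len(shape[1L]), times = shape[2L])
  pc <- rep(seq_len(shape[2L]), each = shape[1L])
  ang <- atan2(pr - center[1L], pc - center[2L]) %% (2 * pi)
  rho <- sqrt((pr - center[1L])^2 + (pc - center[2L])^2)
  rad_i <- stats::approx(x = c(theta, 2 * pi), y = c(rad, rad[1L]),
                         xout = ang, rule = 2)$y
  mask <- matrix(rho <= rad_i, shape[1L], shape[2L])

  # protrusions
  edges_all <- NULL
  tips_all <- NULL
  for (i in seq_along(spec$protrusions)) {
    p <- spec$protrusions[[i]]
    th <- p$origin_angle
    start <- center + soma_radius_at(th, b, aspect) * c(sin(th), cos(th))
    tr <- trace_protrusion(p, start, th, 0)
    lim <- max(tr$edges[, 5L]) + 1
    if (any(tr$edges[, c(1L, 3L)] < 1 + lim | tr$edges[, c(1L, 3L)] > shape[1L] - lim) ||
        any(tr$edges[, c(2L, 4L)] < 1 + lim | tr$edges[, c(2L, 4L)] > shape[2L] - lim))
      stopf("protrusion %d leaves the image bounds", i)
    for (k in seq_len(nrow(tr$edges)))
      mask <- mask | stroke_segment(shape, tr$edges[k, 1:2], tr$edges[k, 3:4],
                                    tr$edges[k, 5L])
    tr$tips$primary <- i
    edges_all <- rbind(edges_all, tr$edges)
    tips_all <- rbind(tips_all, tr$tips)
  }

  n_primary <- length(spec$protrusions)
  gt <- list(
    n_primary = n_primary,
    n_total_tips = if (is.null(tips_all)) 0L else nrow(tips_all),
    tip_lengths_px = if (is.null(tips_all)) numeric(0) else tips_all$length_px,
    tips = tips_all,
    centerlines = edges_all,
    soma_center = center,
    soma_radius_px = b,
    soma_aspect = aspect,
    soma_boundary = data.frame(theta = theta, radius = rad),
    pixel_size_um = spec$pixel_size_um,
    intended_morphoclass = attr(spec, "intended_morphoclass") %||% NA_character_
  )
  list(mask = mask, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a random cell specification
#'
#' Samples a synthetic cell in the panel conditions used throughout the
#' package's validation: 0-6 well-separated protrusions of total centerline
#' length 10-60 px, at most two branch points per cell, mild segment
#' curvature, soma minor semi-axis 8-14 px with aspect up to 1.5, and
#' sub-pixel boundary jitter.  When `class` is given, parameters are instead
#' drawn from ranges squarely inside one of the four morphoclasses and the
#' intended label is recorded in the ground truth.
#'
#' @param seed Integer seed.
#' @param class Optional morphoclass to aim for (see [morphoclass_levels()]).
#' @param image_shape Rendered mask size.
#' @return A [cell_spec()]; attribute `intended_morphoclass` carries the
#'   planted label.
#' @export
random_cell_spec <- function(seed, class = NULL, image_shape = c(231L, 231L)) {
  local_seed(seed, {
    if (is.null(class)) {
      n_prot <- sample(0:6, 1L)
      soma_r <- stats::runif(1, 8, 14)
      aspect <- stats::runif(1, 1, 1.5)
      n_branch <- if (n_prot > 0) sample(0:2, 1L) else 0L
      spec <- build_random_spec(n_prot, n_branch, soma_r, aspect,
                                len_range = c(10, 60), image_shape)
      attr(spec, "intended_morphoclass") <-
        if (n_prot == 0L) "nonpolar" else NA_character_
      spec
    } else {
      class <- match.arg(class, morphoclass_levels())
      spec <- switch(class,
        nonpolar = build_random_spec(0L, 0L, stats::runif(1, 9, 14),
                                     stats::runif(1, 1, 1.2),
                                     c(10, 60), image_shape),
        circular_multipolar = build_random_spec(sample(4:6, 1L), 0L,
                                                stats::runif(1, 8, 10), 1,
                                                c(12, 20), image_shape),
        flat_polar = build_random_spec(sample(1:2, 1L), 0L,
                                       stats::runif(1, 22, 27),
                                       stats::runif(1, 1, 1.2),
                                       c(15, 30), image_shape),
        elongated = build_random_spec(sample(1:2, 1L), 0L,
                                      stats::runif(1, 7, 9),
                                      stats::runif(1, 3.2, 4.2),
                                      c(40, 60), image_shape,
                                      along_major = TRUE))
      attr(spec, "intended_morphoclass") <- class
      spec
    }
  })
}

# Internal: assemble a cell_spec from sampled protrusion parameters.  Assumes
# the RNG is already scoped by the caller.
build_random_spec <- function(n_prot, n_branch, soma_r, aspect, len_range,
                              image_shape, along_major = FALSE) {
  prots <- list()
  if (n_prot > 0L) {
    slots <- (seq_len(max(n_prot, 2L)) - 1L) * 2 * pi / max(n_prot, 2L)
    angles <- (sample(slots, n_prot) + stats::runif(n_prot, -0.2, 0.2)) %% (2 * pi)
    if (along_major)  # protrusions near the major axis keep the cell linear
      angles <- sample(c(0, pi), n_prot) + stats::runif(n_prot, -0.15, 0.15)
    with_branch <- if (n_branch > 0L)
      sample(rep(seq_len(n_prot), length.out = n_branch)) else integer(0)
    for (i in seq_len(n_prot)) {
      nb_i <- sum(with_branch == i)
      # branch-carrying protrusions are long single segments so that the
      # parent tip stays resolvable beyond the branch point
      total <- if (nb_i > 0L) stats::runif(1, max(30, len_range[1L]), max(30, len_range[2L]))
               else stats::runif(1, len_range[1L], len_range[2L])
      nseg <- if (nb_i > 0L) 1L else sample(1:2, 1L)
      lens <- total * (if (nseg == 1L) 1 else c(0.55, 0.45))
      turns <- c(0, stats::runif(nseg - 1L, -0.25, 0.25))
      branches <- list()
      for (bk in seq_len(nb_i)) {
        # two branches on one protrusion go to opposite sides
        sgn <- if (nb_i == 2L) c(-1, 1)[bk] else sample(c(-1, 1), 1L)
        branches[[bk]] <- list(
          segment = nseg, offset = stats::runif(1, 0.35, 1 - 9 / total),
          spec = protrusion_spec(sgn * stats::runif(1, 0.8, 1.3),
                                 lengths = stats::runif(1, 15, 30),
                                 width_px = 1.6))
      }
      prots[[i]] <- protrusion_spec(angles[i], lengths = lens,
                                    turn_angles = turns, branches = branches,
                                    width_px = stats::runif(1, 1.4, 2.0))
    }
  }
  cell_spec(soma_radius_px = soma_r, soma_aspect = aspect, protrusions = prots,
            boundary_jitter_px = 0.4, pixel_size_um = 1,
            image_shape = image_shape)
}
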