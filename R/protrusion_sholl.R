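# Soma/protrusion decomposition of a cell mask and the protrusion metrics:
# primary and total protrusion counts, geodesic root-to-tip lengths,
# branching index, and the Sholl intersection profile.
#
# The mask is thinned to a 1-px skeleton (Guo-Hall, topology preserving,
# 8-connectivity), spurs below a length threshold are pruned, the skeleton
# is split at the soma boundary, and every skeleton component outside the
# soma that touches it becomes a primary protrusion rooted at the crossing
# pixel.  Tips are skeleton endpoints outside the soma; "all protrusions"
# counts tips, so one bifurcation adds one protrusion and the branching
# index (tips/roots) is >= 1 whenever defined.

# One Guo-Hall thinning pass (sub-iteration `odd`), fully vectorized.
guo_hall_pass <- function(m, odd) {
  p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
  p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
  p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
  p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  Nm <- pmin(N1, N2)
  m3 <- if (odd) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
  del <- m & (C == 1L) & (Nm >= 2L) & (Nm <= 3L) & !m3
  m & !del
}

# Topology-preserving thinning of a logical mask to a 1-px skeleton.
thin_mask <- function(mask) {
  m <- mask != 0
  repeat {
    m1 <- guo_hall_pass(m, TRUE)
    m2 <- guo_hall_pass(m1, FALSE)
    if (identical(m2, m)) return(m2)
    m <- m2
  }
}

#' Estimate the soma of a cell mask
#'
#' The soma center is the arg-max of the Euclidean distance transform (ties
#' broken toward the smallest row, then column); the soma mask is the
#' connected component containing the center after morphological opening
#' with a disk of radius half the inscribed radius.  Masks thinner than 3 px
#' everywhere cannot carry a soma and are returned whole, flagged.
#'
#' @param mask A `cell_crop` or logical matrix (one foreground component).
#' @return Object of class `soma_model`: `center` (row, col),
#'   `inscribed_radius_px`, `soma_mask`, `thin_flag`.
#' @export
estimate_soma <- function(mask) {
  if (inherits(mask, "cell_crop")) mask <- mask$mask
  mask <- mask != 0
  if (!any(mask)) stopf("empty mask")
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- matrix(as.numeric(d), nrow(mask))
  rmax <- max(d)
  cand <- which_px(d == rmax)
  center <- cand[order(cand[, 1L], cand[, 2L])[1L], ]
  if (rmax < 1.5) {  # nowhere 3 px thick: the whole mask is "soma"
    return(structure(list(center = center, inscribed_radius_px = rmax,
                          soma_mask = mask, thin_flag = TRUE),
                     class = "soma_model"))
  }
  brush_size <- 2L * as.integer(floor(rmax / 2)) + 1L
  opened <- if (brush_size >= 3L) {
    op <- EBImage::opening(EBImage::Image(mask * 1),
                           EBImage::makeBrush(brush_size, "disc"))
    matrix(as.numeric(op) > 0.5, nrow(mask))
  } else mask
  soma <- if (opened[center[1L], center[2L]]) {
    flood8(opened, matrix(center, 1L))
  } else mask  # opening removed the center: fall back to the whole mask
  structure(list(center = center, inscribed_radius_px = rmax,
                 soma_mask = soma, thin_flag = FALSE),
            class = "soma_model")
}

#' @export
print.soma_model <- function(x, ...) {
  cat(sprintf("<soma_model> center (%d, %d), inscribed radius %.2f px, %d px%s\n",
              x$center[1L], x$center[2L], x$inscribed_radius_px,
              sum(x$soma_mask), if (x$thin_flag) " [thin mask: soma = whole mask]" else ""))
  invisible(x)
}

# Remove skeleton spurs shorter than `prune_px`: a spur is a chain of
# degree-<=2 pixels running from an endpoint into a junction (degree >= 3);
# only such chains are deleted, and only when shorter than the threshold,
# so genuine branch ends are never nibbled away.  Sweeps repeat until
# stable (removing one spur can expose another).
prune_skeleton <- function(skel, prune_px) {
  if (prune_px <= 0) return(skel)
  repeat {
    deg <- neighbor_count8(skel)
    endpoints <- which_px(skel & deg == 1L)
    if (nrow(endpoints) == 0L) return(skel)
    removed_any <- FALSE
    for (e in seq_len(nrow(endpoints))) {
      p <- endpoints[e, ]
      if (!skel[p[1L], p[2L]]) next
      chain <- list(p)
      len <- 0
      prev <- c(NA_integer_, NA_integer_)
      hit_junction <- FALSE
      while (len < prune_px) {
        nb <- sweep(NBR8, 2L, p, "+")
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= nrow(skel) &
              nb[, 2L] >= 1L & nb[, 2L] <= ncol(skel)
        nb <- nb[ok, , drop = FALSE]
        nb <- nb[skel[nb], , drop = FALSE]
        if (!is.na(prev[1L]))
          nb <- nb[!(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L]), , drop = FALSE]
        if (nrow(nb) == 0L) break  # isolated path: a component, not a spur
        if (any(deg[nb] >= 3L)) { hit_junction <- TRUE; break }
        if (nrow(nb) != 1L) break  # ambiguous thinning artifact: leave it
        q <- nb[1L, ]
        len <- len + if (all(abs(q - p) == 1L)) sqrt(2) else 1
        chain <- c(chain, list(q))
        prev <- p; p <- q
      }
      if (hit_junction && len < prune_px) {
        for (pt in chain) skel[pt[1L], pt[2L]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(skel)
  }
}

#' Build the protrusion skeleton graph of a cell
#'
#' Thins the mask to a 1-px skeleton, prunes spurs shorter than `prune_um`,
#' removes the part covered by the soma, and organizes the remainder into
#' rooted protrusion components: each component touching the soma gets a
#' soma-attachment root at the crossing pixel; tips are skeleton endpoints.
#' Root-to-tip geodesic lengths are measured along the skeleton (chords
#' resampled every 4 px to suppress the staircase bias of pixel chains).
#'
#' @param mask A `cell_crop` or logical matrix.
#' @param soma A `soma_model` from [estimate_soma()]; computed when `NULL`.
#' @param prune_um Spur-pruning threshold in micrometres.
#' @param min_protrusion_um Detection floor: tips whose geodesic length falls
#'   below this are not scored as protrusions (short skeleton pokes at the
#'   soma boundary are artefacts of thinning, not processes).  Components
#'   left without tips are dropped entirely.
#' @param pixel_size_um Pixel size (defaults to the crop's, else 1).
#' @return Object of class `skeleton_graph`: `pixels` (n x 2 skeleton pixels
#'   outside the soma), `roots`, `tips` (pixel coordinates), `tip_lengths_px`,
#'   `tip_component`, `n_components`, `soma`, `pixel_size_um`.  A disk with
#'   no skeleton outside the soma yields an empty graph.
#' @export
build_skeleton <- function(mask, soma = NULL, prune_um = 1,
                           min_protrusion_um = 5, pixel_size_um = NULL) {
  if (inherits(mask, "cell_crop")) {
    if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
    mask <- mask$mask
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1
  mask <- mask != 0
  if (is.null(soma)) soma <- estimate_soma(mask)
  skel <- thin_mask(mask)
  skel <- prune_skeleton(skel, prune_px = prune_um / pixel_size_um)
  out <- skel & !soma$soma_mask

  empty <- function() structure(
    list(pixels = matrix(integer(0), 0L, 2L), roots = matrix(integer(0), 0L, 2L),
         tips = matrix(integer(0), 0L, 2L), tip_lengths_px = numeric(0),
         tip_component = integer(0), n_components = 0L, soma = soma,
         pixel_size_um = pixel_size_um), class = "skeleton_graph")
  if (!any(out)) return(empty())

  near_soma <- dilate8(soma$soma_mask)
  lab <- label8(out)
  roots <- NULL; tips <- NULL; tip_lengths <- numeric(0); tip_comp <- integer(0)
  n_comp <- 0L
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    px <- which_px(comp)
    attach <- px[near_soma[px], , drop = FALSE]
    if (nrow(attach) == 0L) next  # floating fragment, not soma-attached
    # cluster attachment pixels: one root per 8-connected attachment site;
    # sites within 4 px of each other are one crossing (skeleton wobble
    # along the soma boundary must not double-count a protrusion)
    amask <- matrix(FALSE, nrow(out), ncol(out))
    amask[attach] <- TRUE
    alab <- label8(amask)
    cents <- t(vapply(seq_len(max(alab)), function(j) {
      colMeans(which_px(alab == j))
    }, numeric(2)))
    grp <- seq_len(nrow(cents))
    if (nrow(cents) > 1L) {
      for (i2 in 2:nrow(cents)) for (j2 in 1:(i2 - 1L))
        if (sqrt(sum((cents[i2, ] - cents[j2, ])^2)) <= 4)
          grp[grp == grp[i2]] <- grp[j2]
    }
    comp_roots <- t(vapply(unique(grp), function(g) {
      cl <- which_px(matrix(alab %in% which(grp == g) & amask,
                            nrow(out), ncol(out)))
      cl[order(cl[, 1L], cl[, 2L])[1L], ]
    }, integer(2)))
    # tips: endpoints of the component that are not attachment pixels
    deg <- neighbor_count8(comp)
    is_tip <- comp & deg <= 1L & !amask
    tp <- which_px(is_tip)
    if (nrow(tp) == 0L) next  # boundary-hugging remnant, not a protrusion
    d <- pixel_dijkstra(px, from = which(px[, 1L] == comp_roots[1L, 1L] &
                                         px[, 2L] == comp_roots[1L, 2L]))
    comp_tips <- NULL; comp_lens <- numeric(0)
    for (t_i in seq_len(nrow(tp))) {
      ti <- which(px[, 1L] == tp[t_i, 1L] & px[, 2L] == tp[t_i, 2L])
      path <- dijkstra_path(d, ti)
      # + 0.5: the soma-boundary crossing lies midway between the root pixel
      # (first pixel outside the soma) and its soma-side neighbour
      len <- resampled_length(px[path, , drop = FALSE]) + 0.5
      if (len * pixel_size_um < min_protrusion_um) next  # below detection floor
      comp_tips <- rbind(comp_tips, tp[t_i, ])
      comp_lens <- c(comp_lens, len)
    }
    if (is.null(comp_tips)) next  # nothing above the floor: not a protrusion
    n_comp <- n_comp + 1L
    roots <- rbind(roots, comp_roots)
    tips <- rbind(tips, comp_tips)
    tip_lengths <- c(tip_lengths, comp_lens)
    tip_comp <- c(tip_comp, rep(n_comp, length(comp_lens)))
  }
  if (is.null(roots)) return(empty())
  structure(list(pixels = which_px(out), roots = roots,
                 tips = if (is.null(tips)) matrix(integer(0), 0L, 2L) else tips,
                 tip_lengths_px = tip_lengths, tip_component = tip_comp,
                 n_components = n_comp, soma = soma,
                 pixel_size_um = pixel_size_um),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d px outside soma, %d root(s), %d tip(s)\n",
              nrow(x$pixels), nrow(x$roots), nrow(x$tips)))
  invisible(x)
}

#' Protrusion metrics from a skeleton graph
#'
#' `n_primary` is the number of soma-attachment roots, `n_total` the number
#' of skeleton tips (so one bifurcation adds one protrusion); lengths are
#' geodesic root-to-tip distances; the branching index is
#' `n_total / n_primary` (NA when no primary protrusion exists).
#'
#' @param skeleton A `skeleton_graph` from [build_skeleton()].
#' @param pixel_size_um Pixel size (defaults to the skeleton's).
#' @return Object of class `protrusion_metrics`: `n_primary`, `n_total`,
#'   `avg_length_um`, `max_length_um`, `branching_index` (NA when
#'   undefined), `tip_lengths_um`.
#' @export
protrusion_metrics <- function(skeleton, pixel_size_um = NULL) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  if (is.null(pixel_size_um)) pixel_size_um <- skeleton$pixel_size_um
  n_primary <- nrow(skeleton$roots)
  n_total <- nrow(skeleton$tips)
  if (n_primary == 0L && n_total > 0L)
    stopf("internal consistency failure: %d tip(s) without any soma-attachment root", n_total)
  lens <- skeleton$tip_lengths_px * pixel_size_um
  structure(list(
    n_primary = n_primary, n_total = n_total,
    avg_length_um = if (n_total > 0L) mean(lens) else NA_real_,
    max_length_um = if (n_total > 0L) max(lens) else NA_real_,
    branching_index = if (n_primary > 0L) n_total / n_primary else NA_real_,
    tip_lengths_um = lens), class = "protrusion_metrics")
}

#' @export
print.protrusion_metrics <- function(x, ...) {
  cat(sprintf("<protrusion_metrics> %d primary / %d total, avg %.1f um, max %.1f um, branching %.2f\n",
              x$n_primary, x$n_total, x$avg_length_um, x$max_length_um,
              x$branching_index))
  invisible(x)
}

#' Sholl profile of a cell skeleton
#'
#' For radii `r = inscribed_radius + k * step` (k = 1, 2, ... until beyond
#' the cell extent), counts the 8-connected components of skeleton pixels
#' lying on the digital circle of radius `r` centered at the soma center
#' (the 8-connected pixel ring, half-width `sqrt(2)/2`, which a skeleton
#' path crossing the circle always intersects).
#'
#' @param skeleton A `skeleton_graph` from [build_skeleton()].
#' @param step_um Radial step in micrometres (> 0; must be at least one
#'   pixel).
#' @param pixel_size_um Pixel size (defaults to the skeleton's).
#' @return Object of class `sholl_profile`: data.frame-like list with
#'   `radii_um` and `intersections`, plus `center` and `step_um`.
#' @export
sholl_profile <- function(skeleton, step_um = 5, pixel_size_um = NULL) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  if (is.null(pixel_size_um)) pixel_size_um <- skeleton$pixel_size_um
  check_number(step_um, "step_um", min = 0, strict = TRUE)
  step_px <- step_um / pixel_size_um
  if (step_px < 1) stopf("step_um is smaller than one pixel")
  ctr <- skeleton$soma$center
  r0 <- skeleton$soma$inscribed_radius_px
  extent <- if (nrow(skeleton$pixels) > 0L)
    max(sqrt((skeleton$pixels[, 1L] - ctr[1L])^2 +
             (skeleton$pixels[, 2L] - ctr[2L])^2)) else r0
  radii_px <- r0 + step_px * seq_len(max(1L, ceiling((extent - r0) / step_px) + 1L))
  nr <- max(nrow(skeleton$soma$soma_mask), 1L)
  nc <- max(ncol(skeleton$soma$soma_mask), 1L)
  inter <- integer(length(radii_px))
  if (nrow(skeleton$pixels) > 0L) {
    dpx <- sqrt((skeleton$pixels[, 1L] - ctr[1L])^2 +
                (skeleton$pixels[, 2L] - ctr[2L])^2)
    for (i in seq_along(radii_px)) {
      # digital (8-connected) circle: half-width sqrt(2)/2, so a diagonal
      # skeleton path (radial step up to sqrt(2)) cannot hop the annulus
      on_circle <- abs(dpx - radii_px[i]) <= sqrt(2) / 2
      if (!any(on_circle)) next
      band <- matrix(FALSE, nr, nc)
      band[skeleton$pixels[on_circle, , drop = FALSE]] <- TRUE
      inter[i] <- n_components8(band)
    }
  }
  structure(list(radii_um = radii_px * pixel_size_um, intersections = inter,
                 center = ctr, step_um = step_um),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> %d radii (%.1f-%.1f um), max %d intersection(s)\n",
              length(x$radii_um), min(x$radii_um), max(x$radii_um),
              if (length(x$intersections)) max(x$intersections) else 0L))
  invisible(x)
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::plot(x$radii_um, x$intersections, type = "s",
                 xlab = "radius (um)", ylab = "intersections", ...)
  invisible(x)
}

#' Full protrusion analysis of one mask
#'
#' Convenience wrapper: soma, skeleton, metrics and Sholl profile in one
#' call.
#'
#' @inheritParams build_skeleton
#' @param sholl_step_um Sholl radial step.
#' @return List with `soma`, `skeleton`, `metrics`, `sholl`.
#' @export
analyze_protrusions <- function(mask, prune_um = 1, min_protrusion_um = 5,
                                sholl_step_um = 5, pixel_size_um = NULL) {
  if (inherits(mask, "cell_crop") && is.null(pixel_size_um))
    pixel_size_um <- mask$pixel_size_um
  soma <- estimate_soma(mask)
  sk <- build_skeleton(mask, soma, prune_um = prune_um,
                       min_protrusion_um = min_protrusion_um,
                       pixel_size_um = pixel_size_um)
  list(soma = soma, skeleton = sk, metrics = protrusion_metrics(sk),
       sholl = sholl_profile(sk, step_um = sholl_step_um))
}
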