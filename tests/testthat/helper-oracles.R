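# Independent oracle implementations used across the suite.  These
# deliberately re-derive quantities from the planted geometry / raw data by
# routes distinct from the package implementation.

# Rasterize a disk mask by the pixel-center rule.
make_disk <- function(r, size = 2L * ceiling(r) + 11L) {
  ctr <- (size + 1) / 2
  px <- expand.grid(row = seq_len(size), col = seq_len(size))
  m <- matrix((px$row - ctr)^2 + (px$col - ctr)^2 <= r^2, size, size)
  m
}

# Rasterize an axis-aligned (then rotated) ellipse with semi-axes a >= b.
make_ellipse <- function(a, b, angle = 0, size = 2L * ceiling(a) + 11L) {
  ctr <- (size + 1) / 2
  px <- expand.grid(row = seq_len(size), col = seq_len(size))
  dr <- px$row - ctr; dc <- px$col - ctr
  u <- dc * cos(angle) + dr * sin(angle)   # along major axis
  v <- -dc * sin(angle) + dr * cos(angle)
  matrix((u / a)^2 + (v / b)^2 <= 1, size, size)
}

# Brute-force central second-moment eccentricity from pixel coordinates
# (explicit loop-free formula, independent of the package's eigen route:
# closed form for 2x2 symmetric eigenvalues).
oracle_eccentricity <- function(mask) {
  w <- which(mask)
  r <- ((w - 1) %% nrow(mask)) + 1
  c <- ((w - 1) %/% nrow(mask)) + 1
  mr <- mean(r); mc <- mean(c)
  m20 <- mean((r - mr)^2); m02 <- mean((c - mc)^2); m11 <- mean((r - mr) * (c - mc))
  t1 <- (m20 + m02) / 2
  t2 <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  lam1 <- t1 + t2; lam2 <- max(t1 - t2, 0)
  sqrt(max(0, 1 - lam2 / lam1))
}

# Super-sampled area (px^2) of the union of the jittered soma polygon and
# the stroked centerlines, from the generator's recorded ground truth.
oracle_area <- function(gt, image_shape, factor = 4L) {
  step <- 1 / factor
  offs <- seq(-0.5 + step / 2, 0.5 - step / 2, by = step)
  sub <- expand.grid(dr = offs, dc = offs)
  grid <- expand.grid(row = seq_len(image_shape[1]), col = seq_len(image_shape[2]))
  inside_frac <- numeric(nrow(grid))
  theta <- gt$soma_boundary$theta; rad <- gt$soma_boundary$radius
  interp_rad <- function(phi) approx(c(theta, 2 * pi), c(rad, rad[1]),
                                     xout = phi %% (2 * pi), rule = 2)$y
  for (k in seq_len(nrow(sub))) {
    pr <- grid$row + sub$dr[k]; pc <- grid$col + sub$dc[k]
    dr <- pr - gt$soma_center[1]; dc <- pc - gt$soma_center[2]
    phi <- atan2(dr, dc)
    inside <- sqrt(dr^2 + dc^2) <= interp_rad(phi)
    if (!is.null(gt$centerlines)) for (e in seq_len(nrow(gt$centerlines))) {
      p1 <- gt$centerlines[e, 1:2]; p2 <- gt$centerlines[e, 3:4]
      wd <- gt$centerlines[e, 5]
      v <- p2 - p1; L2 <- sum(v^2)
      t <- pmin(1, pmax(0, ((pr - p1[1]) * v[1] + (pc - p1[2]) * v[2]) / L2))
      inside <- inside |
        ((pr - (p1[1] + t * v[1]))^2 + (pc - (p1[2] + t * v[2]))^2 <= wd^2)
    }
    inside_frac <- inside_frac + inside
  }
  sum(inside_frac) / nrow(sub)
}

# Continuous-geometry Sholl oracle: sample the planted centerlines densely,
# keep samples outside the soma mask, and for each radius count clusters
# (single-linkage, 1.5 px) of samples falling in the 1-px annulus.
oracle_sholl <- function(gt, soma_mask, center, radii_px, spacing = 0.2) {
  if (is.null(gt$centerlines)) return(rep(0L, length(radii_px)))
  samples <- NULL
  for (e in seq_len(nrow(gt$centerlines))) {
    p1 <- gt$centerlines[e, 1:2]; p2 <- gt$centerlines[e, 3:4]
    L <- sqrt(sum((p2 - p1)^2))
    t <- seq(0, 1, by = spacing / L)
    samples <- rbind(samples, cbind(p1[1] + t * (p2[1] - p1[1]),
                                    p1[2] + t * (p2[2] - p1[2])))
  }
  ri <- pmin(pmax(round(samples[, 1]), 1L), nrow(soma_mask))
  ci <- pmin(pmax(round(samples[, 2]), 1L), ncol(soma_mask))
  outside <- !soma_mask[cbind(ri, ci)]
  samples <- samples[outside, , drop = FALSE]
  d <- sqrt((samples[, 1] - center[1])^2 + (samples[, 2] - center[2])^2)
  vapply(radii_px, function(r) {
    sel <- samples[abs(d - r) <= 0.5, , drop = FALSE]
    if (nrow(sel) == 0L) return(0L)
    if (nrow(sel) == 1L) return(1L)
    # single-linkage clustering at 1.5 px
    grp <- cutree(hclust(dist(sel), method = "single"), h = 1.5)
    length(unique(grp))
  }, integer(1))
}

# Exhaustive-enumeration hypergeometric upper tail: all C(N, k) draws.
oracle_hypergeom <- function(N, n, k, x) {
  if (x == 0) return(1)
  if (k == 0) return(0)
  draws <- combn(N, k)
  mean(colSums(draws <= n) >= x)
}

# Empirical transition matrix from a track table (direct tabulation).
oracle_empirical_transitions <- function(tracks) {
  lv <- morphoclass_levels()
  counts <- matrix(0, 4, 4, dimnames = list(lv, lv))
  for (df in split(tracks, tracks$cell_id)) {
    df <- df[order(df$frame), ]
    if (nrow(df) < 2) next
    for (i in seq_len(nrow(df) - 1)) {
      if (df$mitosis[i + 1]) next
      counts[df$class[i], df$class[i + 1]] <- counts[df$class[i], df$class[i + 1]] + 1
    }
  }
  counts
}

# Radial distances of all planted centerline nodes (segment starts/ends:
# roots, joints, branch attachments, tips) from a center point.
node_radii <- function(gt, center) {
  if (is.null(gt$centerlines)) return(numeric(0))
  pts <- rbind(gt$centerlines[, 1:2, drop = FALSE],
               gt$centerlines[, 3:4, drop = FALSE])
  sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
}

# Tangency radii: distances from the center to the perpendicular foot of
# each centerline edge (when the foot is interior).  At these radii the
# circle is tangent to the centerline and crossing counts are degenerate.
tangency_radii <- function(gt, center) {
  if (is.null(gt$centerlines)) return(numeric(0))
  out <- numeric(0)
  for (e in seq_len(nrow(gt$centerlines))) {
    p1 <- gt$centerlines[e, 1:2]; p2 <- gt$centerlines[e, 3:4]
    v <- p2 - p1
    t <- sum((center - p1) * v) / sum(v^2)
    if (t > 0 && t < 1) {
      foot <- p1 + t * v
      out <- c(out, sqrt(sum((foot - center)^2)))
    }
  }
  out
}

# Branch-attachment radii: edge start points lying strictly interior to
# another edge.  Downstream of these the two strokes stay merged until the
# centerline separation exceeds the combined half-widths, so the skeleton
# bifurcates up to (w1+w2)/(2 sin(theta/2)) ~ 5 px outside the junction.
branch_radii <- function(gt, center) {
  cl <- gt$centerlines
  if (is.null(cl)) return(numeric(0))
  out <- numeric(0)
  for (e in seq_len(nrow(cl))) {
    s <- cl[e, 1:2]
    for (f in seq_len(nrow(cl))) {
      if (f == e) next
      p1 <- cl[f, 1:2]; p2 <- cl[f, 3:4]
      v <- p2 - p1
      t <- sum((s - p1) * v) / sum(v^2)
      if (t > 0.01 && t < 0.99 &&
          sum((s - (p1 + t * v))^2) < 1e-12) {
        out <- c(out, sqrt(sum((s - center)^2)))
        break
      }
    }
  }
  out
}

# Is radius r inside the exclusion zones where the skeleton/oracle
# comparison is degenerate?  +-2 px around nodes and tangencies; an
# asymmetric [-2, +8] window downstream of branch attachments (stroke
# merge zone).
radius_excluded <- function(r, gt, center) {
  nodes <- c(node_radii(gt, center), tangency_radii(gt, center))
  if (any(abs(r - nodes) <= 2)) return(TRUE)
  br <- branch_radii(gt, center)
  any(r - br >= -2 & r - br <= 8)
}
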