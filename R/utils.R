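# Internal helpers shared across modules: local RNG scoping, 8-connected
# pixel topology, and small validation utilities.

#' The four GSC morphoclasses
#'
#' Canonical ordering of the four morphoclass labels used throughout the
#' package: `nonpolar`, `flat_polar`, `circular_multipolar`, `elongated`.
#'
#' @return Character vector of the four labels, in canonical order.
#' @export
morphoclass_levels <- function() {
  c("nonpolar", "flat_polar", "circular_multipolar", "elongated")
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (generators must not have global side effects).
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single finite number", name)
  if (strict && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict && x < min) stopf("`%s` must be >= %g", name, min)
  invisible(x)
}

# Logical matrix -> matrix of row/col indices of TRUE pixels.
which_px <- function(mask) {
  idx <- which(mask)
  cbind(row = ((idx - 1L) %% nrow(mask)) + 1L,
        col = ((idx - 1L) %/% nrow(mask)) + 1L)
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

NBR8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
              dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# Dilate a logical matrix by one 8-connected step.
dilate8 <- function(m) {
  out <- m
  for (k in seq_len(8L)) out <- out | shift_mat(m, NBR8[k, 1L], NBR8[k, 2L])
  out
}

# 8-connected component labelling.  EBImage::bwlabel is 4-connected (and
# C-fast); diagonal-adjacent 4-components are merged by union-find over the
# two diagonal shift directions.
label8 <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  L <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  K <- max(L)
  nr <- nrow(L); nc <- ncol(L)
  if (K <= 1L || nr < 2L || nc < 2L) return(L)
  d1 <- cbind(as.vector(L[-nr, -nc]), as.vector(L[-1L, -1L]))   # \ diagonal
  d2 <- cbind(as.vector(L[-nr, -1L]), as.vector(L[-1L, -nc]))   # / diagonal
  prs <- rbind(d1, d2)
  prs <- prs[prs[, 1L] > 0L & prs[, 2L] > 0L & prs[, 1L] != prs[, 2L], ,
             drop = FALSE]
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (nrow(prs)) {
    prs <- unique(prs)
    for (r in seq_len(nrow(prs))) {
      a <- find(prs[r, 1L]); b <- find(prs[r, 2L])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(K), find, integer(1))
  compact <- match(root, unique(root))
  out <- L
  out[L > 0L] <- compact[L[L > 0L]]
  out
}

# 8-connected flood fill: the connected component(s) of `mask` containing
# the seed pixel(s). `seeds` is a logical matrix or an n x 2 (row, col)
# matrix.
flood8 <- function(mask, seeds) {
  mask <- mask != 0
  if (is.logical(seeds)) {
    seed_idx <- which(seeds & mask)
  } else {
    seed_idx <- seeds[, 1L] + (seeds[, 2L] - 1L) * nrow(mask)
    seed_idx <- seed_idx[mask[seed_idx]]
  }
  if (length(seed_idx) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  L <- label8(mask)
  matrix(L %in% setdiff(unique(L[seed_idx]), 0L), nrow(mask))
}

n_components8 <- function(mask) max(label8(mask))

# Count of 8-neighbours that are TRUE, per pixel.
neighbor_count8 <- function(m) {
  cnt <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L)) cnt <- cnt + shift_mat(m, NBR8[k, 1L], NBR8[k, 2L])
  cnt
}

# Shortest geodesic paths along a set of skeleton pixels (8-connectivity,
# orthogonal step 1, diagonal step sqrt(2)).  `px` is an n x 2 (row, col)
# matrix; `from` an index into its rows.  Returns distances and predecessor
# indices for path reconstruction (simple Dijkstra; skeletons are small).
pixel_dijkstra <- function(px, from) {
  n <- nrow(px)
  key <- px[, 1L] + 1e6 * px[, 2L]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  dist <- rep(Inf, n); dist[from] <- 0
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (k in seq_len(8L)) {
      nk <- as.character((px[u, 1L] + NBR8[k, 1L]) + 1e6 * (px[u, 2L] + NBR8[k, 2L]))
      v <- lookup[[nk]]
      if (is.null(v) || done[v]) next
      w <- if (NBR8[k, 1L] != 0L && NBR8[k, 2L] != 0L) sqrt(2) else 1
      if (dist[u] + w < dist[v]) { dist[v] <- dist[u] + w; pred[v] <- u }
    }
  }
  list(dist = dist, pred = pred)
}

# Reconstruct the pixel path (indices into `px`) from `from` to `to`.
dijkstra_path <- function(d, to) {
  path <- integer(0)
  i <- to
  while (!is.na(i)) { path <- c(i, path); i <- d$pred[i] }
  path
}

# Length of a polyline through points `pts` (n x 2), resampled every
# `every` vertices to suppress the staircase bias of 8-connected chains.
resampled_length <- function(pts, every = 4L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  keep <- unique(c(seq(1L, n, by = every), n))
  p <- pts[keep, , drop = FALSE]
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}
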