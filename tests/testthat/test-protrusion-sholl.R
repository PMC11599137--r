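test_that("a pure disk yields a whole-disk soma and an empty skeleton graph", {
  m <- make_disk(15)
  soma <- estimate_soma(m)
  ctr <- (dim(m) + 1) / 2
  expect_lte(max(abs(soma$center - ctr)), 1)
  expect_gt(sum(soma$soma_mask) / sum(m), 0.9)
  sk <- build_skeleton(m, soma)
  expect_equal(nrow(sk$roots), 0L)
  expect_equal(nrow(sk$tips), 0L)
  pm <- protrusion_metrics(sk)
  expect_equal(pm$n_primary, 0L)
  expect_equal(pm$n_total, 0L)
  expect_true(is.na(pm$avg_length_um) && is.na(pm$branching_index))
})

test_that("soma center recovers the planted center within 2 px", {
  for (s in c(4, 13, 26, 57)) {
    g <- generate_cell_mask(random_cell_spec(seed = s), seed = s)
    soma <- estimate_soma(g$mask)
    expect_lte(sqrt(sum((soma$center - g$ground_truth$soma_center)^2)), 2)
  }
})

test_that("a two-lobed dumbbell yields one soma, in the larger lobe", {
  m <- matrix(FALSE, 60, 120)
  px <- expand.grid(r = 1:60, c = 1:120)
  m[(px$r - 30)^2 + (px$c - 30)^2 <= 15^2] <- TRUE   # large lobe
  m[(px$r - 30)^2 + (px$c - 95)^2 <= 9^2] <- TRUE    # small lobe
  m[28:32, 30:95] <- TRUE                            # neck
  soma <- estimate_soma(m)
  expect_lte(sqrt(sum((soma$center - c(30, 30))^2)), 1.5)
  # brute-force check: distance transform maximum is in the large lobe
  d <- matrix(as.numeric(EBImage::distmap(EBImage::Image(m * 1))), 60)
  expect_equal(max(d[, 1:60]), max(d))
})

test_that("one straight protrusion gives one root, one tip, correct length", {
  spec <- cell_spec(10, protrusions = list(protrusion_spec(0, lengths = 30)),
                    image_shape = c(101L, 101L))
  g <- generate_cell_mask(spec, seed = 2)
  sk <- build_skeleton(as_cell_crop(g$mask), prune_um = 2)
  expect_equal(nrow(sk$roots), 1L)
  expect_equal(nrow(sk$tips), 1L)
  expect_lt(abs(sk$tip_lengths_px - 30), 2)
})

test_that("jitter spurs below the pruning threshold leave an empty graph", {
  spec <- cell_spec(12, soma_aspect = 1, boundary_jitter_px = 0.5,
                    image_shape = c(61L, 61L))
  g <- generate_cell_mask(spec, seed = 9)
  sk <- build_skeleton(as_cell_crop(g$mask), prune_um = 4)
  expect_equal(protrusion_metrics(sk)$n_total, 0L)
})

test_that("increasing the pruning threshold never increases the tip count", {
  for (s in c(6, 21)) {
    g <- generate_cell_mask(random_cell_spec(seed = s), seed = s)
    crop <- as_cell_crop(g$mask)
    soma <- estimate_soma(crop)
    prev <- Inf
    for (prune in c(1, 3, 6, 10)) {
      n <- protrusion_metrics(build_skeleton(crop, soma, prune_um = prune,
                                             min_protrusion_um = 0))$n_total
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("counts and geodesic lengths recover the planted ground truth", {
  ok <- 0; n_cells <- 60; in_tol <- 0; n_tips <- 0
  for (s in 1:n_cells) {
    g <- generate_cell_mask(random_cell_spec(seed = 400 + s), seed = 400 + s)
    gt <- g$ground_truth
    m <- analyze_protrusions(as_cell_crop(g$mask), prune_um = 4)$metrics
    if (m$n_primary == gt$n_primary && m$n_total == gt$n_total_tips) {
      ok <- ok + 1
      if (gt$n_total_tips > 0) {
        err <- abs(sort(m$tip_lengths_um) - sort(gt$tip_lengths_px))
        in_tol <- in_tol + sum(err <= pmax(2, 0.05 * sort(gt$tip_lengths_px)))
        n_tips <- n_tips + gt$n_total_tips
      }
    }
  }
  expect_gte(ok / n_cells, 0.95)
  expect_gte(in_tol / n_tips, 0.95)
})

test_that("branching index is tips/roots and >= 1 whenever defined", {
  branch <- list(segment = 1L, offset = 0.5,
                 spec = protrusion_spec(1.0, lengths = 20))
  spec <- cell_spec(10, protrusions = list(
    protrusion_spec(0, lengths = 40, branches = list(branch)),
    protrusion_spec(2.1, lengths = 35),
    protrusion_spec(4.2, lengths = 35)), image_shape = c(151L, 151L))
  g <- generate_cell_mask(spec, seed = 5)
  m <- analyze_protrusions(as_cell_crop(g$mask), prune_um = 4)$metrics
  expect_equal(m$n_primary, 3L)
  expect_equal(m$n_total, 4L)
  expect_equal(m$branching_index, 4 / 3)
  expect_gte(m$max_length_um, m$avg_length_um)
})

test_that("sholl profile of a single straight protrusion is a unit step", {
  spec <- cell_spec(10, protrusions = list(protrusion_spec(0, lengths = 30)),
                    image_shape = c(101L, 101L))
  g <- generate_cell_mask(spec, seed = 2)
  res <- analyze_protrusions(as_cell_crop(g$mask), prune_um = 2,
                             sholl_step_um = 5)
  r0 <- res$soma$inscribed_radius_px
  expected <- as.integer(res$sholl$radii_um <= r0 + 30 - 1)
  # compare away from the tip radius (discretization window)
  keep <- abs(res$sholl$radii_um - (r0 + 30)) > 2
  expect_equal(res$sholl$intersections[keep], expected[keep])
  # no protrusions: all-zero profile
  disk <- analyze_protrusions(make_disk(12), prune_um = 4)
  expect_true(all(disk$sholl$intersections == 0L))
})

test_that("sholl intersections at the first radius equal the primary count", {
  spec <- cell_spec(10, protrusions = list(
    protrusion_spec(0.3, lengths = 35), protrusion_spec(2.4, lengths = 35),
    protrusion_spec(4.5, lengths = 35)), image_shape = c(121L, 121L))
  g <- generate_cell_mask(spec, seed = 8)
  res <- analyze_protrusions(as_cell_crop(g$mask), prune_um = 4)
  expect_equal(res$sholl$intersections[1L], 3L)
})

test_that("sholl profiles match the continuous-centerline crossing oracle", {
  mismatches <- 0L; compared <- 0L
  for (s in 1:25) {
    g <- generate_cell_mask(random_cell_spec(seed = 600 + s), seed = 600 + s)
    gt <- g$ground_truth
    res <- analyze_protrusions(as_cell_crop(g$mask), prune_um = 4)
    radii_px <- res$sholl$radii_um
    oracle <- oracle_sholl(gt, res$soma$soma_mask, res$soma$center, radii_px)
    # compare only where the count is well-posed: away from skeleton nodes,
    # tangencies, and the stroke merge zone downstream of branch points
    for (i in seq_along(radii_px)) {
      if (radius_excluded(radii_px[i], gt, res$soma$center)) next
      compared <- compared + 1L
      if (res$sholl$intersections[i] != oracle[i]) mismatches <- mismatches + 1L
    }
  }
  expect_gt(compared, 100L)
  expect_equal(mismatches, 0L)
})

test_that("a mask thinner than 3 px everywhere is flagged whole-mask soma", {
  m <- matrix(FALSE, 30, 30); m[15:16, 5:25] <- TRUE
  soma <- estimate_soma(m)
  expect_true(soma$thin_flag)
  expect_identical(soma$soma_mask, m)
})
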