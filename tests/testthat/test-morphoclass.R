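analyze_and_classify <- function(mask, cfg = classifier_config()) {
  crop <- as_cell_crop(mask)
  shape <- compute_shape_features(crop)
  res <- analyze_protrusions(crop, prune_um = 4)
  classify_morphoclass(shape, res$metrics, res$soma, cfg)
}

test_that("cells without protrusions are nonpolar regardless of shape", {
  expect_equal(analyze_and_classify(make_disk(12)), "nonpolar")
  expect_equal(analyze_and_classify(make_ellipse(30, 25)), "nonpolar")
})

test_that("class-designed synthetic panels are assigned their intended class", {
  per_class_n <- 12L
  agree <- 0L; total <- 0L
  for (cls in morphoclass_levels()) {
    for (i in seq_len(per_class_n)) {
      s <- 1000L + 50L * match(cls, morphoclass_levels()) + i
      g <- generate_cell_mask(random_cell_spec(seed = s, class = cls), seed = s)
      got <- analyze_and_classify(g$mask)
      total <- total + 1L
      if (got == cls) agree <- agree + 1L
    }
  }
  expect_gte(agree / total, 0.9)
})

test_that("classifier demands defined features when protrusions exist", {
  shape <- compute_shape_features(make_disk(10))
  soma <- estimate_soma(make_disk(10))
  broken <- structure(list(n_primary = 2L, n_total = 2L,
                           avg_length_um = NA_real_, max_length_um = NA_real_,
                           branching_index = 1, tip_lengths_um = numeric(0)),
                      class = "protrusion_metrics")
  expect_error(classify_morphoclass(shape, broken, soma), "undefined")
})

test_that("morphoclass distributions average replicates with SEM", {
  one <- morphoclass_distribution(list(rep("elongated", 10)))
  expect_equal(one$proportion, c(0, 0, 0, 1))
  two <- morphoclass_distribution(list(
    c(rep("nonpolar", 5), rep("flat_polar", 5)),
    c(rep("circular_multipolar", 5), rep("elongated", 5))))
  expect_equal(two$proportion, rep(0.25, 4))
  expect_warning(
    morphoclass_distribution(list(character(0), rep("nonpolar", 3))),
    "empty replicate")
})

test_that("interphase transitions count steps and exclude the mitosis step", {
  tr <- data.frame(
    cell_id = c(1, 1, 1, 2, 2, 2),
    parent_id = NA_integer_,
    frame = c(1, 2, 3, 1, 2, 3),
    class = c("nonpolar", "nonpolar", "elongated",
              "flat_polar", "flat_polar", "flat_polar"),
    x_px = 0, y_px = 0,
    mitosis = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  tm <- interphase_transitions(tr)
  expect_equal(tm$counts["nonpolar", "nonpolar"], 1L)
  expect_equal(tm$counts["nonpolar", "elongated"], 1L)
  # the flat_polar step into the mitosis frame is excluded
  expect_equal(sum(tm$counts["flat_polar", ]), 1L)
  expect_equal(unname(tm$fraction_changing["nonpolar"]), 1)
  expect_equal(unname(tm$fraction_changing["flat_polar"]), 0)
  # constant-class track gives an identity proportions row
  solo <- interphase_transitions(tr[4:5, ])
  expect_equal(unname(solo$proportions["flat_polar", "flat_polar"]), 1)
})

test_that("mitotic inheritance tabulates daughters per mother class", {
  tr <- data.frame(
    cell_id = c(1, 1, 10, 11, 2, 2, 20, 21),
    parent_id = c(NA, NA, 1, 1, NA, NA, 2, 2),
    frame = c(1, 2, 3, 3, 1, 2, 3, 3),
    class = c("elongated", "elongated", "elongated", "elongated",
              "nonpolar", "nonpolar", "flat_polar", "elongated"),
    x_px = 0, y_px = 0,
    mitosis = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  mi <- mitotic_inheritance(tr)
  expect_equal(unname(mi$proportions["elongated", "elongated"]), 1)
  expect_equal(unname(mi$proportions["nonpolar", "flat_polar"]), 0.5)
  expect_equal(unname(mi$proportions["nonpolar", "elongated"]), 0.5)
  expect_equal(unname(mi$n_mothers_per_class[c("elongated", "nonpolar")]),
               c(1L, 1L))
  expect_equal(sum(mi$n_mothers_per_class), sum(tr$mitosis))
  # orphan daughters are fatal
  bad <- tr; bad$parent_id[3] <- 99
  expect_error(mitotic_inheritance(bad), "99")
})

test_that("transition and inheritance matrices recover planted dynamics", {
  spec <- track_sim_spec(n_cells = 300, n_frames = 80, mitosis_rate = 0.008,
                         seed = 7)
  tr <- generate_tracks(spec)
  tm <- interphase_transitions(tr)
  for (i in 1:4) for (j in 1:4) {
    p <- spec$transition_matrix[i, j]
    se <- sqrt(p * (1 - p) / tm$row_totals[i])
    expect_lte(abs(tm$proportions[i, j] - p), 3 * se + 1e-12)
  }
  expect_equal(unname(rowSums(tm$proportions)), rep(1, 4), tolerance = 1e-12)
  mi <- mitotic_inheritance(tr)
  for (i in 1:4) {
    n_i <- mi$n_daughters_per_class[i]
    if (n_i < 10) next  # too few mothers of this class for a 3 SE bound
    for (j in 1:4) {
      p <- spec$inheritance_matrix[i, j]
      se <- sqrt(p * (1 - p) / n_i)
      expect_lte(abs(mi$proportions[i, j] - p), 3 * se + 1e-12)
    }
  }
})

test_that("MST length is the pre-mitosis nucleus displacement", {
  tr <- data.frame(cell_id = 1, parent_id = NA, frame = 1:3,
                   class = "elongated",
                   x_px = c(0, 0, 3), y_px = c(0, 0, 4),
                   mitosis = c(FALSE, FALSE, TRUE))
  expect_equal(mst_length(tr, pixel_size_um = 0.5), 2.5)
  still <- tr; still$x_px <- 1; still$y_px <- 2
  expect_equal(mst_length(still), 0)
  first <- data.frame(cell_id = 1, parent_id = NA, frame = 1,
                      class = "nonpolar", x_px = 0, y_px = 0, mitosis = TRUE)
  expect_warning(out <- mst_length(first), "undefined")
  expect_true(is.na(out))
})

test_that("mean MST over simulated divisions matches the Rayleigh step length", {
  sd_px <- 3
  spec <- track_sim_spec(n_cells = 400, n_frames = 40, mitosis_rate = 0.01,
                         nucleus_step_sd_px = sd_px, seed = 13)
  tr <- generate_tracks(spec)
  moms <- unique(tr$cell_id[tr$mitosis])
  msts <- vapply(moms, function(id) {
    df <- tr[tr$cell_id == id, ]
    if (sum(df$mitosis) != 1 || which(df$mitosis) == 1) return(NA_real_)
    mst_length(df)
  }, numeric(1))
  msts <- msts[!is.na(msts)]
  expect_gt(length(msts), 50)
  expected <- sd_px * sqrt(pi / 2)               # mean of a Rayleigh step
  se <- sd_px * sqrt((4 - pi) / 2) / sqrt(length(msts))
  expect_lte(abs(mean(msts) - expected), 3 * se)
})

test_that("ttc density and invasion index follow their definitions", {
  expect_equal(ttc_density(2, 100), 2)
  expect_equal(ttc_density(0, 80), 0)
  expect_equal(ttc_density(3, 150), 2)
  expect_error(ttc_density(1, 0), "> 0")
  expect_equal(invasion_index(10, 10), 1)
  expect_equal(invasion_index(5, 10), 2)
  expect_error(invasion_index(12, 10), "cannot exceed")
  set.seed(1)
  core <- runif(20, 1, 50); tot <- core * runif(20, 1, 4)
  expect_identical(invasion_index(core, tot), tot / core)
  expect_equal(invasion_index(core, tot, reciprocal = TRUE),
               1 / invasion_index(core, tot))
})
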