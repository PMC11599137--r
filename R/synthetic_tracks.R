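# Synthetic time-lapse tracks: per-frame morphoclass labels follow a planted
# Markov chain, cells divide at a per-frame mitosis rate with daughter
# classes drawn from a planted inheritance matrix, and nucleus positions
# follow a Gaussian random walk.

check_stochastic <- function(m, name) {
  if (!is.matrix(m) || any(dim(m) != 4L) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-12))
    stopf("`%s` must be a row-stochastic 4x4 matrix (rows sum to 1 within 1e-12)", name)
  invisible(m)
}

#' Specify a time-lapse track simulation
#'
#' Defaults emulate the live-imaging conditions scored in the study system:
#' interphase morphoclass transitions are rare and concentrated in nonpolar
#' cells, daughters mostly inherit the mother's morphoclass, and roughly
#' 40% of cells divide over a ~100-frame movie (per-frame mitosis rate
#' 0.005).
#'
#' @param n_cells Number of founder cells.
#' @param n_frames Number of frames.
#' @param transition_matrix Row-stochastic 4x4 per-frame interphase
#'   transition matrix (rows/cols in [morphoclass_levels()] order).
#' @param mitosis_rate Per-cell per-frame division probability.
#' @param inheritance_matrix Row-stochastic 4x4 daughter-class-given-mother
#'   matrix.
#' @param nucleus_step_sd_px SD of the per-frame Gaussian nucleus step.
#' @param init_probs Initial morphoclass distribution (default uniform).
#' @param seed Integer seed.
#' @return Object of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_cells = 100L, n_frames = 100L,
                           transition_matrix = default_transition_matrix(),
                           mitosis_rate = 0.005,
                           inheritance_matrix = default_inheritance_matrix(),
                           nucleus_step_sd_px = 2,
                           init_probs = rep(0.25, 4L),
                           seed = 1L) {
  check_number(n_cells, "n_cells", min = 0)
  check_number(n_frames, "n_frames", min = 1)
  check_stochastic(transition_matrix, "transition_matrix")
  check_stochastic(inheritance_matrix, "inheritance_matrix")
  check_number(mitosis_rate, "mitosis_rate", min = 0)
  if (mitosis_rate > 1) stopf("`mitosis_rate` must be a probability")
  check_number(nucleus_step_sd_px, "nucleus_step_sd_px", min = 0)
  if (length(init_probs) != 4L || any(init_probs < 0) ||
      abs(sum(init_probs) - 1) > 1e-12)
    stopf("`init_probs` must be 4 probabilities summing to 1")
  structure(list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
                 transition_matrix = transition_matrix,
                 mitosis_rate = mitosis_rate,
                 inheritance_matrix = inheritance_matrix,
                 nucleus_step_sd_px = nucleus_step_sd_px,
                 init_probs = init_probs, seed = as.integer(seed)),
            class = "track_sim_spec")
}

#' @rdname track_sim_spec
#' @export
default_transition_matrix <- function() {
  lv <- morphoclass_levels()
  m <- matrix(c(0.94, 0.02, 0.02, 0.02,   # nonpolar cells are the dynamic ones
                0.010, 0.980, 0.005, 0.005,
                0.010, 0.005, 0.980, 0.005,
                0.010, 0.005, 0.005, 0.980),
              4L, 4L, byrow = TRUE, dimnames = list(lv, lv))
  m
}

#' @rdname track_sim_spec
#' @export
default_inheritance_matrix <- function() {
  lv <- morphoclass_levels()
  matrix(c(0.70, 0.10, 0.10, 0.10,
           0.05, 0.85, 0.05, 0.05,
           0.05, 0.05, 0.85, 0.05,
           0.05, 0.05, 0.05, 0.85),
         4L, 4L, byrow = TRUE, dimnames = list(lv, lv))
}

#' Simulate morphoclass time-lapse tracks
#'
#' @param spec A [track_sim_spec()].
#' @return A `data.frame` track table with columns `cell_id`, `parent_id`
#'   (NA for founders), `frame`, `class`, `x_px`, `y_px`, `mitosis`
#'   (logical; TRUE marks a mother's final frame).  Daughter tracks start
#'   at the following frame at the mother's last position.
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  lv <- morphoclass_levels()
  local_seed(spec$seed, {
    if (spec$n_cells == 0L)
      return(data.frame(cell_id = integer(0), parent_id = integer(0),
                        frame = integer(0), class = character(0),
                        x_px = numeric(0), y_px = numeric(0),
                        mitosis = logical(0)))
    next_id <- spec$n_cells + 1L
    state <- data.frame(
      cell_id = seq_len(spec$n_cells),
      parent_id = NA_integer_,
      class = sample.int(4L, spec$n_cells, replace = TRUE,
                         prob = spec$init_probs),
      x = stats::runif(spec$n_cells, 0, 512),
      y = stats::runif(spec$n_cells, 0, 512))
    rows <- vector("list", spec$n_frames)
    rows[[1L]] <- data.frame(cell_id = state$cell_id,
                             parent_id = state$parent_id, frame = 1L,
                             class = lv[state$class], x_px = state$x,
                             y_px = state$y, mitosis = FALSE)
    for (fr in seq_len(spec$n_frames - 1L)) {
      n <- nrow(state)
      divides <- stats::runif(n) < spec$mitosis_rate
      # mark the mitosis on the mother's current (last) frame
      if (any(divides)) {
        idx <- which(rows[[fr]]$cell_id %in% state$cell_id[divides])
        rows[[fr]]$mitosis[idx] <- TRUE
      }
      # survivors step their class and position
      surv <- state[!divides, , drop = FALSE]
      if (nrow(surv) > 0L) {
        surv$class <- vapply(surv$class, function(ci)
          sample.int(4L, 1L, prob = spec$transition_matrix[ci, ]), integer(1))
        surv$x <- surv$x + stats::rnorm(nrow(surv), 0, spec$nucleus_step_sd_px)
        surv$y <- surv$y + stats::rnorm(nrow(surv), 0, spec$nucleus_step_sd_px)
      }
      # daughters appear at the next frame, two per mother
      kids <- NULL
      if (any(divides)) {
        moms <- state[divides, , drop = FALSE]
        kid_class <- unlist(lapply(moms$class, function(ci)
          sample.int(4L, 2L, replace = TRUE,
                     prob = spec$inheritance_matrix[ci, ])))
        nm <- nrow(moms)
        kids <- data.frame(
          cell_id = next_id + seq_len(2L * nm) - 1L,
          parent_id = rep(moms$cell_id, each = 2L),
          class = kid_class,
          x = rep(moms$x, each = 2L) + stats::rnorm(2L * nm, 0, spec$nucleus_step_sd_px),
          y = rep(moms$y, each = 2L) + stats::rnorm(2L * nm, 0, spec$nucleus_step_sd_px))
        next_id <- next_id + 2L * nm
      }
      state <- rbind(surv, kids)
      rows[[fr + 1L]] <- data.frame(cell_id = state$cell_id,
                                    parent_id = state$parent_id,
                                    frame = fr + 1L, class = lv[state$class],
                                    x_px = state$x, y_px = state$y,
                                    mitosis = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$cell_id, out$frame), ]
    rownames(out) <- NULL
    out
  })
}
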