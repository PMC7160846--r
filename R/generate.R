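#' Generate a synthetic trial-wise beta series with planted multivoxel codes
#'
#' Produces one parameter-estimate volume per trial for both touch conditions
#' of one subject. Inside each planted region, every trial of stickiness
#' levels 1--3 carries that region's level pattern (a fixed random voxel
#' vector scaled by `effect_size`) plus i.i.d. Gaussian noise; level-0 trials
#' and all voxels outside planted regions are pure noise. Trial labels
#' (condition, run, level, block) follow the block-randomized design: 15
#' blocks of the four levels per run, block order randomized per run.
#'
#' @param design An [experiment_design()].
#' @param regions List of [planted_region()] objects; must be disjoint and lie
#'   inside the volume.
#' @param noise_sd Trial noise standard deviation (> 0).
#' @param subject Integer subject index; the subject's noise stream is derived
#'   from `design$seed` and this index.
#' @return A [beta_series()] with `design$n_conditions * n_runs * 60` trials.
#' @examples
#' d <- experiment_design(volume_shape = c(8, 8, 8))
#' r <- planted_region(block_region(c(3, 3, 3), c(3, 3, 3)), "shared")
#' bs <- generate_beta_series(d, list(r), subject = 1)
#' table(bs$labels$level)
#' @export
generate_beta_series <- function(design, regions = list(), noise_sd = 1,
                                 subject = 1L) {
  stopifnot(inherits(design, "experiment_design"), noise_sd > 0)
  shape <- design$volume_shape
  check_regions(regions, shape)
  labels <- trial_label_table(design, subject)
  n_trials <- nrow(labels)
  v <- prod(shape)

  set.seed(derive_seed(design$seed, "beta_noise", subject))
  betas <- array(stats::rnorm(v * n_trials, sd = noise_sd),
                 dim = c(shape, n_trials))

  for (r in regions) {
    if (r$coding_mode == "null" || r$effect_size == 0) next
    lin <- region_linear_indices(r, shape)
    pat <- region_patterns(r, design, subject)  # [voxel, level, condition]
    for (ci in seq_along(design$conditions)) {
      cond <- design$conditions[ci]
      for (lv in 1:3) {
        idx <- which(labels$condition == cond & labels$level == lv)
        for (tr in idx) {
          off <- (tr - 1L) * v
          betas[off + lin] <- betas[off + lin] + pat[, lv, ci]
        }
      }
    }
  }
  beta_series(betas, labels, voxel_size_mm = design$voxel_size_mm,
              subject = subject)
}

check_regions <- function(regions, shape) {
  if (!length(regions)) return(invisible(NULL))
  seen <- integer(0)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    stopifnot(inherits(r, "planted_region"))
    vs <- r$voxel_index_set
    if (any(vs < 1L) || any(vs > matrix(shape, nrow(vs), 3, byrow = TRUE)))
      stop("planted region ", i, " extends outside the volume ",
           paste(shape, collapse = "x"))
    lin <- region_linear_indices(r, shape)
    overlap <- intersect(seen, lin)
    if (length(overlap))
      stop("planted regions overlap: region ", i, " shares ", length(overlap),
           " voxel(s) with an earlier region (first linear index ", overlap[1], ")")
    seen <- c(seen, lin)
  }
  invisible(NULL)
}

region_linear_indices <- function(r, shape) {
  vs <- r$voxel_index_set
  as.integer(vs[, 1] + (vs[, 2] - 1L) * shape[1] +
               (vs[, 3] - 1L) * shape[1] * shape[2])
}

# Pattern array [voxel, level 1..3, condition]; shared mode repeats the same
# draw across conditions, condition_specific draws independently per condition.
region_patterns <- function(r, design, subject) {
  nv <- nrow(r$voxel_index_set)
  base <- if (r$subject_specific)
    derive_seed(r$pattern_seed, "pattern", subject) else r$pattern_seed
  pat <- array(0, dim = c(nv, 3L, design$n_conditions))
  set.seed(base)
  shared_draw <- matrix(stats::rnorm(nv * 3L), nv, 3L) * r$effect_size
  for (ci in seq_len(design$n_conditions)) {
    if (r$coding_mode == "shared") {
      pat[, , ci] <- shared_draw
    } else {
      set.seed(derive_seed(base, "cond_pattern", ci))
      pat[, , ci] <- matrix(stats::rnorm(nv * 3L), nv, 3L) * r$effect_size
    }
  }
  pat
}

# Block-randomized label table: per condition and run, 15 blocks each holding
# the 4 levels in random order. Block order is seeded per subject/run.
trial_label_table <- function(design, subject) {
  rows <- list()
  for (ci in seq_along(design$conditions)) {
    cond <- design$conditions[ci]
    for (run in seq_len(design$n_runs_per_condition)) {
      set.seed(derive_seed(design$seed, paste0("blocks_", cond, "_run", run),
                           subject))
      lev <- unlist(lapply(seq_len(design$n_reps_per_level_per_run),
                           function(b) sample(design$levels)))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, run = run,
        block = rep(seq_len(design$n_reps_per_level_per_run),
                    each = design$n_levels),
        level = lev)
    }
  }
  labels <- do.call(rbind, rows)
  labels$trial <- seq_len(nrow(labels))
  labels[, c("trial", "condition", "run", "level", "block")]
}

#' Generate a synthetic BOLD timeseries from a beta-series ground truth
#'
#' Builds per-run 4D timeseries in which each voxel's signal is the sum over
#' trials of the trial's true amplitude times the hemodynamic-response kernel
#' placed at that trial's Detach onset, plus a low-frequency cosine drift and
#' i.i.d. Gaussian noise. Returns, per (condition, run), the timeseries and an
#' event table (onset_s, duration_s, condition, level, run, block).
#'
#' @param design An [experiment_design()].
#' @param beta_truth A [beta_series()] holding the true trial amplitudes.
#' @param hrf A kernel from [canonical_hrf()].
#' @param drift_amp Amplitude of the low-frequency drift (0 disables it).
#' @param noise_sd Measurement noise SD (0 gives a noiseless series).
#' @param detach_offset_s Seconds from trial start to the Detach event
#'   (3 s touch-and-hold precedes the detach).
#' @return List with one element per (condition, run): each a list with
#'   `timeseries` (4D array `[x, y, z, time]`), `events` (data frame), and
#'   `condition`/`run`.
#' @export
generate_timeseries <- function(design, beta_truth, hrf = canonical_hrf(),
                                drift_amp = 0, noise_sd = 1,
                                detach_offset_s = 3) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(beta_truth, "beta_series"), noise_sd >= 0)
  shape <- design$volume_shape
  v <- prod(shape)
  n_tp <- ceiling((design$baseline_s +
                     design$n_trials_per_run * design$trial_duration_s + 32) /
                    design$tr_s)
  out <- list()
  for (cond in design$conditions) {
    for (run in seq_len(design$n_runs_per_condition)) {
      keep <- beta_truth$labels$condition == cond & beta_truth$labels$run == run
      lab <- beta_truth$labels[keep, , drop = FALSE]
      onsets <- design$baseline_s +
        (seq_len(nrow(lab)) - 1L) * design$trial_duration_s + detach_offset_s
      if (any(onsets > (n_tp - 1L) * design$tr_s))
        stop("trial onsets overrun the run length")
      if (anyDuplicated(onsets))
        stop("overlapping trial onsets within a run")
      events <- data.frame(onset_s = onsets, duration_s = 0,
                           condition = cond, level = lab$level,
                           run = run, block = lab$block, trial = lab$trial)
      dm <- build_design_matrix(events, n_timepoints = n_tp,
                                tr_s = design$tr_s, hrf = hrf,
                                include_intercept = FALSE)
      amp <- t(matrix(beta_truth$betas[, , , keep, drop = FALSE],
                      nrow = v))                       # trials x voxels
      ts_mat <- dm$matrix %*% amp                      # time x voxels
      if (drift_amp != 0) {
        set.seed(derive_seed(design$seed, paste0("drift_", cond, "_run", run),
                             beta_truth$subject))
        t_s <- (seq_len(n_tp) - 1L) * design$tr_s
        n_basis <- max(1L, floor(2 * n_tp * design$tr_s / 128))
        coef <- stats::rnorm(n_basis * v, sd = drift_amp)
        for (k in seq_len(n_basis)) {
          basis <- cos(pi * k * t_s / max(t_s))
          ts_mat <- ts_mat + outer(basis,
                                   coef[((k - 1L) * v + 1L):(k * v)])
        }
      }
      if (noise_sd > 0) {
        set.seed(derive_seed(design$seed, paste0("tsnoise_", cond, "_run", run),
                             beta_truth$subject))
        ts_mat <- ts_mat + stats::rnorm(length(ts_mat), sd = noise_sd)
      }
      out[[paste0(cond, "_run", run)]] <-
        list(timeseries = array(t(ts_mat), dim = c(shape, n_tp)),
             events = events, condition = cond, run = run)
    }
  }
  out
}

#' Generate per-subject behavioral rating means
#'
#' Simulates, for every subject, condition and level, the mean perceived
#' stickiness rating over the 30 trials of that cell (2 runs x 15 reps):
#' cell mean from the [rating_model()] plus a subject-level offset, averaged
#' trial noise, clipped to the 1--5 response scale.
#'
#' @param design An [experiment_design()].
#' @param model A [rating_model()].
#' @return Data frame with columns `subject`, `condition`, `level`, `rating`
#'   (class `rating_table`).
#' @export
generate_ratings <- function(design, model = rating_model()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(model, "rating_model"),
            ncol(model$mean_rating) == design$n_levels)
  n_per_cell <- design$n_runs_per_condition * design$n_reps_per_level_per_run
  rows <- list()
  for (s in seq_len(design$n_subjects)) {
    set.seed(derive_seed(model$seed, "ratings", s))
    offset <- stats::rnorm(1, 0, model$subject_sd)
    for (ci in 1:2) {
      for (lv in design$levels) {
        mu <- model$mean_rating[ci, lv + 1L] + offset
        r <- mean(stats::rnorm(n_per_cell, mu, model$rating_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = rownames(model$mean_rating)[ci],
          level = lv, rating = min(5, max(1, r)))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rating_table", "data.frame")
  out
}
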