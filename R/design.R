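#' Experiment design for the two-touch stickiness paradigm
#'
#' Describes the factorial layout of the scanning sessions: two touch
#' conditions (skin contact, glove contact), two runs per condition, 60 trials
#' per run arranged as 15 blocks of four stickiness levels (0--3, level 0 being
#' the no-tape control), and the acquisition timing.
#'
#' @param n_subjects Number of subjects.
#' @param volume_shape Integer vector of length 3, voxels per axis.
#' @param voxel_size_mm Positive reals of length 3, voxel edge lengths in mm.
#' @param n_conditions Number of touch conditions (2: skin, glove).
#' @param n_runs_per_condition Runs per condition (2).
#' @param n_levels Number of stickiness levels including the level-0 control (4).
#' @param n_reps_per_level_per_run Repetitions of each level per run (15).
#' @param tr_s Repetition time in seconds (1.52).
#' @param trial_duration_s Approximate trial duration in seconds (9).
#' @param baseline_s Initial rest period per run in seconds.
#' @param seed Integer master seed for the design; per-subject and per-stage
#'   seeds are derived from it with [derive_seed()].
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design(n_subjects = 4, volume_shape = c(12, 12, 12))
#' d$n_trials_per_run  # 60
#' @export
experiment_design <- function(n_subjects = 18,
                              volume_shape = c(20L, 20L, 20L),
                              voxel_size_mm = c(3, 3, 3),
                              n_conditions = 2L,
                              n_runs_per_condition = 2L,
                              n_levels = 4L,
                              n_reps_per_level_per_run = 15L,
                              tr_s = 1.52,
                              trial_duration_s = 9,
                              baseline_s = 10,
                              seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            n_conditions == 2L, tr_s > 0, trial_duration_s > 0,
            n_levels >= 2L, n_reps_per_level_per_run >= 1L,
            n_runs_per_condition >= 1L)
  d <- structure(list(
    n_subjects = as.integer(n_subjects),
    volume_shape = as.integer(volume_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    n_conditions = as.integer(n_conditions),
    conditions = c("skin", "glove"),
    n_runs_per_condition = as.integer(n_runs_per_condition),
    n_levels = as.integer(n_levels),
    levels = seq_len(n_levels) - 1L,
    n_reps_per_level_per_run = as.integer(n_reps_per_level_per_run),
    tr_s = tr_s,
    trial_duration_s = trial_duration_s,
    baseline_s = baseline_s,
    seed = as.integer(seed)
  ), class = "experiment_design")
  d$n_trials_per_run <- d$n_levels * d$n_reps_per_level_per_run
  d$n_trials_per_condition <- d$n_trials_per_run * d$n_runs_per_condition
  d
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", x$n_subjects, "subjects;",
      x$n_conditions, "conditions x", x$n_runs_per_condition, "runs x",
      x$n_trials_per_run, "trials (",
      x$n_levels, "levels x", x$n_reps_per_level_per_run, "reps );",
      "volume", paste(x$volume_shape, collapse = "x"),
      "voxels; TR", x$tr_s, "s\n")
  invisible(x)
}

#' Planted multivoxel code region
#'
#' A set of voxels carrying a known level-dependent activity pattern, used to
#' give the synthetic data decodable structure. `shared` regions use the same
#' level-to-pattern mapping in both touch conditions (decodable within each
#' condition and across conditions); `condition_specific` regions draw
#' independent mappings per condition (decodable within but not across);
#' `null` regions plant nothing.
#'
#' @param voxel_index_set Integer matrix, one row per voxel, columns x/y/z
#'   (1-based indices), or the result of [block_region()].
#' @param coding_mode One of `"shared"`, `"condition_specific"`, `"null"`.
#' @param effect_size Pattern amplitude in units of the noise SD.
#' @param pattern_seed Integer seed fixing the level patterns.
#' @param subject_specific If `TRUE` (default) each subject receives its own
#'   pattern draw (derived deterministically from `pattern_seed`), mirroring
#'   the lack of fine-grained pattern alignment across brains; if `FALSE` one
#'   draw is shared by all subjects.
#' @return An object of class `planted_region`.
#' @export
planted_region <- function(voxel_index_set,
                           coding_mode = c("shared", "condition_specific", "null"),
                           effect_size = 3,
                           pattern_seed = 101L,
                           subject_specific = TRUE) {
  coding_mode <- match.arg(coding_mode)
  voxel_index_set <- as.matrix(voxel_index_set)
  stopifnot(ncol(voxel_index_set) == 3L, nrow(voxel_index_set) >= 1L,
            effect_size >= 0)
  storage.mode(voxel_index_set) <- "integer"
  structure(list(voxel_index_set = voxel_index_set,
                 coding_mode = coding_mode,
                 effect_size = effect_size,
                 pattern_seed = as.integer(pattern_seed),
                 subject_specific = isTRUE(subject_specific)),
            class = "planted_region")
}

#' Cuboid voxel index set
#'
#' Convenience constructor of the voxel index set of an axis-aligned block,
#' for planting regions.
#'
#' @param corner Integer length-3 lower corner (1-based).
#' @param size Integer length-3 edge lengths in voxels.
#' @return Integer matrix with one row per voxel.
#' @export
block_region <- function(corner, size) {
  as.matrix(expand.grid(x = corner[1] + seq_len(size[1]) - 1L,
                        y = corner[2] + seq_len(size[2]) - 1L,
                        z = corner[3] + seq_len(size[3]) - 1L))
}

#' Behavioral rating model
#'
#' Mean perceived-stickiness ratings (1--5 scale) per condition and level plus
#' trial-level and subject-level variability. The defaults reproduce the
#' qualitative behavioral pattern of the study: levels 0 and 1 perceived
#' equally in both touch conditions, levels 2 and 3 perceived as less sticky
#' through the glove, and means strictly increasing with physical level within
#' each condition.
#'
#' @param mean_rating 2 x n_levels numeric matrix (rows skin, glove) of mean
#'   ratings in `[1, 5]`.
#' @param rating_sd Trial-to-trial rating SD.
#' @param subject_sd SD of the per-subject rating offset (random intercept).
#' @param seed Integer seed.
#' @return An object of class `rating_model`.
#' @export
rating_model <- function(mean_rating = rbind(skin  = c(1.3, 2.2, 3.6, 4.5),
                                             glove = c(1.3, 2.2, 2.9, 3.8)),
                         rating_sd = 0.8,
                         subject_sd = 0.3,
                         seed = 1L) {
  mean_rating <- as.matrix(mean_rating)
  stopifnot(nrow(mean_rating) == 2L, all(mean_rating >= 1), all(mean_rating <= 5),
            rating_sd >= 0, subject_sd >= 0)
  if (is.null(rownames(mean_rating))) rownames(mean_rating) <- c("skin", "glove")
  structure(list(mean_rating = mean_rating, rating_sd = rating_sd,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "rating_model")
}

#' Derive a reproducible stage seed
#'
#' Stable integer hash of (master seed, stage label, unit index), so that each
#' stochastic stage of the pipeline draws from its own stream and adding
#' subjects never perturbs existing ones. The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @param unit Integer unit (e.g. subject) index, default 0.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, stage, unit = 0L) {
  key <- paste(master, stage, unit, sep = "/")
  h <- 17
  for (ch in utf8ToInt(key)) {
    # multiplicative congruential mix; products stay < 2^53 so doubles are exact
    h <- (h * 69069 + ch) %% 2147483629
  }
  as.integer(h %% 2147483646L) + 1L
}
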