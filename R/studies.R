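# Simulation studies exercising the pipeline end to end on synthetic data
# with known ground truth: chance calibration, familywise error control,
# planted-pattern dissociation, and behavioral-ANOVA operating
# characteristics. These are the package's validation experiments; the
# vignette discusses the study sizes.

#' Chance calibration of the within-condition searchlight
#'
#' Generates a null dataset (no planted regions, trial labels independent of
#' the data), runs the within-condition searchlight for both touch conditions
#' of every subject, and returns the mean decoding accuracy (before chance
#' subtraction) over all valid voxels. With three balanced classes this must
#' sit at 1/3.
#'
#' @param n_subjects Subjects to simulate (default 12).
#' @param volume_shape Volume (default 20^3 voxels).
#' @param seed Master seed.
#' @param spec A [searchlight_spec()].
#' @return List: `mean_accuracy` (grand mean over subjects, conditions and
#'   valid voxels), `per_subject` (matrix subjects x conditions),
#'   `n_valid_voxels`.
#' @export
study_chance_calibration <- function(n_subjects = 12,
                                     volume_shape = c(20, 20, 20),
                                     seed = 1L, spec = searchlight_spec()) {
  design <- experiment_design(n_subjects = n_subjects,
                              volume_shape = volume_shape,
                              seed = derive_seed(seed, "chance_design"))
  per_subject <- matrix(NA_real_, n_subjects, 2,
                        dimnames = list(NULL, design$conditions))
  n_valid <- NA_integer_
  for (s in seq_len(n_subjects)) {
    bs <- normalize_betas(generate_beta_series(design, subject = s))
    for (cond in design$conditions) {
      m <- run_searchlight_within(subset_trials(bs, condition = cond),
                                  spec = spec)
      per_subject[s, cond] <- mean(m$accuracy[m$valid])
      n_valid <- sum(m$valid)
    }
  }
  list(mean_accuracy = mean(per_subject), per_subject = per_subject,
       n_valid_voxels = n_valid)
}

#' Familywise error rate of the sign-flip cluster-size threshold
#'
#' Simulates independent null datasets; for each, computes the subjects'
#' within-condition searchlight accuracy maps, the group one-sided t-map,
#' suprathreshold clusters at the voxelwise threshold, the sign-flip
#' max-cluster-size threshold, and whether any cluster is declared
#' significant. The fraction of datasets with at least one declared cluster
#' estimates the familywise error rate, nominally controlled at `alpha`.
#'
#' @param n_datasets Independent null datasets (default 100).
#' @param n_subjects Subjects per dataset (default 8).
#' @param volume_shape Volume (default 16^3).
#' @param n_perm Sign-flip permutations per dataset (default 200).
#' @param p_voxel Voxelwise one-sided p threshold (default 0.001).
#' @param alpha Familywise alpha (default 0.05).
#' @param connectivity Cluster connectivity (default 18).
#' @param seed Master seed.
#' @param spec A [searchlight_spec()].
#' @return List: `fwer` (fraction), `any_significant` (logical per dataset),
#'   `thresholds` (per-dataset cluster-size thresholds).
#' @export
study_fwer <- function(n_datasets = 100, n_subjects = 8,
                       volume_shape = c(16, 16, 16), n_perm = 200,
                       p_voxel = 0.001, alpha = 0.05, connectivity = 18L,
                       seed = 1L, spec = searchlight_spec()) {
  any_sig <- logical(n_datasets)
  thresholds <- integer(n_datasets)
  for (d in seq_len(n_datasets)) {
    design <- experiment_design(n_subjects = n_subjects,
                                volume_shape = volume_shape,
                                seed = derive_seed(seed, "fwer_dataset", d))
    maps <- lapply(seq_len(n_subjects), function(s) {
      bs <- normalize_betas(generate_beta_series(design, subject = s))
      run_searchlight_within(subset_trials(bs, condition = "skin"),
                             spec = spec)
    })
    stat <- group_ttest(maps)
    observed <- extract_clusters(stat, p_voxel = p_voxel, min_size = 0L,
                                 connectivity = connectivity)
    null <- signflip_null(maps, p_voxel = p_voxel,
                          connectivity = connectivity, n_perm = n_perm,
                          alpha = alpha,
                          seed = derive_seed(seed, "fwer_flips", d))
    decl <- significant_clusters(observed, null)
    any_sig[d] <- nrow(decl) > 0 && any(decl$significant)
    thresholds[d] <- null$threshold_size
  }
  list(fwer = mean(any_sig), any_significant = any_sig,
       thresholds = thresholds)
}

#' Planted-pattern dissociation study
#'
#' Plants one shared-code block (identical level patterns in both touch
#' conditions) and one condition-specific block (independent patterns per
#' condition) and verifies the within-versus-cross decoding logic: the shared
#' block should be recovered as a significant cluster by cross-condition
#' decoding, while the condition-specific block should decode at chance
#' across conditions despite high within-condition accuracy.
#'
#' The planted blocks are 6x6x6 voxels (216 voxels, the scale of the study's
#' reported clusters, 138--739 voxels) and sit in opposite corners of the
#' volume, separated by a full searchlight width so no cube straddles both. A
#' block larger than the 5-voxel cube also means different searchlight
#' centers inside it decode from different pattern subsets, so the
#' region-mean transfer accuracy of the condition-specific block averages
#' over many independent pattern-to-class mappings rather than a single one.
#'
#' @param n_seeds Independent datasets (default 20).
#' @param n_subjects Subjects per dataset (default 12).
#' @param volume_shape Volume (default 18^3).
#' @param effect_size Planted pattern amplitude / noise SD (default 3).
#' @param n_perm Sign-flip permutations (default 100).
#' @param seed Master seed.
#' @param spec A [searchlight_spec()].
#' @return List: `shared_detected` (logical per dataset: a significant cross
#'   cluster overlaps the shared block), `detection_rate`, `com_error_voxels`
#'   (center-of-mass distance of the detecting cluster from the block
#'   center), `cross_specific` and `within_specific` (per-dataset mean raw
#'   accuracy over the condition-specific block), plus the block definitions.
#' @export
study_dissociation <- function(n_seeds = 20, n_subjects = 12,
                               volume_shape = c(18, 18, 18), effect_size = 3,
                               n_perm = 100, seed = 1L,
                               spec = searchlight_spec()) {
  block <- c(6L, 6L, 6L)
  shared_corner <- c(2L, 2L, 2L)
  specific_corner <- volume_shape - block  # leaves a full cube width of gap
  shared_vox <- block_region(shared_corner, block)
  specific_vox <- block_region(specific_corner, block)
  shared_center <- shared_corner + (block - 1) / 2
  lin <- function(vox) as.integer(vox[, 1] + (vox[, 2] - 1) * volume_shape[1] +
                                    (vox[, 3] - 1) * prod(volume_shape[1:2]))
  shared_lin <- lin(shared_vox)
  specific_lin <- lin(specific_vox)

  detected <- logical(n_seeds)
  com_err <- rep(NA_real_, n_seeds)
  cross_specific <- within_specific <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    design <- experiment_design(n_subjects = n_subjects,
                                volume_shape = volume_shape,
                                seed = derive_seed(seed, "dissoc_design", i))
    regions <- list(
      planted_region(shared_vox, "shared", effect_size = effect_size,
                     pattern_seed = derive_seed(seed, "shared_pat", i)),
      planted_region(specific_vox, "condition_specific",
                     effect_size = effect_size,
                     pattern_seed = derive_seed(seed, "specific_pat", i)))
    cross_maps <- vector("list", n_subjects)
    cs <- ws <- 0
    for (s in seq_len(n_subjects)) {
      bs <- normalize_betas(generate_beta_series(design, regions, subject = s))
      skin <- subset_trials(bs, condition = "skin")
      glove <- subset_trials(bs, condition = "glove")
      cross_maps[[s]] <- run_searchlight_cross(skin, glove, spec = spec)
      cs <- cs + mean(cross_maps[[s]]$accuracy[specific_lin])
      ws <- ws + mean(run_searchlight_within(skin, spec = spec)$accuracy[specific_lin])
    }
    cross_specific[i] <- cs / n_subjects
    within_specific[i] <- ws / n_subjects
    stat <- group_ttest(cross_maps)
    observed <- extract_clusters(stat, p_voxel = 0.001, min_size = 0L)
    null <- signflip_null(cross_maps, n_perm = n_perm,
                          seed = derive_seed(seed, "dissoc_flips", i))
    decl <- significant_clusters(observed, null)
    members <- attr(decl, "members")
    hit <- which(decl$significant &
                   vapply(members, function(m)
                     length(intersect(m, shared_lin)) > 0, logical(1)))
    detected[i] <- length(hit) > 0
    if (detected[i]) {
      com <- colMeans(arrayInd(members[[hit[1]]], volume_shape))
      com_err[i] <- sqrt(sum((com - shared_center)^2))
    }
  }
  list(shared_detected = detected, detection_rate = mean(detected),
       com_error_voxels = com_err,
       cross_specific = cross_specific, within_specific = within_specific,
       mean_cross_specific = mean(cross_specific),
       mean_within_specific = mean(within_specific),
       shared_voxels = shared_vox, specific_voxels = specific_vox)
}

#' Operating characteristics of the behavioral RM-ANOVA
#'
#' Repeatedly generates rating tables from a [rating_model()] and records,
#' per dataset, the ANOVA dfs, the interaction p-value and the Tukey
#' condition-difference p per level. With the default model the interaction
#' should be significant and condition differences confined to levels 2--3;
#' with a no-difference model the condition main effect should reject at the
#' nominal rate.
#'
#' @param n_seeds Number of simulated datasets (default 100).
#' @param model A [rating_model()].
#' @param n_subjects Subjects per dataset (default 18).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed.
#' @return List of rates: `interaction_sig`, `pattern_rate` (interaction
#'   significant AND condition differences at levels 2--3 only),
#'   `condition_sig` (main-effect rejection rate), and the dfs of the first
#'   fit.
#' @export
study_rating_anova <- function(n_seeds = 100, model = rating_model(),
                               n_subjects = 18, alpha = 0.05, seed = 1L) {
  inter_sig <- cond_sig <- pattern_ok <- logical(n_seeds)
  dfs <- NULL
  for (i in seq_len(n_seeds)) {
    m <- model
    m$seed <- derive_seed(seed, "rating_seed", i)
    design <- experiment_design(n_subjects = n_subjects,
                                seed = derive_seed(seed, "rating_design", i))
    res <- behavioral_rm_anova(generate_ratings(design, m))
    if (is.null(dfs)) dfs <- res$effects[, c("effect", "df_num", "df_den")]
    inter_sig[i] <- res$effects$p[res$effects$effect == "condition:level"] < alpha
    cond_sig[i] <- res$effects$p[res$effects$effect == "condition"] < alpha
    ph <- res$posthoc$p_adjusted
    pattern_ok[i] <- inter_sig[i] && all(ph[1:2] > alpha) && all(ph[3:4] < alpha)
  }
  list(interaction_sig = mean(inter_sig), condition_sig = mean(cond_sig),
       pattern_rate = mean(pattern_ok), dfs = dfs)
}
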