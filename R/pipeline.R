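# End-to-end orchestration: generate -> normalize -> searchlight -> group
# inference -> report, with a serializable config and a run manifest.

#' Build a pipeline run configuration
#'
#' A plain nested list (YAML-serializable, see [save_config()]) holding every
#' stage's parameters. All randomness downstream is derived from
#' `master_seed` via [derive_seed()].
#'
#' @param n_subjects,volume_shape,noise_sd Design/generation parameters.
#' @param regions List of region descriptions, each a list with `corner`,
#'   `size`, `coding_mode`, `effect_size`, `pattern_seed`.
#' @param normalization_scope `"per_run"` or `"per_condition"`.
#' @param searchlight List: `side_voxels`, `min_in_mask`, `variance_floor`.
#' @param inference List: `p_voxel`, `min_size`, `connectivity`, `n_perm`,
#'   `alpha`.
#' @param master_seed Integer master seed.
#' @param output_dir Output directory.
#' @param save_betas Write every subject's beta series to disk (off by
#'   default; they dominate the disk footprint).
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_subjects = 8,
                       volume_shape = c(16, 16, 16),
                       noise_sd = 1,
                       regions = list(),
                       normalization_scope = "per_run",
                       searchlight = list(side_voxels = 5, min_in_mask = 30,
                                          variance_floor = 1e-6),
                       inference = list(p_voxel = 0.001, min_size = 0,
                                        connectivity = 18, n_perm = 200,
                                        alpha = 0.05),
                       master_seed = 1,
                       output_dir = tempfile("stickmvpa_run_"),
                       save_betas = FALSE) {
  structure(list(n_subjects = n_subjects, volume_shape = volume_shape,
                 noise_sd = noise_sd, regions = regions,
                 normalization_scope = normalization_scope,
                 searchlight = searchlight, inference = inference,
                 master_seed = master_seed, output_dir = output_dir,
                 save_betas = save_betas),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `save_config` returns the path invisibly; `load_config` the
#'   restored `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

config_regions <- function(config) {
  lapply(config$regions, function(r)
    planted_region(block_region(unlist(r$corner), unlist(r$size)),
                   coding_mode = r$coding_mode,
                   effect_size = if (is.null(r$effect_size)) 3 else r$effect_size,
                   pattern_seed = if (is.null(r$pattern_seed)) 101L
                                  else r$pattern_seed))
}

config_design <- function(config) {
  experiment_design(n_subjects = config$n_subjects,
                    volume_shape = config$volume_shape,
                    seed = derive_seed(config$master_seed, "design"))
}

config_spec <- function(config) {
  searchlight_spec(side_voxels = config$searchlight$side_voxels,
                   min_in_mask = config$searchlight$min_in_mask,
                   variance_floor = config$searchlight$variance_floor)
}

# One subject's three searchlight analyses from generated betas.
subject_maps <- function(design, regions, config, spec, s) {
  bs <- generate_beta_series(design, regions, noise_sd = config$noise_sd,
                             subject = s)
  bs <- normalize_betas(bs, scope = config$normalization_scope)
  skin <- subset_trials(bs, condition = "skin")
  glove <- subset_trials(bs, condition = "glove")
  list(within_skin = run_searchlight_within(skin, spec = spec),
       within_glove = run_searchlight_within(glove, spec = spec),
       cross = run_searchlight_cross(skin, glove, spec = spec),
       betas = bs)
}

group_inference <- function(maps, config, seed) {
  stat <- group_ttest(maps)
  inf <- config$inference
  observed <- extract_clusters(stat, p_voxel = inf$p_voxel,
                               min_size = inf$min_size,
                               connectivity = inf$connectivity)
  null <- signflip_null(maps, p_voxel = inf$p_voxel,
                        connectivity = inf$connectivity,
                        n_perm = inf$n_perm, alpha = inf$alpha, seed = seed)
  list(stat = stat, clusters = significant_clusters(observed, null),
       null = null)
}

#' Run the full analysis pipeline
#'
#' Executes, for every subject, beta-series generation, normalization and the
#' three searchlight analyses (within skin, within glove, cross-condition);
#' then the random-effects group inference with the sign-flip cluster-size
#' threshold per analysis; then the reporting stage (per-cluster transfer
#' confusion matrices, direction comparison, level ANOVA, behavioral
#' RM-ANOVA). All artifacts and a manifest are written under
#' `config$output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the group results per analysis, the
#'   reports, and the manifest.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$output_dir, 2) != 0)
    stop("run_full_pipeline(): output_dir is not writable")
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("stickmvpa")),
                   stages = list(), seeds = list())
  manifest_path <- file.path(config$output_dir, "manifest.json")
  persist <- function() jsonlite::write_json(manifest, manifest_path,
                                             auto_unbox = TRUE, digits = NA,
                                             force = TRUE)
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    persist()
    res
  }

  design <- config_design(config)
  regions <- config_regions(config)
  spec <- config_spec(config)

  subjects <- run_stage("searchlight", function() {
    lapply(seq_len(config$n_subjects), function(s) {
      sm <- subject_maps(design, regions, config, spec, s)
      for (an in c("within_skin", "within_glove", "cross"))
        write_accuracy_map(sm[[an]],
                           file.path(config$output_dir,
                                     sprintf("sub-%02d_%s", s, an)))
      if (isTRUE(config$save_betas))
        write_beta_series(sm$betas,
                          file.path(config$output_dir,
                                    sprintf("sub-%02d_betas", s)))
      sm
    })
  })

  groups <- run_stage("inference", function() {
    out <- list()
    for (an in c("within_skin", "within_glove", "cross")) {
      seed <- derive_seed(config$master_seed, paste0("signflip_", an))
      manifest$seeds[[paste0("signflip_", an)]] <<- seed
      g <- group_inference(lapply(subjects, `[[`, an), config, seed)
      write_cluster_table(g$clusters,
                          file.path(config$output_dir,
                                    paste0("clusters_", an, ".tsv")))
      write_permutation_null(g$null,
                             file.path(config$output_dir,
                                       paste0("null_", an, ".json")))
      out[[an]] <- g
    }
    out
  })

  reports <- run_stage("report", function() {
    rep <- list()
    cl <- groups$cross$clusters
    sig_rows <- which(!is.na(cl$significant) & cl$significant)
    members <- attr(cl, "members")
    if (length(sig_rows)) {
      rep$clusters <- lapply(seq_along(sig_rows), function(i) {
        vox <- members[[sig_rows[i]]]
        per_sub <- lapply(subjects, function(sm) {
          bs <- sm$betas
          decode_region(subset_trials(bs, condition = "skin"),
                        subset_trials(bs, condition = "glove"), vox)
        })
        diag_rates <- do.call(rbind, lapply(seq_along(per_sub), function(s) {
          r <- (confusion_rates(per_sub[[s]]$confusion_ab) +
                  confusion_rates(per_sub[[s]]$confusion_ba)) / 2
          data.frame(subject = s, region = i, level = 1:3, rate = diag(r))
        }))
        list(confusions = per_sub,
             direction_test = compare_directions(
               lapply(per_sub, `[[`, "confusion_ab"),
               lapply(per_sub, `[[`, "confusion_ba")),
             diag_rates = diag_rates)
      })
      all_diag <- do.call(rbind, lapply(rep$clusters, `[[`, "diag_rates"))
      rep$level_anova <- level_accuracy_anova(all_diag)
    }
    ratings <- generate_ratings(
      design, rating_model(seed = derive_seed(config$master_seed, "ratings")))
    write_tsv(ratings, file.path(config$output_dir, "ratings.tsv"))
    rep$behavioral <- behavioral_rm_anova(ratings)
    rep
  })

  manifest$seeds$design <- design$seed
  persist()
  invisible(list(groups = groups, reports = reports, manifest = manifest,
                 output_dir = config$output_dir))
}

#' Write a self-describing synthetic dataset to disk
#'
#' Presets: `null` (8 subjects, 16^3, no planted structure),
#' `shared_signal` (adds one shared-code block, cross-decodable),
#' `specific_signal` (one condition-specific block, within-decodable only),
#' `paper_scale` (18 subjects, 2 conditions x 2 runs x 60 trials, TR 1.52 s).
#' Writes per-subject beta series (NIfTI + label TSV), behavioral ratings
#' (TSV), the design description (YAML) and a manifest (JSON).
#'
#' @param preset One of `"null"`, `"shared_signal"`, `"specific_signal"`,
#'   `"paper_scale"`.
#' @param dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides of [experiment_design()] arguments (e.g.
#'   `volume_shape`).
#' @return The directory, invisibly.
#' @export
make_fixture <- function(preset = c("null", "shared_signal",
                                    "specific_signal", "paper_scale"),
                         dir = tempfile("stickmvpa_fixture_"), seed = 1L,
                         ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 paper_scale = list(n_subjects = 18L,
                                    volume_shape = c(20L, 20L, 20L)),
                 list(n_subjects = 8L, volume_shape = c(16L, 16L, 16L)))
  over <- list(...)
  base[names(over)] <- over
  base$seed <- derive_seed(seed, paste0("fixture_", preset))
  design <- do.call(experiment_design, base)
  if (any(design$volume_shape < 6L) && preset != "null")
    stop("make_fixture(): volume too small to hold the planted regions")
  corner <- pmax(1L, design$volume_shape %/% 5L)
  far_corner <- design$volume_shape - 2L           # 3-voxel block at the edge
  regions <- switch(preset,
    null = list(),
    shared_signal = list(planted_region(block_region(corner, c(3, 3, 3)),
                                        "shared", pattern_seed = seed + 11L)),
    specific_signal = list(planted_region(block_region(corner, c(3, 3, 3)),
                                          "condition_specific",
                                          pattern_seed = seed + 12L)),
    paper_scale = list(
      planted_region(block_region(corner, c(3, 3, 3)), "shared",
                     pattern_seed = seed + 11L),
      planted_region(block_region(far_corner, c(3, 3, 3)),
                     "condition_specific", pattern_seed = seed + 12L)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(design$n_subjects)) {
    bs <- generate_beta_series(design, regions, subject = s)
    write_beta_series(bs, file.path(dir, sprintf("sub-%02d_betas", s)))
  }
  ratings <- generate_ratings(design,
                              rating_model(seed = derive_seed(seed, "ratings")))
  write_tsv(ratings, file.path(dir, "ratings.tsv"))
  yaml::write_yaml(unclass(design), file.path(dir, "design.yaml"))
  jsonlite::write_json(
    list(preset = preset, seed = seed,
         n_subjects = design$n_subjects,
         regressors_per_condition = design$n_trials_per_condition,
         regions = lapply(regions, function(r)
           list(coding_mode = r$coding_mode, n_voxels = nrow(r$voxel_index_set),
                effect_size = r$effect_size))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
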