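# Shared fixtures: everything is generated in code at test time.

tiny_design <- function(volume_shape = c(10, 10, 10), n_subjects = 2,
                        seed = 42, ...) {
  experiment_design(n_subjects = n_subjects, volume_shape = volume_shape,
                    seed = seed, ...)
}

# Linear indices of a block inside a volume.
block_lin <- function(corner, size, shape) {
  vox <- block_region(corner, size)
  as.integer(vox[, 1] + (vox[, 2] - 1L) * shape[1] +
               (vox[, 3] - 1L) * shape[1] * shape[2])
}

# Hand-built accuracy map (for group-level tests that need exact values).
fake_map <- function(values, valid = NULL, subject = 1L) {
  if (is.null(valid)) valid <- array(TRUE, dim(values))
  structure(list(values = values, valid = valid,
                 accuracy = values + 1 / 3, analysis = "within_skin",
                 subject = subject, spec = searchlight_spec(),
                 voxel_size_mm = c(3, 3, 3)),
            class = "accuracy_map")
}

# Hand-built group stat map with given t values.
fake_stat <- function(t_values, dof = 17L, valid = NULL) {
  if (is.null(valid)) valid <- array(TRUE, dim(t_values))
  structure(list(t_values = t_values, valid_mask = valid,
                 degenerate = array(FALSE, dim(t_values)),
                 dof = dof, n_subjects = dof + 1L,
                 voxel_size_mm = c(3, 3, 3)),
            class = "group_stat_map")
}

# Independent diagonal-Gaussian log-posterior oracle for GNB checks.
gnb_oracle_log_posterior <- function(model, x) {
  sapply(seq_along(model$classes), function(k) {
    apply(x, 1, function(row)
      model$log_priors[k] +
        sum(stats::dnorm(row, model$means[k, ],
                         sqrt(model$variances[k, ]), log = TRUE)))
  })
}
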