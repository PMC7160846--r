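test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf()
  expect_equal(h$values[1], 0, tolerance = 1e-6)   # zero at onset
  expect_equal(max(h$values), 1)                   # peak-normalized
  # dense-grid oracle for the peak location of the double-gamma difference
  tt <- seq(0, 32, by = 1e-3)
  dense <- dgamma(tt, shape = 6, rate = 1) - dgamma(tt, shape = 16, rate = 1) / 6
  oracle_peak <- tt[which.max(dense)]
  expect_lt(abs(h$t[which.max(h$values)] - oracle_peak), h$sampling_dt_s)
  # later peak delay moves the argmax later, monotonically
  h8 <- canonical_hrf(peak_delay_s = 8)
  expect_gt(h8$t[which.max(h8$values)], h$t[which.max(h$values)])
  expect_error(canonical_hrf(peak_delay_s = -1), "positive")
  expect_error(canonical_hrf(undershoot_delay_s = 3), "undershoot")
})

test_that("design matrix has one column per trial plus nuisance and intercept", {
  ev1 <- data.frame(onset_s = 10)
  d1 <- build_design_matrix(ev1, n_timepoints = 50, tr_s = 1.52)
  expect_equal(ncol(d1$matrix), 2)                 # trial + intercept
  ev60 <- data.frame(onset_s = 10 + (0:59) * 9)
  d60 <- build_design_matrix(ev60, n_timepoints = 400, tr_s = 1.52,
                             nuisance = matrix(rnorm(400 * 6), 400, 6))
  expect_equal(ncol(d60$matrix), 67)               # 60 trials + 6 nuisance + 1
  expect_equal(d60$trial_columns, 1:60)
  expect_error(build_design_matrix(data.frame(onset_s = c(5, 1e5)),
                                   n_timepoints = 50, tr_s = 1.52),
               "event\\(s\\) 2")
})

test_that("trial columns match an independent convolution oracle", {
  tr <- 1.52
  n_tp <- 120
  ev <- data.frame(onset_s = c(20, 29))            # two trials 9 s apart
  h <- canonical_hrf()
  dm <- build_design_matrix(ev, n_timepoints = n_tp, tr_s = tr, hrf = h)
  # oracle: explicit convolution of an impulse train with the kernel on the
  # fine grid via stats::convolve, then TR sampling
  dt <- h$sampling_dt_s
  n_fine <- ceiling((n_tp * tr + 33) / dt)
  oracle_col <- function(onset) {
    stick <- numeric(n_fine)
    stick[round(onset / dt) + 1] <- 1
    conv <- stats::convolve(stick, rev(h$values), type = "open")
    conv[round((seq_len(n_tp) - 1) * tr / dt) + 1]
  }
  for (i in 1:2)
    expect_equal(dm$matrix[, i], oracle_col(ev$onset_s[i]), tolerance = 1e-10)
  expect_equal(cor(dm$matrix[, 1], dm$matrix[, 2]),
               cor(oracle_col(20), oracle_col(29)), tolerance = 1e-10)
})

test_that("noiseless GLM recovers amplitudes to machine precision", {
  d <- tiny_design(volume_shape = c(4, 4, 4), n_reps_per_level_per_run = 2)
  truth <- generate_beta_series(d, subject = 1)
  ts <- generate_timeseries(d, truth, drift_amp = 0, noise_sd = 0)
  run <- ts[[1]]
  dm <- build_design_matrix(run$events, n_timepoints = dim(run$timeseries)[4],
                            tr_s = d$tr_s)
  fit <- fit_trialwise_glm(run$timeseries, dm)
  keep <- truth$labels$condition == run$condition & truth$labels$run == run$run
  expect_equal(fit$betas, truth$betas[, , , keep, drop = FALSE],
               tolerance = 1e-6)
  # residuals orthogonal to the design columns
  v <- prod(dim(run$timeseries)[1:3])
  y <- t(matrix(run$timeseries, nrow = v))
  resid <- y - dm$matrix %*% rbind(t(matrix(fit$betas, nrow = v)),
                                   matrix(0, 1, v))
  expect_lt(max(abs(crossprod(dm$matrix, resid))), 1e-8)
})

test_that("noisy GLM recovery correlates with the truth", {
  d <- tiny_design(volume_shape = c(4, 4, 4), n_reps_per_level_per_run = 4)
  truth <- generate_beta_series(d, subject = 1, noise_sd = 2)  # amplitudes ~N(0,2)
  ts <- generate_timeseries(d, truth, drift_amp = 0.5, noise_sd = 0.8)
  run <- ts[[1]]
  n_tp <- dim(run$timeseries)[4]
  dm <- build_design_matrix(run$events, n_timepoints = n_tp, tr_s = d$tr_s,
                            nuisance = cosine_drift_basis(n_tp, d$tr_s))
  fit <- fit_trialwise_glm(run$timeseries, dm)
  keep <- truth$labels$condition == run$condition & truth$labels$run == run$run
  r <- cor(as.vector(fit$betas), as.vector(truth$betas[, , , keep]))
  expect_gte(r, 0.95)
})

test_that("beta series is invariant under consistent design-column reordering", {
  d <- tiny_design(volume_shape = c(3, 3, 3), n_reps_per_level_per_run = 2)
  truth <- generate_beta_series(d, subject = 1)
  ts <- generate_timeseries(d, truth, drift_amp = 0, noise_sd = 0.5)
  run <- ts[[1]]
  dm <- build_design_matrix(run$events, n_timepoints = dim(run$timeseries)[4],
                            tr_s = d$tr_s)
  perm <- sample(seq_along(dm$trial_columns))
  dm2 <- dm
  dm2$matrix <- cbind(dm$matrix[, perm, drop = FALSE],
                      dm$matrix[, -dm$trial_columns, drop = FALSE])
  dm2$events <- dm$events[perm, , drop = FALSE]
  f1 <- fit_trialwise_glm(run$timeseries, dm)
  f2 <- fit_trialwise_glm(run$timeseries, dm2)
  # f2's trials come out in permuted order with permuted labels: same content
  expect_equal(f2$betas[, , , order(perm), drop = FALSE], f1$betas,
               tolerance = 1e-10)
  expect_equal(f2$labels$trial[order(perm)], f1$labels$trial)
})

test_that("rank deficiency falls back to the minimum-norm solution", {
  set.seed(7)
  ts <- array(rnorm(2 * 2 * 2 * 30), dim = c(2, 2, 2, 30))
  ev <- data.frame(onset_s = c(5, 5))   # duplicated regressor
  dm <- build_design_matrix(ev, n_timepoints = 30, tr_s = 1)
  expect_warning(fit <- fit_trialwise_glm(ts, dm), "rank deficient")
  expect_true(all(is.finite(fit$betas)))
  # minimum norm splits the shared amplitude equally between the twins
  expect_equal(fit$betas[, , , 1], fit$betas[, , , 2], tolerance = 1e-8)
  expect_error(fit_trialwise_glm(ts, dm, mask = array(FALSE, c(2, 2, 2))),
               "mask")
})

test_that("normalization centers and scales within each scope group only", {
  d <- tiny_design(volume_shape = c(3, 3, 3))
  bs <- generate_beta_series(d, subject = 1)
  nb <- normalize_betas(bs, scope = "per_run")
  v <- prod(d$volume_shape)
  m <- matrix(nb$betas, nrow = v)
  groups <- interaction(nb$labels$condition, nb$labels$run)
  for (g in levels(groups)) {
    sub <- m[, groups == g, drop = FALSE]
    expect_equal(max(abs(rowMeans(sub))), 0, tolerance = 1e-12)
    expect_equal(apply(sub, 1, sd), rep(1, v), tolerance = 1e-12)
  }
  # idempotence
  nb2 <- normalize_betas(nb, scope = "per_run")
  expect_equal(nb2$betas, nb$betas, tolerance = 1e-12)
  # leakage guard: perturbing run 2 leaves run 1's normalized values unchanged
  bs2 <- bs
  bs2$betas[, , , bs$labels$run == 2] <- bs2$betas[, , , bs$labels$run == 2] + 5
  nb3 <- normalize_betas(bs2, scope = "per_run")
  expect_identical(nb3$betas[, , , bs$labels$run == 1],
                   nb$betas[, , , bs$labels$run == 1])
})

test_that("zero-variance voxels are zeroed and counted", {
  d <- tiny_design(volume_shape = c(3, 3, 3))
  bs <- generate_beta_series(d, subject = 1)
  bs$betas[1, 1, 1, ] <- 7   # constant voxel
  expect_message(nb <- normalize_betas(bs), "zero-variance")
  expect_true(all(nb$betas[1, 1, 1, ] == 0))
  expect_equal(attr(nb, "n_zero_variance"), 4L)  # one voxel in each of 4 groups
  one_trial <- bs
  one_trial$betas <- bs$betas[, , , 1, drop = FALSE]
  one_trial$labels <- bs$labels[1, , drop = FALSE]
  expect_error(normalize_betas(one_trial), "fewer than 2")
})
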