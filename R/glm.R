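#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a difference of two gamma densities, one
#' modeling the response peak (~5 s) and one the post-stimulus undershoot
#' (~15 s), evaluated on `[0, duration_s]` and rescaled so its maximum is 1.
#' With unit rate, a gamma density with shape `a` peaks at `a - 1` seconds, so
#' the default `peak_delay_s = 6` places the response maximum near 5 s.
#'
#' @param peak_delay_s Shape of the peak gamma (seconds; > 0).
#' @param undershoot_delay_s Shape of the undershoot gamma (seconds; > peak).
#' @param peak_undershoot_ratio Ratio of peak to undershoot amplitude (> 0).
#' @param sampling_dt_s Sampling interval of the kernel (seconds; > 0).
#' @param duration_s Kernel support (seconds).
#' @return Object of class `hrf_kernel`: list with `t` (sample times) and
#'   `values` (kernel, peak-normalized to 1), plus the parameters.
#' @examples
#' h <- canonical_hrf()
#' h$t[which.max(h$values)]  # ~5 s
#' @export
canonical_hrf <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                          peak_undershoot_ratio = 6, sampling_dt_s = 0.1,
                          duration_s = 32) {
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 ||
      peak_undershoot_ratio <= 0 || sampling_dt_s <= 0)
    stop("canonical_hrf(): all parameters must be positive")
  if (undershoot_delay_s <= peak_delay_s)
    stop("canonical_hrf(): undershoot must come after the peak")
  t <- seq(0, duration_s, by = sampling_dt_s)
  h <- stats::dgamma(t, shape = peak_delay_s, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay_s, rate = 1) / peak_undershoot_ratio
  h <- h / max(h)
  structure(list(t = t, values = h, sampling_dt_s = sampling_dt_s,
                 peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_undershoot_ratio = peak_undershoot_ratio),
            class = "hrf_kernel")
}

#' Single-trial design matrix
#'
#' One column per trial: a unit impulse at the trial's Detach onset convolved
#' with the HRF on a fine time grid, then sampled at the TR grid. Optional
#' nuisance columns (e.g. head-motion or low-frequency cosine regressors) and
#' an intercept are appended after the trial columns.
#'
#' @param events Data frame with at least `onset_s`; optional `trial`,
#'   `condition`, `run`, `level`, `block` columns are carried through as the
#'   trial labels of the fitted beta series.
#' @param n_timepoints Number of volumes in the run.
#' @param tr_s Repetition time in seconds.
#' @param hrf Kernel from [canonical_hrf()].
#' @param nuisance Optional numeric matrix `n_timepoints x k` of nuisance
#'   regressors.
#' @param include_intercept Append an all-ones column (default `TRUE`).
#' @return Object of class `design_matrix`: `matrix`, `regressor_labels`,
#'   `trial_columns` (indices of the trial columns, in event order), `events`.
#' @export
build_design_matrix <- function(events, n_timepoints, tr_s,
                                hrf = canonical_hrf(), nuisance = NULL,
                                include_intercept = TRUE) {
  stopifnot(is.data.frame(events), "onset_s" %in% names(events),
            n_timepoints >= 1, tr_s > 0, inherits(hrf, "hrf_kernel"))
  run_end <- (n_timepoints - 1L) * tr_s
  bad <- which(events$onset_s < 0 | events$onset_s > run_end)
  if (length(bad))
    stop("build_design_matrix(): event(s) ", paste(bad, collapse = ", "),
         " fall outside the run [0, ", round(run_end, 2), "] s")
  dt <- hrf$sampling_dt_s
  n_fine <- ceiling((run_end + max(hrf$t)) / dt) + 1L
  n_trials <- nrow(events)
  x <- matrix(0, n_timepoints, n_trials)
  tr_fine_idx <- round((seq_len(n_timepoints) - 1L) * tr_s / dt) + 1L
  for (i in seq_len(n_trials)) {
    col <- numeric(n_fine)
    start <- round(events$onset_s[i] / dt) + 1L
    span <- seq_along(hrf$values)
    col[start + span - 1L] <- hrf$values
    x[, i] <- col[tr_fine_idx]
  }
  labels <- if (!is.null(events$trial)) paste0("trial_", events$trial)
            else paste0("trial_", seq_len(n_trials))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_timepoints)
      stop("build_design_matrix(): nuisance rows (", nrow(nuisance),
           ") must equal n_timepoints (", n_timepoints, ")")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    x <- cbind(x, nuisance)
    labels <- c(labels, colnames(nuisance))
  }
  if (include_intercept) {
    x <- cbind(x, 1)
    labels <- c(labels, "intercept")
  }
  colnames(x) <- labels
  structure(list(matrix = x, regressor_labels = labels,
                 trial_columns = seq_len(n_trials), events = events,
                 tr_s = tr_s),
            class = "design_matrix")
}

#' Low-frequency cosine nuisance regressors
#'
#' Discrete cosine basis covering periods longer than `cutoff_s`, the standard
#' drift model equivalent to high-pass filtering at `1/cutoff_s` Hz.
#'
#' @param n_timepoints Number of volumes.
#' @param tr_s Repetition time (s).
#' @param cutoff_s High-pass cutoff period (default 128 s).
#' @return Matrix `n_timepoints x k` (possibly zero columns).
#' @export
cosine_drift_basis <- function(n_timepoints, tr_s, cutoff_s = 128) {
  t_total <- n_timepoints * tr_s
  k <- max(0L, floor(2 * t_total / cutoff_s))
  if (k == 0L) return(matrix(0, n_timepoints, 0))
  tp <- seq_len(n_timepoints) - 0.5
  m <- sapply(seq_len(k), function(j) cos(pi * j * tp / n_timepoints))
  colnames(m) <- paste0("cosine_", seq_len(k))
  m
}

#' Fit a trial-wise GLM to a 4D timeseries
#'
#' Ordinary least squares per in-mask voxel against the single-trial design;
#' the trial columns' estimates become the beta series. Rank-deficient designs
#' are resolved by the minimum-norm (pseudoinverse) solution with a warning.
#'
#' @param timeseries 4D array `[x, y, z, time]`.
#' @param design A [build_design_matrix()] result.
#' @param mask 3D logical array (default: all voxels).
#' @return A [beta_series()]; voxels outside the mask are 0.
#' @export
fit_trialwise_glm <- function(timeseries, design, mask = NULL) {
  stopifnot(length(dim(timeseries)) == 4L, inherits(design, "design_matrix"))
  d <- dim(timeseries)
  x <- design$matrix
  if (nrow(x) != d[4L])
    stop("fit_trialwise_glm(): design rows (", nrow(x),
         ") must equal timepoints (", d[4L], ")")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))
  if (!any(mask)) stop("fit_trialwise_glm(): mask is empty")
  v <- prod(d[1:3])
  y <- matrix(timeseries, nrow = v)[as.vector(mask), , drop = FALSE]
  y <- t(y)                                     # time x in-mask voxels
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("fit_trialwise_glm(): design is rank deficient (rank ", qx$rank,
            " < ", ncol(x), "); using the minimum-norm solution")
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    coefs <- qr.coef(qx, y)
  }
  trial_b <- coefs[design$trial_columns, , drop = FALSE]  # trials x in-mask
  n_trials <- length(design$trial_columns)
  betas <- array(0, dim = c(d[1:3], n_trials))
  flat <- matrix(0, v, n_trials)
  flat[as.vector(mask), ] <- t(trial_b)
  betas[] <- flat
  ev <- design$events
  labels <- data.frame(
    trial = if (!is.null(ev$trial)) ev$trial else seq_len(n_trials),
    condition = if (!is.null(ev$condition)) ev$condition else "unknown",
    run = if (!is.null(ev$run)) ev$run else 1L,
    level = if (!is.null(ev$level)) ev$level else NA_integer_,
    block = if (!is.null(ev$block)) ev$block else NA_integer_)
  beta_series(betas, labels, mask_ref = "fitted")
}

#' Normalize a beta series for decoding
#'
#' Per voxel, within each normalization group, centers the trial estimates and
#' scales them to unit variance. The default `per_run` scope keeps the
#' two-fold run-wise cross-validation free of train/test leakage. Voxels with
#' zero variance in a group are set to 0 and counted in the
#' `n_zero_variance` attribute.
#'
#' @param bs A [beta_series()].
#' @param scope `"per_run"` (groups = condition x run) or `"per_condition"`.
#' @return The normalized `beta_series`.
#' @export
normalize_betas <- function(bs, scope = c("per_run", "per_condition")) {
  scope <- match.arg(scope)
  stopifnot(inherits(bs, "beta_series"))
  groups <- if (scope == "per_run")
    interaction(bs$labels$condition, bs$labels$run, drop = TRUE)
  else factor(bs$labels$condition)
  d <- dim(bs$betas)
  m <- matrix(bs$betas, nrow = prod(d[1:3]))   # voxels x trials
  n_zero <- 0L
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2L)
      stop("normalize_betas(): group '", g, "' has fewer than 2 trials")
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sub <- sub - mu
    sdv <- sqrt(rowSums(sub^2) / (length(idx) - 1L))
    zero <- sdv == 0
    n_zero <- n_zero + sum(zero)
    sdv[zero] <- 1
    sub <- sub / sdv
    sub[zero, ] <- 0
    m[, idx] <- sub
  }
  if (n_zero > 0L)
    message("normalize_betas(): ", n_zero,
            " zero-variance voxel/group combinations set to 0")
  out <- bs
  out$betas <- array(m, dim = d)
  attr(out, "n_zero_variance") <- n_zero
  attr(out, "normalization_scope") <- scope
  out
}
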