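# Cubical-searchlight GNB decoding.
#
# The GNB log-likelihood decomposes over features, so instead of refitting a
# classifier inside every cube we compute, once per (class, test trial), a
# whole-volume image of per-voxel log-likelihood contributions and accumulate
# it over the 5x5x5 cube with cumulative box sums. Every center then gets the
# exact cube-restricted GNB decision at a cost linear in the volume.

# Moving-window sum of width `side` (odd) along dim 1 of an array, truncated
# at the array edges.
movsum_dim1 <- function(a, side) {
  d <- dim(a)
  n1 <- d[1L]
  half <- (side - 1L) %/% 2L
  m <- matrix(a, nrow = n1)
  cs <- m
  if (n1 > 1L) for (i in 2:n1) cs[i, ] <- cs[i - 1L, ] + cs[i, ]
  hi <- pmin(seq_len(n1) + half, n1)
  lo <- seq_len(n1) - half - 1L
  out <- cs[hi, , drop = FALSE]
  pos <- which(lo > 0L)
  if (length(pos))
    out[pos, ] <- out[pos, , drop = FALSE] - cs[lo[pos], , drop = FALSE]
  dim(out) <- d
  out
}

# Box sum over a side^3 cube (truncated at edges) for a 3D array or a 4D
# array treated as a stack of 3D volumes.
boxsum3 <- function(a, side) {
  nd <- length(dim(a))
  stopifnot(nd %in% c(3L, 4L), side %% 2L == 1L)
  perm <- if (nd == 3L) c(2L, 3L, 1L) else c(2L, 3L, 1L, 4L)
  for (ax in 1:3) {
    a <- movsum_dim1(a, side)
    a <- aperm(a, perm)
  }
  a
}

#' Searchlight specification
#'
#' @param side_voxels Odd cube side in voxels (default 5).
#' @param min_in_mask Minimum in-mask voxels a cube must contain for its
#'   center to be valid (default 30).
#' @param chance_level Chance accuracy subtracted from each center (default
#'   1/3 for the three decoded levels).
#' @param variance_floor Relative GNB variance floor (see [gnb_fit()]).
#' @return Object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(side_voxels = 5L, min_in_mask = 30L,
                             chance_level = 1 / 3, variance_floor = 1e-6) {
  stopifnot(side_voxels %% 2L == 1L, side_voxels >= 1L,
            chance_level > 0, chance_level < 1, min_in_mask >= 1L)
  structure(list(side_voxels = as.integer(side_voxels),
                 min_in_mask = as.integer(min_in_mask),
                 chance_level = chance_level,
                 variance_floor = variance_floor),
            class = "searchlight_spec")
}

# Core: per-center GNB accuracy for one train/test split.
# xtr/xte: trials x V matrices over the full grid; out-of-mask columns are
# ignored (their log-likelihood contribution is zeroed). Returns a 3D array of
# accuracies (NA-free; caller applies validity).
searchlight_fold_accuracy <- function(xtr, ytr, xte, yte, dims, mask_vec,
                                      spec) {
  classes <- sort(unique(ytr))
  k <- length(classes)
  n_te <- nrow(xte)
  v <- prod(dims)
  counts <- as.numeric(table(factor(ytr, levels = classes)))
  log_priors <- log(counts / length(ytr))

  means <- matrix(0, k, v)
  vars <- matrix(0, k, v)
  for (i in seq_len(k)) {
    xi <- xtr[ytr == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    vars[i, ] <- colMeans(xi^2) - means[i, ]^2
  }
  floor_val <- spec$variance_floor * mean(vars[, mask_vec, drop = FALSE])
  vars <- pmax(vars, floor_val)

  best <- NULL
  pred <- NULL
  for (i in seq_len(k)) {
    centered <- sweep(xte, 2L, means[i, ])
    ll <- -sweep(centered^2, 2L, 2 * vars[i, ], "/") -
      matrix(0.5 * log(2 * pi * vars[i, ]), n_te, v, byrow = TRUE)
    ll[, !mask_vec] <- 0
    s <- boxsum3(array(t(ll), dim = c(dims, n_te)), spec$side_voxels)
    s <- matrix(s, nrow = v) + log_priors[i]     # V x n_te
    if (is.null(best)) {
      best <- s
      pred <- matrix(1L, v, n_te)
    } else {
      upd <- s > best                             # strict: ties keep lowest
      best[upd] <- s[upd]
      pred[upd] <- i
    }
  }
  correct <- pred == matrix(match(yte, classes), v, n_te, byrow = TRUE)
  array(rowMeans(correct), dim = dims)
}

new_accuracy_map <- function(values, valid, accuracy, analysis, subject,
                             spec, voxel_size_mm, extra = list()) {
  structure(c(list(values = values, valid = valid, accuracy = accuracy,
                   analysis = analysis, subject = subject, spec = spec,
                   voxel_size_mm = voxel_size_mm), extra),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat("Accuracy map (", x$analysis, "), subject ", x$subject, ": ",
      sum(x$valid), " valid voxels, mean accuracy-chance ",
      round(mean(x$values[x$valid]), 4), "\n", sep = "")
  invisible(x)
}

searchlight_validity <- function(mask, spec) {
  in_cube <- boxsum3(array(as.numeric(mask), dim = dim(mask)),
                     spec$side_voxels)
  mask & (in_cube >= spec$min_in_mask)
}

#' Within-condition searchlight decoding
#'
#' For every in-mask center voxel, decodes the three stickiness levels
#' (1--3) from the normalized betas of the in-mask voxels inside the cube,
#' with a two-fold cross-validation in which each run is one fold. The two
#' fold accuracies are averaged and the chance level subtracted. Level-0
#' trials, if present, are excluded before decoding.
#'
#' @param bs A normalized [beta_series()] holding exactly one condition (or
#'   pass `condition` to select one) with exactly two runs.
#' @param mask 3D logical array (default: all voxels).
#' @param spec A [searchlight_spec()].
#' @param condition Optional condition to subset.
#' @return An `accuracy_map`: `values` (accuracy minus chance), `valid`
#'   (centers whose cube holds at least `min_in_mask` voxels), `accuracy`
#'   (raw mean accuracy).
#' @export
run_searchlight_within <- function(bs, mask = NULL, spec = searchlight_spec(),
                                   condition = NULL) {
  stopifnot(inherits(bs, "beta_series"), inherits(spec, "searchlight_spec"))
  if (!is.null(condition)) bs <- subset_trials(bs, condition = condition)
  conds <- unique(bs$labels$condition)
  if (length(conds) != 1L)
    stop("run_searchlight_within(): beta series holds ", length(conds),
         " conditions; pass `condition` to select one")
  bs <- subset_trials(bs, levels = 1:3)
  runs <- sort(unique(bs$labels$run))
  if (length(runs) != 2L)
    stop("run_searchlight_within(): exactly 2 runs required, found ",
         length(runs))
  if (!all(1:3 %in% bs$labels$level))
    stop("run_searchlight_within(): levels 1-3 must all be present")
  dims <- dim(bs$betas)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  mask_vec <- as.vector(mask)
  x <- beta_matrix(bs)
  x[, !mask_vec] <- 0
  y <- bs$labels$level
  in_run <- lapply(runs, function(r) bs$labels$run == r)
  acc <- 0
  for (f in 1:2) {
    tr <- in_run[[f]]
    te <- in_run[[3L - f]]
    acc <- acc + searchlight_fold_accuracy(
      x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE], y[te],
      dims, mask_vec, spec)
  }
  acc <- acc / 2
  valid <- searchlight_validity(mask, spec)
  new_accuracy_map(values = acc - spec$chance_level, valid = valid,
                   accuracy = acc,
                   analysis = paste0("within_", conds),
                   subject = bs$subject, spec = spec,
                   voxel_size_mm = bs$voxel_size_mm)
}

#' Cross-condition (transfer) searchlight decoding
#'
#' Trains the cube-wise GNB on all level 1--3 trials of one touch condition
#' and tests on all trials of the other, and vice versa; the two direction
#' accuracies are averaged and chance subtracted. Per-direction accuracy
#' volumes are retained for the fold-comparison analyses.
#'
#' @param bs_a,bs_b Normalized [beta_series()] objects, one condition each,
#'   sharing geometry and the level set \{1,2,3\}.
#' @param mask 3D logical array (default: all voxels).
#' @param spec A [searchlight_spec()].
#' @return An `accuracy_map` with extra elements `accuracy_ab` (train A, test
#'   B) and `accuracy_ba`.
#' @export
run_searchlight_cross <- function(bs_a, bs_b, mask = NULL,
                                  spec = searchlight_spec()) {
  stopifnot(inherits(bs_a, "beta_series"), inherits(bs_b, "beta_series"))
  bs_a <- subset_trials(bs_a, levels = 1:3)
  bs_b <- subset_trials(bs_b, levels = 1:3)
  if (!setequal(unique(bs_a$labels$level), unique(bs_b$labels$level)))
    stop("run_searchlight_cross(): the two conditions have different level sets")
  dims <- dim(bs_a$betas)[1:3]
  stopifnot(all(dim(bs_b$betas)[1:3] == dims))
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  mask_vec <- as.vector(mask)
  xa <- beta_matrix(bs_a); xa[, !mask_vec] <- 0
  xb <- beta_matrix(bs_b); xb[, !mask_vec] <- 0
  ya <- bs_a$labels$level
  yb <- bs_b$labels$level
  acc_ab <- searchlight_fold_accuracy(xa, ya, xb, yb, dims, mask_vec, spec)
  acc_ba <- searchlight_fold_accuracy(xb, yb, xa, ya, dims, mask_vec, spec)
  acc <- (acc_ab + acc_ba) / 2
  valid <- searchlight_validity(mask, spec)
  new_accuracy_map(values = acc - spec$chance_level, valid = valid,
                   accuracy = acc, analysis = "cross",
                   subject = bs_a$subject, spec = spec,
                   voxel_size_mm = bs_a$voxel_size_mm,
                   extra = list(accuracy_ab = acc_ab, accuracy_ba = acc_ba))
}

#' Cross-condition decoding of one region of interest
#'
#' Non-searchlight transfer decoding using all voxels of a region as the
#' feature set: GNB trained on all level 1--3 trials of one condition,
#' tested on the other, in both directions. Used to build the per-cluster
#' confusion matrices.
#'
#' @param bs_a,bs_b Normalized one-condition [beta_series()] objects.
#' @param voxel_indices Linear voxel indices of the region.
#' @param variance_floor Relative GNB variance floor.
#' @return List with per-direction predictions, true labels and
#'   [confusion_from_predictions()] matrices (`ab` = trained on `bs_a`).
#' @export
decode_region <- function(bs_a, bs_b, voxel_indices, variance_floor = 1e-6) {
  bs_a <- subset_trials(bs_a, levels = 1:3)
  bs_b <- subset_trials(bs_b, levels = 1:3)
  xa <- beta_matrix(bs_a)[, voxel_indices, drop = FALSE]
  xb <- beta_matrix(bs_b)[, voxel_indices, drop = FALSE]
  ya <- bs_a$labels$level
  yb <- bs_b$labels$level
  pred_ab <- gnb_predict(gnb_fit(xa, ya, variance_floor), xb)
  pred_ba <- gnb_predict(gnb_fit(xb, yb, variance_floor), xa)
  list(pred_ab = pred_ab, true_ab = yb,
       pred_ba = pred_ba, true_ba = ya,
       confusion_ab = confusion_from_predictions(yb, pred_ab),
       confusion_ba = confusion_from_predictions(ya, pred_ba))
}
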