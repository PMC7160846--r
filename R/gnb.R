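#' Fit a Gaussian Naive Bayes classifier
#'
#' Per class and feature: sample mean and maximum-likelihood (biased)
#' variance; class priors from training frequencies. Variances are clamped
#' from below at `variance_floor` times the grand mean of all per-class,
#' per-feature variances, which keeps degenerate (near-constant) features from
#' dominating the log-likelihood.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class labels, one per sample (>= 2 samples per class).
#' @param variance_floor Relative variance floor (default `1e-6`).
#' @return Object of class `gnb_model`: `classes` (sorted unique labels),
#'   `means` and `variances` (class x feature), `log_priors`.
#' @export
gnb_fit <- function(x, y, variance_floor = 1e-6) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), variance_floor >= 0)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("gnb_fit(): class(es) ", paste(small, collapse = ", "),
         " have fewer than 2 samples")
  k <- length(classes)
  p <- ncol(x)
  means <- matrix(0, k, p)
  vars <- matrix(0, k, p)
  for (i in seq_len(k)) {
    xi <- x[y == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    vars[i, ] <- colMeans(xi^2) - means[i, ]^2   # ML (biased) variance
  }
  floor_val <- variance_floor * mean(vars)
  vars <- pmax(vars, floor_val)
  structure(list(classes = classes, means = means, variances = vars,
                 log_priors = log(as.numeric(counts) / length(y)),
                 variance_floor = variance_floor),
            class = "gnb_model")
}

#' Log-posterior (up to the evidence term) of a GNB model
#'
#' @param model A [gnb_fit()] model.
#' @param x Samples x features matrix.
#' @return Matrix samples x classes of `log prior + sum of Gaussian
#'   log-likelihoods`.
#' @export
gnb_log_posterior <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop("gnb_log_posterior(): feature count (", ncol(x),
         ") does not match the model (", ncol(model$means), ")")
  k <- length(model$classes)
  ll <- matrix(0, nrow(x), k)
  for (i in seq_len(k)) {
    mu <- model$means[i, ]
    v <- model$variances[i, ]
    centered <- sweep(x, 2L, mu)
    ll[, i] <- model$log_priors[i] -
      0.5 * sum(log(2 * pi * v)) -
      rowSums(sweep(centered^2, 2L, 2 * v, "/"))
  }
  colnames(ll) <- as.character(model$classes)
  ll
}

#' Predict classes with a GNB model
#'
#' Argmax of the log posterior; ties are broken toward the lowest class label
#' so that forced ties are deterministic.
#'
#' @param model A [gnb_fit()] model.
#' @param x Samples x features matrix.
#' @return Vector of predicted class labels (same type as the training labels).
#' @export
gnb_predict <- function(model, x) {
  lp <- gnb_log_posterior(model, x)
  model$classes[max.col(lp, ties.method = "first")]
}
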