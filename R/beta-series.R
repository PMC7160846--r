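#' Trial-wise beta series container
#'
#' Bundles one volume of trial-wise parameter estimates per trial with the
#' per-trial labels used downstream (condition, run, stickiness level, block).
#'
#' @param betas 4D numeric array `[x, y, z, trial]`.
#' @param labels Data frame with one row per trial and columns `trial`,
#'   `condition`, `run`, `level`, `block` (block may be `NA`).
#' @param voxel_size_mm Numeric length-3 voxel size.
#' @param subject Subject identifier.
#' @param mask_ref Optional identifier of the brain mask the betas refer to.
#' @return Object of class `beta_series`.
#' @export
beta_series <- function(betas, labels, voxel_size_mm = c(3, 3, 3),
                        subject = 1L, mask_ref = NULL) {
  stopifnot(length(dim(betas)) == 4L, nrow(labels) == dim(betas)[4L])
  required <- c("trial", "condition", "run", "level")
  stopifnot(all(required %in% names(labels)))
  if (is.null(labels$block)) labels$block <- NA_integer_
  structure(list(betas = betas,
                 labels = as.data.frame(labels),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 subject = subject,
                 mask_ref = mask_ref),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  d <- dim(x$betas)
  cat("Beta series: subject", x$subject, "-", d[4L], "trials,",
      paste(d[1:3], collapse = "x"), "voxels\n")
  print(table(condition = x$labels$condition, run = x$labels$run))
  invisible(x)
}

#' @export
dim.beta_series <- function(x) dim(x$betas)

#' Subset trials of a beta series
#'
#' @param bs A `beta_series`.
#' @param condition Optional condition name(s) to keep.
#' @param levels Optional stickiness levels to keep (e.g. `1:3` to drop the
#'   level-0 control before decoding).
#' @param runs Optional run numbers to keep.
#' @return A `beta_series` holding the selected trials, in original order.
#' @export
subset_trials <- function(bs, condition = NULL, levels = NULL, runs = NULL) {
  keep <- rep(TRUE, nrow(bs$labels))
  if (!is.null(condition)) keep <- keep & bs$labels$condition %in% condition
  if (!is.null(levels)) keep <- keep & bs$labels$level %in% levels
  if (!is.null(runs)) keep <- keep & bs$labels$run %in% runs
  if (!any(keep)) stop("subset_trials(): no trials left after subsetting")
  out <- bs
  out$betas <- bs$betas[, , , keep, drop = FALSE]
  out$labels <- bs$labels[keep, , drop = FALSE]
  rownames(out$labels) <- NULL
  out
}

# trials x voxels matrix view (voxels in array order)
beta_matrix <- function(bs) {
  d <- dim(bs$betas)
  t(matrix(bs$betas, nrow = prod(d[1:3]), ncol = d[4L]))
}
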