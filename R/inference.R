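# Random-effects group inference on searchlight accuracy maps with a
# sign-flip max-cluster-size permutation threshold.

#' Random-effects group t-map of accuracy maps
#'
#' One-sample t statistic of (accuracy minus chance) against zero across
#' subjects, per voxel valid in every subject; one-sided (greater) inference
#' downstream. Zero-variance voxels receive an infinite sentinel of the mean's
#' sign and are flagged in `degenerate`.
#'
#' @param maps List of `accuracy_map` objects sharing geometry (>= 3).
#' @return Object of class `group_stat_map`: `t_values`, `valid_mask`,
#'   `degenerate`, `dof` (= n - 1), `n_subjects`, `voxel_size_mm`.
#' @export
group_ttest <- function(maps) {
  stopifnot(length(maps) >= 3L)
  dims <- dim(maps[[1]]$values)
  for (m in maps) stopifnot(inherits(m, "accuracy_map"),
                            all(dim(m$values) == dims))
  n <- length(maps)
  x <- vapply(maps, function(m) as.vector(m$values), numeric(prod(dims)))
  valid <- Reduce(`&`, lapply(maps, function(m) m$valid))
  mu <- rowMeans(x)
  sdv <- sqrt(pmax(0, (rowSums(x^2) - n * mu^2) / (n - 1)))
  t_val <- rep(NA_real_, length(mu))
  deg <- sdv == 0
  ok <- !deg
  t_val[ok] <- mu[ok] / (sdv[ok] / sqrt(n))
  t_val[deg] <- sign(mu[deg]) * Inf
  structure(list(t_values = array(t_val, dims),
                 valid_mask = valid,
                 degenerate = array(deg, dims) & valid,
                 dof = n - 1L, n_subjects = n,
                 voxel_size_mm = maps[[1]]$voxel_size_mm),
            class = "group_stat_map")
}

neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1, "18" = dist >= 1 & dist <= 2, "26" = dist >= 1)
  g[keep, , drop = FALSE]
}

# Connected components of a logical 3D array; returns a list of linear-index
# vectors, one per component.
label_components <- function(supra, connectivity = 18L) {
  dims <- dim(supra)
  idx <- which(supra)
  if (!length(idx)) return(list())
  offs <- neighbor_offsets(connectivity)
  comp <- integer(length(idx))
  lookup <- array(0L, dims)
  lookup[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  ncomp <- 0L
  for (start in seq_along(idx)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      for (o in seq_len(nrow(offs))) {
        nb <- coords[i, ] + offs[o, ]
        if (any(nb < 1L) || any(nb > dims)) next
        j <- lookup[nb[1], nb[2], nb[3]]
        if (j != 0L && comp[j] == 0L) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }
  split(idx, comp)
}

#' Extract suprathreshold clusters from a group t-map
#'
#' Thresholds the map at the one-sided Student quantile for `p_voxel` (with
#' the map's dof), labels connected components under the requested
#' connectivity, keeps components larger than `min_size` voxels, and reports
#' size, peak statistic, peak location (voxel indices and mm via the diagonal
#' affine) and the standard-normal equivalent (Z) of the peak t.
#'
#' @param stat A [group_ttest()] map.
#' @param p_voxel Voxelwise one-sided p threshold (default 0.001).
#' @param min_size Only clusters with `size > min_size` are kept (default 0).
#' @param connectivity 6, 18 or 26 (default 18).
#' @return Object of class `cluster_table`: a data frame (one row per
#'   cluster; `size_voxels`, `peak_t`, `peak_z`, `peak_i/j/k` voxel indices,
#'   `peak_mm_x/y/z`, `significant` = NA until [significant_clusters()]),
#'   with the member indices in `attr(, "members")` and the extraction
#'   settings in `attr(, "settings")`.
#' @export
extract_clusters <- function(stat, p_voxel = 0.001, min_size = 0L,
                             connectivity = 18L) {
  stopifnot(inherits(stat, "group_stat_map"), p_voxel > 0, p_voxel < 1)
  t_thr <- stats::qt(1 - p_voxel, df = stat$dof)
  supra <- stat$valid_mask & !is.na(stat$t_values) & stat$t_values > t_thr
  comps <- label_components(supra, connectivity)
  comps <- comps[lengths(comps) > min_size]
  dims <- dim(stat$t_values)
  rows <- lapply(comps, function(members) {
    tv <- stat$t_values[members]
    peak <- members[which.max(tv)]
    co <- arrayInd(peak, dims)[1, ]
    data.frame(size_voxels = length(members),
               peak_t = max(tv),
               peak_z = t_to_z(max(tv), stat$dof),
               peak_i = co[1], peak_j = co[2], peak_k = co[3],
               peak_mm_x = (co[1] - 1) * stat$voxel_size_mm[1],
               peak_mm_y = (co[2] - 1) * stat$voxel_size_mm[2],
               peak_mm_z = (co[3] - 1) * stat$voxel_size_mm[3],
               significant = NA)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size_voxels = integer(0), peak_t = numeric(0),
               peak_z = numeric(0), peak_i = integer(0), peak_j = integer(0),
               peak_k = integer(0), peak_mm_x = numeric(0),
               peak_mm_y = numeric(0), peak_mm_z = numeric(0),
               significant = logical(0))
  if (nrow(out)) {
    ord <- order(-out$size_voxels)
    out <- out[ord, , drop = FALSE]
    comps <- comps[ord]
    rownames(out) <- NULL
  }
  attr(out, "members") <- unname(comps)
  attr(out, "settings") <- list(p_voxel = p_voxel, min_size = min_size,
                                connectivity = as.integer(connectivity),
                                dof = stat$dof)
  class(out) <- c("cluster_table", "data.frame")
  out
}

# Standard-normal equivalent of a t statistic (quantile matching).
t_to_z <- function(t, dof) {
  z <- stats::qnorm(stats::pt(t, dof, lower.tail = FALSE, log.p = TRUE),
                    lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(t)] <- sign(t[!is.finite(t)]) * Inf
  z
}

#' Sign-flip max-cluster-size permutation null
#'
#' Builds the null distribution of the largest suprathreshold cluster size by
#' flipping the sign of each subject's whole accuracy map with an independent
#' fair coin (the exchangeable sign-flip scheme), recomputing the group t-map
#' and the connected components at the same voxelwise threshold, and
#' recording the largest component size (0 when none). The cluster-size
#' significance threshold is the smallest size whose null upper-tail mass is
#' at most `alpha`, so declaring clusters of at least that size controls the
#' familywise error at `alpha` even with the heavily tied discrete null.
#'
#' @param maps List of `accuracy_map` objects (as for [group_ttest()]).
#' @param p_voxel Voxelwise one-sided p threshold.
#' @param connectivity 6, 18 or 26.
#' @param n_perm Number of permutations (>= 100; the study protocol uses 1000).
#' @param alpha Familywise alpha (default 0.05, the top 5% of the null).
#' @param seed Integer seed for the coin flips.
#' @return Object of class `permutation_null`: `max_cluster_sizes`,
#'   `threshold_size`, `alpha`, `n_perm`, `seed`, `settings`.
#' @export
signflip_null <- function(maps, p_voxel = 0.001, connectivity = 18L,
                          n_perm = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 100L, alpha > 0, alpha < 1)
  n <- length(maps)
  stopifnot(n >= 3L)
  dims <- dim(maps[[1]]$values)
  x <- vapply(maps, function(m) as.vector(m$values), numeric(prod(dims)))
  valid <- as.vector(Reduce(`&`, lapply(maps, function(m) m$valid)))
  xv <- x[valid, , drop = FALSE]
  ss <- rowSums(xv^2)                      # invariant under sign flips
  t_thr <- stats::qt(1 - p_voxel, df = n - 1L)
  set.seed(seed)
  max_sizes <- integer(n_perm)
  supra_full <- array(FALSE, dims)
  valid_idx <- which(valid)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    mu <- as.vector(xv %*% signs) / n
    sdv <- sqrt(pmax(0, (ss - n * mu^2) / (n - 1)))
    tv <- ifelse(sdv == 0, sign(mu) * Inf, mu / (sdv / sqrt(n)))
    supra_full[] <- FALSE
    supra_full[valid_idx[tv > t_thr]] <- TRUE
    comps <- label_components(supra_full, connectivity)
    max_sizes[p] <- if (length(comps)) max(lengths(comps)) else 0L
  }
  structure(list(max_cluster_sizes = max_sizes,
                 threshold_size = upper_tail_threshold(max_sizes, alpha),
                 alpha = alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 settings = list(p_voxel = p_voxel,
                                 connectivity = as.integer(connectivity),
                                 dof = n - 1L)),
            class = "permutation_null")
}

# Smallest integer c with P(null >= c) <= alpha.
upper_tail_threshold <- function(sizes, alpha) {
  for (c in sort(unique(c(sizes, max(sizes) + 1L)))) {
    if (mean(sizes >= c) <= alpha) return(as.integer(c))
  }
  max(sizes) + 1L
}

#' Declare significant clusters against a permutation null
#'
#' Marks clusters whose size reaches the permutation cluster-size threshold
#' (`size_voxels >= threshold_size`; the boundary case is significant) and
#' annotates each cluster with the add-one empirical p-value
#' `(1 + #null >= size) / (1 + n_perm)`.
#'
#' @param observed A [extract_clusters()] table.
#' @param null A [signflip_null()] object built with the same `p_voxel` and
#'   `connectivity`.
#' @return The cluster table with `significant` and `p_empirical` filled in.
#' @export
significant_clusters <- function(observed, null) {
  stopifnot(inherits(observed, "cluster_table"),
            inherits(null, "permutation_null"))
  so <- attr(observed, "settings")
  sn <- null$settings
  if (!isTRUE(all.equal(so$p_voxel, sn$p_voxel)) ||
      so$connectivity != sn$connectivity)
    stop("significant_clusters(): observed clusters and permutation null were ",
         "computed with different settings (p_voxel/connectivity)")
  out <- observed
  if (nrow(out)) {
    out$significant <- out$size_voxels >= null$threshold_size
    out$p_empirical <- vapply(out$size_voxels, function(s)
      (1 + sum(null$max_cluster_sizes >= s)) / (1 + null$n_perm), numeric(1))
  } else {
    out$p_empirical <- numeric(0)
  }
  out
}
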