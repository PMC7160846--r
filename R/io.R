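# On-disk formats: NIfTI-1 volumes (diagonal affine from the voxel size),
# TSV label/event/rating tables, JSON stats sidecars.

nifti_image <- function(arr, voxel_size_mm) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- c(voxel_size_mm, rep(1, length(dim(arr)) - 3L))
  im
}

#' Write a beta series as NIfTI + TSV sidecar
#'
#' The trial axis is the 4th dimension of the NIfTI; the sidecar TSV holds one
#' row per trial with the labels.
#'
#' @param bs A [beta_series()].
#' @param path_prefix File path without extension; writes
#'   `<prefix>.nii.gz` and `<prefix>_labels.tsv`.
#' @return The prefix, invisibly.
#' @export
write_beta_series <- function(bs, path_prefix) {
  RNifti::writeNifti(nifti_image(bs$betas, bs$voxel_size_mm),
                     paste0(path_prefix, ".nii.gz"))
  utils::write.table(bs$labels, paste0(path_prefix, "_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_prefix)
}

#' Read a beta series written by [write_beta_series()]
#' @param path_prefix File path without extension.
#' @param subject Subject identifier to attach.
#' @return A [beta_series()].
#' @export
read_beta_series <- function(path_prefix, subject = 1L) {
  im <- RNifti::readNifti(paste0(path_prefix, ".nii.gz"))
  labels <- utils::read.delim(paste0(path_prefix, "_labels.tsv"))
  beta_series(array(as.numeric(im), dim = dim(im)), labels,
              voxel_size_mm = RNifti::pixdim(im)[1:3], subject = subject)
}

#' Write an accuracy map as NIfTI + JSON sidecar
#' @param map An `accuracy_map`.
#' @param path_prefix Path without extension; writes `<prefix>.nii.gz`,
#'   `<prefix>_valid.nii.gz` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_accuracy_map <- function(map, path_prefix) {
  RNifti::writeNifti(nifti_image(map$values, map$voxel_size_mm),
                     paste0(path_prefix, ".nii.gz"))
  RNifti::writeNifti(nifti_image(array(as.numeric(map$valid), dim(map$valid)),
                                 map$voxel_size_mm),
                     paste0(path_prefix, "_valid.nii.gz"))
  jsonlite::write_json(list(analysis = map$analysis, subject = map$subject,
                            chance_level = map$spec$chance_level,
                            side_voxels = map$spec$side_voxels,
                            min_in_mask = map$spec$min_in_mask),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE)
  invisible(path_prefix)
}

#' Write a cluster table as TSV
#' @param clusters A `cluster_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a permutation null as JSON
#' @param null A `permutation_null`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_permutation_null <- function(null, path) {
  jsonlite::write_json(unclass(null), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write events or ratings as TSV
#' @param x Data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
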