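#' Summarize a significance map over an atlas of labeled regions
#'
#' For each integer atlas label, totals the volume of flagged voxels
#' (non-zero, non-NA entries of `voxel_map`). Regions under
#' `min_volume_mm3` are kept but flagged as sub-threshold rather than
#' dropped, mirroring the common reporting rule of listing only regions
#' above ~100 mm^3.
#'
#' @param voxel_map 3D logical or numeric array (significant = TRUE /
#'   non-zero; NA = outside coverage).
#' @param atlas 3D integer array of region labels on the same grid
#'   (0 = background).
#' @param voxel_dims Voxel edge lengths in mm.
#' @param min_volume_mm3 Reporting threshold; default 100.
#' @param region_names Optional named character vector mapping labels to
#'   names.
#' @return Data.frame with columns `region_label`, `region_name`,
#'   `n_voxels`, `volume_mm3`, `above_threshold`, sorted by volume
#'   descending.
#' @export
summarize_regions <- function(voxel_map, atlas, voxel_dims = c(1, 1, 1),
                              min_volume_mm3 = 100, region_names = NULL) {
  if (!all(dim(voxel_map) == dim(atlas)))
    stop("summarize_regions: atlas grid does not match the voxel map")
  vv <- prod(voxel_dims)
  flagged <- !is.na(voxel_map) & (voxel_map != 0)
  labs <- sort(unique(atlas[atlas > 0]))
  counts <- vapply(labs, function(l) sum(flagged[atlas == l]), numeric(1))
  out <- data.frame(
    region_label = as.integer(labs),
    region_name = if (is.null(region_names)) as.character(labs)
                  else unname(region_names[as.character(labs)]),
    n_voxels = as.integer(counts),
    volume_mm3 = counts * vv
  )
  out$above_threshold <- out$volume_mm3 > min_volume_mm3
  out <- out[out$n_voxels > 0, , drop = FALSE]
  out <- out[order(-out$volume_mm3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-region damage correlations and centroid distances
#'
#' For each atlas region (restricted to the cohort's coverage), computes
#' per-subject proportion damage (lesioned voxels in the region divided by
#' the region's covered size) and returns the across-subject Pearson
#' correlation matrix together with the Euclidean distances between region
#' centroids in template-space mm. Low damage correlation between two
#' regions indicates that the cohort can dissociate their functions.
#'
#' @param lm A `lesion_matrix` from [build_matrix()].
#' @param atlas 3D integer label array on the cohort grid.
#' @return List with `regions` (labels retained), `proportion_damage`
#'   (subjects x regions), `correlation` (regions x regions Pearson r) and
#'   `distance_mm` (regions x regions centroid distances).
#' @export
damage_diagnostics <- function(lm, atlas) {
  stopifnot(inherits(lm, "lesion_matrix"))
  if (nrow(lm$matrix) < 3L)
    stop("damage_diagnostics: need at least 3 subjects")
  if (!all(dim(atlas) == lm$dim))
    stop("damage_diagnostics: atlas grid does not match the cohort grid")
  region_of_voxel <- atlas[lm$voxel_index]
  labs <- sort(unique(region_of_voxel[region_of_voxel > 0]))
  keep <- logical(length(labs))
  pd <- matrix(NA_real_, nrow(lm$matrix), length(labs))
  cent <- matrix(NA_real_, length(labs), 3L)
  for (k in seq_along(labs)) {
    cols <- which(region_of_voxel == labs[k])
    if (length(cols) == 0L) next
    prop <- rowMeans(lm$matrix[, cols, drop = FALSE])
    if (sd(prop) == 0) {
      warning("damage_diagnostics: region ", labs[k],
              " has constant damage profile; excluded")
      next
    }
    keep[k] <- TRUE
    pd[, k] <- prop
    idx <- lm$voxel_index[cols]
    ijk <- arrayInd(idx, lm$dim) - 1L      # 0-based voxel indices
    mm <- cbind(ijk, 1) %*% t(lm$affine)
    cent[k, ] <- colMeans(mm[, 1:3, drop = FALSE])
  }
  if (sum(keep) < 2L)
    stop("damage_diagnostics: fewer than 2 usable regions in coverage")
  labs <- labs[keep]
  pd <- pd[, keep, drop = FALSE]
  colnames(pd) <- labs
  cent <- cent[keep, , drop = FALSE]
  dmat <- as.matrix(dist(cent))
  dimnames(dmat) <- list(labs, labs)
  list(regions = as.integer(labs),
       proportion_damage = pd,
       correlation = cor(pd),
       distance_mm = dmat)
}
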