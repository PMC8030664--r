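#' Construct a binary lesion mask
#'
#' @param volume 3D array of 0/1 values in a common template grid.
#' @param affine 4x4 voxel-to-template-mm transform; default a scaled
#'   identity built from `voxel_dims`.
#' @param voxel_dims Voxel edge lengths in mm (length 3).
#' @param subject_id Identifier for the subject.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(volume, affine = NULL, voxel_dims = c(1, 1, 1),
                        subject_id = NA_character_) {
  if (length(dim(volume)) != 3L)
    stop("lesion_mask: volume must be a 3D array")
  vals <- unique(as.vector(volume))
  bad <- setdiff(vals, c(0, 1))
  if (length(bad))
    stop("lesion_mask: mask is not binary; offending value(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  } else {
    affine <- unname(as.matrix(affine))
    if (!all(dim(affine) == c(4L, 4L)))
      stop("lesion_mask: affine must be 4x4")
    voxel_dims <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(volume = array(as.integer(volume), dim(volume)),
                 affine = affine,
                 voxel_dims = as.numeric(voxel_dims),
                 subject_id = as.character(subject_id)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("Lesion mask '%s': grid %s, voxel %s mm, volume %.0f mm^3\n",
              x$subject_id, paste(dim(x$volume), collapse = "x"),
              paste(signif(x$voxel_dims, 3), collapse = "x"),
              lesion_volume_mm3(x)))
  invisible(x)
}

#' Lesion volume of a mask in cubic millimetres
#'
#' Voxel count times the voxel volume implied by the mask header; computed
#' on the full (unfiltered) mask.
#'
#' @param mask A [lesion_mask].
#' @return Volume in mm^3.
#' @export
lesion_volume_mm3 <- function(mask) {
  sum(mask$volume) * prod(mask$voxel_dims)
}

#' Load a cohort of binary lesion masks from NIfTI files
#'
#' Reads each file, validates that it is binary and that all masks share
#' one grid shape and affine.
#'
#' @param paths Character vector of NIfTI paths (.nii or .nii.gz).
#' @param subject_ids Optional ids; default the file names without
#'   extension.
#' @param expected_grid Optional integer triple; if given, every mask must
#'   match it.
#' @return A list of [lesion_mask] objects.
#' @export
load_cohort <- function(paths, subject_ids = NULL, expected_grid = NULL) {
  subject_ids <- subject_ids %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  ref <- NULL
  masks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    vol <- array(as.numeric(img), dim(img))
    aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
    if (!is.null(expected_grid) && !all(dim(vol) == expected_grid))
      stop(sprintf("load_cohort: subject '%s' grid %s does not match expected %s",
                   subject_ids[i], paste(dim(vol), collapse = "x"),
                   paste(expected_grid, collapse = "x")))
    if (is.null(ref)) {
      ref <- list(dim = dim(vol), affine = aff)
    } else if (!all(dim(vol) == ref$dim) ||
               max(abs(aff - ref$affine)) > 1e-4) {
      stop(sprintf("load_cohort: subject '%s' is not on the cohort grid/affine",
                   subject_ids[i]))
    }
    masks[[i]] <- lesion_mask(vol, affine = aff, subject_id = subject_ids[i])
  }
  masks
}

#' Write a cohort of lesion masks as NIfTI files
#'
#' @param masks List of [lesion_mask] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(masks, function(m) {
    p <- file.path(dir, paste0(m$subject_id, ".nii.gz"))
    write_map(m$volume, p, affine = m$affine)
    p
  }, character(1))
  invisible(paths)
}

#' Write a 3D map as NIfTI with a given affine
#'
#' @param vol 3D numeric array.
#' @param path Output path.
#' @param affine 4x4 voxel-to-mm transform.
#' @return Invisibly, `path`.
#' @export
write_map <- function(vol, path, affine = diag(4)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Build the subjects x voxels lesion matrix with a coverage filter
#'
#' Stacks the flattened masks row-wise and retains only voxels lesioned in
#' at least `min_subjects` subjects (the minimum-overlap filter; with the
#' cohort size of the motivating study, 5 of 94 subjects, i.e. >5%).
#' Per-subject lesion volumes are recorded from the unfiltered masks, so
#' the lesion-size covariate is unaffected by the filter.
#'
#' @param masks List of [lesion_mask] on one grid.
#' @param min_subjects Minimum number of lesioned subjects for a voxel to
#'   be retained; default 5.
#' @param min_fraction Alternatively, a fraction of the cohort; when given,
#'   `min_subjects = ceiling(min_fraction * n)`.
#' @return An object of class `lesion_matrix`: list with `matrix`
#'   (subjects x retained voxels, 0/1), `voxel_index` (linear indices of
#'   retained voxels in the grid), `dim`, `affine`, `voxel_dims`,
#'   `lesion_volumes_mm3`, `subject_ids`, `filter_min_subjects`.
#' @export
build_matrix <- function(masks, min_subjects = 5L, min_fraction = NULL) {
  n <- length(masks)
  if (!is.null(min_fraction)) min_subjects <- ceiling(min_fraction * n)
  min_subjects <- as.integer(min_subjects)
  if (n < min_subjects)
    stop("build_matrix: fewer masks than min_subjects")
  d <- dim(masks[[1L]]$volume)
  M <- matrix(0L, n, prod(d))
  for (i in seq_len(n)) {
    if (!all(dim(masks[[i]]$volume) == d))
      stop(sprintf("build_matrix: subject '%s' grid mismatch",
                   masks[[i]]$subject_id))
    M[i, ] <- as.vector(masks[[i]]$volume)
  }
  keep <- which(colSums(M) >= min_subjects)
  if (length(keep) == 0L)
    stop("build_matrix: no voxel is lesioned in at least ", min_subjects,
         " subjects (empty coverage)")
  structure(list(
    matrix = M[, keep, drop = FALSE],
    voxel_index = keep,
    dim = d,
    affine = masks[[1L]]$affine,
    voxel_dims = masks[[1L]]$voxel_dims,
    lesion_volumes_mm3 = vapply(masks, lesion_volume_mm3, numeric(1)),
    subject_ids = vapply(masks, function(m) m$subject_id, character(1)),
    filter_min_subjects = min_subjects
  ), class = "lesion_matrix")
}

#' @export
print.lesion_matrix <- function(x, ...) {
  cat(sprintf(paste0("Lesion matrix: %d subjects x %d voxels ",
                     "(grid %s, coverage filter >= %d subjects)\n"),
              nrow(x$matrix), ncol(x$matrix),
              paste(x$dim, collapse = "x"), x$filter_min_subjects))
  cat(sprintf("  lesion volume: mean %.0f mm^3, range %.0f-%.0f mm^3\n",
              mean(x$lesion_volumes_mm3), min(x$lesion_volumes_mm3),
              max(x$lesion_volumes_mm3)))
  invisible(x)
}

#' Compress identical voxel columns into patches
#'
#' Voxels with the same lesion pattern across all subjects carry identical
#' information for any across-subject model; they are grouped into patches.
#' The compression is lossless: each patch stores its member voxels and its
#' multiplicity (voxel count), and [expand_map] restores full voxel maps.
#' Patches are ordered by their smallest member's linear index.
#'
#' @param lm A `lesion_matrix` from [build_matrix()].
#' @return An object of class `patched_matrix`: list with `matrix`
#'   (subjects x patches, 0/1), `patch_members` (list of grid linear
#'   indices), `patch_sizes` (multiplicities), and the grid metadata
#'   carried over from `lm`.
#' @export
compress_patches <- function(lm) {
  stopifnot(inherits(lm, "lesion_matrix"))
  M <- lm$matrix
  if (ncol(M) == 0L) stop("compress_patches: empty matrix")
  keys <- do.call(paste0, as.data.frame(t(M)))
  first <- !duplicated(keys)
  patch_id <- match(keys, keys[first])     # first-occurrence order = by
  P <- sum(first)                          # smallest member linear index
  members <- split(lm$voxel_index, patch_id)
  structure(list(
    matrix = M[, first, drop = FALSE],
    patch_members = unname(members),
    patch_sizes = as.integer(lengths(members)),
    voxel_index = lm$voxel_index,
    patch_of_voxel = patch_id,
    dim = lm$dim,
    affine = lm$affine,
    voxel_dims = lm$voxel_dims,
    subject_ids = lm$subject_ids
  ), class = "patched_matrix")
}

#' @export
print.patched_matrix <- function(x, ...) {
  cat(sprintf("Patched lesion matrix: %d subjects x %d patches (%d voxels)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$voxel_index)))
  cat(sprintf("  patch sizes: median %d, max %d voxels\n",
              as.integer(stats::median(x$patch_sizes)), max(x$patch_sizes)))
  invisible(x)
}

#' Expand per-patch values to a full voxel map
#'
#' Every voxel in a patch receives that patch's value; voxels outside the
#' coverage filter receive `missing`.
#'
#' @param patch_values Numeric (or logical) vector, one value per patch.
#' @param pm A `patched_matrix` from [compress_patches()].
#' @param missing Fill value outside coverage; default `NA`.
#' @return A 3D array on the cohort grid.
#' @export
expand_map <- function(patch_values, pm, missing = NA_real_) {
  stopifnot(inherits(pm, "patched_matrix"))
  if (length(patch_values) != ncol(pm$matrix))
    stop("expand_map: one value per patch required (got ",
         length(patch_values), ", expected ", ncol(pm$matrix), ")")
  arr <- array(missing, pm$dim)
  arr[pm$voxel_index] <- as.numeric(patch_values)[pm$patch_of_voxel]
  arr
}
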