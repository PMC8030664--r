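test_that("masks validate, measure volume, and round-trip through NIfTI", {
  d <- c(10L, 10L, 10L)
  vol <- array(0L, d); vol[seq_len(135)] <- 1L
  m <- lesion_mask(vol, voxel_dims = c(1, 1, 1), subject_id = "a")
  expect_equal(lesion_volume_mm3(m), 135)
  m3 <- lesion_mask(vol, voxel_dims = c(3, 3, 3), subject_id = "a")
  expect_equal(lesion_volume_mm3(m3), 135 * 27)
  bad <- vol; bad[1] <- 2L
  expect_error(lesion_mask(bad), "not binary")
  # write/load identity on a simulated cohort
  co <- simulate_lesions(sim_config(n_subjects = 4, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- load_cohort(paths)
  for (i in seq_along(co)) {
    expect_identical(back[[i]]$volume, co[[i]]$volume)
    expect_equal(back[[i]]$affine, co[[i]]$affine, tolerance = 1e-6)
  }
  expect_error(load_cohort(paths, expected_grid = c(5, 5, 5)), "grid")
})

test_that("coverage filter retains exactly the voxels lesioned often enough", {
  d <- c(4L, 4L, 2L)
  base <- array(0L, d)
  masks <- lapply(1:6, function(i) {
    v <- base
    if (i <= 5) v[1] <- 1L      # voxel 1: 5 subjects -> retained
    if (i <= 4) v[2] <- 1L      # voxel 2: 4 subjects -> dropped
    v[3] <- 1L                  # voxel 3: all subjects
    lesion_mask(v, subject_id = as.character(i))
  })
  lm <- build_matrix(masks, min_subjects = 5)
  expect_setequal(lm$voxel_index, c(1L, 3L))
  lm1 <- build_matrix(masks, min_subjects = 1)
  expect_setequal(lm1$voxel_index, c(1L, 2L, 3L))
  # the fraction mode enforces ceiling(fraction * n)
  expect_equal(build_matrix(masks, min_fraction = 0.75)$filter_min_subjects, 5L)
  # lesion volumes reflect the unfiltered masks
  expect_equal(lm$lesion_volumes_mm3,
               vapply(masks, lesion_volume_mm3, numeric(1)))
  # disjoint single-voxel lesions cannot satisfy a 2-subject overlap
  lonely <- lapply(1:4, function(i) {
    v <- base; v[i] <- 1L
    lesion_mask(v, subject_id = as.character(i))
  })
  expect_error(build_matrix(lonely, min_subjects = 2), "empty coverage")
})

test_that("coverage filter equals a brute-force recount and is row-equivariant", {
  masks <- random_masks(20, prob = 0.25, seed = 31)
  lm <- build_matrix(masks, min_subjects = 5)
  full <- do.call(rbind, lapply(masks, function(m) as.vector(m$volume)))
  expect_identical(lm$voxel_index, which(colSums(full) >= 5))
  expect_identical(lm$matrix, full[, colSums(full) >= 5, drop = FALSE])
  perm <- sample(20)
  lm2 <- build_matrix(masks[perm], min_subjects = 5)
  expect_identical(lm2$matrix, lm$matrix[perm, ])
  expect_identical(lm2$voxel_index, lm$voxel_index)
})

test_that("patch compression is lossless and deterministically ordered", {
  # all columns identical -> a single patch spanning every voxel
  same <- lapply(1:4, function(i) {
    v <- array(if (i <= 2) 1L else 0L, c(3L, 3L, 1L))
    lesion_mask(v, subject_id = as.character(i))
  })
  pm1 <- compress_patches(build_matrix(same, min_subjects = 1))
  expect_equal(ncol(pm1$matrix), 1L)
  expect_equal(pm1$patch_sizes, 9L)
  # random matrix: expanding each patch column reproduces the voxel matrix
  masks <- random_masks(15, d = c(10L, 10L, 2L), prob = 0.4, seed = 32)
  lm <- build_matrix(masks, min_subjects = 1)
  pm <- compress_patches(lm)
  rebuilt <- pm$matrix[, pm$patch_of_voxel, drop = FALSE]
  expect_identical(unname(rebuilt), unname(lm$matrix))
  # members partition the retained voxels; ordering by first member index
  expect_setequal(unlist(pm$patch_members), lm$voxel_index)
  firsts <- vapply(pm$patch_members, min, numeric(1))
  expect_identical(firsts, sort(firsts))
})

test_that("patch maps expand to voxel maps and invert", {
  masks <- random_masks(8, d = c(6L, 6L, 3L), prob = 0.4, seed = 33)
  pm <- compress_patches(build_matrix(masks, min_subjects = 2))
  vals <- rnorm(ncol(pm$matrix))
  arr <- expand_map(vals, pm)
  # every member voxel carries its patch value; outside coverage is NA
  for (j in seq_along(pm$patch_members))
    expect_true(all(arr[pm$patch_members[[j]]] == vals[j]))
  expect_true(all(is.na(arr[-pm$voxel_index])))
  # regrouping recovers the patch values exactly
  expect_equal(vapply(pm$patch_members, function(mm) arr[mm[1]], numeric(1)),
               vals)
  expect_error(expand_map(vals[-1], pm), "one value per patch")
})

test_that("region summaries count flagged volume per atlas label", {
  d <- c(10L, 10L, 5L)
  atlas <- array(0L, d)
  atlas[1:150] <- 7L
  atlas[151:249] <- 3L
  sig <- array(0, d)
  sig[1:150] <- 1      # 150 voxels in region 7
  sig[151:249] <- 1    # 99 voxels in region 3
  out <- summarize_regions(sig, atlas, voxel_dims = c(1, 1, 1))
  expect_equal(out$volume_mm3[out$region_label == 7], 150)
  expect_true(out$above_threshold[out$region_label == 7])
  expect_false(out$above_threshold[out$region_label == 3])
  expect_equal(out$region_label, c(7L, 3L))   # sorted by volume, descending
  # multi-label random map equals a brute-force per-label count
  set.seed(34)
  atlas2 <- array(sample(0:4, prod(d), TRUE), d)
  sig2 <- array(rbinom(prod(d), 1, 0.3), d)
  out2 <- summarize_regions(sig2, atlas2, voxel_dims = c(2, 2, 2),
                            min_volume_mm3 = 0)
  for (l in 1:4)
    expect_equal(out2$volume_mm3[out2$region_label == l],
                 sum(sig2[atlas2 == l]) * 8)
  expect_error(summarize_regions(sig, atlas[, , 1:4, drop = FALSE]), "grid")
})

test_that("damage diagnostics recover correlations and centroid geometry", {
  d <- c(8L, 4L, 2L)
  atlas <- array(0L, d)
  atlas[1:2, 1:2, 1] <- 1L
  atlas[5:6, 1:2, 1] <- 2L
  atlas[5:6, 3:4, 2] <- 3L
  set.seed(35)
  masks <- lapply(1:10, function(i) {
    v <- array(0L, d)
    hit <- rbinom(1, 1, 0.5)
    v[atlas == 1] <- hit        # regions 1 and 2 damaged identically
    v[atlas == 2] <- hit
    v[atlas == 3] <- rbinom(1, 1, 0.5)
    v[1:2, 3:4, ] <- rbinom(8, 1, 0.6)  # filler so coverage is non-trivial
    lesion_mask(v, voxel_dims = c(2, 2, 2), subject_id = as.character(i))
  })
  lm <- build_matrix(masks, min_subjects = 1)
  dg <- damage_diagnostics(lm, atlas)
  expect_equal(dg$correlation["1", "2"], 1, tolerance = 1e-12)
  # centroids in mm with 2 mm voxels (0-based indices scaled by the affine)
  c1 <- colMeans((arrayInd(which(atlas == 1), d) - 1) * 2)
  c2 <- colMeans((arrayInd(which(atlas == 2), d) - 1) * 2)
  expect_equal(dg$distance_mm["1", "2"], sqrt(sum((c1 - c2)^2)),
               tolerance = 1e-10)
  # a region with a constant damage profile is excluded with a warning
  masks2 <- lapply(masks, function(m) {
    v <- m$volume; v[atlas == 3] <- 1L
    lesion_mask(v, voxel_dims = c(2, 2, 2), subject_id = m$subject_id)
  })
  lm2 <- build_matrix(masks2, min_subjects = 1)
  expect_warning(dg2 <- damage_diagnostics(lm2, atlas), "constant")
  expect_false("3" %in% colnames(dg2$correlation))
})
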