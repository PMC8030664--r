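test_that("simulated lesion volumes honor the clipping range and target mean", {
  cfgs <- lapply(1:5, function(s) sim_config(n_subjects = 40, seed = s))
  vols <- unlist(lapply(cfgs, function(cfg) {
    masks <- simulate_lesions(cfg)
    vv <- prod(cfg$voxel_dims)
    v <- vapply(masks, lesion_volume_mm3, numeric(1))
    # per-mask volume within the clip range, up to voxel rounding
    expect_true(all(v >= 135 - vv / 2 & v <= 104243 + vv / 2))
    v
  }))
  expect_lt(abs(mean(vols) - 14098) / 14098, 0.25)
})

test_that("simulated lesions are connected blobs with guaranteed truth coverage", {
  cfg <- sim_config(n_subjects = 25, seed = 8)
  masks <- simulate_lesions(cfg)
  for (m in masks[1:10]) expect_true(is_connected6(m$volume))
  tm <- truth_maps(cfg)
  expect_false(any(tm$A & tm$B))                 # disjoint ground truths
  cover <- Reduce(`+`, lapply(masks, function(m) m$volume))
  expect_gte(max(cover[tm$A]), cfg$min_truth_overlap)
  expect_gte(max(cover[tm$B]), cfg$min_truth_overlap)
})

test_that("simulation is fully reproducible from its configuration", {
  cfg <- sim_config(n_subjects = 12, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$masks, `[[`, "volume"),
                   lapply(b$masks, `[[`, "volume"))
  expect_identical(a$trials, b$trials)
})

test_that("scored synthetic behavior tracks the generating latents", {
  co <- simulate_cohort(sim_config(seed = 14))
  sc <- score_behavior(co$trials)
  expect_equal(sc$subject_id, co$latents$subject_id)
  expect_true(all(sc$span_phonological >= 1 & sc$span_phonological <= 7))
  expect_true(all(sc$span_semantic > 0 & sc$span_semantic <= 5))
  expect_gt(cor(sc$span_phonological, co$latents$lat_phon,
                method = "spearman"), 0.8)
  expect_gt(cor(sc$span_semantic, co$latents$lat_sem,
                method = "spearman"), 0.8)
  # damage in a score's own truth region lowers that score
  expect_lt(cor(co$latents$frac_A, sc$span_phonological), -0.4)
  expect_lt(cor(co$latents$frac_B, sc$span_semantic), -0.4)
})

test_that("a zero-effect cohort decouples truth-region damage from scores", {
  rs <- vapply(1:6, function(s) {
    co <- simulate_cohort(sim_config(effect = 0, seed = 200 + s))
    sc <- score_behavior(co$trials)
    dv <- residualize_and_scale(sc$span_phonological,
                                list(size = log(co$lesion_volumes)))
    cor(co$latents$frac_A, dv$scaled)
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("generated cohorts reproduce the target score correlations", {
  res <- vapply(1:10, function(s) {
    sc <- score_behavior(simulate_cohort(sim_config(seed = 300 + s))$trials)
    c(cor(sc$span_phonological, sc$span_semantic),
      cor(sc$dprime_phonological, sc$dprime_semantic))
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.51), 0.1)
  expect_lt(abs(mean(res[2, ]) - 0.69), 0.1)
})

test_that("recovery metrics match their defining confusion counts", {
  cfg <- sim_config(seed = 4)
  tm <- truth_maps(cfg)
  coverage <- sort(c(which(tm$A), which(tm$B),
                     sample(which(!tm$A & !tm$B), 500)))
  perfect <- array(0, cfg$grid_shape); perfect[tm$A] <- 1
  r <- evaluate_recovery(perfect, tm$A, coverage)
  expect_equal(r$dice, 1)
  expect_equal(r$fpr, 0)
  empty <- array(0, cfg$grid_shape)
  r0 <- evaluate_recovery(empty, tm$A, coverage)
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$fpr, 0)
  # a random map flags non-truth voxels at its own rate
  set.seed(90)
  q <- 0.2
  fprs <- replicate(50, {
    rand <- array(rbinom(prod(cfg$grid_shape), 1, q), cfg$grid_shape)
    evaluate_recovery(rand, tm$A, coverage)$fpr
  })
  expect_lt(abs(mean(fprs) - q), 3 * sd(fprs) / sqrt(50))
  expect_error(evaluate_recovery(perfect[, , 1:9], tm$A, coverage), "grid")
})

test_that("noisier cohorts are harder to recover", {
  dice_at <- function(noise, s) {
    co <- simulate_cohort(sim_config(noise_sd = noise, shared_wm = 0,
                                     n_subjects = 60, seed = 700 + s))
    sc <- score_behavior(co$trials)
    lmx <- build_matrix(co$masks)
    pm <- compress_patches(lmx)
    dv <- residualize_and_scale(sc$span_phonological,
                                list(size = lmx$lesion_volumes_mm3))
    inf <- patch_inference(pm$matrix, dv$scaled, cost = 1, gamma = 1e-4,
                           n_perm = 99, seed = s,
                           multiplicities = pm$patch_sizes)
    sm <- expand_map(as.numeric(inf$significant), pm, missing = 0)
    evaluate_recovery(sm, co$truth_maps$A, pm)$dice
  }
  lo <- mean(vapply(1:3, function(s) dice_at(0.4, s), numeric(1)))
  hi <- mean(vapply(1:3, function(s) dice_at(3.5, s), numeric(1)))
  expect_gt(lo, hi)
})
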