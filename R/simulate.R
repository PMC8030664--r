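# Synthetic lesion-deficit cohorts ------------------------------------------

#' Configuration for a synthetic lesion-deficit cohort
#'
#' The defaults emulate the statistical structure of an acute
#' left-hemisphere stroke cohort: 94 subjects; lesion volumes drawn from a
#' lognormal moment-matched to mean 14 098 mm^3 and SD 18 641 mm^3 and
#' clipped to 135-104 243 mm^3; spatially clustered blob-like lesions with
#' overlapping coverage; two working-memory deficit scores driven by two
#' disjoint ground-truth regions plus shared variance (target
#' cross-correlation 0.51); and two input-processing discriminability
#' scores with target correlation 0.69. The working grid is deliberately
#' small (24 x 24 x 18 voxels of 3 mm, i.e. 279 936 mm^3) so that full
#' permutation pipelines run at desk scale; with 1 mm voxels the printed
#' lesion volumes could not fit in such a grid.
#'
#' @param grid_shape Integer triple; default `c(24, 24, 18)`.
#' @param voxel_dims Voxel edge lengths in mm; default `c(3, 3, 3)`.
#' @param n_subjects Default 94.
#' @param lesion_size_meanlog,lesion_size_sdlog Lognormal parameters for
#'   lesion volume in mm^3; defaults moment-matched to mean 14 098 and
#'   SD 18 641.
#' @param lesion_size_range Clipping range in mm^3; default
#'   `c(135, 104243)`.
#' @param truth_radius Radius (voxels) of the two spherical ground-truth
#'   regions.
#' @param effect Deficit per unit lesioned fraction of a score's own truth
#'   region, in latent SD units.
#' @param size_coef Deficit per SD of log lesion volume (both scores).
#' @param shared_wm SD of the latent factor shared by the two
#'   working-memory scores (tunes their correlation toward 0.51).
#' @param noise_sd SD of each score's private noise.
#' @param ip_effect,ip_size_coef,shared_ip,ip_noise_sd The analogous
#'   generative constants for the two input-processing scores (shared_ip
#'   tunes their correlation toward 0.69).
#' @param min_truth_overlap Minimum number of subjects whose lesions must
#'   meet each truth region (resampled otherwise); default 5.
#' @param psychometrics Named list mapping latents to trial probabilities:
#'   `span_intercept` and `span_slope` (per task) set
#'   `P(correct at list length L) = plogis(intercept + latent -
#'   slope * (L - min_length))`; `hit_intercept`, `cr_intercept` and
#'   `det_slope` set the picture-word matching hit and correct-rejection
#'   probabilities. Defaults are calibrated so the scored cohort
#'   reproduces the target score distributions and correlations.
#' @param seed Master seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 18L),
                       voxel_dims = c(3, 3, 3),
                       n_subjects = 94L,
                       lesion_size_meanlog = NULL,
                       lesion_size_sdlog = NULL,
                       lesion_size_range = c(135, 104243),
                       truth_radius = 3.5,
                       effect = 4,
                       size_coef = 0.4,
                       shared_wm = 2.0,
                       noise_sd = 0.6,
                       ip_effect = 1.5,
                       ip_size_coef = 0.5,
                       shared_ip = 0.35,
                       ip_noise_sd = 0.95,
                       min_truth_overlap = 5L,
                       psychometrics = list(),
                       seed = 1L) {
  # moment-match the lognormal to the target mean/SD of lesion volume
  target_mean <- 14098; target_sd <- 18641
  s2 <- log(1 + (target_sd / target_mean)^2)
  cfg <- list(
    grid_shape = as.integer(grid_shape),
    voxel_dims = as.numeric(voxel_dims),
    n_subjects = as.integer(n_subjects),
    lesion_size_meanlog = lesion_size_meanlog %||% (log(target_mean) - s2 / 2),
    lesion_size_sdlog = lesion_size_sdlog %||% sqrt(s2),
    lesion_size_range = as.numeric(lesion_size_range),
    truth_radius = truth_radius,
    effect = effect, size_coef = size_coef, shared_wm = shared_wm,
    noise_sd = noise_sd,
    ip_effect = ip_effect, ip_size_coef = ip_size_coef,
    shared_ip = shared_ip, ip_noise_sd = ip_noise_sd,
    min_truth_overlap = as.integer(min_truth_overlap),
    psychometrics = utils::modifyList(list(
      span_intercept = c(phonological_digit_matching = 4.0,
                         semantic_category_probe = 2.6),
      span_slope = c(phonological_digit_matching = 0.65,
                     semantic_category_probe = 0.75),
      hit_intercept = 3.2, cr_intercept = 2.8, det_slope = 0.9
    ), psychometrics),
    seed = as.integer(seed)
  )
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape > 4L),
            all(cfg$voxel_dims > 0), cfg$n_subjects >= 2L,
            cfg$lesion_size_range[1L] > 0,
            diff(cfg$lesion_size_range) > 0, cfg$noise_sd >= 0)
  # ground-truth regions: two disjoint spheres in the central coverage band
  d <- cfg$grid_shape
  cfg$truth_centers <- list(
    A = c(round(d[1L] * 0.33), round(d[2L] * 0.42), round(d[3L] * 0.5)),
    B = c(round(d[1L] * 0.67), round(d[2L] * 0.58), round(d[3L] * 0.5))
  )
  if (sqrt(sum((cfg$truth_centers$A - cfg$truth_centers$B)^2)) <=
      2 * cfg$truth_radius)
    stop("sim_config: truth regions are not disjoint on this grid")
  # spatial prior: lesion seed centers cluster over the two truth regions
  # and a central territory between them, giving overlapping coverage
  cfg$prior_centers <- rbind(cfg$truth_centers$A, cfg$truth_centers$B,
                             round(d * c(0.5, 0.5, 0.5)))
  cfg$prior_weights <- c(0.3, 0.3, 0.4)
  cfg$prior_jitter_sd <- 2.5
  class(cfg) <- "sim_config"
  cfg
}

# voxel-center coordinate table for a grid (1-based indices)
.grid_coords <- function(d) {
  as.matrix(expand.grid(i = seq_len(d[1L]), j = seq_len(d[2L]),
                        k = seq_len(d[3L]), KEEP.OUT.ATTRS = FALSE))
}

# logical sphere mask
.sphere <- function(d, center, radius) {
  co <- .grid_coords(d)
  idx <- which(colSums((t(co) - center)^2) <= radius^2)
  arr <- array(FALSE, d)
  arr[idx] <- TRUE
  arr
}

#' Ground-truth weight maps of a simulation configuration
#'
#' @param cfg A [sim_config].
#' @return Named list of two logical 3D arrays (`A`, `B`), disjoint.
#' @export
truth_maps <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  list(A = .sphere(cfg$grid_shape, cfg$truth_centers$A, cfg$truth_radius),
       B = .sphere(cfg$grid_shape, cfg$truth_centers$B, cfg$truth_radius))
}

# Grow one blob-like lesion: the v nearest voxels to a center under a
# random anisotropic (positive-definite) metric; level sets of a convex
# quadratic sampled on the lattice, hence connected for the anisotropy
# range used.
.grow_blob <- function(d, coords, center, v) {
  R <- qr.Q(qr(matrix(rnorm(9), 3L)))
  s <- runif(3L, 0.65, 1.55)
  A <- R %*% diag(1 / s^2) %*% t(R)
  dx <- t(coords) - center
  dist2 <- colSums(dx * (A %*% dx))
  sel <- order(dist2)[seq_len(v)]
  arr <- array(0L, d)
  arr[sel] <- 1L
  arr
}

#' Simulate a cohort of clustered binary lesion masks
#'
#' Draws each subject's lesion volume from the clipped lognormal, a seed
#' center from the spatial prior, and grows a connected blob of that
#' volume. After generation, each ground-truth region is checked for a
#' voxel lesioned in at least `min_truth_overlap` subjects; offending
#' cohorts have their smallest-lesion subjects resampled with seeds forced
#' to that region (count recorded in the `resampled` attribute).
#'
#' @param cfg A [sim_config].
#' @return List of [lesion_mask] objects (with the cohort affine built
#'   from `voxel_dims`).
#' @export
simulate_lesions <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$grid_shape
  vv <- prod(cfg$voxel_dims)
  ngrid <- prod(d)
  coords <- .grid_coords(d)
  affine <- diag(c(cfg$voxel_dims, 1))
  tm <- truth_maps(cfg)
  n_resampled <- 0L
  masks <- .with_seed(.sub_seed(cfg$seed, "lesion_sim"), {
    draw_mask <- function(id, force_center = NULL) {
      vol <- rlnorm(1L, cfg$lesion_size_meanlog, cfg$lesion_size_sdlog)
      vol <- min(max(vol, cfg$lesion_size_range[1L]),
                 cfg$lesion_size_range[2L])
      v <- max(1L, round(vol / vv))
      if (v > ngrid)
        stop("simulate_lesions: target volume exceeds the grid")
      ctr <- force_center %||% {
        kcl <- sample.int(nrow(cfg$prior_centers), 1L,
                          prob = cfg$prior_weights)
        pmin(pmax(cfg$prior_centers[kcl, ] +
                    round(rnorm(3L, 0, cfg$prior_jitter_sd)), 2L), d - 1L)
      }
      lesion_mask(.grow_blob(d, coords, ctr, v), affine = affine,
                  subject_id = sprintf("sim%03d", id))
    }
    masks <- lapply(seq_len(cfg$n_subjects), draw_mask)
    # guarantee analyzable coverage of both truth regions
    for (nm in names(tm)) {
      reg <- which(tm[[nm]])
      for (attempt in seq_len(50L)) {
        cover <- Reduce(`+`, lapply(masks, function(m) m$volume[reg]))
        if (max(cover) >= cfg$min_truth_overlap) break
        vols <- vapply(masks, function(m) sum(m$volume), numeric(1))
        i <- which.min(vols)
        masks[[i]] <- draw_mask(i, force_center = cfg$truth_centers[[nm]])
        n_resampled <- n_resampled + 1L
      }
    }
    masks
  })
  attr(masks, "resampled") <- n_resampled
  masks
}

#' Simulate behavioral trial tables from lesion masks
#'
#' Implements the generative assumption that the lesion-symptom model
#' tests: damage to a score's ground-truth region lowers that score's
#' latent, as does (log) lesion volume; a shared latent factor induces the
#' target correlation between the two working-memory scores, and a second
#' shared factor does the same for the two input-processing scores.
#' Latents are then expressed at the trial level: per list length,
#' `n_correct ~ Binomial(n_trials, plogis(latent - difficulty))` with the
#' stop rule honored, and detection counts analogously (one shared set of
#' 17 match trials, 17 foils per condition), so that span scoring, stop
#' rules and d-prime corrections are exercised end to end.
#'
#' @param masks List of [lesion_mask] on the configuration grid.
#' @param cfg A [sim_config].
#' @return A list of class `sim_cohort` with elements `masks`,
#'   `truth_maps`, `trials` (long-format table as read by
#'   [score_behavior]), `latents` (the generating per-subject latents and
#'   truth-region damage fractions), `lesion_volumes` (mm^3) and `config`.
#' @export
simulate_behavior <- function(masks, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(masks)
  tm <- truth_maps(cfg)
  regA <- which(tm$A); regB <- which(tm$B)
  frac_A <- vapply(masks, function(m) mean(m$volume[regA]), numeric(1))
  frac_B <- vapply(masks, function(m) mean(m$volume[regB]), numeric(1))
  vols <- vapply(masks, lesion_volume_mm3, numeric(1))
  z_size <- as.numeric(scale(log(vols)))
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  out <- .with_seed(.sub_seed(cfg$seed, "behavior_sim"), {
    u_wm <- rnorm(n); u_ip <- rnorm(n)
    lat_phon <- -cfg$effect * frac_A - cfg$size_coef * z_size +
      cfg$shared_wm * u_wm + rnorm(n, 0, cfg$noise_sd)
    lat_sem <- -cfg$effect * frac_B - cfg$size_coef * z_size +
      cfg$shared_wm * u_wm + rnorm(n, 0, cfg$noise_sd)
    burden <- (frac_A + frac_B) / 2
    lat_ip_ph <- -cfg$ip_effect * burden - cfg$ip_size_coef * z_size +
      cfg$shared_ip * u_ip + rnorm(n, 0, cfg$ip_noise_sd)
    lat_ip_se <- -cfg$ip_effect * burden - cfg$ip_size_coef * z_size +
      cfg$shared_ip * u_ip + rnorm(n, 0, cfg$ip_noise_sd)
    rows <- list()
    add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
    for (i in seq_len(n)) {
      # span tasks, administered with the stop rule
      for (task in names(.span_tasks)) {
        b <- .span_tasks[[task]]
        lat <- if (task == "phonological_digit_matching") lat_phon[i]
               else lat_sem[i]
        psy <- cfg$psychometrics
        lens <- seq(b$min_length, b$max_length)
        for (li in seq_along(lens)) {
          p <- plogis(psy$span_intercept[[task]] + lat -
                        psy$span_slope[[task]] * (lens[li] - b$min_length))
          nc <- rbinom(1L, b$trials[li], p)
          add(subject_id = ids[i], task = task, level = lens[li],
              n_trials = b$trials[li], n_correct = nc)
          if (nc / b$trials[li] < 0.75) break
        }
      }
      # picture-word matching: 17 shared match trials, 17 foils/condition
      psy <- cfg$psychometrics
      p_hit <- plogis(psy$hit_intercept +
                        psy$det_slope * (lat_ip_ph[i] + lat_ip_se[i]) / 2)
      add(subject_id = ids[i], task = "picture_word_matching",
          level = "match", n_trials = 17L,
          n_correct = rbinom(1L, 17L, p_hit))
      for (cond in c("phonological_foil", "semantic_foil")) {
        lat <- if (cond == "phonological_foil") lat_ip_ph[i] else lat_ip_se[i]
        p_cr <- plogis(psy$cr_intercept + psy$det_slope * lat)
        add(subject_id = ids[i], task = "picture_word_matching",
            level = cond, n_trials = 17L,
            n_correct = rbinom(1L, 17L, p_cr))
      }
    }
    list(trials = do.call(rbind, rows),
         latents = data.frame(subject_id = ids,
                              frac_A = frac_A, frac_B = frac_B,
                              z_size = z_size,
                              lat_phon = lat_phon, lat_sem = lat_sem,
                              lat_ip_phon = lat_ip_ph,
                              lat_ip_sem = lat_ip_se))
  })
  structure(list(masks = masks, truth_maps = tm, trials = out$trials,
                 latents = out$latents, lesion_volumes = vols,
                 config = cfg),
            class = "sim_cohort")
}

#' Simulate a complete lesion-deficit cohort
#'
#' Convenience wrapper: [simulate_lesions] then [simulate_behavior].
#'
#' @param cfg A [sim_config].
#' @return A `sim_cohort`; see [simulate_behavior].
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  simulate_behavior(simulate_lesions(cfg), cfg)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic lesion-deficit cohort: %d subjects on a %s grid\n",
              length(x$masks), paste(x$config$grid_shape, collapse = "x")))
  cat(sprintf("  lesion volume mean %.0f mm^3 (range %.0f-%.0f)\n",
              mean(x$lesion_volumes), min(x$lesion_volumes),
              max(x$lesion_volumes)))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Emits NIfTI masks, the behavioral trial TSV, truth-map NIfTIs and a
#' JSON snapshot of the generating configuration — a ready-to-run input
#' set for the file-based pipeline.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort_dir <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort$masks, file.path(dir, "masks"))
  write.table(cohort$trials, file.path(dir, "behavior.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  aff <- cohort$masks[[1L]]$affine
  for (nm in names(cohort$truth_maps))
    write_map(cohort$truth_maps[[nm]] + 0,
              file.path(dir, sprintf("truth_%s.nii.gz", nm)), affine = aff)
  cfg <- cohort$config
  cfg$prior_centers <- apply(cfg$prior_centers, 1L, paste, collapse = ",")
  cfg$truth_centers <- lapply(cfg$truth_centers, paste, collapse = ",")
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Voxelwise recovery metrics of a significance map against ground truth
#'
#' Confusion counts restricted to the covered voxels (those that survived
#' the coverage filter): sensitivity = TP / truth voxels in coverage,
#' false-positive rate = FP / non-truth voxels in coverage, and the Dice
#' overlap 2TP / (2TP + FP + FN).
#'
#' @param significant 3D array (or logical vector over covered voxels)
#'   flagging significant voxels, e.g. `fit$maps$significant`.
#' @param truth 3D logical array of the ground-truth region.
#' @param coverage Linear indices of covered voxels (e.g.
#'   `fit$patches$voxel_index`), or a `patched_matrix`/`lesion_matrix`.
#' @return Named list: `sensitivity`, `fpr`, `dice`, and the counts.
#' @export
evaluate_recovery <- function(significant, truth, coverage) {
  if (inherits(coverage, c("patched_matrix", "lesion_matrix")))
    coverage <- coverage$voxel_index
  if (!is.null(dim(significant))) {
    if (!all(dim(significant) == dim(truth)))
      stop("evaluate_recovery: grid mismatch between map and truth")
    sig <- significant[coverage]
  } else {
    sig <- significant
    if (length(sig) != length(coverage))
      stop("evaluate_recovery: significance vector does not match coverage")
  }
  sig <- !is.na(sig) & (sig != 0)
  tru <- truth[coverage] != 0
  tp <- sum(sig & tru); fp <- sum(sig & !tru)
  fn <- sum(!sig & tru); tn <- sum(!sig & !tru)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
              else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
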