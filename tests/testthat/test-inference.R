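make_problem <- function(n = 24, p = 30, seed = 51, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  y <- if (signal) {
    r <- 0.9 - 0.6 * X[, 1] - 0.4 * X[, 2] + rnorm(n, 0, 0.1)
    (r - min(r)) / (max(r) - min(r))
  } else runif(n)
  list(X = X, y = y)
}

test_that("the add-one permutation p-value follows its formula", {
  pr <- make_problem(signal = TRUE)
  gs <- select_params(pr$X, pr$y, grid = data.frame(cost = 10, gamma = 0.05),
                      n_perm = 1, seed = 3)
  # one permutation, worse than the strongly predictable real fit
  expect_equal(gs$model_p, 0.5)
  expect_gte(min(gs$grid$perm_p), 1 / 2)
  # p-values never fall below the permutation resolution
  gs2 <- select_params(pr$X, pr$y, grid = data.frame(cost = 10, gamma = 0.05),
                       n_perm = 19, seed = 3)
  expect_gte(gs2$model_p, 1 / 20)
})

test_that("selection p-values are calibrated under the null", {
  ps <- vapply(1:200, function(s) {
    pr <- make_problem(n = 20, p = 15, seed = 1000 + s, signal = FALSE)
    select_params(pr$X, pr$y, grid = data.frame(cost = 1, gamma = 0.05),
                  n_perm = 99, seed = s)$model_p
  }, numeric(1))
  # uniform null: mean 0.5 within Monte-Carlo error
  expect_lt(abs(mean(ps) - 0.5), 0.05)
  expect_gt(min(ps), 0.009)
})

test_that("lesion-driven cohorts yield significant models in most seeds", {
  grid <- data.frame(cost = c(1, 1, 100, 100), gamma = c(1e-4, 1e-2, 1e-4, 1e-2))
  sig <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(seed = 600 + s))
    sc <- score_behavior(co$trials)
    lmx <- build_matrix(co$masks)
    pm <- compress_patches(lmx)
    dv <- residualize_and_scale(sc$span_phonological,
                                list(size = lmx$lesion_volumes_mm3))
    gs <- select_params(pm$matrix, dv$scaled, grid = grid, n_perm = 99,
                        seed = s, multiplicities = pm$patch_sizes)
    gs$model_p
  }, numeric(1))
  expect_gte(mean(sig <= 0.05), 0.9)
})

test_that("patch inference is one-sided, sign-coherent and reproducible", {
  pr <- make_problem(n = 30, p = 40, seed = 52)
  inf <- patch_inference(pr$X, pr$y, cost = 10, gamma = 0.02, n_perm = 99,
                         seed = 7)
  # positive betas are never significant regardless of rank
  expect_true(all(inf$patch_beta[inf$significant] < 0))
  expect_true(all(inf$patch_p > 0 & inf$patch_p <= 1))
  expect_gte(min(inf$patch_p), 1 / 100)
  # negating the dependent variable negates the beta map
  f1 <- fit_svr(pr$X, pr$y, cost = 10, gamma = 0.02, tol = 1e-7)
  f2 <- fit_svr(pr$X, -pr$y, cost = 10, gamma = 0.02, tol = 1e-7)
  expect_equal(beta_map(f1), -beta_map(f2), tolerance = 1e-4)
  # identical seeds give identical results end to end
  inf2 <- patch_inference(pr$X, pr$y, cost = 10, gamma = 0.02, n_perm = 99,
                          seed = 7)
  expect_identical(inf$patch_p, inf2$patch_p)
  gs1 <- select_params(pr$X, pr$y, grid = data.frame(cost = 1, gamma = 0.02),
                       n_perm = 49, seed = 11)
  gs2 <- select_params(pr$X, pr$y, grid = data.frame(cost = 1, gamma = 0.02),
                       n_perm = 49, seed = 11)
  expect_identical(gs1$grid, gs2$grid)
  # fresh vs reused permutation streams differ by default
  inf3 <- patch_inference(pr$X, pr$y, cost = 10, gamma = 0.02, n_perm = 99,
                          seed = 7, reuse_selection_permutations = TRUE)
  expect_false(identical(inf$patch_p, inf3$patch_p))
})

test_that("grid candidates outside the canonical search range are rejected", {
  expect_error(default_grid(cost = 1e10), "cost")
  expect_error(default_grid(gamma = 1e-12), "gamma")
  g <- default_grid()
  expect_equal(nrow(g), 12 * 13)
})
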