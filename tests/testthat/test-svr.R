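test_that("the SMO solver reproduces libsvm fits on random problems", {
  skip_if_not_installed("e1071")
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(20:80, 1); p <- sample(40:250, 1)
    X <- matrix(rbinom(n * p, 1, 0.25), n, p)
    y <- runif(n)
    gam <- 10^runif(1, -4, 0); C <- 10^runif(1, -1, 3)
    f <- fit_svr(X, y, cost = C, gamma = gam, tol = 1e-5)
    ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      gamma = gam, cost = C, epsilon = 0.1, scale = FALSE,
                      tolerance = 1e-5)
    expect_lt(max(abs(predict(f) - unname(predict(ref, X)))), 1e-3)
  }
})

test_that("multiplicity-weighted patch kernels equal expanded voxel kernels", {
  set.seed(42)
  n <- 15; P <- 40
  Xp <- matrix(rbinom(n * P, 1, 0.4), n, P)
  mult <- sample(1:6, P, replace = TRUE)
  Xv <- Xp[, rep(seq_len(P), mult)]          # expand columns by multiplicity
  gam <- 0.05
  Kp <- exp(-gam * svrlsm:::.row_dist2(svrlsm:::.scale_mult(Xp, mult)))
  Kv <- exp(-gam * svrlsm:::.row_dist2(Xv))
  expect_lt(max(abs(Kp - Kv)), 1e-12)
})

test_that("training error decreases as cost relaxes regularization", {
  set.seed(43)
  n <- 30; p <- 25
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  y <- plogis(-1.5 * X[, 1] - X[, 2] + rnorm(n, 0, 0.3))
  mse <- vapply(c(0.1, 10, 1000), function(C) {
    f <- fit_svr(X, y, cost = C, gamma = 0.05, epsilon = 0.01)
    mean((y - predict(f))^2)
  }, numeric(1))
  expect_true(all(diff(mse) < 1e-10))
})

test_that("beta maps back-project dual coefficients onto features", {
  set.seed(44)
  n <- 20; p <- 30
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  y <- runif(n)
  f <- fit_svr(X, y, cost = 10, gamma = 0.05)
  expect_equal(beta_map(f), drop(crossprod(X, f$coefs)), tolerance = 1e-12)
  # a model whose residuals all sit inside the tube has no support vectors
  flat <- fit_svr(X, c(rep(0.5, n - 1), 0.5001), cost = 1, gamma = 0.05,
                  epsilon = 0.4)
  expect_error(beta_map(flat), "no support vectors")
  # near the linear-kernel limit, back-projection matches a linear SVR's
  # primal weights (independent fit via libsvm)
  skip_if_not_installed("e1071")
  # at gamma -> 0 the RBF model approaches a linear SVR with effective
  # cost C * gamma, so compare at matched effective regularization
  yl <- plogis(-2 * X[, 1] - 1.5 * X[, 5] + rnorm(n, 0, 0.2))
  fl <- fit_svr(X, yl, cost = 1000, gamma = 1e-3, tol = 1e-6)
  lin <- e1071::svm(X, yl, type = "eps-regression", kernel = "linear",
                    cost = 1, epsilon = 0.1, scale = FALSE)
  w <- drop(crossprod(lin$SV, lin$coefs))
  expect_gt(cor(beta_map(fl), w), 0.99)
})

test_that("cross-validation matches a brute-force leave-one-out oracle", {
  set.seed(45)
  n <- 12; p <- 15
  X <- matrix(rbinom(n * p, 1, 0.35), n, p)
  y <- runif(n)
  got <- cv_mse(X, y, cost = 5, gamma = 0.1, k = n, seed = 9)
  oracle <- mean(vapply(seq_len(n), function(i) {
    f <- fit_svr(X[-i, ], y[-i], cost = 5, gamma = 0.1)
    (y[i] - predict(f, X[i, , drop = FALSE]))^2
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-8)
  # y determined by one dominant (high-multiplicity) patch: held-out
  # error collapses toward zero at high cost
  n2 <- 30
  X2 <- matrix(rbinom(n2 * p, 1, 0.35), n2, p)
  y2 <- 0.1 + 0.8 * X2[, 1]
  expect_lt(cv_mse(X2, y2, cost = 1000, gamma = 0.05, epsilon = 0.01,
                   k = 5, seed = 9,
                   multiplicities = c(50, rep(1, p - 1))), 0.01)
  expect_error(cv_mse(X, y, cost = 1, gamma = 0.1, k = 13), "folds")
  # duplicated rows are tolerated
  Xd <- rbind(X, X[1:3, ]); yd <- c(y, y[1:3])
  expect_true(is.finite(cv_mse(Xd, yd, cost = 1, gamma = 0.1, k = 5,
                               seed = 2)))
})

test_that("degenerate fits are rejected", {
  X <- matrix(rbinom(40, 1, 0.5), 8, 5)
  expect_error(fit_svr(X, rep(0.3, 8), cost = 1, gamma = 0.1), "constant")
  expect_error(fit_svr(X, c(NA, runif(7)), cost = 1, gamma = 0.1),
               "non-finite")
  expect_error(fit_svr(X[1, , drop = FALSE], 0.5, cost = 1, gamma = 0.1),
               "2 subjects")
})
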