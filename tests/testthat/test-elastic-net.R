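test_that("standardization centers, scales by population SD, flags constants", {
  X <- cbind(a = c(0, 1), b = c(3, 3))
  s <- standardize_features(X)
  expect_equal(s$x[, "a"], c(-1, 1))
  expect_equal(s$center[["a"]], 0.5)
  expect_equal(s$scale[["a"]], 0.5)
  expect_true(s$zero_var[["b"]])
  expect_equal(s$x[, "b"], c(0, 0))
  # idempotence on an already-standardized column
  s2 <- standardize_features(s$x[, "a", drop = FALSE])
  expect_equal(s2$x[, 1], s$x[, "a"], tolerance = 1e-12)
  expect_error(standardize_features(cbind(c(1, NA))), "complete")
})

test_that("lambda path is log-spaced from the subgradient bound", {
  set.seed(4)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  s <- standardize_features(X)
  lam <- make_lambda_path(s$x, y, alpha = 0.5, n_lambda = 3,
                          lambda_min_ratio = 0.01)
  lam_max_brute <- max(abs(t(s$x) %*% (y - mean(y)))) / (30 * 0.5)
  expect_equal(lam[1], lam_max_brute, tolerance = 1e-12)
  expect_equal(lam, lam[1] * c(1, 0.1, 0.01), tolerance = 1e-10)
  expect_error(make_lambda_path(s$x, y, alpha = 0), "alpha")
  # at lambda_max the fitted model is the null model
  fit <- enet_fit(s$x, y, lam[1], 0.5)
  expect_true(all(fit$beta == 0))
})

test_that("1-D solution matches a dense grid search of the objective", {
  set.seed(1)
  n <- 50
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- x * 1.0  # univariate OLS coefficient exactly 1
  f <- function(b) mean((y - x * b)^2) / 2 + 0.5 * (0.5 * abs(b) + 0.25 * b^2)
  grid <- seq(-2, 2, by = 1e-5)
  b_grid <- grid[which.min(vapply(grid, f, 0))]
  fit <- enet_fit(matrix(x), y, lambda = 0.5, alpha = 0.5, tol = 1e-10)
  expect_equal(fit$beta[1, 1], b_grid, tolerance = 1e-4)
  expect_equal(fit$beta[1, 1], 0.6, tolerance = 1e-8)  # closed form
  expect_true(fit$converged)
})

test_that("lambda = 0 reproduces ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(40 * 8), 40)
  y <- rnorm(40)
  s <- standardize_features(X)
  fit <- enet_fit(s$x, y, lambda = 0, alpha = 0.5, tol = 1e-10)
  ols <- qr.solve(cbind(1, s$x), y)
  expect_equal(fit$beta[, 1], unname(ols[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-8)
})

test_that("converged fits satisfy KKT and match the active-set oracle", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(20:50, 1)
    p <- sample(3:15, 1)
    X <- matrix(rnorm(n * p), n)
    y <- drop(X[, 1] * rnorm(1, 0, 2)) + rnorm(n)
    s <- standardize_features(X)
    lam <- make_lambda_path(s$x, y, 0.5, 8)
    fit <- enet_fit(s$x, y, lam, 0.5, tol = 1e-10)
    for (l in c(3, 6, 8)) {
      k <- enet_kkt_check(s$x, y, fit$beta[, l], fit$intercept, lam[l], 0.5)
      expect_true(k$ok)
      oracle <- enet_projected_oracle(s$x, y, fit$beta[, l], lam[l], 0.5)
      expect_equal(unname(fit$beta[, l]), oracle, tolerance = 1e-7)
      o_cd <- enet_objective(s$x, y, fit$beta[, l], fit$intercept, lam[l], 0.5)
      o_or <- enet_objective(s$x, y, oracle, fit$intercept, lam[l], 0.5)
      expect_lt(abs(o_cd - o_or), 1e-8 * max(1, abs(o_or)))
    }
  }
})

test_that("the penalized objective never increases across sweeps", {
  set.seed(3)
  X <- matrix(rnorm(60 * 25), 60)
  y <- X[, 1] - 2 * X[, 5] + rnorm(60)
  s <- standardize_features(X)
  lam <- make_lambda_path(s$x, y, 0.5, 10)
  fit <- enet_fit(s$x, y, lam, 0.5, record_objective = TRUE)
  for (tr in fit$objective_trace)
    expect_true(all(diff(tr) <= 1e-12))
})

test_that("a max_iter budget of one sweep flags non-convergence", {
  set.seed(5)
  X <- matrix(rnorm(50 * 10), 50)
  y <- X %*% rnorm(10) + rnorm(50)
  s <- standardize_features(X)
  fit <- enet_fit(s$x, y, 0.001, 0.5, max_iter = 1L)
  expect_false(fit$converged[1])
  expect_error(enet_fit(s$x, c(y[-1], NA), 0.1, 0.5), "non-finite")
})

test_that("warm-started path fits agree with cold single-lambda fits", {
  set.seed(6)
  X <- matrix(rnorm(50 * 12), 50)
  y <- X[, 2] * 1.5 + rnorm(50)
  s <- standardize_features(X)
  lam <- make_lambda_path(s$x, y, 0.5, 12)
  warm <- enet_fit(s$x, y, lam, 0.5, tol = 1e-10)
  for (l in c(4, 9, 12)) {
    cold <- enet_fit(s$x, y, lam[l], 0.5, tol = 1e-10)
    expect_equal(warm$beta[, l], cold$beta[, 1], tolerance = 1e-7)
  }
})

test_that("solutions agree with glmnet under matched conventions", {
  # glmnet standardizes y internally, which rescales the ridge term for a
  # user-supplied lambda; on unit-population-SD y (or with alpha = 1) the
  # objectives coincide.
  suppressMessages(requireNamespace("glmnet"))
  set.seed(2)
  X <- matrix(rnorm(80 * 15), 80)
  y <- X[, 1] * 1.5 - X[, 3] + rnorm(80)
  s <- standardize_features(X)
  yz <- y / sqrt(mean((y - mean(y))^2))
  lam <- make_lambda_path(s$x, yz, 0.5, 30)
  mine <- enet_fit(s$x, yz, lam, 0.5, tol = 1e-10)
  g <- glmnet::glmnet(s$x, yz, alpha = 0.5, lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(mine$beta - as.matrix(g$beta))), 1e-6)
  lam1 <- make_lambda_path(s$x, y, 1, 20)
  m1 <- enet_fit(s$x, y, lam1, 1, tol = 1e-10)
  g1 <- glmnet::glmnet(s$x, y, alpha = 1, lambda = lam1,
                       standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(m1$beta - as.matrix(g1$beta))), 1e-6)
})

test_that("internal CV picks large lambda on noise, small on signal", {
  set.seed(10)
  n <- 60; p <- 30
  X <- matrix(rnorm(n * p), n)
  y_noise <- rnorm(n)
  sel_noise <- select_lambda_cv(X, y_noise, n_folds = 5, n_lambda = 40,
                                seed = 2)
  # null model competitive: chosen lambda in the top quarter of the grid
  expect_lte(which(sel_noise$lambda == sel_noise$lambda_chosen), 10)

  y_sig <- X[, 1] * 3 + rnorm(n, 0, 0.5)
  sel_sig <- select_lambda_cv(X, y_sig, n_folds = 5, n_lambda = 40, seed = 2)
  expect_lt(sel_sig$lambda_chosen, sel_sig$lambda[1])
  i <- which(sel_sig$lambda == sel_sig$lambda_chosen)
  expect_lt(sel_sig$cvm[i], sel_sig$cvm[1])

  # determinism: same seed, same folds and selection
  sel_rep <- select_lambda_cv(X, y_sig, n_folds = 5, n_lambda = 40, seed = 2)
  expect_identical(sel_rep$fold, sel_sig$fold)
  expect_identical(sel_rep$lambda_chosen, sel_sig$lambda_chosen)

  # one-SE rule never picks a smaller lambda than the minimizer
  sel_1se <- select_lambda_cv(X, y_sig, n_folds = 5, n_lambda = 40, seed = 2,
                              lambda_rule = "one_se")
  expect_gte(sel_1se$lambda_chosen, sel_sig$lambda_chosen)
  expect_error(select_lambda_cv(X[1:4, ], y_sig[1:4], n_folds = 10),
               "fewer samples")
})
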