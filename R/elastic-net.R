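# Elastic-net solver surface: standardization, lambda path, coordinate
# descent (src/enet.cpp), and penalty selection by internal k-fold CV.
#
# Objective convention (fixed so alpha = 0.5 is the midpoint between ridge
# and lasso):
#   (1/(2n)) ||y - b0 - X b||^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)

#' Standardize a feature matrix
#'
#' Centers each column to mean 0 and scales by the population standard
#' deviation (divide-by-n), the scaling under which the coordinate-descent
#' update has unit curvature. Zero-variance columns get scale 1, are output
#' as all-zero, and are flagged so the solver never selects them.
#'
#' @param X Numeric matrix, samples x features. No missing values.
#' @return List with `x` (standardized matrix), `center`, `scale`,
#'   `zero_var` (logical flag per column).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("standardize_features requires complete data (impute first)")
  n <- nrow(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(X^2) - ctr^2)
  sc[sc < .Machine$double.eps] <- 0
  zero_var <- sc == 0
  sc[zero_var] <- 1
  Xs <- sweep(X, 2, ctr, "-")
  Xs <- sweep(Xs, 2, sc, "/")
  Xs[, zero_var] <- 0
  list(x = Xs, center = ctr, scale = sc, zero_var = zero_var)
}

#' Lambda path for the elastic net
#'
#' `lambda_max = max_j |<x_j, y - mean(y)>| / (n * alpha)` (the smallest
#' penalty at which all coefficients are zero), log-spaced down to
#' `lambda_max * lambda_min_ratio` with `n_lambda` points.
#'
#' @param Xstd Standardized feature matrix (see [standardize_features()]).
#' @param y Response vector.
#' @param alpha Elastic-net mixing in (0, 1]; the path is undefined at 0.
#' @param n_lambda Number of grid points (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest lambda
#'   (default 0.01).
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
make_lambda_path <- function(Xstd, y, alpha, n_lambda = 100,
                             lambda_min_ratio = 0.01) {
  if (alpha <= 0) stop("lambda path undefined for alpha = 0")
  n <- nrow(Xstd)
  lam_max <- max(abs(crossprod(Xstd, y - mean(y)))) / (n * alpha)
  if (lam_max <= 0) lam_max <- .Machine$double.eps
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Fit the elastic net by cyclic coordinate descent
#'
#' Minimizes the elastic-net objective over a (descending) lambda path with
#' warm starts, via exact cyclic coordinate minimization with
#' soft-thresholding. Stops when the largest absolute coefficient update in
#' a full sweep falls below `tol`; `converged` is accurate per lambda.
#'
#' @param Xstd Standardized matrix from [standardize_features()].
#' @param y Response (centered internally; the intercept is `mean(y)`).
#' @param lambda Penalty value(s), used in the order given (descending
#'   recommended for warm starts).
#' @param alpha Mixing parameter in (0, 1].
#' @param tol Convergence tolerance on coefficient updates (default 1e-8).
#' @param max_iter Sweep budget per lambda (default 100000); exceeding it
#'   sets `converged = FALSE` without erroring.
#' @param warm_start Optional initial coefficient vector.
#' @param record_objective Record the penalized objective after every sweep.
#' @return List of class `enet_fit`: `beta` (p x L matrix), `intercept`,
#'   `lambda`, `alpha`, `niter`, `converged`, and optionally
#'   `objective_trace`.
#' @export
enet_fit <- function(Xstd, y, lambda, alpha = 0.5, tol = 1e-8,
                     max_iter = 100000L, warm_start = NULL,
                     record_objective = FALSE) {
  Xstd <- as.matrix(Xstd)
  if (!all(is.finite(Xstd)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  stopifnot(alpha > 0, alpha <= 1, all(lambda >= 0))
  if (is.null(warm_start)) warm_start <- numeric(ncol(Xstd))
  res <- enet_path_cd(Xstd, as.numeric(y), as.numeric(lambda), alpha,
                      tol, as.integer(max_iter), as.numeric(warm_start),
                      record_objective)
  rownames(res$beta) <- colnames(Xstd)
  structure(list(beta = res$beta, intercept = res$intercept,
                 lambda = as.numeric(lambda), alpha = alpha,
                 niter = as.integer(res$niter),
                 converged = as.logical(res$converged),
                 objective_trace = res$objective_trace),
            class = "enet_fit")
}

#' Elastic-net penalized objective
#'
#' @param Xstd,y Standardized design and response.
#' @param beta,intercept Coefficients (standardized scale) and intercept.
#' @param lambda,alpha Penalty and mixing.
#' @return Objective value.
#' @export
enet_objective <- function(Xstd, y, beta, intercept, lambda, alpha) {
  r <- y - intercept - drop(Xstd %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Check the Karush-Kuhn-Tucker conditions of an elastic-net solution
#'
#' For each feature j with residual r: if `b_j != 0` then
#' `(1/n) x_j'r = lambda * (alpha * sign(b_j) + (1-alpha) * b_j)`; if
#' `b_j == 0` then `|(1/n) x_j'r| <= lambda * alpha`, both within `tol`.
#'
#' @param Xstd,y Standardized design and response.
#' @param beta,intercept Solution to certify.
#' @param lambda,alpha Penalty and mixing.
#' @param tol Certificate tolerance (default 1e-6).
#' @return List with `ok` and the maximum violation `max_violation`.
#' @export
enet_kkt_check <- function(Xstd, y, beta, intercept, lambda, alpha,
                           tol = 1e-6) {
  n <- length(y)
  r <- y - intercept - drop(Xstd %*% beta)
  g <- drop(crossprod(Xstd, r)) / n
  nz <- beta != 0
  viol <- numeric(length(beta))
  viol[nz] <- abs(g[nz] - lambda * (alpha * sign(beta[nz]) +
                                      (1 - alpha) * beta[nz]))
  viol[!nz] <- pmax(0, abs(g[!nz]) - lambda * alpha)
  list(ok = max(viol) <= tol, max_violation = max(viol))
}

#' Select lambda by internal k-fold cross-validation
#'
#' Randomly assigns folds (seeded), fits the whole pipeline -- per-fold
#' standardization and a warm-started lambda path -- inside each training
#' fold, and scores held-out mean squared prediction error. Rule `"min"`
#' picks the error-minimizing lambda (ties broken toward the largest, i.e.
#' sparsest, lambda); `"one_se"` picks the largest lambda whose error is
#' within one standard error of the minimum.
#'
#' @param X Raw (unstandardized) feature matrix, samples x features.
#' @param y Response vector.
#' @param alpha Mixing (default 0.5, the midpoint between ridge and lasso).
#' @param n_folds Number of folds (default 10); must not exceed `n`.
#' @param n_lambda,lambda_min_ratio Path geometry (see
#'   [make_lambda_path()]).
#' @param lambda_rule `"min"` or `"one_se"`.
#' @param seed Integer seed for the fold assignment.
#' @param stratify Optional factor; folds are balanced within its levels
#'   (used to keep both species in every fold of a dual-species clock).
#' @param tol Solver tolerance for the fold fits (default 1e-4; CV error
#'   estimation does not need the final-fit precision).
#' @return List of class `lambda_selection`: `lambda` (grid), `cvm`
#'   (mean CV error per lambda), `cvsd` (its standard error),
#'   `lambda_chosen`, `rule`, `fold` (assignments).
#' @export
select_lambda_cv <- function(X, y, alpha = 0.5, n_folds = 10,
                             n_lambda = 100, lambda_min_ratio = 0.01,
                             lambda_rule = c("min", "one_se"), seed = 1L,
                             stratify = NULL, tol = 1e-4) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stop("fewer samples (", n, ") than folds (", n_folds, ")")
  fold <- make_folds(n, n_folds, seed = seed, stratify = stratify)

  # common grid from the full data so fold errors are comparable
  std_all <- standardize_features(X)
  lambda <- make_lambda_path(std_all$x, y, alpha, n_lambda, lambda_min_ratio)

  errs <- matrix(NA_real_, n, length(lambda))
  for (k in seq_len(n_folds)) {
    in_tr <- fold != k
    if (sum(in_tr) < 2) stop("fold ", k, " leaves < 2 training samples")
    std <- standardize_features(X[in_tr, , drop = FALSE])
    fit <- enet_fit(std$x, y[in_tr], lambda, alpha, tol = tol)
    Xte <- sweep(X[!in_tr, , drop = FALSE], 2, std$center, "-")
    Xte <- sweep(Xte, 2, std$scale, "/")
    pred <- sweep(Xte %*% fit$beta, 2, fit$intercept, "+")
    errs[!in_tr, ] <- (pred - y[!in_tr])^2
  }
  cvm <- colMeans(errs)
  fold_means <- rowsum(errs, fold) / as.vector(table(fold))
  cvsd <- apply(fold_means, 2, stats::sd) / sqrt(n_folds)

  i_min <- which(cvm <= min(cvm) + 1e-15)[1]  # grid descending: first = largest
  chosen <- if (lambda_rule == "min") {
    lambda[i_min]
  } else {
    lambda[which(cvm <= cvm[i_min] + cvsd[i_min])[1]]
  }
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_chosen = chosen, rule = lambda_rule, fold = fold),
            class = "lambda_selection")
}

# Seeded uniform-random fold assignment, optionally stratified. Uses a
# private RNG stream so callers' RNG state is untouched.
make_folds <- function(n, k, seed = 1L, stratify = NULL) {
  fold <- integer(n)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
  }
  withr_seed({
    if (is.null(stratify)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      stratify <- as.factor(stratify)
      for (lev in levels(stratify)) {
        idx <- which(stratify == lev)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
  })
  fold
}
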