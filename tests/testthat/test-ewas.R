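three_arm_annot <- function(n_per = 4, chips = c("chipA", "chipB")) {
  n <- 3 * n_per
  a <- tiny_annot(n, group = rep(c("young_control", "old_control",
                                   "old_treated"), each = n_per),
                  age = rep(c(0.577, 2.096, 2.096), each = n_per))
  a$batch_chip <- rep_len(chips, n)
  a$batch_column <- "C1"
  a
}

test_that("the means-model design has the documented column structure", {
  a <- three_arm_annot(4, chips = "chipA")  # single chip level drops out
  d1 <- build_design(a)
  expect_identical(ncol(d1), 3L)
  expect_true(all(colSums(d1) == 4))

  a2 <- three_arm_annot(4, chips = c("chipA", "chipB"))
  extra <- cbind(f1 = rnorm(12), f2 = rnorm(12))
  d2 <- build_design(a2, extra_factors = extra)
  expect_identical(ncol(d2), 6L)  # 3 conditions + 1 chip dummy + 2 factors
  expect_identical(attr(d2, "condition_cols"),
                   c("conditionold_control", "conditionold_treated",
                     "conditionyoung_control"))

  # chip perfectly confounded with condition: rank error naming the column
  a3 <- three_arm_annot(4)
  a3$batch_chip <- a3$group
  expect_error(build_design(a3), "rank deficient")
})

test_that("unwanted-variation factors recover a planted chip shift", {
  set.seed(71)
  n <- 24; p <- 120
  chip <- rep(c(0, 1), each = n / 2)
  mat <- matrix(rnorm(p * n, 0, 0.05), p, n,
                dimnames = list(sprintf("cg%03d", 1:p),
                                sprintf("s%02d", 1:n)))
  mat <- mat + matrix(chip * 0.5, p, n, byrow = TRUE)
  f <- estimate_ruv_factors(mat, rownames(mat), k = 1)
  expect_gt(abs(cor(f[, 1], chip)), 0.95)
  # bitwise determinism, sign convention included
  expect_identical(f, estimate_ruv_factors(mat, rownames(mat), k = 1))
  expect_gt(f[which.max(abs(f[, 1])), 1], 0)
  # on (near) rank-1 controls the second factor carries almost no variance
  sv <- svd(mat - rowMeans(mat))
  expect_lt(sv$d[2]^2 / sum(sv$d^2), 0.05)
  expect_error(estimate_ruv_factors(mat[1:3, ], rownames(mat)[1:3], k = 5),
               "k = 5")
})

test_that("per-CpG least squares matches the normal-equations oracle", {
  set.seed(72)
  X <- cbind(1, rnorm(6), rnorm(6))
  colnames(X) <- c("i", "a", "b")
  attr(X, "condition_cols") <- character(0)
  beta <- matrix(runif(4 * 6), 4, 6,
                 dimnames = list(paste0("cg", 1:4), paste0("s", 1:6)))
  fits <- fit_cpg_linear_models(beta, X)
  for (i in 1:4) {
    oracle <- solve(crossprod(X), crossprod(X, beta[i, ]))
    expect_equal(unname(fits$coefficients[i, ]), unname(drop(oracle)),
                 tolerance = 1e-10)
  }
  expect_identical(unname(fits$df_residual), rep(3, 4))

  # intercept-only design: coefficient is the row mean
  one <- matrix(1, 6, 1, dimnames = list(NULL, "i"))
  f1 <- fit_cpg_linear_models(beta, one)
  expect_equal(unname(f1$coefficients[, 1]), unname(rowMeans(beta)),
               tolerance = 1e-12)

  # exactly linear response: zero residual variance
  lin <- matrix(rep(X[, 2], 2), 2, 6, byrow = TRUE,
                dimnames = list(c("cgA", "cgB"), paste0("s", 1:6)))
  fl <- fit_cpg_linear_models(lin, X)
  expect_equal(unname(fl$sigma_sq), c(0, 0), tolerance = 1e-20)

  # a row with missing values is fit on its observed subset
  beta2 <- beta
  beta2[2, 1] <- NA
  f2 <- fit_cpg_linear_models(beta2, X)
  obs <- !is.na(beta2[2, ])
  oracle2 <- solve(crossprod(X[obs, ]), crossprod(X[obs, ], beta2[2, obs]))
  expect_equal(unname(f2$coefficients[2, ]), unname(drop(oracle2)),
               tolerance = 1e-10)
  expect_identical(unname(f2$df_residual[2]), 2)
})

test_that("variance moderation recovers a known prior and matches limma", {
  set.seed(7)
  d0 <- 6; s0 <- 1; d <- 4; p <- 5000
  s2 <- (d0 * s0 / rchisq(p, d0)) * rchisq(p, d) / d
  fits <- structure(list(sigma_sq = s2, df_residual = rep(d, p)),
                    class = "cpg_fits")
  pr <- moderate_ebayes(fits)
  expect_gt(pr$d0, 3)
  expect_lt(pr$d0, 12)
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(pr$s0_sq, sq$var.prior, tolerance = 1e-8)
  expect_equal(pr$s_tilde_sq, sq$var.post, tolerance = 1e-8)

  # equal variances: infinite prior df, posterior variance uniform at s0^2
  fits_eq <- structure(list(sigma_sq = rep(2, 50), df_residual = rep(4, 50)),
                       class = "cpg_fits")
  pr_eq <- moderate_ebayes(fits_eq)
  expect_identical(pr_eq$d0, Inf)
  expect_equal(unique(pr_eq$s_tilde_sq), pr_eq$s0_sq)
  expect_error(moderate_ebayes(structure(list(sigma_sq = 1:5,
                                              df_residual = rep(1, 5)),
                                         class = "cpg_fits")), ">= 10")
})

test_that("contrasts propagate linearly with correct standard errors", {
  set.seed(73)
  a <- three_arm_annot(4, chips = "chipA")
  design <- build_design(a)
  beta <- matrix(runif(5 * 12), 5, 12,
                 dimnames = list(paste0("cg", 1:5), a$sample_id))
  fits <- fit_cpg_linear_models(beta, design)
  ct <- contrast_spec("Treatment", c(old_treated = 1, old_control = -1))
  eff <- apply_contrast(fits, ct)
  # balanced means model: effect equals the group-mean difference
  d_means <- rowMeans(beta[, a$group == "old_treated"]) -
    rowMeans(beta[, a$group == "old_control"])
  expect_equal(eff$effect, unname(d_means), tolerance = 1e-10)
  # single indicator picks out the coefficient
  e1 <- apply_contrast(fits, contrast_spec("oc", c(old_control = 1)))
  expect_equal(e1$effect, unname(fits$coefficients[, "conditionold_control"]),
               tolerance = 1e-12)
  # c and -c: opposite effects, same SE
  em <- apply_contrast(fits, contrast_spec("neg", c(old_treated = -1,
                                                    old_control = 1)))
  expect_equal(em$effect, -eff$effect, tolerance = 1e-12)
  expect_equal(em$se_unscaled, eff$se_unscaled, tolerance = 1e-12)
  expect_error(apply_contrast(fits, contrast_spec("bad", c(nothere = 1))),
               "nothere")
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(74)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("reversal summary counts opposite-sign doubly-significant CpGs", {
  age <- data.frame(cpg_id = c("a", "b", "c"), effect = c(1, 1, -1),
                    p_adj = c(0.01, 0.2, 0.01))
  trt <- data.frame(cpg_id = c("a", "b", "c"), effect = c(-1, -1, -1),
                    p_adj = c(0.01, 0.01, 0.04))
  rev <- reversal_summary(age, trt)
  expect_identical(rev$n_both_significant, 2L)
  expect_identical(rev$n_reversed, 1L)  # "a" reversed, "c" same sign
  expect_equal(rev$fraction_reversed, 0.5)
  none <- reversal_summary(age[2, , drop = FALSE], trt[2, , drop = FALSE])
  expect_true(is.na(none$fraction_reversed))
  expect_error(reversal_summary(age[1, ], trt[2, ]), "share no CpGs")
})

test_that("unwanted-variation factors reduce confounded effect bias", {
  # hidden batch correlated with treatment, not given to the model
  set.seed(75)
  n_per <- 9
  a <- three_arm_annot(n_per, chips = "chipA")
  hidden <- ifelse(a$group == "old_treated",
                   rbinom(3 * n_per, 1, 0.85), rbinom(3 * n_per, 1, 0.15))
  p <- 400
  beta <- matrix(0.5 + rnorm(p * 3 * n_per, 0, 0.02), p,
                 dimnames = list(sprintf("cg%03d", 1:p), a$sample_id))
  beta <- beta + matrix(hidden * 0.05, p, 3 * n_per, byrow = TRUE)
  ds <- methylome_dataset(beta, a)
  ct <- list(contrast_spec("Treatment", c(old_treated = 1,
                                          old_control = -1)))
  res0 <- run_ewas(ds, contrasts = ct, ruv_k = 0,
                   batch_fields = character(0))
  res2 <- run_ewas(ds, contrasts = ct, ruv_k = 2,
                   control_cpgs = rownames(beta),
                   batch_fields = character(0))
  bias0 <- median(abs(res0$effect))  # true treatment effect is zero
  bias2 <- median(abs(res2$effect))
  expect_lt(bias2, bias0)
})
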