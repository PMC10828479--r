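test_that("group summaries report n, mean and the n-1 standard error", {
  s <- group_summary(c(1, 2, 3, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(s$mean, c(2, 5))
  expect_equal(s$se[s$group == "a"], 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$se[s$group == "b"], 0)
  # two groups with identical data: identical summaries
  s2 <- group_summary(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$se[1], s2$se[2])
  # singleton group: SE 0, flagged
  s3 <- group_summary(c(1, 2, 3), c("a", "a", "b"))
  expect_false(s3$se_defined[s3$group == "b"])
})

test_that("one-way ANOVA matches the hand-computed toy and its edge cases", {
  an <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(an$F, 1.5, tolerance = 1e-12)  # SSB 1.5, SSW 4, df (1, 4)
  expect_equal(an$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # identical group means
  an0 <- one_way_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)
  # degenerate: zero within-group variance, unequal means
  and <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(and$degenerate)
  expect_equal(and$p, 0)
  expect_error(one_way_anova(1:3, c("a", "a", "a")), "2 groups")
})

test_that("Student's t is pooled-variance with the textbook toy value", {
  tt <- student_t_two_sample(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-12)  # -1.2247
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 4), tolerance = 1e-12)
  # t^2 = F identity for two groups
  an <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(tt$t^2, an$F, tolerance = 1e-12)
  # a = b
  t0 <- student_t_two_sample(c(1, 1), c(1, 1))
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  # swapping flips the sign, p unchanged
  ts <- student_t_two_sample(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ts$t, -tt$t, tolerance = 1e-12)
  expect_equal(ts$p, tt$p, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the rank-sum toy and is rank-invariant", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)  # rank sums 6 and 15
  expect_equal(kw$p, pchisq(27 / 7, 1, lower.tail = FALSE), tolerance = 1e-12)
  # monotone transform leaves H unchanged
  kw2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6))))
  expect_equal(kw2$H, kw$H, tolerance = 1e-12)
  # all identical values
  kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
})

test_that("rejuvenation percentage follows its definition and scaling", {
  expect_equal(rejuvenation_percent(c(2, 2), c(0.5, 0.5)), 75)
  expect_equal(rejuvenation_percent(c(2, 2), c(2, 2)), 0)
  # scale invariance
  set.seed(61)
  a <- runif(6, 1.5, 2.5); b <- runif(6, 0.5, 1.5)
  expect_equal(rejuvenation_percent(a, b), rejuvenation_percent(3 * a, 3 * b),
               tolerance = 1e-12)
  expect_error(rejuvenation_percent(c(-1, -2), c(1, 1)), "> 0")
  # gap-based alternative: treated pulled all the way to young gives 100%
  expect_equal(rejuvenation_percent(c(2, 2), c(1, 1), young_ages = c(1, 1)),
               100)
})

test_that("the rejuvenation table aggregates cells, ranges and grand mean", {
  mk <- function(tissue, clock, ctrl, trt)
    data.frame(tissue = tissue, clock = clock,
               group = rep(c("old_control", "old_treated"), each = 2),
               dnam_age_years = c(ctrl, ctrl, trt, trt))
  pred <- rbind(mk("liver", "c1", 2, 0.8),   # 60%
                mk("liver", "c2", 2, 0.4),   # 80%
                mk("blood", "c1", 2, 0.6))   # 70%
  tab <- rejuvenation_table(pred)
  liver <- tab$per_tissue[tab$per_tissue$tissue == "liver", ]
  expect_equal(liver$mean_percent, 70)
  expect_equal(c(liver$min_percent, liver$max_percent), c(60, 80))
  expect_equal(tab$grand_average, 70)  # mean of per-tissue means (70, 70)
  # single cell: grand average equals the cell
  tab1 <- rejuvenation_table(mk("liver", "c1", 2, 1))
  expect_equal(tab1$grand_average, 50)
  # missing old group in a cell errors, naming it
  bad <- rbind(mk("liver", "c1", 2, 0.8)[1:2, ],
               mk("blood", "c1", 2, 0.6))
  expect_error(rejuvenation_table(bad), "liver")
})

test_that("all three tests hold their nominal level under the null", {
  set.seed(202)
  R <- 600
  rej <- matrix(NA, R, 3)
  for (i in seq_len(R)) {
    g <- rep(c("a", "b", "c"), each = 10)
    v <- rnorm(30)
    rej[i, 1] <- one_way_anova(v, g)$p < 0.05
    rej[i, 2] <- student_t_two_sample(v[1:10], v[11:20])$p < 0.05
    rej[i, 3] <- kruskal_wallis(split(v, g))$p < 0.05
  }
  lo <- qbinom(0.005, R, 0.05) / R
  hi <- qbinom(0.995, R, 0.05) / R
  rates <- colMeans(rej)
  expect_true(all(rates >= lo & rates <= hi))
})

test_that("group_comparison bundles the per-panel statistics", {
  set.seed(77)
  v <- c(rnorm(6, 0.6, 0.05), rnorm(6, 2.1, 0.05), rnorm(6, 0.9, 0.05))
  g <- rep(c("young_control", "old_control", "old_treated"), each = 6)
  gc <- group_comparison(v, g)
  expect_identical(nrow(gc$summary), 3L)
  expect_lt(gc$anova$p, 1e-6)
  expect_lt(gc$ttest$p, 1e-6)
  expect_gt(gc$ttest$t, 0)  # old control older than treated
  expect_lt(gc$kruskal_wallis$p, 0.01)
})
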