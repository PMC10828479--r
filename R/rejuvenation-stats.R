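# Group-level treatment statistics: per-group summaries, one-way ANOVA,
# Student's t (pooled variance), Kruskal-Wallis, and the rejuvenation
# percentage read-out comparing treated and untreated old animals.

#' Per-group n, mean and standard error
#'
#' SE is the sample standard deviation (n-1 denominator) divided by
#' sqrt(n); groups of size 1 report SE 0 with `se_defined = FALSE`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @return Data frame with `group`, `n`, `mean`, `se`, `se_defined`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  parts <- split(values, groups)
  out <- do.call(rbind, lapply(names(parts), function(g) {
    v <- parts[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               se_defined = length(v) > 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA; p is the upper tail of the F distribution with
#' (k-1, n-k) degrees of freedom. If every group has zero within-group
#' variance but the means differ, F is infinite and p = 0 is returned with
#' `degenerate = TRUE`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector with >= 2 groups; total n > number of
#'   groups.
#' @return List with `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("need at least 2 groups")
  if (n <= k) stop("need more observations than groups")
  # detect the degenerate all-variance-between case before calling anova()
  ssw <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  ssb <- sum(tapply(values, groups, length) *
               (tapply(values, groups, mean) - mean(values))^2)
  if (ssw <= 1e-12 * max(ssb, 1e-300)) {
    if (ssb > 0)
      return(list(F = Inf, p = 0, df1 = k - 1, df2 = n - k, degenerate = TRUE))
    return(list(F = 0, p = 1, df1 = k - 1, df2 = n - k, degenerate = TRUE))
  }
  an <- stats::anova(stats::lm(values ~ groups))
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df1 = k - 1, df2 = n - k, degenerate = FALSE)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Two-sided, pooled-variance t with `df = n_a + n_b - 2` (the literal
#' Student's test; Welch's unequal-variance test is available via
#' `welch = TRUE`). Two identical constant samples give t = 0, p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch unequal-variance test instead.
#' @return List with `t`, `p`, `df`.
#' @export
student_t_two_sample <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H with average ranks for ties and the tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p is the chi-square upper tail with
#' k - 1 degrees of freedom. All values identical gives H = 0, p = 1.
#'
#' @param samples List of >= 2 numeric groups, each non-empty, total N >= 3.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(lengths(samples) == 0)) stop("each group must be non-empty")
  values <- unlist(samples)
  if (length(values) < 3) stop("need total N >= 3")
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1, df = length(samples) - 1))
  g <- factor(rep(seq_along(samples), lengths(samples)))
  ht <- stats::kruskal.test(values, g)
  list(H = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Rejuvenation percentage
#'
#' `100 * (mean(old_control) - mean(old_treated)) / mean(old_control)`: the
#' relative reduction of mean epigenetic age in treated versus untreated old
#' animals. Scale-invariant in the age unit. An alternative definition
#' relative to the old-minus-young gap is available via `young_ages`.
#'
#' @param old_control_ages DNAm ages of untreated old animals (mean must be
#'   positive).
#' @param old_treated_ages DNAm ages of treated old animals.
#' @param young_ages Optional DNAm ages of young controls; if given, the
#'   percentage is computed relative to the old-control minus young-control
#'   gap instead (flagged in reports as the gap-based mode).
#' @return Rejuvenation percent (may be negative if treated ages exceed
#'   controls).
#' @export
rejuvenation_percent <- function(old_control_ages, old_treated_ages,
                                 young_ages = NULL) {
  if (!length(old_control_ages) || !length(old_treated_ages))
    stop("both old groups must be non-empty")
  m_ctrl <- mean(old_control_ages)
  m_trt <- mean(old_treated_ages)
  if (is.null(young_ages)) {
    if (m_ctrl <= 0)
      stop("mean(old_control) must be > 0 for the control-relative definition")
    return(100 * (m_ctrl - m_trt) / m_ctrl)
  }
  gap <- m_ctrl - mean(young_ages)
  if (gap <= 0) stop("old-control minus young-control gap must be > 0")
  100 * (m_ctrl - m_trt) / gap
}

#' Rejuvenation table across tissues and clocks
#'
#' One rejuvenation percentage per (tissue, clock) cell, the per-tissue mean
#' and min-max range across clocks, and the unweighted grand mean across
#' tissues.
#'
#' @param predictions Data frame with columns `tissue`, `clock`, `group` and
#'   `dnam_age_years`; every (tissue, clock) cell must contain both
#'   `old_control` and `old_treated` samples.
#' @return List of class `rejuvenation_table` with `cells` (tissue, clock,
#'   percent), `per_tissue` (mean, min, max) and `grand_average`.
#' @export
rejuvenation_table <- function(predictions) {
  need <- c("tissue", "clock", "group", "dnam_age_years")
  stopifnot(all(need %in% names(predictions)))
  cells <- unique(predictions[, c("tissue", "clock")])
  cells$percent <- NA_real_
  for (i in seq_len(nrow(cells))) {
    d <- predictions[predictions$tissue == cells$tissue[i] &
                       predictions$clock == cells$clock[i], ]
    ctrl <- d$dnam_age_years[d$group == "old_control"]
    trt <- d$dnam_age_years[d$group == "old_treated"]
    if (!length(ctrl) || !length(trt))
      stop(sprintf("cell (tissue=%s, clock=%s) lacks an old group",
                   cells$tissue[i], cells$clock[i]))
    cells$percent[i] <- rejuvenation_percent(ctrl, trt)
  }
  per_tissue <- do.call(rbind, lapply(split(cells, cells$tissue), function(d)
    data.frame(tissue = d$tissue[1], mean_percent = mean(d$percent),
               min_percent = min(d$percent), max_percent = max(d$percent),
               n_clocks = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_tissue) <- NULL
  structure(list(cells = cells, per_tissue = per_tissue,
                 grand_average = mean(per_tissue$mean_percent)),
            class = "rejuvenation_table")
}

#' @export
print.rejuvenation_table <- function(x, ...) {
  cat("rejuvenation_table (percent reduction of mean DNAm age,\n",
      " old treated vs old control)\n", sep = "")
  print(x$per_tissue, row.names = FALSE)
  cat(sprintf("grand average across tissues: %.2f%%\n", x$grand_average))
  invisible(x)
}

#' Group comparison bundle for one tissue/clock read-out
#'
#' The statistics reported alongside each treatment bar plot: per-group
#' summaries, the three-group ANOVA, the pooled-variance Student's t of old
#' control versus old treated (young controls omitted), and Kruskal-Wallis.
#'
#' @param values Numeric read-out (e.g. DNAm age).
#' @param groups Group labels including `old_control` and `old_treated`.
#' @return List of class `group_comparison`.
#' @export
group_comparison <- function(values, groups) {
  summ <- group_summary(values, groups)
  an <- one_way_anova(values, groups)
  a <- values[groups == "old_control"]
  b <- values[groups == "old_treated"]
  tt <- if (length(a) >= 2 && length(b) >= 2) student_t_two_sample(a, b)
        else list(t = NA_real_, p = NA_real_, df = NA_real_)
  kw <- kruskal_wallis(split(values, groups))
  structure(list(summary = summ, anova = an, ttest = tt,
                 kruskal_wallis = kw),
            class = "group_comparison")
}
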