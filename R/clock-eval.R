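# External cross-validation of clock specifications and the accuracy
# metrics: age correlation R (Pearson, DNAm age vs chronological age) and
# median absolute error (MAE, years).

#' Cross-validation scheme
#'
#' @param kind `"loocv"` (leave one sample out) or `"kfold"`.
#' @param k Number of folds (kfold only; 2 <= k <= n at use time).
#' @param stratify_by `"none"`, `"tissue"` or `"species"` -- balances folds
#'   within the chosen stratum (kfold only).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("loocv", "kfold"), k = 10,
                      stratify_by = c("none", "tissue", "species"),
                      seed = 1L) {
  kind <- match.arg(kind)
  stratify_by <- match.arg(stratify_by)
  if (kind == "kfold" && k < 2) stop("kfold requires k >= 2")
  structure(list(kind = kind, k = as.integer(k), stratify_by = stratify_by,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Out-of-fold clock predictions
#'
#' For each fold, the entire training pipeline -- imputation,
#' standardization, internal penalty selection and the final fit -- is run
#' with that fold's samples excluded, and the held-out samples are predicted
#' by the resulting clock. Every in-scope sample is predicted exactly once.
#'
#' @param ds A [methylome_dataset()]. Only samples within the spec's
#'   tissue/species scope take part.
#' @param spec A [clock_spec()].
#' @param scheme A [cv_scheme()].
#' @return Data frame with `sample_id`, `true_age`, `pred_age` (years),
#'   `tissue`, `species`, `fold`, and for relative clocks `true_rel`,
#'   `pred_rel`.
#' @export
crossval_predict <- function(ds, spec, scheme = cv_scheme("loocv")) {
  stopifnot(inherits(scheme, "cv_scheme"))
  keep <- scope_index(ds, spec)
  sub <- subset_samples(ds, which(keep))
  n <- ncol(sub$beta)
  if (scheme$kind == "kfold" && scheme$k > n)
    stop("k = ", scheme$k, " exceeds the ", n, " in-scope samples")

  fold <- if (scheme$kind == "loocv") seq_len(n) else
    make_folds(n, scheme$k,
               seed = scheme$seed,
               stratify = switch(scheme$stratify_by,
                                 none = NULL,
                                 tissue = sub$annot$tissue,
                                 species = sub$annot$species))
  n_folds <- max(fold)

  res <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    if (sum(!te) < 2) stop("fold ", f, " leaves < 2 training samples")
    fold_spec <- spec
    fold_spec$seed <- spec$seed + f  # deterministic per-fold internal CV
    clock <- train_clock(subset_samples(sub, which(!te)), fold_spec)
    pred <- predict_ages(clock, subset_samples(sub, which(te)))
    out <- data.frame(sample_id = pred$sample_id,
                      true_age = sub$annot$age[te],
                      pred_age = pred$dnam_age_years,
                      tissue = sub$annot$tissue[te],
                      species = sub$annot$species[te],
                      fold = f, stringsAsFactors = FALSE)
    if (spec$clock_type == "relative") {
      out$true_rel <- to_relative_age(out$true_age, out$species, spec$lifespans)
      out$pred_rel <- pred$dnam_relative_age
    }
    res[[f]] <- out
  }
  out <- do.call(rbind, res)
  out[match(sub$annot$sample_id, out$sample_id), , drop = FALSE]
}

#' Age correlation R
#'
#' Pearson product-moment correlation between the DNAm age estimate and
#' chronological age.
#'
#' @param pred,true Numeric vectors of equal length, n >= 3, neither
#'   constant.
#' @return Correlation in \[-1, 1\].
#' @export
age_correlation <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  if (length(pred) < 3) stop("need at least 3 pairs for a correlation")
  if (stats::sd(pred) == 0 || stats::sd(true) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(pred, true)
}

#' Median absolute error
#'
#' Median of `|pred - true|`; for even n the midpoint of the two central
#' order statistics.
#'
#' @param pred,true Numeric vectors of equal, non-zero length.
#' @return MAE (same units as the inputs, years for absolute clocks).
#' @export
median_abs_error <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  if (length(pred) == 0) stop("empty input")
  stats::median(abs(pred - true))
}

#' Epigenetic age acceleration
#'
#' Element-wise difference between DNAm age and chronological age.
#'
#' @param pred,true Numeric vectors of equal length.
#' @return `pred - true`.
#' @export
age_acceleration <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  pred - true
}

#' Evaluation report: R and MAE overall and per stratum
#'
#' Computes the overall age correlation and median absolute error, and the
#' same per tissue and per species. Strata with fewer than 3 samples or a
#' constant age vector report MAE only, with R flagged unavailable (`NA`).
#'
#' @param predictions Output of [crossval_predict()] (or any data frame with
#'   `true_age`, `pred_age`, `tissue`, `species`).
#' @param group_by Strata to break out (default both tissue and species).
#' @return List of class `eval_report` with `overall` and one data frame per
#'   grouping.
#' @export
evaluate_predictions <- function(predictions,
                                 group_by = c("tissue", "species")) {
  metr <- function(p, t) {
    r <- if (length(p) >= 3 && stats::sd(p) > 0 && stats::sd(t) > 0)
      stats::cor(p, t) else NA_real_
    data.frame(n = length(p), r = r, mae = median_abs_error(p, t))
  }
  overall <- metr(predictions$pred_age, predictions$true_age)
  strata <- lapply(group_by, function(gb) {
    parts <- split(predictions, predictions[[gb]])
    out <- do.call(rbind, lapply(parts, function(d)
      metr(d$pred_age, d$true_age)))
    out <- cbind(stratum = names(parts), out)
    rownames(out) <- NULL
    out
  })
  names(strata) <- paste0("by_", group_by)
  structure(c(list(overall = overall), strata,
              list(n = nrow(predictions))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, R = %.3f, MAE = %.4g years\n",
              x$overall$n, x$overall$r, x$overall$mae))
  for (nm in grep("^by_", names(x), value = TRUE)) {
    cat(" ", nm, ":\n", sep = "")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}
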