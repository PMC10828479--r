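# Clock training: relative-age transform, elastic-net regression of age on
# CpG beta values, and prediction of DNAm age.

#' Convert chronological age to relative age
#'
#' Relative age = age / maximum lifespan of the species, a value in \[0, 1\]
#' that aligns species with very different lifespans on a common scale.
#'
#' @param age Age(s) in years, >= 0.
#' @param species Species name(s), recycled against `age`.
#' @param lifespans Named lifespan table (default [species_lifespans()]).
#' @return Relative age fraction(s).
#' @export
#' @examples
#' to_relative_age(1.9, "rat")    # 0.5
#' to_relative_age(122.5, "human") # 1.0
to_relative_age <- function(age, species, lifespans = species_lifespans()) {
  unknown <- setdiff(unique(species), names(lifespans))
  if (length(unknown))
    stop("no maximum lifespan for species: ", paste(unknown, collapse = ", "))
  if (any(age < 0)) stop("age must be >= 0")
  age / unname(lifespans[species])
}

#' Convert relative age back to years
#'
#' Exact inverse of [to_relative_age()].
#'
#' @param rel Relative age fraction(s).
#' @param species Species name(s).
#' @param lifespans Named lifespan table.
#' @return Age(s) in years.
#' @export
from_relative_age <- function(rel, species, lifespans = species_lifespans()) {
  unknown <- setdiff(unique(species), names(lifespans))
  if (length(unknown))
    stop("no maximum lifespan for species: ", paste(unknown, collapse = ", "))
  rel * unname(lifespans[species])
}

#' Specify an epigenetic clock to be trained
#'
#' @param name Clock name (used in reports and file names).
#' @param clock_type `"absolute"` (response: age in years) or `"relative"`
#'   (response: age / species maximum lifespan).
#' @param tissue_scope `"all"` or a character vector of tissues the clock is
#'   trained on (e.g. the brain regions for a brain clock).
#' @param species_scope Character vector of species included in training.
#' @param alpha Elastic-net mixing (default 0.5, midway between ridge and
#'   lasso; not tuned).
#' @param n_lambda,lambda_min_ratio Penalty path geometry.
#' @param internal_cv_folds Folds for the internal penalty-selection CV
#'   (default 10).
#' @param lambda_rule `"min"` (default) or `"one_se"`.
#' @param lifespans Named lifespan table (needed for relative clocks).
#' @param seed Integer seed for fold assignment.
#' @param tol Solver tolerance for the final fit (default 1e-5; far below
#'   the measurement-noise scale of beta values).
#' @param cv_tol Solver tolerance inside the penalty-selection CV
#'   (default 1e-4).
#' @return An object of class `clock_spec`.
#' @export
clock_spec <- function(name, clock_type = c("absolute", "relative"),
                       tissue_scope = "all", species_scope = "rat",
                       alpha = 0.5, n_lambda = 100, lambda_min_ratio = 0.01,
                       internal_cv_folds = 10,
                       lambda_rule = c("min", "one_se"),
                       lifespans = species_lifespans(), seed = 1L,
                       tol = 1e-5, cv_tol = 1e-4) {
  clock_type <- match.arg(clock_type)
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(alpha > 0, alpha <= 1, internal_cv_folds >= 2)
  structure(list(name = name, clock_type = clock_type,
                 tissue_scope = tissue_scope, species_scope = species_scope,
                 alpha = alpha, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 internal_cv_folds = internal_cv_folds,
                 lambda_rule = lambda_rule, lifespans = lifespans,
                 seed = as.integer(seed), tol = tol, cv_tol = cv_tol),
            class = "clock_spec")
}

# Samples of a dataset within a clock spec's tissue/species scope.
scope_index <- function(ds, spec) {
  keep <- ds$annot$species %in% spec$species_scope
  if (!identical(spec$tissue_scope, "all"))
    keep <- keep & ds$annot$tissue %in% spec$tissue_scope
  keep
}

#' Train an epigenetic clock
#'
#' Filters the dataset to the spec's tissue and species scope, builds the
#' response (age, or relative age for relative clocks), mean-imputes missing
#' beta values per CpG from the training samples, standardizes features,
#' selects the penalty by seeded internal k-fold cross-validation, refits on
#' all training samples at the chosen lambda (warm-started along the path),
#' and back-transforms coefficients to the raw beta scale, stored sparsely.
#'
#' @param ds A [methylome_dataset()].
#' @param spec A [clock_spec()].
#' @return A [clock_model()] carrying the weights, training CpG means (for
#'   prediction-time imputation) and training metadata.
#' @export
train_clock <- function(ds, spec) {
  stopifnot(inherits(ds, "methylome_dataset"), inherits(spec, "clock_spec"))
  keep <- scope_index(ds, spec)
  n <- sum(keep)
  if (n == 0) stop("clock scope selects no samples (tissues: ",
                   paste(spec$tissue_scope, collapse = ","), "; species: ",
                   paste(spec$species_scope, collapse = ","), ")")
  if (n < 10) stop("clock scope selects only ", n, " samples (need >= 10)")
  annot <- ds$annot[keep, , drop = FALSE]
  X <- t(ds$beta[, keep, drop = FALSE])  # samples x CpGs

  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " CpG(s) with no observed values dropped from training")
    X <- X[, !all_missing, drop = FALSE]
  }
  cpg_means <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- cpg_means[na_idx[, 2]]
  }

  y <- if (spec$clock_type == "relative")
    to_relative_age(annot$age, annot$species, spec$lifespans)
  else annot$age

  stratify <- if (length(unique(annot$species)) > 1) annot$species else NULL
  sel <- select_lambda_cv(X, y, alpha = spec$alpha,
                          n_folds = spec$internal_cv_folds,
                          n_lambda = spec$n_lambda,
                          lambda_min_ratio = spec$lambda_min_ratio,
                          lambda_rule = spec$lambda_rule, seed = spec$seed,
                          stratify = stratify, tol = spec$cv_tol %||% 1e-4)
  std <- standardize_features(X)
  path <- sel$lambda[sel$lambda >= sel$lambda_chosen]
  fit <- enet_fit(std$x, y, path, spec$alpha, tol = spec$tol %||% 1e-5)
  b_std <- fit$beta[, length(path)]
  b_raw <- b_std / std$scale
  intercept <- fit$intercept - sum(b_raw * std$center)
  nz <- b_raw != 0

  clock_model(
    name = spec$name, clock_type = spec$clock_type,
    weights = stats::setNames(b_raw[nz], colnames(X)[nz]),
    intercept = intercept,
    tissue_scope = spec$tissue_scope, species_scope = spec$species_scope,
    lifespans = spec$lifespans,
    cpg_means = stats::setNames(cpg_means[nz], colnames(X)[nz]),
    training_meta = list(alpha = spec$alpha, lambda = sel$lambda_chosen,
                         lambda_rule = spec$lambda_rule, n_train = n,
                         n_cpgs_offered = ncol(X), seed = spec$seed,
                         converged = fit$converged[length(path)]))
}

#' Predict DNAm age with a trained clock
#'
#' Applies the linear score `intercept + sum(w_i beta_i)`. At least 80% of
#' the clock's CpGs must be present in the dataset; absent CpGs (and missing
#' cells) are imputed at the clock's stored training means. Absolute clocks
#' return years; relative clocks return the relative age plus years via the
#' sample's species lifespan. Negative estimates are not clipped.
#'
#' @param clock A [clock_model()].
#' @param ds A [methylome_dataset()].
#' @return Data frame with `sample_id`, `dnam_age_years`, `age_acceleration`
#'   (prediction minus chronological age), and for relative clocks
#'   `dnam_relative_age`.
#' @export
predict_ages <- function(clock, ds) {
  stopifnot(inherits(clock, "clock_model"), inherits(ds, "methylome_dataset"))
  cpgs <- names(clock$weights)
  present <- cpgs %in% rownames(ds$beta)
  coverage <- if (length(cpgs)) mean(present) else 1
  if (coverage < 0.8)
    stop(sprintf("dataset covers only %.1f%% of the %d clock CpGs (need >= 80%%)",
                 100 * coverage, length(cpgs)))
  n <- ncol(ds$beta)
  if (length(cpgs) == 0) {
    # null model: the score is the intercept alone
    out <- data.frame(sample_id = ds$annot$sample_id,
                      stringsAsFactors = FALSE)
    if (clock$clock_type == "relative") {
      out$dnam_relative_age <- rep(clock$intercept, n)
      out$dnam_age_years <- from_relative_age(out$dnam_relative_age,
                                              ds$annot$species,
                                              clock$lifespans)
    } else {
      out$dnam_age_years <- rep(clock$intercept, n)
    }
    out$age_acceleration <- out$dnam_age_years - ds$annot$age
    return(out)
  }
  means <- if (is.null(clock$cpg_means))
    stats::setNames(rep(NA_real_, length(cpgs)), cpgs) else clock$cpg_means[cpgs]
  B <- matrix(rep(means, n), nrow = length(cpgs),
              dimnames = list(cpgs, colnames(ds$beta)))
  if (any(present)) {
    obs <- ds$beta[cpgs[present], , drop = FALSE]
    miss <- is.na(obs)
    if (any(miss)) obs[miss] <- B[present, , drop = FALSE][miss]
    B[present, ] <- obs
  }
  if (anyNA(B))
    stop("missing clock CpGs cannot be imputed: the clock stores no training means")
  score <- clock$intercept + drop(crossprod(B, clock$weights))
  out <- data.frame(sample_id = ds$annot$sample_id, stringsAsFactors = FALSE)
  if (clock$clock_type == "relative") {
    out$dnam_relative_age <- score
    out$dnam_age_years <- from_relative_age(score, ds$annot$species,
                                            clock$lifespans)
  } else {
    out$dnam_age_years <- score
  }
  out$age_acceleration <- out$dnam_age_years - ds$annot$age
  out
}
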