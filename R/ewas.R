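# Epigenome-wide association: per-CpG least-squares fits against a means-model
# design (condition one-hot without intercept, batch dummies, optional
# unwanted-variation factors), empirical-Bayes variance moderation,
# contrasts, BH correction, and the age/treatment reversal summary.

#' Build a means-model design matrix
#'
#' Condition (`group`) is encoded as a one-hot means model without intercept;
#' each batch field is one-hot encoded with its first level dropped; extra
#' factor columns (e.g. unwanted-variation vectors) are appended as
#' continuous covariates. The result must have full column rank.
#'
#' @param annot Sample annotation data frame (see [methylome_dataset()]).
#' @param batch_fields Annotation columns treated as batches (default
#'   `batch_chip` and `batch_column`).
#' @param extra_factors Optional numeric matrix (samples x k) of appended
#'   covariates.
#' @return Numeric design matrix with a `condition_cols` attribute naming
#'   the condition columns.
#' @export
build_design <- function(annot, batch_fields = c("batch_chip", "batch_column"),
                         extra_factors = NULL) {
  cond <- factor(annot$group)
  if (any(table(cond) == 0))
    stop("condition level with zero samples: ",
         paste(names(which(table(cond) == 0)), collapse = ", "))
  X <- stats::model.matrix(~ 0 + cond)
  colnames(X) <- paste0("condition", levels(cond))
  cond_cols <- colnames(X)
  for (bf in batch_fields) {
    b <- factor(annot[[bf]])
    if (nlevels(b) > 1) {
      D <- stats::model.matrix(~ b)[, -1, drop = FALSE]
      colnames(D) <- paste0(bf, levels(b)[-1])
      X <- cbind(X, D)
    }
  }
  if (!is.null(extra_factors)) {
    extra_factors <- as.matrix(extra_factors)
    if (is.null(colnames(extra_factors)))
      colnames(extra_factors) <- paste0("factor", seq_len(ncol(extra_factors)))
    X <- cbind(X, extra_factors)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  attr(X, "condition_cols") <- cond_cols
  X
}

#' Estimate unwanted-variation factors from control CpGs
#'
#' Factors are the first k right-singular vectors (sample space) of the
#' row-centered control-CpG submatrix -- latent technical covariates in the
#' spirit of control-feature factor analysis. The sign of each factor is
#' fixed so its largest-magnitude entry is positive, making repeated runs
#' bitwise identical.
#'
#' @param mat CpG x sample matrix (beta or logit-beta values).
#' @param control_cpgs Row names (or indices) of control CpGs; at least k.
#' @param k Number of factors (>= 1).
#' @return Samples x k matrix of factors.
#' @export
estimate_ruv_factors <- function(mat, control_cpgs, k) {
  stopifnot(k >= 1)
  if (length(control_cpgs) < k)
    stop("need at least k = ", k, " control CpGs")
  sub <- mat[control_cpgs, , drop = FALSE]
  sub <- sub - rowMeans(sub)
  if (k > min(dim(sub)))
    stop("k = ", k, " exceeds the rank of the control submatrix")
  sv <- svd(sub, nu = 0, nv = k)
  if (sv$d[k] < max(sv$d) * 1e-12)
    stop("k = ", k, " exceeds the rank of the control submatrix")
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(mat)
  colnames(V) <- paste0("ruv", seq_len(k))
  V
}

#' Pick empirical control CpGs for factor estimation
#'
#' Ranks CpGs by the absolute correlation between age and the residuals of a
#' batch-only (null) model fit per CpG, and returns the fraction with the
#' smallest marginal age association -- CpGs least likely to carry signal,
#' used as empirical controls.
#'
#' @param ds A [methylome_dataset()].
#' @param frac Fraction of CpGs to keep (default 0.1).
#' @param batch_fields Batch columns for the null model.
#' @return Character vector of control CpG ids.
#' @export
select_control_cpgs <- function(ds, frac = 0.1,
                                batch_fields = c("batch_chip", "batch_column")) {
  beta <- ds$beta
  null_terms <- lapply(batch_fields, function(bf) factor(ds$annot[[bf]]))
  keep_terms <- null_terms[vapply(null_terms, nlevels, 1L) > 1]
  X0 <- if (length(keep_terms))
    stats::model.matrix(~ ., data = as.data.frame(keep_terms))
  else matrix(1, ncol(beta), 1)
  resid <- t(stats::lm.fit(X0, t(beta))$residuals)
  age_c <- ds$annot$age - mean(ds$annot$age)
  num <- abs(resid %*% age_c)
  den <- sqrt(rowSums(resid^2)) * sqrt(sum(age_c^2))
  score <- ifelse(den > 0, num / den, 0)
  n_keep <- max(1, round(frac * nrow(beta)))
  rownames(beta)[order(score)][seq_len(n_keep)]
}

#' Fit per-CpG least-squares linear models
#'
#' Ordinary least squares of each CpG's beta values on the design. Rows with
#' missing values are fit on the observed subset when at least one residual
#' degree of freedom remains, otherwise skipped with a warning.
#'
#' @param ds A [methylome_dataset()] (or a CpG x sample matrix).
#' @param design Design matrix from [build_design()].
#' @return List of class `cpg_fits`: `coefficients` (CpG x coefficient),
#'   `sigma_sq`, `df_residual`, `cov_unscaled` (shared, or per-CpG list for
#'   rows with missingness), `design`.
#' @export
fit_cpg_linear_models <- function(ds, design) {
  beta <- if (inherits(ds, "methylome_dataset")) ds$beta else as.matrix(ds)
  n <- ncol(beta)
  stopifnot(nrow(design) == n)
  qx <- qr(design)
  rank <- qx$rank
  if (n <= rank) stop("need more samples than design rank")
  p <- nrow(beta)
  q <- ncol(design)
  cov_shared <- solve(crossprod(design))  # (X'X)^-1 for the full design

  complete <- !apply(is.na(beta), 1, any)
  coefs <- matrix(NA_real_, p, q, dimnames = list(rownames(beta), colnames(design)))
  sigma_sq <- rep(NA_real_, p)
  dfres <- rep(NA_real_, p)
  cov_list <- NULL

  if (any(complete)) {
    Yc <- t(beta[complete, , drop = FALSE])
    fit <- stats::lm.fit(design, Yc)
    cf <- t(as.matrix(fit$coefficients))
    coefs[complete, ] <- cf
    res <- as.matrix(fit$residuals)
    sigma_sq[complete] <- colSums(res^2) / (n - rank)
    dfres[complete] <- n - rank
  }
  if (any(!complete)) {
    cov_list <- vector("list", p)
    skipped <- character(0)
    for (i in which(!complete)) {
      obs <- !is.na(beta[i, ])
      Xi <- design[obs, , drop = FALSE]
      qi <- qr(Xi)
      if (sum(obs) - qi$rank < 1 || qi$rank < q) {
        skipped <- c(skipped, rownames(beta)[i])
        next
      }
      fi <- stats::lm.fit(Xi, beta[i, obs])
      coefs[i, ] <- fi$coefficients
      sigma_sq[i] <- sum(fi$residuals^2) / (sum(obs) - q)
      dfres[i] <- sum(obs) - q
      cov_list[[i]] <- solve(crossprod(Xi))
    }
    if (length(skipped))
      warning(length(skipped), " CpG(s) skipped (insufficient observed data): ",
              paste(utils::head(skipped, 5), collapse = ", "))
  }
  structure(list(coefficients = coefs, sigma_sq = sigma_sq,
                 df_residual = dfres, cov_unscaled = cov_shared,
                 cov_per_cpg = cov_list, design = design),
            class = "cpg_fits")
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (it in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes moderation of per-CpG variances
#'
#' Fits a scaled inverse-chi-square prior (d0, s0^2) to the ensemble of
#' residual variances by matching the first two moments of log(sigma^2)
#' (digamma/trigamma inversion). The posterior variance
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` replaces s^2 in the t statistic,
#' which then has d0 + d degrees of freedom. When the observed log-variance
#' spread is no larger than expected under equal true variances, d0 is
#' infinite and `s~^2 = s0^2` for every CpG.
#'
#' @param fits A `cpg_fits` object (>= 10 CpGs with positive residual df).
#' @return List of class `moderated_prior`: `d0`, `s0_sq`, `s_tilde_sq`
#'   (per CpG), `df_total`.
#' @export
moderate_ebayes <- function(fits) {
  ok <- !is.na(fits$sigma_sq) & fits$df_residual > 0
  if (sum(ok) < 10) stop("need >= 10 CpGs with positive residual df")
  s2 <- fits$sigma_sq[ok]
  d <- fits$df_residual[ok]
  # guard exact zeros (perfect fits) with a tiny floor on the log scale
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s_tilde_sq <- rep(NA_real_, length(fits$sigma_sq))
  if (is.finite(d0)) {
    s_tilde_sq[ok] <- (d0 * s0_sq + d * s2) / (d0 + d)
  } else {
    s_tilde_sq[ok] <- s0_sq
  }
  structure(list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq,
                 df_total = ifelse(ok, fits$df_residual + d0, NA_real_)),
            class = "moderated_prior")
}

#' Contrast specification
#'
#' A signed combination of condition-column coefficients, e.g. the
#' treatment contrast `old_treated - old_control` or the age contrast
#' `old_control - young_control`.
#'
#' @param name Contrast name.
#' @param weights Named numeric vector; names are condition levels (the
#'   `group` values), e.g. `c(old_treated = 1, old_control = -1)`.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, weights) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  structure(list(name = name, weights = weights), class = "contrast_spec")
}

#' Apply a contrast to per-CpG fits
#'
#' Effect = c'b per CpG; the standard error comes from propagating c through
#' the design's unscaled covariance, times the CpG's residual (or moderated)
#' standard deviation.
#'
#' @param fits A `cpg_fits` object.
#' @param contrast A [contrast_spec()].
#' @return Data frame with `cpg_id`, `effect`, `se_unscaled` (the
#'   sigma-free part of the SE), `se_ordinary`.
#' @export
apply_contrast <- function(fits, contrast) {
  cond_cols <- attr(fits$design, "condition_cols")
  want <- paste0("condition", names(contrast$weights))
  unknown <- setdiff(want, cond_cols)
  if (length(unknown))
    stop("contrast names unknown condition columns: ",
         paste(sub("^condition", "", unknown), collapse = ", "))
  cvec <- numeric(ncol(fits$design))
  names(cvec) <- colnames(fits$design)
  cvec[want] <- contrast$weights
  effect <- drop(fits$coefficients %*% cvec)
  seu_shared <- sqrt(drop(t(cvec) %*% fits$cov_unscaled %*% cvec))
  seu <- rep(seu_shared, nrow(fits$coefficients))
  if (!is.null(fits$cov_per_cpg)) {
    for (i in seq_along(fits$cov_per_cpg)) {
      if (!is.null(fits$cov_per_cpg[[i]]))
        seu[i] <- sqrt(drop(t(cvec) %*% fits$cov_per_cpg[[i]] %*% cvec))
    }
  }
  data.frame(cpg_id = rownames(fits$coefficients), effect = effect,
             se_unscaled = seu,
             se_ordinary = seu * sqrt(fits$sigma_sq),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values, capped at 1 and monotone in rank order.
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Run the full EWAS for a set of contrasts
#'
#' Builds the design (optionally augmented with unwanted-variation factors
#' estimated from empirical control CpGs), fits per-CpG models, moderates
#' variances, applies each contrast and adjusts p values per contrast.
#'
#' @param ds A [methylome_dataset()].
#' @param contrasts List of [contrast_spec()]s. Default: the age contrast
#'   (old control minus young control) and the treatment contrast (old
#'   treated minus old control).
#' @param ruv_k Number of unwanted-variation factors (0 disables; default 2).
#' @param control_cpgs Explicit control CpG ids, or `NULL` to select the 10%
#'   of CpGs with the smallest marginal age association.
#' @param batch_fields Batch columns of the annotation to adjust for.
#' @param q Significance threshold on the BH-adjusted p (default 0.05).
#' @return Data frame of class `ewas_result`: one row per CpG x contrast
#'   with `effect`, `t_mod`, `df`, `p`, `p_adj`, `significant`.
#' @export
run_ewas <- function(ds,
                     contrasts = list(
                       contrast_spec("Age", c(old_control = 1,
                                              young_control = -1)),
                       contrast_spec("Treatment", c(old_treated = 1,
                                                    old_control = -1))),
                     ruv_k = 2, control_cpgs = NULL,
                     batch_fields = c("batch_chip", "batch_column"),
                     q = 0.05) {
  extra <- NULL
  if (ruv_k > 0) {
    if (is.null(control_cpgs))
      control_cpgs <- select_control_cpgs(ds, batch_fields = batch_fields)
    extra <- estimate_ruv_factors(ds$beta, control_cpgs, ruv_k)
  }
  design <- build_design(ds$annot, batch_fields = batch_fields,
                         extra_factors = extra)
  fits <- fit_cpg_linear_models(ds, design)
  prior <- moderate_ebayes(fits)
  res <- lapply(contrasts, function(ct) {
    eff <- apply_contrast(fits, ct)
    t_mod <- eff$effect / (eff$se_unscaled * sqrt(prior$s_tilde_sq))
    df <- prior$df_total
    p <- 2 * stats::pt(-abs(t_mod), df)
    ok <- !is.na(p)
    p_adj <- rep(NA_real_, length(p))
    p_adj[ok] <- bh_adjust(p[ok])
    data.frame(cpg_id = eff$cpg_id, contrast = ct$name, effect = eff$effect,
               t_mod = t_mod, df = df, p = p, p_adj = p_adj,
               significant = !is.na(p_adj) & p_adj < q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "prior") <- prior
  class(out) <- c("ewas_result", class(out))
  out
}

#' Reversal summary: treatment effects opposing age effects
#'
#' Among CpGs significant in both the age and the treatment contrast at the
#' chosen threshold, counts those whose effects have opposite signs
#' (reversed) versus the same sign.
#'
#' @param age_results,treat_results Rows of an `ewas_result` for the two
#'   contrasts (must share the CpG universe).
#' @param q_threshold Adjusted-p threshold (default 0.05).
#' @return List with `n_both_significant`, `n_reversed`, `n_same_sign`,
#'   `fraction_reversed` (`NA` when no CpG is doubly significant).
#' @export
reversal_summary <- function(age_results, treat_results, q_threshold = 0.05) {
  common <- intersect(age_results$cpg_id, treat_results$cpg_id)
  if (!length(common)) stop("the two result sets share no CpGs")
  a <- age_results[match(common, age_results$cpg_id), ]
  b <- treat_results[match(common, treat_results$cpg_id), ]
  both <- !is.na(a$p_adj) & !is.na(b$p_adj) &
    a$p_adj < q_threshold & b$p_adj < q_threshold
  n_both <- sum(both)
  n_rev <- sum(both & sign(a$effect) != sign(b$effect))
  list(n_both_significant = n_both, n_reversed = n_rev,
       n_same_sign = n_both - n_rev,
       fraction_reversed = if (n_both > 0) n_rev / n_both else NA_real_)
}
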