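# Small programmatic fixtures shared across test files.

# A minimal valid annotation data frame.
tiny_annot <- function(n, species = "rat", tissue = "blood", age = NULL,
                       group = "none") {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             species = species, tissue = tissue,
             age = if (is.null(age)) seq(0.1, 2, length.out = n) else age,
             sex = rep_len(c("F", "M"), n), group = group,
             batch_chip = rep_len(c("chipA", "chipB"), n),
             batch_column = rep_len(c("C1", "C2"), n),
             stringsAsFactors = FALSE)
}

# A small valid dataset with uniform random beta values.
tiny_dataset <- function(n_cpgs = 5, n_samples = 4, seed = 1, ...) {
  set.seed(seed)
  beta <- matrix(runif(n_cpgs * n_samples), n_cpgs,
                 dimnames = list(sprintf("cg%03d", seq_len(n_cpgs)),
                                 sprintf("s%02d", seq_len(n_samples))))
  methylome_dataset(beta, tiny_annot(n_samples, ...))
}

# Single-species aging simulation used by several training tests.
aging_sim <- function(n = 120, p = 800, noise_sd = 0.3, seed = 11,
                      extra_groups = NULL) {
  groups <- data.frame(group = "none", n = n,
                       age_min = 0.0384, age_max = 2.3)
  if (!is.null(extra_groups)) groups <- rbind(groups, extra_groups)
  cfg <- sim_config(n_cpgs = p, frac_age_related = 0.1,
                    species_specs = list(species_spec("rat", 3.8, groups)),
                    tissues = "blood", tissue_effect_sd = 0,
                    noise_sd = noise_sd, seed = seed)
  simulate_dataset(cfg)
}

# Closed-form elastic-net solution restricted to a fixed active set and sign
# pattern: (A'A/n + lambda(1-alpha) I) b_A = A'y_c/n - lambda*alpha*sign_A.
# Used as the "projected" oracle for solutions found by coordinate descent.
enet_projected_oracle <- function(Xstd, y, beta_hat, lambda, alpha) {
  act <- which(beta_hat != 0)
  b <- numeric(length(beta_hat))
  if (length(act)) {
    A <- Xstd[, act, drop = FALSE]
    n <- nrow(A)
    yc <- y - mean(y)
    M <- crossprod(A) / n + diag(lambda * (1 - alpha), length(act))
    rhs <- crossprod(A, yc) / n - lambda * alpha * sign(beta_hat[act])
    b[act] <- solve(M, rhs)
  }
  b
}

# Brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
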