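# Synthetic multi-tissue, dual-species methylome generator.
#
# Generative model, on the logit (log-odds) scale of the beta value:
#   logit(beta_ic) = baseline_i + slope_i * rel_age_c + tissue_offset_i[t(c)]
#                    + chip_offset[chip(c)] + N(0, noise_sd)
# where rel_age_c is the sample's *effective* relative age: chronological age
# divided by the species maximum lifespan for untreated samples, and shrunk by
# (1 - rho) for old_treated samples (their annotated chronological age stays at
# the old value). The logistic link keeps beta in (0,1) without clipping.

RAT_TISSUES <- c("blood", "liver", "heart", "hypothalamus", "adipose",
                 "cerebellum", "hippocampus", "neocortex", "ovaries",
                 "pituitary", "skin", "substantia_nigra", "whole_brain")

#' Specify one species' samples for the simulator
#'
#' @param name Species name (key into the lifespan table).
#' @param max_lifespan Maximum lifespan in years.
#' @param groups Data frame with columns `group` (one of `young_control`,
#'   `old_control`, `old_treated`, `none`), `n` (samples per tissue), and
#'   `age_min`, `age_max` (years; ages drawn uniformly within).
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, max_lifespan, groups) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "n", "age_min", "age_max") %in% names(groups)))
  if (any(!groups$group %in% SAMPLE_GROUPS))
    stop("unknown group in species_spec: ",
         paste(setdiff(groups$group, SAMPLE_GROUPS), collapse = ", "))
  if (any(groups$n <= 0))
    stop("group sizes must be positive for requested groups")
  if (max_lifespan <= 0) stop("max_lifespan must be > 0")
  structure(list(name = name, max_lifespan = max_lifespan, groups = groups),
            class = "species_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: a mammalian-array
#' scale panel of conserved CpGs (36,000), thirteen rat tissues, a rat
#' (maximum lifespan 3.8 years, ages 0.0384--2.3 years) and optionally a
#' human (122.5 years) cohort, and a three-arm treatment design with six
#' animals per arm: young controls (30 weeks = 0.577 y), old controls and
#' old treated (109 weeks = 2.096 y). The treatment is encoded as a
#' multiplicative shrinkage of effective relative age by `rejuvenation_rho`,
#' so the generative rho is directly comparable to the rejuvenation
#' percentage estimated downstream.
#'
#' @param n_cpgs Number of CpGs (default 36000).
#' @param frac_age_related Fraction of CpGs with a non-zero age slope
#'   (default 0.10).
#' @param species_specs List of [species_spec()] entries. Default: one rat
#'   cohort with a `none`-group training spread plus the three treatment
#'   arms.
#' @param tissues Tissue names (default: the thirteen rat tissues).
#' @param tissue_effect_sd SD of per-CpG, per-tissue offsets (logit units,
#'   default 0.5).
#' @param species_offset_sd SD of per-CpG, per-species baseline offsets
#'   (logit units, default 1). Conserved CpGs share their aging archetype
#'   across species but retain species-level mean differences; this term is
#'   what lets an absolute-age dual-species clock resolve species at all.
#' @param noise_sd Residual SD on the logit scale (default 0.3).
#' @param slope_range Age slopes are drawn uniformly on
#'   `[-slope_range, slope_range]` (logit units per unit relative age,
#'   default 4).
#' @param baseline_sd SD of per-CpG baselines (logit units, default 2).
#' @param rejuvenation_rho Fractional rejuvenation of treated samples'
#'   effective relative age (default 0.6).
#' @param batch_effect_sd SD of per-chip offsets applied to all CpGs (logit
#'   units, default 0.1).
#' @param n_chips Number of array chips samples are distributed over
#'   (default 4).
#' @param seed Integer seed; everything downstream is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cpgs = 36000,
                       frac_age_related = 0.10,
                       species_specs = list(
                         species_spec("rat", 3.8, data.frame(
                           group = c("none", "young_control", "old_control",
                                     "old_treated"),
                           n = c(4, 6, 6, 6),
                           age_min = c(0.0384, 0.577, 2.096, 2.096),
                           age_max = c(2.3, 0.577, 2.096, 2.096)))),
                       tissues = RAT_TISSUES,
                       tissue_effect_sd = 0.5,
                       species_offset_sd = 1,
                       noise_sd = 0.3,
                       slope_range = 4,
                       baseline_sd = 2,
                       rejuvenation_rho = 0.6,
                       batch_effect_sd = 0.1,
                       n_chips = 4,
                       seed = 1L) {
  stopifnot(n_cpgs >= 1, frac_age_related > 0, frac_age_related <= 1,
            noise_sd >= 0, rejuvenation_rho >= 0, rejuvenation_rho <= 1,
            n_chips >= 1, length(tissues) >= 1)
  structure(list(n_cpgs = as.integer(n_cpgs),
                 frac_age_related = frac_age_related,
                 species_specs = species_specs, tissues = tissues,
                 tissue_effect_sd = tissue_effect_sd,
                 species_offset_sd = species_offset_sd, noise_sd = noise_sd,
                 slope_range = slope_range, baseline_sd = baseline_sd,
                 rejuvenation_rho = rejuvenation_rho,
                 batch_effect_sd = batch_effect_sd,
                 n_chips = as.integer(n_chips), seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-CpG archetypes
#'
#' Exactly `round(frac_age_related * n_cpgs)` CpGs get a non-zero age slope,
#' drawn uniformly from `[-slope_range, slope_range]`; the rest have slope 0.
#' Baselines are Normal(0, `baseline_sd`) and each tissue gets a
#' Normal(0, `tissue_effect_sd`) offset per CpG. Deterministic given the
#' config seed (call inside `set.seed`; [simulate_dataset()] does).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; if `NULL` (default) the current RNG state is
#'   used, as when called from [simulate_dataset()].
#' @return List with `baseline`, `slope` (length `n_cpgs`), `tissue_offsets`
#'   (`n_cpgs` x tissues matrix), `age_related` (logical), `cpg_ids`.
#' @export
sample_archetypes <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$n_cpgs
  n_age <- round(config$frac_age_related * p)
  cpg_ids <- sprintf("cg%06d", seq_len(p))
  baseline <- stats::rnorm(p, 0, config$baseline_sd)
  age_idx <- sample.int(p, n_age)
  slope <- numeric(p)
  slope[age_idx] <- stats::runif(n_age, -config$slope_range, config$slope_range)
  offsets <- matrix(stats::rnorm(p * length(config$tissues), 0,
                                 config$tissue_effect_sd),
                    nrow = p, dimnames = list(cpg_ids, config$tissues))
  species_names <- vapply(config$species_specs, `[[`, "", "name")
  sp_off <- matrix(stats::rnorm(p * length(species_names), 0,
                                config$species_offset_sd),
                   nrow = p, dimnames = list(cpg_ids, species_names))
  list(cpg_ids = cpg_ids, baseline = baseline, slope = slope,
       tissue_offsets = offsets, species_offsets = sp_off,
       age_related = slope != 0)
}

#' Noise-free expected beta value of a CpG archetype
#'
#' `plogis(baseline + slope * rel_age + tissue_offset + species_offset)` --
#' the mean of the generative law before measurement noise and batch
#' effects.
#'
#' @param archetypes Result of [sample_archetypes()].
#' @param i CpG index (or id).
#' @param rel_age Relative age (>= 0).
#' @param tissue Tissue name (must be one of the archetype tissues).
#' @param species Species name; may be omitted for single-species
#'   archetypes.
#' @return Expected beta in (0, 1).
#' @export
expected_beta <- function(archetypes, i, rel_age, tissue, species = NULL) {
  if (is.character(i)) i <- match(i, archetypes$cpg_ids)
  if (any(rel_age < 0)) stop("rel_age must be >= 0")
  if (!tissue %in% colnames(archetypes$tissue_offsets))
    stop("unknown tissue: ", tissue)
  sp_cols <- colnames(archetypes$species_offsets)
  if (is.null(species)) {
    if (length(sp_cols) > 1)
      stop("species must be given for multi-species archetypes")
    species <- sp_cols[1]
  }
  if (!species %in% sp_cols) stop("unknown species: ", species)
  stats::plogis(archetypes$baseline[i] + archetypes$slope[i] * rel_age +
                  archetypes$tissue_offsets[i, tissue] +
                  archetypes$species_offsets[i, species])
}

#' Simulate a methylome dataset with known truth
#'
#' Generates samples for every (species, group, tissue) cell of the config,
#' assigns ages uniformly within the group's range, maps treated samples to a
#' rejuvenated effective relative age `(1 - rho) * age / lifespan` (their
#' annotated chronological age stays at the old value), distributes samples
#' over chips, and draws beta values from the logit-normal generative model.
#' Bitwise reproducible for identical configs.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [methylome_dataset()]) and `truth` (the
#'   archetypes, per-sample effective relative age, rho, chip offsets).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  arch <- sample_archetypes(config)

  rows <- list()
  for (sp in config$species_specs) {
    for (g in seq_len(nrow(sp$groups))) {
      grp <- sp$groups[g, ]
      for (tis in config$tissues) {
        rows[[length(rows) + 1]] <- data.frame(
          species = sp$name, tissue = tis, group = grp$group,
          age_min = grp$age_min, age_max = grp$age_max,
          max_lifespan = sp$max_lifespan, n = grp$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  plan <- do.call(rbind, rows)
  plan <- plan[rep(seq_len(nrow(plan)), plan$n), ]
  n <- nrow(plan)
  age <- stats::runif(n, plan$age_min, plan$age_max)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  chip <- sprintf("chip%02d", sample.int(config$n_chips, n, replace = TRUE))
  column <- sprintf("C%d", sample.int(6, n, replace = TRUE))
  rel_age <- age / plan$max_lifespan
  eff_rel_age <- ifelse(plan$group == "old_treated",
                        (1 - config$rejuvenation_rho) * rel_age, rel_age)

  annot <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    species = plan$species, tissue = plan$tissue, age = age, sex = sex,
    group = plan$group, batch_chip = chip, batch_column = column,
    stringsAsFactors = FALSE)

  chip_levels <- sprintf("chip%02d", seq_len(config$n_chips))
  chip_offset <- stats::setNames(
    stats::rnorm(config$n_chips, 0, config$batch_effect_sd), chip_levels)

  # logit-scale mean: baseline + slope*eff_rel + tissue offset +
  # species offset + chip offset
  tis_idx <- match(plan$tissue, colnames(arch$tissue_offsets))
  sp_idx <- match(plan$species, colnames(arch$species_offsets))
  mu <- outer(arch$baseline, rep(1, n)) +
    outer(arch$slope, eff_rel_age) +
    arch$tissue_offsets[, tis_idx, drop = FALSE] +
    arch$species_offsets[, sp_idx, drop = FALSE] +
    matrix(chip_offset[chip], nrow = config$n_cpgs, ncol = n, byrow = TRUE)
  if (config$noise_sd > 0)
    mu <- mu + matrix(stats::rnorm(config$n_cpgs * n, 0, config$noise_sd),
                      nrow = config$n_cpgs)
  beta <- stats::plogis(mu)
  dimnames(beta) <- list(arch$cpg_ids, annot$sample_id)

  truth <- list(archetypes = arch,
                eff_rel_age = stats::setNames(eff_rel_age, annot$sample_id),
                rel_age = stats::setNames(rel_age, annot$sample_id),
                rejuvenation_rho = config$rejuvenation_rho,
                chip_offset = chip_offset, seed = config$seed)
  list(dataset = methylome_dataset(beta, annot), truth = truth)
}

#' Write simulation truth to JSON
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(
    rejuvenation_rho = truth$rejuvenation_rho,
    seed = truth$seed,
    chip_offset = as.list(truth$chip_offset),
    eff_rel_age = as.list(truth$eff_rel_age),
    archetypes = data.frame(cpg_id = truth$archetypes$cpg_ids,
                            baseline = truth$archetypes$baseline,
                            slope = truth$archetypes$slope,
                            age_related = truth$archetypes$age_related))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
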