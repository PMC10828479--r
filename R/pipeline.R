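# Pipeline driver: simulate -> train -> cross-validate -> predict ->
# rejuvenation table -> EWAS, as one reproducible run with derived stage
# seeds and a checksummed manifest.

# Stable stage seed: polynomial hash of (master seed, stage name) in
# [1, 2^31 - 2]. Purely arithmetic, so stage re-runs are reproducible in
# isolation and across platforms.
stage_seed <- function(master_seed, stage) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h + 1)
}

#' Pipeline run configuration
#'
#' @param sim A [sim_config()] (its seed is re-derived from the master
#'   seed), or a list with `beta` and `annot` paths to load real-format
#'   inputs instead.
#' @param clock_specs List of [clock_spec()] entries.
#' @param cv A [cv_scheme()] for the evaluation stage.
#' @param ewas List of EWAS settings: `ruv_k`, `q`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage seed is derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim, clock_specs, cv = cv_scheme("kfold", k = 10,
                                                        stratify_by = "species"),
                       ewas = list(ruv_k = 2, q = 0.05),
                       out_dir = "dnamclock_run", seed = 1L) {
  stopifnot(is.list(clock_specs),
            all(vapply(clock_specs, inherits, TRUE, "clock_spec")))
  nm <- vapply(clock_specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("clock spec names must be unique")
  structure(list(sim = sim, clock_specs = clock_specs, cv = cv, ewas = ewas,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Demonstration run configuration
#'
#' A desk-scale version of the full study design: 4,000 CpGs; four test
#' tissues (blood, liver, heart, hypothalamus); a rat cohort with a training
#' spread plus the three treatment arms (n = 6 each per tissue) and a human
#' cohort; and the six clocks -- pan-tissue, brain, blood, liver, plus the
#' dual-species absolute and relative clocks.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A [run_config()].
#' @export
demo_run_config <- function(out_dir = "dnamclock_demo", seed = 1L) {
  tissues <- c("blood", "liver", "heart", "hypothalamus")
  sim <- sim_config(
    n_cpgs = 4000,
    species_specs = list(
      species_spec("rat", 3.8, data.frame(
        group = c("none", "young_control", "old_control", "old_treated"),
        n = c(15, 6, 6, 6),
        age_min = c(0.0384, 0.577, 2.096, 2.096),
        age_max = c(2.3, 0.577, 2.096, 2.096))),
      species_spec("human", 122.5, data.frame(
        group = "none", n = 9, age_min = 0, age_max = 93))),
    tissues = tissues)
  specs <- list(
    clock_spec("pan_tissue", "absolute", "all", "rat", n_lambda = 50),
    clock_spec("brain", "absolute", "hypothalamus", "rat", n_lambda = 50),
    clock_spec("blood", "absolute", "blood", "rat", n_lambda = 50),
    clock_spec("liver", "absolute", "liver", "rat", n_lambda = 50),
    clock_spec("dual_absolute", "absolute", "all", c("rat", "human"),
               n_lambda = 50),
    clock_spec("dual_relative", "relative", "all", c("rat", "human"),
               n_lambda = 50))
  run_config(sim, specs, cv = cv_scheme("kfold", k = 5,
                                        stratify_by = "species"),
             out_dir = out_dir, seed = seed)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate (or load), train, cross-validate, predict, rejuvenation
#' table and EWAS in order, writes every intermediate artifact in the
#' package's documented formats, and ends with a manifest (config echo,
#' stage seeds, per-artifact MD5 checksums). Two runs with identical configs
#' produce identical manifests. Any stage error aborts with the stage name;
#' artifacts written so far are preserved.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly; artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  artifacts <- character(0)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- list()

  # -- simulate / load ------------------------------------------------------
  truth <- NULL
  ds <- stage("simulate", {
    if (inherits(config$sim, "sim_config")) {
      seeds$simulate <- stage_seed(config$seed, "simulate")
      sim <- config$sim
      sim$seed <- seeds$simulate
      say("simulate: ", sim$n_cpgs, " CpGs")
      r <- simulate_dataset(sim)
      truth <- r$truth
      save_dataset(r$dataset, out("beta.csv"), out("annot.csv"))
      write_truth_json(r$truth, out("truth.json"))
      artifacts <- c(artifacts, "beta.csv", "annot.csv", "truth.json")
      r$dataset
    } else {
      say("load: ", config$sim$beta)
      load_dataset(config$sim$beta, config$sim$annot)
    }
  })
  artifacts <- union(artifacts, intersect(c("beta.csv", "annot.csv",
                                            "truth.json"),
                                          list.files(config$out_dir)))

  # validate clock scopes before any training
  stage("train", {
    for (spec in config$clock_specs) {
      if (!identical(spec$tissue_scope, "all")) {
        missing_t <- setdiff(spec$tissue_scope, unique(ds$annot$tissue))
        if (length(missing_t))
          stop("clock spec '", spec$name, "' names unknown tissue(s): ",
               paste(missing_t, collapse = ", "))
      }
    }
  })

  is_train <- ds$annot$group == "none"
  train_ds <- if (any(is_train)) subset_samples(ds, which(is_train)) else ds
  test_ds <- if (any(!is_train)) subset_samples(ds, which(!is_train)) else NULL

  # -- train ----------------------------------------------------------------
  clocks <- stage("train", {
    lapply(config$clock_specs, function(spec) {
      spec$seed <- stage_seed(config$seed, paste0("train_", spec$name))
      seeds[[paste0("train_", spec$name)]] <<- spec$seed
      say("train: ", spec$name)
      clock <- train_clock(train_ds, spec)
      write_clock_csv(clock, out(paste0("clock_", spec$name, ".csv")))
      clock
    })
  })
  artifacts <- c(artifacts, paste0("clock_",
                                   vapply(config$clock_specs, `[[`, "", "name"),
                                   ".csv"))

  # -- cross-validate -------------------------------------------------------
  eval_report <- stage("evaluate", {
    reports <- lapply(config$clock_specs, function(spec) {
      spec$seed <- stage_seed(config$seed, paste0("eval_", spec$name))
      scheme <- config$cv
      scheme$seed <- stage_seed(config$seed, paste0("evalfold_", spec$name))
      say("evaluate: ", spec$name)
      pred <- crossval_predict(train_ds, spec, scheme)
      rep <- evaluate_predictions(pred)
      list(clock = spec$name, scheme = scheme$kind,
           overall = rep$overall, by_tissue = rep$by_tissue,
           by_species = rep$by_species)
    })
    write_json_file(reports, out("eval_report.json"))
    artifacts <- c(artifacts, "eval_report.json")
    reports
  })
  artifacts <- union(artifacts, "eval_report.json")

  # -- predict --------------------------------------------------------------
  predictions <- stage("predict", if (is.null(test_ds)) NULL else {
    preds <- lapply(clocks, function(clock) {
      keep <- test_ds$annot$species %in% clock$species_scope
      if (!identical(clock$tissue_scope, "all"))
        keep <- keep & test_ds$annot$tissue %in% clock$tissue_scope
      if (!any(keep)) return(NULL)
      sub <- subset_samples(test_ds, which(keep))
      p <- predict_ages(clock, sub)
      if (is.null(p$dnam_relative_age)) p$dnam_relative_age <- NA_real_
      data.frame(clock = clock$name, sample_id = p$sample_id,
                 dnam_age_years = p$dnam_age_years,
                 dnam_relative_age = p$dnam_relative_age,
                 age_acceleration = p$age_acceleration,
                 tissue = sub$annot$tissue, species = sub$annot$species,
                 group = sub$annot$group, age = sub$annot$age,
                 stringsAsFactors = FALSE)
    })
    preds <- do.call(rbind, preds[!vapply(preds, is.null, TRUE)])
    utils::write.csv(preds, out("predictions.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "predictions.csv")
    preds
  })
  artifacts <- union(artifacts, intersect("predictions.csv",
                                          list.files(config$out_dir)))

  # -- rejuvenation ---------------------------------------------------------
  has_arms <- !is.null(predictions) &&
    all(c("old_control", "old_treated") %in% predictions$group)
  rejuv <- stage("rejuvenate", if (!has_arms) NULL else {
    tab <- rejuvenation_table(predictions)
    utils::write.csv(tab$cells, out("rejuvenation.csv"), row.names = FALSE)
    stats_by_cell <- lapply(split(predictions,
                                  predictions[c("tissue", "clock")],
                                  drop = TRUE), function(d) {
      gc <- group_comparison(d$dnam_age_years, d$group)
      list(tissue = d$tissue[1], clock = d$clock[1],
           anova_F = gc$anova$F, anova_p = gc$anova$p,
           ttest_t = gc$ttest$t, ttest_p = gc$ttest$p,
           kw_H = gc$kruskal_wallis$H, kw_p = gc$kruskal_wallis$p)
    })
    write_json_file(list(per_tissue = tab$per_tissue,
                         grand_average = tab$grand_average,
                         stats = unname(stats_by_cell)),
                    out("rejuvenation_stats.json"))
    tab
  })
  artifacts <- union(artifacts, intersect(c("rejuvenation.csv",
                                            "rejuvenation_stats.json"),
                                          list.files(config$out_dir)))

  # -- ewas -----------------------------------------------------------------
  ewas_res <- stage("ewas", if (is.null(test_ds)) NULL else {
    say("ewas: ", nrow(test_ds$beta), " CpGs")
    res <- run_ewas(test_ds, ruv_k = config$ewas$ruv_k %||% 2,
                    q = config$ewas$q %||% 0.05)
    utils::write.csv(res, out("ewas.csv"), row.names = FALSE)
    rev <- reversal_summary(res[res$contrast == "Age", ],
                            res[res$contrast == "Treatment", ],
                            q_threshold = config$ewas$q %||% 0.05)
    write_json_file(rev, out("ewas_reversal.json"))
    res
  })
  artifacts <- union(artifacts, intersect(c("ewas.csv", "ewas_reversal.json"),
                                          list.files(config$out_dir)))

  # -- manifest -------------------------------------------------------------
  manifest <- stage("manifest", {
    files <- sort(intersect(artifacts, list.files(config$out_dir)))
    sums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
    names(sums) <- files
    man <- list(config = echo_config(config),
                stage_seeds = seeds,
                checksums = sums)
    write_json_file(man, out("manifest.json"))
    man
  })
  say("done: ", config$out_dir)
  invisible(manifest)
}

# Plain-list echo of a run_config for the manifest (classes stripped so the
# JSON is stable).
echo_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(config))
}
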