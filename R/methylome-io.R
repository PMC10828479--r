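#' @useDynLib dnamclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor lm median pchisq pf plogis pt qlogis rnorm runif
#'   sd t.test kruskal.test anova p.adjust var setNames qnorm
#' @importFrom utils read.csv write.csv head
NULL

SAMPLE_GROUPS <- c("young_control", "old_control", "old_treated", "none")
SAMPLE_SEXES <- c("F", "M", "unknown")
ANNOT_COLUMNS <- c("sample_id", "species", "tissue", "age", "sex", "group",
                   "batch_chip", "batch_column")

#' Default species maximum-lifespan table
#'
#' Maximum lifespans (in years) used to convert chronological age to relative
#' age (age / maximum lifespan). The defaults are 3.8 years for the rat and
#' 122.5 years for the human.
#'
#' @param ... Named lifespans (years) that add to or override the defaults,
#'   e.g. `species_lifespans(mouse = 4)`.
#' @return Named numeric vector mapping species name to maximum lifespan.
#' @export
#' @examples
#' species_lifespans()
species_lifespans <- function(...) {
  tab <- c(rat = 3.8, human = 122.5)
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("lifespans must be named by species")
    tab[names(extra)] <- as.numeric(extra)
  }
  if (any(tab <= 0)) stop("all maximum lifespans must be > 0")
  tab
}

#' Construct a methylome dataset
#'
#' Bundles a CpG-by-sample beta-value matrix with per-sample annotations.
#' Beta values are methylation fractions in \[0, 1\]; `NA` marks missing
#' measurements.
#'
#' @param beta Numeric matrix, CpGs in rows, samples in columns. Row names are
#'   CpG identifiers, column names sample ids.
#' @param annot Data frame with one row per sample and columns `sample_id`,
#'   `species`, `tissue`, `age` (years), `sex` (`F`/`M`/`unknown`), `group`
#'   (`young_control`/`old_control`/`old_treated`/`none`), `batch_chip`,
#'   `batch_column`. Row order must follow `colnames(beta)`.
#' @param validate Check invariants and stop on violations (default `TRUE`).
#' @return An object of class `methylome_dataset` with elements `beta` and
#'   `annot`.
#' @export
methylome_dataset <- function(beta, annot, validate = TRUE) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  annot <- as.data.frame(annot, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ANNOT_COLUMNS, names(annot))
  if (length(missing_cols))
    stop("annotation lacks required columns: ", paste(missing_cols, collapse = ", "))
  annot <- annot[, ANNOT_COLUMNS]
  annot$sample_id <- as.character(annot$sample_id)
  annot$species <- as.character(annot$species)
  annot$tissue <- as.character(annot$tissue)
  annot$age <- as.numeric(annot$age)
  annot$sex <- as.character(annot$sex)
  annot$group <- as.character(annot$group)
  annot$batch_chip <- as.character(annot$batch_chip)
  annot$batch_column <- as.character(annot$batch_column)
  rownames(annot) <- NULL
  ds <- structure(list(beta = beta, annot = annot), class = "methylome_dataset")
  if (validate) {
    findings <- validate_dataset(ds)
    if (length(findings))
      stop("invalid methylome dataset:\n  ", paste(findings, collapse = "\n  "))
  }
  ds
}

#' @export
print.methylome_dataset <- function(x, ...) {
  cat(sprintf("methylome_dataset: %d CpGs x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  species: %s\n", paste(unique(x$annot$species), collapse = ", ")))
  cat(sprintf("  tissues: %s\n", paste(unique(x$annot$tissue), collapse = ", ")))
  cat(sprintf("  groups:  %s\n",
              paste(sprintf("%s(%d)", names(table(x$annot$group)),
                            table(x$annot$group)), collapse = ", ")))
  cat(sprintf("  age range: %.3f-%.3f years\n",
              min(x$annot$age), max(x$annot$age)))
  invisible(x)
}

#' @export
dim.methylome_dataset <- function(x) dim(x$beta)

#' Validate a methylome dataset
#'
#' Checks every structural invariant of the data model and returns one
#' human-readable finding per violation (an empty character vector means the
#' dataset is valid). Findings, not errors, so callers can report them all.
#'
#' @param ds A `methylome_dataset`.
#' @return Character vector of findings; `character(0)` if valid.
#' @export
validate_dataset <- function(ds) {
  findings <- character(0)
  beta <- ds$beta
  annot <- ds$annot
  cpg_ids <- rownames(beta)
  sample_ids <- colnames(beta)
  if (is.null(cpg_ids)) findings <- c(findings, "beta matrix has no CpG row names")
  if (is.null(sample_ids)) findings <- c(findings, "beta matrix has no sample column names")
  if (!is.null(cpg_ids) && anyDuplicated(cpg_ids))
    findings <- c(findings, sprintf("duplicate CpG ids: %s",
      paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", ")))
  if (anyDuplicated(annot$sample_id))
    findings <- c(findings, sprintf("duplicate sample ids: %s",
      paste(unique(annot$sample_id[duplicated(annot$sample_id)]), collapse = ", ")))
  if (nrow(annot) != ncol(beta)) {
    findings <- c(findings, sprintf(
      "annotation has %d rows but beta has %d sample columns", nrow(annot), ncol(beta)))
  } else if (!is.null(sample_ids) && !identical(annot$sample_id, sample_ids)) {
    findings <- c(findings, "annotation sample order does not match beta columns")
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    shown <- utils::head(bad, 5)
    findings <- c(findings, sprintf(
      "beta outside [0,1] at %s%s",
      paste(sprintf("(%s, %s)=%g", rownames(beta)[shown[, 1]],
                    colnames(beta)[shown[, 2]],
                    beta[shown]), collapse = "; "),
      if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else ""))
  }
  all_na <- which(rowSums(!is.na(beta)) == 0)
  for (i in all_na)
    findings <- c(findings, sprintf("CpG %s has no observed beta values", rownames(beta)[i]))
  bad_age <- which(is.na(annot$age) | annot$age < 0)
  for (i in bad_age)
    findings <- c(findings, sprintf("sample %s has invalid age %s",
                                    annot$sample_id[i], annot$age[i]))
  empty_sp <- which(is.na(annot$species) | annot$species == "")
  for (i in empty_sp)
    findings <- c(findings, sprintf("sample %s has empty species", annot$sample_id[i]))
  bad_sex <- which(!annot$sex %in% SAMPLE_SEXES)
  for (i in bad_sex)
    findings <- c(findings, sprintf("sample %s has unknown sex code '%s'",
                                    annot$sample_id[i], annot$sex[i]))
  bad_grp <- which(!annot$group %in% SAMPLE_GROUPS)
  for (i in bad_grp)
    findings <- c(findings, sprintf("sample %s has unknown group '%s'",
                                    annot$sample_id[i], annot$group[i]))
  findings
}

#' Load a methylome dataset from CSV files
#'
#' The beta matrix CSV has a first column `cpg_id` and one column per sample;
#' the annotation CSV has one row per sample. Sample order follows the beta
#' matrix columns. Empty cells and `NA` tokens are read as missing.
#'
#' @param beta_path Path to the beta matrix CSV.
#' @param annot_path Path to the sample annotation CSV.
#' @return A validated [methylome_dataset()].
#' @export
load_dataset <- function(beta_path, annot_path) {
  if (!file.exists(beta_path)) stop("beta file not found: ", beta_path)
  if (!file.exists(annot_path)) stop("annotation file not found: ", annot_path)
  raw <- utils::read.csv(beta_path, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"cpg_id" %in% names(raw)[1])
    stop("beta CSV must have 'cpg_id' as its first column")
  beta <- as.matrix(raw[, -1, drop = FALSE])
  rownames(beta) <- raw$cpg_id
  storage.mode(beta) <- "double"
  annot <- utils::read.csv(annot_path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  missing_in_annot <- setdiff(colnames(beta), annot$sample_id)
  missing_in_beta <- setdiff(annot$sample_id, colnames(beta))
  if (length(missing_in_annot) || length(missing_in_beta))
    stop("sample sets differ between beta and annotation",
         if (length(missing_in_annot))
           paste0("; missing from annotation: ",
                  paste(missing_in_annot, collapse = ", ")) else "",
         if (length(missing_in_beta))
           paste0("; missing from beta: ",
                  paste(missing_in_beta, collapse = ", ")) else "")
  annot <- annot[match(colnames(beta), annot$sample_id), , drop = FALSE]
  methylome_dataset(beta, annot)
}

#' Save a methylome dataset to CSV files
#'
#' Inverse of [load_dataset()]: a save/load round trip reproduces the dataset
#' values exactly (missing values written as `NA`). Full precision is kept
#' (17 significant digits).
#'
#' @param ds A valid `methylome_dataset` with at least one sample.
#' @param beta_path,annot_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
save_dataset <- function(ds, beta_path, annot_path) {
  stopifnot(inherits(ds, "methylome_dataset"))
  if (ncol(ds$beta) == 0) stop("refusing to write a dataset with 0 samples")
  findings <- validate_dataset(ds)
  if (length(findings))
    stop("refusing to write invalid dataset:\n  ", paste(findings, collapse = "\n  "))
  fmt <- formatC(ds$beta, digits = 17, format = "g")
  fmt[is.na(ds$beta)] <- NA
  df <- data.frame(cpg_id = rownames(ds$beta), fmt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, beta_path, row.names = FALSE, na = "NA", quote = FALSE)
  utils::write.csv(ds$annot, annot_path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(c(beta = beta_path, annot = annot_path))
}

#' Construct a clock model object
#'
#' A trained epigenetic clock: an intercept plus sparse per-CpG weights,
#' applied as `intercept + sum(w_i * beta_i)`. Absolute clocks report years;
#' relative clocks report age / maximum lifespan and need a lifespan entry for
#' every species in scope to back-transform to years.
#'
#' @param name Clock name.
#' @param clock_type `"absolute"` or `"relative"`.
#' @param weights Named numeric vector of per-CpG coefficients (per unit
#'   beta); entries that are exactly zero are dropped.
#' @param intercept Intercept (years for absolute clocks, relative-age units
#'   for relative clocks).
#' @param tissue_scope Character vector of tissues, or `"all"`.
#' @param species_scope Character vector of species the clock applies to.
#' @param lifespans Named lifespan vector (see [species_lifespans()]).
#' @param cpg_means Named vector of training-set mean beta per clock CpG, used
#'   to impute CpGs absent at prediction time.
#' @param training_meta List of training metadata (alpha, lambda, n_train,
#'   seed, ...).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, clock_type = c("absolute", "relative"),
                        weights, intercept,
                        tissue_scope = "all", species_scope = "rat",
                        lifespans = species_lifespans(),
                        cpg_means = NULL, training_meta = list()) {
  clock_type <- match.arg(clock_type)
  weights <- weights[weights != 0]
  if (length(weights) && (is.null(names(weights)) || any(names(weights) == "")))
    stop("weights must be named by CpG id")
  if (clock_type == "relative") {
    missing_ls <- setdiff(species_scope, names(lifespans))
    if (length(missing_ls))
      stop("relative clock lacks lifespans for: ", paste(missing_ls, collapse = ", "))
  }
  structure(list(name = name, clock_type = clock_type,
                 intercept = as.numeric(intercept),
                 weights = weights,
                 tissue_scope = tissue_scope,
                 species_scope = species_scope,
                 lifespans = lifespans[names(lifespans) %in% species_scope |
                                         length(species_scope) == 0],
                 cpg_means = cpg_means,
                 training_meta = training_meta),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model '%s' (%s age)\n", x$name, x$clock_type))
  cat(sprintf("  %d CpG weights, intercept %.4g\n", length(x$weights), x$intercept))
  cat(sprintf("  tissues: %s | species: %s\n",
              paste(x$tissue_scope, collapse = ","),
              paste(x$species_scope, collapse = ",")))
  invisible(x)
}

#' Write a clock model to CSV
#'
#' Two-column CSV (`term`, `coefficient`) with an `(Intercept)` row first and
#' one row per non-zero CpG weight. Metadata (clock type, scopes, lifespans,
#' training means, alpha/lambda) is carried in `#`-prefixed header lines so a
#' relative clock file is self-describing.
#'
#' @param clock A `clock_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clock_csv <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  meta <- list(name = clock$name, clock_type = clock$clock_type,
               tissue_scope = clock$tissue_scope,
               species_scope = clock$species_scope,
               lifespans = as.list(clock$lifespans),
               cpg_means = as.list(clock$cpg_means),
               training_meta = clock$training_meta)
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  w <- clock$weights[clock$weights != 0]
  body <- data.frame(term = c("(Intercept)", names(w)),
                     coefficient = c(clock$intercept, unname(w)),
                     stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("term,coefficient", con)
  writeLines(sprintf("%s,%s", body$term,
                     format(body$coefficient, digits = 17, trim = TRUE,
                            scientific = TRUE)), con)
  invisible(path)
}

#' Read a clock model from CSV
#'
#' Inverse of [write_clock_csv()]; a write/read round trip is an identity on
#' the intercept and all weights.
#'
#' @param path Path to a clock CSV.
#' @return A `clock_model`.
#' @export
read_clock_csv <- function(path) {
  if (!file.exists(path)) stop("clock file not found: ", path)
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  if (length(meta_lines))
    meta <- jsonlite::fromJSON(sub("^#\\s*", "", meta_lines[1]))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  if (!all(c("term", "coefficient") %in% names(tab)))
    stop("clock CSV must have columns term, coefficient")
  is_int <- tab$term == "(Intercept)"
  if (sum(is_int) != 1) stop("clock CSV must contain exactly one (Intercept) row")
  cpgs <- tab$term[!is_int]
  if (anyDuplicated(cpgs))
    stop("duplicate CpG rows in clock CSV: ",
         paste(unique(cpgs[duplicated(cpgs)]), collapse = ", "))
  weights <- stats::setNames(tab$coefficient[!is_int], cpgs)
  clock_model(name = meta$name %||% tools::file_path_sans_ext(basename(path)),
              clock_type = meta$clock_type %||% "absolute",
              weights = weights,
              intercept = tab$coefficient[is_int],
              tissue_scope = meta$tissue_scope %||% "all",
              species_scope = meta$species_scope %||% "rat",
              lifespans = if (!is.null(meta$lifespans))
                unlist(meta$lifespans) else species_lifespans(),
              cpg_means = if (!is.null(meta$cpg_means) && length(meta$cpg_means))
                unlist(meta$cpg_means) else NULL,
              training_meta = meta$training_meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset a dataset to given samples (logical/integer index or sample ids).
subset_samples <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, ds$annot$sample_id)
  methylome_dataset(ds$beta[, idx, drop = FALSE],
                    ds$annot[idx, , drop = FALSE], validate = FALSE)
}
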