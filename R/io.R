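# CSV readers/writers with validation, and the structured run configuration.

SEED_TABLE_COLS <- c("seed_id", "plant_id", "population_id",
                     "maternal_ploidy_x", "embryo_peak_mean", "embryo_cv",
                     "endosperm_peak_mean", "endosperm_cv",
                     "standard_peak_mean", "standard_label")

#' Read a per-seed measurement table
#'
#' Reads and validates the seed-table CSV (one row per seed: peak means and
#' CVs for embryo, endosperm and internal standard, plus maternal context).
#' Rows with missing endosperm fields are flagged in a logical
#' `endosperm_missing` column, never dropped; rows missing the embryo or
#' standard peak are likewise kept (they become `FAILED` downstream).
#'
#' @param path CSV file with a header row; `#` lines are comments.
#' @param ploidy_range Admissible maternal ploidies (default 4--8).
#' @return A validated tibble.
#' @export
read_seed_table <- function(path, ploidy_range = 4:8) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          seed_id = "c", plant_id = "c", population_id = "c",
                          standard_label = "c", .default = "d"))
  validate_seed_table(tb, ploidy_range)
}

#' Validate an in-memory seed table
#'
#' @inheritParams read_seed_table
#' @param tb Data frame shaped like the seed-table CSV.
#' @return The validated tibble with an `endosperm_missing` flag column.
#' @export
validate_seed_table <- function(tb, ploidy_range = 4:8) {
  missing_cols <- setdiff(SEED_TABLE_COLS, names(tb))
  if (length(missing_cols) > 0)
    abort(paste0("seed table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tb$seed_id))
    abort(paste0("duplicate seed_id: ",
                 paste(unique(tb$seed_id[duplicated(tb$seed_id)]), collapse = ", ")))
  bad_ploidy <- !tb$maternal_ploidy_x %in% ploidy_range
  if (any(bad_ploidy))
    abort(paste0("maternal_ploidy_x outside ", min(ploidy_range), "..",
                 max(ploidy_range), " for seed(s): ",
                 paste(tb$seed_id[bad_ploidy], collapse = ", ")))
  for (col in c("embryo_peak_mean", "endosperm_peak_mean", "standard_peak_mean")) {
    bad <- !is.na(tb[[col]]) & tb[[col]] <= 0
    if (any(bad))
      abort(paste0("non-positive ", col, " for seed(s): ",
                   paste(tb$seed_id[bad], collapse = ", ")))
  }
  tb <- tibble::as_tibble(tb)
  tb$endosperm_missing <- is.na(tb$endosperm_peak_mean)
  tb
}

#' Write per-seed calls with a provenance header
#'
#' Writes one CSV row per seed call, preceded by a `#` comment block that
#' records the package version, the configuration hash and the RNG seed, so
#' every results file is traceable to its run. Re-reading with
#' [read_results()] reproduces the call fields exactly.
#'
#' @param calls Non-empty tibble of seed calls.
#' @param path Output path.
#' @param config Optional run configuration (hashed into the header).
#' @param rng_seed RNG seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(calls, path, config = NULL, rng_seed = NA_integer_) {
  if (is.null(calls) || nrow(calls) == 0)
    abort("no calls to write (empty input)")
  col_code <- vapply(calls, function(x)
    switch(class(x)[[1]], character = "c", integer = "i", logical = "l",
           factor = "c", "d"), character(1))
  header <- c(
    "# fcss results",
    paste0("# package_version: ", as.character(utils::packageVersion("fcss"))),
    paste0("# config_hash: ",
           if (is.null(config)) "none" else rlang::hash(config)),
    paste0("# rng_seed: ", rng_seed),
    paste0("# col_classes: ", paste(col_code, collapse = "")))
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    abort(paste0("cannot open for writing: ", path)))
  writeLines(header, con)
  close(con)
  # quote empty strings are not distinguishable from NA in CSV; write NA
  # explicitly so character fields round-trip exactly
  readr::write_csv(calls, path, append = TRUE, col_names = TRUE, na = "NA",
                   quote = "all")
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path Path to the results CSV.
#' @return Tibble of calls (header comments skipped).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  head <- readLines(path, n = 10)
  types <- sub("^# col_classes: ", "", grep("^# col_classes: ", head,
                                            value = TRUE))
  readr::read_csv(path, comment = "#", show_col_types = FALSE, na = "NA",
                  col_types = if (length(types) == 1) types[[1]] else NULL)
}

#' Read a binned fluorescence histogram CSV
#'
#' @param path CSV with columns `channel`, `count` (optionally `seed_id`
#'   for a multi-seed file).
#' @return Tibble with strictly increasing channels per seed.
#' @export
read_histogram_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  h <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("channel", "count") %in% names(h)))
    abort("histogram CSV needs columns channel, count")
  h
}

#' Read a pollen-count CSV
#'
#' @param path CSV with columns `plant_id`, `population_id`, `ploidy_x`,
#'   `n_viable`, `n_scored`.
#' @return Validated tibble.
#' @export
read_pollen_table <- function(path) {
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("plant_id", "population_id", "ploidy_x", "n_viable", "n_scored")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0)
    abort(paste0("pollen CSV missing column(s): ", paste(miss, collapse = ", ")))
  if (any(tb$n_viable < 0 | tb$n_viable > tb$n_scored))
    abort("n_viable must lie in [0, n_scored]")
  tb
}

#' Read a pollination-outcome CSV
#'
#' @param path CSV with columns `plant_id`, `flower_id`, `treatment`
#'   (`self`/`outcross`), `n_viable_seeds`, `n_ovules`.
#' @return Validated tibble with upper-case treatments.
#' @export
read_pollination_table <- function(path) {
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("plant_id", "flower_id", "treatment", "n_viable_seeds", "n_ovules")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0)
    abort(paste0("pollination CSV missing column(s): ",
                 paste(miss, collapse = ", ")))
  tb$treatment <- toupper(tb$treatment)
  if (!all(tb$treatment %in% c("SELF", "OUTCROSS")))
    abort("treatment must be self or outcross")
  if (any(tb$n_viable_seeds < 0 | tb$n_viable_seeds > tb$n_ovules))
    abort("n_viable_seeds must lie in [0, n_ovules]")
  tb
}

#' Run configuration for the analysis pipeline
#'
#' Collects every tunable of the analysis stages: classification thresholds,
#' the ploidy-call tolerance, the calibration, Monte Carlo settings, the
#' Shannon log base, the pollen/ovule classification table and the
#' Bonferroni family policy. Serializable to YAML so that every results
#' artifact can embed a hash of the exact configuration.
#'
#' @param calibration An [calibration()] object.
#' @param thresholds [classification_thresholds()].
#' @param ploidy_tolerance Relative tolerance of [call_ploidy()].
#' @param mc_reps Monte Carlo replicate count (default 10000).
#' @param rng_seed RNG seed for the association test.
#' @param shannon_base Log base of the Shannon index.
#' @param cruden [cruden_table()]-shaped boundary table.
#' @param bonferroni_family `"all_pairs"` (default) or a fixed integer.
#' @param single_sperm_sexual See [genomic_contributions()].
#' @param out_dir Output directory for CLI runs.
#' @return A list of class `fcss_run_config`.
#' @export
run_config <- function(calibration = default_calibration(),
                       thresholds = classification_thresholds(),
                       ploidy_tolerance = 0.05,
                       mc_reps = 10000L,
                       rng_seed = 1L,
                       shannon_base = exp(1),
                       cruden = cruden_table(),
                       bonferroni_family = "all_pairs",
                       single_sperm_sexual = FALSE,
                       out_dir = ".") {
  stopifnot(inherits(calibration, "fcss_calibration"),
            inherits(thresholds, "fcss_thresholds"),
            ploidy_tolerance > 0, mc_reps >= 1)
  structure(list(calibration = calibration, thresholds = thresholds,
                 ploidy_tolerance = ploidy_tolerance,
                 mc_reps = as.integer(mc_reps),
                 rng_seed = as.integer(rng_seed),
                 shannon_base = shannon_base, cruden = cruden,
                 bonferroni_family = bonferroni_family,
                 single_sperm_sexual = single_sperm_sexual,
                 out_dir = out_dir),
            class = "fcss_run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config An [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `fcss_run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "fcss_run_config"))
  x <- list(
    calibration = list(ploidy_x = config$calibration$ploidy_x,
                       ratio = config$calibration$ratio,
                       standard_label = config$calibration$standard_label),
    thresholds = unclass(config$thresholds),
    ploidy_tolerance = config$ploidy_tolerance,
    mc_reps = config$mc_reps, rng_seed = config$rng_seed,
    shannon_base = config$shannon_base,
    cruden = list(class = config$cruden$class,
                  upper_bound = config$cruden$upper_bound),
    bonferroni_family = config$bonferroni_family,
    single_sperm_sexual = config$single_sperm_sexual,
    out_dir = config$out_dir)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    calibration = calibration(x$calibration$ploidy_x, x$calibration$ratio,
                              x$calibration$standard_label),
    thresholds = do.call(classification_thresholds, x$thresholds),
    ploidy_tolerance = x$ploidy_tolerance,
    mc_reps = x$mc_reps, rng_seed = x$rng_seed,
    shannon_base = x$shannon_base,
    cruden = tibble::tibble(class = x$cruden$class,
                            upper_bound = as.numeric(x$cruden$upper_bound)),
    bonferroni_family = x$bonferroni_family,
    single_sperm_sexual = isTRUE(x$single_sperm_sexual),
    out_dir = x$out_dir)
}
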