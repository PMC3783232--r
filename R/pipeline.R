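# The per-seed calling stage and the end-to-end pipeline driver.

#' Call seeds from a measurement table
#'
#' The cytometry + inference stage: converts embryo/endosperm peak means to
#' sample/standard ratios, calls DNA ploidies against the calibration,
#' computes the peak index, classifies each seed's developmental pathway
#' and decomposes the ploidies into female and male genomic contributions
#' with the maternal:paternal endosperm dosage ratio.
#'
#' @param seed_table Validated seed table (see [read_seed_table()] /
#'   [validate_seed_table()], or the simulator's `seed_table`).
#' @param config An [run_config()] carrying calibration and thresholds.
#' @return A seed-call tibble: identifiers and maternal context plus
#'   `embryo_x`, `embryo_called_x`, `endosperm_x`, `peak_index`, `pathway`,
#'   `flag`, `f_embryo_x`, `m_embryo_x`, `f_endosperm_x`, `m_endosperm_x`,
#'   `endosperm_ratio_p`, `clipped`.
#' @export
call_seeds <- function(seed_table, config = run_config()) {
  stopifnot(inherits(config, "fcss_run_config"))
  tb <- validate_seed_table(seed_table,
                            ploidy_range = unique(seed_table$maternal_ploidy_x))
  cal <- config$calibration

  ratio_of <- function(mean) ifelse(
    is.na(mean) | is.na(tb$standard_peak_mean), NA_real_,
    mean / tb$standard_peak_mean)
  emb_pl <- call_ploidy(ratio_of(tb$embryo_peak_mean), cal,
                        tolerance = config$ploidy_tolerance)
  end_pl <- call_ploidy(ratio_of(tb$endosperm_peak_mean), cal,
                        tolerance = config$ploidy_tolerance)
  pi_val <- ifelse(is.na(tb$endosperm_peak_mean) | is.na(tb$embryo_peak_mean),
                   NA_real_,
                   tb$endosperm_peak_mean / tb$embryo_peak_mean)

  cls <- classify_pathway(emb_pl$continuous_x, pi_val, tb$maternal_ploidy_x,
                          th = config$thresholds)
  calls <- tibble::tibble(
    seed_id = tb$seed_id, plant_id = tb$plant_id,
    population_id = tb$population_id,
    maternal_ploidy_x = tb$maternal_ploidy_x,
    embryo_x = emb_pl$continuous_x,
    embryo_called_x = emb_pl$called_x,
    endosperm_x = end_pl$continuous_x,
    peak_index = pi_val,
    pathway = cls$pathway, flag = cls$flag,
    f_embryo_x = NA_real_, m_embryo_x = NA_real_,
    f_endosperm_x = NA_real_, m_endosperm_x = NA_real_,
    endosperm_ratio_p = NA_real_, clipped = FALSE)

  dec <- calls$pathway %in% c("SEXUAL", "APOMICTIC", "Z_DOUBLED",
                              "L_UNREDUCED_EGG")
  if (any(dec)) {
    gc <- genomic_contributions(calls$embryo_x[dec], calls$endosperm_x[dec],
                                calls$maternal_ploidy_x[dec],
                                calls$pathway[dec],
                                single_sperm_sexual = config$single_sperm_sexual,
                                seed_id = calls$seed_id[dec],
                                on_inconsistent = "flag")
    calls$f_embryo_x[dec] <- gc$f_embryo_x
    calls$m_embryo_x[dec] <- gc$m_embryo_x
    calls$f_endosperm_x[dec] <- gc$f_endosperm_x
    calls$m_endosperm_x[dec] <- gc$m_endosperm_x
    calls$clipped[dec] <- gc$clipped
    # a seed whose pathway algebra cannot be satisfied is not trusted:
    # keep the measurement, mark it unclassified
    bad <- which(dec)[gc$inconsistent]
    if (length(bad) > 0) {
      calls$pathway[bad] <- "UNKNOWN"
      calls$flag[bad] <- paste0(
        ifelse(calls$flag[bad] == "", "", paste0(calls$flag[bad], ";")),
        "inconsistent_contributions")
    }
    ok <- dec & !is.na(calls$f_endosperm_x) & calls$f_endosperm_x > 0
    calls$endosperm_ratio_p[ok] <-
      endosperm_ratio(calls$f_endosperm_x[ok], calls$m_endosperm_x[ok])
  }
  calls
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — seed calling (cytometry + inference),
#' per-plant summaries, the Monte Carlo mode-association test, and
#' per-population summaries with the Shannon cytotype diversity — and
#' returns them as one results bundle. Deterministic given the
#' configuration (including its RNG seed). Stage failures abort with the
#' stage name; an undefined association test (all informative seeds of one
#' mode) is recorded as `NULL` with a warning rather than aborting.
#'
#' @param seed_table Seed measurement table.
#' @param config An [run_config()].
#' @param composition Optional population cytotype composition
#'   (`population_id`, `ploidy_x`, `n_individuals`) for the Shannon index;
#'   defaults to the plants present in the seed table.
#' @return A list of class `fcss_results`: `calls`, `plants`, `association`,
#'   `populations`, `log` (per-stage record counts), `n_warnings`, `config`.
#' @export
run_pipeline <- function(seed_table, config = run_config(),
                         composition = NULL) {
  stopifnot(inherits(config, "fcss_run_config"))
  warnings_seen <- character()
  note <- function(w) { warnings_seen <<- c(warnings_seen, w); warn(w) }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e))))
  }

  calls <- stage("call_seeds", call_seeds(seed_table, config))
  n_flagged <- sum(calls$flag != "")
  if (n_flagged > 0)
    note(sprintf("%d seed call(s) carry flags", n_flagged))

  plants <- stage("summarize_plants", summarize_plants(calls))
  informative <- dplyr::filter(plants, .data$n_informative > 0)

  association <- NULL
  if (nrow(informative) > 0 &&
      sum(informative$n_sexual) > 0 && sum(informative$n_apomictic) > 0) {
    association <- stage("association", monte_carlo_association(
      informative, n_reps = config$mc_reps, rng_seed = config$rng_seed))
  } else {
    note("association test undefined: informative seeds do not span both modes")
  }

  populations <- if (nrow(calls) > 0 && any(calls$pathway != "FAILED")) {
    stage("summarize_populations",
          summarize_populations(calls, composition = composition,
                                base = config$shannon_base))
  } else {
    note("no callable seeds: population summary empty")
    tibble::tibble()
  }

  log <- tibble::tibble(
    stage = c("call_seeds", "summarize_plants", "association",
              "summarize_populations"),
    n_in = c(nrow(seed_table), nrow(calls), nrow(informative), nrow(calls)),
    n_out = c(nrow(calls), nrow(plants),
              if (is.null(association)) 0L else 1L, nrow(populations)))

  structure(list(calls = calls, plants = plants, association = association,
                 populations = populations, log = log,
                 n_warnings = length(warnings_seen),
                 warnings = warnings_seen, config = config),
            class = "fcss_results")
}

#' @export
print.fcss_results <- function(x, ...) {
  cat("FCSS pipeline results\n")
  print(x$log)
  tallies <- dplyr::count(x$calls, .data$pathway)
  print(tallies)
  if (!is.null(x$association)) print(x$association)
  invisible(x)
}
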