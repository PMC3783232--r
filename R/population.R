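# Population-level descriptors: cytotype diversity, seed-formation tallies,
# and the gene-flow regression screen for tetraploids.

#' Shannon diversity of a cytotype composition
#'
#' `H = -sum p_i log p_i` over cytotypes with positive counts. Natural
#' logarithm by default; the base is configurable.
#'
#' @param counts Non-negative per-cytotype counts (named or not).
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon index `H >= 0`; 0 iff a single cytotype is present.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    abort("counts must be non-negative with a positive total")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Summarize seed calls and cytotype composition per population
#'
#' @param calls Seed-call tibble with `population_id` and `pathway`.
#' @param composition Optional population composition tibble
#'   (`population_id`, `ploidy_x`, `n_individuals`) from which the Shannon
#'   index is computed; when absent, the composition is tallied from the
#'   plants present in `calls` (needs `plant_id`, `maternal_ploidy_x`).
#' @param base Logarithm base for the Shannon index.
#' @return A tibble with one row per population: per-pathway seed tallies
#'   and `shannon_H`.
#' @export
summarize_populations <- function(calls, composition = NULL, base = exp(1)) {
  tallies <- calls |>
    dplyr::count(.data$population_id, .data$pathway) |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "n",
                       values_fill = 0L)
  for (p in PATHWAY_LEVELS)
    if (!p %in% names(tallies)) tallies[[p]] <- 0L
  tallies <- tallies |>
    dplyr::transmute(population_id = .data$population_id,
                     n_sexual = .data$SEXUAL, n_apomictic = .data$APOMICTIC,
                     n_l = .data$L_UNREDUCED_EGG, n_z = .data$Z_DOUBLED,
                     n_unknown = .data$UNKNOWN, n_failed = .data$FAILED,
                     n_seeds = .data$n_sexual + .data$n_apomictic + .data$n_l +
                       .data$n_z + .data$n_unknown + .data$n_failed)

  if (is.null(composition)) {
    stopifnot(all(c("plant_id", "maternal_ploidy_x") %in% names(calls)))
    composition <- calls |>
      dplyr::distinct(.data$population_id, .data$plant_id,
                      .data$maternal_ploidy_x) |>
      dplyr::count(.data$population_id, ploidy_x = .data$maternal_ploidy_x,
                   name = "n_individuals")
  }
  H <- composition |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(shannon_H = shannon_index(.data$n_individuals,
                                               base = .env$base),
                     n_individuals = sum(.data$n_individuals),
                     n_cytotypes = dplyr::n_distinct(.data$ploidy_x[
                       .data$n_individuals > 0]),
                     .groups = "drop")
  dplyr::left_join(tallies, H, by = "population_id")
}

#' Simple linear regression with the F test of the slope
#'
#' Ordinary least squares of `y` on `x` with the overall F statistic on
#' `(1, n - 2)` degrees of freedom; for simple regression
#' `F = r^2 (n - 2) / (1 - r^2)`.
#'
#' @param x Predictor values (not constant).
#' @param y Response values.
#' @return An object of class `fcss_ols` with fields `slope`, `intercept`,
#'   `r_squared`, `F_stat`, `df1`, `df2`, `p_value`, `n_points` and the
#'   underlying `lm` fit.
#' @export
ols_with_F <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 points for the regression")
  if (isTRUE(all.equal(stats::var(x), 0)) || sd(x) == 0)
    abort("constant predictor: singular design")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a precision warning
  fstat <- unname(sm$fstatistic)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    F_stat = fstat[1], df1 = fstat[2], df2 = fstat[3],
    p_value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    n_points = length(x), fit = fit),
    class = "fcss_ols")
}

#' @export
print.fcss_ols <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x;  R2 = %.3f,  F(%d,%d) = %.3f,  P = %.4g\n",
              x$n_points, x$intercept, x$slope, x$r_squared,
              x$df1, x$df2, x$F_stat, x$p_value))
  invisible(x)
}

#' Gene-flow screen: male genomic contribution vs cytotype diversity
#'
#' For sexually derived seeds of tetraploid mothers, regresses the
#' population mean male genomic contribution to the embryo on the
#' population's cytotype Shannon diversity. Under strict intracytotype
#' pollination the male contribution is flat in diversity; heteroploid
#' pollen flow raises it in cytologically diverse populations.
#'
#' @param calls Seed-call tibble (needs `population_id`,
#'   `maternal_ploidy_x`, `pathway`, `m_embryo_x` and, when
#'   `include_unreduced`, `embryo_x`/`endosperm_x`).
#' @param populations Population summary with `population_id` and
#'   `shannon_H` (see [summarize_populations()]).
#' @param maternal_x Maternal cytotype screened (default 4).
#' @param per_seed Fit on per-seed points instead of population means.
#' @param include_unreduced Also include seeds labelled `L_UNREDUCED_EGG`,
#'   re-deriving their male contribution under the fertilized-reduced-egg
#'   algebra `m = 2 embryo_x - endosperm_x` (default `TRUE`). An embryo
#'   above the maternal ploidy with a low peak index can equally be an
#'   intercytotype sexual seed — exactly the pollen-flow signal this screen
#'   looks for — and the two cases are observationally indistinguishable.
#' @return A list of class `fcss_geneflow`: the `fcss_ols` fit and the
#'   per-population points (`population_id`, `shannon_H`, `mean_m_embryo_x`,
#'   `n_seeds`).
#' @export
tetraploid_geneflow_screen <- function(calls, populations, maternal_x = 4,
                                       per_seed = FALSE,
                                       include_unreduced = TRUE) {
  keep <- c("SEXUAL", if (include_unreduced) "L_UNREDUCED_EGG")
  sel <- calls |>
    dplyr::filter(.data$pathway %in% .env$keep,
                  .data$maternal_ploidy_x == .env$maternal_x,
                  is.finite(.data$m_embryo_x)) |>
    dplyr::mutate(m_embryo_x = ifelse(
      .data$pathway == "L_UNREDUCED_EGG",
      pmax(0, 2 * .data$embryo_x - .data$endosperm_x),
      .data$m_embryo_x))
  pts <- sel |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(mean_m_embryo_x = mean(.data$m_embryo_x),
                     n_seeds = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(dplyr::select(populations, "population_id", "shannon_H"),
                      by = "population_id")
  if (nrow(pts) < 3)
    abort(sprintf("insufficient data: %d population(s) with %dx sexual seeds (need >= 3)",
                  nrow(pts), maternal_x))
  fit <- if (per_seed) {
    seeds <- dplyr::inner_join(
      sel, dplyr::select(populations, "population_id", "shannon_H"),
      by = "population_id")
    ols_with_F(seeds$shannon_H, seeds$m_embryo_x)
  } else {
    ols_with_F(pts$shannon_H, pts$mean_m_embryo_x)
  }
  structure(list(fit = fit, points = pts, per_seed = per_seed,
                 maternal_x = maternal_x),
            class = "fcss_geneflow")
}

#' @export
print.fcss_geneflow <- function(x, ...) {
  cat(sprintf("Gene-flow screen for %dx sexual seeds over %d populations\n",
              x$maternal_x, nrow(x$points)))
  print(x$fit)
  invisible(x)
}
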