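# Breeding-system statistics: seed set under selfing vs outcrossing,
# pollen/ovule ratio classification, and pollen viability among cytotypes.

#' Poisson regression of viable seed number on pollination treatment
#'
#' Models the number of viable seeds per flower as Poisson with a log link
#' and treatment (`SELF` baseline vs `OUTCROSS`) as the predictor, fitted by
#' iteratively reweighted least squares (`stats::glm`). Repeated flowers of
#' the same pollen-receptor plant are accounted for with a cluster-robust
#' (sandwich) covariance over plants, in place of a plant-level random
#' intercept.
#'
#' @param outcomes Tibble of pollination outcomes: `plant_id`, `flower_id`,
#'   `treatment` (`"SELF"`/`"OUTCROSS"`), `n_viable_seeds`, `n_ovules`.
#' @return An object of class `fcss_glm` with the treatment coefficient
#'   (log rate ratio outcross vs self), robust SE, z and p, plus flags.
#' @export
poisson_glm_seedset <- function(outcomes) {
  stopifnot(all(c("plant_id", "treatment", "n_viable_seeds") %in% names(outcomes)))
  tr <- toupper(as.character(outcomes$treatment))
  if (!all(tr %in% c("SELF", "OUTCROSS")))
    abort("treatment must be SELF or OUTCROSS")
  if (length(unique(tr)) < 2) abort("both treatments must be present")
  if (any(outcomes$n_viable_seeds < 0)) abort("negative seed counts")

  d <- data.frame(y = as.numeric(outcomes$n_viable_seeds),
                  treatment = factor(tr, levels = c("SELF", "OUTCROSS")),
                  plant = as.character(outcomes$plant_id))
  separation <- any(tapply(d$y, d$treatment, sum) == 0)
  if (separation)
    warn("all-zero counts in one treatment arm: coefficient unreliable (separation)")
  fit <- glm(y ~ treatment, family = poisson(), data = d,
             control = list(epsilon = 1e-10, maxit = 100))
  vc <- sandwich::vcovCL(fit, cluster = d$plant)
  est <- coef(fit)
  se <- sqrt(pmax(diag(vc), 0))
  z <- ifelse(se > 0, est / se, NA_real_)
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * pnorm(-abs(unname(z))))
  structure(list(
    coefficients = coefs, link = "log", family = "poisson",
    n_obs = nrow(d), n_groups = length(unique(d$plant)),
    separation = separation, fit = fit, vcov = vc),
    class = "fcss_glm")
}

#' @export
print.fcss_glm <- function(x, ...) {
  cat(sprintf("GLM (%s, %s link), %d observations, %d groups%s\n",
              x$family, x$link, x$n_obs, x$n_groups,
              if (isTRUE(x$separation)) " [separation flagged]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Proportion of flowers setting at least one viable seed, per treatment
#'
#' @param outcomes Pollination outcomes (see [poisson_glm_seedset()]).
#' @return Tibble `treatment`, `n_flowers`, `n_success`, `pct_success`.
#' @export
flower_success_proportions <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  outcomes |>
    dplyr::mutate(treatment = toupper(as.character(.data$treatment))) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(n_flowers = dplyr::n(),
                     n_success = sum(.data$n_viable_seeds >= 1),
                     pct_success = 100 * .data$n_success / .data$n_flowers,
                     .groups = "drop")
}

#' Default pollen/ovule classification table
#'
#' Ordered breeding-system classes with the P/O boundaries separating them,
#' after Cruden's classical compilation. A ratio falls in the class above
#' the highest boundary it reaches; the top class is unbounded.
#'
#' @return Tibble with `class` and `upper_bound` (the boundary above which
#'   the next class begins; `Inf` for the top class).
#' @export
cruden_table <- function() {
  tibble::tibble(
    class = c("cleistogamy", "obligate_autogamy", "facultative_autogamy",
              "facultative_xenogamy", "xenogamy"),
    upper_bound = c(4.7, 27.7, 168.5, 796.6, Inf))
}

#' Pollen/ovule ratio and breeding-system class
#'
#' Computes the P/O ratio of a flower and classifies the breeding system
#' against an ordered boundary table (default [cruden_table()]). A ratio
#' exactly on a boundary is assigned to the higher class and flagged.
#'
#' @param pollen_per_flower Pollen grains per flower.
#' @param ovules_per_flower Ovules per flower (at least 1).
#' @param table Boundary table (`class`, `upper_bound` ascending).
#' @return Tibble `po_ratio`, `class`, `boundary_flag`.
#' @export
po_ratio_and_classify <- function(pollen_per_flower, ovules_per_flower,
                                  table = cruden_table()) {
  if (any(ovules_per_flower < 1)) abort("ovules per flower must be >= 1")
  stopifnot(all(c("class", "upper_bound") %in% names(table)),
            !is.unsorted(table$upper_bound))
  ratio <- as.numeric(pollen_per_flower) / as.numeric(ovules_per_flower)
  ub <- table$upper_bound
  # class i covers ratios in (ub[i-1], ub[i]); a ratio equal to ub[i] is
  # promoted into class i+1 with the boundary flag
  idx <- purrr::map_int(ratio, function(r) {
    i <- which(r < ub)[1]
    if (is.na(i)) length(ub) else i
  })
  on_boundary <- purrr::map_lgl(ratio, function(r) any(r == ub[is.finite(ub)]))
  tibble::tibble(po_ratio = ratio,
                 class = table$class[idx],
                 boundary_flag = on_boundary)
}

#' Pollen viability comparisons among cytotypes
#'
#' Pools the proportion of viable pollen over individuals for each cytotype
#' within populations, then fits weighted binomial (logit link) regressions
#' of that proportion on cytotype — one model per baseline cytotype so that
#' every pairwise contrast appears against a baseline — weighting pooled
#' proportions by the number of individuals behind them. Pairwise contrast
#' p-values are Bonferroni-multiplied by the number of unordered cytotype
#' pairs and capped at 1.
#'
#' @param counts Tibble of per-individual pollen counts: `plant_id`,
#'   `population_id`, `ploidy_x`, `n_viable`, `n_scored`.
#' @param family_size Bonferroni family size; default `choose(k, 2)` for `k`
#'   cytotypes (all unordered pairs).
#' @return An object of class `fcss_pollen`: tibble `contrasts` (one row per
#'   ordered baseline/other pair: `baseline_x`, `other_x`, `estimate`
#'   (log-odds difference), `std_error`, `statistic`, `p_value`,
#'   `p_adjusted`), the pooled data, the per-baseline `fcss_glm`-style fits,
#'   and `family_size`.
#' @export
pollen_viability_glm <- function(counts, family_size = NULL) {
  stopifnot(all(c("population_id", "ploidy_x", "n_viable", "n_scored") %in%
                  names(counts)))
  if (any(counts$n_viable > counts$n_scored | counts$n_viable < 0))
    abort("n_viable must lie in [0, n_scored]")
  zero <- counts$n_scored == 0
  if (any(zero)) {
    warn(sprintf("dropping %d record(s) with zero scored grains", sum(zero)))
    counts <- counts[!zero, ]
  }
  pooled <- counts |>
    dplyr::group_by(.data$population_id, .data$ploidy_x) |>
    dplyr::summarise(prop_viable = sum(.data$n_viable) / sum(.data$n_scored),
                     n_individuals = dplyr::n(),
                     n_scored = sum(.data$n_scored), .groups = "drop")
  cyto <- sort(unique(pooled$ploidy_x))
  if (length(cyto) < 2) abort("need at least 2 cytotypes")
  if (is.null(family_size)) family_size <- choose(length(cyto), 2)

  fits <- purrr::map(cyto, function(b) {
    d <- pooled
    d$ploidy <- factor(d$ploidy_x, levels = c(b, setdiff(cyto, b)))
    suppressWarnings(
      glm(prop_viable ~ ploidy, family = binomial(), weights = n_individuals,
          data = d))
  })
  names(fits) <- paste0("baseline_", cyto)

  contrasts <- purrr::map2_dfr(fits, cyto, function(f, b) {
    sm <- summary(f)$coefficients
    rows <- grepl("^ploidy", rownames(sm))
    tibble::tibble(
      baseline_x = b,
      other_x = as.numeric(sub("^ploidy", "", rownames(sm)[rows])),
      estimate = unname(sm[rows, 1]), std_error = unname(sm[rows, 2]),
      statistic = unname(sm[rows, 3]), p_value = unname(sm[rows, 4]))
  }) |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_value * .env$family_size))
  structure(list(contrasts = contrasts, pooled = pooled, fits = fits,
                 family_size = family_size, cytotypes = cyto),
            class = "fcss_pollen")
}

#' @export
print.fcss_pollen <- function(x, ...) {
  cat(sprintf("Pollen viability logistic regressions: %d cytotypes, Bonferroni family %d\n",
              length(x$cytotypes), x$family_size))
  print(x$contrasts)
  invisible(x)
}
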