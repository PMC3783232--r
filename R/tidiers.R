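# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a Monte Carlo association test
#'
#' @param x An `fcss_assoc` object.
#' @param ... Unused.
#' @return One row per side (`sex_given`, `apo_given`): observed statistic,
#'   null mean and 95% envelope, p-value.
#' @export
tidy.fcss_assoc <- function(x, ...) {
  tibble::tibble(
    side = c("sex_given", "apo_given"),
    observed_pct = unname(x$observed),
    null_mean_pct = x$null_summary$null_mean,
    null_q025 = x$null_summary$null_q025,
    null_q975 = x$null_summary$null_q975,
    p_value = c(x$p_value_sex, x$p_value_apo))
}

#' @rdname tidy.fcss_assoc
#' @export
glance.fcss_assoc <- function(x, ...) {
  tibble::tibble(n_plants = x$n_plants, n_seeds = x$n_seeds,
                 n_reps = x$n_reps, rng_seed = x$rng_seed,
                 null_model = x$null_model,
                 p_value_sex = x$p_value_sex, p_value_apo = x$p_value_apo)
}

#' Tidy a simple regression fit
#'
#' @param x An `fcss_ols` object.
#' @param ... Unused.
#' @return One row per term with estimates and standard errors.
#' @export
tidy.fcss_ols <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std_error = sm[, 2], statistic = sm[, 3], p_value = sm[, 4])
}

#' @rdname tidy.fcss_ols
#' @export
glance.fcss_ols <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, F_stat = x$F_stat,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value,
                 n_points = x$n_points)
}

#' Tidy a gene-flow screen
#'
#' @param x An `fcss_geneflow` object.
#' @param ... Unused.
#' @return Term-level tibble of the underlying regression.
#' @export
tidy.fcss_geneflow <- function(x, ...) tidy(x$fit)

#' @rdname tidy.fcss_geneflow
#' @export
glance.fcss_geneflow <- function(x, ...) {
  dplyr::mutate(glance(x$fit), maternal_x = x$maternal_x,
                per_seed = x$per_seed)
}

#' Tidy a breeding-system GLM
#'
#' @param x An `fcss_glm` object.
#' @param ... Unused.
#' @return Coefficient tibble with cluster-robust errors.
#' @export
tidy.fcss_glm <- function(x, ...) x$coefficients

#' @rdname tidy.fcss_glm
#' @export
glance.fcss_glm <- function(x, ...) {
  tibble::tibble(family = x$family, link = x$link, n_obs = x$n_obs,
                 n_groups = x$n_groups, separation = x$separation,
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' Tidy pollen-viability comparisons
#'
#' @param x An `fcss_pollen` object.
#' @param ... Unused.
#' @return The pairwise-contrast tibble with Bonferroni-adjusted p-values.
#' @export
tidy.fcss_pollen <- function(x, ...) x$contrasts

#' @rdname tidy.fcss_pollen
#' @export
glance.fcss_pollen <- function(x, ...) {
  tibble::tibble(n_cytotypes = length(x$cytotypes),
                 n_contrasts = nrow(x$contrasts),
                 family_size = x$family_size,
                 n_pooled_points = nrow(x$pooled))
}
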