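# Within-plant association of reproductive modes: the observed mixing
# statistic, its Monte Carlo permutation test, and the exclusive-mode
# probability algebra.

#' Build the plant-by-mode matrix for the association test
#'
#' @param plants Per-plant summary as from [summarize_plants()] (needs
#'   `plant_id`, `n_sexual`, `n_apomictic`). Plants without informative
#'   seeds are dropped.
#' @return A tibble `plant_id`, `n_sexual`, `n_apomictic`, `n_informative`.
#' @export
mode_matrix <- function(plants) {
  stopifnot(all(c("plant_id", "n_sexual", "n_apomictic") %in% names(plants)))
  plants |>
    dplyr::transmute(plant_id = .data$plant_id,
                     n_sexual = as.integer(.data$n_sexual),
                     n_apomictic = as.integer(.data$n_apomictic),
                     n_informative = .data$n_sexual + .data$n_apomictic) |>
    dplyr::filter(.data$n_informative > 0)
}

#' Observed mode-association statistic
#'
#' The percentage of plants with at least one sexually derived seed that
#' also formed at least one seed via apomixis, and vice versa. Low values
#' indicate that the two modes segregate among individuals.
#'
#' @param m Mode matrix (see [mode_matrix()]).
#' @return Named numeric vector `c(sex_given = , apo_given = )`, in percent:
#'   `sex_given` is the mixed share among sexual-bearing plants, `apo_given`
#'   among apomictic-bearing plants.
#' @export
association_statistic <- function(m) {
  has_s <- m$n_sexual >= 1L
  has_a <- m$n_apomictic >= 1L
  if (!any(has_s)) abort("no plant with a sexual seed: statistic undefined (sexual side)")
  if (!any(has_a)) abort("no plant with an apomictic seed: statistic undefined (apomictic side)")
  both <- has_s & has_a
  c(sex_given = 100 * sum(both) / sum(has_s),
    apo_given = 100 * sum(both) / sum(has_a))
}

# vectorised statistic over a plants x replicates matrix of per-plant
# sexual-seed counts, given the fixed per-plant informative totals
.assoc_stat_matrix <- function(s_counts, n_informative) {
  a_counts <- n_informative - s_counts
  has_s <- s_counts >= 1L
  has_a <- a_counts >= 1L
  both <- has_s & has_a
  rbind(sex_given = 100 * colSums(both) / colSums(has_s),
        apo_given = 100 * colSums(both) / colSums(has_a))
}

#' Monte Carlo permutation test of mode association within plants
#'
#' Tests whether sexual and apomictic seed formation co-occur within
#' maternal plants as often as expected if modes were assigned to seeds at
#' random. Null replicates pool the mode labels of all informative seeds and
#' permute them across plants while preserving each plant's number of
#' informative seeds (labels conditioned on both margins). The association
#' statistic is recomputed per replicate; the one-sided p-value
#' `(1 + #(null <= observed)) / (n_reps + 1)` asks whether the observed
#' mixing falls below the null (mode separation), with the add-one
#' correction so p is never exactly zero. An unconditional variant
#' (`null = "binomial"`) redraws each seed's label independently with the
#' pooled sexual frequency instead of permuting.
#'
#' @param m Mode matrix (see [mode_matrix()]).
#' @param n_reps Number of null replicates (default 10000).
#' @param rng_seed Integer seed for reproducibility.
#' @param null `"permutation"` (default) or `"binomial"`.
#' @return An object of class `fcss_assoc`: observed statistics, p-values,
#'   null summaries and the null draws.
#' @export
monte_carlo_association <- function(m, n_reps = 10000, rng_seed = 1L,
                                    null = c("permutation", "binomial")) {
  null <- match.arg(null)
  stopifnot(n_reps >= 1)
  m <- mode_matrix(m)
  n_i <- m$n_informative
  total_s <- sum(m$n_sexual)
  total <- sum(n_i)
  if (total_s == 0L || total_s == total)
    abort("all informative seeds share one mode: association test undefined")
  obs <- association_statistic(m)

  plant_idx <- rep.int(seq_len(nrow(m)), n_i)
  set.seed(rng_seed)
  if (null == "permutation") {
    labels <- rep(c(TRUE, FALSE), c(total_s, total - total_s))
    perm <- vapply(seq_len(n_reps), function(i) sample(labels),
                   logical(total))
  } else {
    perm <- matrix(runif(total * n_reps) < total_s / total, nrow = total)
  }
  s_counts <- rowsum(perm + 0L, plant_idx)
  null_stats <- .assoc_stat_matrix(s_counts, n_i)

  p <- vapply(c("sex_given", "apo_given"), function(k)
    (1 + sum(null_stats[k, ] <= obs[[k]])) / (n_reps + 1), numeric(1))
  null_summary <- tibble::tibble(
    side = c("sex_given", "apo_given"),
    null_mean = c(mean(null_stats[1, ]), mean(null_stats[2, ])),
    null_q025 = c(quantile(null_stats[1, ], 0.025),
                  quantile(null_stats[2, ], 0.025)),
    null_q975 = c(quantile(null_stats[1, ], 0.975),
                  quantile(null_stats[2, ], 0.975)))
  structure(list(
    observed = obs,
    p_value_sex = p[["sex_given"]],
    p_value_apo = p[["apo_given"]],
    null_summary = null_summary,
    null_stats = null_stats,
    n_reps = as.integer(n_reps),
    rng_seed = as.integer(rng_seed),
    null_model = null,
    n_plants = nrow(m),
    n_seeds = total),
    class = "fcss_assoc")
}

#' @export
print.fcss_assoc <- function(x, ...) {
  cat("Monte Carlo mode-association test (", x$null_model, " null, ",
      x$n_reps, " replicates, seed ", x$rng_seed, ")\n", sep = "")
  cat(sprintf("  mixed among sexual-bearing plants:    %.1f%% (null mean %.1f%%), p = %.4g\n",
              x$observed[["sex_given"]], x$null_summary$null_mean[1],
              x$p_value_sex))
  cat(sprintf("  mixed among apomictic-bearing plants: %.1f%% (null mean %.1f%%), p = %.4g\n",
              x$observed[["apo_given"]], x$null_summary$null_mean[2],
              x$p_value_apo))
  invisible(x)
}

#' Probability of forming all sampled seeds via one mode
#'
#' Under random, independent assignment of modes to seeds with per-seed
#' probability `p_mode`, the chance that all `n_seeds` seeds of a plant take
#' that mode is `p_mode ^ n_seeds`.
#'
#' @param p_mode Per-seed probability of the mode.
#' @param n_seeds Number of seeds sampled per plant.
#' @return Probability in `[0, 1]`.
#' @export
exclusive_mode_probability <- function(p_mode, n_seeds) {
  stopifnot(all(p_mode >= 0 & p_mode <= 1), all(n_seeds >= 1))
  p_mode^n_seeds
}

#' Per-seed mode probability implied by a single-mode plant fraction
#'
#' Inverse of [exclusive_mode_probability()]: the per-seed probability that
#' would make a plant with `n_seeds` sampled seeds single-mode with
#' probability `single_mode_fraction`, i.e. `fraction ^ (1 / n_seeds)`.
#'
#' @param single_mode_fraction Fraction of single-mode plants, in `(0, 1]`.
#' @param n_seeds Seeds per plant.
#' @return Per-seed probability.
#' @export
per_seed_probability_from_fraction <- function(single_mode_fraction, n_seeds) {
  stopifnot(all(single_mode_fraction > 0 & single_mode_fraction <= 1),
            all(n_seeds >= 1))
  single_mode_fraction^(1 / n_seeds)
}

#' Percentage of plants forming all analysed seeds via one mode
#'
#' @param m Mode matrix (see [mode_matrix()]); only informative plants count.
#' @return Percentage of informative plants with all seeds of one mode.
#' @export
single_mode_fraction <- function(m) {
  m <- mode_matrix(m)
  if (nrow(m) == 0) abort("no informative plants")
  100 * mean(m$n_sexual == 0L | m$n_apomictic == 0L)
}
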