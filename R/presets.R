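# The published study's count surface and the simulation preset that
# emulates its design.

#' Observed reproductive-pathway counts by maternal cytotype
#'
#' The per-cytotype seed tallies of the mixed-ploidy field study behind this
#' package: 354 informative seeds from 115 plants, with sexually derived,
#' apomictic and irregular seeds per maternal cytotype, together with the
#' study-wide numbers of embryo-only ("unknown") and failed seeds.
#'
#' @return A list with `counts` (tibble: `ploidy_x`, `n_sexual`,
#'   `n_apomictic`, `n_irregular`), `n_plants`, `n_mixed_plants`,
#'   `n_seeds_total`, `n_unknown`, `n_failed`.
#' @export
study_counts <- function() {
  list(
    counts = tibble::tibble(
      ploidy_x = 4:8,
      n_sexual = c(92L, 0L, 4L, 5L, 1L),
      n_apomictic = c(1L, 145L, 25L, 39L, 39L),
      n_irregular = c(0L, 2L, 1L, 0L, 0L)),
    n_plants = 115L,
    n_mixed_plants = 7L,
    n_seeds_total = 432L,
    n_unknown = 61L,
    n_failed = 17L)
}

#' Summary fractions from the observed count surface
#'
#' Recomputes the study's headline percentages from the raw tallies: the
#' yield of informative seeds (clear embryo and endosperm signals), the
#' share of sexual and apomictic seeds among them, and the share of sexual
#' seeds in the tetraploid cytotype.
#'
#' @param sc Output of [study_counts()] (or a like-shaped list).
#' @return Tibble with one row: `n_informative`, `pct_informative`,
#'   `pct_sexual`, `pct_apomictic`, `pct_tetraploid_sexual`.
#' @export
seed_screen_summary <- function(sc = study_counts()) {
  ct <- sc$counts
  informative <- sum(ct$n_sexual + ct$n_apomictic + ct$n_irregular)
  tetra <- ct[ct$ploidy_x == 4, ]
  tibble::tibble(
    n_informative = informative,
    pct_informative = 100 * informative / sc$n_seeds_total,
    pct_sexual = 100 * sum(ct$n_sexual) / informative,
    pct_apomictic = 100 * sum(ct$n_apomictic) / informative,
    pct_tetraploid_sexual = 100 * tetra$n_sexual /
      (tetra$n_sexual + tetra$n_apomictic + tetra$n_irregular))
}

#' Simulation preset emulating the published study design
#'
#' Builds a [sim_config()] whose per-cytotype pathway probabilities equal
#' the study's empirical frequencies (e.g. 92/93 sexual for tetraploids and
#' 145/147 apomictic for pentaploids among informative seeds, scaled by the
#' study-wide informative-seed yield of 354/432, with the remainder split
#' between embryo-only and failed seeds at their observed rates), and whose
#' population layout spreads 115 plants over 22 populations with per-
#' cytotype plant numbers proportional to the per-cytotype seed tallies.
#' The irregular seeds are apportioned as one unreduced-egg and one
#' doubled-embryo-sac seed among pentaploids and one unreduced-egg seed
#' among hexaploids.
#'
#' @param ... Overrides passed on to [sim_config()] (e.g. `rng_seed`,
#'   `peak_cv`, `intercytotype_rate`).
#' @return An `fcss_sim_config`.
#' @export
table2_preset <- function(...) {
  sc <- study_counts()
  ct <- sc$counts
  p_inf <- (sc$n_seeds_total - sc$n_unknown - sc$n_failed) / sc$n_seeds_total
  p_unk <- sc$n_unknown / sc$n_seeds_total
  p_fail <- sc$n_failed / sc$n_seeds_total

  # irregular split: pentaploids carry one L and one Z seed, hexaploids one L
  n_l <- c(0, 1, 1, 0, 0)
  n_z <- c(0, 1, 0, 0, 0)
  probs <- purrr::map(seq_len(nrow(ct)), function(i) {
    inf <- ct$n_sexual[i] + ct$n_apomictic[i] + ct$n_irregular[i]
    c(SEXUAL = ct$n_sexual[i] / inf * p_inf,
      APOMICTIC = ct$n_apomictic[i] / inf * p_inf,
      L_UNREDUCED_EGG = n_l[i] / inf * p_inf,
      Z_DOUBLED = n_z[i] / inf * p_inf,
      UNKNOWN = p_unk,
      FAILED = p_fail)
  })
  names(probs) <- as.character(ct$ploidy_x)

  # 22 populations, 115 plants; per-cytotype plant numbers proportional to
  # the cytotype seed tallies at ~3.76 seeds per plant; nine populations
  # hold two cytotypes side by side, as in the study area
  populations <- tibble::tribble(
    ~population_id, ~ploidy_x, ~n_plants,
    "pop01", 4, 5,
    "pop02", 4, 5,
    "pop03", 4, 4,
    "pop04", 4, 4,
    "pop05", 4, 3, "pop05", 5, 3,
    "pop06", 4, 3, "pop06", 5, 3,
    "pop07", 5, 6,
    "pop08", 5, 6,
    "pop09", 5, 6,
    "pop10", 5, 6,
    "pop11", 5, 5,
    "pop12", 5, 5,
    "pop13", 5, 5, "pop13", 7, 2,
    "pop14", 5, 3, "pop14", 6, 2,
    "pop15", 4, 2, "pop15", 6, 2,
    "pop16", 4, 2, "pop16", 6, 2,
    "pop17", 6, 2, "pop17", 7, 3,
    "pop18", 6, 2, "pop18", 8, 3,
    "pop19", 7, 3, "pop19", 8, 3,
    "pop20", 7, 3, "pop20", 8, 3,
    "pop21", 7, 3, "pop21", 8, 4,
    "pop22", 4, 2)
  sim_config(populations = populations, pathway_probs = probs, ...)
}
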