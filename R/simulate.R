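# Generative model for complete FCSS studies: mixed-cytotype populations,
# per-cytotype reproductive-mode probabilities, reduced/unreduced gametes
# with meiotic disturbance, pseudogamous endosperm with one or two sperm,
# Gaussian fluorescence peaks, and pollen / pollination records.

#' Simulation configuration
#'
#' Assembles and validates the generative parameters for [simulate_study()].
#'
#' @param populations Tibble with one row per population-by-cytotype block:
#'   `population_id`, `ploidy_x`, `n_plants`.
#' @param pathway_probs Named list mapping cytotype (as character, e.g.
#'   `"4"`) to a probability vector over the six pathways
#'   (`SEXUAL`, `APOMICTIC`, `L_UNREDUCED_EGG`, `Z_DOUBLED`, `UNKNOWN`,
#'   `FAILED`); each must sum to 1.
#' @param seeds_per_plant Integer range `c(min, max)` of seeds analysed per
#'   plant (default 3--5, the study's sampling design).
#' @param meiotic_sd SD (chromosome sets) of the disturbance added to the
#'   reduced gametic number before rounding to the half-integer grid
#'   (default 0: regular meiosis).
#' @param intercytotype_rate Probability that the effective pollen donor is
#'   of another cytotype (default 0). Heteroploid donors are restricted to
#'   cytotypes actually present in the seed's population, so pure
#'   populations receive no heteroploid pollen regardless of this rate.
#' @param donor_ploidy_probs Named weight vector over donor cytotypes used
#'   when an intercytotype pollination occurs (renormalised over the other
#'   cytotypes present in the population).
#' @param two_sperm_prob Probability that the pseudogamous endosperm of a
#'   parthenogenetic seed receives two sperm rather than one (default 0.5;
#'   the two cases cannot be separated observationally).
#' @param gain Fluorescence units per chromosome set (default 25, placing a
#'   tetraploid embryo at channel 100).
#' @param peak_cv Within-peak coefficient of variation, percent (default 3).
#' @param events_per_peak Nuclei measured per peak (default 3000).
#' @param standard_position Nominal internal-standard peak mean (default
#'   32.5, clear of the half-integer sample-peak ladder).
#' @param standard_label Internal-standard name.
#' @param pollen_viability Named per-cytotype mean proportion of viable
#'   pollen grains.
#' @param pollen_logit_sd Between-individual SD of viability on the logit
#'   scale (default 1; individual pollen quality is highly variable).
#' @param pollen_scored_range Pollen grains screened per individual
#'   (default 94--211).
#' @param pollination_plants Number of pollen-receptor plants in the
#'   crossing experiment (default 38).
#' @param flowers_per_treatment Flowers per plant and treatment (default 2).
#' @param self_mean,outcross_mean Mean viable seeds per selfed / outcrossed
#'   flower (defaults 0.2 and 2).
#' @param plant_log_sd SD of the per-plant log-scale random effect on seed
#'   set (default 0.5).
#' @param ovules_range Ovules per flower (default 8--16).
#' @param po_ratio_meanlog,po_ratio_sdlog Log-normal parameters of the
#'   per-flower pollen/ovule ratio (defaults matching a high-P/O obligate
#'   outcrosser).
#' @param rng_seed Integer RNG seed.
#' @return A validated list of class `fcss_sim_config`.
#' @export
sim_config <- function(populations,
                       pathway_probs,
                       seeds_per_plant = c(3L, 5L),
                       meiotic_sd = 0,
                       intercytotype_rate = 0,
                       donor_ploidy_probs = c(`4` = 0.2, `5` = 0.2, `6` = 0.2,
                                              `7` = 0.2, `8` = 0.2),
                       two_sperm_prob = 0.5,
                       gain = 25,
                       peak_cv = 3,
                       events_per_peak = 3000L,
                       standard_position = 32.5,
                       standard_label = "internal",
                       pollen_viability = c(`4` = 0.85, `5` = 0.35, `6` = 0.55,
                                            `7` = 0.65, `8` = 0.45),
                       pollen_logit_sd = 1,
                       pollen_scored_range = c(94L, 211L),
                       pollination_plants = 38L,
                       flowers_per_treatment = 2L,
                       self_mean = 0.2,
                       outcross_mean = 2,
                       plant_log_sd = 0.5,
                       ovules_range = c(8L, 16L),
                       po_ratio_meanlog = log(7288.92) - 0.5 * log(1 + (5018.08 / 7288.92)^2),
                       po_ratio_sdlog = sqrt(log(1 + (5018.08 / 7288.92)^2)),
                       rng_seed = 1L) {
  stopifnot(is.data.frame(populations),
            all(c("population_id", "ploidy_x", "n_plants") %in% names(populations)),
            all(populations$n_plants >= 1))
  cyto <- sort(unique(populations$ploidy_x))
  probs <- purrr::map(pathway_probs, function(p) {
    p <- p[PATHWAY_LEVELS]
    p[is.na(p)] <- 0
    names(p) <- PATHWAY_LEVELS
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      abort("pathway probabilities must be non-negative and sum to 1")
    p
  })
  missing <- setdiff(as.character(cyto), names(probs))
  if (length(missing) > 0)
    abort(paste0("pathway_probs missing cytotype(s): ",
                 paste(missing, collapse = ", ")))
  stopifnot(length(seeds_per_plant) == 2, seeds_per_plant[1] >= 1,
            seeds_per_plant[2] >= seeds_per_plant[1],
            meiotic_sd >= 0, intercytotype_rate >= 0, intercytotype_rate <= 1,
            two_sperm_prob >= 0, two_sperm_prob <= 1,
            gain > 0, peak_cv >= 0, events_per_peak >= 1,
            standard_position > 0)
  if (any(donor_ploidy_probs < 0) || sum(donor_ploidy_probs) <= 0)
    abort("donor_ploidy_probs must be non-negative with positive total")
  structure(list(
    populations = tibble::as_tibble(populations),
    pathway_probs = probs,
    seeds_per_plant = as.integer(seeds_per_plant),
    meiotic_sd = meiotic_sd,
    intercytotype_rate = intercytotype_rate,
    donor_ploidy_probs = donor_ploidy_probs,
    two_sperm_prob = two_sperm_prob,
    gain = gain, peak_cv = peak_cv,
    events_per_peak = as.integer(events_per_peak),
    standard_position = standard_position,
    standard_label = standard_label,
    pollen_viability = pollen_viability,
    pollen_logit_sd = pollen_logit_sd,
    pollen_scored_range = as.integer(pollen_scored_range),
    pollination_plants = as.integer(pollination_plants),
    flowers_per_treatment = as.integer(flowers_per_treatment),
    self_mean = self_mean, outcross_mean = outcross_mean,
    plant_log_sd = plant_log_sd,
    ovules_range = as.integer(ovules_range),
    po_ratio_meanlog = po_ratio_meanlog, po_ratio_sdlog = po_ratio_sdlog,
    rng_seed = as.integer(rng_seed)),
    class = "fcss_sim_config")
}

#' Calibration implied by a simulation configuration
#'
#' The sample/standard ratios that reference individuals of chromosome-set
#' numbers 4, 5 and 7 would yield under the configured fluorescence gain and
#' standard position.
#'
#' @param cfg An [sim_config()] object.
#' @return An [calibration()] object.
#' @export
sim_calibration <- function(cfg) {
  stopifnot(inherits(cfg, "fcss_sim_config"))
  x <- c(4, 5, 7)
  calibration(x, cfg$gain * x / cfg$standard_position,
              standard_label = cfg$standard_label)
}

# gametic chromosome-set number on the half-integer grid (aneuploidy
# coarse-grained to 0.5x steps; FCSS cannot resolve finer)
round_half <- function(x) pmax(0.5, round(2 * x) / 2)

#' Simulate a complete FCSS study
#'
#' Draws, for every seed of every plant: a developmental pathway from the
#' cytotype's pathway probabilities; reduced (or unreduced) gametic numbers
#' on a half-integer grid with optional meiotic disturbance; a pollen donor
#' (own cytotype, or another under `intercytotype_rate`); and the resulting
#' true embryo and endosperm ploidies
#' (`SEXUAL`: embryo = egg + sperm, endosperm = 2 egg + sperm;
#' `APOMICTIC`: embryo = maternal, endosperm = 2 maternal + 1-or-2 sperm;
#' `L_UNREDUCED_EGG`: embryo = maternal + sperm, endosperm = 2 maternal + sperm;
#' `Z_DOUBLED`: embryo = 2 maternal, endosperm = 4 maternal + sperm;
#' `UNKNOWN`: endosperm signal suppressed; `FAILED`: no signal).
#' Fluorescence peak means are `gain * x` observed through the empirical
#' mean of `events_per_peak` Gaussian draws at the configured CV, alongside
#' an internal-standard peak. Pollen-viability counts and a self/outcross
#' pollination experiment are generated per configuration. All ground truth
#' is recorded.
#'
#' @param cfg An [sim_config()] object.
#' @param emit_histograms Also bin per-seed event draws into fluorescence
#'   histograms (tibble `seed_id`, `channel`, `count`); off by default, as
#'   the histogram route is only needed to exercise peak extraction.
#' @param channels Bin centres for histogram emission.
#' @return A list of class `fcss_sim`: `seed_table`, `ground_truth`,
#'   `pollen_counts`, `pollination`, `histograms` (or `NULL`),
#'   `calibration`, `config`.
#' @export
simulate_study <- function(cfg, emit_histograms = FALSE,
                           channels = seq(1, 1023, by = 2)) {
  stopifnot(inherits(cfg, "fcss_sim_config"))
  set.seed(cfg$rng_seed)

  plants <- cfg$populations |>
    dplyr::mutate(block = dplyr::row_number()) |>
    dplyr::group_by(.data$block) |>
    dplyr::reframe(population_id = .data$population_id,
                   maternal_ploidy_x = .data$ploidy_x,
                   plant_rep = seq_len(.data$n_plants)) |>
    dplyr::mutate(plant_id = sprintf("P%02d_%dx_%02d",
                                     match(.data$population_id,
                                           unique(.data$population_id)),
                                     .data$maternal_ploidy_x,
                                     .data$plant_rep)) |>
    dplyr::select("population_id", "plant_id", "maternal_ploidy_x")

  n_seeds <- sample(seq(cfg$seeds_per_plant[1], cfg$seeds_per_plant[2]),
                    nrow(plants), replace = TRUE)
  seeds <- plants[rep(seq_len(nrow(plants)), n_seeds), ]
  seeds$seed_rep <- unlist(lapply(n_seeds, seq_len))
  seeds$seed_id <- paste0(seeds$plant_id, "_s", seeds$seed_rep)
  n <- nrow(seeds)

  # pathway draw per seed from the maternal cytotype's probabilities
  pw <- vapply(seeds$maternal_ploidy_x, function(mx) {
    p <- cfg$pathway_probs[[as.character(mx)]]
    sample(PATHWAY_LEVELS, 1L, prob = p)
  }, character(1))

  mx <- as.numeric(seeds$maternal_ploidy_x)
  donor <- mx
  # heteroploid pollen must come from a cytotype present in the population:
  # pure populations receive none, so realized heteroploid flow scales with
  # the local cytotype mixture (the basis of the gene-flow screen)
  comp <- split(cfg$populations$ploidy_x, cfg$populations$population_id)
  inter <- runif(n) < cfg$intercytotype_rate
  for (i in which(inter)) {
    present <- setdiff(unique(comp[[seeds$population_id[i]]]), mx[i])
    w <- cfg$donor_ploidy_probs[as.character(present)]
    w[is.na(w)] <- 0
    if (length(present) > 0 && sum(w) > 0)
      donor[i] <- present[sample.int(length(present), 1L, prob = w)]
  }
  egg <- round_half(mx / 2 + rnorm(n, 0, cfg$meiotic_sd))
  sperm <- round_half(donor / 2 + rnorm(n, 0, cfg$meiotic_sd))
  n_sperm <- 1L + rbinom(n, 1L, cfg$two_sperm_prob)

  emb <- end <- rep(NA_real_, n)
  f_emb <- m_emb <- f_end <- m_end <- rep(NA_real_, n)
  s <- pw == "SEXUAL"
  emb[s] <- egg[s] + sperm[s];      end[s] <- 2 * egg[s] + sperm[s]
  f_emb[s] <- egg[s]; m_emb[s] <- sperm[s]
  f_end[s] <- 2 * egg[s]; m_end[s] <- sperm[s]
  a <- pw == "APOMICTIC"
  emb[a] <- mx[a];                  end[a] <- 2 * mx[a] + n_sperm[a] * sperm[a]
  f_emb[a] <- mx[a]; m_emb[a] <- 0
  f_end[a] <- 2 * mx[a]; m_end[a] <- n_sperm[a] * sperm[a]
  l <- pw == "L_UNREDUCED_EGG"
  emb[l] <- mx[l] + sperm[l];       end[l] <- 2 * mx[l] + sperm[l]
  f_emb[l] <- mx[l]; m_emb[l] <- sperm[l]
  f_end[l] <- 2 * mx[l]; m_end[l] <- sperm[l]
  z <- pw == "Z_DOUBLED"
  emb[z] <- 2 * mx[z];              end[z] <- 4 * mx[z] + sperm[z]
  f_emb[z] <- 2 * mx[z]; m_emb[z] <- 0
  f_end[z] <- 4 * mx[z]; m_end[z] <- sperm[z]
  u <- pw == "UNKNOWN"
  emb[u] <- mx[u]                   # endosperm signal missing, embryo reads
  f_emb[u] <- NA_real_

  # observed peak means: empirical mean of events_per_peak Gaussian draws
  obs_mean <- function(x) {
    out <- rep(NA_real_, length(x))
    i <- !is.na(x)
    m <- cfg$gain * x[i]
    out[i] <- rnorm(sum(i), m, (cfg$peak_cv / 100) * m / sqrt(cfg$events_per_peak))
    out
  }
  emb_mean <- obs_mean(emb)
  end_mean <- obs_mean(end)
  std_mean <- obs_mean(rep(cfg$standard_position / cfg$gain, n))
  cv_obs <- function(present) {
    ifelse(present,
           pmax(0, cfg$peak_cv * (1 + rnorm(n, 0, 1 / sqrt(2 * cfg$events_per_peak)))),
           NA_real_)
  }

  failed <- pw == "FAILED"
  emb_mean[failed] <- NA_real_
  std_mean[failed] <- NA_real_

  seed_table <- tibble::tibble(
    seed_id = seeds$seed_id,
    plant_id = seeds$plant_id,
    population_id = seeds$population_id,
    maternal_ploidy_x = as.integer(seeds$maternal_ploidy_x),
    embryo_peak_mean = emb_mean,
    embryo_cv = cv_obs(!is.na(emb_mean)),
    endosperm_peak_mean = end_mean,
    endosperm_cv = cv_obs(!is.na(end_mean)),
    standard_peak_mean = std_mean,
    standard_label = cfg$standard_label)

  ground_truth <- tibble::tibble(
    seed_id = seeds$seed_id, plant_id = seeds$plant_id,
    population_id = seeds$population_id,
    maternal_ploidy_x = as.integer(seeds$maternal_ploidy_x),
    true_pathway = pw,
    egg_x = ifelse(s, egg, NA_real_),
    sperm_x = sperm, n_sperm = n_sperm, donor_ploidy_x = donor,
    true_embryo_x = emb, true_endosperm_x = end,
    true_f_embryo_x = f_emb, true_m_embryo_x = m_emb,
    true_f_endosperm_x = f_end, true_m_endosperm_x = m_end)

  histograms <- NULL
  if (emit_histograms)
    histograms <- make_histograms(seed_table, emb, end, cfg, channels)

  pollen_counts <- simulate_pollen(plants, cfg)
  pollination <- simulate_pollination(cfg)

  structure(list(seed_table = seed_table, ground_truth = ground_truth,
                 pollen_counts = pollen_counts, pollination = pollination,
                 histograms = histograms,
                 calibration = sim_calibration(cfg), config = cfg),
            class = "fcss_sim")
}

#' @export
print.fcss_sim <- function(x, ...) {
  cat("Simulated FCSS study: ", nrow(x$seed_table), " seeds, ",
      dplyr::n_distinct(x$seed_table$plant_id), " plants, ",
      dplyr::n_distinct(x$seed_table$population_id), " populations\n", sep = "")
  print(dplyr::count(x$ground_truth, .data$true_pathway))
  invisible(x)
}

make_histograms <- function(seed_table, emb, end, cfg, channels) {
  binw <- channels[2] - channels[1]
  breaks <- c(channels - binw / 2, channels[length(channels)] + binw / 2)
  bin_events <- function(x) {
    if (is.na(x)) return(integer(length(channels)))
    ev <- rnorm(cfg$events_per_peak, cfg$gain * x,
                (cfg$peak_cv / 100) * cfg$gain * x)
    ev <- pmin(pmax(ev, breaks[1]), breaks[length(breaks)] - 1e-9)
    tabulate(findInterval(ev, breaks), nbins = length(channels))
  }
  purrr::map_dfr(seq_len(nrow(seed_table)), function(i) {
    failed <- is.na(emb[i]) && is.na(end[i])
    counts <- bin_events(emb[i]) + bin_events(end[i]) +
      if (failed) integer(length(channels)) else
        bin_events(cfg$standard_position / cfg$gain)
    tibble::tibble(seed_id = seed_table$seed_id[i],
                   channel = channels, count = counts)
  })
}

simulate_pollen <- function(plants, cfg) {
  n <- nrow(plants)
  mu <- cfg$pollen_viability[as.character(plants$maternal_ploidy_x)]
  p <- stats::plogis(stats::qlogis(pmin(pmax(mu, 1e-6), 1 - 1e-6)) +
                       rnorm(n, 0, cfg$pollen_logit_sd))
  n_scored <- sample(seq(cfg$pollen_scored_range[1], cfg$pollen_scored_range[2]),
                     n, replace = TRUE)
  tibble::tibble(plant_id = plants$plant_id,
                 population_id = plants$population_id,
                 ploidy_x = as.integer(plants$maternal_ploidy_x),
                 n_viable = rbinom(n, n_scored, p),
                 n_scored = n_scored)
}

simulate_pollination <- function(cfg) {
  plant_id <- sprintf("X%02d", seq_len(cfg$pollination_plants))
  re <- rnorm(cfg$pollination_plants, 0, cfg$plant_log_sd)
  grid <- tidyr::expand_grid(
    plant_id = plant_id,
    treatment = c("SELF", "OUTCROSS"),
    flower_rep = seq_len(cfg$flowers_per_treatment))
  grid$flower_id <- paste0(grid$plant_id, "_", substr(grid$treatment, 1, 1),
                           grid$flower_rep)
  mu <- ifelse(grid$treatment == "SELF", cfg$self_mean, cfg$outcross_mean) *
    exp(re[match(grid$plant_id, plant_id)])
  n_ovules <- sample(seq(cfg$ovules_range[1], cfg$ovules_range[2]),
                     nrow(grid), replace = TRUE)
  n_seeds <- pmin(stats::rpois(nrow(grid), mu), n_ovules)
  tibble::tibble(plant_id = grid$plant_id, flower_id = grid$flower_id,
                 treatment = grid$treatment,
                 n_viable_seeds = as.integer(n_seeds),
                 n_ovules = as.integer(n_ovules),
                 po_ratio = stats::rlnorm(nrow(grid), cfg$po_ratio_meanlog,
                                          cfg$po_ratio_sdlog))
}
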