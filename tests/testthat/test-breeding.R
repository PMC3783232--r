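make_outcomes <- function(self_means, out_means, plant_ids = NULL) {
  n <- length(self_means)
  if (is.null(plant_ids)) plant_ids <- paste0("pl", seq_len(n))
  tibble::tibble(
    plant_id = rep(plant_ids, 2),
    flower_id = paste0(rep(plant_ids, 2), "_", rep(c("s", "o"), each = n)),
    treatment = rep(c("SELF", "OUTCROSS"), each = n),
    n_viable_seeds = c(self_means, out_means),
    n_ovules = pmax(c(self_means, out_means), 12))
}

test_that("Poisson IRLS equals the closed-form two-group log rate ratio", {
  oc <- make_outcomes(c(0, 1, 0, 2, 1), c(3, 5, 2, 6, 4))
  fit <- poisson_glm_seedset(oc)
  cf <- fit$coefficients
  m_self <- mean(c(0, 1, 0, 2, 1)); m_out <- mean(c(3, 5, 2, 6, 4))
  expect_equal(cf$estimate[cf$term == "(Intercept)"], log(m_self),
               tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "treatmentOUTCROSS"],
               log(m_out / m_self), tolerance = 1e-8)
})

test_that("identical arms give a near-zero coefficient", {
  oc <- make_outcomes(c(2, 3, 1, 2), c(2, 3, 1, 2))
  fit <- poisson_glm_seedset(oc)
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "treatmentOUTCROSS"], 0,
               tolerance = 1e-8)
  z <- cf$statistic[cf$term == "treatmentOUTCROSS"]
  # perfectly balanced clusters give a zero sandwich variance; either way
  # there is no evidence of a treatment effect
  expect_true(is.na(z) || abs(z) < 0.1)
})

test_that("a generator-set rate ratio is recovered within 2 robust SEs", {
  cfg <- tiny_config(self_mean = 0.2, outcross_mean = 2,
                     pollination_plants = 60, flowers_per_treatment = 4,
                     rng_seed = 12)
  sim <- simulate_study(cfg)
  fit <- poisson_glm_seedset(sim$pollination)
  cf <- dplyr::filter(fit$coefficients, term == "treatmentOUTCROSS")
  expect_lt(abs(cf$estimate - log(10)), 2 * cf$std_error)
  expect_lt(cf$p_value, 0.001)
})

test_that("an all-zero arm is flagged as separation", {
  oc <- make_outcomes(c(0, 0, 0), c(2, 3, 1))
  fit <- NULL
  w <- testthat::capture_warnings(fit <- poisson_glm_seedset(oc))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation)
})

test_that("flower success proportions are per-arm percentages", {
  oc <- make_outcomes(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), rep(3, 10))
  fs <- flower_success_proportions(oc)
  expect_equal(fs$pct_success[fs$treatment == "SELF"], 20)
  expect_equal(fs$pct_success[fs$treatment == "OUTCROSS"], 100)
  oc0 <- make_outcomes(c(0, 0), c(0, 0))
  expect_true(all(flower_success_proportions(oc0)$pct_success == 0))
})

test_that("simulator arms near the study's rates reproduce its proportions", {
  # invert E[1 - exp(-c exp(X))] over the plant effect X ~ N(0, sd^2) to
  # find the per-flower rates implying the published 9.3% / 65.5% arms
  sdlog <- 0.4
  arm_rate <- function(target) {
    f <- function(c) {
      stats::integrate(function(z)
        (1 - exp(-c * exp(sdlog * z))) * dnorm(z), -8, 8)$value - target
    }
    stats::uniroot(f, c(1e-4, 20))$root
  }
  cfg <- tiny_config(self_mean = arm_rate(0.093),
                     outcross_mean = arm_rate(0.655),
                     pollination_plants = 250, flowers_per_treatment = 2,
                     plant_log_sd = sdlog, rng_seed = 6)
  sim <- simulate_study(cfg)
  fs <- flower_success_proportions(sim$pollination)
  p_self <- fs$pct_success[fs$treatment == "SELF"]
  p_out <- fs$pct_success[fs$treatment == "OUTCROSS"]
  # allow binomial error at the number of independent plants (flowers of a
  # plant share its random effect)
  expect_lt(abs(p_self - 9.3), 3 * 100 * sqrt(0.093 * 0.907 / 250))
  expect_lt(abs(p_out - 65.5), 3 * 100 * sqrt(0.655 * 0.345 / 250))
})

test_that("P/O ratios classify against the ordered Cruden-style table", {
  # the study's tetraploid mean P/O marks an obligate outcrosser
  cls <- po_ratio_and_classify(7288.92 * 450, 450)
  expect_equal(cls$po_ratio, 7288.92)
  expect_equal(cls$class, "xenogamy")
  expect_false(cls$boundary_flag)

  expect_equal(po_ratio_and_classify(100, 10)$class, "obligate_autogamy")
  expect_equal(po_ratio_and_classify(3, 1)$class, "cleistogamy")
  # exact boundary promotes to the higher class with a flag
  b <- po_ratio_and_classify(27.7, 1)
  expect_equal(b$class, "facultative_autogamy")
  expect_true(b$boundary_flag)
  expect_error(po_ratio_and_classify(10, 0), "ovules")
})

test_that("identical cytotype viabilities yield non-significant contrasts", {
  counts <- tidyr::expand_grid(pop = paste0("p", 1:6), cyto = c(4, 5)) |>
    dplyr::mutate(plant_id = paste0(pop, "_", cyto),
                  population_id = pop, ploidy_x = cyto,
                  n_viable = 80, n_scored = 100)
  fit <- pollen_viability_glm(counts)
  expect_true(all(fit$contrasts$p_adjusted > 0.99))
  expect_equal(fit$family_size, 1L)
})

test_that("five cytotypes give ten pairwise contrasts, Bonferroni factor 10", {
  cfg <- table2_preset(rng_seed = 33)
  sim <- simulate_study(cfg)
  fit <- pollen_viability_glm(sim$pollen_counts)
  expect_equal(fit$family_size, 10)
  # every ordered pair appears once per baseline: 5 baselines x 4 contrasts
  expect_equal(nrow(fit$contrasts), 20L)
  expect_equal(nrow(dplyr::distinct(fit$contrasts,
                                    pmin(baseline_x, other_x),
                                    pmax(baseline_x, other_x))), 10L)
  expect_true(all(fit$contrasts$p_adjusted >= fit$contrasts$p_value - 1e-12))
  expect_true(all(fit$contrasts$p_adjusted <= 1))
})

test_that("contrasts are antisymmetric under baseline swap", {
  cfg <- table2_preset(rng_seed = 34)
  sim <- simulate_study(cfg)
  fit <- pollen_viability_glm(sim$pollen_counts)
  ct <- fit$contrasts
  for (i in seq_len(nrow(ct))) {
    rev <- ct[ct$baseline_x == ct$other_x[i] & ct$other_x == ct$baseline_x[i], ]
    expect_equal(rev$estimate, -ct$estimate[i], tolerance = 1e-6)
    expect_equal(rev$p_value, ct$p_value[i], tolerance = 1e-6)
  }
})

test_that("cytotype viability differences survive the Bonferroni screen", {
  # weighting pooled proportions by the number of individuals makes the
  # information scale with plants, not grains, so separating the full
  # viability profile (0.85, 0.35, 0.55, 0.65, 0.45) at adjusted p < 0.001
  # needs hundreds of individuals per cytotype; here the tetraploid
  # contrasts (the largest gaps) are tested against every other cytotype
  set.seed(55)
  mus <- c(`4` = 0.85, `5` = 0.35, `6` = 0.55, `7` = 0.65, `8` = 0.45)
  sim_counts <- function() {
    tidyr::expand_grid(cyto = 4:8, pop = 1:40, ind = 1:8) |>
      dplyr::mutate(
        plant_id = paste0(cyto, "_", pop, "_", ind),
        population_id = paste0("c", cyto, "p", pop),
        ploidy_x = cyto,
        n_scored = sample(94:211, dplyr::n(), replace = TRUE),
        p = stats::plogis(stats::qlogis(mus[as.character(cyto)]) +
                            rnorm(dplyr::n(), 0, 0.3)),
        n_viable = rbinom(dplyr::n(), n_scored, p))
  }
  hits <- replicate(10, {
    ct <- pollen_viability_glm(sim_counts())$contrasts
    tetra <- ct[ct$baseline_x == 4, ]
    all(tetra$p_adjusted < 0.001)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("breeding fits expose tidy/glance and pollen results autoplot", {
  oc <- make_outcomes(c(0, 1, 0), c(3, 5, 2))
  fit <- poisson_glm_seedset(oc)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_groups, 3L)
  sim <- simulate_study(table2_preset(rng_seed = 44))
  pv <- pollen_viability_glm(sim$pollen_counts)
  expect_s3_class(autoplot(pv), "ggplot")
  expect_equal(glance(pv)$n_contrasts, 20L)
})
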