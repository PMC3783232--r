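test_that("pathway classification reproduces the defining cases", {
  th <- classification_thresholds()
  # doubled maternal ploidy in an apomictically derived embryo (5x -> 10x)
  expect_equal(classify_pathway(10, 2.4, 5, th)$pathway, "Z_DOUBLED")
  # regular sexual seed: maternal ploidy recovered, index 1.5
  expect_equal(classify_pathway(4, 1.5, 4, th)$pathway, "SEXUAL")
  # apomictic: maternal ploidy recovered, index >= 2
  expect_equal(classify_pathway(5, 2.8, 5, th)$pathway, "APOMICTIC")
  # fertilized unreduced egg: embryo above maternal, index < 2
  expect_equal(classify_pathway(7, 1.6, 5, th)$pathway, "L_UNREDUCED_EGG")
  # missing signals
  expect_equal(classify_pathway(NA, NA, 5, th)$pathway, "FAILED")
  expect_equal(classify_pathway(5, NA, 5, th)$pathway, "UNKNOWN")
})

test_that("classification agrees with an independent rule re-implementation", {
  th <- classification_thresholds()
  oracle <- function(e, pi, m) {
    if (is.na(e)) return("FAILED")
    if (is.na(pi)) return("UNKNOWN")
    near <- function(a, b, tol) abs(a - b) <= tol * b
    if (near(e, 2 * m, th$doubled_match_tol)) return("Z_DOUBLED")
    if (pi < th$pi_boundary && near(e, m, th$maternal_match_tol)) return("SEXUAL")
    if (pi < th$pi_boundary && e > m * (1 + th$maternal_match_tol))
      return("L_UNREDUCED_EGG")
    if (pi >= th$pi_boundary && near(e, m, th$maternal_match_tol))
      return("APOMICTIC")
    "UNKNOWN"
  }
  grid <- expand.grid(e = seq(2, 16, by = 0.25),
                      pi = c(1.2, 1.5, 1.9, 2.0, 2.1, 2.5, 3.2),
                      m = 4:8)
  got <- classify_pathway(grid$e, grid$pi, grid$m, th)$pathway
  want <- mapply(oracle, grid$e, grid$pi, grid$m)
  expect_equal(got, unname(want))
})

test_that("near-boundary peak indices are flagged", {
  out <- classify_pathway(c(5, 5), c(1.95, 1.5), 5)
  expect_match(out$flag[1], "near_boundary")
  expect_equal(out$flag[2], "")
})

test_that("genomic contributions solve the stated identities exactly", {
  gc <- genomic_contributions(4, 6, 4, "SEXUAL")
  expect_equal(unlist(gc[1, 1:4], use.names = FALSE), c(2, 2, 4, 2))
  gc <- genomic_contributions(5, 12, 5, "APOMICTIC")
  expect_equal(unlist(gc[1, 1:4], use.names = FALSE), c(5, 0, 10, 2))
  gc <- genomic_contributions(7, 12, 5, "L_UNREDUCED_EGG")
  expect_equal(unlist(gc[1, 1:4], use.names = FALSE), c(5, 2, 10, 2))
  gc <- genomic_contributions(10, 22, 5, "Z_DOUBLED")
  expect_equal(unlist(gc[1, 1:4], use.names = FALSE), c(10, 0, 20, 2))
})

test_that("contributions conserve embryo and endosperm ploidy", {
  sim <- simulate_study(table2_preset(rng_seed = 21, peak_cv = 2))
  res <- call_seeds(sim$seed_table,
                    run_config(calibration = sim$calibration))
  dec <- res[res$pathway %in% c("SEXUAL", "APOMICTIC", "Z_DOUBLED",
                                "L_UNREDUCED_EGG") & !res$clipped, ]
  expect_gt(nrow(dec), 300)
  expect_lt(max(abs(dec$f_embryo_x + dec$m_embryo_x - dec$embryo_x)), 1e-9)
  expect_lt(max(abs(dec$f_endosperm_x + dec$m_endosperm_x - dec$endosperm_x)),
            1e-9)
  expect_true(all(dec$f_embryo_x >= 0 & dec$m_embryo_x >= 0 &
                    dec$f_endosperm_x >= 0 & dec$m_endosperm_x >= 0))
})

test_that("strongly negative components raise an inconsistency error", {
  expect_error(genomic_contributions(4, 9, 4, "SEXUAL", seed_id = "s1"),
               "s1")
  # small negative clipped to zero with a flag
  gc <- genomic_contributions(4, 8.1, 4, "SEXUAL")
  expect_true(gc$clipped)
  expect_equal(gc$m_embryo_x, 0)
})

test_that("endosperm ratio is paternal dosage per two maternal units", {
  expect_equal(endosperm_ratio(4, 2), 1)
  expect_equal(endosperm_ratio(10, 2), 0.4)
  expect_equal(endosperm_ratio(8, 0), 0)
  expect_error(endosperm_ratio(0, 2), "positive")
})

test_that("balanced sexual seeds give peak index 1.5 and 2m:1p exactly", {
  for (m in c(4, 6, 8)) {
    emb <- m; endo <- 1.5 * m   # f = m/2 gametes on both sides
    expect_equal(peak_index(endo * 25, emb * 25), 1.5)
    gc <- genomic_contributions(emb, endo, m, "SEXUAL")
    expect_equal(gc$f_embryo_x, m / 2)
    expect_equal(endosperm_ratio(gc$f_endosperm_x, gc$m_endosperm_x), 1)
  }
})

test_that("m and f are perfectly anticorrelated at fixed embryo ploidy", {
  # m_embryo = 2 embryo_x - endosperm_x: at constant embryo ploidy the
  # estimates trade off one-for-one, a built-in artifact of the algebra
  endosperm <- seq(5.6, 6.4, by = 0.1)
  gc <- genomic_contributions(rep(4, length(endosperm)), endosperm,
                              4, "SEXUAL")
  expect_equal(cor(gc$f_embryo_x, gc$m_embryo_x), -1)
})

test_that("plant summaries tally modes and flag mixed plants", {
  calls <- tibble::tibble(
    plant_id = c("a", "a", "a", "b", "b", "b"),
    pathway = c("SEXUAL", "SEXUAL", "SEXUAL", "SEXUAL", "APOMICTIC", "UNKNOWN"))
  s <- summarize_plants(calls)
  expect_equal(s$n_sexual, c(3L, 1L))
  expect_equal(s$n_apomictic, c(0L, 1L))
  expect_equal(s$mixed, c(FALSE, TRUE))
  expect_equal(s$n_informative, c(3L, 2L))
  expect_equal(nrow(summarize_plants(calls[0, ])), 0L)
})

test_that("irregular pathways can be excluded from the mode tallies", {
  calls <- tibble::tibble(plant_id = "a",
                          pathway = c("L_UNREDUCED_EGG", "Z_DOUBLED"))
  s1 <- summarize_plants(calls)
  expect_equal(c(s1$n_sexual, s1$n_apomictic), c(1L, 1L))
  s2 <- summarize_plants(calls, l_as_sexual = FALSE, z_as_apomictic = FALSE)
  expect_equal(c(s2$n_sexual, s2$n_apomictic), c(0L, 0L))
})

test_that("noiseless pipeline tallies equal the generator's bookkeeping", {
  sim <- simulate_study(table2_preset(rng_seed = 9, peak_cv = 0))
  res <- call_seeds(sim$seed_table, run_config(calibration = sim$calibration))
  joined <- dplyr::inner_join(res, sim$ground_truth, by = "seed_id")
  expect_equal(joined$pathway, joined$true_pathway)
  truth_tally <- table(sim$ground_truth$true_pathway)
  call_tally <- table(res$pathway)
  expect_equal(as.vector(call_tally[names(truth_tally)]),
               as.vector(truth_tally))
})
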