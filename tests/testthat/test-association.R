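test_that("the observed association statistic is a hand count", {
  expect_equal(unname(association_statistic(mm(c(3, 0, 1), c(0, 3, 2)))),
               c(50, 50))
  expect_equal(unname(association_statistic(mm(c(3, 0), c(0, 3)))), c(0, 0))
  expect_equal(unname(association_statistic(mm(c(1, 2), c(2, 1)))), c(100, 100))
  expect_error(association_statistic(mm(c(0, 0), c(1, 2))), "sexual")
})

test_that("Monte Carlo p-values match exhaustive enumeration on a toy case", {
  # 3 plants x 2 seeds, pooled labels {S,S,S,A,A,A}: all C(6,3) = 20
  # assignments of the S labels to seed slots
  m <- mm(c(2, 1, 0), c(0, 1, 2))
  plant_of <- rep(1:3, each = 2)
  stats_all <- apply(utils::combn(6, 3), 2, function(sx) {
    s <- tabulate(plant_of[sx], nbins = 3)
    a <- c(2, 2, 2) - s
    both <- s >= 1 & a >= 1
    c(100 * sum(both) / sum(s >= 1), 100 * sum(both) / sum(a >= 1))
  })
  obs <- association_statistic(m)
  p_exact_sex <- mean(stats_all[1, ] <= obs[["sex_given"]])
  p_exact_apo <- mean(stats_all[2, ] <= obs[["apo_given"]])

  res <- monte_carlo_association(m, n_reps = 20000, rng_seed = 99)
  se <- function(p) sqrt(p * (1 - p) / 20000)
  expect_lt(abs(res$p_value_sex - p_exact_sex), 3 * se(p_exact_sex))
  expect_lt(abs(res$p_value_apo - p_exact_apo), 3 * se(p_exact_apo))
})

test_that("p-values are calibrated under the permutational null", {
  set.seed(1234)
  n_plants <- 25
  seeds_per <- sample(3:5, n_plants, replace = TRUE)
  total <- sum(seeds_per)
  n_sex_total <- round(total * 0.4)
  plant_of <- rep(seq_len(n_plants), seeds_per)
  pvals <- replicate(500, {
    lab <- sample(rep(c(1, 0), c(n_sex_total, total - n_sex_total)))
    s <- tabulate(plant_of * lab + 1, nbins = n_plants + 1)[-1]
    m <- mm(s, seeds_per - s)
    monte_carlo_association(m, n_reps = 199,
                            rng_seed = sample.int(1e6, 1))$p_value_sex
  })
  # the statistic is discrete with heavy mass at full mixing, so the
  # p-value distribution is stochastically above uniform (conservative):
  # valid calibration means rejection never exceeds the nominal level
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    emp <- mean(pvals <= alpha)
    expect_lt(emp, alpha + 3 * sqrt(alpha * (1 - alpha) / 500))
  }
  expect_gt(mean(pvals), 0.45)   # and not degenerately anti-conservative
  expect_gt(sd(pvals), 0.1)
})

test_that("a fully separated configuration is significant at 10 000 reps", {
  m <- mm(c(rep(4, 10), rep(0, 10)), c(rep(0, 10), rep(4, 10)))
  res <- monte_carlo_association(m, n_reps = 10000, rng_seed = 17)
  expect_lte(res$p_value_sex, 0.001)
  expect_lte(res$p_value_apo, 0.001)
  expect_equal(unname(res$observed), c(0, 0))
})

test_that("the test is invariant to plant order and reproducible", {
  m <- mm(c(3, 0, 1, 2, 0), c(0, 3, 2, 1, 4))
  r1 <- monte_carlo_association(m, n_reps = 500, rng_seed = 5)
  r2 <- monte_carlo_association(m[sample(5), ], n_reps = 500, rng_seed = 5)
  expect_equal(r1$observed, r2$observed)
  r3 <- monte_carlo_association(m, n_reps = 500, rng_seed = 5)
  expect_identical(r1$p_value_sex, r3$p_value_sex)
  expect_identical(r1$null_stats, r3$null_stats)
})

test_that("increasing mode separation never increases the p-value", {
  # nested configurations: same pool (8 S, 8 A over 4 plants x 4 seeds),
  # progressively unmixed
  configs <- list(
    mm(c(2, 2, 2, 2), c(2, 2, 2, 2)),   # fully mixed
    mm(c(3, 3, 1, 1), c(1, 1, 3, 3)),
    mm(c(4, 3, 1, 0), c(0, 1, 3, 4)),
    mm(c(4, 4, 0, 0), c(0, 0, 4, 4)))   # fully separated
  p <- vapply(configs, function(m)
    monte_carlo_association(m, n_reps = 4000, rng_seed = 31)$p_value_sex,
    numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("degenerate pools are rejected", {
  expect_error(monte_carlo_association(mm(c(2, 2), c(0, 0)), n_reps = 10),
               "one mode")
})

test_that("exclusive-mode probabilities reproduce the published algebra", {
  p_sex <- 102 / 354
  p_apo <- 249 / 354
  expect_equal(round(100 * exclusive_mode_probability(p_sex, 3), 1), 2.4)
  expect_equal(round(100 * exclusive_mode_probability(p_sex, 5), 1), 0.2)
  expect_equal(round(100 * exclusive_mode_probability(p_apo, 3), 1), 34.8)
  expect_equal(round(100 * exclusive_mode_probability(p_apo, 5), 1), 17.2)
  expect_equal(exclusive_mode_probability(1, 7), 1)

  frac <- 108 / 115
  expect_equal(round(100 * per_seed_probability_from_fraction(frac, 5), 1), 98.8)
  expect_equal(round(100 * per_seed_probability_from_fraction(frac, 3), 1), 97.9)
  expect_equal(per_seed_probability_from_fraction(1, 4), 1)
})

test_that("exclusive-mode probability and its inverse are mutual inverses", {
  for (q in c(0.1, 0.5, 0.939)) {
    for (n in c(3, 5)) {
      expect_equal(
        exclusive_mode_probability(per_seed_probability_from_fraction(q, n), n),
        q)
    }
  }
})

test_that("single-mode fraction counts pure plants among informative ones", {
  m <- mm(c(rep(1, 108), rep(1, 7)), c(rep(0, 108), rep(1, 7)))
  expect_equal(round(single_mode_fraction(m), 1), 93.9)
  expect_equal(single_mode_fraction(mm(c(1, 2), c(0, 0))), 100)
  expect_equal(single_mode_fraction(mm(c(1, 2), c(1, 1))), 0)
})

test_that("tidy/glance and autoplot work on association results", {
  res <- monte_carlo_association(mm(c(3, 0, 1), c(0, 3, 2)),
                                 n_reps = 200, rng_seed = 2)
  td <- tidy(res)
  expect_equal(nrow(td), 2L)
  expect_true(all(td$p_value > 0 & td$p_value <= 1))
  expect_equal(glance(res)$n_plants, 3L)
  expect_s3_class(autoplot(res), "ggplot")
})
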