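test_that("bootstrap is seeded, degenerate-safe, and collapses for identical patients", {
  co <- toy_cohort(exac_b = rep(5, 6), exac_t = rep(1, 6),
                   cost_b = rep(1000, 6), cost_t = rep(3000, 6))
  ci <- bootstrap_icer_ci(co, "exacerbations_avoided", reps = 500, seed = 3)
  expect_equal(ci$point, 2000 / 4)
  expect_equal(ci$lower, ci$point)
  expect_equal(ci$upper, ci$point)
  expect_equal(ci$dropped, 0)

  co2 <- toy_cohort(exac_b = c(7, 3, 6), exac_t = c(1, 2, 0),
                    cost_b = c(9000, 11000, 15000),
                    cost_t = c(13000, 14000, 16000))
  a <- bootstrap_icer_ci(co2, "exacerbations_avoided", reps = 2000, seed = 1)
  b <- bootstrap_icer_ci(co2, "exacerbations_avoided", reps = 2000, seed = 1)
  c <- bootstrap_icer_ci(co2, "exacerbations_avoided", reps = 2000, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_lte(a$lower, a$point)
  expect_gte(a$upper, a$point)

  expect_error(bootstrap_icer_ci(co2[co2$patient_id == "P01", ]), "at least 2")
})

test_that("degenerate effectiveness replicates are dropped and counted", {
  # one patient improves, one worsens by the same amount: resamples that
  # pick a balanced mix give zero mean effectiveness difference
  co <- toy_cohort(exac_b = c(4, 2), exac_t = c(2, 4),
                   cost_b = c(1000, 1000), cost_t = c(2000, 3000))
  ci <- bootstrap_icer_ci(co, "exacerbations_avoided", reps = 2000, seed = 9)
  expect_gt(ci$dropped, 0)
  expect_lt(ci$dropped, 2000)
  # the NMB statistic has no degenerate replicates on the same cohort
  cn <- bootstrap_icer_ci(co, "exacerbations_avoided", reps = 2000, seed = 9,
                          statistic = "nmb", wtp = 1000)
  expect_equal(cn$dropped, 0)
})

test_that("bootstrap percentiles agree with exhaustive resample enumeration", {
  # n = 3: all 27 ordered resamples are equally likely; compare against the
  # exact quantiles of that finite distribution
  d_e <- c(6, 4, 3); d_c <- c(4000, 1000, 2500)
  co <- toy_cohort(exac_b = d_e, exac_t = c(0, 0, 0),
                   cost_b = c(0, 0, 0), cost_t = d_c)
  grid <- expand.grid(1:3, 1:3, 1:3)
  oracle <- apply(grid, 1, function(i) mean(d_c[i]) / mean(d_e[i]))
  oracle_q <- function(p) min(oracle[vapply(oracle, function(x)
    mean(oracle <= x), numeric(1)) >= p])
  ci <- bootstrap_icer_ci(co, "exacerbations_avoided", reps = 20000, seed = 4)
  # each atom carries mass 1/27 > 0.025, so the exact 2.5th/97.5th
  # percentiles sit on the extreme atoms and the empirical percentile
  # lands there almost surely
  expect_equal(ci$lower, oracle_q(0.025), tolerance = 1e-9)
  expect_equal(ci$upper, oracle_q(0.975), tolerance = 1e-9)
  expect_equal(ci$point, mean(d_c) / mean(d_e))
})

test_that("PSA sampling is seeded and handles degenerate inputs", {
  expect_equal(nrow(psa_simulate(list(mean = 1, sd = 0), list(mean = 2, sd = 0),
                                 list(mean = 0, sd = 0), list(mean = 1, sd = 0),
                                 n = 0)), 0)
  fixed <- psa_simulate(list(mean = 1000, sd = 0), list(mean = 1500, sd = 0),
                        list(mean = 0.5, sd = 0), list(mean = 0.8, sd = 0),
                        n = 50, seed = 1)
  expect_true(all(fixed$delta_cost == 500))
  expect_true(all(fixed$delta_eff == 0.8 - 0.5))

  args <- list(list(mean = 11544, sd = 9137), list(mean = 14043, sd = 3822),
               list(mean = 0.729, sd = 0.071), list(mean = 0.867, sd = 0.039))
  a <- do.call(psa_simulate, c(args, n = 2000, seed = 5))
  b <- do.call(psa_simulate, c(args, n = 2000, seed = 5))
  expect_identical(a, b)
  # CLT check on the package's own generator
  expect_lt(abs(mean(a$delta_cost) - 2499),
            2 * sqrt(9137^2 + 3822^2) / sqrt(2000))
  expect_error(psa_simulate(list(mean = 1), list(mean = 2, sd = 1),
                            list(mean = 0, sd = 1), list(mean = 1, sd = 1)),
               "mean and sd")
})

test_that("cost-effectiveness probability and dominance match hand evaluation", {
  hand <- tibble::tibble(delta_eff = c(0.1, 0.1, -0.1),
                         delta_cost = c(1000, 5000, 100))
  # NMB at 24,000: 1400 > 0; -2600 < 0; -2500 < 0
  expect_equal(prob_cost_effective(hand, 24000), 1 / 3)
  dominant <- tibble::tibble(delta_eff = c(1, 2), delta_cost = c(-1, -2))
  expect_equal(prob_cost_effective(dominant, 100), 1)
  dominated <- tibble::tibble(delta_eff = c(-1, -2), delta_cost = c(1, 2))
  expect_equal(prob_cost_effective(dominated, 100), 0)

  mixed <- tibble::tibble(delta_eff = c(0.1, 0.1, -0.1),
                          delta_cost = c(-10, 5, -5))
  expect_equal(dominance_fraction(mixed), 1 / 3)
  expect_equal(dominance_fraction(dominant), 1)
  expect_equal(dominance_fraction(tibble::tibble(delta_eff = 1, delta_cost = 1)), 0)
})

test_that("the acceptability curve is consistent with pointwise probabilities", {
  set.seed(11)
  samples <- tibble::tibble(delta_eff = runif(500, 0.01, 1),
                            delta_cost = rnorm(500, 2000, 3000))
  one <- ceac(samples, 24000)
  expect_equal(one$probability, prob_cost_effective(samples, 24000))
  curve <- ceac(samples, seq(1000, 50000, by = 1000))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # with every delta_eff > 0 the curve is non-decreasing in WTP
  expect_true(all(diff(curve$probability) >= 0))
  expect_equal(ceac(tibble::tibble(delta_eff = c(1, 1), delta_cost = c(-1, -2)),
                    c(10, 100, 1000))$probability, c(1, 1, 1))
  expect_error(ceac(samples, c(-1, 5)), "positive")
  # shifting every incremental cost upward never raises the probability
  for (shift in c(500, 2000, 10000)) {
    shifted <- samples
    shifted$delta_cost <- shifted$delta_cost + shift
    expect_lte(prob_cost_effective(shifted, 24000),
               prob_cost_effective(samples, 24000))
  }
})

test_that("Cohen's d follows the paired conventions and magnitude bands", {
  same <- cohens_d(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$d, 0)
  expect_equal(same$band, "insignificant")
  expect_equal(cohens_d(c(6, 5, 4), c(1, 1, 1), convention = "pooled")$d,
               4 / sqrt((1 + 0) / 2))
  pre <- c(6, 5, 4, 7); post <- c(2, 3, 1, 2)
  expect_equal(cohens_d(pre, post)$d, mean(pre - post) / sd(pre - post))
  expect_equal(cohens_d(pre, post, convention = "baseline_sd")$d,
               mean(pre - post) / sd(pre))
  es <- cohens_d(pre, post, reps = 500, seed = 2)
  expect_lte(es$ci_low, es$d)
  expect_gte(es$ci_high, es$d)
  expect_error(cohens_d(c(1, 1, 1), c(0, 0, 0)), "undefined")
  expect_error(cohens_d(1, 2), "length")
})

test_that("effect-size bands partition the line with 1.45 assigned upward", {
  d_to_band <- function(d) prepostCE:::effect_size_band(d)
  expect_equal(d_to_band(0.1), "insignificant")
  expect_equal(d_to_band(0.15), "small")
  expect_equal(d_to_band(0.5), "medium")
  expect_equal(d_to_band(-0.5), "medium")
  expect_equal(d_to_band(0.8), "large")
  expect_equal(d_to_band(1.2), "very_large")
  expect_equal(d_to_band(1.45), "enormous")
  expect_equal(d_to_band(3), "enormous")
  grid <- seq(-3, 3, by = 0.01)
  expect_false(any(is.na(vapply(grid, d_to_band, character(1)))))
})
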