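test_that("empty cohort and invalid parameters are handled", {
  p <- default_cohort_params(n = 0)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 0)
  expect_true(all(c("patient_id", "period", "act_score") %in% names(co)))

  expect_error(cohort_params(n = -1, marginals = default_cohort_params()$marginals),
               "n must be")
  mg_bad <- data.frame(variable = "x", period = "baseline", family = "gamma",
                       mean = 1, sd = -1, lower = 0, upper = Inf)
  expect_error(cohort_params(n = 2, marginals = mg_bad), "sd")
  mg_deg <- data.frame(variable = "x", period = "baseline", family = "normal",
                       mean = 1, sd = 2, lower = 3, upper = 3)
  expect_error(cohort_params(n = 2, marginals = mg_deg), "degenerate")
  p2 <- default_cohort_params()
  p2$correlations$rho[1] <- 1.5
  expect_error(generate_cohort(p2))
})

test_that("same seed reproduces the cohort bit for bit, different seeds differ", {
  p <- default_cohort_params(n = 30)
  a <- generate_cohort(p, seed = 5)
  b <- generate_cohort(p, seed = 5)
  c <- generate_cohort(p, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("generated records satisfy the patient-record invariants", {
  for (s in 1:3) {
    co <- generate_cohort(default_cohort_params(n = 150), seed = s)
    expect_true(all(co$act_score >= 5 & co$act_score <= 25))
    expect_true(all(co$act_score == round(co$act_score)))
    counts <- c("severe_exacerbations", "ed_visits", "admissions",
                "hospital_days", "ocs_courses")
    for (v in counts) {
      expect_true(all(co[[v]] >= 0 & co[[v]] == round(co[[v]])))
    }
    expect_true(all(co$ocs_maintenance_mg_day >= 0))
    expect_true(all(co$ics_ug_day >= 0))
    expect_true(all(co$fev1_ml > 0 & co$fev1_pct > 0))
    # flag consistency: dependence implies a positive maintenance dose
    expect_true(all(co$ocs_maintenance_mg_day[co$corticosteroid_dependent] > 0))
    # fully paired
    expect_equal(sum(co$period == "baseline"), sum(co$period == "treatment"))
    expect_setequal(co$patient_id[co$period == "baseline"],
                    co$patient_id[co$period == "treatment"])
  }
})

test_that("a 44-patient cohort recovers the calibration means within 2 SE", {
  co <- generate_cohort(default_cohort_params(), seed = 1)
  b <- co[co$period == "baseline", ]
  expect_equal(nrow(b), 44)
  # 2 SE bands around the published baseline means
  expect_lt(abs(mean(b$severe_exacerbations) - 5.50), 2 * 2.63 / sqrt(44))
  expect_lt(abs(mean(b$act_score) - 13.71), 2 * 4.01 / sqrt(44))
  expect_lt(abs(mean(b$ocs_maintenance_mg_day) - 19.3), 2 * 8.8 / sqrt(44))
  t <- co[co$period == "treatment", ]
  expect_lt(abs(mean(t$severe_exacerbations) - 0.66), 2 * 0.94 / sqrt(44))
  expect_true(all(t$biologic == "benralizumab"))
})

test_that("the calibration preset encodes the published summary statistics", {
  p <- default_cohort_params()
  expect_equal(p$n, 44)
  mg <- p$marginals
  pick <- function(v, per, col) mg[[col]][mg$variable == v & mg$period == per]
  expect_equal(pick("severe_exacerbations", "treatment", "mean"), 0.66)
  expect_equal(pick("severe_exacerbations", "treatment", "sd"), 0.94)
  expect_equal(pick("ed_visits", "baseline", "mean"), 4.1)
  expect_equal(pick("cost_biologic", "treatment", "mean"), 12832.04)
  rho <- p$correlations
  expect_equal(rho$rho[rho$var1 == "severe_exacerbations" &
                       rho$var2 == "cost_ocs" & rho$period1 == "baseline" &
                       rho$period2 == "baseline"], 0.839)
})

test_that("cohort CSV and params YAML round-trip", {
  co <- generate_cohort(default_cohort_params(n = 10), seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  co2 <- read_cohort(f)
  expect_equal(as.data.frame(co2), as.data.frame(co), tolerance = 1e-12)

  p <- default_cohort_params(n = 10)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_params(p, fy)
  p2 <- read_cohort_params(fy)
  expect_equal(p2$n, p$n)
  expect_equal(p2$marginals$mean, p$marginals$mean)
  expect_equal(p2$correlations$rho, p$correlations$rho)
  expect_identical(generate_cohort(p2, seed = 9), generate_cohort(p, seed = 9))
})

test_that("moment-matched ACT marginal hits its targets exactly in distribution", {
  lat <- prepostCE:::act_match_latent(21.33, 2.21, 5, 25)
  mo <- prepostCE:::act_moments(lat$mu, lat$sigma, 5, 25)
  expect_equal(mo[["mean"]], 21.33, tolerance = 1e-4)
  expect_equal(mo[["sd"]], 2.21, tolerance = 1e-4)
})
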