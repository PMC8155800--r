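sched <- default_unit_costs()

test_that("first-year dose counts follow the regimen descriptors", {
  # q4w x 3 loading then q8w: weeks 0,4,8,16,24,32,40,48
  expect_equal(doses_in_first_year(sched$drugs$benralizumab$regimen), 8)
  # plain q4w: weeks 0,4,...,48
  expect_equal(doses_in_first_year(sched$drugs$mepolizumab$regimen), 13)
  expect_equal(doses_in_first_year(list(loading_doses = 0,
                                        maintenance_interval_weeks = 1)), 52)
  expect_error(doses_in_first_year(list(loading_doses = 0,
                                        maintenance_interval_weeks = 0)),
               "positive")
  expect_error(doses_in_first_year(list(loading_doses = 2,
                                        loading_interval_weeks = -1,
                                        maintenance_interval_weeks = 4)),
               "positive")
  # the per-dose price implied by the annual benralizumab cost
  expect_equal(sched$drugs$benralizumab$annual_cost / 8, 1720.33)
})

test_that("single-resource records are priced from the schedule", {
  one_ed <- patient_period_cost(list(ed_visits = 1), sched)
  expect_equal(one_ed$ed_visits, 144.24)
  expect_equal(one_ed$total, 144.24)

  empty <- patient_period_cost(list(), sched)
  expect_equal(empty$total, 0)
  expect_true(all(as.numeric(empty[1, ]) == 0))

  mixed <- patient_period_cost(
    list(ed_visits = 2, n_emergency_visit_observation = 1), sched)
  expect_equal(mixed$ed_visits, 2 * 144.24 + 392.03)

  biol <- patient_period_cost(list(biologic = "benralizumab"), sched)
  expect_equal(biol$biologic, 13762.64)
  both <- patient_period_cost(list(biologic = "omalizumab+mepolizumab"), sched)
  expect_equal(both$biologic, 17042.61 + 10661.43)

  expect_error(patient_period_cost(list(n_acupuncture = 1), sched),
               "acupuncture")
  expect_error(patient_period_cost(list(biologic = "aspirin"), sched),
               "aspirin")
})

test_that("totals are the exact category sum, in cents, for arbitrary records", {
  co <- generate_cohort(default_cohort_params(n = 25), seed = 8)
  for (i in seq_len(nrow(co))) {
    b <- patient_period_cost(co[i, ], sched)
    cats <- c(b$tests, b$ocs, b$ics, b$ed_visits, b$admissions, b$biologic)
    expect_identical(round(b$total * 100), round(sum(round(cats * 100))))
    expect_true(all(cats >= 0))
  }
})

test_that("adding a unit of any priced resource never decreases the total", {
  base <- list(ed_visits = 1, hospital_days = 2, ocs_courses = 1,
               ocs_maintenance_mg_day = 5, ics_ug_day = 400,
               n_spirometry_bd = 2)
  t0 <- patient_period_cost(base, sched)$total
  for (res in names(sched$resource_costs)) {
    rec <- base
    key <- paste0("n_", res)
    rec[[key]] <- (rec[[key]] %||% 0) + 1
    expect_gte(patient_period_cost(rec, sched)$total, t0)
  }
})

test_that("cohort cost summaries behave on degenerate and known inputs", {
  co <- toy_cohort(exac_b = c(4, 4), exac_t = c(1, 1),
                   cost_b = c(100, 300), cost_t = c(200, 200))
  s <- cohort_cost_summary(co, "baseline")
  expect_equal(s$mean[s$category == "total"], 200)
  # identical patients: zero SD everywhere
  co2 <- toy_cohort(exac_b = c(4, 4), exac_t = c(1, 1),
                    cost_b = c(250, 250), cost_t = c(100, 100))
  expect_true(all(cohort_cost_summary(co2, "baseline")$sd == 0))
  expect_error(cohort_cost_summary(co[0, ], "baseline"), "no records")
})

test_that("a calibrated cohort recovers the published annual totals", {
  co <- generate_cohort(default_cohort_params(), seed = 2)
  s_b <- cohort_cost_summary(co, "baseline")
  s_t <- cohort_cost_summary(co, "treatment")
  tot_b <- s_b$mean[s_b$category == "total"]
  tot_t <- s_t$mean[s_t$category == "total"]
  expect_lt(abs(tot_b - 11544), 2 * 9137 / sqrt(44))
  expect_lt(abs(tot_t - 14043), 2 * 3822 / sqrt(44))
})

test_that("schedules round-trip through YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_unit_costs(sched, fy)
  write_unit_costs(sched, fj)
  for (s2 in list(read_unit_costs(fy), read_unit_costs(fj))) {
    expect_equal(s2$resource_costs$emergency_visit, 144.24)
    expect_equal(s2$drugs$benralizumab$annual_cost, 13762.64)
    expect_equal(patient_period_cost(list(ed_visits = 1), s2)$total, 144.24)
  }
  # the packaged fixture matches the in-code default
  pkg_file <- system.file("extdata", "unit_costs_2020.yaml",
                          package = "prepostCE")
  expect_true(nzchar(pkg_file))
  s3 <- read_unit_costs(pkg_file)
  expect_equal(unlist(s3$resource_costs), unlist(sched$resource_costs))
})
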