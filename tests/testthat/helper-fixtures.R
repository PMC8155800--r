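# Fixture builders shared across tests. All cohorts are constructed in
# code; no data files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal paired cohort with explicit exacerbation counts, ACT scores and
# per-patient costs (carried in the cost_ed column; other categories 0).
toy_cohort <- function(exac_b, exac_t, cost_b, cost_t,
                       act_b = NULL, act_t = NULL) {
  n <- length(exac_b)
  if (is.null(act_b)) act_b <- rep(13, n)
  if (is.null(act_t)) act_t <- rep(21, n)
  mk <- function(period, exac, cost, act) tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)), period = period,
    act_score = act,
    severe_exacerbations = exac,
    ed_visits = 0, admissions = 0, hospital_days = 0,
    ocs_courses = 0, ocs_maintenance_mg_day = 0,
    corticosteroid_dependent = FALSE, ics_ug_day = 0,
    fev1_ml = 1500, fev1_pct = 70, biologic = "none",
    cost_tests = 0, cost_ocs = 0, cost_ics = 0,
    cost_ed = cost, cost_admissions = 0, cost_biologic = 0)
  rbind(mk("baseline", exac_b, cost_b, act_b),
        mk("treatment", exac_t, cost_t, act_t))
}

# One patient-period record for the response classifier.
resp_record <- function(exac, act, fev1_pct, fev1_ml, ocs) {
  list(severe_exacerbations = exac, act_score = act, fev1_pct = fev1_pct,
       fev1_ml = fev1_ml, ocs_maintenance_mg_day = ocs)
}

# Paired records guaranteed to land in a given response category.
category_pair <- function(category) {
  b <- resp_record(6, 13, 60, 1400, 20)
  t <- switch(category,
    complete_response = resp_record(0, 22, 85, 1900, 0),
    controlled_asthma = resp_record(1, 21, 70, 1600, 0),
    partial_response = resp_record(2, 18, 70, 1700, 8),
    no_response = resp_record(6, 14, 61, 1450, 16)
  )
  list(baseline = b, treatment = t)
}

# Cohort tibble whose patients fall into the requested categories.
category_cohort <- function(counts) {
  rows_b <- list(); rows_t <- list(); id <- 0
  for (cat in names(counts)) {
    for (k in seq_len(counts[[cat]])) {
      id <- id + 1
      pr <- category_pair(cat)
      rows_b[[id]] <- c(list(patient_id = sprintf("P%03d", id),
                             period = "baseline"), pr$baseline)
      rows_t[[id]] <- c(list(patient_id = sprintf("P%03d", id),
                             period = "treatment"), pr$treatment)
    }
  }
  dplyr::bind_rows(c(lapply(rows_b, tibble::as_tibble),
                     lapply(rows_t, tibble::as_tibble)))
}

# Random single-period record satisfying the generator's invariants, for
# property-style loops.
random_record <- function() {
  list(severe_exacerbations = sample(0:8, 1),
       act_score = sample(5:25, 1),
       fev1_pct = round(runif(1, 30, 110)),
       fev1_ml = round(runif(1, 800, 3000)),
       ocs_maintenance_mg_day = round(runif(1, 0, 30)))
}
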