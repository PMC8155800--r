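# Direct-cost accounting. All euro arithmetic is carried in integer cents
# and surfaces as euros rounded to the cent, so category totals are exact.

#' Unit-cost schedule
#'
#' Euro prices for healthcare resources and asthma drugs, 2020 Spanish
#' public-sector tariffs. `default_unit_costs()` returns the packaged
#' schedule; `read_unit_costs()`/`write_unit_costs()` round-trip a schedule
#' through YAML or JSON (by file extension).
#'
#' @details The schedule prices:
#' * resources per unit (emergency visit, observation, hospital day at the
#'   general and pneumology rates, spirometry with/without bronchodilation,
#'   IgE, FeNO, prick test, haemogram, biochemistry, non-contrast CT);
#' * biologics per treatment year (omalizumab, mepolizumab, benralizumab),
#'   with the benralizumab regimen descriptor (30 mg every 4 weeks for 3
#'   doses, then every 8 weeks);
#' * oral corticosteroids per 7-day course (5 mg and 30 mg strengths) and
#'   inhaled corticosteroid packs (200 ug x 200 puffs).
#'
#' Two pricing conventions are explicit parameters rather than hard-coded:
#' maintenance OCS is priced per mg-day scaled from the 5 mg course
#' (`ocs_mg_day_eur = 11.86 / 7 / 5`), and hospital days default to the
#' pneumology rate (`admission_rate = "hospital_day_pneumology"`).
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param schedule A `unit_cost_schedule` object.
#' @return A `unit_cost_schedule` object (list with `resource_costs`,
#'   `drugs`, OCS/ICS pricing fields, `currency_year`).
#' @examples
#' sched <- default_unit_costs()
#' sched$resource_costs[["emergency_visit"]]
#' @export
default_unit_costs <- function() {
  new_unit_cost_schedule(list(
    currency_year = 2020,
    resource_costs = list(
      emergency_visit = 144.24,
      emergency_visit_observation = 392.03,
      hospital_day = 495.59,
      hospital_day_pneumology = 386.65,
      spirometry = 40.57,
      spirometry_bd = 60.49,
      ige = 21.50,
      feno = 39.00,
      prick_test = 134.70,
      haemogram = 5.30,
      biochemistry = 83.50,
      ct_non_contrast = 55.38
    ),
    drugs = list(
      omalizumab = list(dose = "150 mg",
                        regimen = NULL,   # IgE/weight-based; annual cost as given
                        annual_cost = 17042.61),
      mepolizumab = list(dose = "100 mg",
                         regimen = list(loading_doses = 0,
                                        loading_interval_weeks = NA,
                                        maintenance_interval_weeks = 4),
                         annual_cost = 10661.43),
      benralizumab = list(dose = "30 mg",
                          regimen = list(loading_doses = 3,
                                         loading_interval_weeks = 4,
                                         maintenance_interval_weeks = 8),
                          annual_cost = 13762.64)
    ),
    ocs_course_5mg_eur = 11.86,
    ocs_course_30mg_eur = 23.73,
    ocs_course_eur = 23.73,          # price applied per recorded OCS course
    ocs_mg_day_eur = 11.86 / 7 / 5,  # maintenance: per mg prednisone per day
    ics_pack_eur = 36.96,
    ics_pack_ug = 200 * 200,         # 200 ug x 200 puffs
    admission_rate = "hospital_day_pneumology"
  ))
}

new_unit_cost_schedule <- function(x) {
  prices <- unlist(x$resource_costs)
  if (any(prices < 0)) stop_prepost("unit costs must be >= 0")
  structure(x, class = "unit_cost_schedule")
}

#' @export
print.unit_cost_schedule <- function(x, ...) {
  cat("<unit_cost_schedule>", length(x$resource_costs), "resources,",
      length(x$drugs), "drugs, euros of", x$currency_year, "\n")
  invisible(x)
}

#' @rdname default_unit_costs
#' @export
write_unit_costs <- function(schedule, path) {
  x <- unclass(schedule)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname default_unit_costs
#' @export
read_unit_costs <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  x$resource_costs <- as.list(x$resource_costs)
  new_unit_cost_schedule(x)
}

#' Number of drug administrations in the first treatment year
#'
#' Counts doses falling in weeks 0-51 inclusive, with the first dose at
#' week 0: `loading_doses` administrations every
#' `loading_interval_weeks`, then maintenance every
#' `maintenance_interval_weeks` starting one maintenance interval after
#' the last loading dose. With `loading_doses = 0` the maintenance
#' schedule starts at week 0.
#'
#' @param regimen List with `loading_doses`, `loading_interval_weeks`,
#'   `maintenance_interval_weeks`.
#' @return Integer dose count.
#' @examples
#' # benralizumab: 30 mg q4w x 3, then q8w -> weeks 0,4,8,16,24,32,40,48
#' doses_in_first_year(list(loading_doses = 3, loading_interval_weeks = 4,
#'                          maintenance_interval_weeks = 8))
#' @export
doses_in_first_year <- function(regimen) {
  ld <- regimen$loading_doses %||% 0
  li <- regimen$loading_interval_weeks
  mi <- regimen$maintenance_interval_weeks
  if (is.null(mi) || is.na(mi) || mi <= 0) {
    stop_prepost("maintenance interval must be a positive number of weeks")
  }
  if (ld > 0 && (is.null(li) || is.na(li) || li <= 0)) {
    stop_prepost("loading interval must be a positive number of weeks")
  }
  weeks <- if (ld > 0) (seq_len(ld) - 1) * li else numeric(0)
  start <- if (ld > 0) weeks[length(weeks)] + mi else 0
  weeks <- c(weeks, seq(start, 51, by = mi))
  sum(weeks < 52)
}

resource_category <- function(name) {
  ifelse(grepl("^emergency", name), "ed_visits",
         ifelse(grepl("^hospital_day", name), "admissions", "tests"))
}

#' Cost a single patient-period
#'
#' Converts one patient-period record into a per-category cost breakdown:
#' `tests` (diagnostic resource counts priced by the schedule), `ocs`
#' (courses plus maintenance dose), `ics` (annual microgram consumption
#' priced by pack), `ed_visits`, `admissions` (hospital days at the
#' configured rate), and `biologic` (annual cost of the recorded drug;
#' names joined with `+` are summed).
#'
#' @param record A one-row cohort tibble or named list for one
#'   patient-period (fields as in [generate_cohort()]).
#' @param schedule A [default_unit_costs()]-style schedule.
#' @param period Optional; if `record` has several rows, selects
#'   `"baseline"` or `"treatment"`.
#' @return A `cost_breakdown`: tibble with one row and columns `tests`,
#'   `ocs`, `ics`, `ed_visits`, `admissions`, `biologic`, `total`
#'   (euros, exact to the cent; `total` is the exact category sum).
#' @examples
#' sched <- default_unit_costs()
#' rec <- list(ed_visits = 1)
#' patient_period_cost(rec, sched)$ed_visits  # 144.24
#' @export
patient_period_cost <- function(record, schedule, period = NULL) {
  if (is.data.frame(record) && !is.null(period)) {
    record <- record[record$period == period, , drop = FALSE]
    if (nrow(record) != 1) stop_prepost("record must resolve to one row")
  }
  record <- as.list(record)
  num <- function(field) {
    v <- record[[field]]
    if (is.null(v) || length(v) == 0 || is.na(v)) 0 else as.numeric(v)
  }
  prices <- schedule$resource_costs
  cents <- c(tests = 0, ocs = 0, ics = 0, ed_visits = 0,
             admissions = 0, biologic = 0)

  # resource-use counts: columns n_<resource>
  rcols <- grep("^n_", names(record), value = TRUE)
  for (rc in rcols) {
    key <- sub("^n_", "", rc)
    if (is.null(prices[[key]])) {
      stop_prepost("resource '", key, "' is not priced in the schedule")
    }
    cat <- resource_category(key)
    cents[cat] <- cents[cat] + num(rc) * as_cents(prices[[key]])
  }
  cents["ed_visits"] <- cents["ed_visits"] +
    num("ed_visits") * as_cents(prices$emergency_visit)
  cents["admissions"] <- cents["admissions"] +
    num("hospital_days") * as_cents(prices[[schedule$admission_rate]])
  cents["ocs"] <- cents["ocs"] +
    num("ocs_courses") * as_cents(schedule$ocs_course_eur) +
    round(num("ocs_maintenance_mg_day") * 365 * schedule$ocs_mg_day_eur * 100)
  cents["ics"] <- cents["ics"] +
    round(num("ics_ug_day") * 365 / schedule$ics_pack_ug *
            schedule$ics_pack_eur * 100)
  drug <- record$biologic
  if (!is.null(drug) && !is.na(drug) && nzchar(drug) && drug != "none") {
    for (d in strsplit(drug, "+", fixed = TRUE)[[1]]) {
      if (is.null(schedule$drugs[[d]])) {
        stop_prepost("drug '", d, "' is not priced in the schedule")
      }
      cents["biologic"] <- cents["biologic"] +
        as_cents(schedule$drugs[[d]]$annual_cost)
    }
  }
  cents <- round(cents)
  out <- tibble::as_tibble(as.list(cents_to_euros(cents)))
  out$total <- cents_to_euros(sum(cents))
  class(out) <- c("cost_breakdown", class(out))
  out
}

#' Per-category cost summary over a cohort
#'
#' Mean and SD per cost category (plus total) across patients in one
#' period. `basis = "generated"` summarises the generator's calibrated
#' `cost_*` columns; `basis = "computed"` prices each record through
#' [patient_period_cost()] with `schedule`.
#'
#' @param cohort Cohort tibble (one row per patient-period).
#' @param period `"baseline"` or `"treatment"`.
#' @param schedule Required for `basis = "computed"`.
#' @param basis `"generated"` or `"computed"`.
#' @return Tibble with columns `category`, `mean`, `sd`.
#' @export
cohort_cost_summary <- function(cohort, period,
                                basis = c("generated", "computed"),
                                schedule = NULL) {
  basis <- match.arg(basis)
  rows <- cohort[cohort$period == period, , drop = FALSE]
  if (nrow(rows) == 0) stop_prepost("no records for period '", period, "'")
  cats <- c("tests", "ocs", "ics", "ed_visits", "admissions", "biologic")
  if (basis == "generated") {
    cols <- c(tests = "cost_tests", ocs = "cost_ocs", ics = "cost_ics",
              ed_visits = "cost_ed", admissions = "cost_admissions",
              biologic = "cost_biologic")
    if (!all(cols %in% names(rows))) {
      stop_prepost("cohort lacks generated cost_* columns; ",
                   "use basis = 'computed' with a schedule")
    }
    m <- as.data.frame(rows[, cols])
    names(m) <- cats
  } else {
    if (is.null(schedule)) stop_prepost("basis = 'computed' needs a schedule")
    m <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      as.data.frame(patient_period_cost(rows[i, ], schedule))[cats]
    }))
  }
  m$total <- rowSums(m)
  tibble::tibble(
    category = c(cats, "total"),
    mean = unname(vapply(m, mean, numeric(1))),
    sd = if (nrow(m) > 1) unname(vapply(m, sd, numeric(1))) else rep(0, ncol(m))
  )
}

#' Per-patient total annual cost for a period
#'
#' Sums each patient's cost categories for one period. `cost_basis =
#' "total"` uses all categories; `"exacerbation_related"` excludes
#' scheduled diagnostics and ICS (total minus tests minus ics), the
#' package's documented reading of an exacerbation-driven cost aggregate.
#' Generated `cost_*` columns are used when present; otherwise records are
#' priced through [patient_period_cost()] with `schedule`.
#'
#' @param cohort Cohort tibble.
#' @param period `"baseline"` or `"treatment"`.
#' @param cost_basis `"total"` or `"exacerbation_related"`.
#' @param schedule Optional [default_unit_costs()]-style schedule.
#' @return Named numeric vector (euros), ordered by `patient_id`.
#' @export
patient_total_costs <- function(cohort, period,
                                cost_basis = c("total", "exacerbation_related"),
                                schedule = NULL) {
  cost_basis <- match.arg(cost_basis)
  rows <- cohort[cohort$period == period, , drop = FALSE]
  rows <- rows[order(rows$patient_id), , drop = FALSE]
  cols <- c("cost_tests", "cost_ocs", "cost_ics", "cost_ed",
            "cost_admissions", "cost_biologic")
  if (all(cols %in% names(rows))) {
    tot <- rowSums(as.data.frame(rows[, cols]))
    if (cost_basis == "exacerbation_related") {
      tot <- tot - rows$cost_tests - rows$cost_ics
    }
  } else {
    if (is.null(schedule)) {
      stop_prepost("cohort lacks cost_* columns; supply a schedule")
    }
    tot <- vapply(seq_len(nrow(rows)), function(i) {
      b <- patient_period_cost(rows[i, ], schedule)
      if (cost_basis == "exacerbation_related") {
        b$total - b$tests - b$ics
      } else b$total
    }, numeric(1))
  }
  setNames(tot, rows$patient_id)
}
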