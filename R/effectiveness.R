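# Effectiveness measures and biologic-response classification for severe
# asthma. The Asthma Control Test (ACT) runs from 5 (uncontrolled) to 25
# (complete control); a score >= 20 denotes controlled asthma and a
# 3-point gain is the minimal clinically important difference (MCID).

check_act <- function(act) {
  if (any(!is.finite(act)) || any(act < 5) || any(act > 25)) {
    stop_prepost("ACT score must lie in [5, 25]")
  }
  act
}

#' ACT effectiveness rate
#'
#' Effectiveness expressed as the fraction of the full ACT scale achieved:
#' score / 25.
#'
#' @param act_score ACT score(s) in \[5, 25\].
#' @return Numeric in \[0.2, 1\].
#' @examples
#' act_effectiveness_rate(c(13.71, 21.33))
#' @export
act_effectiveness_rate <- function(act_score) {
  check_act(act_score) / 25
}

#' Controlled asthma (ACT >= 20)
#'
#' @param act_score ACT score(s) in \[5, 25\].
#' @return Logical.
#' @export
is_controlled <- function(act_score) {
  check_act(act_score) >= 20
}

#' Minimal clinically important ACT difference reached
#'
#' TRUE when the post score exceeds the pre score by at least 3 points.
#'
#' @param act_pre,act_post ACT scores in \[5, 25\].
#' @param mcid Point gain regarded clinically important (default 3).
#' @return Logical.
#' @export
mcid_reached <- function(act_pre, act_post, mcid = 3) {
  check_act(act_pre); check_act(act_post)
  (act_post - act_pre) >= mcid
}

#' Response-classification rule set
#'
#' Thresholds for the four Spanish-consensus response categories, exposed
#' as data so the (ambiguously published) partial-response predicate can
#' be overridden. Categories are evaluated best-to-worst with conjunctive
#' criteria; the first full match wins.
#'
#' * complete: zero severe exacerbations, ACT >= `act_controlled`, FEV1 >=
#'   `fev1_pct_complete` % predicted, maintenance OCS discontinued;
#' * controlled: <= `max_exac_controlled` severe exacerbations, ACT >=
#'   `act_controlled`, OCS discontinued (FEV1 unconstrained);
#' * partial: exacerbation criterion (reduction >= `partial_exac_reduction`
#'   or fewer than `partial_exac_count_lt` exacerbations), AND a
#'   symptomatic/functional gain (ACT gain >= `mcid`, or ACT >=
#'   `act_controlled`, or FEV1 gain > `fev1_gain_ml` mL and >
#'   `fev1_gain_rel` of baseline), AND OCS dose reduced by more than
#'   `partial_ocs_reduction` (or discontinued);
#' * no_response otherwise.
#'
#' @param ... Override any default threshold by name.
#' @return A named list of thresholds.
#' @export
response_rules <- function(...) {
  rules <- list(
    act_controlled = 20,
    mcid = 3,
    fev1_pct_complete = 80,
    max_exac_controlled = 1,
    partial_exac_reduction = 0.5,
    partial_exac_count_lt = 2,
    fev1_gain_ml = 100,
    fev1_gain_rel = 0.10,
    partial_ocs_reduction = 0.5
  )
  mods <- list(...)
  bad <- setdiff(names(mods), names(rules))
  if (length(bad)) stop_prepost("unknown rule(s): ", paste(bad, collapse = ", "))
  utils::modifyList(rules, mods)
}

response_levels <- c("no_response", "partial_response",
                     "controlled_asthma", "complete_response")

#' Classify the response to a biologic treatment year
#'
#' Applies the rule set of [response_rules()] to one patient's paired
#' baseline and treatment records.
#'
#' @param baseline,treatment Named lists or one-row data frames with
#'   `severe_exacerbations`, `act_score`, `fev1_pct`, `fev1_ml`,
#'   `ocs_maintenance_mg_day`.
#' @param rules A [response_rules()] list.
#' @return A list with `category` (factor over the four levels) and the
#'   individual `criteria` booleans.
#' @examples
#' b <- list(severe_exacerbations = 6, act_score = 13, fev1_pct = 60,
#'           fev1_ml = 1400, ocs_maintenance_mg_day = 20)
#' t <- list(severe_exacerbations = 0, act_score = 22, fev1_pct = 85,
#'           fev1_ml = 1900, ocs_maintenance_mg_day = 0)
#' classify_response(b, t)$category
#' @export
classify_response <- function(baseline, treatment, rules = response_rules()) {
  b <- as.list(baseline); t <- as.list(treatment)
  need <- c("severe_exacerbations", "act_score", "fev1_pct", "fev1_ml",
            "ocs_maintenance_mg_day")
  for (f in need) {
    if (is.null(b[[f]]) || is.null(t[[f]]) ||
        is.na(b[[f]]) || is.na(t[[f]])) {
      stop_prepost("classification needs field '", f, "' in both periods")
    }
  }
  check_act(c(b$act_score, t$act_score))
  exac_red <- if (b$severe_exacerbations > 0) {
    (b$severe_exacerbations - t$severe_exacerbations) / b$severe_exacerbations
  } else if (t$severe_exacerbations == 0) 1 else -Inf
  ocs_stopped <- t$ocs_maintenance_mg_day == 0
  ocs_red <- if (b$ocs_maintenance_mg_day > 0) {
    (b$ocs_maintenance_mg_day - t$ocs_maintenance_mg_day) /
      b$ocs_maintenance_mg_day
  } else if (ocs_stopped) 1 else -Inf
  fev1_gain <- t$fev1_ml - b$fev1_ml

  crit <- list(
    zero_exacerbations = t$severe_exacerbations == 0,
    act_controlled = t$act_score >= rules$act_controlled,
    fev1_at_least_80pct = t$fev1_pct >= rules$fev1_pct_complete,
    ocs_discontinued = ocs_stopped,
    exac_at_most_1 = t$severe_exacerbations <= rules$max_exac_controlled,
    exac_improved = exac_red >= rules$partial_exac_reduction ||
      t$severe_exacerbations < rules$partial_exac_count_lt,
    act_mcid = (t$act_score - b$act_score) >= rules$mcid,
    fev1_gain = fev1_gain > rules$fev1_gain_ml &&
      fev1_gain > rules$fev1_gain_rel * b$fev1_ml,
    ocs_halved = ocs_red > rules$partial_ocs_reduction || ocs_stopped
  )

  category <- if (crit$zero_exacerbations && crit$act_controlled &&
                  crit$fev1_at_least_80pct && crit$ocs_discontinued) {
    "complete_response"
  } else if (crit$exac_at_most_1 && crit$act_controlled &&
             crit$ocs_discontinued) {
    "controlled_asthma"
  } else if (crit$exac_improved &&
             (crit$act_mcid || crit$act_controlled || crit$fev1_gain) &&
             crit$ocs_halved) {
    "partial_response"
  } else {
    "no_response"
  }
  list(category = factor(category, levels = response_levels),
       criteria = crit)
}

#' Classify every patient in a cohort
#'
#' @param cohort Cohort tibble with paired baseline/treatment rows.
#' @param rules A [response_rules()] list.
#' @return Tidy tibble: `patient_id`, `category`, and one logical column
#'   per criterion (suitable for an audit CSV).
#' @export
classify_cohort <- function(cohort, rules = response_rules()) {
  ids <- unique(cohort$patient_id)
  rows <- lapply(ids, function(id) {
    b <- cohort[cohort$patient_id == id & cohort$period == "baseline", ]
    t <- cohort[cohort$patient_id == id & cohort$period == "treatment", ]
    if (nrow(b) != 1 || nrow(t) != 1) {
      stop_prepost("patient ", id, " lacks paired baseline/treatment rows")
    }
    cl <- classify_response(b, t, rules)
    tibble::as_tibble(c(list(patient_id = id,
                             category = as.character(cl$category)),
                        cl$criteria))
  })
  out <- dplyr::bind_rows(rows)
  out$category <- factor(out$category, levels = response_levels)
  out
}

#' Response-category counts for a cohort
#'
#' @inheritParams classify_cohort
#' @return Named integer vector over all four categories (sums to the
#'   number of patients).
#' @export
cohort_response_counts <- function(cohort, rules = response_rules()) {
  if (nrow(cohort) == 0) {
    return(setNames(integer(length(response_levels)), response_levels))
  }
  cl <- classify_cohort(cohort, rules)
  table(cl$category)
}
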