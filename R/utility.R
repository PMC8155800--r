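# Health-state utility and QALY accounting over the 1-year horizon.

#' Utility map from asthma control to EQ-5D-style utility
#'
#' Published Spanish utility weights for severe asthma: 0.91 when
#' controlled (ACT >= 20), 0.73 when uncontrolled. Two mappings are
#' provided because the dichotomous map cannot reproduce every published
#' cohort-mean utility:
#' * `"dichotomous"` (default, the stated method): 0.91 if ACT >= 20,
#'   else 0.73;
#' * `"act_linear"`: linear in ACT between (5, uncontrolled) and
#'   (25, controlled).
#'
#' @param utility_controlled,utility_uncontrolled Utility weights in
#'   \[0, 1\] with controlled >= uncontrolled.
#' @param mode `"dichotomous"` or `"act_linear"`.
#' @param horizon_years Time horizon (no discounting; default 1).
#' @return A `utility_map` object.
#' @export
utility_map <- function(utility_controlled = 0.91,
                        utility_uncontrolled = 0.73,
                        mode = c("dichotomous", "act_linear"),
                        horizon_years = 1) {
  mode <- match.arg(mode)
  if (utility_controlled < 0 || utility_controlled > 1 ||
      utility_uncontrolled < 0 || utility_uncontrolled > 1) {
    stop_prepost("utilities must lie in [0, 1]")
  }
  if (utility_controlled < utility_uncontrolled) {
    stop_prepost("controlled utility must be >= uncontrolled utility")
  }
  if (horizon_years < 0) stop_prepost("horizon must be >= 0")
  structure(list(utility_controlled = utility_controlled,
                 utility_uncontrolled = utility_uncontrolled,
                 mode = mode, horizon_years = horizon_years),
            class = "utility_map")
}

#' Patient utility from the ACT score
#'
#' @param act_score ACT score(s) in \[5, 25\].
#' @param map A [utility_map()].
#' @return Utilities in `[utility_uncontrolled, utility_controlled]`.
#' @examples
#' patient_utility(c(19, 22), utility_map())
#' @export
patient_utility <- function(act_score, map = utility_map()) {
  check_act(act_score)
  switch(map$mode,
    dichotomous = ifelse(act_score >= 20, map$utility_controlled,
                         map$utility_uncontrolled),
    act_linear = map$utility_uncontrolled +
      (act_score - 5) / 20 *
        (map$utility_controlled - map$utility_uncontrolled)
  )
}

#' Quality-adjusted life-years over a horizon
#'
#' Utility times years; no discounting (the analysis horizon is one
#' year).
#'
#' @param utility Utility weight(s) in \[0, 1\].
#' @param horizon_years Years.
#' @return QALYs.
#' @export
qalys <- function(utility, horizon_years = 1) {
  if (any(utility < 0 | utility > 1)) stop_prepost("utility must be in [0, 1]")
  if (any(horizon_years < 0)) stop_prepost("horizon must be >= 0")
  utility * horizon_years
}

#' Incremental utility between treatment and baseline periods
#'
#' Difference of cohort mean utilities (treatment minus baseline), each
#' derived from ACT scores through `map`.
#'
#' @param cohort Cohort tibble with paired periods.
#' @param map A [utility_map()].
#' @return A list with `baseline_mean`, `treatment_mean`, `increment`.
#' @export
incremental_utility <- function(cohort, map = utility_map()) {
  u_b <- patient_utility(cohort$act_score[cohort$period == "baseline"], map)
  u_t <- patient_utility(cohort$act_score[cohort$period == "treatment"], map)
  if (!length(u_b) || !length(u_t)) {
    stop_prepost("cohort must contain both periods")
  }
  list(baseline_mean = mean(u_b), treatment_mean = mean(u_t),
       increment = mean(u_t) - mean(u_b))
}
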