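# Deterministic cost-effectiveness arithmetic: incremental ratios,
# cost-effectiveness-plane quadrants, net monetary and net health benefit.

#' Incremental cost-effectiveness ratio
#'
#' `(cost_post - cost_pre) / (eff_post - eff_pre)`, euros per
#' effectiveness unit. A zero effectiveness difference leaves the ratio
#' undefined: the function returns `NA` with a warning pointing to the
#' net-benefit statistics, never an infinity.
#'
#' @param cost_pre,cost_post Euros per patient per year.
#' @param eff_pre,eff_post Effectiveness in the chosen measure's units.
#' @return Euros per effectiveness unit (unrounded), or `NA` if the
#'   effectiveness difference is zero.
#' @examples
#' icer(11544, 14043, 13.71, 21.33)   # euros per ACT point
#' @export
icer <- function(cost_pre, cost_post, eff_pre, eff_post) {
  de <- eff_post - eff_pre
  if (isTRUE(all(de == 0))) {
    warning("effectiveness difference is zero: ICER undefined; ",
            "use nmb()/nhb() for decision-making", call. = FALSE)
    return(NA_real_)
  }
  (cost_post - cost_pre) / de
}

#' Cost of a k-point gain in an effectiveness score
#'
#' `k` times the per-point ICER, e.g. the cost of the 3-point minimal
#' clinically important ACT difference.
#'
#' @inheritParams icer
#' @param k Number of points.
#' @return Euros.
#' @examples
#' cost_per_k_points(11544, 14043, 13.71, 21.33, k = 3)
#' @export
cost_per_k_points <- function(cost_pre, cost_post, eff_pre, eff_post, k) {
  k * icer(cost_pre, cost_post, eff_pre, eff_post)
}

#' Cost-effectiveness ratio against a fractional effect
#'
#' Incremental cost divided by an effect expressed as a fraction of a
#' whole patient-equivalent (e.g. the relative reduction in exacerbations,
#' or the gain in the ACT effectiveness rate): the cost of achieving the
#' full effect in one patient.
#'
#' @param delta_cost Incremental cost, euros.
#' @param fraction_effect Fraction in (0, 1].
#' @return Euros per whole-patient-equivalent.
#' @examples
#' cer_fractional(2912, 0.8814)
#' @export
cer_fractional <- function(delta_cost, fraction_effect) {
  if (any(fraction_effect <= 0 | fraction_effect > 1)) {
    stop_prepost("fraction_effect must lie in (0, 1]")
  }
  delta_cost / fraction_effect
}

#' Net monetary benefit
#'
#' `delta_eff * wtp - delta_cost`: the monetary value of the incremental
#' effect at the willingness-to-pay threshold, minus the incremental
#' cost. Positive values indicate a cost-effective intervention.
#'
#' @param delta_eff Incremental effectiveness.
#' @param delta_cost Incremental cost, euros.
#' @param wtp Willingness to pay, euros per effectiveness unit (> 0).
#' @return Euros.
#' @examples
#' nmb(0.138, 2499, 24000)
#' @export
nmb <- function(delta_eff, delta_cost, wtp) {
  if (any(wtp <= 0)) stop_prepost("wtp must be > 0")
  delta_eff * wtp - delta_cost
}

#' Net health benefit
#'
#' `delta_eff - delta_cost / wtp`: the incremental effect net of the
#' health displaced elsewhere by funding the incremental cost. Identical
#' to `nmb() / wtp`.
#'
#' @inheritParams nmb
#' @return Effectiveness units.
#' @examples
#' nhb(0.138, 2499, 24000)
#' @export
nhb <- function(delta_eff, delta_cost, wtp) {
  if (any(wtp <= 0)) stop_prepost("wtp must be > 0")
  delta_eff - delta_cost / wtp
}

#' Cost-effectiveness plane quadrant and decision label
#'
#' Partitions (incremental effectiveness, incremental cost) pairs:
#' NE (more effective, more costly: trade-off), SE (more effective, less
#' costly: dominant), NW (less effective, more costly: dominated), SW
#' (less effective, less costly: trade-off). Axis cases are resolved so
#' the labelling is total: equal effectiveness with lower (higher) cost is
#' dominant (dominated), as is equal cost with higher (lower)
#' effectiveness; the origin is labelled equivalent.
#'
#' @param delta_eff,delta_cost Incremental effectiveness and cost
#'   (vectorised).
#' @return Tibble with `delta_eff`, `delta_cost`, `quadrant`
#'   (NE/SE/NW/SW/origin), `decision`
#'   (trade-off/dominant/dominated/equivalent).
#' @examples
#' plane_quadrant(c(0.138, 1, -1), c(2499, -1, 1))
#' @export
plane_quadrant <- function(delta_eff, delta_cost) {
  quadrant <- ifelse(delta_eff > 0 & delta_cost > 0, "NE",
              ifelse(delta_eff > 0 & delta_cost < 0, "SE",
              ifelse(delta_eff < 0 & delta_cost > 0, "NW",
              ifelse(delta_eff < 0 & delta_cost < 0, "SW",
              # axis cases
              ifelse(delta_eff == 0 & delta_cost < 0, "SE",
              ifelse(delta_eff == 0 & delta_cost > 0, "NW",
              ifelse(delta_eff > 0, "SE",
              ifelse(delta_eff < 0, "NW", "origin"))))))))
  decision <- ifelse(quadrant %in% c("NE", "SW"), "trade-off",
              ifelse(quadrant == "SE", "dominant",
              ifelse(quadrant == "NW", "dominated", "equivalent")))
  tibble::tibble(delta_eff = delta_eff, delta_cost = delta_cost,
                 quadrant = quadrant, decision = decision)
}

#' Full deterministic cost-effectiveness result
#'
#' Computes the incremental cost and effectiveness, the ICER (or `NA`
#' when undefined), the plane quadrant with its decision label, and the
#' net monetary and net health benefit at the given threshold.
#'
#' @inheritParams icer
#' @param wtp Willingness-to-pay threshold, euros per effectiveness unit.
#' @param measure Free-text name of the effectiveness measure (carried
#'   into the result for reporting).
#' @return A `ce_result` list: `measure`, `delta_cost`, `delta_eff`,
#'   `icer`, `quadrant`, `decision`, `wtp`, `nmb`, `nhb`.
#' @examples
#' ce_result(11544, 14043, 0.729, 0.867, wtp = 24000, measure = "utility")
#' @export
ce_result <- function(cost_pre, cost_post, eff_pre, eff_post,
                      wtp = 24000, measure = "effectiveness") {
  de <- eff_post - eff_pre
  dc <- cost_post - cost_pre
  q <- plane_quadrant(de, dc)
  structure(list(
    measure = measure,
    delta_cost = dc,
    delta_eff = de,
    icer = if (de == 0) NA_real_ else dc / de,
    quadrant = q$quadrant,
    decision = q$decision,
    wtp = wtp,
    nmb = nmb(de, dc, wtp),
    nhb = nhb(de, dc, wtp)
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>", x$measure, "\n")
  cat(sprintf("  dC = %.2f EUR  dE = %.4f  (%s: %s)\n",
              x$delta_cost, x$delta_eff, x$quadrant, x$decision))
  cat(sprintf("  ICER = %s EUR/unit\n",
              if (is.na(x$icer)) "undefined" else format(round(x$icer, 2))))
  cat(sprintf("  NMB = %.2f EUR, NHB = %.4f at WTP %.0f\n",
              x$nmb, x$nhb, x$wtp))
  invisible(x)
}

#' Serialise a ce_result to JSON
#'
#' @param x A [ce_result()].
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
ce_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "ce_result"))
  if (is.null(path)) {
    jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
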