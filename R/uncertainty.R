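# Uncertainty quantification: percentile-bootstrap confidence intervals
# for ratio statistics, first-order Monte Carlo probabilistic sensitivity
# analysis (PSA), acceptability curves, dominance fractions, and paired
# effect sizes.

effectiveness_measures <- c("exacerbations_avoided", "act_points",
                            "act_rate", "utility")

# Per-patient effectiveness difference (treatment improvement) for a
# measure, ordered by patient_id.
patient_eff_diffs <- function(cohort, measure, map = utility_map()) {
  measure <- match.arg(measure, effectiveness_measures)
  b <- cohort[cohort$period == "baseline", ]
  t <- cohort[cohort$period == "treatment", ]
  b <- b[order(b$patient_id), ]; t <- t[order(t$patient_id), ]
  if (!identical(b$patient_id, t$patient_id)) {
    stop_prepost("cohort is not fully paired across periods")
  }
  switch(measure,
    exacerbations_avoided = b$severe_exacerbations - t$severe_exacerbations,
    act_points = t$act_score - b$act_score,
    act_rate = (t$act_score - b$act_score) / 25,
    utility = patient_utility(t$act_score, map) -
      patient_utility(b$act_score, map)
  )
}

#' Percentile-bootstrap confidence interval for the cohort ICER
#'
#' Resamples patients with replacement (paired baseline/treatment records
#' stay together, resample size equals the cohort size), recomputes the
#' ICER in each replicate as mean incremental cost over mean incremental
#' effectiveness, and returns the 2.5th and 97.5th percentiles (for
#' `conf = 0.95`). Replicates with zero mean incremental effectiveness
#' have no defined ratio; they are dropped and counted. Setting
#' `statistic = "nmb"` bootstraps the net monetary benefit instead, which
#' has no degenerate replicates.
#'
#' @param cohort Paired cohort tibble.
#' @param measure One of `"exacerbations_avoided"`, `"act_points"`,
#'   `"act_rate"`, `"utility"`.
#' @param cost_basis `"total"` (all cost categories) or
#'   `"exacerbation_related"` (total minus scheduled diagnostics and ICS).
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param statistic `"icer"` (default) or `"nmb"`.
#' @param wtp Threshold used when `statistic = "nmb"`.
#' @param conf Confidence level.
#' @param map [utility_map()] used for the utility measure.
#' @return List of class `boot_ci`: `statistic`, `measure`, `point`,
#'   `lower`, `upper`, `reps`, `dropped` (degenerate replicates), `seed`,
#'   `conf`.
#' @export
bootstrap_icer_ci <- function(cohort, measure = "exacerbations_avoided",
                              cost_basis = "total", reps = 10000,
                              seed = 1, statistic = c("icer", "nmb"),
                              wtp = 24000, conf = 0.95,
                              map = utility_map()) {
  statistic <- match.arg(statistic)
  if (reps < 1) stop_prepost("reps must be >= 1")
  d_e <- patient_eff_diffs(cohort, measure, map)
  n <- length(d_e)
  if (n < 2) stop_prepost("bootstrap needs a cohort of at least 2 patients")
  d_c <- patient_total_costs(cohort, "treatment", cost_basis) -
    patient_total_costs(cohort, "baseline", cost_basis)
  stat <- function(mc, me) {
    if (statistic == "icer") mc / me else nmb(me, mc, wtp)
  }
  point <- stat(mean(d_c), mean(d_e))
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
    mc <- colMeans(matrix(d_c[idx], nrow = n))
    me <- colMeans(matrix(d_e[idx], nrow = n))
    keep <- if (statistic == "icer") me != 0 else rep(TRUE, reps)
    if (!any(keep)) {
      stop_prepost("all bootstrap replicates have zero incremental ",
                   "effectiveness; the ICER cannot be bootstrapped")
    }
    vals <- stat(mc[keep], me[keep])
    alpha <- (1 - conf) / 2
    qs <- quantile(vals, c(alpha, 1 - alpha), names = FALSE)
    structure(list(statistic = statistic, measure = measure, point = point,
                   lower = qs[1], upper = qs[2], reps = reps,
                   dropped = sum(!keep), seed = seed, conf = conf),
              class = "boot_ci")
  })
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("<boot_ci> %s (%s): %.2f [%.2f, %.2f] (%d reps, %d dropped)\n",
              x$statistic, x$measure, x$point, x$lower, x$upper,
              x$reps, x$dropped))
  invisible(x)
}

#' First-order Monte Carlo PSA samples
#'
#' Simulates a hypothetical cohort of `n` patients: for each, annual
#' costs are drawn for the baseline and treatment regimens (gamma by
#' default - non-negative and right-skewed, as annual healthcare costs
#' are) and effectiveness for both regimens (normal by default, optionally
#' truncated to the measure's valid range), all independently. Each
#' simulated patient contributes one incremental pair.
#'
#' @param cost_pre,cost_post,eff_pre,eff_post Lists `list(mean =, sd =)`
#'   parameterising the four distributions.
#' @param n Number of simulated patients.
#' @param seed RNG seed.
#' @param cost_family `"gamma"` or `"normal"`.
#' @param eff_family `"normal"` or `"gamma"`.
#' @param eff_bounds Length-2 truncation bounds for effectiveness draws.
#' @return Tibble with `replicate_id`, `delta_cost`, `delta_eff`.
#' @examples
#' psa_simulate(list(mean = 11544, sd = 9137), list(mean = 14043, sd = 3822),
#'              list(mean = 0.729, sd = 0.071), list(mean = 0.867, sd = 0.039),
#'              n = 100, seed = 1)
#' @export
psa_simulate <- function(cost_pre, cost_post, eff_pre, eff_post,
                         n = 10000, seed = 1,
                         cost_family = "gamma", eff_family = "normal",
                         eff_bounds = c(-Inf, Inf)) {
  if (n < 0) stop_prepost("n must be >= 0")
  draw <- function(spec, family, lower = -Inf, upper = Inf) {
    if (is.null(spec$mean) || is.null(spec$sd) || spec$sd < 0) {
      stop_prepost("distribution needs mean and sd >= 0")
    }
    if (n == 0) return(numeric(0))
    if (spec$sd == 0) return(rep(spec$mean, n))
    u <- runif(n)
    qf <- marginal_quantile_fun(family, spec$mean, spec$sd,
                                lower = max(lower, if (family == "gamma") 0 else -Inf),
                                upper = upper)
    qf(u)
  }
  with_seed(seed, {
    cp <- draw(cost_pre, cost_family, lower = 0)
    ct <- draw(cost_post, cost_family, lower = 0)
    ep <- draw(eff_pre, eff_family, eff_bounds[1], eff_bounds[2])
    et <- draw(eff_post, eff_family, eff_bounds[1], eff_bounds[2])
    tibble::tibble(replicate_id = seq_len(n),
                   delta_cost = ct - cp,
                   delta_eff = et - ep)
  })
}

#' PSA input distributions from an observed cohort
#'
#' Summarises a paired cohort into the four (mean, sd) pairs that
#' parameterise [psa_simulate()] for a given measure and cost basis.
#'
#' @inheritParams bootstrap_icer_ci
#' @return List with `cost_pre`, `cost_post`, `eff_pre`, `eff_post` and a
#'   suggested `eff_bounds`.
#' @export
psa_inputs_from_cohort <- function(cohort, measure = "utility",
                                   cost_basis = "total",
                                   map = utility_map()) {
  measure <- match.arg(measure, effectiveness_measures)
  cb <- patient_total_costs(cohort, "baseline", cost_basis)
  ct <- patient_total_costs(cohort, "treatment", cost_basis)
  eff <- function(period) {
    act <- cohort$act_score[cohort$period == period]
    switch(measure,
      exacerbations_avoided = cohort$severe_exacerbations[cohort$period == period],
      act_points = act,
      act_rate = act_effectiveness_rate(act),
      utility = patient_utility(act, map)
    )
  }
  eb <- eff("baseline"); et <- eff("treatment")
  bounds <- switch(measure,
    exacerbations_avoided = c(0, Inf),
    act_points = c(5, 25),
    act_rate = c(0.2, 1),
    utility = c(map$utility_uncontrolled, map$utility_controlled))
  list(cost_pre = list(mean = mean(cb), sd = sd(cb)),
       cost_post = list(mean = mean(ct), sd = sd(ct)),
       eff_pre = list(mean = mean(eb), sd = sd(eb)),
       eff_post = list(mean = mean(et), sd = sd(et)),
       eff_bounds = bounds,
       # for exacerbations, effectiveness is the *reduction*, so the PSA
       # delta must be baseline minus treatment
       flip_eff = measure == "exacerbations_avoided")
}

#' Probability of cost-effectiveness at a threshold
#'
#' Fraction of PSA samples with positive net monetary benefit at `wtp`.
#'
#' @param samples Tibble from [psa_simulate()] (`delta_cost`,
#'   `delta_eff`).
#' @param wtp Willingness-to-pay threshold (> 0).
#' @return Fraction in \[0, 1\].
#' @export
prob_cost_effective <- function(samples, wtp) {
  if (nrow(samples) == 0) stop_prepost("no PSA samples")
  mean(nmb(samples$delta_eff, samples$delta_cost, wtp) > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' [prob_cost_effective()] evaluated on a grid of thresholds.
#'
#' @inheritParams prob_cost_effective
#' @param wtp_grid Increasing vector of positive thresholds.
#' @return Tibble with `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (any(wtp_grid <= 0) || is.unsorted(wtp_grid)) {
    stop_prepost("wtp_grid must be positive and sorted")
  }
  tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) prob_cost_effective(samples, w),
                         numeric(1))
  )
}

#' Fraction of PSA samples in the dominant (SE) quadrant
#'
#' More effective and less costly than the comparator.
#'
#' @inheritParams prob_cost_effective
#' @return Fraction in \[0, 1\].
#' @export
dominance_fraction <- function(samples) {
  if (nrow(samples) == 0) stop_prepost("no PSA samples")
  mean(samples$delta_eff > 0 & samples$delta_cost < 0)
}

effect_size_bands <- c(insignificant = 0.15, small = 0.40, medium = 0.75,
                       large = 1.10, very_large = 1.45, enormous = Inf)

effect_size_band <- function(d) {
  names(effect_size_bands)[findInterval(abs(d), c(effect_size_bands),
                                        left.open = FALSE) + 1L]
}

#' Cohen's d for paired pre-post samples
#'
#' `d = (mean(pre) - mean(post)) / denominator`, with the denominator set
#' by `convention`: the SD of the paired differences (`"sd_diff"`,
#' default), the pooled SD (`"pooled"`, root mean of the two variances),
#' or the baseline SD (`"baseline_sd"`). The magnitude is banded as
#' insignificant (< 0.15), small (< 0.40), medium (< 0.75), large
#' (< 1.10), very large (< 1.45) or enormous (>= 1.45). The confidence
#' interval is a percentile bootstrap over patients (paired resampling).
#'
#' @param pre,post Paired numeric vectors (n >= 2).
#' @param convention Denominator convention.
#' @param reps Bootstrap replicates for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return List of class `effect_size`: `d`, `ci_low`, `ci_high`, `band`,
#'   `convention`.
#' @examples
#' cohens_d(c(6, 5, 4), c(1, 1, 1), convention = "pooled")$d
#' @export
cohens_d <- function(pre, post,
                     convention = c("sd_diff", "pooled", "baseline_sd"),
                     reps = 2000, seed = 1, conf = 0.95) {
  convention <- match.arg(convention)
  if (length(pre) != length(post) || length(pre) < 2) {
    stop_prepost("pre and post must be paired vectors of length >= 2")
  }
  denom_fun <- switch(convention,
    sd_diff = function(p, q) sd(p - q),
    pooled = function(p, q) sqrt((var(p) + var(q)) / 2),
    baseline_sd = function(p, q) sd(p)
  )
  d_of <- function(p, q) {
    num <- mean(p) - mean(q)
    den <- denom_fun(p, q)
    if (den == 0) {
      if (num == 0) return(0)  # no change at all: no effect
      stop_prepost("zero ", convention, " denominator with a non-zero ",
                   "mean difference: effect size undefined")
    }
    num / den
  }
  d <- d_of(pre, post)
  n <- length(pre)
  ci <- with_seed(seed, {
    vals <- vapply(seq_len(reps), function(r) {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch(d_of(pre[i], post[i]), error = function(e) NA_real_)
    }, numeric(1))
    alpha <- (1 - conf) / 2
    quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  })
  structure(list(d = d, ci_low = ci[1], ci_high = ci[2],
                 band = effect_size_band(d), convention = convention),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.3f [%.3f, %.3f] (%s; %s convention)\n",
              x$d, x$ci_low, x$ci_high, x$band, x$convention))
  invisible(x)
}
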